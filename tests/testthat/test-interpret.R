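test_that("temporal profiles aggregate selectivity scores per class", {
  cfg <- tinyConfig()
  model <- modelInit(cfg, seed = 1)
  dfcs <- tinyDFCs(4, K = 7, D = 10)

  # single session: profile equals that session's score vector
  one <- dfcs[[1]]
  tr <- predictSession(model, one)$traces
  pr <- classTemporalProfile(model, list(one), classLabel(one))
  expect_equal(pr$mean_s, selectivityScores(tr[[1]]))
  pr_last <- classTemporalProfile(model, list(one), classLabel(one),
                                  trace_block = "last")
  expect_equal(pr_last$mean_s, selectivityScores(tr[[length(tr)]]))
  expect_identical(pr$n_sessions, 1L)

  # z-scored profile is standardized across windows
  prz <- classTemporalProfile(model, dfcs, 1L, zscore = TRUE)
  expect_equal(mean(prz$z), 0, tolerance = 1e-12)
  expect_equal(sd(prz$z), 1, tolerance = 1e-12)
  expect_error(classTemporalProfile(model, dfcs, 5L), "no sessions")
})

test_that("activation-curve ranking matches brute-force influence", {
  head <- headInit(3, hidden = 2, n_classes = 2, seed = 4)
  model <- modelInit(tinyConfig(D = 10L, L = 3L), seed = 4)
  model@head <- head
  set.seed(5)
  probes <- matrix(runif(20 * 3, -0.8, 0.8), 20, 3)

  # brute force: mean over probes and outputs of |phi_{j,i}(x_i)|
  nb <- nBasis(head$layer1$grid)
  brute <- sapply(1:3, function(i) {
    mean(sapply(1:2, function(j) {
      cf <- head$layer1$coef[((i - 1) * nb + 1):(i * nb), j]
      mean(abs(edgeActivation(probes[, i], head$layer1$wb[j, i], cf,
                              head$layer1$grid)))
    }))
  })
  rk <- rankActivationCurves(model, probes, top_k = 3)
  expect_identical(rk$ranking, order(brute, decreasing = TRUE))
  expect_equal(unname(rk$influence), brute[rk$ranking], tolerance = 1e-10)

  # a fully pruned input ranks last with zero influence
  head2 <- head
  head2$layer1$wb[, 2] <- 0
  head2$layer1$coef[(nb + 1):(2 * nb), ] <- 0
  model@head <- head2
  rk2 <- rankActivationCurves(model, probes, top_k = 3)
  expect_identical(rk2$ranking[3], 2L)
  expect_equal(unname(rk2$influence[3]), 0)

  # doubling a base weight doubles influence when the spline is off
  head3 <- head
  head3$layer1$coef <- head3$layer1$coef * 0
  model@head <- head3
  i1 <- rankActivationCurves(model, probes, 3)$influence
  head3$layer1$wb <- head3$layer1$wb * 2
  model@head <- head3
  i2 <- rankActivationCurves(model, probes, 3)$influence
  expect_equal(unname(i2), unname(2 * i1), tolerance = 1e-12)
  expect_warning(rankActivationCurves(model, probes, 10), "clamped")
})

test_that("attribution is exact on a linear surrogate pipeline", {
  # linear encoder (identity activation), identity Mamba, identity-base KAN
  # with splines off: the whole pipeline is linear and the Jacobian is known
  cfg <- tinyConfig(D = 10L, L = 4L)
  cfg$vae$activation <- "identity"
  cfg$head$base_activation <- "identity"
  model <- modelInit(cfg, seed = 6)
  for (l in 1:2) {
    model@mamba$params[[paste0("b", l, ".Wout")]] <-
      model@mamba$params[[paste0("b", l, ".Wout")]] * 0
  }
  model@head$layer1$coef <- model@head$layer1$coef * 0
  model@head$layer2$coef <- model@head$layer2$coef * 0
  # strip encoder hidden-layer bias contributions from the map: keep biases,
  # they only shift the logit, not the Jacobian
  W1 <- model@vae$params$enc_W1          # D x 6
  Wmu <- model@vae$params$W_mu           # 6 x 4
  Whead <- model@head$layer2$wb %*% model@head$layer1$wb   # C x L
  # logit_c = (1/K) sum_k Whead[c, ] Wmu' W1' v_k + const
  Wlin <- t(W1 %*% Wmu %*% t(Whead))     # C x D
  d <- tinyDFCs(1, K = 6, D = 10)[[1]]
  at <- gradientAttribution(model, d, 1L)
  # the per-window gradient of logit c is Wlin[c, ] / K for every window,
  # so the window-averaged attribution equals Wlin[c, ] / K
  expected <- devectorize(Wlin[2, ] / nrow(dfcVectors(d)), 5, diagonal = 0)
  expect_equal(attributionValues(at), expected, tolerance = 1e-10)
  expect_identical(nROIs(at), 5L)
  expect_error(gradientAttribution(model, d, 3L), "out of range")
})

test_that("attribution matches finite differences on the nonlinear model", {
  cfg <- tinyConfig(D = 10L, L = 4L)
  model <- modelInit(cfg, seed = 7)
  d <- tinyDFCs(1, K = 5, D = 10)[[1]]
  V <- dfcVectors(d)
  G <- dfcmamba:::modelInputGradient(model, V, 1L)
  h <- 1e-6
  for (probe in list(c(1, 3), c(4, 9), c(5, 10))) {
    Vp <- V; Vp[probe[1], probe[2]] <- V[probe[1], probe[2]] + h
    Vm <- V; Vm[probe[1], probe[2]] <- V[probe[1], probe[2]] - h
    fd <- (dfcmamba:::sessionForward(model, Vp)$logits[2] -
           dfcmamba:::sessionForward(model, Vm)$logits[2]) / (2 * h)
    expect_lt(abs(fd - G[probe[1], probe[2]]), 1e-6)
  }

  # class linearity: attribution of the logit difference is the difference
  a0 <- colMeans(dfcmamba:::modelInputGradient(model, V, 0L))
  a1 <- colMeans(dfcmamba:::modelInputGradient(model, V, 1L))
  at0 <- gradientAttribution(model, d, 0L)
  at1 <- gradientAttribution(model, d, 1L)
  expect_equal(attributionValues(at1) - attributionValues(at0),
               devectorize(a1 - a0, 5, diagonal = 0), tolerance = 1e-12)

  # zero downstream weights: zero attribution
  m0 <- model
  hp <- dfcmamba:::headParams(m0@head)
  m0@head <- dfcmamba:::headSetParams(m0@head, lapply(hp, function(x) x * 0))
  expect_true(all(attributionValues(gradientAttribution(m0, d, 1L)) == 0))
})

test_that("top-percent thresholding keeps ceil(p% of D) connections", {
  set.seed(8)
  A <- matrix(rnorm(116^2), 116)
  A <- (A + t(A)) / 2; diag(A) <- 0
  at <- new("AttributionMatrix", class_label = 0L, values = A,
            roi_names = paste0("ROI_", 1:116))
  top <- thresholdTopPercent(at, 1)
  expect_identical(nrow(top), 67L)          # ceil(0.01 * 6670)
  expect_true(all(diff(-abs(top$score)) >= 0))
  expect_identical(nrow(thresholdTopPercent(at, 100)), 6670L)

  # deterministic lexicographic tie-break at the cutoff
  B <- matrix(0, 4, 4)
  B[1, 2] <- B[2, 1] <- 0.5
  B[1, 3] <- B[3, 1] <- 0.5
  B[2, 4] <- B[4, 2] <- 0.5
  atB <- new("AttributionMatrix", class_label = 0L, values = B,
             roi_names = paste0("R", 1:4))
  top2 <- thresholdTopPercent(atB, 34)   # ceil(0.34 * 6) = 3 of the ties
  expect_identical(top2$i, c(1L, 1L, 2L))
  expect_identical(top2$j, c(2L, 3L, 4L))
})

test_that("region ranking is by node strength", {
  A <- matrix(0, 5, 5)
  A[2, 4] <- A[4, 2] <- 3
  at <- new("AttributionMatrix", class_label = 1L, values = A,
            roi_names = paste0("R", 1:5))
  rk <- regionRanking(at, 3)
  expect_setequal(rk$roi[1:2], c("R2", "R4"))
  expect_equal(rk$strength[1], 3)

  set.seed(9)
  M <- matrix(rnorm(36), 6); M <- (M + t(M)) / 2; diag(M) <- 0
  atM <- new("AttributionMatrix", class_label = 0L, values = M,
             roi_names = paste0("R", 1:6))
  rkM <- regionRanking(atM, 6)
  brute <- sort(rowSums(abs(M)), decreasing = TRUE)
  expect_equal(rkM$strength, unname(brute))
})

test_that("rescaled-input attribution can be expressed per correlation unit", {
  cfg <- tinyConfig(D = 10L, L = 4L)
  model <- modelInit(cfg, seed = 10)
  d <- tinyDFCs(1, K = 5, D = 10)[[1]]
  a_unit <- gradientAttribution(model, d, 0L)
  a_r <- gradientAttribution(model, d, 0L, per_r = TRUE)
  expect_equal(attributionValues(a_r), attributionValues(a_unit) / 2)
})
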