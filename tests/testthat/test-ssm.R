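test_that("discretization has the contracted closed forms and limits", {
  expect_equal(discretizeZoh(-1, 2, log(2))$a_bar, 0.5)
  expect_equal(discretizeZoh(-1, 2, log(2))$b_bar, 2 * log(2))
  # delta -> 0+: the state is fully carried forward
  expect_equal(discretizeZoh(-3, 1, 1e-12)$a_bar, 1, tolerance = 1e-9)
  # exact ZOH agrees with the Euler rule to first order in delta
  for (delta in c(0.01, 0.001)) {
    e <- discretizeZoh(-1, 1, delta, "euler")$b_bar
    z <- discretizeZoh(-1, 1, delta, "zoh")$b_bar
    expect_lt(abs(z - e) / abs(z), delta)
  }
})

test_that("selective parameters are softplus-positive and literal", {
  cfg <- mambaConfig(d_model = 3, d_state = 2, d_conv = 2, expand = 1,
                     n_layers = 1, dropout_p = 0)
  mam <- mambaInit(cfg, seed = 1)
  K <- 3
  u <- matrix(rnorm(K * 3), K, 3)
  z <- matrix(rnorm(K * 3), K, 3)
  # zero Delta projection: softplus(0) = log 2 everywhere
  mam$params$`b1.wdelta` <- numeric(3)
  mam$params$`b1.bdelta` <- numeric(3)
  sp <- selectiveParameters(mam, 1, u, z)
  expect_equal(sp$delta, matrix(log(2), K, 3))
  expect_true(all(sp$delta > 0))
  # very negative pre-activation: Delta -> 0+ but never 0
  mam$params$`b1.bdelta` <- rep(-40, 3)
  expect_true(all(selectiveParameters(mam, 1, u, z)$delta > 0))

  # manual check of the per-channel linear maps of the block input
  mam$params$`b1.bdelta` <- c(0.1, -0.2, 0.3)
  mam$params$`b1.wdelta` <- c(1, 0.5, -1)
  sp <- selectiveParameters(mam, 1, u, z)
  expect_equal(sp$delta[2, 3], log1p(exp(-u[2, 3] + 0.3)), tolerance = 1e-12)
  WB <- mam$params$`b1.WB`
  # column (d - 1) * d_state + n holds B[, d, n]
  expect_equal(sp$B[1, 2, 1], sum(z[1, ] * WB[, 3]), tolerance = 1e-12)
  expect_equal(sp$C[3, 1, 2],
               sum(z[3, ] * mam$params$`b1.WC`[, 2]), tolerance = 1e-12)
})

test_that("the selective scan equals the naive recurrence and its limits", {
  set.seed(21)
  for (rep in 1:4) {
    K <- sample(2:8, 1); di <- sample(1:4, 1); ds <- sample(1:3, 1)
    u <- matrix(rnorm(K * di), K, di)
    delta <- matrix(runif(K * di, 0.05, 1), K, di)
    B <- array(rnorm(K * di * ds), c(K, di, ds))
    C <- array(rnorm(K * di * ds), c(K, di, ds))
    A <- -matrix(runif(di * ds, 0.2, 2), di, ds)
    for (m in c("euler", "zoh")) {
      expect_lt(max(abs(ssmScan(u, delta, B, C, A, m) -
                        oracleScan(u, delta, B, C, A, m))), 1e-6)
    }
  }

  # a_bar ~ 1, b_bar = 1, C = 1, all-ones input: y telescopes to k
  K <- 6
  y <- ssmScan(matrix(1, K, 1), matrix(1, K, 1),
               array(1, c(K, 1, 1)), array(1, c(K, 1, 1)),
               matrix(-1e-12, 1, 1))
  expect_equal(drop(y), 1:K, tolerance = 1e-9)

  # strongly negative A forgets everything: output is memoryless
  set.seed(4)
  u <- matrix(rnorm(10), 5, 2)
  delta <- matrix(1, 5, 2)
  B <- array(rnorm(20), c(5, 2, 2)); C <- array(rnorm(20), c(5, 2, 2))
  Ainf <- matrix(-1e6, 2, 2)
  y <- ssmScan(u, delta, B, C, Ainf)
  memless <- sapply(1:2, function(d)
    sapply(1:5, function(k) sum(C[k, d, ] * B[k, d, ] * u[k, d])))
  expect_equal(y, memless, tolerance = 1e-9)
})

test_that("Mamba blocks satisfy the structural identities", {
  cfg <- mambaConfig(d_model = 4, d_state = 2, d_conv = 3, expand = 2,
                     n_layers = 1, dropout_p = 0)
  set.seed(5)
  Z <- matrix(rnorm(6 * 4), 6, 4)

  # zero output projection: pure residual
  mam <- mambaInit(cfg, seed = 2)
  mam$params$`b1.Wout` <- mam$params$`b1.Wout` * 0
  mam$params$`b1.bout` <- mam$params$`b1.bout` * 0
  expect_equal(mambaBlock(mam, 1, Z)$output, Z, tolerance = 1e-12)

  # closed gate: G = SiLU(0) = 0 kills the scan branch
  mam2 <- mambaInit(cfg, seed = 2)
  mam2$params$`b1.Wg` <- mam2$params$`b1.Wg` * 0
  mam2$params$`b1.bg` <- mam2$params$`b1.bg` * 0
  expect_equal(mambaBlock(mam2, 1, Z)$output, Z, tolerance = 1e-12)

  # recorded time steps are strictly positive
  mam3 <- mambaInit(cfg, seed = 3)
  out <- mambaBlock(mam3, 1, Z)
  expect_true(all(traceDelta(out$trace) > 0))

  # causality: perturbing window k' leaves outputs before k' unchanged
  kprime <- 4
  Zp <- Z; Zp[kprime, ] <- Zp[kprime, ] + rnorm(4)
  o1 <- mambaBlock(mam3, 1, Z)$output
  o2 <- mambaBlock(mam3, 1, Zp)$output
  expect_equal(o1[1:(kprime - 1), ], o2[1:(kprime - 1), ], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(o1[kprime, ], o2[kprime, ])))

  # full block against a step-by-step reference composition
  bp <- dfcmamba:::blockParams(mam3, 1)
  zc <- Z - rowMeans(Z)
  zn <- zc / sqrt(rowMeans(zc^2) + 1e-5)
  zp <- t(t(zn) * bp$ln_g + bp$ln_b)
  X <- t(t(zp %*% bp$Wx) + bp$bx)
  G <- dfcmamba:::silu(t(t(zp %*% bp$Wg) + bp$bg))
  # causal depthwise conv, literal loop
  u_pre <- matrix(0, 6, 8)
  for (k in 1:6) for (d in 1:8) {
    acc <- bp$bconv[d]
    for (j in 1:3) {
      kk <- k - 3 + j
      if (kk >= 1) acc <- acc + bp$Wconv[d, j] * X[kk, d]
    }
    u_pre[k, d] <- acc
  }
  u <- dfcmamba:::silu(u_pre)
  sp <- selectiveParameters(mam3, 1, u, zp)
  A <- -exp(t(bp$Alog))
  y <- ssmScan(u, sp$delta, sp$B, sp$C, A)
  ref <- Z + t(t((y * G) %*% bp$Wout) + bp$bout)
  expect_equal(mambaBlock(mam3, 1, Z)$output, ref, tolerance = 1e-8)
})

test_that("temporal encoding mean-pools the final block output", {
  cfg <- mambaConfig(d_model = 3, d_state = 2, d_conv = 2, expand = 2,
                     n_layers = 2, dropout_p = 0)
  mam <- mambaInit(cfg, seed = 7)
  # identity blocks: context is the plain row mean
  for (l in 1:2) {
    mam$params[[paste0("b", l, ".Wout")]] <-
      mam$params[[paste0("b", l, ".Wout")]] * 0
  }
  row <- c(0.3, -1, 2)
  Zc <- matrix(rep(row, each = 5), 5, 3)
  et <- encodeTemporal(mam, Zc)
  expect_equal(et$context, row, tolerance = 1e-12)
  set.seed(8)
  Zr <- matrix(rnorm(15), 5, 3)
  expect_equal(encodeTemporal(mam, Zr)$context, colMeans(Zr),
               tolerance = 1e-7)

  # order sensitivity on a planted trend (non-identity blocks)
  mam2 <- mambaInit(cfg, seed = 9)
  # trend in one channel only (a common shift across channels would be
  # absorbed by the per-window layer norm)
  Zt <- matrix(0.2, 5, 3)
  Zt[, 1] <- seq(-2, 2, length.out = 5)
  c1 <- encodeTemporal(mam2, Zt)$context
  c2 <- encodeTemporal(mam2, Zt[5:1, ])$context
  expect_gt(max(abs(c1 - c2)), 1e-8)
  expect_length(c1, 3)
  expect_length(encodeTemporal(mam2, Zt)$traces, 2)
})

test_that("selectivity scores average the trace across channels", {
  tr <- new("SelectivityTrace", delta = matrix(2.5, 4, 3), block = 1L)
  expect_equal(selectivityScores(tr), rep(2.5, 4))
  set.seed(10)
  d <- matrix(runif(12, 0.1, 1), 4, 3)
  tr2 <- new("SelectivityTrace", delta = d, block = 1L)
  expect_equal(selectivityScores(tr2), apply(d, 1, mean))
  d2 <- d; d2[2, ] <- 2 * d[2, ]
  expect_equal(selectivityScores(new("SelectivityTrace", delta = d2,
                                     block = 1L))[2],
               2 * selectivityScores(tr2)[2])
})

test_that("stack gradients match finite differences", {
  cfg <- mambaConfig(d_model = 3, d_state = 2, d_conv = 2, expand = 2,
                     n_layers = 2, dropout_p = 0)
  mam <- mambaInit(cfg, seed = 4)
  set.seed(5)
  Z <- matrix(rnorm(5 * 3), 5, 3)
  lossM <- function() sum(dfcmamba:::mambaStackForward(mam, Z)$context^2)
  fw <- dfcmamba:::mambaStackForward(mam, Z)
  bb <- dfcmamba:::mambaStackBackward(mam, fw, 2 * fw$context, nrow(Z))
  for (nm in c("b1.Wconv", "b1.WB", "b1.Alog", "b2.wdelta", "b2.ln_g")) {
    gnum <- finiteDiff(function() mam$params[[nm]],
                       function(p) mam$params[[nm]] <<- p, lossM)
    expect_lt(max(abs(gnum - bb$grads[[nm]])) / (1e-6 + max(abs(gnum))), 1e-3)
  }
  gnumZ <- finiteDiff(function() Z, function(p) Z <<- p, lossM)
  expect_lt(max(abs(gnumZ - bb$dZ)), 1e-6)
})
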