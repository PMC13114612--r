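test_that("the B-spline basis has G + p members forming a partition of unity", {
  g <- splineGrid(-1, 1, 5, 3)
  expect_identical(nBasis(g), 8L)
  pts <- seq(-1, 1, length.out = 100)
  B <- bsplineBasis(pts, g)
  expect_identical(ncol(B), 8L)
  expect_true(all(B >= 0))
  expect_lt(max(abs(rowSums(B) - 1)), 1e-10)
  # midpoint explicitly
  expect_lt(abs(sum(bsplineBasis(0, g)) - 1), 1e-10)
})

test_that("basis values match an independent textbook recursion", {
  g <- splineGrid(-0.5, 2, 4, 3)
  probes <- seq(-0.4, 1.9, length.out = 20)
  B <- bsplineBasis(probes, g)
  for (pi in seq_along(probes)) {
    for (i in seq_len(nBasis(g))) {
      expect_lt(abs(B[pi, i] - oracleBspline(probes[pi], i, g$p, g$knots)),
                1e-10)
    }
  }
  # derivative against central finite differences of the basis itself
  D <- bsplineBasis(probes, g, derivative = TRUE)
  h <- 1e-6
  Dn <- (bsplineBasis(probes + h, g) - bsplineBasis(probes - h, g)) / (2 * h)
  expect_lt(max(abs(D - Dn)), 1e-5)
})

test_that("edge activations combine the SiLU base and the spline", {
  g <- splineGrid()
  x <- seq(-0.95, 0.95, length.out = 9)
  # spline off: phi = SiLU, phi(0) = 0
  expect_equal(edgeActivation(x, 1, numeric(8), g), x / (1 + exp(-x)))
  expect_equal(edgeActivation(0, 1, numeric(8), g), 0)
  # base off, unit coefficients: partition of unity gives phi = 1 inside
  expect_equal(edgeActivation(x, 0, rep(1, 8), g), rep(1, 9),
               tolerance = 1e-10)
  # random case against explicit evaluation
  set.seed(2)
  cf <- rnorm(8)
  phi <- edgeActivation(0.37, 1.5, cf, g)
  ref <- 1.5 * 0.37 / (1 + exp(-0.37)) +
    sum(cf * sapply(1:8, function(i) oracleBspline(0.37, i, g$p, g$knots)))
  expect_lt(abs(phi - ref), 1e-10)
})

test_that("KAN layers sum independent edges and detect dead edges", {
  g <- splineGrid()
  l11 <- kanLayerInit(1, 1, g, seed = 3)
  x <- 0.4
  nb <- nBasis(g)
  expect_equal(kanLayer(l11, x),
               edgeActivation(x, l11$wb[1, 1], l11$coef[, 1], g))

  # two inputs, spline off: closed form
  l2 <- kanLayerInit(2, 1, g, seed = 4)
  l2$coef <- l2$coef * 0
  l2$wb <- matrix(c(2, -3), 1, 2)
  x2 <- c(0.3, -0.6)
  silu <- function(v) v / (1 + exp(-v))
  expect_equal(drop(kanLayer(l2, x2)), 2 * silu(0.3) - 3 * silu(-0.6),
               tolerance = 1e-12)

  # zeroing one input's weights removes its influence entirely
  l3 <- kanLayerInit(2, 2, g, seed = 5)
  l3$wb[, 2] <- 0
  l3$coef[(nb + 1):(2 * nb), ] <- 0
  a <- kanLayer(l3, c(0.2, 0.9))
  b <- kanLayer(l3, c(0.2, -0.8))
  expect_equal(a, b, tolerance = 1e-12)
  expect_error(kanLayer(l3, c(1, 2, 3)), "does not match")
})

test_that("with all spline coefficients zero the KAN is a SiLU additive model", {
  head <- headInit(3, hidden = 2, n_classes = 2, seed = 6)
  head$layer1$coef <- head$layer1$coef * 0
  head$layer2$coef <- head$layer2$coef * 0
  x <- c(0.1, -0.4, 0.8)
  silu <- function(v) v / (1 + exp(-v))
  h <- as.vector(head$layer1$wb %*% silu(x))
  ref <- as.vector(head$layer2$wb %*% silu(h))
  expect_equal(classify(head, x)$logits, ref, tolerance = 1e-12)
})

test_that("classification is a deterministic softmax over the two KAN layers", {
  head <- headInit(4, hidden = 3, n_classes = 4, seed = 7)
  x <- c(0.5, -0.5, 0.1, 0.9)
  out <- classify(head, x)
  expect_length(out$probs, 4)
  expect_equal(sum(out$probs), 1, tolerance = 1e-9)
  expect_true(all(out$probs > 0 & out$probs < 1))
  expect_identical(classify(head, x)$logits, out$logits)
  # equal logits give the uniform distribution
  expect_equal(dfcmamba:::softmaxRows(matrix(3, 1, 4))[1, ], rep(0.25, 4))
})

test_that("grid refresh preserves the spline where it is representable", {
  g <- splineGrid(-1, 1, 5, 3)
  layer <- kanLayerInit(2, 2, g, seed = 8)
  # constant spline part: representable exactly on any grid
  layer$coef <- matrix(0.7, nrow(layer$coef), ncol(layer$coef))

  # same-range refresh: domain (almost) unchanged, curves preserved
  act <- seq(-1, 1, length.out = 50)
  l2 <- updateGrid(layer, act)
  probes <- seq(-0.9, 0.9, length.out = 40)
  for (j in 1:2) for (i in 1:2) {
    nb <- nBasis(g)
    before <- edgeActivation(probes, layer$wb[j, i],
                             layer$coef[((i - 1) * nb + 1):(i * nb), j], g)
    after <- edgeActivation(probes, l2$wb[j, i],
                            l2$coef[((i - 1) * nb + 1):(i * nb), j], l2$grid)
    expect_lt(max(abs(before - after)), 1e-3)
  }

  # domain doubled: old probe points unchanged within refit tolerance
  l3 <- updateGrid(layer, c(-2, 2))
  expect_equal(l3$grid$x_min, -2 - 0.04)
  nb <- nBasis(g)
  before <- edgeActivation(probes, layer$wb[1, 1], layer$coef[1:nb, 1], g)
  after <- edgeActivation(probes, l3$wb[1, 1], l3$coef[1:nb, 1], l3$grid)
  expect_lt(max(abs(before - after)), 1e-3)

  # degenerate sample: warn, keep grid
  expect_warning(l4 <- updateGrid(layer, rep(0.2, 10)), "degenerate")
  expect_identical(l4$grid, layer$grid)
})

test_that("curve extraction reads parameters directly", {
  g <- splineGrid()
  layer <- kanLayerInit(2, 2, g, seed = 9)
  layer$coef <- layer$coef * 0
  cv <- extractCurve(layer, 1, 1, n_points = 50)
  expect_equal(cv$phi, cv$x / (1 + exp(-cv$x)) * layer$wb[1, 1],
               tolerance = 1e-12)
  expect_identical(cv$monotonicity, "increasing")

  # hand-built increasing spline: ramped coefficients
  nb <- nBasis(g)
  layer$wb[2, 1] <- 0
  layer$coef[1:nb, 2] <- seq(0, 2, length.out = nb)
  expect_identical(extractCurve(layer, 2, 1)$monotonicity, "increasing")

  # pruned edge: flat zero curve
  layer$wb[1, 2] <- 0
  cv0 <- extractCurve(layer, 1, 2)
  expect_true(all(abs(cv0$phi) < 1e-12))
  expect_error(extractCurve(layer, 3, 1), "out of range")
})

test_that("KAN layer gradients match finite differences", {
  layer <- kanLayerInit(3, 2, splineGrid(), seed = 10)
  set.seed(11)
  X <- matrix(runif(8 * 3, -0.9, 0.9), 8, 3)
  lossK <- function() sum(kanLayer(layer, X)^2)
  fw <- dfcmamba:::kanLayerForwardCore(layer, X)
  bk <- dfcmamba:::kanLayerBackwardCore(layer, fw, 2 * fw$Y)
  for (nm in c("wb", "coef")) {
    gnum <- finiteDiff(function() layer[[nm]],
                       function(p) layer[[nm]] <<- p, lossK)
    expect_lt(max(abs(gnum - bk[[nm]])) / (1e-8 + max(abs(gnum))), 1e-4)
  }
  gX <- finiteDiff(function() X, function(p) X <<- p, lossK)
  expect_lt(max(abs(gX - bk$dX)), 1e-6)
})

test_that("parameter counts itemize spline coefficients and base weights", {
  cfg <- tinyConfig()
  model <- modelInit(cfg, seed = 1)
  pc <- parameterCount(model)
  expect_true(all(c("vae", "mamba", "kan spline coefficients",
                    "kan base weights") %in% pc$component))
  nb <- cfg$head$grid_size + cfg$head$spline_order
  n_edges <- cfg$vae$latent_dim * cfg$head$hidden +
    cfg$head$hidden * cfg$head$n_classes
  expect_identical(pc$n_parameters[pc$component == "kan spline coefficients"],
                   as.integer(n_edges * nb))
  expect_identical(pc$n_parameters[pc$component == "kan base weights"],
                   as.integer(n_edges))
})
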