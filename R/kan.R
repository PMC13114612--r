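# Kolmogorov-Arnold classifier head: cubic B-spline edge activations with a
# scaled SiLU residual term, summed at nodes. Spline coefficients are stored
# as a ((G+p) * n_in) x n_out matrix (basis index fastest within each input
# block) so the layer forward is two matrix products.

#' Uniform B-spline grid
#'
#' A uniform knot vector with `G` intervals of degree-`p` splines over
#' `[x_min, x_max]`, extended by `p` knots on each side (G + 2p + 1 knots in
#' total), giving `G + p` basis functions.
#'
#' @param x_min,x_max domain bounds (default `[-1, 1]`).
#' @param G number of grid intervals (default 5).
#' @param p spline degree (default 3, cubic).
#' @return A list with class `"SplineGrid"`.
#' @examples
#' g <- splineGrid()
#' nBasis(g)  # G + p = 8
#' @export
splineGrid <- function(x_min = -1, x_max = 1, G = 5L, p = 3L) {
  stopifnot(x_min < x_max, G >= 1L, p >= 1L)
  h <- (x_max - x_min) / G
  knots <- x_min + h * seq(-p, G + p)
  structure(list(x_min = x_min, x_max = x_max, G = as.integer(G),
                 p = as.integer(p), h = h, knots = knots),
            class = "SplineGrid")
}

#' @rdname splineGrid
#' @param grid a `SplineGrid`.
#' @export
nBasis <- function(grid) grid$G + grid$p

#' Evaluate all B-spline basis functions
#'
#' Cox-de Boor recursion over the uniform extended knot vector, vectorized
#' over evaluation points. Inside `[x_min, x_max]` the `G + p` values are
#' nonnegative and sum to one (partition of unity); outside the extended
#' support they decay to zero. The right domain endpoint is included by
#' closure of the last interior interval.
#'
#' @param x numeric vector of evaluation points.
#' @param grid a [splineGrid()].
#' @param derivative if `TRUE`, return first derivatives of the basis
#'   functions instead of values.
#' @return `length(x)` x `(G + p)` matrix.
#' @export
bsplineBasis <- function(x, grid, derivative = FALSE) {
  kn <- grid$knots
  m <- length(kn)
  n_int <- m - 1L
  # degree-0 indicators: locate the half-open interval, closing the last
  # in-domain interval at x_max
  pos <- floor((x - kn[1L]) / grid$h)
  at_max <- x >= grid$x_max & x <= grid$x_max
  pos[at_max] <- grid$p + grid$G - 1L
  valid <- pos >= 0 & pos <= n_int - 1L & is.finite(x)
  B <- matrix(0, length(x), n_int)
  if (any(valid))
    B[cbind(which(valid), pos[valid] + 1L)] <- 1
  deg_target <- if (derivative) grid$p - 1L else grid$p
  for (d in seq_len(deg_target)) {
    ncols <- n_int - d
    Bn <- matrix(0, length(x), ncols)
    for (i in seq_len(ncols)) {
      left <- (x - kn[i]) / (kn[i + d] - kn[i])
      right <- (kn[i + d + 1L] - x) / (kn[i + d + 1L] - kn[i + 1L])
      Bn[, i] <- left * B[, i] + right * B[, i + 1L]
    }
    B <- Bn
  }
  if (!derivative) return(B)
  # d/dx B_{i,p} = p * (B_{i,p-1}/(t_{i+p}-t_i) - B_{i+1,p-1}/(t_{i+p+1}-t_{i+1}))
  p <- grid$p
  ncols <- m - 1L - p
  D <- matrix(0, length(x), ncols)
  for (i in seq_len(ncols)) {
    D[, i] <- p * (B[, i] / (kn[i + p] - kn[i]) -
                   B[, i + 1L] / (kn[i + p + 1L] - kn[i + 1L]))
  }
  D
}

baseFun <- function(x, base_activation) {
  if (base_activation == "silu") silu(x) else x
}
baseFunGrad <- function(x, base_activation) {
  if (base_activation == "silu") siluGrad(x) else x * 0 + 1
}

#' Evaluate one edge activation
#'
#' `phi(x) = w_b * SiLU(x) + sum_i c_i * B_i(x)`: a scaled residual SiLU
#' plus a learnable B-spline.
#'
#' @param x numeric vector of inputs.
#' @param w_b scalar base weight.
#' @param coeffs numeric vector of `G + p` spline coefficients.
#' @param grid a [splineGrid()].
#' @param base_activation `"silu"` (default) or `"identity"`.
#' @return Numeric vector `phi(x)`.
#' @export
edgeActivation <- function(x, w_b, coeffs, grid, base_activation = "silu") {
  drop(w_b * baseFun(x, base_activation) + bsplineBasis(x, grid) %*% coeffs)
}

#' Initialize a KAN layer
#'
#' Base weights start at 1 and spline coefficients at N(0, 0.1^2), so the
#' layer begins as a SiLU-weighted additive model with a small random
#' spline perturbation (which also breaks the symmetry between output
#' units).
#'
#' @param n_in,n_out layer widths.
#' @param grid shared [splineGrid()] for all edges of the layer.
#' @param seed RNG seed.
#' @param base_activation `"silu"` (default) or `"identity"`.
#' @return List with `n_in`, `n_out`, `grid`, `base_activation`, `wb`
#'   (n_out x n_in) and `coef` (((G+p) * n_in) x n_out).
#' @export
kanLayerInit <- function(n_in, n_out, grid = splineGrid(), seed = 0L,
                         base_activation = c("silu", "identity")) {
  base_activation <- match.arg(base_activation)
  set.seed(deriveSeed(seed, "kan-layer", n_in, n_out))
  nb <- nBasis(grid)
  list(n_in = as.integer(n_in), n_out = as.integer(n_out), grid = grid,
       base_activation = base_activation,
       wb = matrix(1, n_out, n_in),
       coef = matrix(stats::rnorm(nb * n_in * n_out, 0, 0.1),
                     nb * n_in, n_out))
}

# basis design of a whole input batch: n x (nb * n_in), input blocks of nb.
# One vectorized basis evaluation over all entries, then a reshape.
kanDesign <- function(X, grid, derivative = FALSE) {
  n <- nrow(X); n_in <- ncol(X)
  nb <- nBasis(grid)
  B <- bsplineBasis(as.vector(X), grid, derivative)  # (n * n_in) x nb
  matrix(aperm(array(B, c(n, n_in, nb)), c(1L, 3L, 2L)), n, nb * n_in)
}

kanLayerForwardCore <- function(layer, X) {
  Phi <- kanDesign(X, layer$grid)
  Y <- baseFun(X, layer$base_activation) %*% t(layer$wb) + Phi %*% layer$coef
  list(Y = Y, Phi = Phi, X = X)
}

# dY -> parameter grads and input grad
kanLayerBackwardCore <- function(layer, cache, dY) {
  nb <- nBasis(layer$grid)
  dwb <- crossprod(dY, baseFun(cache$X, layer$base_activation))
  dcoef <- crossprod(cache$Phi, dY)
  dX <- (dY %*% layer$wb) * baseFunGrad(cache$X, layer$base_activation)
  PhiD <- kanDesign(cache$X, layer$grid, derivative = TRUE)
  S <- (dY %*% t(layer$coef)) * PhiD
  for (i in seq_len(layer$n_in)) {
    cols <- ((i - 1L) * nb + 1L):(i * nb)
    dX[, i] <- dX[, i] + rowSums(S[, cols, drop = FALSE])
  }
  list(wb = dwb, coef = dcoef, dX = dX)
}

#' Apply a KAN layer
#'
#' `y_j = sum_i phi_{j,i}(x_i)`: each output unit sums its own independent
#' edge activations of the inputs; no parameters are shared between edges.
#'
#' @param layer a [kanLayerInit()] container.
#' @param x input vector of length `n_in` or an n x n_in matrix.
#' @return Output vector of length `n_out` (or n x n_out matrix).
#' @export
kanLayer <- function(layer, x) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  if (ncol(X) != layer$n_in)
    stop(sprintf("input width %d does not match n_in %d", ncol(X), layer$n_in))
  Y <- kanLayerForwardCore(layer, X)$Y
  if (is.matrix(x)) Y else Y[1L, ]
}

#' Refresh a KAN layer's grid to span observed activations
#'
#' Sets the new domain to the range of the activation sample (with a
#' relative margin) and refits the spline coefficients of every edge by
#' least squares so that the refitted spline matches the old one on a dense
#' probe grid over the old domain. A degenerate sample (zero range) leaves
#' the layer untouched with a warning.
#'
#' @param layer a [kanLayerInit()] container.
#' @param activations numeric sample of this layer's inputs (vector or
#'   matrix).
#' @param margin relative margin added on both sides (default 0.01).
#' @param n_probe number of probe points for the least-squares refit.
#' @return The updated layer.
#' @export
updateGrid <- function(layer, activations, margin = 0.01, n_probe = 200L) {
  act <- as.numeric(activations)
  if (length(act) == 0L) stop("empty activation sample")
  lo <- min(act); hi <- max(act)
  if (lo == hi) {
    warning("degenerate activation range; grid kept unchanged")
    return(layer)
  }
  pad <- margin * (hi - lo)
  new_grid <- splineGrid(lo - pad, hi + pad, layer$grid$G, layer$grid$p)
  # probe over the new domain: there the refit design is always well
  # conditioned, and it is where future inputs live; when the domain grows
  # (the usual case) the probes cover the old domain as well. Targets are
  # the old spline with constant (clamped) extrapolation beyond its domain,
  # so the refit reproduces in-domain behavior instead of chasing the
  # basis decay outside it.
  probes <- seq(new_grid$x_min, new_grid$x_max, length.out = n_probe)
  clamped <- pmin(pmax(probes, layer$grid$x_min), layer$grid$x_max)
  Phi_old <- bsplineBasis(clamped, layer$grid)
  Phi_new <- bsplineBasis(probes, new_grid)
  nb <- nBasis(layer$grid)
  # targets for all edges at once: coef blocks share the per-input design
  Cold <- matrix(layer$coef, nb)            # nb x (n_in * n_out)
  Targets <- Phi_old %*% Cold
  Cnew <- qr.coef(qr(Phi_new), Targets)
  Cnew[is.na(Cnew)] <- 0
  layer$coef <- matrix(Cnew, nb * layer$n_in, layer$n_out)
  layer$grid <- new_grid
  layer
}

#' Sample one edge activation curve
#'
#' Reads `phi_{j,i}` of a layer directly from its parameters (no input data
#' required) on a uniform grid over the spline domain, and reports whether
#' the sampled curve is monotone.
#'
#' @param layer a [kanLayerInit()] container.
#' @param j output index (1-based).
#' @param i input index (1-based).
#' @param n_points number of samples (default 100).
#' @return List with `x`, `phi`, and `monotonicity` (`"increasing"`,
#'   `"decreasing"` or `"none"`).
#' @export
extractCurve <- function(layer, j, i, n_points = 100L) {
  if (j < 1L || j > layer$n_out || i < 1L || i > layer$n_in)
    stop("edge index out of range")
  nb <- nBasis(layer$grid)
  x <- seq(layer$grid$x_min, layer$grid$x_max, length.out = n_points)
  cf <- layer$coef[((i - 1L) * nb + 1L):(i * nb), j]
  phi <- edgeActivation(x, layer$wb[j, i], cf, layer$grid,
                        layer$base_activation)
  d <- diff(phi)
  tol <- 1e-12 + 1e-9 * max(abs(phi))
  mono <- if (all(d >= -tol)) "increasing" else if (all(d <= tol)) "decreasing" else "none"
  list(x = x, phi = phi, monotonicity = mono)
}

# ---- classifier heads -------------------------------------------------------

#' Initialize the classifier head
#'
#' The default is a two-layer KAN (`n_in -> hidden -> n_classes`) with a
#' shared grid per layer; `type = "mlp"` substitutes a standard two-layer
#' ReLU MLP of the same widths (the ablation head).
#'
#' @param n_in input width (the temporal context dimension).
#' @param hidden hidden width (default 64).
#' @param n_classes number of classes C.
#' @param grid_size,spline_order B-spline grid parameters G and p.
#' @param seed RNG seed.
#' @param type `"kan"` (default) or `"mlp"`.
#' @param base_activation base term of KAN edges, `"silu"` (default) or
#'   `"identity"`.
#' @return A head container (list) with `type` and layer parameters.
#' @export
headInit <- function(n_in, hidden = 64L, n_classes, grid_size = 5L,
                     spline_order = 3L, seed = 0L,
                     type = c("kan", "mlp"),
                     base_activation = c("silu", "identity")) {
  type <- match.arg(type)
  base_activation <- match.arg(base_activation)
  if (type == "kan") {
    g <- function() splineGrid(-1, 1, grid_size, spline_order)
    list(type = "kan", n_in = as.integer(n_in), hidden = as.integer(hidden),
         n_classes = as.integer(n_classes),
         layer1 = kanLayerInit(n_in, hidden, g(), deriveSeed(seed, "h1"),
                               base_activation),
         layer2 = kanLayerInit(hidden, n_classes, g(), deriveSeed(seed, "h2"),
                               base_activation))
  } else {
    set.seed(deriveSeed(seed, "mlp-head"))
    list(type = "mlp", n_in = as.integer(n_in), hidden = as.integer(hidden),
         n_classes = as.integer(n_classes),
         W1 = initMatrix(n_in, hidden), b1 = numeric(hidden),
         W2 = initMatrix(hidden, n_classes), b2 = numeric(n_classes))
  }
}

# head parameters as a flat named list (for Adam)
headParams <- function(head) {
  if (head$type == "kan") {
    list(`l1.wb` = head$layer1$wb, `l1.coef` = head$layer1$coef,
         `l2.wb` = head$layer2$wb, `l2.coef` = head$layer2$coef)
  } else {
    list(W1 = head$W1, b1 = head$b1, W2 = head$W2, b2 = head$b2)
  }
}

headSetParams <- function(head, p) {
  if (head$type == "kan") {
    head$layer1$wb <- p$`l1.wb`; head$layer1$coef <- p$`l1.coef`
    head$layer2$wb <- p$`l2.wb`; head$layer2$coef <- p$`l2.coef`
  } else {
    head$W1 <- p$W1; head$b1 <- p$b1; head$W2 <- p$W2; head$b2 <- p$b2
  }
  head
}

headForward <- function(head, X) {
  if (head$type == "kan") {
    fw1 <- kanLayerForwardCore(head$layer1, X)
    fw2 <- kanLayerForwardCore(head$layer2, fw1$Y)
    list(logits = fw2$Y, cache = list(fw1 = fw1, fw2 = fw2))
  } else {
    pre1 <- sweep(X %*% head$W1, 2L, head$b1, "+")
    H <- relu(pre1)
    logits <- sweep(H %*% head$W2, 2L, head$b2, "+")
    list(logits = logits, cache = list(X = X, pre1 = pre1, H = H))
  }
}

headBackward <- function(head, cache, dLogits) {
  if (head$type == "kan") {
    b2 <- kanLayerBackwardCore(head$layer2, cache$fw2, dLogits)
    b1 <- kanLayerBackwardCore(head$layer1, cache$fw1, b2$dX)
    list(grads = list(`l1.wb` = b1$wb, `l1.coef` = b1$coef,
                      `l2.wb` = b2$wb, `l2.coef` = b2$coef),
         dX = b1$dX)
  } else {
    dH <- tcrossprod(dLogits, head$W2)
    gW2 <- crossprod(cache$H, dLogits)
    gb2 <- colSums(dLogits)
    dpre1 <- dH * (cache$pre1 > 0)
    gW1 <- crossprod(cache$X, dpre1)
    gb1 <- colSums(dpre1)
    list(grads = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2),
         dX = tcrossprod(dpre1, head$W1))
  }
}

#' Classify a temporal context vector
#'
#' Runs the two-layer head on one or more context vectors and returns
#' logits and softmax probabilities (probabilities computed only here, at
#' evaluation; training consumes the logits through the cross-entropy op).
#'
#' @param head a [headInit()] container.
#' @param context numeric vector of length `n_in` or an n x n_in matrix.
#' @return List with `logits` and `probs` (rows sum to 1).
#' @export
classify <- function(head, context) {
  X <- if (is.matrix(context)) context else matrix(context, nrow = 1L)
  if (ncol(X) != head$n_in)
    stop(sprintf("context width %d does not match head input %d",
                 ncol(X), head$n_in))
  logits <- headForward(head, X)$logits
  probs <- softmaxRows(logits)
  if (!is.matrix(context)) {
    logits <- logits[1L, ]; probs <- probs[1L, ]
  }
  list(logits = logits, probs = probs)
}

#' Itemized parameter counts
#'
#' Counts learnable parameters per component and, for KAN layers, itemizes
#' spline coefficients (`(G + p)` per edge) separately from the per-edge
#' base weights, which are counted in their own row.
#'
#' @param model a [DFCModel-class].
#' @return A data.frame with columns `component` and `n_parameters`.
#' @export
parameterCount <- function(model) {
  cnt <- function(pl) sum(vapply(pl, length, integer(1)))
  rows <- data.frame(component = "vae", n_parameters = cnt(model@vae$params))
  if (length(model@mamba))
    rows <- rbind(rows, data.frame(component = "mamba",
                                   n_parameters = cnt(model@mamba$params)))
  hp <- headParams(model@head)
  if (model@head$type == "kan") {
    rows <- rbind(rows,
      data.frame(component = "kan spline coefficients",
                 n_parameters = length(hp$`l1.coef`) + length(hp$`l2.coef`)),
      data.frame(component = "kan base weights",
                 n_parameters = length(hp$`l1.wb`) + length(hp$`l2.wb`)))
  } else {
    rows <- rbind(rows, data.frame(component = "mlp head",
                                   n_parameters = cnt(hp)))
  }
  rows
}
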