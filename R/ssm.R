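# Selective state-space (S6 / Mamba) temporal encoder.
#
# Internal convention: per-window channel quantities are K x d_inner matrices;
# per-channel state quantities are stored d_state x d_inner (state index
# fastest), so a K x (d_state * d_inner) matrix row flattens one time step.
# Public array interfaces use the more natural K x d_inner x d_state layout.

#' Mamba stack configuration
#'
#' @param d_model model width (latent dimension fed in; 128 at full scale).
#' @param d_state internal SSM state dimension per channel (default 16).
#' @param d_conv causal depthwise convolution kernel width (default 4).
#' @param expand expansion factor E; `d_inner = expand * d_model` (default 2).
#' @param n_layers number of stacked blocks (default 2).
#' @param dropout_p dropout probability applied after the depthwise
#'   convolution in training mode (default 0.15).
#' @param discretization `"euler"` (the simplified per-channel rule
#'   `Abar = exp(Delta * A)`, `Bbar = Delta * B`; default) or `"zoh"` (exact
#'   zero-order hold `Bbar = (Abar - 1) / A * B`); the two agree to first
#'   order in `Delta`.
#' @param bc_source where the input-dependent B and C projections read
#'   from: `"block_input"` (the layer-normalized block input; default) or
#'   `"conv_output"` (the post-convolution activation, as in the original
#'   S6 formulation).
#' @return A named list of settings.
#' @export
mambaConfig <- function(d_model, d_state = 16L, d_conv = 4L, expand = 2L,
                        n_layers = 2L, dropout_p = 0.15,
                        discretization = c("euler", "zoh"),
                        bc_source = c("block_input", "conv_output")) {
  discretization <- match.arg(discretization)
  bc_source <- match.arg(bc_source)
  stopifnot(d_model >= 1L, d_state >= 1L, d_conv >= 1L, expand >= 1L,
            n_layers >= 1L, dropout_p >= 0, dropout_p < 1)
  list(d_model = as.integer(d_model), d_state = as.integer(d_state),
       d_conv = as.integer(d_conv), expand = as.integer(expand),
       d_inner = as.integer(expand * d_model), n_layers = as.integer(n_layers),
       dropout_p = dropout_p, discretization = discretization,
       bc_source = bc_source)
}

#' Initialize a stack of Mamba blocks
#'
#' Parameters per block: input and gate projections, per-channel causal
#' depthwise convolution kernels, the selective projections for Delta
#' (per-channel scalar affine of the post-convolution activation, softplus
#' output) and B/C (per-channel linear maps of the block input), the
#' negative-real diagonal state matrix A (stored as `log(-A)`, initialized
#' `A[d, n] = -(n)`, n = 1..d_state, the standard real-diagonal
#' simplification of HiPPO-style initialization), output projection and
#' layer-norm scale/shift. The Delta bias is initialized so that
#' `softplus(bias)` is uniform in `[0.001, 0.1]`.
#'
#' @param cfg a [mambaConfig()] list.
#' @param seed integer seed for initialization.
#' @return List with `cfg` and flat parameter list `params` (names prefixed
#'   by block, e.g. `"b1.Wx"`).
#' @export
mambaInit <- function(cfg, seed = 0L) {
  set.seed(deriveSeed(seed, "mamba-init"))
  p <- list()
  dm <- cfg$d_model; di <- cfg$d_inner; ds <- cfg$d_state
  src_dim <- if (cfg$bc_source == "block_input") dm else di
  for (l in seq_len(cfg$n_layers)) {
    pre <- paste0("b", l, ".")
    p[[paste0(pre, "Wx")]] <- initMatrix(dm, di)
    p[[paste0(pre, "bx")]] <- numeric(di)
    p[[paste0(pre, "Wg")]] <- initMatrix(dm, di)
    p[[paste0(pre, "bg")]] <- numeric(di)
    p[[paste0(pre, "Wconv")]] <- matrix(stats::runif(di * cfg$d_conv,
                                                     -1, 1) / sqrt(cfg$d_conv),
                                        di, cfg$d_conv)
    p[[paste0(pre, "bconv")]] <- numeric(di)
    p[[paste0(pre, "wdelta")]] <- stats::runif(di, -1, 1) / sqrt(di)
    dt <- stats::runif(di, 0.001, 0.1)
    p[[paste0(pre, "bdelta")]] <- log(expm1(dt))
    p[[paste0(pre, "WB")]] <- initMatrix(src_dim, di * ds) / sqrt(ds)
    p[[paste0(pre, "WC")]] <- initMatrix(src_dim, di * ds) / sqrt(ds)
    p[[paste0(pre, "Alog")]] <- matrix(log(rep(seq_len(ds), di)), ds, di)
    p[[paste0(pre, "Wout")]] <- initMatrix(di, dm)
    p[[paste0(pre, "bout")]] <- numeric(dm)
    p[[paste0(pre, "ln_g")]] <- rep(1, dm)
    p[[paste0(pre, "ln_b")]] <- numeric(dm)
  }
  list(cfg = cfg, params = p)
}

# extract the parameters of block l with prefix stripped
blockParams <- function(mamba, l) {
  pre <- paste0("b", l, ".")
  nm <- names(mamba$params)
  sel <- startsWith(nm, pre)
  out <- mamba$params[sel]
  names(out) <- substring(nm[sel], nchar(pre) + 1L)
  out
}

#' Zero-order-hold / Euler discretization of a scalar SSM channel
#'
#' For a continuous state coefficient `a < 0`, input coefficient `b` and a
#' positive step `delta`: `a_bar = exp(delta * a)` under both rules;
#' `b_bar = delta * b` under the simplified Euler rule (default) or
#' `b_bar = (exp(delta * a) - 1) / a * b` under exact zero-order hold. The
#' two agree to first order in `delta`.
#'
#' @param a real (typically negative) state coefficient.
#' @param b real input coefficient.
#' @param delta positive time step.
#' @param method `"euler"` or `"zoh"`.
#' @return List with `a_bar` and `b_bar`.
#' @export
discretizeZoh <- function(a, b, delta, method = c("euler", "zoh")) {
  method <- match.arg(method)
  stopifnot(all(delta > 0))
  a_bar <- exp(delta * a)
  b_bar <- if (method == "euler") delta * b else (a_bar - 1) / a * b
  list(a_bar = a_bar, b_bar = b_bar)
}

# ---- core scan --------------------------------------------------------------

# u, Delta: K x d_inner. Bmat, Cmat: K x (d_state * d_inner), state fastest.
# A: d_state x d_inner (negative reals). Returns y (K x d_inner) plus the
# per-step state and transition caches needed by the backward pass. The
# sequential recurrence runs in compiled code (src/scan.cpp).
scanForwardCore <- function(u, Delta, Bmat, Cmat, A, method) {
  .scan_forward(u, Delta, Bmat, Cmat, as.vector(A), method == "euler")
}

# Backward of the scan. dy: K x d_inner. Returns du, dDelta (K x d_inner),
# dBmat, dCmat (K x ds*di), dA (d_state x d_inner).
scanBackwardCore <- function(dy, u, Delta, Bmat, Cmat, A, method, fw) {
  out <- .scan_backward(dy, u, Delta, Bmat, Cmat, as.vector(A),
                        method == "euler", fw$Hmat, fw$Abarmat)
  out$dA <- matrix(out$dA, nrow(A), ncol(A))
  out
}

#' Run the selective scan
#'
#' The per-channel diagonal SSM recurrence with input-dependent parameters:
#' for channel d, `h_k = exp(Delta[k,d] * A[d,]) * h_{k-1} +
#' Bbar[k,d,] * u[k,d]` with `h_0 = 0`, and `y[k,d] = <C[k,d,], h_k>`. The
#' contract is sequence-order dependent (causal).
#'
#' @param u_seq K x d_inner input matrix.
#' @param delta K x d_inner matrix of positive time steps.
#' @param B,C arrays of dimension `c(K, d_inner, d_state)`.
#' @param A d_inner x d_state matrix of negative reals.
#' @param method discretization rule, `"euler"` (default) or `"zoh"`.
#' @return K x d_inner output matrix.
#' @export
ssmScan <- function(u_seq, delta, B, C, A, method = c("euler", "zoh")) {
  method <- match.arg(method)
  K <- nrow(u_seq); di <- ncol(u_seq); ds <- ncol(A)
  stopifnot(all(dim(B) == c(K, di, ds)), all(dim(C) == c(K, di, ds)),
            all(dim(delta) == c(K, di)), nrow(A) == di, all(delta > 0))
  toMat <- function(X) t(matrix(aperm(X, c(3L, 2L, 1L)), ds * di, K))
  fw <- scanForwardCore(u_seq, delta, toMat(B), toMat(C), t(A), method)
  fw$y
}

#' Input-dependent selective parameters of one block
#'
#' Computes the S6 selectivity quantities: `Delta[k, d] =
#' softplus(wdelta[d] * u[k, d] + bdelta[d])` from the post-convolution
#' activation, and per-channel linear maps `B[k, d, ] = WB^(d) src_k`,
#' `C[k, d, ] = WC^(d) src_k` where `src` is the layer-normalized block
#' input (default) or the post-convolution activation, per the stack's
#' `bc_source` setting.
#'
#' @param mamba a [mambaInit()] container.
#' @param block 1-based block index.
#' @param u_seq K x d_inner post-convolution activations.
#' @param z_seq K x d_model layer-normalized block inputs.
#' @return List with `delta` (K x d_inner, all entries > 0) and `B`, `C`
#'   (arrays `c(K, d_inner, d_state)`).
#' @export
selectiveParameters <- function(mamba, block, u_seq, z_seq) {
  bp <- blockParams(mamba, block)
  cfg <- mamba$cfg
  src <- if (cfg$bc_source == "block_input") z_seq else u_seq
  pre <- rowPlus(rowTimes(u_seq, bp$wdelta), bp$bdelta)
  Delta <- softplus(pre)
  K <- nrow(u_seq)
  toArr <- function(M) aperm(array(t(M), c(cfg$d_state, cfg$d_inner, K)),
                             c(3L, 2L, 1L))
  list(delta = Delta, B = toArr(src %*% bp$WB), C = toArr(src %*% bp$WC))
}

# ---- block forward / backward ----------------------------------------------

layerNormForward <- function(Z, g, b, eps = 1e-5) {
  m <- rowMeans(Z)
  xc <- Z - m
  v <- rowMeans(xc^2)
  s <- sqrt(v + eps)
  zn <- xc / s
  zp <- rowPlus(rowTimes(zn, g), b)
  list(zp = zp, zn = zn, s = s)
}

layerNormBackward <- function(dzp, cache, g) {
  dzn <- rowTimes(dzp, g)
  dg <- colSums(dzp * cache$zn)
  db <- colSums(dzp)
  mean_dzn <- rowMeans(dzn)
  mean_dzn_zn <- rowMeans(dzn * cache$zn)
  dx <- (dzn - mean_dzn - cache$zn * mean_dzn_zn) / cache$s
  list(dx = dx, dg = dg, db = db)
}

causalConvForward <- function(X, Wconv, bconv) {
  K <- nrow(X); di <- ncol(X); dc <- ncol(Wconv)
  Xpad <- rbind(matrix(0, dc - 1L, di), X)
  u_pre <- matrix(rep(bconv, each = K), K, di)
  for (j in seq_len(dc)) {
    u_pre <- u_pre + rowTimes(Xpad[j:(j + K - 1L), , drop = FALSE], Wconv[, j])
  }
  list(u_pre = u_pre, Xpad = Xpad)
}

causalConvBackward <- function(du_pre, Xpad, Wconv) {
  K <- nrow(du_pre); di <- ncol(du_pre); dc <- ncol(Wconv)
  dW <- matrix(0, di, dc)
  dXpad <- Xpad * 0
  for (j in seq_len(dc)) {
    rows <- j:(j + K - 1L)
    dW[, j] <- colSums(du_pre * Xpad[rows, , drop = FALSE])
    dXpad[rows, ] <- dXpad[rows, ] + rowTimes(du_pre, Wconv[, j])
  }
  list(dW = dW, db = colSums(du_pre),
       dX = dXpad[dc:(dc + K - 1L), , drop = FALSE])
}

# Forward through one Mamba block. Returns output, the selectivity trace and
# the cache for the backward pass. Dropout (train_mode only) is applied to
# the post-convolution activation; the caller is responsible for seeding RNG.
mambaBlockForward <- function(mamba, block, Z, train_mode = FALSE) {
  bp <- blockParams(mamba, block)
  cfg <- mamba$cfg
  K <- nrow(Z)
  ln <- layerNormForward(Z, bp$ln_g, bp$ln_b)
  zp <- ln$zp
  X <- rowPlus(zp %*% bp$Wx, bp$bx)
  Gpre <- rowPlus(zp %*% bp$Wg, bp$bg)
  G <- silu(Gpre)
  cv <- causalConvForward(X, bp$Wconv, bp$bconv)
  u_act <- silu(cv$u_pre)
  if (train_mode && cfg$dropout_p > 0) {
    mask <- matrix(stats::rbinom(length(u_act), 1L, 1 - cfg$dropout_p),
                   K, cfg$d_inner) / (1 - cfg$dropout_p)
    u <- u_act * mask
  } else {
    mask <- NULL
    u <- u_act
  }
  src <- if (cfg$bc_source == "block_input") zp else u
  dpre <- rowPlus(rowTimes(u, bp$wdelta), bp$bdelta)
  Delta <- softplus(dpre)
  Bmat <- src %*% bp$WB
  Cmat <- src %*% bp$WC
  A <- -exp(bp$Alog)
  sc <- scanForwardCore(u, Delta, Bmat, Cmat, A, cfg$discretization)
  Yg <- sc$y * G
  out <- rowPlus(Yg %*% bp$Wout, bp$bout)
  Zout <- Z + out
  list(Zout = Zout, Delta = Delta,
       cache = list(ln = ln, zp = zp, X = X, Gpre = Gpre, G = G,
                    u_pre = cv$u_pre, Xpad = cv$Xpad, mask = mask, u = u,
                    dpre = dpre, Delta = Delta, Bmat = Bmat, Cmat = Cmat,
                    A = A, scan = sc, Yg = Yg, y = sc$y))
}

# Backward through one block: dZout -> parameter grads + dZ (input grad).
mambaBlockBackward <- function(mamba, block, dZout, cache) {
  bp <- blockParams(mamba, block)
  cfg <- mamba$cfg
  g <- list()
  # output projection and residual
  dYg <- tcrossprod(dZout, bp$Wout)
  g$Wout <- crossprod(cache$Yg, dZout)
  g$bout <- colSums(dZout)
  dy <- dYg * cache$G
  dG <- dYg * cache$y
  dGpre <- dG * siluGrad(cache$Gpre)
  g$Wg <- crossprod(cache$zp, dGpre)
  g$bg <- colSums(dGpre)
  dzp <- tcrossprod(dGpre, bp$Wg)
  # scan
  sb <- scanBackwardCore(dy, cache$u, cache$Delta, cache$Bmat, cache$Cmat,
                         cache$A, cfg$discretization, cache$scan)
  du <- sb$du
  # Delta projection
  dpre_grad <- sb$dDelta * sigmoid(cache$dpre)
  g$wdelta <- colSums(dpre_grad * cache$u)
  g$bdelta <- colSums(dpre_grad)
  du <- du + rowTimes(dpre_grad, bp$wdelta)
  # B / C projections
  src <- if (cfg$bc_source == "block_input") cache$zp else cache$u
  g$WB <- crossprod(src, sb$dBmat)
  g$WC <- crossprod(src, sb$dCmat)
  dsrc <- tcrossprod(sb$dBmat, bp$WB) + tcrossprod(sb$dCmat, bp$WC)
  if (cfg$bc_source == "block_input") dzp <- dzp + dsrc else du <- du + dsrc
  # A (stored as log(-A); dA/dAlog = A)
  g$Alog <- sb$dA * cache$A
  # dropout + conv activation
  if (!is.null(cache$mask)) du <- du * cache$mask
  du_pre <- du * siluGrad(cache$u_pre)
  cvb <- causalConvBackward(du_pre, cache$Xpad, bp$Wconv)
  g$Wconv <- cvb$dW
  g$bconv <- cvb$db
  dX <- cvb$dX
  g$Wx <- crossprod(cache$zp, dX)
  g$bx <- colSums(dX)
  dzp <- dzp + tcrossprod(dX, bp$Wx)
  # layer norm
  lnb <- layerNormBackward(dzp, cache$ln, bp$ln_g)
  g$ln_g <- lnb$dg
  g$ln_b <- lnb$db
  names(g) <- paste0("b", block, ".", names(g))
  list(grads = g, dZ = lnb$dx + dZout)
}

#' Apply one Mamba block
#'
#' LayerNorm, parallel input/gate projections, causal depthwise
#' convolution, SiLU, selective scan, multiplicative SiLU gate, output
#' projection and residual connection. Dropout after the convolution is
#' active only in training mode. The time-step values recorded during the
#' scan are returned as a [SelectivityTrace-class].
#'
#' @param mamba a [mambaInit()] container.
#' @param block 1-based block index.
#' @param Z K x d_model input matrix.
#' @param train_mode logical; enables dropout.
#' @return List with `output` (K x d_model) and `trace`.
#' @export
mambaBlock <- function(mamba, block, Z, train_mode = FALSE) {
  fw <- mambaBlockForward(mamba, block, Z, train_mode)
  list(output = fw$Zout,
       trace = new("SelectivityTrace", delta = fw$Delta,
                   block = as.integer(block)))
}

# Stack forward: returns context (mean-pooled), per-block raw Delta traces
# (wrapped into SelectivityTrace objects only at the evaluation surface, to
# keep the training path lean) + caches.
mambaStackForward <- function(mamba, Z, train_mode = FALSE) {
  caches <- vector("list", mamba$cfg$n_layers)
  traces <- vector("list", mamba$cfg$n_layers)
  H <- Z
  for (l in seq_len(mamba$cfg$n_layers)) {
    fw <- mambaBlockForward(mamba, l, H, train_mode)
    caches[[l]] <- fw$cache
    traces[[l]] <- fw$Delta
    H <- fw$Zout
  }
  list(context = colMeans(H), O = H, traces = traces, caches = caches)
}

wrapTraces <- function(raw) {
  lapply(seq_along(raw), function(l)
    new("SelectivityTrace", delta = raw[[l]], block = l))
}

# Stack backward from d(context): distributes dc / K to all rows, walks the
# blocks in reverse. Returns parameter grads and dZ (grad w.r.t. the input
# latent sequence).
mambaStackBackward <- function(mamba, fw, dContext, K) {
  dH <- matrix(rep(dContext / K, each = K), K, length(dContext))
  grads <- NULL
  for (l in rev(seq_len(mamba$cfg$n_layers))) {
    bb <- mambaBlockBackward(mamba, l, dH, fw$caches[[l]])
    grads <- c(grads, bb$grads)
    dH <- bb$dZ
  }
  list(grads = grads, dZ = dH)
}

#' Encode a latent sequence into a temporal context vector
#'
#' Applies the stacked Mamba blocks sequentially, then mean-pools the final
#' block's output rows into a single context vector `c = (1/K) sum_k O_k`.
#'
#' @param mamba a [mambaInit()] container.
#' @param Z a [LatentSequence-class] or a K x d_model matrix.
#' @param train_mode logical; enables dropout inside the blocks.
#' @return List with `context` (length d_model), `output` (K x d_model
#'   final block output) and `traces` (list of [SelectivityTrace-class],
#'   one per block).
#' @export
encodeTemporal <- function(mamba, Z, train_mode = FALSE) {
  Zm <- if (is(Z, "LatentSequence")) Z@values else Z
  if (ncol(Zm) != mamba$cfg$d_model)
    stop(sprintf("input width %d does not match d_model %d",
                 ncol(Zm), mamba$cfg$d_model))
  fw <- mambaStackForward(mamba, Zm, train_mode)
  list(context = fw$context, output = fw$O, traces = wrapTraces(fw$traces))
}

#' Temporal importance scores from a selectivity trace
#'
#' `s_k = (1 / d_inner) * sum_d Delta[k, d]`: the per-window mean of the
#' recorded time-step values. Large values mean the scan prioritized fresh
#' information at window k; small values mean prior state was carried
#' forward.
#'
#' @param trace a [SelectivityTrace-class].
#' @return Numeric vector of length K, all entries positive.
#' @export
selectivityScores <- function(trace) {
  stopifnot(is(trace, "SelectivityTrace"))
  if (length(trace@delta) == 0L) stop("empty trace")
  rowMeans(trace@delta)
}
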