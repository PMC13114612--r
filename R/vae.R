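# Per-window variational autoencoder: MLP encoder with parallel mu / log-var
# heads, reparameterized sampling, mirror decoder with sigmoid output, and the
# ELBO loss. Forward passes cache every intermediate needed by the
# hand-written backward passes; gradients are validated against finite
# differences in the test suite.

#' Initialize a variational autoencoder
#'
#' Builds the parameter container for an MLP VAE. The encoder maps a
#' D-dimensional window vector through `encoder_dims` hidden widths
#' (ReLU) into two parallel affine heads producing the posterior mean and
#' log-variance of length `latent_dim`; the decoder mirrors the encoder and
#' ends in a sigmoid so reconstructions live in (0, 1), matching
#' unit-rescaled correlation inputs. Weights are fan-in uniform, seeded.
#'
#' @param encoder_dims integer vector: input width D followed by the hidden
#'   widths, e.g. `c(6670, 2048, 1024, 512, 256)` at full scale or
#'   `c(190, 64, 32)` for the desk preset.
#' @param latent_dim latent width L (128 at full scale).
#' @param kl_weight weight of the KL term in the ELBO (default 1.0).
#' @param seed integer seed for weight initialization.
#' @param activation hidden nonlinearity, `"relu"` (default) or
#'   `"identity"` (linear encoder/decoder, used for analytic surrogates).
#' @return A list with elements `arch` (architecture metadata) and `params`
#'   (flat named list of weight/bias arrays).
#' @examples
#' vae <- vaeInit(c(10, 8), 4, seed = 1)
#' names(vae$params)
#' @export
vaeInit <- function(encoder_dims, latent_dim, kl_weight = 1.0, seed = 0L,
                    activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  encoder_dims <- as.integer(encoder_dims)
  latent_dim <- as.integer(latent_dim)
  stopifnot(length(encoder_dims) >= 1L, all(encoder_dims > 0L), latent_dim > 0L)
  set.seed(deriveSeed(seed, "vae-init"))
  p <- list()
  n_hidden <- length(encoder_dims) - 1L
  for (l in seq_len(n_hidden)) {
    p[[paste0("enc_W", l)]] <- initMatrix(encoder_dims[l], encoder_dims[l + 1L])
    p[[paste0("enc_b", l)]] <- numeric(encoder_dims[l + 1L])
  }
  last <- encoder_dims[length(encoder_dims)]
  p$W_mu  <- initMatrix(last, latent_dim); p$b_mu  <- numeric(latent_dim)
  p$W_sig <- initMatrix(last, latent_dim); p$b_sig <- numeric(latent_dim)
  dec_dims <- c(latent_dim, rev(encoder_dims))
  for (l in seq_len(length(dec_dims) - 1L)) {
    p[[paste0("dec_W", l)]] <- initMatrix(dec_dims[l], dec_dims[l + 1L])
    p[[paste0("dec_b", l)]] <- numeric(dec_dims[l + 1L])
  }
  list(arch = list(encoder_dims = encoder_dims, latent_dim = latent_dim,
                   decoder_dims = dec_dims, kl_weight = kl_weight,
                   activation = activation),
       params = p)
}

vaeAct <- function(vae, x) if (vae$arch$activation == "relu") relu(x) else x
vaeActGrad <- function(vae, pre) {
  if (vae$arch$activation == "relu") (pre > 0) * 1 else pre * 0 + 1
}

# Encoder forward over a batch V (n x D). Returns mu, log_var and the cache
# of layer inputs / pre-activations.
vaeEncodeForward <- function(vae, V) {
  n_hidden <- length(vae$arch$encoder_dims) - 1L
  H <- V
  inputs <- vector("list", n_hidden)   # layer inputs
  pre <- vector("list", n_hidden)      # pre-activations
  for (l in seq_len(n_hidden)) {
    inputs[[l]] <- H
    A <- H %*% vae$params[[paste0("enc_W", l)]]
    A <- rowPlus(A, vae$params[[paste0("enc_b", l)]])
    pre[[l]] <- A
    H <- vaeAct(vae, A)
  }
  mu <- rowPlus(H %*% vae$params$W_mu, vae$params$b_mu)
  log_var <- rowPlus(H %*% vae$params$W_sig, vae$params$b_sig)
  list(mu = mu, log_var = log_var,
       cache = list(inputs = inputs, pre = pre, H_last = H))
}

#' Encode window vectors to latent posteriors
#'
#' Runs the encoder MLP and the two parallel affine heads. Accepts a single
#' window vector or a batch (rows = windows).
#'
#' @param vae a [vaeInit()] container.
#' @param v numeric vector of length D, or an n x D matrix.
#' @return A list with `mu` and `log_var`, each n x L (1 x L for a vector
#'   input).
#' @export
vaeEncode <- function(vae, v) {
  V <- if (is.matrix(v)) v else matrix(v, nrow = 1L)
  if (ncol(V) != vae$arch$encoder_dims[1L])
    stop(sprintf("input width %d does not match encoder input %d",
                 ncol(V), vae$arch$encoder_dims[1L]))
  fw <- vaeEncodeForward(vae, V)
  list(mu = fw$mu, log_var = fw$log_var)
}

#' Reparameterized latent sample
#'
#' `z = mu + exp(log_var / 2) * noise`. The noise is supplied by the caller
#' (standard-normal in training; injectable for tests; zero recovers the
#' posterior mean).
#'
#' @param mu,log_var posterior parameters (vectors or matrices of equal
#'   shape).
#' @param noise same shape as `mu`.
#' @return Latent sample of the same shape.
#' @export
reparameterize <- function(mu, log_var, noise) {
  mu + exp(log_var / 2) * noise
}

#' KL divergence of diagonal-Gaussian posteriors to the standard normal
#'
#' Per sample: `-1/2 * sum_j (1 + log_var_j - mu_j^2 - exp(log_var_j))`,
#' always nonnegative, zero iff the posterior equals the prior.
#'
#' @param mu,log_var posterior parameters; vectors (one sample) or matrices
#'   (rows = samples).
#' @return Scalar for vector input, otherwise one value per row.
#' @export
klDivergence <- function(mu, log_var) {
  if (!is.matrix(mu)) { mu <- matrix(mu, 1L); log_var <- matrix(log_var, 1L) }
  kl <- -0.5 * rowSums(1 + log_var - mu^2 - exp(log_var))
  if (length(kl) == 1L) kl[[1L]] else kl
}

#' Batch-mean squared reconstruction error
#'
#' `(1 / N_b) * sum_n ||v_n - vhat_n||^2`: the squared error is summed over
#' the feature dimension and averaged over the batch, so duplicating rows
#' leaves the value unchanged.
#'
#' @param v,v_hat equal-shaped vectors or matrices (rows = samples).
#' @return Nonnegative scalar.
#' @export
reconstructionLoss <- function(v, v_hat) {
  if (!is.matrix(v)) { v <- matrix(v, 1L); v_hat <- matrix(v_hat, 1L) }
  mean(rowSums((v - v_hat)^2))
}

# Decoder forward with cache; final layer sigmoid.
vaeDecodeForward <- function(vae, Z) {
  n_layers <- length(vae$arch$decoder_dims) - 1L
  H <- Z
  inputs <- vector("list", n_layers)
  pre <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    inputs[[l]] <- H
    A <- H %*% vae$params[[paste0("dec_W", l)]]
    A <- rowPlus(A, vae$params[[paste0("dec_b", l)]])
    pre[[l]] <- A
    H <- if (l < n_layers) vaeAct(vae, A) else sigmoid(A)
  }
  list(v_hat = H, cache = list(inputs = inputs, pre = pre))
}

#' Decode latent vectors to reconstructions
#'
#' Mirror MLP with a sigmoid output layer; every entry of the
#' reconstruction lies strictly inside (0, 1).
#'
#' @param vae a [vaeInit()] container.
#' @param z latent vector of length L or an n x L matrix.
#' @return Reconstruction of width D (matrix for matrix input).
#' @export
vaeDecode <- function(vae, z) {
  Z <- if (is.matrix(z)) z else matrix(z, nrow = 1L)
  if (ncol(Z) != vae$arch$latent_dim)
    stop(sprintf("latent width %d does not match latent_dim %d",
                 ncol(Z), vae$arch$latent_dim))
  out <- vaeDecodeForward(vae, Z)$v_hat
  if (is.matrix(z)) out else out[1L, ]
}

# Full forward pass for training: encode, sample, decode, losses.
# noise = NULL means posterior-mean (deterministic) path.
vaeForwardFull <- function(vae, V, noise = NULL) {
  enc <- vaeEncodeForward(vae, V)
  eps <- if (is.null(noise)) matrix(0, nrow(enc$mu), ncol(enc$mu)) else noise
  Z <- enc$mu + exp(enc$log_var / 2) * eps
  dec <- vaeDecodeForward(vae, Z)
  recon <- reconstructionLoss(V, dec$v_hat)
  kl_per <- -0.5 * rowSums(1 + enc$log_var - enc$mu^2 - exp(enc$log_var))
  kl <- mean(kl_per)
  list(V = V, mu = enc$mu, log_var = enc$log_var, eps = eps, Z = Z,
       v_hat = dec$v_hat, recon = recon, kl = kl,
       total = recon + vae$arch$kl_weight * kl,
       enc_cache = enc$cache, dec_cache = dec$cache)
}

#' Evidence-lower-bound loss of a window batch
#'
#' `total = recon + kl_weight * kl`, with the reconstruction term from
#' [reconstructionLoss()] and the KL term averaged over the batch (matching
#' the batch-mean convention of the reconstruction term, so the relative
#' weighting is batch-size invariant).
#'
#' @param vae a [vaeInit()] container.
#' @param v batch matrix (rows = window vectors) or a single vector.
#' @param noise optional reparameterization noise of the same shape as the
#'   posterior mean; `NULL` (default) uses the deterministic mean path.
#' @return List with `total`, `recon`, `kl`.
#' @export
vaeLoss <- function(vae, v, noise = NULL) {
  V <- if (is.matrix(v)) v else matrix(v, nrow = 1L)
  fw <- vaeForwardFull(vae, V, noise)
  list(total = fw$total, recon = fw$recon, kl = fw$kl)
}

# Backward through the decoder from d(loss)/d(v_hat); returns grads and dZ.
vaeDecodeBackward <- function(vae, dec_cache, v_hat, dVhat) {
  n_layers <- length(vae$arch$decoder_dims) - 1L
  grads <- list()
  dH <- dVhat * v_hat * (1 - v_hat)   # through final sigmoid
  for (l in rev(seq_len(n_layers))) {
    if (l < n_layers) dH <- dH * vaeActGrad(vae, dec_cache$pre[[l]])
    grads[[paste0("dec_W", l)]] <- crossprod(dec_cache$inputs[[l]], dH)
    grads[[paste0("dec_b", l)]] <- colSums(dH)
    dH <- tcrossprod(dH, vae$params[[paste0("dec_W", l)]])
  }
  list(grads = grads, dZ = dH)
}

# Backward through the encoder from dMu / dLogVar; optionally also returns
# the gradient with respect to the input batch (needed for attribution).
vaeEncodeBackward <- function(vae, enc_cache, dMu, dLogVar, wrt_input = FALSE) {
  grads <- list(
    W_mu  = crossprod(enc_cache$H_last, dMu),
    b_mu  = colSums(dMu),
    W_sig = crossprod(enc_cache$H_last, dLogVar),
    b_sig = colSums(dLogVar)
  )
  dH <- tcrossprod(dMu, vae$params$W_mu) + tcrossprod(dLogVar, vae$params$W_sig)
  n_hidden <- length(vae$arch$encoder_dims) - 1L
  for (l in rev(seq_len(n_hidden))) {
    dH <- dH * vaeActGrad(vae, enc_cache$pre[[l]])
    grads[[paste0("enc_W", l)]] <- crossprod(enc_cache$inputs[[l]], dH)
    grads[[paste0("enc_b", l)]] <- colSums(dH)
    dH <- tcrossprod(dH, vae$params[[paste0("enc_W", l)]])
  }
  list(grads = grads, dV = if (wrt_input) dH else NULL)
}

# Gradients of the ELBO (plus an optional external gradient dZ_extra flowing
# into the latent sample from downstream consumers) with respect to all VAE
# parameters. `loss_scale` multiplies the ELBO contribution (alpha weighting
# in joint training); dZ_extra is used as-is.
vaeBackwardFull <- function(vae, fw, dZ_extra = NULL, loss_scale = 1,
                            wrt_input = FALSE) {
  n <- nrow(fw$V)
  beta <- vae$arch$kl_weight
  dVhat <- loss_scale * 2 * (fw$v_hat - fw$V) / n
  dec <- vaeDecodeBackward(vae, fw$dec_cache, fw$v_hat, dVhat)
  dZ <- dec$dZ
  if (!is.null(dZ_extra)) dZ <- dZ + dZ_extra
  # z = mu + exp(lv/2) * eps
  sig <- exp(fw$log_var / 2)
  dMu <- dZ
  dLogVar <- dZ * fw$eps * sig / 2
  # KL term (batch mean): d/dmu = mu/n, d/dlv = -(1 - exp(lv))/(2n)
  dMu <- dMu + loss_scale * beta * fw$mu / n
  dLogVar <- dLogVar - loss_scale * beta * (1 - exp(fw$log_var)) / (2 * n)
  enc <- vaeEncodeBackward(vae, fw$enc_cache, dMu, dLogVar, wrt_input)
  dV_direct <- if (wrt_input) -dVhat else NULL  # recon also depends on V directly
  list(grads = c(enc$grads, dec$grads),
       dV = if (wrt_input) enc$dV + dV_direct else NULL)
}

#' Encode a dFC sequence window by window
#'
#' Applies the encoder independently to each of the K windows of a
#' [DFCSequence-class] (row k of the output derives only from window k). In
#' `"posterior-mean"` mode the result is deterministic; in `"sampled"` mode
#' each row is a reparameterized draw using the supplied seed.
#'
#' @param vae a [vaeInit()] container.
#' @param dfc a [DFCSequence-class] object.
#' @param mode `"posterior-mean"` (default) or `"sampled"`.
#' @param seed RNG seed for `"sampled"` mode.
#' @return A [LatentSequence-class] with a K x L `values` matrix.
#' @export
encodeSequence <- function(vae, dfc, mode = c("posterior-mean", "sampled"),
                           seed = 0L) {
  mode <- match.arg(mode)
  stopifnot(is(dfc, "DFCSequence"))
  post <- vaeEncode(vae, dfc@vectors)
  if (mode == "sampled") {
    set.seed(deriveSeed(seed, "encode-seq", dfc@session_id))
    eps <- matrix(stats::rnorm(length(post$mu)), nrow(post$mu), ncol(post$mu))
    Z <- reparameterize(post$mu, post$log_var, eps)
  } else {
    Z <- post$mu
  }
  new("LatentSequence", values = Z, source = mode,
      subject_id = dfc@subject_id, session_id = dfc@session_id,
      label = dfc@label)
}
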