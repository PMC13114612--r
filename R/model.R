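# Composition of the three components into the end-to-end classifier:
# window vectors -> VAE latent sequence -> (Mamba stack | mean pooling) ->
# context vector -> head -> logits. One forward/backward pair per session.

#' Assemble an untrained model from a configuration
#'
#' Instantiates the VAE, the Mamba stack (unless `config$mamba$use_mamba`
#' is `FALSE`, the mean-pooling ablation) and the classifier head from a
#' resolved configuration (see [defaultConfig()]), with all weights
#' initialized from `seed`.
#'
#' @param config resolved configuration list.
#' @param seed integer seed.
#' @return A [DFCModel-class] with `phase = 0`.
#' @export
modelInit <- function(config, seed = 0L) {
  vc <- config$vae
  vae <- vaeInit(vc$encoder_dims, vc$latent_dim, vc$kl_weight,
                 deriveSeed(seed, "vae"), vc$activation)
  mamba <- list()
  if (isTRUE(config$mamba$use_mamba)) {
    mc <- config$mamba
    mcfg <- mambaConfig(vc$latent_dim, mc$d_state, mc$d_conv, mc$expand,
                        mc$n_layers, mc$dropout_p, mc$discretization,
                        mc$bc_source)
    mamba <- mambaInit(mcfg, deriveSeed(seed, "mamba"))
  }
  hc <- config$head
  head <- headInit(vc$latent_dim, hc$hidden, hc$n_classes, hc$grid_size,
                   hc$spline_order, deriveSeed(seed, "head"), hc$type,
                   hc$base_activation %||% "silu")
  new("DFCModel", vae = vae, mamba = mamba, head = head, config = config,
      phase = 0L, seed = as.integer(seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Forward through the whole pipeline for one session's window matrix V
# (K x D). noise (K x L) selects the sampled latent path; NULL = posterior
# mean. train_mode enables dropout inside the Mamba blocks (caller seeds the
# RNG). Returns logits, probs, VAE losses and all caches.
sessionForward <- function(model, V, train_mode = FALSE, noise = NULL) {
  vfw <- vaeForwardFull(model@vae, V, noise)
  K <- nrow(V)
  if (length(model@mamba)) {
    mfw <- mambaStackForward(model@mamba, vfw$Z, train_mode)
    context <- mfw$context
  } else {
    mfw <- NULL
    context <- colMeans(vfw$Z)
  }
  hfw <- headForward(model@head, matrix(context, 1L))
  logits <- hfw$logits[1L, ]
  list(V = V, vfw = vfw, mfw = mfw, hfw = hfw, context = context,
       logits = logits, probs = drop(softmaxRows(hfw$logits)),
       vae_total = vfw$total, vae_recon = vfw$recon, vae_kl = vfw$kl)
}

# Backward for the joint objective alpha * L_VAE + cls_weight * CE(label).
# Returns per-group gradient lists. loss value returned for bookkeeping.
sessionBackward <- function(model, fw, label, alpha, cls_weight) {
  C <- model@head$n_classes
  onehot <- numeric(C); onehot[label + 1L] <- 1
  dLogits <- matrix(cls_weight * (fw$probs - onehot), 1L)
  hb <- headBackward(model@head, fw$hfw$cache, dLogits)
  dContext <- hb$dX[1L, ]
  K <- nrow(fw$V)
  if (length(model@mamba)) {
    mb <- mambaStackBackward(model@mamba, fw$mfw, dContext, K)
    dZ <- mb$dZ
    mamba_grads <- mb$grads
  } else {
    dZ <- matrix(rep(dContext / K, each = K), K)
    mamba_grads <- NULL
  }
  vb <- vaeBackwardFull(model@vae, fw$vfw, dZ_extra = dZ, loss_scale = alpha)
  ce <- -log(max(fw$probs[label + 1L], 1e-300))
  list(vae = vb$grads, mamba = mamba_grads, head = hb$grads,
       loss = alpha * fw$vae_total + cls_weight * ce, ce = ce)
}

#' Predict class probabilities for one session
#'
#' Deterministic evaluation path: posterior-mean encoding of every window,
#' temporal encoding (dropout off), classifier head, softmax.
#'
#' @param model a trained [DFCModel-class].
#' @param dfc a [DFCSequence-class] (or a K x D matrix).
#' @return Named list with `probs` (length C, sums to 1), `logits`, and
#'   `traces` (per-block selectivity traces; `NULL` without Mamba).
#' @export
predictSession <- function(model, dfc) {
  V <- if (is(dfc, "DFCSequence")) dfc@vectors else dfc
  if (ncol(V) != model@vae$arch$encoder_dims[1L])
    stop(sprintf("feature width %d does not match model input %d",
                 ncol(V), model@vae$arch$encoder_dims[1L]))
  fw <- sessionForward(model, V, train_mode = FALSE, noise = NULL)
  list(probs = fw$probs, logits = fw$logits,
       traces = if (is.null(fw$mfw)) NULL else wrapTraces(fw$mfw$traces))
}

# Gradient of one class logit with respect to the session input features:
# d logit_c / d V, a K x D matrix, evaluated on the deterministic path
# (z = posterior mean). The backbone of Jacobian attribution.
modelInputGradient <- function(model, V, class_idx) {
  fw <- sessionForward(model, V, train_mode = FALSE, noise = NULL)
  C <- model@head$n_classes
  if (class_idx < 0L || class_idx >= C) stop("class index out of range")
  dLogits <- matrix(0, 1L, C); dLogits[1L, class_idx + 1L] <- 1
  hb <- headBackward(model@head, fw$hfw$cache, dLogits)
  dContext <- hb$dX[1L, ]
  K <- nrow(V)
  if (length(model@mamba)) {
    mb <- mambaStackBackward(model@mamba, fw$mfw, dContext, K)
    dZ <- mb$dZ
  } else {
    dZ <- matrix(rep(dContext / K, each = K), K)
  }
  # deterministic path: z = mu, so the whole dZ flows through the mean head
  eb <- vaeEncodeBackward(model@vae, fw$vfw$enc_cache, dMu = dZ,
                          dLogVar = dZ * 0, wrt_input = TRUE)
  eb$dV
}

# deep-copy trainable parameters of all groups
modelSnapshot <- function(model) {
  list(vae = model@vae$params,
       mamba = if (length(model@mamba)) model@mamba$params else NULL,
       head = headParams(model@head))
}

modelRestore <- function(model, snap) {
  model@vae$params <- snap$vae
  if (!is.null(snap$mamba)) model@mamba$params <- snap$mamba
  model@head <- headSetParams(model@head, snap$head)
  model
}
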