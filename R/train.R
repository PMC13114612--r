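# Two-phase training: unsupervised VAE pre-training (phase 1), then joint
# fine-tuning of the full pipeline with differential learning rates and a
# warmup freeze of the VAE (phase 2). Subject-level evaluation throughout.

#' Mean cross-entropy of a logit batch
#'
#' `-(1 / N_b) * sum_n log softmax(logits_n)[label_n]`, computed via
#' log-sum-exp for stability.
#'
#' @param logits numeric vector (one sample) or n x C matrix.
#' @param labels integer vector of 0-based class indices.
#' @return Nonnegative scalar.
#' @examples
#' crossEntropy(c(0, 0), 0L)  # log(2)
#' @export
crossEntropy <- function(logits, labels) {
  L <- if (is.matrix(logits)) logits else matrix(logits, nrow = 1L)
  labels <- as.integer(labels)
  if (any(labels < 0L | labels >= ncol(L)))
    stop("label out of range [0, C)")
  lse <- logSumExpRows(L)
  picked <- L[cbind(seq_len(nrow(L)), labels + 1L)]
  mean(lse - picked)
}

#' Subject-level split with largest-remainder allocation
#'
#' Assigns whole subjects (never individual sessions) to train/validation/
#' test partitions, per class: each class's subject count is multiplied by
#' the target fractions, integer parts are allocated first and the
#' remaining slots go to the partitions with the largest fractional
#' remainders. Subject order within class is shuffled by `seed`.
#'
#' @param labels data.frame with columns `subject_id` and `class_label`
#'   (one row per session; subjects may repeat).
#' @param fractions length-3 numeric summing to 1 (default 70/10/20).
#' @param seed RNG seed for the within-class shuffle.
#' @return List with character vectors `train`, `val`, `test`.
#' @export
makeSubjectSplit <- function(labels, fractions = c(0.7, 0.1, 0.2), seed = 0L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9)
  subj <- unique(labels[, c("subject_id", "class_label")])
  if (anyDuplicated(subj$subject_id))
    stop("a subject appears with more than one class label")
  set.seed(deriveSeed(seed, "split"))
  out <- list(train = character(), val = character(), test = character())
  for (cl in sort(unique(subj$class_label))) {
    ids <- sample(subj$subject_id[subj$class_label == cl])
    n <- length(ids)
    raw <- fractions * n
    base <- floor(raw)
    rem <- raw - base
    extra <- order(rem, decreasing = TRUE)[seq_len(n - sum(base))]
    counts <- base
    counts[extra] <- counts[extra] + 1L
    cuts <- cumsum(counts)
    out$train <- c(out$train, ids[seq_len(counts[1L])])
    if (counts[2L] > 0) out$val <- c(out$val, ids[(cuts[1L] + 1L):cuts[2L]])
    if (counts[3L] > 0) out$test <- c(out$test, ids[(cuts[2L] + 1L):cuts[3L]])
  }
  out
}

#' Check that a split is leak-free
#'
#' Errors if any subject id appears in more than one partition.
#'
#' @param split list with `train`, `val`, `test` id vectors.
#' @return Invisibly `TRUE`.
#' @export
assertSplitLeakFree <- function(split) {
  all_ids <- c(split$train, split$val, split$test)
  dup <- unique(all_ids[duplicated(all_ids)])
  if (length(dup))
    stop(sprintf("subject(s) span partitions: %s", paste(dup, collapse = ", ")))
  invisible(TRUE)
}

# stack the window vectors of a session list into one matrix
stackWindows <- function(dfcs) {
  do.call(rbind, lapply(dfcs, function(d) d@vectors))
}

#' Phase 1: unsupervised VAE pre-training
#'
#' Trains the VAE alone on the training-partition windows (labels unused;
#' validation/test windows never enter) by minimizing the ELBO with Adam.
#' The checkpoint with the lowest validation reconstruction loss
#' (posterior-mean path, deterministic) is returned.
#'
#' @param vae a [vaeInit()] container.
#' @param train_windows n x D matrix of training window vectors.
#' @param val_windows matrix of validation window vectors.
#' @param epochs,batch_size,lr optimization settings.
#' @param seed RNG seed (shuffling and reparameterization noise).
#' @return List with `vae` (best checkpoint), `history` (per-epoch train
#'   loss and validation reconstruction loss) and `best_epoch`.
#' @export
pretrainVAE <- function(vae, train_windows, val_windows, epochs = 100L,
                        batch_size = 32L, lr = 1e-3, seed = 0L) {
  if (is.null(train_windows) || nrow(train_windows) == 0L)
    stop("empty training set")
  st <- adamInit(vae$params)
  n <- nrow(train_windows)
  L <- vae$arch$latent_dim
  best <- list(val = Inf, params = vae$params, epoch = 0L)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_recon = numeric())
  set.seed(deriveSeed(seed, "vae-train"))
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; n_b <- 0L
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      V <- train_windows[idx, , drop = FALSE]
      eps <- matrix(stats::rnorm(length(idx) * L), length(idx), L)
      fw <- vaeForwardFull(vae, V, eps)
      gr <- vaeBackwardFull(vae, fw)$grads
      upd <- adamStep(vae$params, gr, st, lr)
      vae$params <- upd$params; st <- upd$state
      ep_loss <- ep_loss + fw$total; n_b <- n_b + 1L
    }
    val_recon <- {
      vf <- vaeForwardFull(vae, val_windows, NULL)
      vf$recon
    }
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss / n_b,
                                   val_recon = val_recon))
    if (val_recon < best$val)
      best <- list(val = val_recon, params = vae$params, epoch = ep)
  }
  vae$params <- best$params
  list(vae = vae, history = hist, best_epoch = best$epoch)
}

# group sessions by subject; returns list(ids, labels, index list)
sessionsBySubject <- function(dfcs) {
  ids <- vapply(dfcs, function(d) d@subject_id, character(1))
  labs <- vapply(dfcs, function(d) d@label, integer(1))
  subj <- unique(ids)
  idx <- lapply(subj, function(s) which(ids == s))
  lab <- vapply(idx, function(ii) labs[ii[1L]], integer(1))
  list(subjects = subj, labels = lab, index = idx)
}

#' Average session probabilities into a subject prediction
#'
#' Arithmetic mean of the per-session probability vectors; the predicted
#' label is the argmax with first-index-wins tie-breaking.
#'
#' @param session_probs list of equal-length probability vectors (>= 1).
#' @return List with `probs` and 0-based `label`.
#' @export
aggregateSubject <- function(session_probs) {
  if (length(session_probs) == 0L) stop("no sessions for subject")
  probs <- Reduce(`+`, session_probs) / length(session_probs)
  list(probs = probs, label = which.max(probs) - 1L)
}

# subject-level predictions for a session list
predictSubjects <- function(model, dfcs) {
  grp <- sessionsBySubject(dfcs)
  probs <- lapply(grp$index, function(ii) {
    aggregateSubject(lapply(ii, function(i) predictSession(model, dfcs[[i]])$probs))
  })
  list(subjects = grp$subjects, truth = grp$labels,
       probs = do.call(rbind, lapply(probs, `[[`, "probs")),
       pred = vapply(probs, `[[`, integer(1), "label"))
}

#' Classification metrics from predictions
#'
#' Subject-level confusion matrix (rows = truth), accuracy and
#' macro-averaged precision/recall/F1 in percent (a class never predicted
#' contributes precision 0, with a warning), and for binary problems the
#' AUC of the positive-class (class 1) probabilities computed as the
#' Wilcoxon rank statistic, scaled to percent.
#'
#' @param truth integer vector of 0-based true labels.
#' @param pred integer vector of 0-based predicted labels.
#' @param probs optional n x C probability matrix (needed for AUC).
#' @param n_classes number of classes (default: inferred).
#' @return List with `accuracy`, `precision`, `recall`, `f1`, `auc` (NA for
#'   non-binary), and `confusion`.
#' @export
classificationMetrics <- function(truth, pred, probs = NULL,
                                  n_classes = max(c(truth, pred)) + 1L) {
  C <- as.integer(n_classes)
  conf <- matrix(0L, C, C,
                 dimnames = list(truth = 0:(C - 1L), pred = 0:(C - 1L)))
  for (i in seq_along(truth)) conf[truth[i] + 1L, pred[i] + 1L] <-
      conf[truth[i] + 1L, pred[i] + 1L] + 1L
  acc <- sum(diag(conf)) / sum(conf)
  prec <- rec <- f1 <- numeric(C)
  for (c in seq_len(C)) {
    tp <- conf[c, c]
    pp <- sum(conf[, c])   # predicted positives
    ap <- sum(conf[c, ])   # actual positives
    if (pp == 0) {
      warning(sprintf("class %d never predicted; precision counted as 0", c - 1L))
      prec[c] <- 0
    } else prec[c] <- tp / pp
    rec[c] <- if (ap == 0) 0 else tp / ap
    f1[c] <- if (prec[c] + rec[c] == 0) 0 else
      2 * prec[c] * rec[c] / (prec[c] + rec[c])
  }
  auc <- NA_real_
  if (C == 2L && !is.null(probs)) {
    sc <- probs[, 2L]
    pos <- sc[truth == 1L]; neg <- sc[truth == 0L]
    if (length(pos) && length(neg)) {
      r <- rank(c(pos, neg))
      auc <- 100 * (sum(r[seq_along(pos)]) -
                    length(pos) * (length(pos) + 1) / 2) /
        (length(pos) * length(neg))
    }
  }
  list(accuracy = 100 * acc, precision = 100 * mean(prec),
       recall = 100 * mean(rec), f1 = 100 * mean(f1), auc = auc,
       confusion = conf)
}

#' Subject-level evaluation of a model
#'
#' Predicts every session, averages probabilities within subject, and
#' computes [classificationMetrics()].
#'
#' @param model a trained [DFCModel-class].
#' @param dfcs list of [DFCSequence-class] sessions (one partition).
#' @return Metrics list plus `subjects`, `truth`, `pred`, `probs`.
#' @export
evaluateModel <- function(model, dfcs) {
  if (length(dfcs) == 0L) stop("no sessions to evaluate")
  ps <- predictSubjects(model, dfcs)
  m <- classificationMetrics(ps$truth, ps$pred, ps$probs,
                             model@head$n_classes)
  c(m, ps[c("subjects", "truth", "pred", "probs")])
}

#' Phase 2: joint fine-tuning
#'
#' Optimizes `alpha * L_VAE + cls_weight * L_cls` over training sessions
#' with Adam and differential learning rates: the Mamba stack and head at
#' `lr_mamba_kan`, the VAE at `lr_vae` — and not at all during the first
#' `warmup_epochs` epochs, during which its parameters are bit-identical to
#' the phase-1 checkpoint. The VAE loss is recomputed on the same windows
#' that feed the classifier. KAN grids are refreshed every
#' `grid_update_every` epochs from a buffer of recent activations. The
#' checkpoint with the highest validation subject-level accuracy (ties:
#' lower validation loss) is returned.
#'
#' @param model a [DFCModel-class] (typically with a phase-1 VAE).
#' @param train_dfcs,val_dfcs lists of [DFCSequence-class] sessions.
#' @param cfg training section of the configuration (see [defaultConfig()]).
#' @param seed RNG seed.
#' @return List with `model` (best checkpoint, `phase = 2`), `history`.
#' @export
jointFinetune <- function(model, train_dfcs, val_dfcs, cfg, seed = 0L) {
  if (cfg$warmup_epochs > cfg$phase2_epochs)
    stop("warmup_epochs must not exceed phase2_epochs")
  if (length(train_dfcs) == 0L) stop("empty training set")
  L <- model@vae$arch$latent_dim
  st_vae <- adamInit(model@vae$params)
  st_mamba <- if (length(model@mamba)) adamInit(model@mamba$params) else NULL
  st_head <- adamInit(headParams(model@head))
  n <- length(train_dfcs)
  buf <- matrix(numeric(0), 0L, model@head$n_in)
  best <- list(acc = -Inf, loss = Inf, snap = modelSnapshot(model), epoch = 0L)
  hist <- data.frame()
  set.seed(deriveSeed(seed, "joint-train"))
  for (ep in seq_len(cfg$phase2_epochs)) {
    frozen <- ep <= cfg$warmup_epochs
    ord <- sample.int(n)
    ep_loss <- 0; ep_ce <- 0; n_b <- 0L
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      g_vae <- g_mamba <- g_head <- NULL
      b_loss <- 0
      for (i in idx) {
        d <- train_dfcs[[i]]
        K <- nrow(d@vectors)
        eps <- matrix(stats::rnorm(K * L), K, L)
        fw <- sessionForward(model, d@vectors, train_mode = TRUE, noise = eps)
        bw <- sessionBackward(model, fw, d@label, cfg$alpha, cfg$cls_weight)
        g_vae <- addGrads(g_vae, bw$vae)
        if (!is.null(bw$mamba)) g_mamba <- addGrads(g_mamba, bw$mamba)
        g_head <- addGrads(g_head, bw$head)
        b_loss <- b_loss + bw$loss
        buf <- rbind(buf, fw$context)
        if (nrow(buf) > 1024L) buf <- buf[(nrow(buf) - 1024L + 1L):nrow(buf), ,
                                          drop = FALSE]
      }
      nb <- length(idx)
      if (!frozen) {
        upd <- adamStep(model@vae$params, scaleGrads(g_vae, 1 / nb), st_vae,
                        cfg$lr_vae, cfg$adam_beta1, cfg$adam_beta2, cfg$adam_eps)
        model@vae$params <- upd$params; st_vae <- upd$state
      }
      if (!is.null(g_mamba)) {
        upd <- adamStep(model@mamba$params, scaleGrads(g_mamba, 1 / nb),
                        st_mamba, cfg$lr_mamba_kan, cfg$adam_beta1,
                        cfg$adam_beta2, cfg$adam_eps)
        model@mamba$params <- upd$params; st_mamba <- upd$state
      }
      upd <- adamStep(headParams(model@head), scaleGrads(g_head, 1 / nb),
                      st_head, cfg$lr_mamba_kan, cfg$adam_beta1,
                      cfg$adam_beta2, cfg$adam_eps)
      model@head <- headSetParams(model@head, upd$params)
      st_head <- upd$state
      ep_loss <- ep_loss + b_loss / nb; n_b <- n_b + 1L
    }
    # periodic KAN grid refresh from the activation buffer
    if (model@head$type == "kan" && cfg$grid_update_every > 0 &&
        ep %% cfg$grid_update_every == 0L && nrow(buf) > 8L) {
      h1 <- kanLayer(model@head$layer1, buf)
      model@head$layer1 <- suppressWarnings(updateGrid(model@head$layer1, buf))
      model@head$layer2 <- suppressWarnings(updateGrid(model@head$layer2, h1))
    }
    ev <- evaluateModel(model, val_dfcs)
    val_loss <- mean(vapply(val_dfcs, function(d) {
      fw <- sessionForward(model, d@vectors)
      ce <- -log(max(fw$probs[d@label + 1L], 1e-300))
      cfg$alpha * fw$vae_total + cfg$cls_weight * ce
    }, numeric(1)))
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss / n_b,
                                   val_acc = ev$accuracy, val_loss = val_loss,
                                   vae_frozen = frozen))
    if (ev$accuracy > best$acc ||
        (ev$accuracy == best$acc && val_loss < best$loss)) {
      best <- list(acc = ev$accuracy, loss = val_loss,
                   snap = modelSnapshot(model), epoch = ep)
    }
  }
  model <- modelRestore(model, best$snap)
  model@phase <- 2L
  list(model = model, history = hist, best_epoch = best$epoch)
}

#' Run the full two-phase pipeline on one split
#'
#' Builds a model from the configuration, pre-trains the VAE on the
#' training windows (phase 1, skipped for the `"no_pretrain"` variant),
#' jointly fine-tunes (phase 2) and evaluates on the test partition at the
#' subject level. Ablation variants: `"no_mamba"` (mean-pooled latents
#' straight to the KAN), `"mlp_head"` (Mamba + MLP head), `"mean_pool"`
#' (mean-pooled latents to an MLP head).
#'
#' @param dfcs list of [DFCSequence-class] sessions (whole cohort).
#' @param split subject-id split list (see [makeSubjectSplit()]).
#' @param config resolved configuration (see [defaultConfig()]).
#' @param seed RNG seed controlling initialization, noise, dropout and
#'   shuffling.
#' @param variant one of `"full"`, `"no_pretrain"`, `"no_mamba"`,
#'   `"mlp_head"`, `"mean_pool"`.
#' @return List with `model`, `report` (test metrics), `history`.
#' @export
trainPipeline <- function(dfcs, split, config, seed = 0L,
                          variant = c("full", "no_pretrain", "no_mamba",
                                      "mlp_head", "mean_pool")) {
  variant <- match.arg(variant)
  assertSplitLeakFree(split)
  if (variant %in% c("no_mamba", "mean_pool")) config$mamba$use_mamba <- FALSE
  if (variant %in% c("mlp_head", "mean_pool")) config$head$type <- "mlp"
  sid <- vapply(dfcs, function(d) d@subject_id, character(1))
  tr <- dfcs[sid %in% split$train]
  va <- dfcs[sid %in% split$val]
  te <- dfcs[sid %in% split$test]
  if (!length(tr) || !length(va) || !length(te))
    stop("every partition needs at least one session")
  model <- modelInit(config, seed)
  p1 <- NULL
  if (variant != "no_pretrain") {
    p1 <- pretrainVAE(model@vae, stackWindows(tr), stackWindows(va),
                      config$train$phase1_epochs,
                      config$train$phase1_batch_size %||% config$train$batch_size,
                      config$train$lr_phase1, seed)
    model@vae <- p1$vae
    model@phase <- 1L
  }
  p2 <- jointFinetune(model, tr, va, config$train, seed)
  report <- evaluateModel(p2$model, te)
  list(model = p2$model, report = report,
       history = list(phase1 = if (is.null(p1)) NULL else p1$history,
                      phase2 = p2$history))
}

#' Repeat a pipeline over seeds and compare to a baseline
#'
#' Runs [trainPipeline()] once per seed and tabulates per-seed test
#' metrics with mean and standard deviation. If `baseline` (a result of a
#' previous `multiSeedRun()` with the same seeds) is given, a two-sided
#' paired t-test on run-level accuracies is reported; zero-variance
#' difference vectors are flagged instead of crashing (t = 0, p = 1 when
#' all differences are zero; |t| = Inf, p = 0 when the differences are a
#' nonzero constant).
#'
#' @param dfcs,split,config as in [trainPipeline()].
#' @param seeds integer vector of seeds (default 0:4).
#' @param variant pipeline variant.
#' @param baseline optional result of a previous run to compare against.
#' @return List with `per_seed` (data.frame), `mean`, `sd`, and `vs_baseline`
#'   (NULL or list with `t`, `p`, `significant`, `flag`).
#' @export
multiSeedRun <- function(dfcs, split, config, seeds = 0:4,
                         variant = "full", baseline = NULL) {
  if (length(seeds) < 1L) stop("need at least one seed")
  rows <- lapply(seeds, function(s) {
    r <- trainPipeline(dfcs, split, config, s, variant)$report
    data.frame(seed = s, accuracy = r$accuracy, precision = r$precision,
               recall = r$recall, f1 = r$f1, auc = r$auc)
  })
  per_seed <- do.call(rbind, rows)
  res <- list(per_seed = per_seed,
              mean = colMeans(per_seed[, -1L], na.rm = TRUE),
              sd = apply(per_seed[, -1L], 2L, stats::sd),
              vs_baseline = NULL)
  if (!is.null(baseline)) {
    if (!identical(baseline$per_seed$seed, per_seed$seed))
      stop("baseline run used different seeds")
    res$vs_baseline <- pairedComparison(per_seed$accuracy,
                                        baseline$per_seed$accuracy)
  }
  res
}

#' Paired t-test of run-level accuracies
#'
#' Two-sided paired t-test (alpha = 0.05 decision flag) with degenerate
#' cases handled: all-zero differences give t = 0, p = 1; constant nonzero
#' differences give |t| = Inf, p = 0 — both flagged.
#'
#' @param x,y equal-length numeric vectors (e.g. per-seed accuracies).
#' @return List with `t`, `p`, `significant`, `flag`.
#' @export
pairedComparison <- function(x, y) {
  if (length(x) != length(y)) stop("runs have different lengths")
  d <- x - y
  if (stats::sd(d) == 0) {
    if (all(d == 0))
      return(list(t = 0, p = 1, significant = FALSE,
                  flag = "zero-variance (identical runs)"))
    return(list(t = sign(mean(d)) * Inf, p = 0, significant = TRUE,
                flag = "zero-variance (constant nonzero difference)"))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       significant = tt$p.value < 0.05, flag = NA_character_)
}
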