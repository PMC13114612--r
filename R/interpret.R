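# Three-layer interpretability: selectivity-based temporal importance
# profiles, KAN activation-curve ranking, and Jacobian attribution of class
# logits back to region-pair connectivity features.

#' Bundled AAL-116 region labels
#'
#' The 116 region names of the Automated Anatomical Labeling atlas, in
#' standard order, for labeling attribution maps computed on real
#' parcellated data. Synthetic runs default to `ROI_1..ROI_N`.
#'
#' @return Character vector of length 116.
#' @export
aalLabels <- function() {
  readLines(system.file("extdata", "aal116_labels.txt",
                        package = "dfcmamba"))
}

#' Class temporal-importance profile
#'
#' Runs every session of one class through the model, extracts the
#' selectivity scores `s_k` (mean time-step per window) from the recorded
#' trace, and averages across sessions. Optionally z-scores the class-mean
#' curve across its K windows (the default presentation, centering class
#' curves near zero).
#'
#' @param model a trained [DFCModel-class] with a Mamba stack.
#' @param dfcs list of [DFCSequence-class] sessions.
#' @param class_label 0-based class whose sessions are profiled.
#' @param zscore z-score the class-mean curve across windows (default
#'   `FALSE`).
#' @param trace_block which block's trace to use: `"first"` (default),
#'   `"last"`, or `"mean"` over blocks. The first block sits closest to the
#'   latent input and its time steps track window *content*; deeper blocks
#'   are free to develop position-dependent gating strategies, which makes
#'   their profiles less reproducible across training runs.
#' @return List with `class_label`, `mean_s`, `sd_s` (across sessions),
#'   `z` (z-scored mean curve or NULL) and `n_sessions`.
#' @export
classTemporalProfile <- function(model, dfcs, class_label, zscore = FALSE,
                                 trace_block = c("first", "last", "mean")) {
  trace_block <- match.arg(trace_block)
  if (!length(model@mamba)) stop("model has no Mamba stack (no traces)")
  sel <- Filter(function(d) d@label == class_label, dfcs)
  if (!length(sel)) stop(sprintf("no sessions with class %d", class_label))
  S <- vapply(sel, function(d) {
    tr <- predictSession(model, d)$traces
    switch(trace_block,
           first = selectivityScores(tr[[1L]]),
           last = selectivityScores(tr[[length(tr)]]),
           mean = rowMeans(vapply(tr, selectivityScores,
                                  numeric(nrow(tr[[1L]]@delta)))))
  }, numeric(nrow(sel[[1L]]@vectors)))
  mean_s <- rowMeans(S)
  sd_s <- apply(S, 1L, stats::sd)
  z <- NULL
  if (zscore) z <- (mean_s - mean(mean_s)) / stats::sd(mean_s)
  list(class_label = as.integer(class_label), mean_s = mean_s, sd_s = sd_s,
       z = z, n_sessions = length(sel))
}

#' Rank first-layer KAN inputs by activation influence
#'
#' Influence of input dimension i = mean over probe vectors and over output
#' units j of `|phi_{j,i}(x_i)|` in the first KAN layer. The top-ranked
#' dimensions' activation curves are extracted for inspection.
#'
#' @param model a trained [DFCModel-class] with a KAN head.
#' @param probes matrix of context vectors (rows), e.g. the evaluation-set
#'   contexts; see [modelContexts()].
#' @param top_k number of top dimensions whose curves to extract (clamped
#'   to the layer width with a warning).
#' @param n_points samples per extracted curve.
#' @return List with `influence` (named vector, descending), `ranking`
#'   (input indices) and `curves` (list of [extractCurve()] results of the
#'   top edge per ranked input, named `"j<out>_i<in>"`).
#' @export
rankActivationCurves <- function(model, probes, top_k = 10L, n_points = 100L) {
  if (model@head$type != "kan") stop("head is not a KAN")
  layer <- model@head$layer1
  if (top_k > layer$n_in) {
    warning(sprintf("top_k clamped from %d to n_in = %d", top_k, layer$n_in))
    top_k <- layer$n_in
  }
  nb <- nBasis(layer$grid)
  # per-edge |phi| averaged over probes, then over outputs j
  infl <- numeric(layer$n_in)
  edge_mean <- matrix(0, layer$n_out, layer$n_in)
  for (i in seq_len(layer$n_in)) {
    x <- probes[, i]
    Phi <- bsplineBasis(x, layer$grid)
    cf <- layer$coef[((i - 1L) * nb + 1L):(i * nb), , drop = FALSE]
    vals <- outer(baseFun(x, layer$base_activation), layer$wb[, i]) + Phi %*% cf
    edge_mean[, i] <- colMeans(abs(vals))
    infl[i] <- mean(abs(vals))
  }
  ranking <- order(infl, decreasing = TRUE)
  top <- ranking[seq_len(top_k)]
  curves <- lapply(top, function(i) {
    j <- which.max(edge_mean[, i])
    c(list(j = j, i = i), extractCurve(layer, j, i, n_points))
  })
  names(curves) <- vapply(curves, function(cv) sprintf("j%d_i%d", cv$j, cv$i),
                          character(1))
  list(influence = infl[ranking], ranking = ranking, curves = curves)
}

#' Evaluation-time context vectors
#'
#' Convenience helper: the temporal context vector of every session,
#' stacked into a matrix (rows = sessions) for use as activation probes.
#'
#' @param model a trained [DFCModel-class].
#' @param dfcs list of [DFCSequence-class] sessions.
#' @return n_sessions x d_model matrix.
#' @export
modelContexts <- function(model, dfcs) {
  t(vapply(dfcs, function(d) {
    sessionForward(model, d@vectors)$context
  }, numeric(model@head$n_in)))
}

#' Jacobian attribution of a class logit to connectivity features
#'
#' The gradient of the target-class logit with respect to every window's
#' input features, averaged over the K windows of a session and then over
#' sessions, mapped back to a symmetric N x N matrix with zero diagonal.
#' Computed on the deterministic evaluation path through the full pipeline
#' (encoder mean, temporal encoder, head). When the model consumes
#' unit-rescaled correlations, `per_r = TRUE` converts the scores to
#' per-correlation units via the chain-rule factor 1/2.
#'
#' @param model a trained [DFCModel-class].
#' @param dfcs a [DFCSequence-class] or list of them (typically the test
#'   sessions of one class).
#' @param class_label 0-based target class.
#' @param roi_names optional region names (default `ROI_1..ROI_N`).
#' @param per_r report scores per correlation unit rather than per model
#'   input unit (default `FALSE`).
#' @return An [AttributionMatrix-class].
#' @export
gradientAttribution <- function(model, dfcs, class_label, roi_names = NULL,
                                per_r = FALSE) {
  if (is(dfcs, "DFCSequence")) dfcs <- list(dfcs)
  if (!length(dfcs)) stop("no sessions supplied")
  C <- model@head$n_classes
  if (class_label < 0L || class_label >= C) stop("class index out of range")
  n <- dfcs[[1L]]@n_rois
  acc <- NULL
  for (d in dfcs) {
    G <- modelInputGradient(model, d@vectors, class_label)
    a <- colMeans(G)                       # 1/K sum_k d logit / d v_k
    acc <- if (is.null(acc)) a else acc + a
  }
  a <- acc / length(dfcs)
  if (per_r && dfcs[[1L]]@rescaled) a <- a / 2
  A <- devectorize(a, n, diagonal = 0)
  if (is.null(roi_names)) roi_names <- paste0("ROI_", seq_len(n))
  new("AttributionMatrix", class_label = as.integer(class_label),
      values = A, roi_names = roi_names)
}

#' Keep the top percent of attributed connections
#'
#' Ranks the D = N(N-1)/2 unique region pairs by `|a_ij|` and keeps the
#' `ceiling(percent / 100 * D)` strongest, ties at the cutoff broken by
#' (i, j) lexicographic order.
#'
#' @param attribution an [AttributionMatrix-class].
#' @param percent percentage of connections to keep, in (0, 100].
#' @return data.frame with 1-based `i`, `j`, `roi_i`, `roi_j`, `score`,
#'   sorted by descending `|score|`.
#' @export
thresholdTopPercent <- function(attribution, percent = 1) {
  stopifnot(percent > 0, percent <= 100)
  A <- attribution@values
  n <- nrow(A)
  ut <- which(upper.tri(A), arr.ind = TRUE)
  df <- data.frame(i = ut[, 1L], j = ut[, 2L], score = A[ut])
  keep <- ceiling(percent / 100 * nrow(df))
  ord <- order(-abs(df$score), df$i, df$j)
  df <- df[ord[seq_len(keep)], ]
  df$roi_i <- attribution@roi_names[df$i]
  df$roi_j <- attribution@roi_names[df$j]
  rownames(df) <- NULL
  df[, c("i", "j", "roi_i", "roi_j", "score")]
}

#' Rank regions by attribution strength
#'
#' Node strength per region: `strength_i = sum_j |a_ij|` over incident
#' connections, ranked descending.
#'
#' @param attribution an [AttributionMatrix-class].
#' @param top_n number of regions to report (default 20, clamped to N).
#' @return data.frame with `rank`, `roi`, `strength`.
#' @export
regionRanking <- function(attribution, top_n = 20L) {
  s <- rowSums(abs(attribution@values))
  top_n <- min(top_n, length(s))
  ord <- order(s, decreasing = TRUE)[seq_len(top_n)]
  data.frame(rank = seq_len(top_n), roi = attribution@roi_names[ord],
             strength = s[ord], row.names = NULL)
}
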