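#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib dfcmamba, .registration = TRUE
NULL

#' ROI time series for one scan session
#'
#' Container for the regional BOLD signals of a single resting-state fMRI
#' scan session after parcellation: an N x T matrix (N regions of interest,
#' T time points) together with subject/session identifiers, a 0-based class
#' label and the repetition time.
#'
#' @slot subject_id character(1), subject identifier.
#' @slot session_id character(1), session identifier (unique within subject).
#' @slot label integer(1), 0-based class index.
#' @slot data numeric matrix, N x T, one row per ROI.
#' @slot tr_seconds numeric(1), repetition time in seconds.
#'
#' @seealso [ROITimeSeries()] for the constructor, [buildDFC()] for the
#'   sliding-window correlation pipeline.
#' @export
setClass("ROITimeSeries",
  representation(
    subject_id = "character",
    session_id = "character",
    label      = "integer",
    data       = "matrix",
    tr_seconds = "numeric"
  )
)

setValidity("ROITimeSeries", function(object) {
  msgs <- character()
  d <- object@data
  if (!is.numeric(d)) msgs <- c(msgs, "data must be a numeric matrix")
  if (nrow(d) < 2L) msgs <- c(msgs, "need at least 2 ROIs")
  if (ncol(d) < 2L) msgs <- c(msgs, "need at least 2 time points")
  if (is.numeric(d) && any(!is.finite(d)))
    msgs <- c(msgs, "data contains non-finite entries")
  if (length(object@label) != 1L || is.na(object@label) || object@label < 0L)
    msgs <- c(msgs, "label must be a single non-negative integer")
  if (length(object@tr_seconds) != 1L || object@tr_seconds <= 0)
    msgs <- c(msgs, "tr_seconds must be a positive scalar")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn ROITimeSeries-class Constructor.
#' @param subject_id,session_id character identifiers.
#' @param label 0-based integer class index.
#' @param data numeric N x T matrix (rows = ROIs).
#' @param tr_seconds repetition time in seconds.
#' @return A validated `ROITimeSeries` object.
#' @examples
#' ts <- ROITimeSeries("s1", "s1_a", 0L, matrix(rnorm(40), 4, 10), 3.0)
#' nROIs(ts)
#' @export
ROITimeSeries <- function(subject_id, session_id, label, data,
                          tr_seconds = 3.0) {
  new("ROITimeSeries",
      subject_id = as.character(subject_id),
      session_id = as.character(session_id),
      label = as.integer(label),
      data = data,
      tr_seconds = as.numeric(tr_seconds))
}

#' Sliding-window dynamic functional connectivity sequence
#'
#' The vectorized dFC representation of one session: a K x D matrix whose
#' k-th row holds the upper-triangular entries (row-major over pairs i < j)
#' of the Pearson correlation matrix of window k, with D = N(N-1)/2. Window
#' starts are 0-based; window k covers time points `[start, start + Lw)`.
#'
#' @slot subject_id,session_id character identifiers.
#' @slot label integer(1), 0-based class index.
#' @slot vectors numeric K x D matrix of correlations (or unit-rescaled
#'   correlations when built with `rescale_to_unit = TRUE`).
#' @slot window_starts integer K, 0-based window start indices.
#' @slot n_rois integer(1), N.
#' @slot rescaled logical(1), whether entries live in `[0, 1]` rather than
#'   `[-1, 1]`.
#'
#' @export
setClass("DFCSequence",
  representation(
    subject_id    = "character",
    session_id    = "character",
    label         = "integer",
    vectors       = "matrix",
    window_starts = "integer",
    n_rois        = "integer",
    rescaled      = "logical"
  )
)

setValidity("DFCSequence", function(object) {
  msgs <- character()
  v <- object@vectors
  n <- object@n_rois
  if (ncol(v) != n * (n - 1L) / 2L)
    msgs <- c(msgs, "ncol(vectors) must equal n_rois*(n_rois-1)/2")
  if (nrow(v) != length(object@window_starts))
    msgs <- c(msgs, "one window start per row required")
  lo <- if (isTRUE(object@rescaled)) 0 else -1
  hi <- 1
  if (any(v < lo - 1e-12 | v > hi + 1e-12))
    msgs <- c(msgs, sprintf("entries outside [%g, %g]", lo, hi))
  if (length(msgs)) msgs else TRUE
})

#' Latent sequence of per-window VAE encodings
#'
#' K x L matrix of latent vectors, one row per dFC window, produced by
#' encoding each window independently (no cross-window mixing). `source`
#' records whether rows are posterior means (deterministic, evaluation) or
#' reparameterized samples (training).
#'
#' @slot values numeric K x L matrix.
#' @slot source character(1), `"posterior-mean"` or `"sampled"`.
#' @slot subject_id,session_id character identifiers.
#' @slot label integer(1), 0-based class index.
#'
#' @export
setClass("LatentSequence",
  representation(
    values     = "matrix",
    source     = "character",
    subject_id = "character",
    session_id = "character",
    label      = "integer"
  )
)

setValidity("LatentSequence", function(object) {
  msgs <- character()
  if (!object@source %in% c("posterior-mean", "sampled"))
    msgs <- c(msgs, "source must be 'posterior-mean' or 'sampled'")
  if (any(!is.finite(object@values)))
    msgs <- c(msgs, "latent values must be finite")
  if (length(msgs)) msgs else TRUE
})

#' Selectivity trace of the S6 scan
#'
#' Per-window, per-channel time-step values Delta recorded during the
#' selective scan of one Mamba block. All entries are strictly positive
#' (softplus-parameterized). Row means give the temporal importance scores.
#'
#' @slot delta numeric K x d_inner matrix of time-step values.
#' @slot block integer(1), 1-based index of the block the trace came from.
#'
#' @seealso [selectivityScores()]
#' @export
setClass("SelectivityTrace",
  representation(delta = "matrix", block = "integer")
)

setValidity("SelectivityTrace", function(object) {
  if (length(object@delta) == 0L) return("empty trace")
  if (any(object@delta <= 0)) return("all time-step values must be > 0")
  TRUE
})

#' Jacobian attribution map over region pairs
#'
#' Symmetric N x N matrix of connection-level attribution scores for one
#' target class: the gradient of the class logit with respect to each
#' windowed connectivity feature, averaged over windows (and typically over
#' the sessions of the class). The diagonal is zero; per-region strength is
#' the sum of absolute attributions over incident connections.
#'
#' @slot class_label integer(1), 0-based target class.
#' @slot values numeric N x N symmetric matrix, zero diagonal.
#' @slot roi_names character N.
#'
#' @seealso [gradientAttribution()], [regionRanking()], [thresholdTopPercent()]
#' @export
setClass("AttributionMatrix",
  representation(
    class_label = "integer",
    values      = "matrix",
    roi_names   = "character"
  )
)

setValidity("AttributionMatrix", function(object) {
  msgs <- character()
  a <- object@values
  if (nrow(a) != ncol(a)) msgs <- c(msgs, "values must be square")
  else {
    if (max(abs(a - t(a))) > 1e-8) msgs <- c(msgs, "values must be symmetric")
    if (max(abs(diag(a))) > 1e-12) msgs <- c(msgs, "diagonal must be zero")
    if (length(object@roi_names) != nrow(a))
      msgs <- c(msgs, "one roi name per region required")
  }
  if (length(msgs)) msgs else TRUE
})

#' Fitted dFC sequence classifier
#'
#' Bundles the three trainable components (VAE, Mamba stack, KAN head or an
#' ablation substitute), their configurations, and training provenance
#' (phase tag, seed). Parameters are stored as plain named lists of numeric
#' arrays; use the accessors rather than reaching into slots.
#'
#' @slot vae list, VAE parameters (see [vaeInit()]).
#' @slot mamba list, Mamba stack parameters (see [mambaInit()]); may be
#'   empty for the mean-pooling ablation.
#' @slot head list, classifier head parameters (KAN or MLP).
#' @slot config list, resolved configuration (all sections).
#' @slot phase integer(1), 0 = untrained, 1 = VAE pre-trained, 2 = jointly
#'   fine-tuned.
#' @slot seed integer(1), training seed.
#'
#' @export
setClass("DFCModel",
  representation(
    vae    = "list",
    mamba  = "list",
    head   = "list",
    config = "list",
    phase  = "integer",
    seed   = "integer"
  )
)

# ---- show methods -----------------------------------------------------------

setMethod("show", "ROITimeSeries", function(object) {
  cat(sprintf("ROITimeSeries: subject %s, session %s, label %d\n",
              object@subject_id, object@session_id, object@label))
  cat(sprintf("  %d ROIs x %d time points, TR = %.2f s\n",
              nrow(object@data), ncol(object@data), object@tr_seconds))
})

setMethod("show", "DFCSequence", function(object) {
  cat(sprintf("DFCSequence: subject %s, session %s, label %d\n",
              object@subject_id, object@session_id, object@label))
  cat(sprintf("  %d windows x %d features (N = %d ROIs)%s\n",
              nrow(object@vectors), ncol(object@vectors), object@n_rois,
              if (object@rescaled) ", rescaled to [0, 1]" else ""))
})

setMethod("show", "LatentSequence", function(object) {
  cat(sprintf("LatentSequence: %d windows x %d latent dims (%s)\n",
              nrow(object@values), ncol(object@values), object@source))
})

setMethod("show", "SelectivityTrace", function(object) {
  cat(sprintf("SelectivityTrace: block %d, %d windows x %d channels\n",
              object@block, nrow(object@delta), ncol(object@delta)))
})

setMethod("show", "AttributionMatrix", function(object) {
  cat(sprintf("AttributionMatrix: class %d, %d x %d regions\n",
              object@class_label, nrow(object@values), ncol(object@values)))
})

setMethod("show", "DFCModel", function(object) {
  tag <- c("untrained", "VAE pre-trained", "jointly fine-tuned")[object@phase + 1L]
  cat(sprintf("DFCModel (%s, seed %d)\n", tag, object@seed))
  cat(sprintf("  VAE: [%s] -> L = %d\n",
              paste(object@config$vae$encoder_dims, collapse = ", "),
              object@config$vae$latent_dim))
  if (length(object@mamba))
    cat(sprintf("  Mamba: %d blocks, d_model = %d, d_state = %d\n",
                object@config$mamba$n_layers, object@config$mamba$d_model,
                object@config$mamba$d_state))
  else cat("  Temporal encoder: mean pooling (no Mamba)\n")
  cat(sprintf("  Head: %s -> %d classes\n",
              object@config$head$type, object@config$head$n_classes))
})

# ---- accessors --------------------------------------------------------------

#' Accessors for dfcmamba containers
#'
#' Small read-only accessors for the S4 containers: identifiers, labels,
#' matrices and dimensions.
#'
#' @param x an object of the documented class.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("sessionId", function(x) standardGeneric("sessionId"))
#' @rdname accessors
#' @export
setGeneric("classLabel", function(x) standardGeneric("classLabel"))
#' @rdname accessors
#' @export
setGeneric("seriesData", function(x) standardGeneric("seriesData"))
#' @rdname accessors
#' @export
setGeneric("dfcVectors", function(x) standardGeneric("dfcVectors"))
#' @rdname accessors
#' @export
setGeneric("windowStarts", function(x) standardGeneric("windowStarts"))
#' @rdname accessors
#' @export
setGeneric("nROIs", function(x) standardGeneric("nROIs"))
#' @rdname accessors
#' @export
setGeneric("latentValues", function(x) standardGeneric("latentValues"))
#' @rdname accessors
#' @export
setGeneric("traceDelta", function(x) standardGeneric("traceDelta"))
#' @rdname accessors
#' @export
setGeneric("attributionValues", function(x) standardGeneric("attributionValues"))
#' @rdname accessors
#' @export
setGeneric("roiNames", function(x) standardGeneric("roiNames"))
#' @rdname accessors
#' @export
setGeneric("modelConfig", function(x) standardGeneric("modelConfig"))
#' @rdname accessors
#' @export
setGeneric("trainingPhase", function(x) standardGeneric("trainingPhase"))

#' @rdname accessors
#' @export
setMethod("subjectId", "ROITimeSeries", function(x) x@subject_id)
#' @rdname accessors
#' @export
setMethod("subjectId", "DFCSequence", function(x) x@subject_id)
#' @rdname accessors
#' @export
setMethod("sessionId", "ROITimeSeries", function(x) x@session_id)
#' @rdname accessors
#' @export
setMethod("sessionId", "DFCSequence", function(x) x@session_id)
#' @rdname accessors
#' @export
setMethod("classLabel", "ROITimeSeries", function(x) x@label)
#' @rdname accessors
#' @export
setMethod("classLabel", "DFCSequence", function(x) x@label)
#' @rdname accessors
#' @export
setMethod("classLabel", "AttributionMatrix", function(x) x@class_label)
#' @rdname accessors
#' @export
setMethod("seriesData", "ROITimeSeries", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("dfcVectors", "DFCSequence", function(x) x@vectors)
#' @rdname accessors
#' @export
setMethod("windowStarts", "DFCSequence", function(x) x@window_starts)
#' @rdname accessors
#' @export
setMethod("nROIs", "ROITimeSeries", function(x) nrow(x@data))
#' @rdname accessors
#' @export
setMethod("nROIs", "DFCSequence", function(x) x@n_rois)
#' @rdname accessors
#' @export
setMethod("nROIs", "AttributionMatrix", function(x) nrow(x@values))
#' @rdname accessors
#' @export
setMethod("latentValues", "LatentSequence", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("traceDelta", "SelectivityTrace", function(x) x@delta)
#' @rdname accessors
#' @export
setMethod("attributionValues", "AttributionMatrix", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("roiNames", "AttributionMatrix", function(x) x@roi_names)
#' @rdname accessors
#' @export
setMethod("modelConfig", "DFCModel", function(x) x@config)
#' @rdname accessors
#' @export
setMethod("trainingPhase", "DFCModel", function(x) x@phase)
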