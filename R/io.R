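# Dataset I/O (per-session CSV matrices, labels table, split JSON),
# checkpoint serialization and dataset validation.

#' Write a cohort to disk
#'
#' Layout: `sessions/<session_id>.csv` (N rows x T columns, no header),
#' `labels.csv` (`subject_id`, `session_id`, `class_label`) and
#' `split.json` (`{"train": [...], "val": [...], "test": [...]}`) — exactly
#' the formats the loaders consume.
#'
#' @param cohort result of [generateCohort()] (or a list with the same
#'   shape).
#' @param dir output directory (created if needed).
#' @return Invisibly `dir`.
#' @export
writeCohort <- function(cohort, dir) {
  sess_dir <- file.path(dir, "sessions")
  dir.create(sess_dir, recursive = TRUE, showWarnings = FALSE)
  for (ts in cohort$sessions) {
    utils::write.table(ts@data,
                       file.path(sess_dir, paste0(ts@session_id, ".csv")),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  utils::write.csv(cohort$labels, file.path(dir, "labels.csv"),
                   row.names = FALSE)
  jsonlite::write_json(cohort$split, file.path(dir, "split.json"))
  invisible(dir)
}

#' Read one session matrix
#'
#' Accepts N x T CSV/TSV matrices, optionally with a header row of time
#' indices and/or a first column of ROI names; rejects non-finite entries.
#'
#' @param path CSV/TSV file.
#' @param subject_id,session_id,label,tr_seconds metadata for the object.
#' @return An [ROITimeSeries-class].
#' @export
readROISession <- function(path, subject_id, session_id, label,
                           tr_seconds = 3.0) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = FALSE,
                           stringsAsFactors = FALSE)
  # optional header row (any non-numeric cell in row 1 beyond column 1)
  first_row <- suppressWarnings(as.numeric(unlist(raw[1L, -1L])))
  if (anyNA(first_row)) raw <- raw[-1L, , drop = FALSE]
  # optional ROI-name column
  first_col <- suppressWarnings(as.numeric(raw[[1L]]))
  if (anyNA(first_col)) raw <- raw[, -1L, drop = FALSE]
  m <- as.matrix(raw)
  mode(m) <- "numeric"
  if (any(!is.finite(m))) {
    bad <- which(rowSums(!is.finite(m)) > 0)
    stop(sprintf("non-finite entries in %s (row %s)", path,
                 paste(bad, collapse = ", ")))
  }
  dimnames(m) <- NULL
  ROITimeSeries(subject_id, session_id, label, m, tr_seconds)
}

#' Read a cohort directory
#'
#' Inverse of [writeCohort()]: loads all session matrices listed in the
#' labels table, plus the split JSON if present.
#'
#' @param dir cohort directory.
#' @param tr_seconds repetition time to attach to sessions.
#' @return List with `sessions`, `labels`, `split` (`NULL` if absent).
#' @export
readCohort <- function(dir, tr_seconds = 3.0) {
  labels <- utils::read.csv(file.path(dir, "labels.csv"),
                            stringsAsFactors = FALSE)
  sessions <- lapply(seq_len(nrow(labels)), function(i) {
    readROISession(file.path(dir, "sessions",
                             paste0(labels$session_id[i], ".csv")),
                   labels$subject_id[i], labels$session_id[i],
                   labels$class_label[i], tr_seconds)
  })
  split_path <- file.path(dir, "split.json")
  split <- if (file.exists(split_path)) {
    s <- jsonlite::read_json(split_path, simplifyVector = TRUE)
    lapply(s, as.character)
  } else NULL
  list(sessions = sessions, labels = labels, split = split)
}

#' Validate a cohort directory
#'
#' Checks matrix shapes, finiteness, label coverage and session/subject
#' consistency; returns a report with summary counts and a character
#' vector of violations (empty when clean).
#'
#' @param dir cohort directory (see [writeCohort()] for the layout).
#' @return List with `ok`, `violations`, `n_subjects`, `n_sessions`,
#'   `per_class` (session counts per class).
#' @export
validateDataset <- function(dir) {
  violations <- character()
  labels_path <- file.path(dir, "labels.csv")
  if (!file.exists(labels_path))
    return(list(ok = FALSE, violations = "labels.csv missing",
                n_subjects = 0L, n_sessions = 0L, per_class = integer()))
  labels <- utils::read.csv(labels_path, stringsAsFactors = FALSE)
  need <- c("subject_id", "session_id", "class_label")
  if (!all(need %in% names(labels)))
    violations <- c(violations, sprintf("labels.csv lacks columns: %s",
      paste(setdiff(need, names(labels)), collapse = ", ")))
  shapes <- list()
  for (i in seq_len(nrow(labels))) {
    f <- file.path(dir, "sessions", paste0(labels$session_id[i], ".csv"))
    if (!file.exists(f)) {
      violations <- c(violations, sprintf("missing session file: %s", f))
      next
    }
    m <- tryCatch(as.matrix(utils::read.csv(f, header = FALSE)),
                  error = function(e) NULL)
    if (is.null(m)) {
      violations <- c(violations, sprintf("unreadable session file: %s", f))
      next
    }
    mode(m) <- "numeric"
    if (any(!is.finite(m))) {
      bad <- which(rowSums(!is.finite(m)) > 0)[1L]
      violations <- c(violations,
        sprintf("non-finite values in %s (row %d)", basename(f), bad))
    }
    shapes[[length(shapes) + 1L]] <- dim(m)
  }
  if (length(shapes) > 1L) {
    dd <- unique(do.call(rbind, shapes))
    if (nrow(dd) > 1L)
      violations <- c(violations, "inconsistent session matrix shapes")
  }
  subj_cls <- unique(labels[, c("subject_id", "class_label")])
  if (anyDuplicated(subj_cls$subject_id))
    violations <- c(violations, "a subject carries multiple class labels")
  list(ok = length(violations) == 0L, violations = violations,
       n_subjects = length(unique(labels$subject_id)),
       n_sessions = nrow(labels),
       per_class = table(labels$class_label))
}

#' Save a model checkpoint
#'
#' Single-file serialized container with the full parameter set,
#' architecture metadata, training phase tag and package version; bitwise
#' round-trip guaranteed by [loadCheckpoint()].
#'
#' @param model a [DFCModel-class].
#' @param path output path.
#' @return Invisibly `path`.
#' @export
saveCheckpoint <- function(model, path) {
  saveRDS(list(format = "dfcmamba-checkpoint",
               version = as.character(utils::packageVersion("dfcmamba")),
               phase = model@phase, seed = model@seed,
               config = model@config, vae = model@vae,
               mamba = model@mamba, head = model@head),
          path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' Restores a [DFCModel-class] saved by [saveCheckpoint()]; corrupt files
#' and architecture mismatches produce clean errors.
#'
#' @param path checkpoint path.
#' @param expect_config optional configuration that the checkpoint must
#'   match (sections `vae`, `mamba`, `head`).
#' @return A [DFCModel-class].
#' @export
loadCheckpoint <- function(path, expect_config = NULL) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop(sprintf("cannot read checkpoint %s: %s", path, conditionMessage(e))))
  if (!is.list(obj) || !identical(obj$format, "dfcmamba-checkpoint"))
    stop(sprintf("%s is not a dfcmamba checkpoint", path))
  if (!is.null(expect_config)) {
    for (sec in c("vae", "mamba", "head")) {
      if (!identical(obj$config[[sec]], expect_config[[sec]]))
        stop(sprintf("checkpoint architecture mismatch in section '%s'", sec))
    }
  }
  new("DFCModel", vae = obj$vae, mamba = obj$mamba, head = obj$head,
      config = obj$config, phase = obj$phase, seed = obj$seed)
}

#' Initialize a model from a phase-1 checkpoint
#'
#' Copies only the VAE parameters from a phase-1 checkpoint into a freshly
#' initialized model (Mamba and head remain at their random init), the
#' phase-2 starting point.
#'
#' @param model a [DFCModel-class] (fresh).
#' @param ckpt_path path to a phase-1 checkpoint.
#' @return The model with the pre-trained VAE, `phase = 1`.
#' @export
applyVAECheckpoint <- function(model, ckpt_path) {
  ck <- loadCheckpoint(ckpt_path)
  if (ck@phase < 1L) stop("checkpoint is not pre-trained (phase 0)")
  if (!identical(ck@vae$arch, model@vae$arch))
    stop("VAE architecture mismatch between checkpoint and model")
  model@vae$params <- ck@vae$params
  model@phase <- 1L
  model
}
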