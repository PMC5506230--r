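#' EEG recording container
#'
#' A minimal multichannel EEG container: a samples-by-channels numeric matrix
#' with electrode labels as column names and a sampling rate in Hz. Values
#' are in microvolts.
#'
#' @param data Numeric matrix, samples in rows, channels in columns. Column
#'   names are the electrode labels.
#' @param srate Sampling rate in Hz.
#' @return An object of class `mweeg_recording`.
#' @export
new_recording <- function(data, srate) {
  stopifnot(is.matrix(data), is.numeric(data), srate > 0)
  if (is.null(colnames(data))) stop("recording data must have electrode labels as colnames",
                                    call. = FALSE)
  structure(list(data = data, srate = srate), class = "mweeg_recording")
}

#' @export
print.mweeg_recording <- function(x, ...) {
  cat(sprintf("<EEG recording: %d channels x %d samples (%.1f s at %g Hz)>\n",
              ncol(x$data), nrow(x$data), nrow(x$data) / x$srate, x$srate))
  cat("  channels:", paste(colnames(x$data), collapse = " "), "\n")
  invisible(x)
}

#' Session annotations container
#'
#' Section boundaries, probe answers and per-trial reaction times for one
#' recording session. Sections are contiguous blocks of task EEG; each ends
#' with one thought probe answered on a 7-point Likert scale (1 =
#' task-centered, 7 = task-independent).
#'
#' @param section_onsets Numeric vector, onset of each section in seconds
#'   from the start of the recording.
#' @param section_duration Duration of each section in seconds.
#' @param probe_answers Integer vector in 1..7, one per section.
#' @param rts List of numeric vectors, per-trial reaction times (s) for each
#'   section.
#' @return An object of class `mweeg_annotations`.
#' @export
new_annotations <- function(section_onsets, section_duration, probe_answers, rts) {
  stopifnot(length(section_onsets) == length(probe_answers),
            length(section_onsets) == length(rts))
  if (!all(probe_answers %in% 1:7))
    stop("probe answers must be integers in 1..7", call. = FALSE)
  structure(list(section_onsets = section_onsets,
                 section_duration = section_duration,
                 probe_answers = as.integer(probe_answers),
                 rts = rts,
                 n_sections = length(section_onsets)),
            class = "mweeg_annotations")
}

#' @export
print.mweeg_annotations <- function(x, ...) {
  cat(sprintf("<session annotations: %d sections of %g s, probe answers %s>\n",
              x$n_sections, x$section_duration,
              paste(range(x$probe_answers), collapse = "-")))
  invisible(x)
}

#' Write / read a session to a plain container on disk
#'
#' Serializes a recording plus annotations as a raw little-endian double
#' matrix (`<stem>.dat`, column-major samples-by-channels) with a JSON
#' sidecar (`<stem>.json`) holding dimensions, electrode labels, sampling
#' rate and annotations. The format is deliberately trivial so that any
#' numerical environment can read it back.
#'
#' @param recording An `mweeg_recording`.
#' @param annotations An `mweeg_annotations` (optional for `write_session`).
#' @param stem Path stem; `.dat` and `.json` are appended.
#' @return `write_session` returns `stem` invisibly; `read_session` returns
#'   a list with elements `recording` and `annotations`.
#' @export
write_session <- function(recording, annotations = NULL, stem) {
  con <- file(paste0(stem, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.vector(recording$data), con, size = 8, endian = "little")
  meta <- list(n_samples = nrow(recording$data),
               channels = colnames(recording$data),
               srate = recording$srate)
  if (!is.null(annotations))
    meta$annotations <- list(section_onsets = annotations$section_onsets,
                             section_duration = annotations$section_duration,
                             probe_answers = annotations$probe_answers,
                             rts = annotations$rts)
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' @rdname write_session
#' @export
read_session <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  n <- meta$n_samples * length(meta$channels)
  con <- file(paste0(stem, ".dat"), "rb")
  on.exit(close(con))
  x <- readBin(con, "double", n = n, size = 8, endian = "little")
  rec <- new_recording(matrix(x, nrow = meta$n_samples,
                              dimnames = list(NULL, meta$channels)), meta$srate)
  ann <- NULL
  if (!is.null(meta$annotations)) {
    a <- meta$annotations
    rts <- a$rts
    if (is.matrix(rts)) rts <- lapply(seq_len(nrow(rts)), function(i) rts[i, ])
    ann <- new_annotations(a$section_onsets, a$section_duration, a$probe_answers, rts)
  }
  list(recording = rec, annotations = ann)
}
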