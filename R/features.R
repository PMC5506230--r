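#' Cut a recording into 1-s epochs aligned to sections
#'
#' Divides the task EEG into non-overlapping 1-s epochs that never span a
#' section boundary. With the default session geometry each section
#' contributes `trials_per_section * trial_interval` epochs (20), so a
#' default 42-section session yields 840 epochs. Probe and instruction time
#' is not part of the recording and therefore not epoched.
#'
#' @param recording An `mweeg_recording`.
#' @param annotations Matching `mweeg_annotations`; section onsets must fall
#'   on whole seconds.
#' @return An object of class `mweeg_epochs`: a samples x channels x epochs
#'   array plus per-epoch section indices and artifact flags.
#' @export
segment_epochs <- function(recording, annotations) {
  srate <- recording$srate
  on <- annotations$section_onsets
  dur <- annotations$section_duration
  if (any(abs(on - round(on)) > 1e-9) || abs(dur - round(dur)) > 1e-9)
    stop("section boundaries must align with whole seconds", call. = FALSE)
  if (abs(dur * srate - round(dur * srate)) > 1e-9)
    stop("section duration must be a whole number of samples", call. = FALSE)
  need <- (max(on) + dur) * srate
  if (nrow(recording$data) < need)
    stop(sprintf("recording truncated: %d samples present, %d required by annotations",
                 nrow(recording$data), as.integer(need)), call. = FALSE)
  per_sec <- as.integer(dur)                   # 1-s epochs per section
  n_epochs <- per_sec * annotations$n_sections
  C <- ncol(recording$data)
  data <- array(0, c(srate, C, n_epochs),
                dimnames = list(NULL, colnames(recording$data), NULL))
  section <- integer(n_epochs)
  k <- 0L
  for (s in seq_len(annotations$n_sections)) {
    s0 <- on[s] * srate
    for (e in seq_len(per_sec)) {
      k <- k + 1L
      data[, , k] <- recording$data[s0 + (e - 1L) * srate + seq_len(srate), ]
      section[k] <- s
    }
  }
  structure(list(data = data, section = section,
                 flagged = rep(FALSE, n_epochs),
                 srate = srate, channels = colnames(recording$data)),
            class = "mweeg_epochs")
}

#' @export
print.mweeg_epochs <- function(x, ...) {
  cat(sprintf("<%d epochs of %d samples x %d channels; %d flagged as artifact>\n",
              dim(x$data)[3], dim(x$data)[1], dim(x$data)[2], sum(x$flagged)))
  invisible(x)
}

#' Flag artifact-contaminated epochs
#'
#' An epoch is flagged when any channel exceeds a peak-to-peak amplitude
#' threshold or a sample-to-sample gradient threshold. Flagged epochs are
#' excluded from all spectral estimates downstream; sections left with fewer
#' than `min_clean` clean epochs are dropped entirely (recorded in the
#' `dropped_sections` attribute).
#'
#' The thresholds replace the proprietary vendor detection rule of the
#' acquisition software with a documented, testable equivalent. Defaults
#' (200 microvolts peak-to-peak, 150 microvolts per sample) follow common
#' EEG practice and sit above the generator's background activity at its
#' natural spread but well below its injected transients.
#'
#' @param epochs An `mweeg_epochs` object.
#' @param p2p_limit Peak-to-peak threshold in microvolts (default 200).
#' @param grad_limit Gradient threshold in microvolts per sample (default 150).
#' @param min_clean Minimum clean epochs for a section to survive (default 4).
#' @return The epochs object with updated `flagged`, plus attribute
#'   `dropped_sections`.
#' @export
reject_artifacts <- function(epochs, p2p_limit = 200, grad_limit = 150,
                             min_clean = 4) {
  d <- epochs$data
  n_ep <- dim(d)[3]
  flagged <- vapply(seq_len(n_ep), function(k) {
    x <- d[, , k, drop = FALSE]
    dim(x) <- dim(d)[1:2]
    p2p <- apply(x, 2, function(col) diff(range(col)))
    if (any(p2p > p2p_limit)) return(TRUE)
    any(apply(x, 2, function(col) max(abs(diff(col)))) > grad_limit)
  }, logical(1))
  epochs$flagged <- flagged
  clean_per_sec <- tapply(!flagged, epochs$section, sum)
  dropped <- as.integer(names(clean_per_sec)[clean_per_sec < min_clean])
  attr(epochs, "dropped_sections") <- dropped
  epochs
}

## One-sided raw DFT of every epoch at the bins used by the band scheme.
## Returns complex array bins x channels x epochs plus the bin frequencies.
epoch_spectra <- function(epochs, bands = kubicki_bands()) {
  d <- epochs$data
  n <- dim(d)[1]; C <- dim(d)[2]; K <- dim(d)[3]
  res <- epochs$srate / n
  bins <- band_bins(bands, resolution = res)
  freqs <- sort(unique(unlist(bins)))
  idx <- as.integer(round(freqs / res)) + 1L    # DFT bin index (1-based)
  dim(d) <- c(n, C * K)
  X <- stats::mvfft(d)[idx, , drop = FALSE]
  dim(X) <- c(length(idx), C, K)
  list(X = X, freqs = freqs, bins = bins)
}

#' Band power of a single epoch
#'
#' Mean squared spectral magnitude over the discrete-frequency bins of each
#' band, per channel. The transform is the raw (unnormalized) DFT of the
#' epoch, so Parseval's identity reads
#' `sum_k |X_k|^2 = N * sum_t x_t^2`; any fixed normalization would cancel
#' in the later within-subject standardization. A 1-s epoch gives 1 Hz
#' resolution, and each bin belongs to the band whose half-hertz interval
#' contains its center frequency.
#'
#' @param epoch Numeric samples x channels matrix (one clean epoch).
#' @param srate Sampling rate in Hz.
#' @param bands Band scheme, as from [kubicki_bands()].
#' @param window Either `"rectangular"` (default; the plain DFT) or
#'   `"hann"` for a tapered variant.
#' @return A channels x bands matrix of nonnegative power values.
#' @export
band_power <- function(epoch, srate, bands = kubicki_bands(),
                       window = c("rectangular", "hann")) {
  window <- match.arg(window)
  stopifnot(is.matrix(epoch))
  n <- nrow(epoch)
  if (window == "hann")
    epoch <- epoch * (0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1)))
  res <- srate / n
  bins <- band_bins(bands, resolution = res)
  X <- stats::mvfft(epoch)
  P <- abs(X)^2
  out <- sapply(bins, function(f) {
    idx <- as.integer(round(f / res)) + 1L
    colMeans(P[idx, , drop = FALSE])
  })
  if (is.null(dim(out))) out <- matrix(out, nrow = ncol(epoch),
                                       dimnames = list(colnames(epoch), names(bins)))
  rownames(out) <- colnames(epoch)
  out
}

#' Magnitude-squared coherence between two channels over a section
#'
#' Estimates the cross- and auto-spectra by averaging the raw per-epoch DFT
#' products over the section's clean epochs and forms
#' `|S_xy|^2 / (S_xx * S_yy)` per bin, then averages the bins of each band.
#' Averaging over at least two epochs is required: with a single segment the
#' estimator is identically 1.
#'
#' @param epochs An `mweeg_epochs` object restricted to one section, or any
#'   set of epochs to pool.
#' @param pair Character vector of two electrode labels.
#' @param bands Band scheme.
#' @return Named numeric vector of per-band coherence values in \[0, 1\].
#' @export
band_coherence <- function(epochs, pair, bands = kubicki_bands()) {
  stopifnot(length(pair) == 2)
  keep <- which(!epochs$flagged)
  if (length(keep) < 2)
    stop("coherence needs >= 2 clean epochs (single-segment coherence is identically 1)",
         call. = FALSE)
  ia <- match(pair[1], epochs$channels)
  ib <- match(pair[2], epochs$channels)
  if (anyNA(c(ia, ib))) stop("unknown electrode in pair", call. = FALSE)
  sp <- epoch_spectra(epochs, bands)
  Xa <- sp$X[, ia, keep, drop = FALSE]; dim(Xa) <- c(length(sp$freqs), length(keep))
  Xb <- sp$X[, ib, keep, drop = FALSE]; dim(Xb) <- c(length(sp$freqs), length(keep))
  Sxy <- rowMeans(Xa * Conj(Xb))
  Sxx <- rowMeans(abs(Xa)^2)
  Syy <- rowMeans(abs(Xb)^2)
  msc <- Mod(Sxy)^2 / pmax(Sxx * Syy, .Machine$double.xmin)
  vapply(sp$bins, function(f) mean(msc[match(f, sp$freqs)]), 0)
}

## All feature names for a montage and band scheme, in fixed column order:
## per-band electrode powers first, then per-band electrode-pair coherences,
## pairs enumerated in montage order (i < j).
feature_names <- function(montage, bands = kubicki_bands()) {
  bn <- bands$band
  pw <- as.vector(outer(montage, bn, function(e, b) paste0("power_", e, "_", b)))
  prs <- utils::combn(montage, 2)
  ch <- as.vector(outer(paste0("coh_", prs[1, ], "_", prs[2, ]), bn, paste, sep = "_"))
  c(pw, ch)
}

#' Aggregate epochs into per-section feature rows
#'
#' Computes, for every surviving section, the per-channel band power
#' (averaged over the section's clean epochs) and the per-pair band
#' coherence, producing one row per section with
#' `E + E(E-1)/2` features per band — 1,224 columns for 17 electrodes and
#' 8 bands. The response column carries the section's raw probe answer;
#' [normalize_within_subject()] standardizes it later.
#'
#' @param epochs An `mweeg_epochs` object with artifact flags set (see
#'   [reject_artifacts()]); sections listed in its `dropped_sections`
#'   attribute are skipped.
#' @param annotations The session's `mweeg_annotations`.
#' @param subject Subject identifier stored in the `subject` column.
#' @param bands Band scheme.
#' @return A data frame with columns `subject`, `section`, `response`,
#'   `n_clean_epochs`, then the feature columns in fixed order.
#' @export
aggregate_sections <- function(epochs, annotations, subject = 1L,
                               bands = kubicki_bands()) {
  dropped <- attr(epochs, "dropped_sections")
  if (is.null(dropped)) dropped <- integer(0)
  sp <- epoch_spectra(epochs, bands)
  nb <- length(sp$freqs)
  C <- length(epochs$channels)
  band_idx <- lapply(sp$bins, function(f) match(f, sp$freqs))
  pairs <- utils::combn(C, 2)
  nP <- ncol(pairs)
  sections <- setdiff(sort(unique(epochs$section)), dropped)
  nmames <- feature_names(epochs$channels, bands)
  rows <- vector("list", length(sections))
  for (si in seq_along(sections)) {
    s <- sections[si]
    keep <- which(epochs$section == s & !epochs$flagged)
    K <- length(keep)
    if (K < 2) next                          # cannot form coherence
    X <- sp$X[, , keep, drop = FALSE]        # bins x C x K
    ## auto-spectra and band power
    P <- abs(X)^2
    Sauto <- apply(P, c(1, 2), mean)         # bins x C
    pw <- vapply(band_idx, function(ix) colMeans(Sauto[ix, , drop = FALSE]), numeric(C))
    ## cross-spectra per bin via one C x K by K x C product
    msc <- matrix(0, nb, nP)
    for (f in seq_len(nb)) {
      Xf <- X[f, , , drop = FALSE]; dim(Xf) <- c(C, K)
      S <- (Xf %*% Conj(t(Xf))) / K
      d <- Re(diag(S))
      num <- Mod(S[cbind(pairs[1, ], pairs[2, ])])^2
      den <- pmax(d[pairs[1, ]] * d[pairs[2, ]], .Machine$double.xmin)
      msc[f, ] <- num / den
    }
    co <- vapply(band_idx, function(ix) colMeans(msc[ix, , drop = FALSE]), numeric(nP))
    rows[[si]] <- c(as.vector(pw), as.vector(co))
  }
  keep_rows <- !vapply(rows, is.null, logical(1))
  feat <- do.call(rbind, rows[keep_rows])
  colnames(feat) <- nmames
  out <- data.frame(subject = subject,
                    section = sections[keep_rows],
                    response = annotations$probe_answers[sections[keep_rows]],
                    n_clean_epochs = as.vector(
                      tapply(!epochs$flagged, epochs$section, sum)[as.character(sections[keep_rows])]),
                    check.names = FALSE)
  cbind(out, as.data.frame(feat, check.names = FALSE))
}

#' Full feature extraction for one session
#'
#' Convenience chain: [bandpass_notch()], [segment_epochs()],
#' [reject_artifacts()], [aggregate_sections()].
#'
#' @param session An `mweeg_session` (or a list with `recording` and
#'   `annotations`).
#' @param subject Subject id for the output rows.
#' @param bands Band scheme.
#' @param filter Apply the band-pass/notch stage (default TRUE).
#' @param ... Passed to [reject_artifacts()].
#' @return Per-section feature rows, as from [aggregate_sections()].
#' @export
session_features <- function(session, subject = session$subject,
                             bands = kubicki_bands(), filter = TRUE, ...) {
  rec <- session$recording
  if (filter) rec <- bandpass_notch(rec)
  ep <- segment_epochs(rec, session$annotations)
  ep <- reject_artifacts(ep, ...)
  aggregate_sections(ep, session$annotations, subject = subject, bands = bands)
}

#' Feature table for a whole synthetic cohort
#'
#' Generates each subject's session, extracts its per-section features and
#' row-binds the results, discarding the raw EEG as it goes so that memory
#' stays flat in the number of subjects.
#'
#' @param config An [sim_config()] object.
#' @param bands Band scheme.
#' @param ... Passed to [session_features()].
#' @return A list with `features` (the stacked feature rows, raw responses),
#'   `annotations` (per-subject `mweeg_annotations`) and `truth`
#'   (per-subject latent ground truth).
#' @export
cohort_feature_table <- function(config, bands = kubicki_bands(), ...) {
  feats <- vector("list", config$n_subjects)
  anns <- vector("list", config$n_subjects)
  truths <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    s <- generate_session(config, i)
    feats[[i]] <- session_features(s, subject = i, bands = bands, ...)
    anns[[i]] <- s$annotations
    truths[[i]] <- s$truth
  }
  list(features = do.call(rbind, feats), annotations = anns, truth = truths)
}

#' Standardize features and response within each subject
#'
#' Per subject, every feature column and the response are centered and
#' scaled to mean 0 and SD 1 using the population-SD convention (divide by
#' n). Zero-variance columns are set to 0 with a warning; subjects with
#' fewer than two sections are excluded with a message. Applying the
#' operation twice equals applying it once.
#'
#' @param rows Feature rows, as from [aggregate_sections()].
#' @return The standardized rows.
#' @export
normalize_within_subject <- function(rows) {
  meta <- c("subject", "section", "n_clean_epochs")
  fcols <- setdiff(names(rows), meta)
  out <- split(rows, rows$subject)
  out <- lapply(out, function(block) {
    if (nrow(block) < 2) {
      message(sprintf("subject %s excluded: fewer than 2 sections", block$subject[1]))
      return(NULL)
    }
    zeroed <- character(0)
    for (cn in fcols) {
      v <- block[[cn]]
      s <- sd_pop(v)
      if (s < .Machine$double.eps * max(1, abs(mean(v)))) {
        block[[cn]] <- rep(0, length(v))
        zeroed <- c(zeroed, cn)
      } else block[[cn]] <- (v - mean(v)) / s
    }
    if (length(zeroed))
      warning(sprintf("subject %s: %d zero-variance column(s) set to 0",
                      block$subject[1], length(zeroed)), call. = FALSE)
    block
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(out) <- NULL
  out
}
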