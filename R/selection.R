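#' Correlation screen of predictors against the response
#'
#' Computes the absolute Pearson correlation of every training feature
#' column with the training response — the univariate filter statistic used
#' to build predictor sets. Zero-variance columns get `|r| = 0` with a
#' warning. The screen must only ever see the training partition.
#'
#' @param dataset An `mweeg_dataset` (its `train` part is used), or a list
#'   with elements `x` (matrix) and `y`.
#' @return Named numeric vector of `|r|` values, one per feature.
#' @export
correlation_screen <- function(dataset) {
  tr <- if (inherits(dataset, "mweeg_dataset")) dataset$train else dataset
  X <- tr$x; y <- tr$y
  sds <- apply(X, 2, stats::sd)
  dead <- sds < .Machine$double.eps
  r <- rep(0, ncol(X))
  names(r) <- colnames(X)
  if (any(!dead))
    r[!dead] <- abs(as.vector(stats::cor(X[, !dead, drop = FALSE], y)))
  if (any(dead))
    warning(sprintf("%d zero-variance column(s) assigned |r| = 0", sum(dead)),
            call. = FALSE)
  r
}

## Parse feature names of the grammar power_<el>_<band> / coh_<el1>_<el2>_<band>
## against a montage; returns the electrodes each feature involves.
feature_electrodes <- function(names, montage) {
  lapply(names, function(nm) {
    parts <- strsplit(nm, "_", fixed = TRUE)[[1]]
    if (parts[1] == "power" && length(parts) == 3 && parts[2] %in% montage)
      return(parts[2])
    if (parts[1] == "coh" && length(parts) == 4 &&
        all(parts[2:3] %in% montage))
      return(parts[2:3])
    stop(sprintf("unparseable feature name '%s'", nm), call. = FALSE)
  })
}

#' Count the distinct electrodes a predictor set uses
#'
#' A power feature contributes one electrode, a coherence feature two; the
#' count is the size of the union.
#'
#' @param set A predictor set from [build_threshold_sets()] or
#'   [single_best_set()], or a character vector of feature names.
#' @param montage Electrode labels for name validation.
#' @return Integer electrode count.
#' @export
electrodes_used <- function(set, montage = NULL) {
  nms <- if (is.list(set) && !is.null(set$members)) set$members else set
  if (is.null(montage)) {
    if (is.list(set) && !is.null(set$montage)) montage <- set$montage
    else montage <- unique(unlist(strsplit(sub("^(power|coh)_", "", nms), "_")))
  }
  length(unique(unlist(feature_electrodes(nms, montage))))
}

#' Build the threshold-swept family of predictor sets
#'
#' One predictor set per correlation threshold on the grid `0, step, 2*step,
#' ...` up to the largest multiple of `step` not exceeding the maximum
#' `|r|`. A feature belongs to a set when its `|r|` is at least the
#' threshold (inclusive, so the top feature survives into the top set), and
#' sets are therefore nested. With the maximum `|r| = 0.346` reported for
#' real data and the default step 0.01, the grid has 35 sets (0.00--0.34).
#'
#' @param screen Named `|r|` vector from [correlation_screen()].
#' @param step Threshold grid step (default 0.01).
#' @param montage Electrode labels used for electrode accounting; inferred
#'   from the feature names when `NULL`.
#' @return A list of predictor sets, each a list with `threshold`,
#'   `members`, `electrodes`, `n_electrodes` and `montage`.
#' @export
build_threshold_sets <- function(screen, step = 0.01, montage = NULL) {
  if (is.null(montage))
    montage <- unique(unlist(strsplit(sub("^(power|coh)_", "", names(screen)), "_")))
  top <- max(screen)
  thresholds <- seq(0, max(floor(top / step) * step, 0), by = step)
  lapply(thresholds, function(th) {
    members <- names(screen)[screen >= th]
    els <- unique(unlist(feature_electrodes(members, montage)))
    list(threshold = th, members = members, electrodes = els,
         n_electrodes = length(els), montage = montage)
  })
}

#' The single best predictor set
#'
#' The set holding exactly one feature: the arg-max of the screen's `|r|`.
#' Ties are broken by the fixed feature-name (column) order, and a tie is
#' reported via `message()`.
#'
#' @inheritParams build_threshold_sets
#' @return A predictor set in the same shape as [build_threshold_sets()]
#'   entries, with `threshold = NA`.
#' @export
single_best_set <- function(screen, montage = NULL) {
  if (is.null(montage))
    montage <- unique(unlist(strsplit(sub("^(power|coh)_", "", names(screen)), "_")))
  top <- which(screen == max(screen))
  if (length(top) > 1)
    message(sprintf("|r| tie among %d features; keeping '%s' (first in column order)",
                    length(top), names(screen)[top[1]]))
  member <- names(screen)[top[1]]
  els <- unique(unlist(feature_electrodes(member, montage)))
  list(threshold = NA_real_, members = member, electrodes = els,
       n_electrodes = length(els), montage = montage)
}
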