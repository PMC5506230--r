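#' Exclude subjects with a flat mind-wandering report range
#'
#' Removes every subject whose raw probe answers span fewer than
#' `min_mw_range` points (max minus min), the report-quality rule applied
#' before any normalization: a subject who always answers the same value
#' carries no within-subject signal to predict.
#'
#' @param rows Feature rows with a raw (unnormalized) `response` column.
#' @param min_mw_range Minimum required answer range in Likert points
#'   (default 2).
#' @return The surviving rows; excluded subject ids are attached as the
#'   `excluded_subjects` attribute.
#' @export
exclude_subjects <- function(rows, min_mw_range = 2) {
  rng <- tapply(rows$response, rows$subject, function(a) max(a) - min(a))
  bad <- names(rng)[rng < min_mw_range]
  if (length(bad))
    message(sprintf("excluding %d subject(s) with MW report range < %g: %s",
                    length(bad), min_mw_range, paste(bad, collapse = ", ")))
  out <- rows[!(rows$subject %in% bad), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded_subjects") <- bad
  out
}

#' Split rows into training and test partitions by whole subjects
#'
#' Whole subjects are assigned at random to the test partition so that no
#' subject contributes rows to both sides. The number of test subjects is
#' `round(n_subjects * test_fraction)` with round-half-up, at least 1 and at
#' most `n_subjects - 1`.
#'
#' @param rows Feature rows with a `subject` column.
#' @param test_fraction Fraction of subjects held out (default 1/3).
#' @param seed Integer seed making the assignment deterministic.
#' @return A list with `train` and `test` row subsets and the `manifest`
#'   (named character vector, subject -> partition).
#' @export
split_by_subject <- function(rows, test_fraction = 1 / 3, seed = 1L) {
  subjects <- unique(rows$subject)
  n <- length(subjects)
  if (n < 3) stop("need at least 3 subjects to split", call. = FALSE)
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must lie strictly between 0 and 1", call. = FALSE)
  n_test <- floor(n * test_fraction + 0.5)          # round half up
  n_test <- min(max(n_test, 1L), n - 1L)
  test_subj <- with_seed(seed, sample(subjects, n_test))
  manifest <- stats::setNames(ifelse(subjects %in% test_subj, "test", "train"),
                              subjects)
  list(train = rows[!(rows$subject %in% test_subj), , drop = FALSE],
       test = rows[rows$subject %in% test_subj, , drop = FALSE],
       manifest = manifest)
}

#' Drop outlier sections on already-normalized features
#'
#' Removes every row in which any feature's within-subject z-score exceeds
#' `z_max` in absolute value. The rule is applied to training and test rows
#' alike; the count of dropped rows is reported via `message()`.
#'
#' @param rows Normalized feature rows (see [normalize_within_subject()]).
#' @param z_max Absolute z-score threshold (default 5).
#' @return The surviving rows, with attribute `n_dropped`.
#' @export
remove_outlier_sections <- function(rows, z_max = 5) {
  fcols <- setdiff(names(rows), c("subject", "section", "response", "n_clean_epochs"))
  m <- as.matrix(rows[, fcols, drop = FALSE])
  bad <- apply(abs(m) > z_max, 1, any)
  if (any(bad))
    message(sprintf("dropping %d outlier section(s) with |z| > %g", sum(bad), z_max))
  out <- rows[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(bad)
  out
}

#' Scale train and test partitions by training statistics
#'
#' Centers and scales every feature column of both partitions using the
#' training partition's mean and population SD only, so no information
#' flows from test to train. Columns with zero training variance are
#' dropped from both partitions with a warning.
#'
#' @param train,test Feature row subsets from [split_by_subject()].
#' @return An object of class `mweeg_dataset`: a list with `train` and
#'   `test` (each a list with predictor matrix `x`, response `y`, `subject`)
#'   plus the scaling statistics `center` and `scale`.
#' @export
scale_by_training <- function(train, test) {
  fcols <- setdiff(names(train), c("subject", "section", "response", "n_clean_epochs"))
  Xtr <- as.matrix(train[, fcols, drop = FALSE])
  ctr <- colMeans(Xtr)
  scl <- apply(Xtr, 2, sd_pop)
  dead <- scl < .Machine$double.eps
  if (any(dead)) {
    warning(sprintf("dropping %d zero-training-variance column(s)", sum(dead)),
            call. = FALSE)
    Xtr <- Xtr[, !dead, drop = FALSE]
    ctr <- ctr[!dead]; scl <- scl[!dead]
    fcols <- fcols[!dead]
  }
  Xte <- as.matrix(test[, fcols, drop = FALSE])
  sc <- function(X) sweep(sweep(X, 2, ctr), 2, scl, "/")
  structure(list(
    train = list(x = sc(Xtr), y = train$response, subject = train$subject),
    test = list(x = sc(Xte), y = test$response, subject = test$subject),
    center = ctr, scale = scl, features = fcols),
    class = "mweeg_dataset")
}

#' @export
print.mweeg_dataset <- function(x, ...) {
  cat(sprintf("<modeling dataset: %d train / %d test rows, %d features, %d/%d subjects>\n",
              nrow(x$train$x), nrow(x$test$x), length(x$features),
              length(unique(x$train$subject)), length(unique(x$test$subject))))
  invisible(x)
}
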