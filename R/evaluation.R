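#' Held-out correlation between predictions and measured responses
#'
#' @param model A fitted family member (`mweeg_svr` or `lm`) or a numeric
#'   vector of predictions.
#' @param part Test partition (list with `x` and `y`); ignored when
#'   `model` is already a prediction vector, in which case `y` must be
#'   given.
#' @param y Measured responses (defaults to `part$y`).
#' @return A list with `r` (Pearson correlation) and `n` (sample count).
#' @export
heldout_correlation <- function(model, part = NULL, y = part$y) {
  pred <- if (is.numeric(model)) model
  else if (inherits(model, "lm")) stats::predict(model, newdata = data.frame(x = part$x))
  else predict(model, part$x[, model$feature_names, drop = FALSE])
  n <- length(y)
  if (n < 3) stop("need at least 3 held-out samples", call. = FALSE)
  if (stats::sd(pred) == 0) {
    ## a constant predictor has no linear association with the response
    warning("constant predictions: held-out r reported as 0", call. = FALSE)
    return(list(r = 0, n = n, degenerate = TRUE))
  }
  list(r = stats::cor(pred, y), n = n, degenerate = FALSE)
}

#' Two-sided test of a Pearson correlation against zero
#'
#' Uses the exact-null t statistic `t = r * sqrt((n - 2) / (1 - r^2))` on
#' `n - 2` degrees of freedom. A correlation of exactly +-1 cannot be
#' tested this way; the p value is then reported as the double-precision
#' underflow floor and flagged.
#'
#' @param r Correlation coefficient.
#' @param n Sample count (>= 3).
#' @return A list with `p`, `statistic` (t), `df` and `floored`.
#' @export
correlation_test <- function(r, n) {
  if (n < 3) stop("need n >= 3", call. = FALSE)
  if (abs(r) >= 1)
    return(list(p = .Machine$double.xmin, statistic = Inf, df = n - 2,
                floored = TRUE))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(p = 2 * stats::pt(-abs(t), df = n - 2), statistic = t, df = n - 2,
       floored = FALSE)
}

#' Test the difference between two correlation coefficients
#'
#' Compares `r1` and `r2` measured on the same `n` samples. Two methods:
#' \describe{
#'   \item{independent}{Fisher-z difference
#'     `Z = (atanh(r1) - atanh(r2)) / sqrt(2 / (n - 3))`, appropriate when
#'     the two coefficients come from independent samples;}
#'   \item{dependent}{Steiger's Z for two correlations sharing one variable
#'     (both models are scored against the same measured responses), which
#'     requires `r12`, the correlation between the two prediction series.}
#' }
#' The dependent method is the default in [build_report()] because the
#' compared models are evaluated on identical test rows. P values are
#' one-sided for the directional hypothesis `r1 > r2` by default.
#'
#' @param r1,r2 The two correlations.
#' @param n Common sample count (> 3).
#' @param method `"dependent"` or `"independent"`.
#' @param r12 Correlation between the two prediction series (dependent
#'   method only).
#' @param sidedness `"one"` (default) or `"two"`.
#' @return A list with `Z`, `p`, and the `method` tag.
#' @export
r_difference_test <- function(r1, r2, n, method = c("dependent", "independent"),
                              r12 = NULL, sidedness = c("one", "two")) {
  method <- match.arg(method)
  sidedness <- match.arg(sidedness)
  if (n <= 3) stop("need n > 3", call. = FALSE)
  if (max(abs(c(r1, r2))) >= 1) stop("correlations must lie in (-1, 1)", call. = FALSE)
  z1 <- atanh(r1); z2 <- atanh(r2)
  if (method == "independent") {
    Z <- (z1 - z2) / sqrt(2 / (n - 3))
  } else {
    if (is.null(r12)) stop("dependent method requires r12", call. = FALSE)
    rb <- (r1 + r2) / 2
    psi <- r12 * (1 - 2 * rb^2) - 0.5 * rb^2 * (1 - 2 * rb^2 - r12^2)
    s <- psi / (1 - rb^2)^2
    ## identical prediction series give 0/0; no difference means Z = 0
    Z <- sqrt(n - 3) * (z1 - z2) / sqrt(max(2 - 2 * s, 1e-12))
  }
  p <- if (sidedness == "one") stats::pnorm(Z, lower.tail = FALSE)
  else 2 * stats::pnorm(-abs(Z))
  list(Z = Z, p = p, method = method, sidedness = sidedness)
}

#' Behavioral validation: RT variance against reported mind-wandering
#'
#' Within each subject, correlates the per-section reaction-time variance
#' with the raw probe answers, Fisher-transforms the coefficients
#' (`z = atanh(r)`) and applies a one-sample Wilcoxon signed-rank test of
#' the z values against zero (exact for 25 or fewer subjects
#' without ties, normal approximation otherwise). A positive shift confirms that reported MW
#' intensity tracks behavioral variability.
#'
#' @param annotations List of per-subject `mweeg_annotations`.
#' @param alternative `"greater"` (one-sided, default) or `"two.sided"`.
#' @return A list with per-subject `r`, Fisher `z`, and the signed-rank `p`
#'   and statistic `V`. Subjects with degenerate (constant) RT variance or
#'   answers are skipped with a warning.
#' @export
behavioral_validation <- function(annotations, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  rs <- vapply(seq_along(annotations), function(i) {
    a <- annotations[[i]]
    v <- vapply(a$rts, stats::var, 0)
    if (stats::sd(v) == 0 || stats::sd(a$probe_answers) == 0) {
      warning(sprintf("subject %d skipped in behavioral validation (constant series)", i),
              call. = FALSE)
      return(NA_real_)
    }
    stats::cor(v, a$probe_answers)
  }, 0)
  rs <- rs[!is.na(rs)]
  if (length(rs) < 2) stop("too few usable subjects", call. = FALSE)
  z <- atanh(pmin(pmax(rs, -1 + 1e-12), 1 - 1e-12))
  exact_ok <- length(z) <= 25 && !any(z == 0) && !anyDuplicated(abs(z))
  wt <- stats::wilcox.test(z, mu = 0, alternative = alternative,
                           exact = exact_ok)
  list(r = rs, z = z, p = wt$p.value, V = unname(wt$statistic),
       alternative = alternative)
}

#' Full model-comparison report
#'
#' Scores all five models on the held-out partition and assembles the
#' comparison tables: per-model held-out Pearson r with its correlation
#' test, the eight pairwise r-difference tests (each of Models 1--4 against
#' Model 5; RBF vs linear at full and limited electrodes; full vs limited
#' electrodes for each kernel), and, when annotations are supplied, the
#' behavioral RT-variance validation.
#'
#' @param family An `mweeg_model_family`.
#' @param dataset The `mweeg_dataset` whose `test` part is scored.
#' @param annotations Optional list of per-subject annotations for the
#'   behavioral validation.
#' @param method Comparison method for [r_difference_test()].
#' @param sidedness P-value sidedness for the comparisons.
#' @return An object of class `mweeg_report` with elements `accuracy`
#'   (data frame: model, r, p), `comparisons` (data frame: model_a,
#'   model_b, Z, p, method), `n_test`, and optionally `behavioral`.
#' @export
build_report <- function(family, dataset, annotations = NULL,
                         method = "dependent", sidedness = "one") {
  te <- dataset$test
  preds <- lapply(names(family$models), function(nm) family_predict(family, nm, te))
  names(preds) <- names(family$models)
  n <- length(te$y)
  acc <- do.call(rbind, lapply(names(preds), function(nm) {
    hc <- heldout_correlation(preds[[nm]], y = te$y)
    ct <- correlation_test(hc$r, hc$n)
    data.frame(model = nm, r = hc$r, p = ct$p)
  }))
  pairs <- rbind(
    c("model1", "model5"), c("model2", "model5"),
    c("model3", "model5"), c("model4", "model5"),
    c("model1", "model3"), c("model2", "model4"),
    c("model1", "model2"), c("model3", "model4"))
  comp <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    r1 <- acc$r[acc$model == a]; r2 <- acc$r[acc$model == b]
    r12 <- if (stats::sd(preds[[a]]) == 0 || stats::sd(preds[[b]]) == 0) 0
    else stats::cor(preds[[a]], preds[[b]])
    dt <- r_difference_test(r1, r2, n, method = method, r12 = r12,
                            sidedness = sidedness)
    data.frame(model_a = a, model_b = b, Z = dt$Z, p = dt$p,
               method = dt$method)
  }))
  rep <- list(accuracy = acc, comparisons = comp, n_test = n,
              thresholds = family$thresholds,
              single_feature = family$single_feature)
  if (!is.null(annotations)) rep$behavioral <- behavioral_validation(annotations)
  structure(rep, class = "mweeg_report")
}

#' @export
print.mweeg_report <- function(x, ...) {
  cat(sprintf("<model report on %d held-out sections>\n", x$n_test))
  cat("  held-out accuracy (Pearson r, correlation-test p):\n")
  a <- x$accuracy
  for (i in seq_len(nrow(a)))
    cat(sprintf("    %-7s r = %+.3f  p = %.3g\n", a$model[i], a$r[i], a$p[i]))
  cat("  pairwise r-difference tests:\n")
  cmp <- x$comparisons
  for (i in seq_len(nrow(cmp)))
    cat(sprintf("    %s vs %s: Z = %+.2f  p = %.3g (%s)\n",
                cmp$model_a[i], cmp$model_b[i], cmp$Z[i], cmp$p[i], cmp$method[i]))
  if (!is.null(x$behavioral))
    cat(sprintf("  behavioral validation: median within-subject r = %.2f, signed-rank p = %.3g\n",
                stats::median(x$behavioral$r), x$behavioral$p))
  invisible(x)
}

#' Serialize / restore a report
#'
#' Lossless JSON round-trip of an `mweeg_report`.
#'
#' @param report An `mweeg_report`.
#' @param path File path.
#' @return `report_write` returns `path` invisibly; `report_read` the
#'   restored report.
#' @export
report_write <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname report_write
#' @export
report_read <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$accuracy <- as.data.frame(x$accuracy)
  x$comparisons <- as.data.frame(x$comparisons)
  if (!is.null(x$thresholds)) x$thresholds <- unlist(x$thresholds)
  structure(x, class = "mweeg_report")
}
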