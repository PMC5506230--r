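#' Fit the five-model family over a threshold sweep
#'
#' For every predictor set in `sets` and both kernels, runs
#' [grid_search_cv()] on the training partition and records the best
#' cross-validated MSE with its chosen hyperparameters (the sweep table).
#' The five reported models are then:
#' \describe{
#'   \item{Model 1}{RBF kernel at the overall best-CV predictor set;}
#'   \item{Model 2}{RBF kernel at the best-CV set among sets using at most
#'     `electrode_budget` electrodes;}
#'   \item{Model 3}{linear kernel at its overall best-CV set;}
#'   \item{Model 4}{linear kernel at its best-CV set within the budget;}
#'   \item{Model 5}{ordinary least-squares simple regression on the
#'     single best predictor.}
#' }
#' Each SVR model is refitted on the full training partition at its winning
#' hyperparameters.
#'
#' @param dataset An `mweeg_dataset` from [scale_by_training()].
#' @param sets Predictor sets from [build_threshold_sets()] (training
#'   screen).
#' @param single_set The single-best-predictor set from
#'   [single_best_set()]; computed from the screen when omitted (requires
#'   `screen`).
#' @param screen Optional screen used to derive `single_set`.
#' @param electrode_budget Maximum electrodes for Models 2 and 4
#'   (default 9).
#' @param grid Hyperparameter candidates for both kernels
#'   (default [default_grid()]).
#' @param k_folds Cross-validation folds (default 10).
#' @param seed Fold-assignment seed.
#' @return An object of class `mweeg_model_family`: the five fitted models
#'   (`models`, named `model1`..`model5`), the sweep table (`sweep`, one
#'   row per threshold with per-kernel MSE and hyperparameters), and the
#'   selected thresholds.
#' @export
fit_model_family <- function(dataset, sets, single_set = NULL, screen = NULL,
                             electrode_budget = 9, grid = default_grid(),
                             k_folds = 10, seed = 1L) {
  stopifnot(inherits(dataset, "mweeg_dataset"))
  if (is.null(single_set)) {
    if (is.null(screen)) stop("provide single_set or screen", call. = FALSE)
    single_set <- single_best_set(screen)
  }
  tr <- dataset$train
  n_el <- vapply(sets, `[[`, 0, "n_electrodes")
  if (!any(n_el <= electrode_budget))
    stop(sprintf("no predictor set uses <= %d electrodes", electrode_budget),
         call. = FALSE)

  cv_one <- function(set, kernel) {
    X <- tr$x[, set$members, drop = FALSE]
    grid_search_cv(X, tr$y, kernel, grid = grid, k_folds = k_folds, seed = seed)
  }
  cvs <- lapply(sets, function(s)
    list(rbf = cv_one(s, "rbf"), linear = cv_one(s, "linear")))

  sweep_tab <- do.call(rbind, lapply(seq_along(sets), function(i) {
    s <- sets[[i]]; r <- cvs[[i]]$rbf; l <- cvs[[i]]$linear
    data.frame(threshold = s$threshold, n_features = length(s$members),
               n_electrodes = s$n_electrodes,
               rbf_mse = r$scores$cv_mse[r$best], rbf_gamma = r$gamma,
               rbf_epsilon = r$epsilon, rbf_C = r$C,
               linear_mse = l$scores$cv_mse[l$best],
               linear_epsilon = l$epsilon, linear_C = l$C)
  }))

  pick <- function(kernel, budget = Inf) {
    mses <- vapply(cvs, function(z) z[[kernel]]$scores$cv_mse[z[[kernel]]$best], 0)
    ok <- n_el <= budget
    which(ok)[which.min(mses[ok])]
  }
  refit <- function(i, kernel) {
    s <- sets[[i]]; cv <- cvs[[i]][[kernel]]
    m <- svr_fit(tr$x[, s$members, drop = FALSE], tr$y,
                 if (kernel == "rbf") "rbf" else "linear",
                 C = cv$C, epsilon = cv$epsilon, gamma = cv$gamma)
    attr(m, "set") <- s
    attr(m, "cv_mse") <- cv$scores$cv_mse[cv$best]
    m
  }
  i1 <- pick("rbf"); i2 <- pick("rbf", electrode_budget)
  i3 <- pick("linear"); i4 <- pick("linear", electrode_budget)

  df5 <- data.frame(y = tr$y, x = tr$x[, single_set$members[1]])
  m5 <- stats::lm(y ~ x, data = df5)
  attr(m5, "set") <- single_set

  models <- list(model1 = refit(i1, "rbf"), model2 = refit(i2, "rbf"),
                 model3 = refit(i3, "linear"), model4 = refit(i4, "linear"),
                 model5 = m5)
  structure(list(models = models, sweep = sweep_tab,
                 thresholds = c(model1 = sets[[i1]]$threshold,
                                model2 = sets[[i2]]$threshold,
                                model3 = sets[[i3]]$threshold,
                                model4 = sets[[i4]]$threshold),
                 electrode_budget = electrode_budget,
                 single_feature = single_set$members[1]),
            class = "mweeg_model_family")
}

#' Predictions from any family member on a dataset partition
#'
#' @param family An `mweeg_model_family`.
#' @param which Model name, `"model1"`..`"model5"`.
#' @param part A dataset partition (list with `x`), e.g. `dataset$test`.
#' @return Numeric predictions.
#' @export
family_predict <- function(family, which, part) {
  m <- family$models[[which]]
  if (inherits(m, "lm"))
    return(unname(stats::predict(m,
      newdata = data.frame(x = part$x[, family$single_feature]))))
  predict(m, part$x[, m$feature_names, drop = FALSE])
}

#' @export
print.mweeg_model_family <- function(x, ...) {
  cat("<five-model family over the correlation-threshold sweep>\n")
  for (nm in names(x$models)) {
    m <- x$models[[nm]]
    if (inherits(m, "lm")) {
      cat(sprintf("  %s: OLS on single predictor %s\n", nm, x$single_feature))
    } else {
      s <- attr(m, "set")
      cat(sprintf("  %s: %s kernel, threshold %.2f, %d features, %d electrodes, CV MSE %.4f\n",
                  nm, m$kernel, s$threshold, length(s$members), s$n_electrodes,
                  attr(m, "cv_mse")))
    }
  }
  invisible(x)
}

#' @export
summary.mweeg_model_family <- function(object, ...) {
  print(object)
  cat(sprintf("  electrode budget for models 2/4: %d\n", object$electrode_budget))
  cat("  sweep table:\n")
  print(utils::head(object$sweep, 40), digits = 3)
  invisible(object)
}

#' Plot the threshold sweep
#'
#' Cross-validated MSE of both kernels against the correlation threshold,
#' with the electrode count of each predictor set on a secondary axis.
#'
#' @param x An `mweeg_model_family`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mweeg_model_family <- function(x, ...) {
  sw <- x$sweep
  rng <- range(c(sw$rbf_mse, sw$linear_mse))
  graphics::plot(sw$threshold, sw$rbf_mse, type = "b", pch = 16, col = "firebrick",
                 ylim = rng, xlab = "correlation threshold |r|",
                 ylab = "10-fold CV MSE", ...)
  graphics::lines(sw$threshold, sw$linear_mse, type = "b", pch = 1, col = "steelblue")
  graphics::legend("topleft", legend = c("RBF", "linear"), pch = c(16, 1),
                   col = c("firebrick", "steelblue"), bty = "n")
  usr <- graphics::par("usr")
  scale <- (usr[4] - usr[3]) / max(sw$n_electrodes)
  graphics::lines(sw$threshold, usr[3] + sw$n_electrodes * scale * 0.25,
                  lty = 3, col = "gray40")
  invisible(x)
}
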