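#' Fit an epsilon-insensitive support vector regression
#'
#' Minimizes the regularized epsilon-insensitive objective
#' `C * sum_i max(|y_i - f(x_i)| - epsilon, 0) + 0.5 * ||beta||^2`
#' with `f(x) = <beta, phi(x)> + beta0`, for the linear kernel
#' (`k(x, z) = x'z`) or the radial-basis kernel
#' (`k(x, z) = exp(-gamma * ||x - z||^2)`). The convex dual is solved
#' on a package-computed kernel matrix by the SMO solver of \pkg{kernlab};
#' for small problems (`n <= refine_max_n`) the
#' returned dual coefficients are then polished to tight optimality by an
#' exact pairwise coordinate-descent pass and the intercept is re-optimized
#' exactly by minimizing the piecewise-linear loss in one dimension, so the
#' fitted objective matches the true optimum to well below 1e-6.
#'
#' Training samples whose residual lies strictly inside the epsilon tube
#' have zero dual coefficient at optimality (non-support samples).
#'
#' @param x Numeric predictor matrix (rows = samples).
#' @param y Numeric response vector.
#' @param kernel `"linear"` or `"rbf"`.
#' @param C Regularization weight (> 0).
#' @param epsilon Insensitivity half-width (>= 0).
#' @param gamma RBF width; defaults to `1/ncol(x)` and is ignored by the
#'   linear kernel.
#' @param refine_max_n Sample-count bound below which the exact dual polish
#'   runs (default 64; the polish is quadratic in n).
#' @param K Optional precomputed training kernel matrix (as produced by the
#'   package for `x`); avoids recomputing the Gram in tight loops.
#' @return An object of class `mweeg_svr` with the dual coefficients
#'   (`theta`, one per training sample), intercept `b`, and for the linear
#'   kernel the explicit weight vector `w`.
#' @seealso [predict.mweeg_svr()], [svr_objective()], [grid_search_cv()]
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(40), 20)
#' y <- x[, 1] - 0.5 * x[, 2] + rnorm(20, 0, 0.1)
#' m <- svr_fit(x, y, "linear", C = 1, epsilon = 0.1)
#' cor(predict(m, x), y)
#' @export
svr_fit <- function(x, y, kernel = c("linear", "rbf"), C = 1, epsilon = 0.1,
                    gamma = NULL, refine_max_n = 64, K = NULL) {
  kernel <- match.arg(kernel)
  x <- as.matrix(x)
  if (nrow(x) == 0) stop("cannot fit on zero samples", call. = FALSE)
  if (nrow(x) != length(y)) stop("nrow(x) must match length(y)", call. = FALSE)
  if (C <= 0 || epsilon < 0) stop("need C > 0 and epsilon >= 0", call. = FALSE)
  if (is.null(gamma)) gamma <- 1 / ncol(x)
  if (kernel == "rbf" && gamma <= 0) stop("need gamma > 0", call. = FALSE)
  n <- nrow(x)
  if (is.null(K)) K <- kernel_matrix(x, x, kernel, gamma)

  sol <- solve_svr_dual(K, y, C, epsilon)
  theta <- sol$theta
  if (n <= refine_max_n) {
    theta <- polish_dual(theta, K, y, C, epsilon)
    b <- optimal_intercept(y - as.vector(K %*% theta), epsilon)
  } else b <- sol$b

  structure(list(kernel = kernel, C = C, epsilon = epsilon,
                 gamma = if (kernel == "rbf") gamma else NA_real_,
                 theta = theta, b = b,
                 x = x, y = y, feature_names = colnames(x),
                 w = if (kernel == "linear") as.vector(crossprod(x, theta)) else NULL),
            class = "mweeg_svr")
}

## Solve the epsilon-SVR dual on a precomputed kernel via kernlab's SMO.
solve_svr_dual <- function(K, y, C, epsilon) {
  n <- length(y)
  fit <- tryCatch(
    suppressWarnings(kernlab::ksvm(kernlab::as.kernelMatrix(K), y,
                                   type = "eps-svr", C = C, epsilon = epsilon,
                                   scaled = FALSE, tol = 1e-6)),
    error = function(e) NULL)                 # e.g. all samples inside the tube
  theta <- rep(0, n)
  if (!is.null(fit)) {
    theta[kernlab::SVindex(fit)] <- as.vector(kernlab::coef(fit))
    b <- -kernlab::b(fit)
  } else {
    b <- optimal_intercept(y, epsilon)
  }
  list(theta = theta, b = b)
}

kernel_matrix <- function(a, b, kernel, gamma) {
  if (kernel == "linear") return(a %*% t(b))
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * a %*% t(b)
  exp(-gamma * pmax(d2, 0))
}

## Exact pairwise coordinate descent on the dual in theta-space:
## maximize -0.5 t'Kt + y't - eps*||t||_1 subject to sum(t) = 0, |t_i| <= C.
## Each (i, j) step moves along e_i - e_j with an exact piecewise-quadratic
## line search (kinks where t_i + d or t_j - d crosses zero).
polish_dual <- function(theta, K, y, C, eps, sweeps = 100, tol = 1e-13) {
  n <- length(y)
  if (n < 2) return(theta)
  g <- y - as.vector(K %*% theta)
  for (s in seq_len(sweeps)) {
    best_gain <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      eta <- max(K[i, i] + K[j, j] - 2 * K[i, j], 1e-14)
      ti <- theta[i]; tj <- theta[j]
      lo <- max(-C - ti, tj - C); hi <- min(C - ti, tj + C)
      if (hi <= lo) next
      kinks <- sort(unique(pmin(pmax(c(-ti, tj), lo), hi)))
      edges <- unique(c(lo, kinks, hi))
      cand <- edges
      for (k in seq_len(length(edges) - 1)) {
        mid <- (edges[k] + edges[k + 1]) / 2
        si <- sign(ti + mid); sj <- sign(tj - mid)
        dstar <- ((g[i] - g[j]) - eps * si + eps * sj) / eta
        cand <- c(cand, min(max(dstar, edges[k]), edges[k + 1]))
      }
      gain <- vapply(cand, function(d)
        -0.5 * eta * d^2 + (g[i] - g[j]) * d -
          eps * (abs(ti + d) + abs(tj - d)) + eps * (abs(ti) + abs(tj)), 0)
      k <- which.max(gain)
      if (gain[k] > 1e-15) {
        d <- cand[k]
        theta[i] <- ti + d; theta[j] <- tj - d
        g <- g - d * (K[, i] - K[, j])
        best_gain <- max(best_gain, gain[k])
      }
    }
    if (best_gain < tol) break
  }
  theta
}

## Exact minimizer of sum_i max(|r_i - b| - eps, 0) over b: evaluate the
## piecewise-linear loss at its breakpoints and take the argmin plateau's
## midpoint.
optimal_intercept <- function(r, eps) {
  bks <- sort(c(r - eps, r + eps))
  loss <- vapply(bks, function(b) sum(pmax(abs(r - b) - eps, 0)), 0)
  i <- which(loss <= min(loss) + 1e-12 * max(1, min(loss)))
  mean(range(bks[i]))
}

#' Predict from a fitted SVR model
#'
#' @param object An `mweeg_svr` model.
#' @param newdata Numeric matrix whose columns match the training features
#'   (checked by name when both sides are named).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.mweeg_svr <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (nrow(newdata) == 0) return(numeric(0))
  if (!is.null(object$feature_names) && !is.null(colnames(newdata))) {
    if (!identical(colnames(newdata), object$feature_names)) {
      if (!all(object$feature_names %in% colnames(newdata)))
        stop("newdata is missing model feature columns", call. = FALSE)
      newdata <- newdata[, object$feature_names, drop = FALSE]
    }
  } else if (ncol(newdata) != ncol(object$x)) {
    stop("newdata has the wrong number of columns", call. = FALSE)
  }
  if (object$kernel == "linear")
    return(as.vector(newdata %*% object$w) + object$b)
  K <- kernel_matrix(newdata, object$x, "rbf", object$gamma)
  as.vector(K %*% object$theta) + object$b
}

#' Training objective value of a fitted SVR
#'
#' Evaluates `0.5 * ||beta||^2 + C * sum max(|residual| - epsilon, 0)` on
#' the model's own training data — the quantity the fit minimizes, used by
#' the solver-correctness checks.
#'
#' @param model An `mweeg_svr`.
#' @return The primal objective value.
#' @export
svr_objective <- function(model) {
  K <- kernel_matrix(model$x, model$x, model$kernel,
                     if (model$kernel == "rbf") model$gamma else NA)
  f <- as.vector(K %*% model$theta) + model$b
  0.5 * sum(model$theta * (K %*% model$theta)) +
    model$C * sum(pmax(abs(model$y - f) - model$epsilon, 0))
}

#' @export
print.mweeg_svr <- function(x, ...) {
  nsv <- sum(abs(x$theta) > 1e-12)
  cat(sprintf("<epsilon-SVR: %s kernel, C=%g, epsilon=%g%s; %d/%d support samples>\n",
              x$kernel, x$C, x$epsilon,
              if (x$kernel == "rbf") sprintf(", gamma=%g", x$gamma) else "",
              nsv, length(x$theta)))
  invisible(x)
}

#' @export
coef.mweeg_svr <- function(object, ...) {
  if (object$kernel == "linear")
    c(`(intercept)` = object$b,
      stats::setNames(object$w, object$feature_names))
  else stats::setNames(c(object$b, object$theta),
                       c("(intercept)", paste0("theta_", seq_along(object$theta))))
}

#' @export
summary.mweeg_svr <- function(object, ...) {
  print(object)
  cat(sprintf("  features: %d%s\n", ncol(object$x),
              if (!is.null(object$feature_names))
                paste0(" (", paste(utils::head(object$feature_names, 4), collapse = ", "),
                       if (ncol(object$x) > 4) ", ..." else "", ")") else ""))
  invisible(object)
}

#' Default hyperparameter grid
#'
#' Powers-of-two candidate grids: `C` in 2^(-4..2) and `epsilon` in
#' 2^(-6..1). The RBF width `gamma` is fixed at `1/p` (one over the number
#' of features) rather than searched; both choices can be overridden by
#' passing an explicit grid to [grid_search_cv()].
#'
#' @param C Candidate values for `C`.
#' @param epsilon Candidate values for `epsilon`.
#' @return A data frame of candidates, enumerated epsilon-fastest.
#' @export
default_grid <- function(C = 2^(-4:2), epsilon = 2^(-6:1)) {
  expand.grid(epsilon = epsilon, C = C, KEEP.OUT.ATTRS = FALSE)[, c("C", "epsilon")]
}

#' Grid search with k-fold cross-validated MSE
#'
#' Rows are partitioned into `k_folds` folds of as-equal-as-possible size
#' under a seed; every candidate is fitted on each fold's complement and
#' scored by the mean squared error on the held-out fold; a candidate's
#' score is the mean of its fold MSEs and the winner is the minimizer, ties
#' going to the earlier candidate in grid order.
#'
#' @param x,y Training predictors and response.
#' @param kernel `"linear"` or `"rbf"`.
#' @param grid Data frame of candidates with columns `C` and `epsilon`
#'   (optionally `gamma`); default [default_grid()].
#' @param k_folds Number of folds (default 10).
#' @param seed Fold-assignment seed.
#' @param gamma RBF width used when the grid has no `gamma` column
#'   (default `1/ncol(x)`).
#' @return A list of class `mweeg_cv` with the per-candidate `scores`
#'   (`grid` plus column `cv_mse`), the winning row index `best`, and the
#'   chosen `C`, `epsilon`, `gamma`.
#' @export
grid_search_cv <- function(x, y, kernel = c("linear", "rbf"),
                           grid = default_grid(), k_folds = 10, seed = 1L,
                           gamma = NULL) {
  kernel <- match.arg(kernel)
  x <- as.matrix(x)
  n <- nrow(x)
  if (nrow(grid) == 0) stop("empty hyperparameter grid", call. = FALSE)
  if (k_folds < 2 || k_folds > n)
    stop("k_folds must lie in 2..n", call. = FALSE)
  if (is.null(gamma)) gamma <- 1 / ncol(x)
  fold <- with_seed(seed, sample(rep(seq_len(k_folds), length.out = n)))
  gammas <- if ("gamma" %in% names(grid)) unique(grid$gamma) else gamma
  ## the kernel matrix is computed once per gamma and sliced per fold,
  ## which keeps the sweep linear, not cubic, in the feature count
  Ks <- lapply(gammas, function(gm) kernel_matrix(x, x, kernel, gm))
  mse <- matrix(0, nrow(grid), k_folds)
  for (f in seq_len(k_folds)) {
    hold <- fold == f
    for (g in seq_len(nrow(grid))) {
      gm <- if ("gamma" %in% names(grid)) grid$gamma[g] else gamma
      K <- Ks[[match(gm, gammas)]]
      sol <- solve_svr_dual(K[!hold, !hold, drop = FALSE], y[!hold],
                            grid$C[g], grid$epsilon[g])
      pred <- as.vector(K[hold, !hold, drop = FALSE] %*% sol$theta) + sol$b
      mse[g, f] <- mean((y[hold] - pred)^2)
    }
  }
  cv <- rowMeans(mse)
  best <- which.min(cv)                        # which.min takes the first tie
  scores <- cbind(grid, cv_mse = cv)
  structure(list(scores = scores, best = best,
                 C = grid$C[best], epsilon = grid$epsilon[best],
                 gamma = if ("gamma" %in% names(grid)) grid$gamma[best] else gamma,
                 kernel = kernel, k_folds = k_folds, seed = seed),
            class = "mweeg_cv")
}

#' @export
print.mweeg_cv <- function(x, ...) {
  cat(sprintf("<grid search: %s kernel, %d candidates, %d folds; best C=%g epsilon=%g (CV MSE %.4f)>\n",
              x$kernel, nrow(x$scores), x$k_folds, x$C, x$epsilon,
              x$scores$cv_mse[x$best]))
  invisible(x)
}
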