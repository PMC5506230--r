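test_that("a constant response inside the tube gives the trivial fit", {
  x <- matrix(rnorm(20), 10, 2)
  m <- svr_fit(x, rep(3, 10), "linear", C = 1, epsilon = 0.5)
  expect_equal(unname(predict(m, x)), rep(3, 10), tolerance = 1e-8)
  expect_equal(sum(m$w^2), 0, tolerance = 1e-10)
  expect_equal(svr_objective(m), 0, tolerance = 1e-10)
})

test_that("small instances reach the brute-force dual-QP optimum, both kernels", {
  set.seed(11)
  for (trial in 1:8) {
    n <- sample(4:8, 1); p <- sample(1:3, 1)
    X <- matrix(rnorm(n * p), n); y <- rnorm(n)
    C <- 2^runif(1, -2, 2); eps <- 2^runif(1, -4, -1)
    for (kern in c("linear", "rbf")) {
      gamma <- 1 / p
      K <- if (kern == "linear") X %*% t(X) else rbf_gram(X, gamma)
      m <- svr_fit(X, y, kern, C = C, epsilon = eps, gamma = gamma)
      oracle <- svr_dual_oracle(K, y, C, eps)
      expect_lt(abs(svr_objective(m) - oracle$objective), 1e-6)
      if (kern == "rbf") {
        ## with a full-rank kernel, samples strictly inside the tube are
        ## non-support (rank-deficient linear kernels admit equally optimal
        ## representations that spread weight over duplicate directions)
        f <- predict(m, X)
        inside <- abs(y - f) < eps - 1e-4
        expect_true(all(abs(m$theta[inside]) < 1e-4))
      }
    }
  }
})

test_that("raising C never increases the training epsilon-insensitive loss", {
  set.seed(3)
  X <- matrix(rnorm(60), 20, 3)
  y <- X[, 1] + rnorm(20, 0, 0.4)
  loss <- vapply(c(0.1, 1, 10, 100), function(C) {
    m <- svr_fit(X, y, "linear", C = C, epsilon = 0.1)
    sum(pmax(abs(y - predict(m, X)) - 0.1, 0))
  }, 0)
  expect_true(all(diff(loss) <= 1e-8))
})

test_that("linear predictions equal the explicit dot product and empty input works", {
  set.seed(5)
  X <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rnorm(10)
  m <- svr_fit(X, y, "linear", C = 2, epsilon = 0.05)
  expect_equal(predict(m, X), as.vector(X %*% m$w) + m$b, tolerance = 1e-12)
  expect_length(predict(m, X[0, , drop = FALSE]), 0)
  expect_error(predict(m, X[, 1:2, drop = FALSE]), "column")
})

test_that("with a huge RBF width the fit interpolates training data within the tube", {
  set.seed(9)
  X <- matrix(rnorm(12), 6, 2)
  y <- rnorm(6)
  m <- svr_fit(X, y, "rbf", C = 1000, epsilon = 0.01, gamma = 100)
  expect_true(all(abs(y - predict(m, X)) <= 0.01 + 1e-6))
})

test_that("epsilon 0 with large C approaches least squares on tall instances", {
  set.seed(13)
  X <- matrix(rnorm(200), 100, 2)
  y <- 2 * X[, 1] - X[, 2] + rnorm(100, 0, 0.3)
  m <- svr_fit(X, y, "linear", C = 1e4, epsilon = 0)
  ls <- stats::lm.fit(cbind(1, X), y)$coefficients
  expect_equal(c(m$b, m$w), unname(ls), tolerance = 0.05)
})

test_that("grid search scores every candidate by held-out fold MSE", {
  set.seed(7)
  X <- matrix(rnorm(12), 6, 2)
  y <- X[, 1] + rnorm(6, 0, 0.1)
  grid <- default_grid(C = c(0.5, 2), epsilon = 0.1)
  cv <- grid_search_cv(X, y, "linear", grid = grid, k_folds = 2, seed = 4)
  ## hand-computed cross-validation with the same folds
  fold <- mweeg:::with_seed(4, sample(rep(1:2, length.out = 6)))
  manual <- vapply(seq_len(nrow(grid)), function(g) {
    mean(vapply(1:2, function(f) {
      m <- svr_fit(X[fold != f, ], y[fold != f], "linear",
                   C = grid$C[g], epsilon = grid$epsilon[g])
      mean((y[fold == f] - predict(m, X[fold == f, , drop = FALSE]))^2)
    }, 0))
  }, 0)
  expect_equal(cv$scores$cv_mse, manual, tolerance = 1e-6)
  expect_equal(cv$best, which.min(manual))
  ## the winner never scores worse than any other candidate
  expect_true(all(cv$scores$cv_mse[cv$best] <= cv$scores$cv_mse))

  ## single-candidate grids are returned as-is; empty grids refused
  one <- grid_search_cv(X, y, "rbf", grid = default_grid(C = 1, epsilon = 0.2),
                        k_folds = 3, seed = 1)
  expect_equal(one$C, 1); expect_equal(one$epsilon, 0.2)
  expect_error(grid_search_cv(X, y, "rbf", grid = default_grid(C = numeric(0)),
                              k_folds = 2, seed = 1), "empty")
})

test_that("fold sizes are as equal as possible", {
  fold <- mweeg:::with_seed(1, sample(rep(seq_len(10), length.out = 440)))
  expect_true(all(table(fold) == 44))
  fold2 <- mweeg:::with_seed(1, sample(rep(seq_len(3), length.out = 10)))
  expect_true(all(table(fold2) %in% 3:4))
})

test_that("the default hyperparameter grid spans the powers of two", {
  g <- default_grid()
  expect_setequal(unique(g$C), 2^(-4:2))
  expect_setequal(unique(g$epsilon), 2^(-6:1))
  expect_equal(nrow(g), 56)
})
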