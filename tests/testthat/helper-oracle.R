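# Independent brute-force oracle for the epsilon-SVR dual: a dense
# box-constrained QP over (alpha, alpha*) solved with nloptr's SLSQP,
# entirely separate from the package's SMO fitting path.
svr_dual_oracle <- function(K, y, C, eps) {
  n <- length(y)
  H0 <- rbind(cbind(K, -K), cbind(-K, K))
  cvec <- c(eps - y, eps + y)
  fn <- function(x) 0.5 * sum(x * (H0 %*% x)) + sum(cvec * x)
  gr <- function(x) as.vector(H0 %*% x) + cvec
  res <- nloptr::slsqp(
    x0 = rep(0, 2 * n), fn = fn, gr = gr,
    lower = rep(0, 2 * n), upper = rep(C, 2 * n),
    heq = function(x) sum(x[1:n]) - sum(x[(n + 1):(2 * n)]),
    heqjac = function(x) matrix(c(rep(1, n), rep(-1, n)), 1),
    control = list(xtol_rel = 1e-14, maxeval = 20000))
  x <- pmin(pmax(res$par, 0), C)
  theta <- x[1:n] - x[(n + 1):(2 * n)]
  ## at the optimum the dual value equals the primal optimum
  list(theta = theta, objective = -fn(x))
}

# Primal objective evaluated from first principles.
svr_primal_objective <- function(theta, b, K, y, C, eps) {
  f <- as.vector(K %*% theta) + b
  0.5 * sum(theta * (K %*% theta)) + C * sum(pmax(abs(y - f) - eps, 0))
}

rbf_gram <- function(X, gamma) exp(-gamma * as.matrix(dist(X))^2)
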