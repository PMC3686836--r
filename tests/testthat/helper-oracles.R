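# Independent oracles and small data builders used across the suite.

# Normal-equation solution by explicit matrix inversion: the brute-force
# least-squares oracle, kept deliberately naive.
normal_equation_oracle <- function(X, y) {
  drop(solve(t(X) %*% X) %*% t(X) %*% y)
}

# Exhaustive LTS oracle: least-squares fit on every h-subset, objective
# re-evaluated on the full data (sum of the h smallest squared
# residuals). Feasible for n <= 12.
lts_exhaustive_oracle <- function(X, y, h) {
  n <- nrow(X)
  best <- list(obj = Inf, beta = NULL)
  for (idx in utils::combn(n, h, simplify = FALSE)) {
    Xs <- X[idx, , drop = FALSE]
    if (qr(Xs)$rank < ncol(X)) next
    beta <- drop(solve(t(Xs) %*% Xs) %*% t(Xs) %*% y[idx])
    r2 <- sort((y - drop(X %*% beta))^2)
    obj <- sum(r2[seq_len(h)])
    if (obj < best$obj) best <- list(obj = obj, beta = beta)
  }
  best
}

# n points on an exact line with optional gross y-outliers at the end.
make_line_data <- function(n = 20, intercept = 2, slope = 3,
                           n_outliers = 0, shift = 1000) {
  x <- seq_len(n)
  y <- intercept + slope * x
  if (n_outliers > 0) {
    y[(n - n_outliers + 1):n] <- y[(n - n_outliers + 1):n] + shift
  }
  list(X = cbind("(Intercept)" = 1, x = x), y = y)
}

# Balanced two-arm dataset with exchangeable arms (no true effect).
make_null_cea <- function(n = 200, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    effect = rnorm(n, 5, 1),
    cost = rnorm(n, 50, 5),
    arm = rep(c(0, 1), length.out = n),
    x = rnorm(n, 2, 0.5)
  )
}
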