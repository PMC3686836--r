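#' @useDynLib nbreg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# --- design-matrix plumbing -------------------------------------------

# Validate an (X, y) regression problem: numeric, n > p, full column rank.
# On rank deficiency the error names the offending column.
check_design <- function(X, y) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (n <= p) stop("need more observations than parameters (n > p)", call. = FALSE)
  if (anyNA(X) || anyNA(y)) stop("design matrix and response must be complete", call. = FALSE)
  qrx <- qr(X)
  if (qrx$rank < p) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1):p]]
    if (is.null(bad)) bad <- qrx$pivot[(qrx$rank + 1):p]
    stop("singular design: column(s) ", paste(bad, collapse = ", "),
         " linearly dependent on the others", call. = FALSE)
  }
  list(X = X, y = y, n = n, p = p)
}

new_fit_result <- function(method, X, y, beta, se, scale, weights,
                           converged = TRUE, iterations = 0L,
                           objective = NA_real_, subset = NULL,
                           trace = NULL, df_residual = NULL) {
  beta <- as.numeric(beta)
  names(beta) <- colnames(X)
  names(se) <- colnames(X)
  fitted <- drop(X %*% beta)
  structure(
    list(
      method = method,
      coefficients = beta,
      se = as.numeric(se),
      scale = scale,
      weights = as.numeric(weights),
      residuals = y - fitted,
      fitted = fitted,
      converged = converged,
      iterations = as.integer(iterations),
      objective = objective,
      subset = subset,
      trace = trace,
      n = nrow(X),
      p = ncol(X),
      df_residual = if (is.null(df_residual)) nrow(X) - ncol(X) else df_residual,
      qr_xtx_inv = chol2inv(qr.R(qr(X)))
    ),
    class = "nbreg_fit"
  )
}

#' @export
print.nbreg_fit <- function(x, ...) {
  cat("<nbreg_fit> method:", x$method,
      if (!x$converged) "(NOT converged)", "\n")
  print(round(rbind(estimate = x$coefficients, std.error = x$se), 5))
  cat("residual scale:", signif(x$scale, 6),
      " n:", x$n, " iterations:", x$iterations, "\n")
  invisible(x)
}

#' @export
coef.nbreg_fit <- function(object, ...) object$coefficients

#' @export
residuals.nbreg_fit <- function(object, ...) object$residuals

# --- scale -------------------------------------------------------------

#' Median-absolute-deviation residual scale
#'
#' `median(|r - median(r)|) / 0.6745`, the Gaussian-consistent MAD used
#' as the residual scale inside every M-type iteration.
#'
#' @param residuals Numeric vector, length >= 2.
#' @return A positive scalar.
#' @examples
#' mad_scale(c(-1, 0, 1)) # 1/0.6745
#' @export
mad_scale <- function(residuals) {
  if (length(residuals) < 2) stop("need at least two residuals", call. = FALSE)
  s <- stats::median(abs(residuals - stats::median(residuals))) / 0.6745
  if (s <= 0) {
    stop("degenerate residual scale: more than half the residuals are ",
         "identical (exact fit?)", call. = FALSE)
  }
  s
}

# --- OLS ---------------------------------------------------------------

#' Ordinary least squares with classical standard errors
#'
#' @param X Numeric design matrix including an intercept column.
#' @param y Numeric response.
#' @return A `"nbreg_fit"` with coefficients, classical standard errors
#'   (`sigma^2 (X'X)^{-1}`), residual scale `sqrt(RSS/(n-p))` and unit
#'   weights.
#' @export
ols_fit <- function(X, y) {
  d <- check_design(X, y)
  fit <- stats::lm.fit(d$X, d$y)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / (d$n - d$p)
  xtx_inv <- chol2inv(qr.R(fit$qr))
  se <- sqrt(pmax(diag(xtx_inv) * sigma2, 0))
  new_fit_result("ols", d$X, d$y, fit$coefficients, se,
                 scale = sqrt(sigma2), weights = rep(1, d$n),
                 objective = rss)
}

# Sandwich-style covariance for M-type fits at scale `scale`:
#   K^2 * scale^2 * [sum(psi^2)/(n-p)] / mean(psi')^2 * (X'X)^{-1}
# with Huber's finite-sample correction
#   K = 1 + p/n * var(psi') / mean(psi')^2.
m_stderr <- function(X, u, spec, scale, xtx_inv) {
  n <- nrow(X); p <- ncol(X)
  psi <- spec$psi(u)
  psip <- spec$psi_prime(u)
  mpsip <- mean(psip)
  if (!is.finite(mpsip) || mpsip <= 0) return(rep(NA_real_, p))
  K <- 1 + p / n * stats::var(psip) / mpsip^2
  s2 <- K^2 * scale^2 * (sum(psi^2) / (n - p)) / mpsip^2
  sqrt(pmax(diag(xtx_inv) * s2, 0))
}

exact_fit_result <- function(method, X, y, beta, iterations = 0L) {
  new_fit_result(method, X, y, beta, se = rep(0, ncol(X)), scale = 0,
                 weights = rep(1, nrow(X)), converged = TRUE,
                 iterations = iterations, objective = 0)
}

# --- M-estimation ------------------------------------------------------

#' M-estimation by iteratively reweighted least squares
#'
#' Minimizes `sum(rho((y - X b) / sigma))` for the chosen loss family,
#' with the MAD scale recomputed from the residuals at every iteration.
#' Starts from the OLS fit. Standard errors use the M-estimation
#' asymptotic covariance with Huber's small-sample correction.
#'
#' @inheritParams ols_fit
#' @param spec A [rho_spec()] other than `"ols"`.
#' @param max_iter Maximum IRLS iterations.
#' @param tol Relative coefficient-change convergence tolerance.
#' @return A `"nbreg_fit"`; `converged = FALSE` (not an error) if the
#'   iteration limit is hit. Final weights are `weight_eval(r/sigma)`.
#' @export
m_fit <- function(X, y, spec, max_iter = 100L, tol = 1e-8) {
  stopifnot(inherits(spec, "rho_spec"))
  if (spec$name == "ols") stop("use ols_fit() for the squared-error family", call. = FALSE)
  d <- check_design(X, y)
  start <- stats::lm.fit(d$X, d$y)
  beta <- start$coefficients
  xtx_inv <- chol2inv(qr.R(start$qr))

  r <- d$y - drop(d$X %*% beta)
  y_spread <- stats::median(abs(d$y - stats::median(d$y)))
  if (stats::median(abs(r - stats::median(r))) <= 1e-12 * max(1, y_spread)) {
    # degenerate scale at the start: report the exact/near-exact fit
    return(exact_fit_result(spec$name, d$X, d$y, beta))
  }

  converged <- FALSE
  iter <- 0L
  sigma <- mad_scale(r)
  repeat {
    iter <- iter + 1L
    w <- spec$wgt(r / sigma)
    fit <- stats::lm.wfit(d$X, d$y, pmax(w, 1e-12))
    delta <- abs(fit$coefficients - beta)
    beta <- fit$coefficients
    r <- d$y - drop(d$X %*% beta)
    med_abs <- stats::median(abs(r - stats::median(r)))
    if (med_abs <= 0) {
      return(exact_fit_result(spec$name, d$X, d$y, beta, iterations = iter))
    }
    sigma <- med_abs / 0.6745
    if (all(delta < tol * (1 + abs(beta)))) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
  }
  u <- r / sigma
  new_fit_result(spec$name, d$X, d$y, beta,
                 se = m_stderr(d$X, u, spec, sigma, xtx_inv),
                 scale = sigma, weights = spec$wgt(u),
                 converged = converged, iterations = iter,
                 objective = sum(spec$rho(u)))
}

# --- S- and MM-estimation ---------------------------------------------

#' S-estimation of regression
#'
#' Minimizes the bisquare M-scale of the residuals, tuned to the
#' requested breakdown point, by random p-subset sampling with
#' weighted-least-squares refinement steps (the search runs in compiled
#' code with its own seeded RNG stream).
#'
#' @inheritParams ols_fit
#' @param bdp Breakdown point in (0, 0.5]; 0.5 gives bisquare
#'   `c0 = 1.548`.
#' @param n_starts Number of random p-subsets.
#' @param k_steps Refinement I-steps per start before the best
#'   candidates are polished to convergence.
#' @param seed Integer seed for the subset search; `NULL` draws one from
#'   the session RNG (so `set.seed()` upstream still fixes the result).
#' @return A `"nbreg_fit"` whose `scale` is the minimized M-scale.
#' @export
s_fit <- function(X, y, bdp = 0.5, n_starts = 200L, k_steps = 2L,
                  seed = NULL) {
  stopifnot(bdp > 0, bdp <= 0.5, n_starts >= 1)
  d <- check_design(X, y)
  if (d$n < d$p + 1) stop("too few points to form p-subsets", call. = FALSE)
  c0 <- bisquare_bdp_constant(bdp)
  b <- bdp * c0^2 / 6
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  res <- cpp_s(d$X, d$y, c0, b, as.integer(n_starts), as.integer(k_steps),
               10L, as.integer(seed))
  beta <- res$beta
  scale <- res$scale
  if (scale <= 0) return(exact_fit_result("s", d$X, d$y, beta))
  spec0 <- rho_spec("tukey", c0)
  r <- d$y - drop(d$X %*% beta)
  u <- r / scale
  xtx_inv <- chol2inv(qr.R(qr(d$X)))
  new_fit_result("s", d$X, d$y, beta,
                 se = m_stderr(d$X, u, spec0, scale, xtx_inv),
                 scale = scale, weights = spec0$wgt(u),
                 objective = mean(spec0$rho(u)))
}

#' MM-estimation
#'
#' A bisquare M-step tuned to the requested Gaussian efficiency,
#' initialized at the S-estimation coefficients and run at the S-scale,
#' which is never updated. Combines the S-stage's high breakdown point
#' with high efficiency at the Gaussian model.
#'
#' @inheritParams s_fit
#' @param efficiency Gaussian efficiency of the final M-step, in
#'   (0.5, 1); 0.95 gives bisquare `c1 = 4.685`.
#' @param max_iter,tol IRLS controls as in [m_fit()].
#' @return A `"nbreg_fit"`; `trace` holds the objective
#'   `sum(rho(r/s_S))` across iterations (non-increasing).
#' @export
mm_fit <- function(X, y, efficiency = 0.95, bdp = 0.5, n_starts = 200L,
                   k_steps = 2L, seed = NULL, max_iter = 100L, tol = 1e-8) {
  stopifnot(efficiency > 0.5, efficiency < 1)
  d <- check_design(X, y)
  s_stage <- s_fit(d$X, d$y, bdp = bdp, n_starts = n_starts,
                   k_steps = k_steps, seed = seed)
  sigma <- s_stage$scale
  beta <- s_stage$coefficients
  if (sigma <= 0) {
    out <- exact_fit_result("mm", d$X, d$y, beta)
    return(out)
  }
  spec <- rho_spec("tukey", bisquare_efficiency_constant(efficiency))
  r <- d$y - drop(d$X %*% beta)
  obj <- sum(spec$rho(r / sigma))
  trace <- obj
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    w <- spec$wgt(r / sigma)
    if (sum(w) <= 0) break
    fit <- stats::lm.wfit(d$X, d$y, pmax(w, 1e-12))
    delta <- abs(fit$coefficients - beta)
    cand_r <- d$y - drop(d$X %*% fit$coefficients)
    cand_obj <- sum(spec$rho(cand_r / sigma))
    if (cand_obj > obj + 1e-10 * (1 + abs(obj))) break # safeguard descent
    beta <- fit$coefficients
    r <- cand_r
    obj <- cand_obj
    trace <- c(trace, obj)
    if (all(delta < tol * (1 + abs(beta)))) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
  }
  u <- r / sigma
  xtx_inv <- chol2inv(qr.R(qr(d$X)))
  new_fit_result("mm", d$X, d$y, beta,
                 se = m_stderr(d$X, u, spec, sigma, xtx_inv),
                 scale = sigma, weights = spec$wgt(u),
                 converged = converged, iterations = iter,
                 objective = obj, trace = trace)
}

# --- least trimmed squares --------------------------------------------

default_lts_h <- function(n, p) {
  max(floor(3 * n / 4), floor((n + p + 1) / 2))
}

#' Least trimmed squares via the concentration algorithm
#'
#' Minimizes the sum of the `h` smallest squared residuals by random
#' p-subset starts followed by concentration (C-) steps, the best
#' candidates being concentrated to convergence. The returned fit is the
#' least-squares refit on the covered h-subset: covered observations get
#' weight 1, trimmed ones weight 0. The residual scale applies the usual
#' Gaussian consistency factor for `h/n` coverage, and standard errors
#' come from the covered-subset least-squares covariance with that
#' corrected scale.
#'
#' @inheritParams ols_fit
#' @param h Coverage count, `floor((n+p+1)/2) <= h <= n`; default
#'   `floor(3n/4)` (bounded below), which tolerates up to 25%
#'   contamination.
#' @param n_starts Random p-subset starts (default 500).
#' @param n_csteps C-steps applied to every start before the best
#'   `n_keep` candidates are concentrated to convergence.
#' @param n_keep Candidates kept for full concentration.
#' @param seed Integer seed for the subset search; `NULL` draws one from
#'   the session RNG.
#' @return A `"nbreg_fit"` with `objective` (the trimmed sum of squares),
#'   `subset` (covered row indices) and `trace` (objective per C-step of
#'   the winning candidate, non-increasing).
#' @export
lts_fit <- function(X, y, h = NULL, n_starts = 500L, n_csteps = 10L,
                    n_keep = 10L, seed = NULL) {
  d <- check_design(X, y)
  if (is.null(h)) h <- default_lts_h(d$n, d$p)
  h <- as.integer(h)
  hmin <- floor((d$n + d$p + 1) / 2)
  if (h < hmin || h > d$n) {
    stop("h must lie in [", hmin, ", ", d$n, "]", call. = FALSE)
  }
  if (h == d$n) {
    out <- ols_fit(d$X, d$y)
    out$method <- "lts"
    out$subset <- seq_len(d$n)
    return(out)
  }
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  res <- cpp_lts(d$X, d$y, h, as.integer(n_starts), as.integer(n_csteps),
                 as.integer(n_keep), as.integer(seed))
  subset <- as.integer(res$subset)
  Xh <- d$X[subset, , drop = FALSE]
  yh <- d$y[subset]
  refit <- stats::lm.fit(Xh, yh)
  beta <- refit$coefficients
  rss_h <- sum(refit$residuals^2)

  # Gaussian consistency factor for hard h/n trimming
  alpha <- h / d$n
  qa <- stats::qnorm((1 + alpha) / 2)
  cons <- alpha / (alpha - 2 * qa * stats::dnorm(qa))
  s2 <- if (h > d$p) rss_h / (h - d$p) * cons else 0
  xtx_h_inv <- chol2inv(qr.R(refit$qr))
  se <- sqrt(pmax(diag(xtx_h_inv) * s2, 0))

  w <- numeric(d$n)
  w[subset] <- 1
  new_fit_result("lts", d$X, d$y, beta, se, scale = sqrt(s2), weights = w,
                 objective = res$objective, subset = subset,
                 trace = as.numeric(res$trace))
}

# --- one-sided inference ----------------------------------------------

#' One-sided test of a positive regression coefficient
#'
#' Upper-tail p-value of `beta[index] / se[index]` against a t reference
#' with `n - p` degrees of freedom: the test of H0 `coefficient <= 0`
#' against H1 `coefficient > 0` used to declare cost-effectiveness when
#' the tested coefficient is the incremental net benefit.
#'
#' @param fit A `"nbreg_fit"`.
#' @param index Coefficient position (2 = the treatment indicator in a
#'   net-benefit design).
#' @return p-value in \[0, 1\].
#' @export
coef_test_onesided <- function(fit, index = 2L) {
  stopifnot(inherits(fit, "nbreg_fit"))
  se <- fit$se[index]
  if (!is.finite(se) || se <= 0) {
    stop("standard error is zero or undefined for coefficient ", index,
         call. = FALSE)
  }
  stat <- fit$coefficients[index] / se
  unname(stats::pt(stat, df = fit$df_residual, lower.tail = FALSE))
}

# --- dispatch ----------------------------------------------------------

nbreg_methods <- function() c("ols", "huber", "hampel", "tukey", "mm", "lts")

# One front door for all six estimators; `control` carries the
# method-specific knobs.
fit_engine <- function(X, y, method, control = list()) {
  method <- match.arg(method, nbreg_methods())
  ctl <- utils::modifyList(
    list(tuning = NULL, efficiency = 0.95, bdp = 0.5, h = NULL,
         n_starts = NULL, n_csteps = 10L, k_steps = 2L, n_keep = 10L,
         seed = NULL, max_iter = 100L, tol = 1e-8),
    control
  )
  switch(method,
    ols = ols_fit(X, y),
    huber = ,
    hampel = ,
    tukey = m_fit(X, y, rho_spec(method, ctl$tuning),
                  max_iter = ctl$max_iter, tol = ctl$tol),
    mm = mm_fit(X, y, efficiency = ctl$efficiency, bdp = ctl$bdp,
                n_starts = if (is.null(ctl$n_starts)) 200L else ctl$n_starts,
                k_steps = ctl$k_steps, seed = ctl$seed,
                max_iter = ctl$max_iter, tol = ctl$tol),
    lts = lts_fit(X, y, h = ctl$h,
                  n_starts = if (is.null(ctl$n_starts)) 500L else ctl$n_starts,
                  n_csteps = ctl$n_csteps, n_keep = ctl$n_keep,
                  seed = ctl$seed)
  )
}
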