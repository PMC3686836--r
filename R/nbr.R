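# Cost-effectiveness semantics: net benefit, NBR fits at a
# willingness-to-pay, the one-sided cost-effectiveness test, probabilities
# of cost-effectiveness and CEAC curves.

# Validate patient-level data and pull out the analysis columns.
validate_cea <- function(data, effect = "effect", cost = "cost",
                         arm = "arm", covariates = NULL) {
  stopifnot(is.data.frame(data))
  need <- c(effect, cost, arm, covariates)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop("column(s) not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  sub <- data[need]
  na_rows <- which(!stats::complete.cases(sub))
  if (length(na_rows)) {
    stop("missing values in rows: ",
         paste(utils::head(na_rows, 10), collapse = ", "),
         if (length(na_rows) > 10) " ...", call. = FALSE)
  }
  a <- data[[arm]]
  vals <- sort(unique(a))
  if (!all(vals %in% c(0, 1))) {
    stop("arm column must be coded 0/1; found value(s): ",
         paste(setdiff(vals, c(0, 1)), collapse = ", "), call. = FALSE)
  }
  if (length(vals) < 2) {
    stop("both arms must be present in the data", call. = FALSE)
  }
  cov_mat <- if (length(covariates)) {
    m <- as.matrix(data[covariates])
    storage.mode(m) <- "double"
    m
  } else {
    matrix(numeric(0), nrow(data), 0)
  }
  list(effect = as.numeric(data[[effect]]),
       cost = as.numeric(data[[cost]]),
       arm = as.numeric(a),
       covariates = cov_mat,
       labels = covariates,
       n = nrow(data))
}

#' Per-subject net benefit
#'
#' `wtp * effect - cost` for every subject: the monetary value of the
#' observed effectiveness at willingness-to-pay `wtp`, net of cost.
#'
#' @param data Data frame of patient-level records.
#' @param wtp Willingness-to-pay per unit of effectiveness (>= 0).
#' @param effect,cost Names of the effectiveness and cost columns.
#' @return Numeric vector of length `nrow(data)`, in currency units.
#' @examples
#' d <- data.frame(effect = c(1, 2), cost = c(10, 30))
#' net_benefit(d, wtp = 10) # 0, -10
#' @export
net_benefit <- function(data, wtp, effect = "effect", cost = "cost") {
  if (!is.numeric(wtp) || length(wtp) != 1 || wtp < 0) {
    stop("wtp must be a single nonnegative number", call. = FALSE)
  }
  stopifnot(is.data.frame(data), all(c(effect, cost) %in% names(data)))
  wtp * as.numeric(data[[effect]]) - as.numeric(data[[cost]])
}

#' Fit a net-benefit regression at one willingness-to-pay
#'
#' Regresses the per-subject net benefit on the treatment indicator and
#' covariates: `wtp*E - C = b0 + b_T*arm + b_1*x_1 + ... + e`. The
#' coefficient on `arm` is the incremental net benefit (INB) of the
#' intervention; H0 `INB <= 0` is tested one-sided against H1 `INB > 0`,
#' and the probability of cost-effectiveness is 1 minus that p-value.
#'
#' @inheritParams net_benefit
#' @param method One of `"ols"`, `"huber"`, `"hampel"`, `"tukey"`,
#'   `"mm"`, `"lts"`.
#' @param arm Name of the 0/1 treatment column (1 = intervention).
#' @param covariates Character vector of covariate columns (may be
#'   empty).
#' @param ... Estimator controls passed through: `tuning`, `efficiency`,
#'   `bdp`, `h`, `n_starts`, `n_csteps`, `k_steps`, `seed`, `max_iter`,
#'   `tol` (see [m_fit()], [mm_fit()], [lts_fit()]).
#' @return An object of class `"nbr_fit"`: the engine fit plus `wtp`,
#'   `inb`, `p_value`, `prob_ce` (= 1 - p) and `outlier_prop` (share of
#'   observations with final weight below 0.5; `NA` for OLS). Use
#'   [tidy()] / [glance()] to extract tibbles.
#' @examples
#' d <- sim_nbr_data(sim_config(n = 200, outlier_prop = 0), seed = 1)
#' fit <- fit_nbr(d, wtp = 12, method = "ols", covariates = "x")
#' glance(fit)
#' @export
fit_nbr <- function(data, wtp, method = "ols", effect = "effect",
                    cost = "cost", arm = "arm", covariates = NULL, ...) {
  method <- match.arg(method, nbreg_methods())
  cea <- validate_cea(data, effect, cost, arm, covariates)
  y <- net_benefit(data, wtp, effect, cost)
  X <- cbind("(Intercept)" = 1, arm = cea$arm, cea$covariates)
  if (length(cea$labels)) {
    colnames(X)[-(1:2)] <- cea$labels
  }
  fit <- withCallingHandlers(
    fit_engine(X, y, method, control = list(...)),
    error = function(e) {
      stop("net-benefit fit (method=", method, ", wtp=", wtp, ") failed: ",
           conditionMessage(e), call. = FALSE)
    }
  )
  p <- coef_test_onesided(fit, 2L)
  structure(
    list(fit = fit, wtp = wtp, method = method,
         inb = unname(fit$coefficients[2]),
         p_value = p, prob_ce = 1 - p,
         outlier_prop = outlier_proportion(fit),
         n = cea$n, covariates = cea$labels),
    class = "nbr_fit"
  )
}

#' @export
print.nbr_fit <- function(x, ...) {
  cat("Net-benefit regression (", x$method, ") at WTP = ", x$wtp, "\n",
      sep = "")
  cat("  incremental net benefit:", signif(x$inb, 6), "\n")
  cat("  one-sided p (H1: INB > 0):", signif(x$p_value, 4),
      " P(cost-effective):", signif(x$prob_ce, 4), "\n")
  if (is.finite(x$outlier_prop)) {
    cat("  flagged outlier share (weight < 0.5):",
        signif(x$outlier_prop, 3), "\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Coefficient-level summary of a net-benefit regression
#'
#' @param x An `"nbr_fit"`.
#' @param ... Unused.
#' @return A tibble with one row per model term: estimate, standard
#'   error, t statistic and two-sided p-value. The one-sided
#'   cost-effectiveness test lives in [glance()].
#' @export
tidy.nbr_fit <- function(x, ...) {
  f <- x$fit
  stat <- ifelse(f$se > 0, f$coefficients / f$se, NA_real_)
  tibble::tibble(
    term = names(f$coefficients),
    estimate = unname(f$coefficients),
    std.error = unname(f$se),
    statistic = unname(stat),
    p.value = unname(2 * stats::pt(abs(stat), f$df_residual,
                                   lower.tail = FALSE))
  )
}

#' One-row summary of a net-benefit regression
#'
#' @param x An `"nbr_fit"`.
#' @param ... Unused.
#' @return A tibble with the willingness-to-pay, method, incremental net
#'   benefit, one-sided p-value, regression probability of
#'   cost-effectiveness, flagged outlier share, residual scale,
#'   convergence flag and sample size.
#' @export
glance.nbr_fit <- function(x, ...) {
  tibble::tibble(
    wtp = x$wtp,
    method = x$method,
    inb = x$inb,
    p_one_sided = x$p_value,
    prob_ce_regression = x$prob_ce,
    outlier_proportion = x$outlier_prop,
    scale = x$fit$scale,
    converged = x$fit$converged,
    n = x$n
  )
}

#' Share of observations flagged as outliers by a robust fit
#'
#' The fraction of observations whose final robustness weight falls
#' below 0.5; for least trimmed squares this is exactly the trimmed
#' fraction (weights are 0/1). The 0.5 threshold is a reporting
#' convention, not part of the estimation.
#'
#' @param fit A `"nbreg_fit"` from a robust estimator.
#' @return Proportion in \[0, 1\]; `NA` for an OLS fit (OLS never
#'   downweights).
#' @export
outlier_proportion <- function(fit) {
  stopifnot(inherits(fit, "nbreg_fit"))
  if (fit$method == "ols") return(NA_real_)
  mean(fit$weights < 0.5)
}

#' Bootstrap probability of cost-effectiveness
#'
#' Nonparametric case bootstrap: subjects are resampled with
#' replacement, the net-benefit regression is refit, and the probability
#' of cost-effectiveness is the fraction of replicates with a positive
#' incremental net benefit. Replicates that lose an arm entirely are
#' redrawn (and counted in the `n_redrawn` attribute).
#'
#' @inheritParams fit_nbr
#' @param B Number of bootstrap replicates (>= 100).
#' @param seed Optional integer seed for reproducible resampling.
#' @return Probability in \[0, 1\] with attribute `n_redrawn`.
#' @export
prob_ce_bootstrap <- function(data, wtp, method = "ols", B = 1000L,
                              seed = NULL, effect = "effect",
                              cost = "cost", arm = "arm",
                              covariates = NULL, ...) {
  if (B < 100) stop("B must be at least 100", call. = FALSE)
  validate_cea(data, effect, cost, arm, covariates)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(data)
  pos <- 0L
  redrawn <- 0L
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(data[[arm]][idx])) == 2L) break
      redrawn <- redrawn + 1L
      if (redrawn > 100L * B) {
        stop("bootstrap cannot draw two-arm replicates", call. = FALSE)
      }
    }
    f <- fit_nbr(data[idx, , drop = FALSE], wtp, method, effect, cost,
                 arm, covariates, ...)
    pos <- pos + (f$inb > 0)
  }
  if (redrawn > 0) {
    rlang::inform(paste0(redrawn, " bootstrap replicate(s) redrawn for a missing arm"))
  }
  structure(pos / B, n_redrawn = redrawn)
}

#' Cost-effectiveness acceptability curve
#'
#' Fits the net-benefit regression at every willingness-to-pay on the
#' grid and records the probability of cost-effectiveness (1 minus the
#' one-sided p-value; optionally the bootstrap probability as well).
#'
#' @inheritParams fit_nbr
#' @param wtp Strictly increasing grid of nonnegative
#'   willingness-to-pay values.
#' @param bootstrap If `TRUE`, add a bootstrap probability column.
#' @param B,seed Bootstrap controls (see [prob_ce_bootstrap()]).
#' @return A tibble of class `"nbr_ceac"` with columns `wtp`, `method`,
#'   `inb`, `prob_ce` and, if requested, `prob_ce_bootstrap`. Plot with
#'   [autoplot()] or [plot_ceac()].
#' @examples
#' d <- sim_nbr_data(sim_config(n = 300, outlier_prop = 0), seed = 2)
#' ceac(d, wtp = c(5, 10, 15), covariates = "x")
#' @export
ceac <- function(data, wtp, method = "ols", effect = "effect",
                 cost = "cost", arm = "arm", covariates = NULL,
                 bootstrap = FALSE, B = 1000L, seed = NULL, ...) {
  if (!length(wtp)) stop("wtp grid must be nonempty", call. = FALSE)
  if (any(wtp < 0) || is.unsorted(wtp, strictly = TRUE)) {
    stop("wtp grid must be nonnegative and strictly increasing",
         call. = FALSE)
  }
  rows <- purrr::map(wtp, function(l) {
    g <- tryCatch(
      glance(fit_nbr(data, l, method, effect, cost, arm, covariates, ...)),
      error = function(e) {
        stop("CEAC failed at wtp = ", l, ": ", conditionMessage(e),
             call. = FALSE)
      }
    )
    out <- g[c("wtp", "method", "inb", "prob_ce_regression")]
    names(out)[4] <- "prob_ce"
    if (bootstrap) {
      out$prob_ce_bootstrap <- as.numeric(
        prob_ce_bootstrap(data, l, method, B = B, seed = seed,
                          effect = effect, cost = cost, arm = arm,
                          covariates = covariates, ...)
      )
    }
    out
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("nbr_ceac", class(out))
  out
}

#' Table of net-benefit fits across methods and willingness-to-pay
#'
#' One row per (method, wtp) combination: incremental net benefit,
#' one-sided p-value, regression probability of cost-effectiveness,
#' optional bootstrap probability, and the flagged outlier share. A
#' failing estimator is reported in its `error` column without aborting
#' the other methods.
#'
#' @inheritParams fit_nbr
#' @param wtp Numeric vector of willingness-to-pay values.
#' @param methods Character vector of estimators to run.
#' @param bootstrap If `TRUE`, add bootstrap probabilities.
#' @param B,seed Bootstrap controls.
#' @return A tibble with `length(methods) * length(wtp)` rows.
#' @export
fit_nbr_table <- function(data, wtp, methods = nbreg_methods(),
                          effect = "effect", cost = "cost", arm = "arm",
                          covariates = NULL, bootstrap = FALSE,
                          B = 1000L, seed = NULL, ...) {
  methods <- match.arg(methods, nbreg_methods(), several.ok = TRUE)
  grid <- expand.grid(wtp = wtp, method = methods,
                      stringsAsFactors = FALSE)
  rows <- purrr::pmap(grid, function(wtp, method) {
    res <- tryCatch(
      glance(fit_nbr(data, wtp, method, effect, cost, arm, covariates, ...)),
      error = function(e) {
        tibble::tibble(wtp = wtp, method = method, inb = NA_real_,
                       p_one_sided = NA_real_,
                       prob_ce_regression = NA_real_,
                       outlier_proportion = NA_real_, scale = NA_real_,
                       converged = NA, n = nrow(data),
                       error = conditionMessage(e))
      }
    )
    if (!"error" %in% names(res)) res$error <- NA_character_
    if (bootstrap && is.na(res$error)) {
      res$prob_ce_bootstrap <- as.numeric(
        prob_ce_bootstrap(data, wtp, method, B = B, seed = seed,
                          effect = effect, cost = cost, arm = arm,
                          covariates = covariates, ...)
      )
    }
    res
  })
  dplyr::bind_rows(rows)
}
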