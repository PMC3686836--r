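#' Symmetric loss families for M-type regression
#'
#' A `rho_spec` bundles the loss `rho`, its derivative `psi`, the IRLS
#' weight function `psi(r)/r` and the derivative `psi'` for one of the
#' families used by the net-benefit regression estimators: squared error
#' (`"ols"`), Huber, Hampel three-part redescending, and Tukey's bisquare.
#'
#' Default tuning constants are the usual 95%-Gaussian-efficiency choices:
#' Huber `k = 1.345`, Hampel `(a, b, c) = (1.7, 3.4, 8.5)`, bisquare
#' `c = 4.685`. All rho functions satisfy `rho(0) = 0`, are symmetric and
#' nondecreasing in `|r|`; the redescending families (Hampel, bisquare)
#' are constant beyond their outermost tuning constant, so gross outliers
#' receive zero weight.
#'
#' @param name One of `"ols"`, `"huber"`, `"hampel"`, `"tukey"`.
#' @param tuning Numeric vector of positive tuning constants: `k` for
#'   Huber, `c(a, b, c)` with `a < b < c` for Hampel, `c` for bisquare,
#'   empty/`NULL` for `"ols"`. `NULL` selects the family default.
#' @return An object of class `"rho_spec"`: a list with elements `name`,
#'   `tuning` and vectorized functions `rho`, `psi`, `psi_prime`, `wgt`.
#' @examples
#' sp <- rho_spec("huber")
#' sp$rho(c(0, 1.345, 10))
#' rho_spec("tukey")$wgt(c(0, 2, 10))
#' @export
rho_spec <- function(name = c("ols", "huber", "hampel", "tukey"),
                     tuning = NULL) {
  name <- match.arg(name)
  tuning <- switch(name,
    ols = numeric(0),
    huber = if (is.null(tuning)) 1.345 else tuning,
    hampel = if (is.null(tuning)) c(1.7, 3.4, 8.5) else tuning,
    tukey = if (is.null(tuning)) 4.685 else tuning
  )
  n_expect <- c(ols = 0L, huber = 1L, hampel = 3L, tukey = 1L)[[name]]
  if (length(tuning) != n_expect || any(tuning <= 0)) {
    stop("invalid tuning for family '", name, "': expected ", n_expect,
         " positive constant(s)", call. = FALSE)
  }
  if (name == "hampel" && (tuning[1] >= tuning[2] || tuning[2] >= tuning[3])) {
    stop("hampel tuning must satisfy a < b < c", call. = FALSE)
  }

  fns <- switch(name,
    ols = list(
      rho = function(r) r^2 / 2,
      psi = function(r) r,
      psi_prime = function(r) rep_len(1, length(r)),
      wgt = function(r) rep_len(1, length(r))
    ),
    huber = local({
      k <- tuning[1]
      list(
        rho = function(r) ifelse(abs(r) <= k, r^2 / 2, k * abs(r) - k^2 / 2),
        psi = function(r) pmin(pmax(r, -k), k),
        psi_prime = function(r) as.numeric(abs(r) <= k),
        wgt = function(r) pmin(1, k / pmax(abs(r), .Machine$double.eps))
      )
    }),
    hampel = local({
      a <- tuning[1]; b <- tuning[2]; cc <- tuning[3]
      psi1 <- function(r) {
        x <- abs(r)
        v <- numeric(length(r))
        v[x <= a] <- x[x <= a]
        v[x > a & x <= b] <- a
        mid <- x > b & x < cc
        v[mid] <- a * (cc - x[mid]) / (cc - b)
        v * sign(r)
      }
      list(
        rho = function(r) {
          x <- abs(r)
          v <- numeric(length(r))
          i1 <- x <= a
          v[i1] <- x[i1]^2 / 2
          i2 <- x > a & x <= b
          v[i2] <- a * x[i2] - a^2 / 2
          i3 <- x > b & x < cc
          v[i3] <- a * b - a^2 / 2 +
            (a / 2) * (cc - b) * (1 - ((cc - x[i3]) / (cc - b))^2)
          v[x >= cc] <- a * b - a^2 / 2 + a * (cc - b) / 2
          v
        },
        psi = psi1,
        psi_prime = function(r) {
          x <- abs(r)
          v <- numeric(length(r))
          v[x <= a] <- 1
          v[x > b & x < cc] <- -a / (cc - b)
          v
        },
        wgt = function(r) {
          u <- psi1(r) / r
          u[r == 0] <- 1
          pmin(pmax(u, 0), 1)
        }
      )
    }),
    tukey = local({
      cc <- tuning[1]
      list(
        rho = function(r) {
          out <- rep_len(cc^2 / 6, length(r))
          i <- abs(r) < cc
          out[i] <- cc^2 / 6 * (1 - (1 - (r[i] / cc)^2)^3)
          out
        },
        psi = function(r) {
          v <- numeric(length(r))
          i <- abs(r) < cc
          v[i] <- r[i] * (1 - (r[i] / cc)^2)^2
          v
        },
        psi_prime = function(r) {
          v <- numeric(length(r))
          i <- abs(r) < cc
          u2 <- (r[i] / cc)^2
          v[i] <- (1 - u2) * (1 - 5 * u2)
          v
        },
        wgt = function(r) {
          v <- numeric(length(r))
          i <- abs(r) < cc
          v[i] <- (1 - (r[i] / cc)^2)^2
          v
        }
      )
    })
  )
  structure(c(list(name = name, tuning = tuning), fns), class = "rho_spec")
}

#' Evaluate a loss family
#'
#' Convenience evaluators for a [rho_spec()]: the loss itself, its
#' derivative (the influence function), and the IRLS weight
#' `psi(r) / r` (1 at the origin by continuity).
#'
#' @param spec A [rho_spec()].
#' @param r Numeric vector of (scaled) residuals.
#' @return Numeric vector of the same length as `r`.
#' @export
rho_eval <- function(spec, r) {
  stopifnot(inherits(spec, "rho_spec"))
  spec$rho(r)
}

#' @rdname rho_eval
#' @export
psi_eval <- function(spec, r) {
  stopifnot(inherits(spec, "rho_spec"))
  spec$psi(r)
}

#' @rdname rho_eval
#' @export
weight_eval <- function(spec, r) {
  stopifnot(inherits(spec, "rho_spec"))
  spec$wgt(r)
}

#' @export
print.rho_spec <- function(x, ...) {
  cat("<rho_spec> family:", x$name,
      if (length(x$tuning)) paste0("tuning: ", paste(x$tuning, collapse = ", ")),
      "\n")
  invisible(x)
}

# --- tuning-constant solvers for the bisquare family -------------------

.tuning_cache <- new.env(parent = emptyenv())

# E[rho_c(Z)] for Z ~ N(0,1), bisquare with rho(inf) = c^2/6
.bisq_erho <- function(cc) {
  f <- function(z) {
    sp <- rho_spec("tukey", cc)
    sp$rho(z) * stats::dnorm(z)
  }
  2 * stats::integrate(f, 0, cc)$value +
    2 * cc^2 / 6 * stats::pnorm(cc, lower.tail = FALSE)
}

#' Bisquare tuning constant for a target breakdown point
#'
#' Solves `E[rho_c(Z)] = bdp * rho_c(Inf)` for standard-normal `Z`, the
#' consistency condition making the S-estimator's M-scale Fisher
#' consistent at the Gaussian model with the requested breakdown point.
#' `bdp = 0.5` gives `c = 1.5476`.
#'
#' @param bdp Breakdown point in (0, 0.5].
#' @return The tuning constant `c`.
#' @export
bisquare_bdp_constant <- function(bdp) {
  stopifnot(bdp > 0, bdp <= 0.5)
  key <- paste0("bdp", format(bdp, digits = 12))
  if (!is.null(.tuning_cache[[key]])) return(.tuning_cache[[key]])
  g <- function(cc) .bisq_erho(cc) / (cc^2 / 6) - bdp
  out <- stats::uniroot(g, c(0.2, 40), tol = 1e-10)$root
  .tuning_cache[[key]] <- out
  out
}

#' Bisquare tuning constant for a target Gaussian efficiency
#'
#' Solves `(E[psi'_c(Z)])^2 / E[psi_c(Z)^2] = efficiency` for
#' standard-normal `Z`. `efficiency = 0.95` gives `c = 4.685`, the
#' constant used by the final M-step of MM-estimation.
#'
#' @param efficiency Asymptotic efficiency at the Gaussian model, in
#'   (0.5, 1).
#' @return The tuning constant `c`.
#' @export
bisquare_efficiency_constant <- function(efficiency) {
  stopifnot(efficiency > 0.5, efficiency < 1)
  key <- paste0("eff", format(efficiency, digits = 12))
  if (!is.null(.tuning_cache[[key]])) return(.tuning_cache[[key]])
  eff <- function(cc) {
    sp <- rho_spec("tukey", cc)
    epsi2 <- 2 * stats::integrate(function(z) sp$psi(z)^2 * stats::dnorm(z),
                                  0, cc)$value
    epsip <- 2 * stats::integrate(function(z) sp$psi_prime(z) * stats::dnorm(z),
                                  0, cc)$value
    epsip^2 / epsi2
  }
  g <- function(cc) eff(cc) - efficiency
  out <- stats::uniroot(g, c(1, 40), tol = 1e-10)$root
  .tuning_cache[[key]] <- out
  out
}
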