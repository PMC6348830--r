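# Time-integrated activity coefficients.
#
# For f(t) = sum_i A_i exp(-lambda_i t) with amplitudes in percent of
# injected activity, the TIAC (residence time) per unit administered
# activity is the exact integral
#     TIAC = integral_0^inf f(t)/100 dt = sum_i (A_i/100) / lambda_i
# in hours for organs (h/mL for blood concentration curves). The standard
# error follows by the delta method, se = sqrt(g' C g), with g the
# gradient of the TIAC with respect to the free fit parameters and C their
# covariance; a seeded Monte-Carlo oracle cross-checks it.

#' TIAC estimate
#'
#' @param value TIAC, >= 0 (h for organs, h/mL for blood).
#' @param se Standard error (same unit), >= 0 or `NA`.
#' @param species,region Labels.
#' @param unit `"h"` or `"h_per_ml"`.
#' @return Object of class `tiac_estimate`.
#' @export
tiac_estimate <- function(value, se = NA_real_, species = NA_character_,
                          region = NA_character_, unit = "h") {
  if (!is_number(value) || value < 0) stop_bk("TIAC value must be >= 0")
  if (!is.na(se) && se < 0) stop_bk("TIAC se must be >= 0")
  structure(
    list(value = value, se = se, species = species, region = region,
         unit = unit),
    class = "tiac_estimate"
  )
}

#' @export
print.tiac_estimate <- function(x, ...) {
  cat(sprintf("<tiac_estimate> %s/%s: %.4g +/- %.2g %s\n",
              x$species, x$region, x$value, x$se, x$unit))
  invisible(x)
}

# closed-form integral of an exp_model / 100 over [0, Inf)
model_tiac_value <- function(model) {
  if (any(model$terms$lambda <= 0)) {
    stop_bk("non-integrable model: every lambda must be > 0")
  }
  sum(model$terms$A / 100 / model$terms$lambda)
}

#' Physical-decay upper bound on an organ TIAC
#'
#' The activity ever present in a region can at most decay with the
#' physical constant, so the TIAC is bounded by
#' \eqn{\sum_{A_i > 0} (A_i/100)/\lambda_{phys}}.
#'
#' @param model An [exp_model()].
#' @return Upper bound in hours (may be `Inf` if `lambda_phys = 0`).
#' @export
tiac_physical_bound <- function(model) {
  if (model$lambda_phys <= 0) return(Inf)
  pos <- model$terms$A > 0
  sum(model$terms$A[pos] / 100) / model$lambda_phys
}

# gradient of the TIAC w.r.t. the internal free parameters of a form
.tiac_gradient <- function(form, par) {
  switch(form,
    mono = c(1 / (100 * par[2]), -par[1] / (100 * par[2]^2)),
    bi = c(1 / (100 * par[2]), -par[1] / (100 * par[2]^2),
           1 / (100 * par[4]), -par[3] / (100 * par[4]^2)),
    bi_uptake = {
      l1 <- par[2]; l2 <- par[2] + par[3]
      c((1 / l1 - 1 / l2) / 100,
        par[1] * (-1 / l1^2 + 1 / l2^2) / 100,
        par[1] / (100 * l2^2))
    }
  )
}

#' Delta-method standard error of a TIAC
#'
#' First-order Gaussian error propagation through the analytic TIAC
#' expression: `se = sqrt(g' C g)` with `g` the gradient of
#' \eqn{\sum_i (A_i/100)/\lambda_i} with respect to the free parameters
#' (in the fit's internal parameterization) and `C` the fit covariance.
#'
#' @param fit A `fit_result` from [fit_candidates()].
#' @return Standard error, same unit as the TIAC.
#' @export
propagate_error <- function(fit) {
  stopifnot(inherits(fit, "fit_result"))
  C <- fit$cov
  if (is.null(C)) stop_bk("fit carries no covariance")
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1e-300)) {
    stop_bk("covariance is not positive semi-definite")
  }
  g <- .tiac_gradient(fit$form, fit$par)
  sqrt(max(drop(t(g) %*% C %*% g), 0))
}

#' Integrate a fitted model into a TIAC
#'
#' Exact closed-form integration of the fitted sum of exponentials over
#' `[0, Inf)` (no quadrature), divided by 100 to convert percent of
#' injected activity into fraction. Organ TIACs come out in hours, blood
#' concentration TIACs in h/mL. The standard error is attached via
#' [propagate_error()] when the input is a fit with covariance.
#'
#' @param fit A `fit_result` from [fit_candidates()], or a bare
#'   [exp_model()] (then `se` is `NA`).
#' @param with_se Compute the delta-method standard error? Default `TRUE`
#'   for fits.
#' @return A [tiac_estimate()].
#' @export
#' @examples
#' m <- exp_model(A = c(30, 10), lambda = c(0.5, 0.01), lambda_phys = 0.004)
#' integrate_tiac(m)$value # 0.3/0.5 + 0.1/0.01 = 10.6 h
integrate_tiac <- function(fit, with_se = TRUE) {
  if (inherits(fit, "exp_model")) {
    return(tiac_estimate(model_tiac_value(fit), NA_real_))
  }
  stopifnot(inherits(fit, "fit_result"))
  if (!isTRUE(fit$converged)) stop_bk("fit did not converge")
  value <- model_tiac_value(fit$model)
  se <- if (with_se) propagate_error(fit) else NA_real_
  unit <- if (identical(fit$unit, "pct_ia_per_ml")) "h_per_ml" else "h"
  tiac_estimate(value, se, fit$species, fit$region, unit)
}

# TIACs for a matrix of internal-parameter draws (rows)
.tiac_of_draws <- function(form, draws) {
  switch(form,
    mono = draws[, 1] / (100 * draws[, 2]),
    bi = draws[, 1] / (100 * draws[, 2]) + draws[, 3] / (100 * draws[, 4]),
    bi_uptake = draws[, 1] / 100 *
      (1 / draws[, 2] - 1 / (draws[, 2] + draws[, 3]))
  )
}

# rows violating the rate constraints (lambda >= lambda_phys, dlambda > 0)
.invalid_draws <- function(form, draws, lambda_phys) {
  switch(form,
    mono = draws[, 2] < lambda_phys,
    bi = draws[, 2] < lambda_phys | draws[, 4] < lambda_phys,
    bi_uptake = draws[, 2] < lambda_phys | draws[, 3] <= 0
  )
}

#' Monte-Carlo oracle for the TIAC standard error
#'
#' Samples the free parameters from a multivariate normal with the fit's
#' estimate and covariance, rejects draws violating the rate constraints
#' (`lambda >= lambda_phys`; washout faster than uptake for the bi_uptake
#' form) and redraws, and returns the sample standard deviation of the
#' analytic TIAC over the accepted draws. Used as an independent check of
#' [propagate_error()]; a rejection rate above 50% signals a regime where
#' the linearized (delta-method) error is not meaningful and is an error.
#'
#' @param fit A `fit_result`.
#' @param n_draws Number of accepted draws, >= 1000. Default 1e5.
#' @param seed Integer seed (reproducible; caller's RNG preserved).
#' @return Standard error estimate (sample SD).
#' @export
mc_error_oracle <- function(fit, n_draws = 1e5, seed = 1L) {
  stopifnot(inherits(fit, "fit_result"))
  if (n_draws < 1000) stop_bk("n_draws must be >= 1000")
  C <- fit$cov
  if (max(abs(C)) == 0) return(0)
  lambda_phys <- fit$model$lambda_phys
  with_preserved_seed(seed, {
    accepted <- matrix(numeric(0), ncol = length(fit$par))
    total <- 0L
    rejected <- 0L
    while (nrow(accepted) < n_draws) {
      m <- max(2L * (n_draws - nrow(accepted)), 1000L)
      draws <- MASS::mvrnorm(m, mu = fit$par, Sigma = C)
      bad <- .invalid_draws(fit$form, draws, lambda_phys)
      total <- total + m
      rejected <- rejected + sum(bad)
      if (rejected / total > 0.5 && total >= 1000L) {
        stop_bk("rejection rate ", round(100 * rejected / total), "% > 50%: ",
                "delta-method error propagation is invalid in this regime")
      }
      accepted <- rbind(accepted, draws[!bad, , drop = FALSE])
    }
    sd(.tiac_of_draws(fit$form, accepted[seq_len(n_draws), , drop = FALSE]))
  })
}
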