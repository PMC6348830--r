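# Weighted sum-of-exponentials fitting with a physical-decay rate floor
# and AICc model selection.
#
# Candidate forms:
#   mono       f(t) = A exp(-lambda t)                      p = 2
#   bi         f(t) = A1 exp(-l1 t) + A2 exp(-l2 t)         p = 4
#   bi_uptake  f(t) = A (exp(-l1 t) - exp(-l2 t)), l2 > l1  p = 3
# All rates are effective (>= lambda_phys). bi_uptake is parameterized
# internally as (A, lambda1, dlambda) with lambda2 = lambda1 + dlambda so
# the ordering constraint becomes a simple box bound.
#
# Weighting is chi-square with the curve's per-point sigmas treated as
# known (they encode the assumed 10% quantification uncertainty), so the
# parameter covariance is the unscaled inverse Gauss-Newton normal matrix
# (J'J)^-1 of the sigma-scaled residuals.

.bk_forms <- c("mono", "bi", "bi_uptake")

.form_npar <- c(mono = 2L, bi = 4L, bi_uptake = 3L)

.form_parnames <- list(
  mono = c("A", "lambda"),
  bi = c("A1", "lambda1", "A2", "lambda2"),
  bi_uptake = c("A", "lambda1", "dlambda")
)

normalize_form <- function(form) {
  f <- gsub("-", "_", tolower(form))
  if (!all(f %in% .bk_forms)) {
    stop_bk("unknown model form(s): ", paste(setdiff(form, .bk_forms), collapse = ", "))
  }
  f
}

# model value for internal parameter vector
.form_value <- function(form, par, t) {
  switch(form,
    mono = par[1] * exp(-par[2] * t),
    bi = par[1] * exp(-par[2] * t) + par[3] * exp(-par[4] * t),
    bi_uptake = par[1] * (exp(-par[2] * t) - exp(-(par[2] + par[3]) * t))
  )
}

# Jacobian d f / d par, rows = t, cols = parameters
.form_jac <- function(form, par, t) {
  switch(form,
    mono = {
      e <- exp(-par[2] * t)
      cbind(e, -par[1] * t * e)
    },
    bi = {
      e1 <- exp(-par[2] * t); e2 <- exp(-par[4] * t)
      cbind(e1, -par[1] * t * e1, e2, -par[3] * t * e2)
    },
    bi_uptake = {
      e1 <- exp(-par[2] * t); e2 <- exp(-(par[2] + par[3]) * t)
      cbind(e1 - e2, par[1] * t * (e2 - e1), par[1] * t * e2)
    }
  )
}

.form_bounds <- function(form, lambda_phys) {
  switch(form,
    mono = list(lower = c(0, lambda_phys), upper = c(Inf, Inf)),
    bi = list(lower = c(0, lambda_phys, 0, lambda_phys),
              upper = c(Inf, Inf, Inf, Inf)),
    bi_uptake = list(lower = c(0, lambda_phys, 1e-10),
                     upper = c(Inf, Inf, Inf))
  )
}

# internal parameters -> exp_model terms
.form_model <- function(form, par, lambda_phys) {
  switch(form,
    mono = exp_model(par[1], par[2], lambda_phys),
    bi = exp_model(c(par[1], par[3]), c(par[2], par[4]), lambda_phys),
    bi_uptake = exp_model(c(par[1], -par[1]),
                          c(par[2], par[2] + par[3]), lambda_phys)
  )
}

# log-linear regression on positive points; returns c(A, lambda) or NULL
.loglin <- function(t, y) {
  keep <- is.finite(y) & y > 0
  if (sum(keep) < 2L) return(NULL)
  fit <- lm(log(y[keep]) ~ t[keep])
  c(A = exp(unname(coef(fit)[1])), lambda = -unname(coef(fit)[2]))
}

#' Curve-peeling start values for an exponential fit
#'
#' Classical initialization: a log-linear regression on the tail of the
#' curve yields the slow term; a log-linear fit of the positive residuals
#' over the early points yields the fast term. Zero-valued points are
#' excluded from the log steps and the result is clipped into the fit
#' bounds (amplitudes >= 0, rates >= `lambda_phys`).
#'
#' @param curve A [tac_curve()].
#' @param form `"mono"`, `"bi"` or `"bi_uptake"` (alias `"bi-uptake"`).
#' @param lambda_phys Physical decay constant (1/h).
#' @return Named numeric vector of start values in the internal
#'   parameterization (see [fit_candidates()]).
#' @export
initial_params <- function(curve, form, lambda_phys = lambda_phys_lu177()) {
  form <- normalize_form(form)
  tt <- curve$samples$t
  yy <- curve$samples$value
  if (all(yy <= 0)) stop_bk("cannot initialize from all-zero values")
  n <- length(tt)
  ymax <- max(yy)

  clip <- function(par) {
    b <- .form_bounds(form, lambda_phys)
    pmin(pmax(par, b$lower), b$upper)
  }

  if (form == "mono") {
    start <- .loglin(tt, yy)
    if (is.null(start)) stop_bk("fewer than 2 positive values for mono start")
    return(clip(setNames(start, .form_parnames$mono)))
  }

  # slow term from the tail (at least 2 points, about half the curve)
  ntail <- max(2L, floor(n / 2))
  idx_tail <- seq.int(n - ntail + 1L, n)
  slow <- .loglin(tt[idx_tail], yy[idx_tail])
  if (is.null(slow)) slow <- .loglin(tt, yy)
  if (is.null(slow)) stop_bk("fewer than 2 positive values for tail start")
  slow["lambda"] <- max(slow["lambda"], lambda_phys)

  if (form == "bi") {
    idx_head <- seq_len(n - ntail)
    resid <- yy[idx_head] - slow["A"] * exp(-slow["lambda"] * tt[idx_head])
    fast <- .loglin(tt[idx_head], resid)
    if (is.null(fast)) {
      fast <- c(A = max(ymax - slow[["A"]], ymax / 2),
                lambda = 10 * slow[["lambda"]])
    }
    par <- c(fast[["A"]], max(fast[["lambda"]], 2 * slow[["lambda"]]),
             slow[["A"]], slow[["lambda"]])
    return(clip(setNames(par, .form_parnames$bi)))
  }

  # bi_uptake: slow washout from the tail; the fast (uptake) rate set from
  # the time of the observed peak
  t_peak <- tt[which.max(yy)]
  dl <- max(3 / max(t_peak, min(tt[tt > 0], 1)), 10 * slow[["lambda"]]) -
    slow[["lambda"]]
  par <- c(slow[["A"]], slow[["lambda"]], max(dl, 1e-6))
  clip(setNames(par, .form_parnames$bi_uptake))
}

# one Levenberg-Marquardt run; returns list(par, chi2, converged).
# A strict pass (ftol/ptol 1e-13, for exact recovery on noiseless data) is
# followed, if it stalls at the iteration limit on a weakly identified
# ridge, by a polish pass at standard tolerances from the stalled point.
.lm_run <- function(par0, form, tt, yy, ss, lambda_phys) {
  b <- .form_bounds(form, lambda_phys)
  par0 <- pmin(pmax(par0, b$lower), 1e12)
  one_pass <- function(p0, ftol, ptol, maxiter) {
    suppressWarnings(try(minpack.lm::nls.lm(
      par = p0,
      lower = b$lower, upper = b$upper,
      fn = function(p) (.form_value(form, p, tt) - yy) / ss,
      jac = function(p) .form_jac(form, p, tt) / ss,
      control = minpack.lm::nls.lm.control(
        maxiter = maxiter, maxfev = 20 * maxiter,
        ftol = ftol, ptol = ptol, gtol = 0
      )
    ), silent = TRUE))
  }
  res <- one_pass(par0, ftol = 1e-13, ptol = 1e-13, maxiter = 1000)
  if (inherits(res, "try-error")) {
    return(list(par = par0, chi2 = Inf, converged = FALSE,
                message = as.character(res)))
  }
  if (res$info %in% c(-1, 5)) {
    polish <- one_pass(res$par, ftol = 1e-10, ptol = 1e-10, maxiter = 500)
    if (!inherits(polish, "try-error")) res <- polish
  }
  list(par = res$par, chi2 = res$deviance,
       converged = res$info %in% 1:3, message = res$message)
}

#' Fit candidate exponential models to a time-activity curve
#'
#' Weighted least squares minimizing \eqn{\sum_k ((y_k - f(t_k))/\sigma_k)^2}
#' with the curve's sigmas, rates bounded below by `lambda_phys`.
#' Each candidate is started from the curve-peeling values
#' ([initial_params()]) plus `n_starts` seeded log-uniform perturbations
#' (biexponential weighted least squares is multi-modal); the best
#' converged run is kept. The parameter covariance is the inverse
#' Gauss-Newton normal matrix of the sigma-scaled residuals and the AICc
#' is computed from the weighted deviance:
#' \eqn{AICc = \chi^2 + 2p + 2p(p+1)/(n-p-1)} (infinite when
#' \eqn{n \le p+1}).
#'
#' @param curve A [tac_curve()] (a per-point sigma floor of 1e-9 in curve
#'   units is applied to avoid infinite weights).
#' @param lambda_phys Physical decay constant (1/h). Default Lu-177.
#' @param candidates Subset of `"mono"`, `"bi"`, `"bi_uptake"`.
#' @param n_starts Number of perturbed restarts per candidate. Default 20.
#' @param start_seed Seed for the restart perturbations (fits are
#'   deterministic given this seed; the caller's RNG state is preserved).
#' @return List of `fit_result` objects, one per candidate that converged
#'   and had enough points. Each has elements `form`, `par`, `cov`
#'   (internal parameterization), `model` ([exp_model()]), `chi2`, `aicc`,
#'   `n_points`, `weights_cv`, `converged`, plus the curve labels.
#' @export
#' @examples
#' sc <- default_scenarios()[["pig/kidneys"]]
#' cv <- generate_curve(sc, noise_model(cv = 0.1, seed = 7))
#' fits <- fit_candidates(cv, candidates = c("mono", "bi"))
#' select_model(fits)$form
fit_candidates <- function(curve, lambda_phys = lambda_phys_lu177(),
                           candidates = c("mono", "bi", "bi_uptake"),
                           n_starts = 20L, start_seed = 20177L) {
  stopifnot(inherits(curve, "tac_curve"))
  candidates <- normalize_form(candidates)
  tt <- curve$samples$t
  yy <- curve$samples$value
  ss <- pmax(curve$samples$sigma, 1e-9)
  n <- length(tt)

  feasible <- candidates[.form_npar[candidates] + 1L <= n]
  if (!length(feasible)) {
    stop_bk("curve ", curve$species, "/", curve$region, " has ", n,
            " points; every candidate needs at least p+1 points ",
            "(p = ", paste(.form_npar[candidates], collapse = ", "), ")")
  }

  diagnostics <- character(0)
  fits <- list()
  for (form in feasible) {
    p <- .form_npar[[form]]
    start <- try(initial_params(curve, form, lambda_phys), silent = TRUE)
    if (inherits(start, "try-error")) {
      diagnostics <- c(diagnostics, paste0(form, ": ", as.character(start)))
      next
    }
    # peeled start plus seeded log-uniform perturbations in [1/3, 3]
    perturb <- with_preserved_seed(
      start_seed + match(form, .bk_forms),
      replicate(n_starts, start * exp(runif(p, -log(3), log(3))),
                simplify = FALSE)
    )
    best <- NULL
    for (par0 in c(list(start), perturb)) {
      run <- .lm_run(par0, form, tt, yy, ss, lambda_phys)
      if (run$converged && (is.null(best) || run$chi2 < best$chi2)) best <- run
    }
    if (is.null(best)) {
      diagnostics <- c(diagnostics, paste0(form, ": no start converged"))
      next
    }
    J <- .form_jac(form, best$par, tt) / ss
    JtJ <- crossprod(J)
    covm <- tryCatch(chol2inv(chol(JtJ)),
                     error = function(e) MASS::ginv(JtJ))
    dimnames(covm) <- list(.form_parnames[[form]], .form_parnames[[form]])
    aicc <- if (n - p - 1L > 0L) {
      best$chi2 + 2 * p + 2 * p * (p + 1) / (n - p - 1)
    } else {
      Inf
    }
    fits[[form]] <- structure(
      list(
        form = form,
        par = setNames(best$par, .form_parnames[[form]]),
        cov = covm,
        model = .form_model(form, best$par, lambda_phys),
        chi2 = best$chi2,
        aicc = aicc,
        n_points = n,
        weights_cv = median(ss / pmax(yy, 1e-9)),
        converged = TRUE,
        species = curve$species,
        region = curve$region,
        unit = curve$unit
      ),
      class = "fit_result"
    )
  }
  if (!length(fits)) {
    stop_bk("no candidate converged for ", curve$species, "/", curve$region,
            ": ", paste(diagnostics, collapse = "; "))
  }
  fits
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s/%s form=%s chi2=%.4g AICc=%.4g n=%d\n",
              x$species %||% "?", x$region %||% "?", x$form, x$chi2,
              x$aicc, x$n_points))
  print(x$model)
  invisible(x)
}

#' Select the best fit by corrected AIC
#'
#' Returns the converged fit with the lowest AICc. Ties (|delta AICc| <
#' 0.01, or all AICc infinite) are broken toward the model with fewer free
#' parameters.
#'
#' @param fits List of `fit_result` objects from [fit_candidates()].
#' @return The selected `fit_result`.
#' @export
select_model <- function(fits) {
  fits <- Filter(function(f) isTRUE(f$converged), fits)
  if (!length(fits)) stop_bk("no converged fits to select from")
  aicc <- vapply(fits, function(f) f$aicc, numeric(1))
  npar <- vapply(fits, function(f) length(f$par), numeric(1))
  best <- min(aicc)
  tied <- if (is.finite(best)) which(aicc - best < 0.01) else seq_along(fits)
  pick <- tied[order(npar[tied], aicc[tied])][1]
  fits[[pick]]
}
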