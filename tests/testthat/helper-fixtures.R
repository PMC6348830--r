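# Shared fixtures: random valid models, a quadrature oracle, CSV writers.

lp177 <- lambda_phys_lu177()

# Seeded generator of random valid exponential models (1 or 2 positive
# terms, or an uptake-washout pair), rates >= lambda_phys.
random_models <- function(n, seed, lambda_phys = lp177,
                          forms = c("mono", "bi", "bi_uptake")) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      get(".Random.seed", envir = .GlobalEnv)
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv))
    set.seed(seed)
    code
  }
  withr_seed({
    lapply(seq_len(n), function(i) {
      form <- sample(forms, 1)
      lam_slow <- lambda_phys * 10^runif(1, 0.05, 1.5)
      lam_fast <- lam_slow * 10^runif(1, 0.5, 2)
      A1 <- 10^runif(1, -0.5, 1.5)
      A2 <- 10^runif(1, -0.5, 1.5)
      switch(form,
        mono = exp_model(A1, lam_slow, lambda_phys),
        bi = exp_model(c(A1, A2), c(lam_fast, lam_slow), lambda_phys),
        bi_uptake = exp_model(c(A1, -A1), c(lam_slow, lam_fast), lambda_phys)
      )
    })
  })
}

# independent numerical oracle for the TIAC: adaptive quadrature on [0, Inf)
quad_tiac <- function(model) {
  stats::integrate(function(t) predict(model, t) / 100, 0, Inf,
                   rel.tol = 1e-12, abs.tol = 0)$value
}

# write a curves CSV from a data frame of rows
write_curve_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# noiseless curve sampled from a model on a schedule (sigma = 10%)
exact_curve <- function(model, schedule, species = "pig",
                        region = "kidneys", unit = "pct_ia") {
  vals <- predict(model, schedule)
  tac_curve(species, region, unit, t = schedule, value = vals,
            sigma = pmax(0.10 * vals, 1e-9))
}

pig_schedule <- c(0.5, 2, 3, 4, 50, 100, 150, 250)

# Build a fit_result directly from a model plus a controlled covariance
# (AR(1)-type correlation, relative SEs). Rate SEs are capped so the
# lambda >= lambda_phys constraint stays several SDs away: the regime in
# which delta-method propagation is the appropriate tool.
synthetic_fit <- function(model, rel_se = 0.05, rho = 0.3) {
  tm <- model$terms
  lp <- model$lambda_phys
  if (all(tm$A >= 0)) {
    if (nrow(tm) == 1L) {
      form <- "mono"
      par <- c(A = tm$A[1], lambda = tm$lambda[1])
    } else {
      form <- "bi"
      par <- c(A1 = tm$A[1], lambda1 = tm$lambda[1],
               A2 = tm$A[2], lambda2 = tm$lambda[2])
    }
  } else {
    form <- "bi_uptake"
    pos <- which(tm$A >= 0); neg <- which(tm$A < 0)
    par <- c(A = tm$A[pos], lambda1 = tm$lambda[pos],
             dlambda = tm$lambda[neg] - tm$lambda[pos])
  }
  se <- rel_se * abs(par)
  is_rate <- grepl("lambda", names(par))
  headroom <- ifelse(names(par) == "dlambda", par, pmax(par - lp, 0))
  se[is_rate] <- pmin(se[is_rate], headroom[is_rate] / 6)
  p <- length(par)
  R <- rho^abs(outer(seq_len(p), seq_len(p), "-"))
  covm <- diag(se) %*% R %*% diag(se)
  dimnames(covm) <- list(names(par), names(par))
  structure(
    list(form = form, par = par, cov = covm, model = model, chi2 = 0,
         aicc = NA_real_, n_points = NA_integer_, weights_cv = rel_se,
         converged = TRUE, species = "synthetic", region = "organ",
         unit = "pct_ia"),
    class = "fit_result"
  )
}
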