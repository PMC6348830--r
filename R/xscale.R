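# Interspecies extrapolation of TIACs: the five published methods.
#
#   Method 1  same biodistribution: TIAC_h = TIAC_a
#   Method 2  relative mass scaling:
#             TIAC_h = TIAC_a * (m_organ/m_WB)_h / (m_organ/m_WB)_a
#   Method 3  time scaling: the biological time axis is stretched by
#             c = (m_WB_h / m_WB_a)^0.25, i.e. each effective rate becomes
#             lambda_phys + (lambda - lambda_phys)/c (physical decay is a
#             nuclide property, not physiology; set scale_physical_decay
#             to TRUE for the naive lambda/c variant)
#   Method 4  combined: Method 3 then Method 2
#   Method 5  allometric: TIAC_h = TIAC_a * (m_WB_h/m_WB_a)^(b-1),
#             b = 0.92 (liver), 0.85 (kidneys) by default
#
# For the blood region, Method 2 uses total blood volume (1 g/mL) in place
# of the organ mass and refuses when a profile lacks it — mirroring the
# exclusion of mouse blood from scaling when no blood volume is known.

#' Scaled TIAC
#'
#' Result of one extrapolation method applied to one animal TIAC.
#'
#' @param method Method id 1..5.
#' @param source_species Animal species label.
#' @param region Region label.
#' @param value Scaled TIAC, >= 0.
#' @param unit `"h"` or `"h_per_ml"`.
#' @param inputs Named list recording the masses/exponents used.
#' @return Object of class `scaled_tiac`.
#' @export
scaled_tiac <- function(method, source_species, region, value, unit = "h",
                        inputs = list()) {
  if (!(method %in% 1:5)) stop_bk("method must be in 1..5")
  if (!is_number(value) || value < 0) stop_bk("scaled TIAC must be >= 0")
  structure(
    list(method = as.integer(method), source_species = source_species,
         region = region, value = value, unit = unit, inputs = inputs),
    class = "scaled_tiac"
  )
}

#' @export
print.scaled_tiac <- function(x, ...) {
  cat(sprintf("<scaled_tiac> method %d, %s/%s: %.4g %s\n",
              x$method, x$source_species, x$region, x$value, x$unit))
  invisible(x)
}

# organ mass fraction m_organ/m_WB; blood uses volume at 1 g/mL
.mass_fraction <- function(profile, region) {
  if (identical(region, "blood")) {
    if (is.null(profile$blood_volume_ml)) {
      stop_bk("Method 2 refused: no blood volume available for species '",
              profile$name, "' (cannot form a blood mass fraction)")
    }
    return(profile$blood_volume_ml / 1000 / profile$m_wb)
  }
  m <- unname(profile$organ_masses[region])
  if (is.null(profile$organ_masses) || is.na(m)) {
    stop_bk("Method 2 refused: species '", profile$name,
            "' has no organ mass for region '", region, "'")
  }
  m / profile$m_wb
}

#' Method 1: same biodistribution
#'
#' The human TIAC is taken equal to the animal TIAC (no extrapolation).
#'
#' @param tiac A [tiac_estimate()].
#' @return A [scaled_tiac()] with the value and unit unchanged.
#' @export
method1_same <- function(tiac) {
  stopifnot(inherits(tiac, "tiac_estimate"))
  scaled_tiac(1L, tiac$species, tiac$region, tiac$value, tiac$unit)
}

#' Method 2: relative mass scaling
#'
#' Multiplies the animal TIAC by the ratio of human to animal organ mass
#' fractions (organ mass over whole-body mass). For the blood region the
#' total blood volume (at 1 g/mL) stands in for the organ mass; the method
#' refuses when the needed mass or volume is missing from a profile.
#'
#' @param tiac A [tiac_estimate()].
#' @param animal,human [species_profile()]s.
#' @param region Region to look up; defaults to the TIAC's region.
#' @return A [scaled_tiac()].
#' @export
method2_mass <- function(tiac, animal, human, region = tiac$region) {
  stopifnot(inherits(tiac, "tiac_estimate"),
            inherits(animal, "species_profile"),
            inherits(human, "species_profile"))
  fa <- .mass_fraction(animal, region)
  fh <- .mass_fraction(human, region)
  scaled_tiac(2L, tiac$species, region, tiac$value * fh / fa, tiac$unit,
              inputs = list(fraction_animal = fa, fraction_human = fh))
}

#' Method 3: time scaling
#'
#' Physiological time runs faster in small animals; the biological time
#' axis is stretched by \eqn{c = (m_{WB,h}/m_{WB,a})^{q}} with `q` the
#' `time_exponent` (default 1/4). Each effective rate becomes
#' \eqn{\lambda_{phys} + (\lambda - \lambda_{phys})/c} by default —
#' only the biological component is physiology — or \eqn{\lambda/c} when
#' `spec$scale_physical_decay` is `TRUE`. Amplitudes are unchanged and the
#' TIAC is recomputed analytically from the scaled model, so the operation
#' needs fitted model parameters, not just a TIAC value.
#'
#' @param fit A `fit_result` from [fit_candidates()], or an [exp_model()].
#' @param animal_m_wb,human_m_wb Whole-body masses (kg), > 0, or
#'   [species_profile()]s.
#' @param spec A [scaling_spec()].
#' @return List with `model` (the time-scaled [exp_model()]) and `scaled`
#'   (a [scaled_tiac()]).
#' @export
method3_time <- function(fit, animal_m_wb, human_m_wb,
                         spec = scaling_spec()) {
  model <- if (inherits(fit, "exp_model")) fit else fit$model
  species <- if (inherits(fit, "fit_result")) fit$species else NA_character_
  region <- if (inherits(fit, "fit_result")) fit$region else NA_character_
  unit <- if (identical(attr(fit, "unit") %||% fit$unit, "pct_ia_per_ml")) {
    "h_per_ml"
  } else {
    "h"
  }
  if (inherits(animal_m_wb, "species_profile")) animal_m_wb <- animal_m_wb$m_wb
  if (inherits(human_m_wb, "species_profile")) human_m_wb <- human_m_wb$m_wb
  if (!is_number(animal_m_wb) || animal_m_wb <= 0 ||
      !is_number(human_m_wb) || human_m_wb <= 0) {
    stop_bk("whole-body masses must be positive")
  }
  lp <- model$lambda_phys
  if (any(model$terms$lambda < lp - 1e-12)) {
    stop_bk("input model has a rate below lambda_phys")
  }
  cc <- (human_m_wb / animal_m_wb)^spec$time_exponent
  new_lambda <- if (spec$scale_physical_decay) {
    model$terms$lambda / cc
  } else {
    lp + (model$terms$lambda - lp) / cc
  }
  scaled_model <- exp_model(model$terms$A, new_lambda,
                            if (spec$scale_physical_decay) lp / cc else lp)
  st <- scaled_tiac(3L, species, region, model_tiac_value(scaled_model),
                    unit, inputs = list(c = cc,
                                        time_exponent = spec$time_exponent,
                                        scale_physical_decay =
                                          spec$scale_physical_decay))
  list(model = scaled_model, scaled = st)
}

#' Method 4: combined time and relative mass scaling
#'
#' Applies time scaling ([method3_time()]) first, then relative mass
#' scaling ([method2_mass()]) to the time-scaled TIAC.
#'
#' @param fit A `fit_result` (or [exp_model()] with `species`/`region`
#'   taken from the profiles call).
#' @param animal,human [species_profile()]s.
#' @param region Region label; defaults to the fit's region.
#' @param spec A [scaling_spec()].
#' @return A [scaled_tiac()].
#' @export
method4_combined <- function(fit, animal, human,
                             region = if (inherits(fit, "fit_result")) fit$region else NULL,
                             spec = scaling_spec()) {
  if (is.null(region)) stop_bk("region must be given for a bare model")
  m3 <- method3_time(fit, animal, human, spec)
  t3 <- tiac_estimate(m3$scaled$value, NA_real_,
                      species = m3$scaled$source_species,
                      region = region, unit = m3$scaled$unit)
  m2 <- method2_mass(t3, animal, human, region)
  scaled_tiac(4L, t3$species, region, m2$value, t3$unit,
              inputs = c(m3$scaled$inputs, m2$inputs))
}

#' Method 5: allometric scaling
#'
#' Scales the animal TIAC by a power of the whole-body mass ratio,
#' \eqn{TIAC_h = TIAC_a (m_{WB,h}/m_{WB,a})^{b-1}}, with the organ-specific
#' exponent `b` from `spec$allometric_b` (defaults: liver 0.92,
#' kidneys 0.85).
#'
#' @param tiac A [tiac_estimate()].
#' @param animal_m_wb,human_m_wb Whole-body masses (kg) or
#'   [species_profile()]s.
#' @param region Region whose exponent to use; defaults to the TIAC's.
#' @param spec A [scaling_spec()].
#' @return A [scaled_tiac()].
#' @export
#' @examples
#' t_liver <- tiac_estimate(0.75, species = "mouse", region = "liver")
#' method5_allometric(t_liver, 0.026, 61)$value # ~0.40 h
method5_allometric <- function(tiac, animal_m_wb, human_m_wb,
                               region = tiac$region,
                               spec = scaling_spec()) {
  stopifnot(inherits(tiac, "tiac_estimate"))
  if (inherits(animal_m_wb, "species_profile")) animal_m_wb <- animal_m_wb$m_wb
  if (inherits(human_m_wb, "species_profile")) human_m_wb <- human_m_wb$m_wb
  b <- unname(spec$allometric_b[region])
  if (is.na(b)) {
    stop_bk("no allometric exponent configured for region '", region, "'")
  }
  ratio <- human_m_wb / animal_m_wb
  scaled_tiac(5L, tiac$species, region, tiac$value * ratio^(b - 1),
              tiac$unit, inputs = list(mass_ratio = ratio, b = b))
}

#' Round a comparison factor for reporting
#'
#' Factors >= 3.5 are reported to the nearest integer ("a factor of 4"),
#' smaller ones to one decimal ("a factor of 1.3").
#'
#' @param x Positive factor(s).
#' @return Rounded factor(s).
#' @export
round_factor <- function(x) {
  ifelse(x >= 3.5, round(x), round(x, 1))
}

#' Compare scaled TIACs against the human reference
#'
#' For each scaled value the matching human reference (same region) is
#' looked up; the report gives the over/under-estimation factor: when the
#' scaled prediction is below the reference the human value is
#' *underestimated* by `reference/scaled`, above it *overestimated* by
#' `scaled/reference`. Factors are additionally rounded for display by
#' `rounding` (default [round_factor()]).
#'
#' @param scaled List of [scaled_tiac()]s.
#' @param human_ref List of [tiac_estimate()]s for the human reference
#'   (matched by region and unit).
#' @param rounding Function mapping a factor to its display value.
#' @return A `comparison_report` data frame with columns `species`,
#'   `region`, `method`, `scaled`, `reference`, `ratio`, `direction`,
#'   `factor_display`.
#' @export
compare_tiacs <- function(scaled, human_ref, rounding = round_factor) {
  if (inherits(scaled, "scaled_tiac")) scaled <- list(scaled)
  if (inherits(human_ref, "tiac_estimate")) human_ref <- list(human_ref)
  ref_key <- vapply(human_ref, function(h) paste(h$region, h$unit),
                    character(1))
  rows <- lapply(scaled, function(s) {
    idx <- match(paste(s$region, s$unit), ref_key)
    if (is.na(idx)) {
      stop_bk("no human reference TIAC for region '", s$region,
              "' [", s$unit, "]")
    }
    ref <- human_ref[[idx]]$value
    if (s$value == ref) {
      ratio <- 1; dir <- "equal"
    } else if (s$value < ref) {
      ratio <- ref / s$value; dir <- "under"
    } else {
      ratio <- s$value / ref; dir <- "over"
    }
    data.frame(
      species = s$source_species, region = s$region, method = s$method,
      scaled = s$value, reference = ref, ratio = ratio, direction = dir,
      factor_display = rounding(ratio), stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(species = character(0), region = character(0),
                      method = integer(0), scaled = numeric(0),
                      reference = numeric(0), ratio = numeric(0),
                      direction = character(0), factor_display = numeric(0),
                      stringsAsFactors = FALSE)
  }
  class(out) <- c("comparison_report", class(out))
  out
}
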