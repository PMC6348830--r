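# Published reference inputs used by the desk-scale reproduction path.

#' Published reference TIACs for the three study populations
#'
#' TIACs (with standard errors) for kidneys, liver and blood of the mouse,
#' pig and human cohorts, as printed in the source study's summary table
#' (Method 1, same biodistribution). Organ TIACs are in hours per unit
#' administered activity; blood TIACs are concentration integrals in h/mL
#' (the source prints the blood unit inconsistently as "ml/h" in one table
#' and "h/ml" in another — the integral of a per-mL fraction over time is
#' h/mL, which this package standardizes on).
#'
#' These values are *inputs* for the closed-form extrapolation methods
#' (1, 2 and 5) and for validating the arithmetic chain; they are not
#' computed by this package.
#'
#' @return Data frame with columns `species`, `region`, `value`, `se`,
#'   `unit`.
#' @export
#' @examples
#' reference_tiacs()
reference_tiacs <- function() {
  data.frame(
    species = rep(c("mouse", "pig", "human"), each = 3),
    region = rep(c("kidneys", "liver", "blood"), times = 3),
    value = c(1.44, 0.75, 0.0370,
              7.67, 4.08, 0.0002,
              5.85, 5.32, 0.0002),
    se = c(8.5e-2, 4.1e-2, 2.0e-3,
           1.8e-1, 9.4e-2, 3.4e-6,
           4.2e-1, 3.4e-1, 8.2e-5),
    unit = rep(c("h", "h", "h_per_ml"), times = 3),
    stringsAsFactors = FALSE
  )
}

#' Reference TIACs as tiac_estimate objects
#'
#' Convenience accessor over [reference_tiacs()].
#'
#' @param species Optional species filter.
#' @return Named list of [tiac_estimate()]s, names `"species/region"`.
#' @export
reference_tiac_estimates <- function(species = NULL) {
  df <- reference_tiacs()
  if (!is.null(species)) df <- df[df$species %in% species, ]
  out <- lapply(seq_len(nrow(df)), function(i) {
    tiac_estimate(df$value[i], df$se[i], df$species[i], df$region[i],
                  df$unit[i])
  })
  names(out) <- paste(df$species, df$region, sep = "/")
  out
}
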