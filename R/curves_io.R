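# Time-activity curve container and file I/O.
#
# Curves CSV dialect (fixed for bit-exact interchange): comma-separated,
# dot decimal, UTF-8, mandatory header, columns
#   species,region,time_h,value,unit[,sigma]
# Units are explicit strings: "pct_ia" (%IA, organs) or "pct_ia_per_ml"
# (%IA/mL, blood). Mixing units within one (species, region) group is an
# error. A missing sigma is filled as 0.10 * value, the systematic
# activity-quantification uncertainty assumed throughout.

.bk_units <- c("pct_ia", "pct_ia_per_ml")

.unit_synonyms <- c(
  "pct_ia" = "pct_ia", "%ia" = "pct_ia", "pctia" = "pct_ia",
  "percent_ia" = "pct_ia", "a%" = "pct_ia",
  "pct_ia_per_ml" = "pct_ia_per_ml", "%ia/ml" = "pct_ia_per_ml",
  "pct_ia/ml" = "pct_ia_per_ml", "percent_ia_per_ml" = "pct_ia_per_ml"
)

#' Time-activity curve
#'
#' Sampled uptake versus time for one species and region, with per-point
#' 1-sigma uncertainties. Organ curves carry percent of injected activity
#' (`"pct_ia"`); blood curves carry percent of injected activity per mL
#' (`"pct_ia_per_ml"`).
#'
#' @param species Species label (e.g. `"mouse"`, `"pig"`, `"human"`).
#' @param region Region label (e.g. `"kidneys"`, `"liver"`, `"blood"`).
#' @param unit One of `"pct_ia"`, `"pct_ia_per_ml"`.
#' @param t Sampling times since administration (h), strictly increasing,
#'   all >= 0; at least 2 points.
#' @param value Uptake at each time, >= 0.
#' @param sigma 1-sigma uncertainties (> 0), same unit as `value`. If
#'   `NULL` or `NA` entries, filled as `0.10 * value`.
#' @return Object of class `tac_curve`: list with `species`, `region`,
#'   `unit` and a data frame `samples` (columns `t`, `value`, `sigma`).
#' @export
#' @examples
#' tac_curve("human", "kidneys", "pct_ia",
#'           t = c(1, 3, 24, 72), value = c(4.8, 4.3, 3.6, 2.8))
tac_curve <- function(species, region, unit, t, value, sigma = NULL) {
  unit <- match.arg(unit, .bk_units)
  n <- length(t)
  if (n < 2L) stop_bk("a curve needs at least 2 samples (", species, "/", region, ")")
  if (length(value) != n) stop_bk("'t' and 'value' lengths differ")
  if (any(t < 0)) stop_bk("negative times in ", species, "/", region)
  if (any(diff(t) <= 0)) {
    stop_bk("times must be strictly increasing in ", species, "/", region)
  }
  if (any(value < 0)) stop_bk("negative uptake values in ", species, "/", region)
  if (is.null(sigma)) sigma <- rep(NA_real_, n)
  if (length(sigma) != n) stop_bk("'sigma' length differs from 't'")
  sigma <- ifelse(is.na(sigma), 0.10 * value, sigma)
  if (any(sigma <= 0)) {
    stop_bk("sigma must be > 0 in ", species, "/", region,
            " (zero-valued points need an explicit positive sigma)")
  }
  structure(
    list(species = species, region = region, unit = unit,
         samples = data.frame(t = t, value = value, sigma = sigma)),
    class = "tac_curve"
  )
}

#' @export
print.tac_curve <- function(x, ...) {
  cat(sprintf("<tac_curve> %s/%s [%s], %d samples, t = %g..%g h\n",
              x$species, x$region, x$unit, nrow(x$samples),
              min(x$samples$t), max(x$samples$t)))
  invisible(x)
}

#' Read time-activity curves from CSV
#'
#' Parses the package's curves CSV dialect (see [tac_curve()]) and groups
#' rows into one curve per `(species, region)`, sorted by time. Missing or
#' empty `sigma` entries are filled as `0.10 * value`.
#'
#' @param path CSV file path.
#' @param unit_policy `"strict"` accepts only the canonical unit tokens
#'   `"pct_ia"` / `"pct_ia_per_ml"`; `"coerce"` additionally maps common
#'   synonyms such as `"%IA"` and `"%IA/mL"`.
#' @return Named list of [tac_curve()] objects, names `"species/region"`.
#' @export
read_curves <- function(path, unit_policy = c("strict", "coerce")) {
  unit_policy <- match.arg(unit_policy)
  if (!file.exists(path)) stop_bk("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  needed <- c("species", "region", "time_h", "value", "unit")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop_bk("curves CSV lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"sigma" %in% names(df)) df$sigma <- NA_real_
  df$sigma <- suppressWarnings(as.numeric(df$sigma))

  if (unit_policy == "coerce") {
    key <- tolower(trimws(df$unit))
    mapped <- .unit_synonyms[key]
    if (anyNA(mapped)) {
      stop_bk("unrecognized unit token(s): ",
              paste(unique(df$unit[is.na(mapped)]), collapse = ", "))
    }
    df$unit <- unname(mapped)
  } else if (!all(df$unit %in% .bk_units)) {
    stop_bk("unknown unit(s) under strict policy: ",
            paste(setdiff(unique(df$unit), .bk_units), collapse = ", "))
  }

  groups <- split(df, paste(df$species, df$region, sep = "/"))
  curves <- lapply(names(groups), function(g) {
    d <- groups[[g]]
    if (anyDuplicated(d$time_h)) {
      stop_bk("duplicate time points in group ", g)
    }
    if (length(unique(d$unit)) != 1L) {
      stop_bk("mixed units within group ", g, ": ",
              paste(unique(d$unit), collapse = ", "))
    }
    d <- d[order(d$time_h), ]
    tac_curve(d$species[1], d$region[1], d$unit[1],
              t = d$time_h, value = d$value, sigma = d$sigma)
  })
  names(curves) <- names(groups)
  curves
}

#' Write time-activity curves to CSV
#'
#' Inverse of [read_curves()]; numbers are written at full double precision
#' so a write/read round trip is bit-identical.
#'
#' @param curves List of [tac_curve()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_curves <- function(curves, path) {
  rows <- lapply(curves, function(cv) {
    data.frame(
      species = cv$species, region = cv$region,
      time_h = fmt_full(cv$samples$t),
      value = fmt_full(cv$samples$value),
      unit = cv$unit,
      sigma = fmt_full(cv$samples$sigma),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Species profile
#'
#' Whole-body mass and optional organ masses / blood volume for one
#' species, feeding the mass-based extrapolation methods.
#'
#' @param name Species label.
#' @param m_wb Whole-body mass (kg), > 0.
#' @param organ_masses Named numeric vector/list, region -> mass (kg);
#'   optional per region.
#' @param blood_volume_ml Total blood volume (mL); optional.
#' @return Object of class `species_profile`.
#' @export
species_profile <- function(name, m_wb, organ_masses = NULL,
                            blood_volume_ml = NULL) {
  if (!is_number(m_wb) || m_wb <= 0) {
    stop_bk("whole-body mass for ", name, " must be a positive number")
  }
  om <- NULL
  if (!is.null(organ_masses) && length(organ_masses)) {
    om <- unlist(organ_masses)
    if (is.null(names(om)) || any(!nzchar(names(om)))) {
      stop_bk("organ_masses must be named by region (", name, ")")
    }
    if (any(!is.finite(om)) || any(om <= 0)) {
      stop_bk("organ masses must be positive (", name, ")")
    }
  }
  if (!is.null(blood_volume_ml)) {
    if (!is_number(blood_volume_ml) || blood_volume_ml <= 0) {
      stop_bk("blood volume must be positive (", name, ")")
    }
  }
  structure(
    list(name = name, m_wb = m_wb, organ_masses = om,
         blood_volume_ml = blood_volume_ml),
    class = "species_profile"
  )
}

#' Read species profiles from JSON
#'
#' Expected shape:
#' `{"mouse": {"m_wb": 0.026, "organ_masses": {"kidneys": 4e-4}, "blood_volume_ml": 2.0}, ...}`
#'
#' @param path JSON file path.
#' @return Named list of [species_profile()] objects.
#' @export
read_species_profiles <- function(path) {
  if (!file.exists(path)) stop_bk("file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  raw <- raw[!startsWith(names(raw), "_")] # "_comment" and friends
  if (!length(raw)) stop_bk("no species in ", path)
  out <- lapply(names(raw), function(nm) {
    p <- raw[[nm]]
    if (is.null(p$m_wb)) stop_bk("species ", nm, " lacks m_wb")
    species_profile(nm, m_wb = p$m_wb,
                    organ_masses = p$organ_masses,
                    blood_volume_ml = p$blood_volume_ml)
  })
  names(out) <- names(raw)
  out
}

#' Default species profiles
#'
#' Ships the cohort-mean whole-body masses of the three study populations
#' (mouse 0.026 kg, pig 28 kg, human 61 kg) together with *assumed*
#' reference organ masses (ICRP-style adult values for humans; literature
#' rodent and juvenile-pig values) and blood volumes. The organ masses and
#' blood volumes are stand-in literature values, not measured study data;
#' override them via your own profiles JSON for serious use.
#'
#' @return Named list of [species_profile()] objects.
#' @export
default_species_profiles <- function() {
  read_species_profiles(
    system.file("extdata", "species_profiles.json", package = "biokinscale",
                mustWork = TRUE)
  )
}

#' Interspecies scaling configuration
#'
#' Parameters of the extrapolation methods: the time-scaling exponent
#' (default 1/4, the classical physiological-time exponent), per-region
#' allometric exponents b (defaults: liver 0.92, kidneys 0.85), and whether
#' time scaling stretches the full effective rates (`scale_physical_decay =
#' TRUE`) or only their biological component above the physical-decay floor
#' (default `FALSE`; radioactive decay is a nuclide property, not
#' physiology).
#'
#' @param time_exponent Positive exponent for Method 3. Default 0.25.
#' @param allometric_b Named numeric vector region -> exponent, each in
#'   (0, 1].
#' @param scale_physical_decay Logical, see above.
#' @param method Optional method id in 1..5 (used when a spec describes a
#'   single method run).
#' @return Object of class `scaling_spec`.
#' @export
scaling_spec <- function(time_exponent = 0.25,
                         allometric_b = c(liver = 0.92, kidneys = 0.85),
                         scale_physical_decay = FALSE,
                         method = NULL) {
  if (!is_number(time_exponent) || time_exponent <= 0) {
    stop_bk("time_exponent must be > 0")
  }
  b <- unlist(allometric_b)
  if (length(b) && (is.null(names(b)) || any(b <= 0) || any(b > 1))) {
    stop_bk("allometric_b must be named, with 0 < b <= 1")
  }
  if (!is.null(method) && !(method %in% 1:5)) stop_bk("method must be in 1..5")
  structure(
    list(time_exponent = time_exponent, allometric_b = b,
         scale_physical_decay = isTRUE(scale_physical_decay),
         method = method),
    class = "scaling_spec"
  )
}

#' Read a scaling configuration from JSON
#'
#' Shape: `{"method": 3, "time_exponent": 0.25,
#' "allometric_b": {"liver": 0.92, "kidneys": 0.85},
#' "scale_physical_decay": false}` — all fields optional.
#'
#' @param path JSON file path.
#' @return A [scaling_spec()].
#' @export
read_scaling_spec <- function(path) {
  if (!file.exists(path)) stop_bk("file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  scaling_spec(
    time_exponent = raw$time_exponent %||% 0.25,
    allometric_b = raw$allometric_b %||% c(liver = 0.92, kidneys = 0.85),
    scale_physical_decay = raw$scale_physical_decay %||% FALSE,
    method = raw$method
  )
}

#' Write a comparison report to CSV or JSON
#'
#' Numbers are serialized at full precision; the human-readable rounded
#' factor is carried alongside in `factor_display`.
#'
#' @param report A `comparison_report` data frame from [compare_tiacs()]
#'   (an empty report writes a header-only file).
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("csv", "json")) {
  format <- match.arg(format)
  cols <- c("species", "region", "method", "scaled", "reference",
            "ratio", "direction", "factor_display")
  df <- as.data.frame(report)[, cols, drop = FALSE]
  if (format == "csv") {
    out <- df
    for (cc in c("scaled", "reference", "ratio", "factor_display")) {
      out[[cc]] <- fmt_full(out[[cc]])
    }
    write.csv(out, path, row.names = FALSE, quote = FALSE,
              fileEncoding = "UTF-8")
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", digits = NA,
                         na = "null", auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}
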