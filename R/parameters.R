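# Built-in parameter tables, receptor exposure constants, unit helpers and
# classification scales. Everything downstream consumes these.

#' Analyte identifiers
#'
#' The eight metal(loid)s covered by the pipeline, in the fixed column order
#' used by all tables and results: As, Cr, Cu, Fe, Mn, Ni, Pb, Zn.
#'
#' @return Character vector of length eight.
#' @export
#' @examples
#' hm_metals()
hm_metals <- function() {
  c("As", "Cr", "Cu", "Fe", "Mn", "Ni", "Pb", "Zn")
}

#' Built-in per-metal parameter table
#'
#' Returns the constants the indices and risk equations need, one row per
#' analyte (fixed order, see [hm_metals()]):
#'
#' * `si_eu`, `si_who`: drinking-water standard limits (ug/L) from the
#'   EU Directive 2020/2184 and the WHO 2017 guidelines. The EU row has no
#'   Zn limit; the working standard `si` uses the EU values with Zn = 1000
#'   (the WHO value), the combination under which the pollution indices
#'   reproduce the study's reported values.
#' * `ual`: upper allowable limit for the metal index (identical to `si`).
#' * `cbg`: background level used by the ecological risk index. The source
#'   table prints these in ug/g; they are applied numerically as-is against
#'   ug/L water concentrations (see the methods vignette).
#' * `tr`: Hakanson toxic-response factor (dimensionless).
#' * `kp`: dermal permeability coefficient (cm/h).
#' * `rfd_oral`: oral reference dose (mg/kg/day).
#' * `abs_derm`: dermal absorption fraction in (0, 1].
#' * `rfd_dermal`: dermal reference dose, `rfd_oral * abs_derm` (see
#'   [rfd_dermal()]).
#' * `csf_oral`, `csf_dermal`: cancer slope factors (per mg/kg/day), defined
#'   only for the carcinogens As, Cr and Pb; `NA` elsewhere.
#'
#' @param config Optional overrides: either a named list of
#'   `list(metal = list(field = value))` entries or the path to a JSON file
#'   with the same structure. Unknown metals or fields are an error.
#' @return A data frame of class `"hm_params"` with row names `hm_metals()`.
#' @export
#' @examples
#' p <- default_parameters()
#' p["As", "tr"]
#' default_parameters(list(Mn = list(cbg = 600)))["Mn", "cbg"]
default_parameters <- function(config = NULL) {
  m <- hm_metals()
  p <- data.frame(
    row.names = m,
    si_eu     = c(10, 25, 2000, 200, 50, 20, 10, NA),
    si_who    = c(10, 50, 3000, 300, 50, 70, 10, 1000),
    cbg       = c(10, 30, 30, 15000, 500, 20, 20, 100),
    tr        = c(10, 2, 5, 1, 1, 5, 5, 1),
    kp        = c(0.001, 0.002, 0.001, 0.001, 0.001, 0.0002, 0.0001, 0.0006),
    rfd_oral  = c(0.0003, 0.003, 0.04, 0.7, 0.024, 0.02, 0.0014, 0.3),
    abs_derm  = c(1, 0.025, 0.3, 0.2, 0.04, 0.04, 0.3, 0.2),
    csf_oral  = c(1.5, 0.5, NA, NA, NA, NA, 0.5, NA),
    csf_dermal = c(50, 500, NA, NA, NA, NA, 500, NA)
  )
  # working standard for HPI/MI: EU limits, Zn falls back to the WHO value
  p$si  <- ifelse(is.na(p$si_eu), p$si_who, p$si_eu)
  p$ual <- p$si
  p$rfd_dermal <- rfd_dermal(p$rfd_oral, p$abs_derm)
  if (!is.null(config)) {
    if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
    if (!is.list(config)) stop("`config` must be a named list or a JSON file path")
    for (metal in names(config)) {
      if (!metal %in% m) stop("unknown metal in config: ", metal)
      ov <- config[[metal]]
      bad <- setdiff(names(ov), names(p))
      if (length(bad)) stop("unknown parameter field(s): ", paste(bad, collapse = ", "))
      for (f in names(ov)) p[metal, f] <- ov[[f]]
    }
    p$rfd_dermal <- rfd_dermal(p$rfd_oral, p$abs_derm)
  }
  class(p) <- c("hm_params", "data.frame")
  p
}

#' @export
print.hm_params <- function(x, ...) {
  cat("Per-metal parameter table (", nrow(x), " analytes)\n", sep = "")
  print.data.frame(x, digits = 4, ...)
  invisible(x)
}

#' Dermal reference dose
#'
#' The dermal reference dose is the oral reference dose scaled by the
#' gastrointestinal/dermal absorption fraction: `RfD_dermal = RfD_oral * ABS`.
#'
#' @param rfd_oral Oral reference dose (mg/kg/day), positive.
#' @param abs_frac Absorption fraction in (0, 1].
#' @return Dermal reference dose (mg/kg/day).
#' @export
#' @examples
#' rfd_dermal(0.024, 0.04)   # 0.00096
rfd_dermal <- function(rfd_oral, abs_frac) {
  if (any(!is.finite(rfd_oral)) || any(rfd_oral <= 0))
    stop("`rfd_oral` must be positive")
  if (any(!is.finite(abs_frac)) || any(abs_frac <= 0) || any(abs_frac > 1))
    stop("`abs_frac` must lie in (0, 1]")
  rfd_oral * abs_frac
}

#' Convert micrograms per litre to milligrams per litre
#'
#' Monitoring data are reported in ug/L; the risk equations take mg/L. The
#' conversion is applied exactly once, at the risk-module boundary.
#'
#' @param x Concentration(s) in ug/L, non-negative.
#' @return Concentration(s) in mg/L.
#' @export
ugL_to_mgL <- function(x) {
  if (any(!is.finite(x)) || any(x < 0)) stop("concentrations must be non-negative")
  x * 1e-3
}

#' Receptor exposure constants
#'
#' Default exposure profiles for the two receptors:
#'
#' | constant | meaning | adult | child | units |
#' |---|---|---|---|---|
#' | IR | water intake rate | 2.2 | 1.8 | L/day |
#' | EF | exposure frequency | 350 | 350 | days/year |
#' | ED | exposure duration | 70 | 6 | years |
#' | ET | water-contact time | 0.58 | 1 | h/day |
#' | SA | exposed skin area | 18000 | 6600 | cm^2 |
#' | BW | body weight | 70 | 15 | kg |
#' | CF | volume conversion | 1e-3 | 1e-3 | L/cm^3 |
#' | AT | averaging time | 25550 | 2190 | days |
#'
#' The averaging time is applied to the hazard quotients as well as to
#' carcinogenic risk (see the methods vignette).
#'
#' @param receptor `"adult"` or `"child"`.
#' @param ... Named overrides for individual constants (must be positive).
#' @return A list of class `"hm_profile"` with the constants plus `receptor`.
#' @export
#' @examples
#' exposure_profile("child")$BW
exposure_profile <- function(receptor = c("adult", "child"), ...) {
  receptor <- match.arg(receptor)
  prof <- switch(receptor,
    adult = list(IR = 2.2, EF = 350, ED = 70, ET = 0.58, SA = 18000,
                 BW = 70, CF = 1e-3, AT = 25550),
    child = list(IR = 1.8, EF = 350, ED = 6, ET = 1, SA = 6600,
                 BW = 15, CF = 1e-3, AT = 2190)
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(prof))
  if (length(bad)) stop("unknown exposure constant(s): ", paste(bad, collapse = ", "))
  for (f in names(ov)) {
    if (!is.finite(ov[[f]]) || ov[[f]] <= 0) stop("exposure constant ", f, " must be positive")
    prof[[f]] <- ov[[f]]
  }
  prof$receptor <- receptor
  class(prof) <- "hm_profile"
  prof
}

#' @export
print.hm_profile <- function(x, ...) {
  cat("Exposure profile:", x$receptor, "\n")
  v <- unlist(x[setdiff(names(x), "receptor")])
  print(v)
  invisible(x)
}

#' Classification scales for the pollution and risk indices
#'
#' Returns the ordered class bands used to label index values:
#'
#' * `HPI`: low (< 15), medium (15 to 30, both ends inclusive), high (> 30).
#' * `MI`: very clean (< 0.3), clean, partly affected, moderately affected,
#'   heavily affected, severally affected (> 6), with cut points
#'   0.3, 1, 2, 4, 6.
#' * `RI`: low (< 30), moderate (30 to 60), considerable (60 to 120),
#'   very high (> 120).
#' * `HI` (also used for HQ): safe (<= 1), unsafe (> 1).
#' * `CR`: negligible (< 1e-6), acceptable (1e-6 to 1e-4),
#'   unacceptable (> 1e-4).
#'
#' Bands partition the non-negative reals; every value maps to exactly one
#' label. The upper bound of each band is inclusive, so e.g. HPI = 15 and
#' HPI = 30 are both "medium".
#'
#' @param index One of `"HPI"`, `"MI"`, `"RI"`, `"HI"`, `"CR"`.
#' @return A data frame of class `"hm_scale"` with columns `label`, `lower`,
#'   `upper` (upper inclusive).
#' @export
#' @examples
#' classification_scale("MI")
classification_scale <- function(index = c("HPI", "MI", "RI", "HI", "CR")) {
  index <- match.arg(index)
  # `upper_closed` marks bands whose printed range includes its upper bound
  # (e.g. the HPI "medium" band is 15 <= HPI <= 30).
  sc <- switch(index,
    HPI = data.frame(label = c("low", "medium", "high"),
                     lower = c(0, 15, 30), upper = c(15, 30, Inf),
                     upper_closed = c(FALSE, TRUE, TRUE)),
    MI  = data.frame(label = c("very clean", "clean", "partly affected",
                               "moderately affected", "heavily affected",
                               "severally affected"),
                     lower = c(0, 0.3, 1, 2, 4, 6),
                     upper = c(0.3, 1, 2, 4, 6, Inf),
                     upper_closed = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE)),
    RI  = data.frame(label = c("low", "moderate", "considerable", "very high"),
                     lower = c(0, 30, 60, 120), upper = c(30, 60, 120, Inf),
                     upper_closed = c(FALSE, FALSE, FALSE, TRUE)),
    HI  = data.frame(label = c("safe", "unsafe"),
                     lower = c(0, 1), upper = c(1, Inf),
                     upper_closed = c(TRUE, TRUE)),
    CR  = data.frame(label = c("negligible", "acceptable", "unacceptable"),
                     lower = c(0, 1e-6, 1e-4), upper = c(1e-6, 1e-4, Inf),
                     upper_closed = c(FALSE, TRUE, TRUE))
  )
  attr(sc, "index") <- index
  class(sc) <- c("hm_scale", "data.frame")
  sc
}

#' Classify an index value
#'
#' Maps a non-negative value onto the unique class band of a scale. The lower
#' band claims values strictly below its upper bound except that boundary
#' values belong to the band whose printed range includes them: a band's
#' `upper` bound is inclusive (HPI = 15 is "medium" because its middle band
#' is 15 to 30 inclusive; values strictly below 15 are "low").
#'
#' @param value Numeric vector, non-negative.
#' @param scale An `"hm_scale"` from [classification_scale()], or the name of
#'   one.
#' @return Character vector of class labels.
#' @export
#' @examples
#' classify(15, "HPI")    # "medium"
#' classify(125, "RI")    # "very high"
classify <- function(value, scale) {
  if (is.character(scale)) scale <- classification_scale(scale)
  if (any(!is.finite(value)) || any(value < 0)) stop("index values must be non-negative")
  vapply(value, function(v) {
    # first band (in order) whose upper bound is not yet exceeded
    hit <- which(v < scale$upper | (scale$upper_closed & v <= scale$upper))[1]
    scale$label[hit]
  }, character(1))
}
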