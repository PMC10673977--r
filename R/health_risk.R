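# Deterministic USEPA human-health risk chain: chronic daily intake for the
# ingestion and dermal pathways, hazard quotient / hazard index, and
# carcinogenic risk for the metals with a cancer slope factor.

#' Chronic daily intake, ingestion pathway
#'
#' `CDI_oral = C * IR * EF * ED / (BW * AT)` with the concentration in mg/L;
#' the result is a dose in mg per kg body weight per day.
#'
#' @param c_mgL Concentration (mg/L), non-negative. Use [ugL_to_mgL()] at the
#'   module boundary.
#' @param profile An `"hm_profile"` from [exposure_profile()].
#' @return CDI (mg/kg/day).
#' @export
#' @examples
#' cdi_oral(0.00129, exposure_profile("adult"))
cdi_oral <- function(c_mgL, profile) {
  if (any(!is.finite(c_mgL)) || any(c_mgL < 0)) stop("concentration must be non-negative")
  c_mgL * profile$IR * profile$EF * profile$ED / (profile$BW * profile$AT)
}

#' Chronic daily intake, dermal pathway
#'
#' `CDI_dermal = C * ET * EF * Kp * SA * CF * ED / (BW * AT)`: water-contact
#' time, dermal permeability, exposed skin area and a cm^3-to-L conversion
#' replace the intake rate of the ingestion pathway.
#'
#' @inheritParams cdi_oral
#' @param kp Dermal permeability coefficient (cm/h), positive.
#' @return CDI (mg/kg/day).
#' @export
cdi_dermal <- function(c_mgL, profile, kp) {
  if (any(!is.finite(c_mgL)) || any(c_mgL < 0)) stop("concentration must be non-negative")
  if (any(!is.finite(kp)) || any(kp <= 0)) stop("`kp` must be positive")
  c_mgL * profile$ET * profile$EF * kp * profile$SA * profile$CF * profile$ED /
    (profile$BW * profile$AT)
}

#' Hazard quotient
#'
#' `HQ = CDI / RfD` for the matching pathway (oral CDI against the oral
#' reference dose, dermal CDI against the dermal reference dose).
#'
#' @param cdi Chronic daily intake (mg/kg/day), non-negative.
#' @param rfd Reference dose (mg/kg/day), positive.
#' @return Dimensionless hazard quotient.
#' @export
hazard_quotient <- function(cdi, rfd) {
  if (any(!is.finite(rfd)) || any(rfd <= 0)) stop("`rfd` must be positive")
  if (any(!is.finite(cdi)) || any(cdi < 0)) stop("`cdi` must be non-negative")
  cdi / rfd
}

#' Hazard index
#'
#' The sum of the oral and dermal hazard quotients, `HI = HQ_oral +
#' HQ_dermal`; values above 1 flag potential non-carcinogenic concern.
#'
#' @param hq_oral,hq_dermal Non-negative hazard quotients.
#' @return Dimensionless hazard index.
#' @export
hazard_index <- function(hq_oral, hq_dermal) {
  if (any(hq_oral < 0) || any(hq_dermal < 0)) stop("hazard quotients must be non-negative")
  hq_oral + hq_dermal
}

#' Carcinogenic risk
#'
#' `CR = CDI * CSF`: incremental lifetime cancer probability. Defined only
#' for metals with a cancer slope factor (As, Cr, Pb); calling it with a
#' missing CSF is an error - the risk table reports such metals as
#' "not applicable" rather than zero.
#'
#' @param cdi Chronic daily intake (mg/kg/day).
#' @param csf Cancer slope factor (per mg/kg/day).
#' @return Lifetime cancer probability; classify with the `"CR"` scale
#'   (acceptable between 1e-6 and 1e-4).
#' @export
carcinogenic_risk <- function(cdi, csf) {
  if (any(is.na(csf))) stop("no cancer slope factor defined for this metal")
  if (any(!is.finite(cdi)) || any(cdi < 0)) stop("`cdi` must be non-negative")
  cdi * csf
}

#' Full deterministic risk table
#'
#' Crosses metal x receptor x period x scope (each site plus the pooled
#' cross-site mean) through the whole chain: oral and dermal CDI, hazard
#' quotients, hazard index with its safe/unsafe verdict, and - for the
#' carcinogens - oral and dermal CR with their classifications. Metals
#' without a slope factor get `NA` risk and class `"not applicable"`.
#'
#' @param summaries An `"hm_summary"` data frame.
#' @param params Parameter table from [default_parameters()].
#' @param profiles List of exposure profiles; default adult and child.
#' @return Data frame of class `"hm_risk"`, one row per (scope, period,
#'   metal, receptor).
#' @export
#' @examples
#' rt <- risk_table(danube_site_means())
#' subset(rt, scope == "pooled" & metal == "As" & receptor == "adult")
risk_table <- function(summaries, params = default_parameters(),
                       profiles = list(exposure_profile("adult"),
                                       exposure_profile("child"))) {
  out <- list()
  if (is.null(summaries) || !nrow(summaries)) {
    return(structure(data.frame(), class = c("hm_risk", "data.frame")))
  }
  for (period in intersect(levels(summaries$period), unique(as.character(summaries$period)))) {
    s <- summaries[summaries$period == period, , drop = FALSE]
    scopes <- c(as.list(unique(s$site)), list("pooled"))
    for (scope in scopes) {
      conc <- if (identical(scope, "pooled")) pooled_means(summaries, period)
              else stats::setNames(s$mean_ugL[s$site == scope], s$metal[s$site == scope])
      for (metal in intersect(hm_metals(), names(conc))) {
        c_mgL <- ugL_to_mgL(conc[[metal]])
        for (prof in profiles) {
          co <- cdi_oral(c_mgL, prof)
          cd <- cdi_dermal(c_mgL, prof, params[metal, "kp"])
          hqo <- hazard_quotient(co, params[metal, "rfd_oral"])
          hqd <- hazard_quotient(cd, params[metal, "rfd_dermal"])
          hi <- hazard_index(hqo, hqd)
          has_csf <- !is.na(params[metal, "csf_oral"])
          cro <- if (has_csf) carcinogenic_risk(co, params[metal, "csf_oral"]) else NA_real_
          crd <- if (has_csf) carcinogenic_risk(cd, params[metal, "csf_dermal"]) else NA_real_
          out[[length(out) + 1L]] <- data.frame(
            scope = scope, period = period, metal = metal,
            receptor = prof$receptor,
            cdi_oral = co, cdi_dermal = cd,
            hq_oral = hqo, hq_dermal = hqd,
            hi = hi, hi_class = classify(hi, "HI"),
            cr_oral = cro, cr_dermal = crd,
            cr_oral_class = if (has_csf) classify(cro, "CR") else "not applicable",
            cr_dermal_class = if (has_csf) classify(crd, "CR") else "not applicable")
        }
      }
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("hm_risk", "data.frame")
  out
}

#' @export
print.hm_risk <- function(x, ...) {
  cat("USEPA risk table:", nrow(x), "rows")
  if (all(c("scope", "period", "metal", "receptor") %in% names(x)))
    cat(" (", length(unique(x$scope)), "scopes x",
        length(unique(x$period)), "periods x",
        length(unique(x$metal)), "metals x",
        length(unique(x$receptor)), "receptors )")
  cat("\n")
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}
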