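# Pollution and ecological indices: HPI, MI and Hakanson RI, all linear in
# the concentration vector, each with its classification scale.

new_hm_index <- function(index, value, contributions, scope, period) {
  structure(list(index = index, value = value,
                 class = classify(value, index),
                 contributions = contributions,
                 scope = scope, period = period),
            class = "hm_index")
}

check_conc <- function(conc) {
  miss <- setdiff(hm_metals(), names(conc))
  if (length(miss)) stop("missing metal(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(conc)) || any(conc < 0)) stop("concentrations must be non-negative")
  conc[hm_metals()]
}

#' Heavy-metal pollution index (HPI)
#'
#' The weighted arithmetic mean of per-metal sub-indices
#' `Qi = 100 * Ci / Si` with weights `Wi = 1 / Si`, where `Si` is the
#' drinking-water standard limit of metal `i`:
#' `HPI = sum(Wi * Qi) / sum(Wi)`. Values below 15 are low pollution, 15-30
#' medium, above 30 high.
#'
#' @param conc Named per-metal mean concentrations (ug/L); all eight metals
#'   required.
#' @param params Parameter table from [default_parameters()]; `si` supplies
#'   the standards.
#' @param scope,period Optional labels carried into the result.
#' @return An `"hm_index"` object: `value`, `class` and per-metal
#'   `contributions` (the `Wi * Qi` terms, which re-sum to
#'   `value * sum(Wi)`).
#' @export
#' @examples
#' hpi(pooled_means(danube_site_means(), "APR_SEP"))   # ~21.91, medium
hpi <- function(conc, params = default_parameters(), scope = "pooled", period = NA) {
  conc <- check_conc(conc)
  si <- stats::setNames(params$si, rownames(params))[hm_metals()]
  if (any(si <= 0)) stop("standard limits must be positive")
  w <- 1 / si
  q <- 100 * conc / si
  new_hm_index("HPI", sum(w * q) / sum(w), w * q / sum(w), scope, period)
}

#' Metal index (MI)
#'
#' The sum over metals of the mean concentration divided by its upper
#' allowable limit, `MI = sum(Ci / UALi)`; six classes from "very clean"
#' (< 0.3) to "severally affected" (> 6).
#'
#' @inheritParams hpi
#' @return An `"hm_index"` object; `contributions` are the `Ci / UALi` terms
#'   (summing exactly to `value`).
#' @export
#' @examples
#' metal_index(pooled_means(danube_site_means(), "APR_SEP"))   # ~4.13
metal_index <- function(conc, params = default_parameters(), scope = "pooled",
                        period = NA) {
  conc <- check_conc(conc)
  ual <- stats::setNames(params$ual, rownames(params))[hm_metals()]
  if (any(ual <= 0)) stop("upper allowable limits must be positive")
  contrib <- conc / ual
  new_hm_index("MI", sum(contrib), contrib, scope, period)
}

#' Hakanson potential ecological risk index (RI)
#'
#' Per-metal risk factor `Er = Tr * Cave / Cbg` (toxic-response factor times
#' the ratio of the mean concentration to the background level), summed over
#' metals: `RI = sum(Er)`. Below 30 is low risk; 30-60 moderate; 60-120
#' considerable; above 120 very high.
#'
#' @inheritParams hpi
#' @return An `"hm_index"` object; `contributions` are the per-metal `Er`.
#' @export
#' @examples
#' ecological_risk(pooled_means(danube_site_means(), "APR_SEP"))   # ~3.35, low
ecological_risk <- function(conc, params = default_parameters(), scope = "pooled",
                            period = NA) {
  conc <- check_conc(conc)
  tr <- stats::setNames(params$tr, rownames(params))[hm_metals()]
  cbg <- stats::setNames(params$cbg, rownames(params))[hm_metals()]
  if (any(is.na(cbg)) || any(cbg <= 0)) stop("background values must be positive")
  er <- tr * conc / cbg
  new_hm_index("RI", sum(er), er, scope, period)
}

#' @export
print.hm_index <- function(x, digits = 4, ...) {
  cat(x$index,
      if (!is.na(x$period)) paste0("[", x$scope, ", ", x$period, "]")
      else paste0("[", x$scope, "]"),
      "=", format(x$value, digits = digits), "->", x$class, "\n")
  cat("  per-metal contributions:\n")
  print(round(x$contributions, digits + 2))
  invisible(x)
}

#' All three indices for every site and the pooled scope
#'
#' Convenience wrapper: computes HPI, MI and RI per site and period and for
#' the cross-site pooled means of each period. By linearity of all three
#' indices, the pooled value equals the mean of the per-site values.
#'
#' @param summaries An `"hm_summary"` (e.g. from [summarize_sites()] or
#'   [danube_site_means()]).
#' @param params Parameter table.
#' @return Data frame with columns `scope`, `period`, `index`, `value`,
#'   `class`.
#' @export
site_indices <- function(summaries, params = default_parameters()) {
  out <- list()
  for (period in levels(summaries$period)) {
    s <- summaries[summaries$period == period, , drop = FALSE]
    if (!nrow(s)) next
    scopes <- c(as.list(unique(s$site)), list("pooled"))
    for (scope in scopes) {
      conc <- if (identical(scope, "pooled")) pooled_means(summaries, period)
              else stats::setNames(s$mean_ugL[s$site == scope], s$metal[s$site == scope])
      for (f in list(hpi, metal_index, ecological_risk)) {
        r <- f(conc, params, scope = scope, period = period)
        out[[length(out) + 1L]] <- data.frame(scope = scope, period = period,
                                              index = r$index, value = r$value,
                                              class = r$class)
      }
    }
  }
  do.call(rbind, out)
}
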