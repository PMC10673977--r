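# Seeded synthetic monitoring-data generator: lognormal marginals calibrated
# by method of moments to per-site seasonal target means, with an optional
# Gaussian copula to induce inter-metal rank correlation.

#' Method-of-moments lognormal calibration
#'
#' Given a target arithmetic mean and coefficient of variation, returns the
#' log-scale parameters of the lognormal distribution with exactly that mean
#' and CV: `sdlog^2 = log(1 + cv^2)`, `meanlog = log(mean) - sdlog^2 / 2`.
#'
#' @param mean Target mean (ug/L), positive.
#' @param cv Target coefficient of variation (sd/mean), positive.
#' @return Named numeric vector `c(meanlog, sdlog)`.
#' @export
#' @examples
#' lognormal_params(100, 0.5)   # sdlog = sqrt(log(1.25))
lognormal_params <- function(mean, cv) {
  if (any(!is.finite(mean)) || any(mean <= 0)) stop("`mean` must be positive")
  if (any(!is.finite(cv)) || any(cv <= 0)) stop("`cv` must be positive")
  s2 <- log(1 + cv^2)
  c(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Specify a synthetic monitoring campaign
#'
#' Bundles everything [generate_dataset()] needs: per-site seasonal target
#' means, a coefficient of variation for the lognormal marginals, the
#' campaign window with a fixed number of samples per month, a seed, and
#' optional inter-metal Spearman correlation targets induced through a
#' Gaussian copula.
#'
#' @param targets Data frame with columns `site`, `period`, `metal`,
#'   `mean_ugL` giving the per-cell target mean; defaults to the packaged
#'   Danube per-site seasonal means ([danube_site_means()]).
#' @param cv Coefficient of variation of the per-sample concentrations around
#'   the cell mean; a single value or a named per-metal vector. Default 0.4.
#' @param start,end Campaign window; samples are placed on the 15th of each
#'   month. Defaults: 2013-01-01 to 2019-12-31 (84 monthly dates).
#' @param samples_per_month Samples drawn per site and month (default 1).
#' @param seed Integer seed; the generated dataset is a pure function of the
#'   spec.
#' @param correlations Optional data frame with columns `metal1`, `metal2`,
#'   `rho` of target Spearman correlations in (-1, 1); unlisted pairs are
#'   independent.
#' @return An object of class `"hm_genspec"`.
#' @export
generator_spec <- function(targets = danube_site_means(), cv = 0.4,
                           start = "2013-01-01", end = "2019-12-31",
                           samples_per_month = 1, seed = 42,
                           correlations = NULL) {
  stopifnot(all(c("site", "period", "metal", "mean_ugL") %in% names(targets)))
  if (any(targets$mean_ugL <= 0)) stop("target means must be positive")
  if (any(cv <= 0)) stop("`cv` must be positive")
  if (!is.null(correlations)) {
    stopifnot(all(c("metal1", "metal2", "rho") %in% names(correlations)))
    if (any(abs(correlations$rho) >= 1)) stop("correlation targets must lie in (-1, 1)")
  }
  structure(list(targets = as.data.frame(targets), cv = cv,
                 start = as.Date(start), end = as.Date(end),
                 samples_per_month = as.integer(samples_per_month),
                 seed = as.integer(seed), correlations = correlations),
            class = "hm_genspec")
}

#' @export
print.hm_genspec <- function(x, ...) {
  cat("Synthetic campaign spec:", length(unique(x$targets$site)), "sites,",
      format(x$start), "to", format(x$end), "\n",
      " cv:", paste(x$cv, collapse = "/"),
      " samples/month:", x$samples_per_month, " seed:", x$seed, "\n")
  invisible(x)
}

# Spearman -> Pearson conversion for a Gaussian copula, then the full
# correlation matrix over the eight metals (identity off the listed pairs).
copula_matrix <- function(correlations) {
  m <- hm_metals()
  R <- diag(length(m))
  dimnames(R) <- list(m, m)
  if (!is.null(correlations)) {
    for (i in seq_len(nrow(correlations))) {
      a <- correlations$metal1[i]; b <- correlations$metal2[i]
      if (!all(c(a, b) %in% m)) stop("unknown metal in correlation target: ", a, "/", b)
      rp <- 2 * sin(pi * correlations$rho[i] / 6)
      R[a, b] <- R[b, a] <- rp
    }
  }
  ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-10) stop("correlation targets do not form a positive semi-definite matrix")
  R
}

#' Generate a synthetic monitoring dataset
#'
#' Draws one 8-analyte sample vector per (site, date, replicate): a Gaussian
#' copula draw is mapped through `pnorm` to uniforms and then through the
#' lognormal quantile function whose parameters are method-of-moments
#' calibrated ([lognormal_params()]) to the spec's target mean for that
#' site's period and the spec's CV. Concentrations are therefore strictly
#' positive, right-skewed, seasonally structured, and rank-correlated across
#' metals as requested. Identical specs yield identical datasets.
#'
#' @param spec An `"hm_genspec"` from [generator_spec()].
#' @return An `"hm_dataset"` (see [read_monitoring_csv()] for the layout).
#' @export
#' @examples
#' ds <- generate_dataset(generator_spec(samples_per_month = 1, seed = 1))
#' print(ds)
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "hm_genspec"))
  m <- hm_metals()
  R <- copula_matrix(spec$correlations)
  L <- chol(R)
  months <- seq(spec$start, spec$end, by = "month")
  dates <- as.Date(format(months, "%Y-%m-15"))
  sites <- sort(unique(spec$targets$site))
  grid <- expand.grid(rep = seq_len(spec$samples_per_month), date = dates,
                      site = sites, stringsAsFactors = FALSE)
  grid$period <- as.character(assign_period(grid$date))
  n <- nrow(grid)
  cv <- if (length(spec$cv) == 1) stats::setNames(rep(spec$cv, length(m)), m) else spec$cv[m]

  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)
  U <- stats::pnorm(matrix(stats::rnorm(n * length(m)), n, length(m)) %*% L)

  key <- paste(spec$targets$site, spec$targets$period, spec$targets$metal)
  mu_lookup <- stats::setNames(spec$targets$mean_ugL, key)
  recs <- vector("list", length(m))
  for (j in seq_along(m)) {
    target <- mu_lookup[paste(grid$site, grid$period, m[j])]
    if (any(is.na(target))) stop("missing target mean for metal ", m[j])
    s2 <- log(1 + cv[m[j]]^2)
    conc <- stats::qlnorm(U[, j], meanlog = log(target) - s2 / 2, sdlog = sqrt(s2))
    recs[[j]] <- data.frame(site = grid$site, date = grid$date + (grid$rep - 1L),
                            metal = m[j], concentration_ugL = conc)
  }
  new_hm_dataset(do.call(rbind, recs))
}
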