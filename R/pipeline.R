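# End-to-end orchestration: one config in, a bundle of tidy CSVs plus a
# human-readable summary out.

#' Run the full assessment pipeline
#'
#' Executes summarise -> indices -> deterministic risk -> Monte Carlo ->
#' correlation/clustering on either an input monitoring CSV or a synthetic
#' campaign generated from a spec, and writes the result bundle to an
#' output directory:
#'
#' * `summaries.csv` - per-site/period concentration summaries
#' * `indices.csv` - HPI/MI/RI per site and pooled, with classes
#' * `risk.csv` - the full deterministic risk table
#' * `mc_summary.csv`, `mc_sensitivity.csv` - Monte Carlo percentiles and
#'   sensitivity shares per endpoint run
#' * `correlation.csv`, `cluster.nwk` - Spearman matrix and metal tree
#' * `report.md` - every index value with its class and every HI/CR with its
#'   threshold verdict, plus the seed and config echo
#'
#' The run is a pure function of the config: all stochastic stages are
#' seeded from `config$seed`. Any stage failure aborts the run and removes
#' the partially written bundle.
#'
#' @param config A named list (or path to a JSON file) with fields:
#'   `input` (monitoring CSV path) *or* `generator` (arguments for
#'   [generator_spec()]) - exactly one of the two; optional `params`
#'   (overrides for [default_parameters()]), `mc` (list with `n`,
#'   `endpoints`), `seed` (default 42) and `output` (directory, default
#'   `"aquametal-out"`).
#' @return Invisibly, a list with all intermediate results.
#' @export
#' @examples
#' \donttest{
#' out <- run_pipeline(list(generator = list(samples_per_month = 1),
#'                          seed = 7, mc = list(n = 500),
#'                          output = tempfile("bundle")))
#' names(out)
#' }
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (!is.list(config)) stop("`config` must be a list or a JSON file path")
  has_input <- !is.null(config$input)
  has_gen <- !is.null(config$generator)
  if (has_input == has_gen)
    stop("config must contain exactly one of `input` (CSV path) or `generator` (spec)")
  seed <- if (is.null(config$seed)) 42L else as.integer(config$seed)
  outdir <- if (is.null(config$output)) "aquametal-out" else config$output
  params <- default_parameters(config$params)
  mc_n <- if (!is.null(config$mc$n)) as.integer(config$mc$n) else 10000L

  fresh <- !dir.exists(outdir)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok && fresh) unlink(outdir, recursive = TRUE))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  # an input CSV may hold raw records or an already-summarised means table
  dataset <- stage("input", {
    if (has_input) {
      hdr <- names(utils::read.csv(config$input, nrows = 1))
      if ("mean_ugL" %in% hdr) read_summary_csv(config$input)
      else read_monitoring_csv(config$input)
    } else {
      gen <- config$generator
      gen$seed <- if (is.null(gen$seed)) seed else gen$seed
      generate_dataset(do.call(generator_spec, gen))
    }
  })
  summaries <- stage("summarize",
    if (inherits(dataset, "hm_summary")) dataset else summarize_sites(dataset))
  idx <- stage("indices", site_indices(summaries, params))
  risk <- stage("risk", risk_table(summaries, params))

  mc_runs <- stage("montecarlo", {
    runs <- list()
    for (period in levels(summaries$period)) {
      for (receptor in c("adult", "child")) {
        prof <- exposure_profile(receptor)
        exp_d <- mc_exposure_dists(prof)
        for (metal in hm_metals()) {
          pool <- summaries$mean_ugL[summaries$period == period &
                                       summaries$metal == metal]
          if (length(pool) < 2) next
          d <- c(list(C = conc_dist(ugL_to_mgL(pool))), exp_d)
          mc <- run_mc(metal, receptor, "oral", "HQ", d, params,
                       profile = prof, n = mc_n, seed = seed)
          runs[[paste(metal, receptor, period, "oral_HQ", sep = "_")]] <- mc
        }
      }
    }
    runs
  })

  # correlation needs per-sample records; a summary-table input has none
  have_records <- inherits(dataset, "hm_dataset")
  cors <- if (have_records) stage("correlate", {
    lapply(stats::setNames(levels(summaries$period), levels(summaries$period)),
           function(p) spearman_matrix(dataset, p))
  }) else NULL
  tree <- if (have_records) stage("cluster", cluster_metals(cors[[1]])) else NULL

  stage("write", {
    utils::write.csv(summaries, file.path(outdir, "summaries.csv"), row.names = FALSE)
    utils::write.csv(idx, file.path(outdir, "indices.csv"), row.names = FALSE)
    utils::write.csv(risk, file.path(outdir, "risk.csv"), row.names = FALSE)
    mcs <- do.call(rbind, lapply(names(mc_runs), function(k) {
      s <- mc_runs[[k]]$summary
      data.frame(run = k, mean = s[["mean"]], p5 = s[["p5"]],
                 p50 = s[["p50"]], p95 = s[["p95"]])
    }))
    utils::write.csv(mcs, file.path(outdir, "mc_summary.csv"), row.names = FALSE)
    sens <- do.call(rbind, lapply(names(mc_runs), function(k)
      cbind(run = k, mc_sensitivity(mc_runs[[k]]))))
    utils::write.csv(sens, file.path(outdir, "mc_sensitivity.csv"), row.names = FALSE)
    if (have_records) {
      rr <- cors[[1]]$rho
      utils::write.csv(data.frame(metal = rownames(rr), rr),
                       file.path(outdir, "correlation.csv"), row.names = FALSE)
      export_newick(tree, file.path(outdir, "cluster.nwk"))
    }
    writeLines(render_report(idx, risk, mc_runs, seed, config),
               file.path(outdir, "report.md"))
  })
  ok <- TRUE
  invisible(list(dataset = dataset, summaries = summaries, indices = idx,
                 risk = risk, mc = mc_runs, correlations = cors, tree = tree,
                 output = outdir, seed = seed))
}

scale_sentence <- function(index) {
  switch(index,
    HPI = "low (HPI < 15), medium (15 <= HPI <= 30), high (HPI > 30)",
    MI = paste("very clean (MI < 0.3), clean (0.3-1), partly affected (1-2),",
               "moderately affected (2-4), heavily affected (4-6),",
               "severally affected (MI > 6)"),
    RI = "low (RI < 30), moderate (30-60), considerable (60-120), very high (> 120)",
    HI = "safe (HI <= 1), unsafe (HI > 1)",
    CR = "negligible (< 1e-6), acceptable (1e-6 to 1e-4), unacceptable (> 1e-4)")
}

render_report <- function(idx, risk, mc_runs, seed, config) {
  lines <- c("# Surface-water heavy-metal risk assessment", "",
             paste("Seed:", seed), "",
             "## Pollution and ecological indices", "")
  pooled <- idx[idx$scope == "pooled", ]
  for (i in seq_len(nrow(pooled)))
    lines <- c(lines, sprintf("- %s (%s): %.4g -> **%s** [scale: %s]",
                              pooled$index[i], pooled$period[i], pooled$value[i],
                              pooled$class[i], scale_sentence(pooled$index[i])))
  lines <- c(lines, "", "## Deterministic health risk (pooled)", "")
  pr <- risk[risk$scope == "pooled", ]
  for (i in seq_len(nrow(pr))) {
    lines <- c(lines, sprintf("- HI %s %s (%s): %.4e -> %s [scale: %s]",
                              pr$metal[i], pr$receptor[i], pr$period[i], pr$hi[i],
                              pr$hi_class[i], scale_sentence("HI")))
    if (!is.na(pr$cr_oral[i]))
      lines <- c(lines, sprintf("  - CR oral %.4e -> %s; CR dermal %.4e -> %s [scale: %s]",
                                pr$cr_oral[i], pr$cr_oral_class[i], pr$cr_dermal[i],
                                pr$cr_dermal_class[i], scale_sentence("CR")))
  }
  lines <- c(lines, "", "## Monte Carlo 95th percentiles (oral HQ)", "")
  for (k in names(mc_runs))
    lines <- c(lines, sprintf("- %s: p95 = %.4e", k, mc_runs[[k]]$summary[["p95"]]))
  # the output path is run-specific and kept out of the echo so that two
  # runs of the same analysis config produce identical bundles
  config$output <- NULL
  c(lines, "", paste("Config echo:", jsonlite::toJSON(config, auto_unbox = TRUE)))
}
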