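# Shared helpers: tiny monitoring files and datasets built in code.

write_monitoring_file <- function(rows) {
  path <- tempfile(fileext = ".csv")
  header <- "site,date,metal,concentration_ugL"
  writeLines(c(header, rows), path)
  path
}

# A small in-memory dataset: `n_dates` dates per site, all eight metals.
toy_dataset <- function(sites = c("S1", "S2"), n_dates = 6, seed = 11) {
  set.seed(seed)
  dates <- seq(as.Date("2015-01-15"), by = "month", length.out = n_dates)
  grid <- expand.grid(site = sites, date = dates, metal = hm_metals(),
                      stringsAsFactors = FALSE)
  grid$concentration_ugL <- stats::rlnorm(nrow(grid), meanlog = 1, sdlog = 0.3)
  path <- tempfile(fileext = ".csv")
  utils::write.csv(grid, path, row.names = FALSE, quote = FALSE)
  read_monitoring_csv(path)
}

# Brute-force Spearman rho: Pearson correlation of average ranks, written
# out from first principles as an independent oracle.
brute_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) / sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Brute-force linear-interpolation percentile on the sorted sample.
brute_percentile <- function(x, q) {
  s <- sort(x)
  h <- (length(s) - 1) * q / 100 + 1
  lo <- floor(h)
  s[lo] + (h - lo) * (s[min(lo + 1, length(s))] - s[lo])
}
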