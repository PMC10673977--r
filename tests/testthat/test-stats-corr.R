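test_that("the KS pre-check accepts normal and rejects strongly skewed samples", {
  ok <- 0
  for (seed in 1:20) {
    set.seed(seed)
    if (ks_normality(rnorm(1e4))$p.value > 0.05) ok <- ok + 1
  }
  expect_gte(ok, 19)
  set.seed(2)
  expect_lt(ks_normality(rlnorm(500, 0, 1))$p.value, 0.01)
  expect_error(ks_normality(rep(3, 10)), "degenerate")
  expect_error(ks_normality(1:4), "at least 5")
})

test_that("Spearman matrix matches a brute-force rank correlation oracle", {
  ds <- toy_dataset(sites = "S1", n_dates = 8)
  sm <- spearman_matrix(ds, "ALL")
  r <- ds$records
  wide <- sapply(hm_metals(), function(m)
    r$concentration_ugL[r$metal == m][order(r$date[r$metal == m])])
  for (i in 1:7) for (j in (i + 1):8) {
    expect_equal(sm$rho[i, j], brute_spearman(wide[, i], wide[, j]),
                 tolerance = 1e-12)
  }
  expect_equal(sm$rho, t(sm$rho))
  expect_equal(unname(diag(sm$rho)), rep(1, 8))
  expect_true(all(abs(sm$rho) <= 1))
  expect_true(all(sm$flag[upper.tri(sm$flag)] %in% c("p<0.01", "p<0.05", "ns")))
})

test_that("perfectly monotone pairs reach +1/-1 and transforms do not matter", {
  rows <- unlist(lapply(1:8, function(i) {
    d <- sprintf("2015-04-%02d", i)
    c(sprintf("S1,%s,Fe,%g", d, i * 10),
      sprintf("S1,%s,Mn,%g", d, 100 - i),
      sprintf("S1,%s,As,%g", d, exp(i / 2)),
      unlist(lapply(c("Cr", "Cu", "Ni", "Pb", "Zn"), function(m)
        sprintf("S1,%s,%s,%g", d, m, 1 + ((i * 7) %% 5)))))
  }))
  ds <- read_monitoring_csv(write_monitoring_file(rows))
  sm <- spearman_matrix(ds, "APR_SEP")
  expect_equal(sm$rho["Fe", "Mn"], -1)
  expect_equal(sm$rho["Fe", "As"], 1)   # exp(i/2) is a monotone transform of i
  # strictly monotone transform of one variable leaves rho unchanged
  ds2 <- ds
  fe <- ds2$records$metal == "Fe"
  ds2$records$concentration_ugL[fe] <- log(ds2$records$concentration_ugL[fe])
  expect_equal(spearman_matrix(ds2, "APR_SEP")$rho, sm$rho)
})

test_that("sparse pairs are reported missing rather than zero", {
  rows <- c("S1,2015-04-01,Fe,1", "S1,2015-04-01,Mn,2",
            "S1,2015-05-01,Fe,2", "S1,2015-05-01,Mn,1")
  ds <- read_monitoring_csv(write_monitoring_file(rows))
  sm <- spearman_matrix(ds, "APR_SEP", min_n = 5)
  expect_true(is.na(sm$rho["Fe", "Mn"]))
  expect_equal(sm$n["Fe", "Mn"], 2L)
  expect_error(cluster_metals(sm), "missing pair")
})

test_that("clustering recovers planted block structure", {
  m <- hm_metals()
  rho <- diag(8); dimnames(rho) <- list(m, m)
  b1 <- c("Fe", "Cr", "Mn", "Zn"); b2 <- c("Pb", "Ni", "Cu")
  rho[b1, b1] <- 1; rho[b2, b2] <- 1
  tree <- cluster_metals(rho)
  grp <- cut_metal_tree(tree, 3)
  expect_equal(length(unique(grp[b1])), 1)
  expect_equal(length(unique(grp[b2])), 1)
  expect_equal(length(unique(grp[c("Fe", "Pb", "As")])), 3)
  # merge heights are monotone non-decreasing
  expect_true(all(diff(tree$hclust$height) >= -1e-12))
  # with no correlation at all, every merge sits at height 1
  id <- diag(8); dimnames(id) <- list(m, m)
  expect_equal(unname(cluster_metals(id)$hclust$height), rep(1, 7))
})

test_that("cluster output depends only on the matrix, not record order", {
  ds <- toy_dataset(sites = c("S1", "S2", "S3"), n_dates = 10)
  sm1 <- spearman_matrix(ds, "ALL")
  shuffled <- ds
  set.seed(3)
  shuffled$records <- shuffled$records[sample(nrow(shuffled$records)), ]
  sm2 <- spearman_matrix(shuffled, "ALL")
  expect_equal(sm1$rho, sm2$rho)
  expect_identical(cluster_metals(sm1)$hclust$merge, cluster_metals(sm2)$hclust$merge)
  nwk <- export_newick(cluster_metals(sm1))
  expect_match(nwk, "^\\(.*\\);$")
  expect_true(all(vapply(hm_metals(), grepl, logical(1), x = nwk, fixed = TRUE)))
})

test_that("copula-planted correlation structure is recovered as clusters", {
  cors <- data.frame(metal1 = c("Fe", "Cr", "Cr"), metal2 = c("Mn", "Fe", "Zn"),
                     rho = c(0.40, 0.33, 0.37))
  ds <- generate_dataset(generator_spec(samples_per_month = 4, seed = 17,
                                        correlations = cors))
  sm <- spearman_matrix(ds, "APR_SEP")
  # pooling across sites adds between-site association on top of the copula,
  # so assert the planted pair is strongly and most correlated, not its value
  expect_gt(sm$rho["Fe", "Mn"], 0.3)
  off <- sm$rho; diag(off) <- NA
  expect_equal(which.max(apply(off, 1, max, na.rm = TRUE)) %in%
                 match(c("Fe", "Mn"), rownames(off)), TRUE)
  tree <- cluster_metals(sm)
  grp <- cut_metal_tree(tree, 3)
  expect_equal(grp[["Fe"]], grp[["Mn"]])   # the correlated metals co-cluster
})
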