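fixture_pool <- function(metal, period) {
  s <- danube_site_means()
  ugL_to_mgL(s$mean_ugL[s$period == period & s$metal == metal])
}

deterministic_hq <- function(metal, receptor, pathway, c_mgL,
                             params = default_parameters()) {
  prof <- exposure_profile(receptor)
  cdi <- if (pathway == "oral") cdi_oral(c_mgL, prof)
         else cdi_dermal(c_mgL, prof, params[metal, "kp"])
  hazard_quotient(cdi, params[metal, if (pathway == "oral") "rfd_oral" else "rfd_dermal"])
}

test_that("point-mass specs reproduce the deterministic chain exactly", {
  c0 <- mean(fixture_pool("As", "APR_SEP"))
  mc <- run_mc("As", "adult", "oral", "HQ", dists = list(C = c0), n = 10, seed = 1)
  expect_equal(unique(mc$samples), deterministic_hq("As", "adult", "oral", c0))
  expect_length(mc$samples, 10)
  mcd <- run_mc("As", "child", "dermal", "HQ", dists = list(C = c0), n = 5, seed = 1)
  expect_equal(unique(mcd$samples), deterministic_hq("As", "child", "dermal", c0))
  expect_warning(mc_sensitivity(mc), "point masses")
})

test_that("vanishing spread collapses every percentile to the deterministic value", {
  c0 <- mean(fixture_pool("Cr", "OCT_MAR"))
  prof <- exposure_profile("child")
  d <- c(list(C = dist_spec("C", "lognormal", mean = c0, cv = 1e-6)),
         mc_exposure_dists(prof, cv = c(IR = 1e-6, EF = 1e-6, ED = 1e-6, ET = 1e-6,
                                        SA = 1e-6, AT = 1e-6, BW = 1e-6)))
  mc <- run_mc("Cr", "child", "oral", "HQ", d, n = 2000, seed = 3)
  det <- deterministic_hq("Cr", "child", "oral", c0)
  for (q in c(5, 50, 95))
    expect_equal(mc_percentile(mc$samples, q), det, tolerance = 1e-4)
})

test_that("the simulated mean converges to the deterministic value", {
  pool <- fixture_pool("As", "APR_SEP")
  prof <- exposure_profile("child")
  d <- c(list(C = dist_spec("C", "lognormal", mean = mean(pool),
                            cv = sd(pool) / mean(pool))),
         mc_exposure_dists(prof, cv = c(IR = 0.1, EF = 0.1, ED = 0.1, ET = 0.1,
                                        SA = 0.1, AT = 0.1, BW = 0.1)))
  mc <- run_mc("As", "child", "oral", "HQ", d, n = 1e4, seed = 1)
  det <- deterministic_hq("As", "child", "oral", mean(pool))
  expect_lt(abs(mc$summary[["mean"]] / det - 1), 0.03)
  # and with the package's default exposure CVs
  d2 <- c(list(C = conc_dist(pool)), mc_exposure_dists(prof))
  mc2 <- run_mc("As", "child", "oral", "HQ", d2, n = 1e4, seed = 2)
  expect_lt(abs(mc2$summary[["mean"]] / det - 1), 0.03)
})

test_that("identical seeds reproduce the simulation bit for bit", {
  d <- c(list(C = conc_dist(fixture_pool("Pb", "APR_SEP"))),
         mc_exposure_dists(exposure_profile("adult")))
  a <- run_mc("Pb", "adult", "oral", "CR", d, n = 500, seed = 11)
  b <- run_mc("Pb", "adult", "oral", "CR", d, n = 500, seed = 11)
  expect_identical(a$samples, b$samples)
  expect_identical(a$inputs, b$inputs)
  c <- run_mc("Pb", "adult", "oral", "CR", d, n = 500, seed = 12)
  expect_false(identical(a$samples, c$samples))
})

test_that("percentiles follow the linear-interpolation convention", {
  expect_equal(mc_percentile(c(1, 2, 3, 4, 5), 50), 3)
  expect_equal(mc_percentile(rep(7, 10), c(5, 50, 95)), rep(7, 3))
  expect_equal(mc_percentile(0:100, 95), 95)
  set.seed(21)
  for (i in 1:5) {
    x <- rlnorm(50 + i)
    for (q in c(5, 37.5, 50, 90, 95))
      expect_equal(mc_percentile(x, q), brute_percentile(x, q))
  }
  expect_error(mc_percentile(numeric(0), 50), "empty")
  expect_error(mc_percentile(1:5, 120), "\\[0, 100\\]")
})

test_that("with only the concentration stochastic, HQ percentiles couple monotonically", {
  pool <- fixture_pool("Mn", "APR_SEP")
  cd <- conc_dist(pool)
  mc <- run_mc("Mn", "child", "oral", "HQ", dists = list(C = cd), n = 5000, seed = 4)
  for (q in c(5, 50, 95)) {
    cq <- mc_percentile(mc$inputs[, "C"], q)
    expect_equal(mc_percentile(mc$samples, q),
                 deterministic_hq("Mn", "child", "oral", cq), tolerance = 1e-10)
  }
})

test_that("sensitivity shares are normalised, signed and correctly ordered", {
  # raw-sample concentration variability (generator default CV 0.4)
  c_mean <- mean(fixture_pool("As", "APR_SEP"))
  d <- c(list(C = dist_spec("C", "lognormal", mean = c_mean, cv = 0.4)),
         mc_exposure_dists(exposure_profile("child")))
  mc <- run_mc("As", "child", "oral", "CR", d, n = 1e4, seed = 6)
  sens <- mc_sensitivity(mc)
  expect_equal(sum(sens$share_pct), 100)
  expect_identical(sens$parameter, c("C", "IR", "EF", "ED", "AT", "BW"))
  signs <- setNames(sign(sens$rho), sens$parameter)
  expect_true(all(signs[c("C", "IR", "EF", "ED")] == 1))
  expect_true(all(signs[c("AT", "BW")] == -1))
  # a variable the output does not depend on shows ~zero rank correlation
  set.seed(99)
  dummy <- rnorm(mc$n)
  expect_lt(abs(cor(dummy, mc$samples, method = "spearman")), 0.05)
})

test_that("carcinogenic endpoints require a slope factor", {
  d <- list(C = 1e-3)
  expect_error(run_mc("Mn", "adult", "oral", "CR", d, n = 10, seed = 1),
               "slope factor")
  expect_error(run_mc("As", "adult", "oral", "HQ", list(), n = 10, seed = 1),
               "concentration")
})

test_that("truncated-normal sampling never returns non-positive draws", {
  d <- dist_spec("BW", "normal", mean = 1, sd = 2)   # heavy truncation
  set.seed(8)
  x <- sample_dist(d, 5000)
  expect_true(all(x > 0))
  expect_gt(mean(x), 1)   # truncation shifts the mean upward
  e <- dist_spec("C", "empirical", values = c(1, 2, 3))
  expect_true(all(sample_dist(e, 100) %in% c(1, 2, 3)))
})
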