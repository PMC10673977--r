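# Expected intake values were frozen from direct hand evaluation of the
# intake equations at the stated constants.

test_that("chronic daily intake matches hand-evaluated doses", {
  ad <- exposure_profile("adult")
  ch <- exposure_profile("child")
  expect_equal(cdi_oral(0.00129, ad), 3.8877e-5, tolerance = 1e-4)
  expect_equal(cdi_oral(0.00129, ch), 1.48438e-4, tolerance = 1e-4)
  expect_equal(cdi_oral(0, ad), 0)
  expect_equal(cdi_dermal(0.00129, ad, 0.001), 1.8449e-7, tolerance = 1e-4)
  expect_equal(cdi_dermal(0.00129, ch, 0.001), 5.4428e-7, tolerance = 1e-4)
  expect_equal(cdi_dermal(0, ad, 0.001), 0)
  expect_error(cdi_dermal(0.001, ad, 0), "positive")
  expect_error(cdi_oral(-1, ad), "non-negative")
})

test_that("hazard quotient and index compose as ratios and sums", {
  expect_equal(hazard_quotient(0.002, 0.004), 0.5)
  expect_equal(hazard_quotient(0, 1), 0)
  expect_error(hazard_quotient(1, 0), "positive")
  expect_equal(hazard_index(0.3, 0.05), 0.35)
  expect_equal(hazard_index(0, 0), 0)
  expect_equal(classify(hazard_index(0, 0), "HI"), "safe")
  expect_error(hazard_index(-0.1, 0), "non-negative")
})

test_that("per-site adult oral HQ spans the reported ranges", {
  s <- danube_site_means()
  rt <- risk_table(s)
  aps <- subset(rt, period == "APR_SEP" & receptor == "adult" & scope != "pooled")
  hq_as <- aps$hq_oral[aps$metal == "As"]
  hq_mn <- aps$hq_oral[aps$metal == "Mn"]
  expect_equal(range(round(hq_as, 2)), c(0.12, 0.14))
  expect_true(all(hq_as >= 0.115 & hq_as <= 0.145))
  expect_equal(round(min(hq_mn), 3), 0.050)
  expect_equal(round(max(hq_mn), 3), 0.091)
})

test_that("pooled hazard indices reproduce the reported per-metal lists", {
  s <- danube_site_means()
  rt <- subset(risk_table(s), scope == "pooled")
  golden <- list(
    APR_SEP.adult = c(As = 1.3049e-1, Cr = 1.9819e-2, Cu = 3.0854e-3,
                      Fe = 2.2947e-2, Mn = 7.4476e-2, Ni = 4.1716e-3,
                      Pb = 2.8275e-2, Zn = 1.5280e-3),
    APR_SEP.child = c(As = 4.9771e-1, Cr = 7.0938e-2, Cu = 1.1739e-2,
                      Fe = 8.7153e-2, Mn = 2.7751e-1, Ni = 1.5844e-2,
                      Pb = 1.0792e-1, Zn = 5.8156e-3),
    OCT_MAR.adult = c(As = 1.4506e-1, Cr = 1.8789e-2, Cu = 2.8208e-3,
                      Fe = 1.7778e-2, Mn = 5.5776e-2, Ni = 3.8697e-3,
                      Zn = 1.5887e-3),
    OCT_MAR.child = c(As = 5.5325e-1, Cr = 6.7253e-2, Cu = 1.0732e-2,
                      Fe = 6.7521e-2, Mn = 2.0783e-1, Ni = 1.4697e-2,
                      Zn = 6.0466e-3))
  for (k in names(golden)) {
    per <- sub("\\..*$", "", k); rec <- sub("^.*\\.", "", k)
    hi <- setNames(rt$hi[rt$period == per & rt$receptor == rec],
                   rt$metal[rt$period == per & rt$receptor == rec])
    expect_equal(hi[names(golden[[k]])], golden[[k]], tolerance = 5e-3)
  }
  # the fixture's Oct-Mar Pb mean (1.234 ug/L) gives these directly
  expect_equal(rt$hi[rt$period == "OCT_MAR" & rt$receptor == "adult" & rt$metal == "Pb"],
               0.026612, tolerance = 1e-3)
  expect_true(all(rt$hi < 1))
  expect_true(all(rt$hi_class == "safe"))
})

test_that("carcinogenic risk applies only where a slope factor exists", {
  s <- danube_site_means()
  p <- default_parameters()
  ch <- exposure_profile("child")
  cdi <- cdi_oral(ugL_to_mgL(pooled_means(s, "APR_SEP")[["As"]]), ch)
  expect_equal(cdi, 1.4877e-4, tolerance = 1e-3)
  cr <- carcinogenic_risk(cdi, p["As", "csf_oral"])
  expect_equal(cr, 2.232e-4, tolerance = 1e-3)
  expect_equal(classify(cr, "CR"), "unacceptable")
  # child dermal Pb, Oct-Mar pooled: low and acceptable
  cdid <- cdi_dermal(ugL_to_mgL(pooled_means(s, "OCT_MAR")[["Pb"]]), ch, p["Pb", "kp"])
  crd <- carcinogenic_risk(cdid, p["Pb", "csf_dermal"])
  expect_equal(crd, 2.604e-5, tolerance = 1e-3)
  expect_equal(classify(crd, "CR"), "acceptable")
  expect_equal(carcinogenic_risk(0, 1.5), 0)
  expect_error(carcinogenic_risk(1e-5, p["Mn", "csf_oral"]), "slope factor")
  rt <- risk_table(s)
  expect_true(all(is.na(rt$cr_oral[rt$metal == "Mn"])))
  expect_true(all(rt$cr_oral_class[rt$metal == "Mn"] == "not applicable"))
})

test_that("the risk table is internally consistent and complete", {
  s <- danube_site_means()
  rt <- risk_table(s)
  expect_equal(nrow(rt), 8 * 2 * 2 * 8)   # scopes(7+pooled) x periods x metals x receptors
  expect_equal(rt$hi, rt$hq_oral + rt$hq_dermal)
  expect_true(all(rt[, c("cdi_oral", "cdi_dermal", "hq_oral", "hq_dermal", "hi")] >= 0))
  expect_equal(nrow(risk_table(danube_site_means()[0, ])), 0)
})

test_that("risk scales linearly in concentration and child exceeds adult", {
  p <- default_parameters()
  ad <- exposure_profile("adult"); ch <- exposure_profile("child")
  for (m in hm_metals()) {
    c1 <- 0.002
    hq1 <- hazard_quotient(cdi_oral(c1, ad), p[m, "rfd_oral"])
    hq2 <- hazard_quotient(cdi_oral(2 * c1, ad), p[m, "rfd_oral"])
    expect_equal(hq2, 2 * hq1)
    # child dose rate per unit concentration exceeds the adult's
    expect_gt(cdi_oral(c1, ch), cdi_oral(c1, ad))
    # dermal/oral HQ ratio is a pure constant of the exposure profile
    r1 <- hazard_quotient(cdi_dermal(c1, ad, p[m, "kp"]), p[m, "rfd_dermal"]) /
      hazard_quotient(cdi_oral(c1, ad), p[m, "rfd_oral"])
    r2 <- hazard_quotient(cdi_dermal(5 * c1, ad, p[m, "kp"]), p[m, "rfd_dermal"]) /
      hazard_quotient(cdi_oral(5 * c1, ad), p[m, "rfd_oral"])
    expect_equal(r1, r2)
  }
})
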