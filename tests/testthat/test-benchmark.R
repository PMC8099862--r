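# CV profiles, dilution linearity, ratio accuracy and missing-value groups.

test_that("dilution designs validate amounts and derive expected ratios", {
  d <- dilution_design()
  expect_equal(d$amounts, c(2, 1, 0.5, 0.2, 0.1))
  expect_equal(unname(expected_ratios(d)), c(1, 2, 4, 10, 20))
  expect_equal(nrow(d$runs), 15L)
  expect_error(dilution_design(c(1, 2)), "strictly decreasing")
  expect_error(dilution_design(c(2, -1)), "strictly decreasing|> 0")
})

test_that("CV% is the n-1 sample sd over the mean, excluding singletons", {
  m <- matrix(c(9, 10, 11,
                5, 5, 5,
                7, NA, NA), nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("r1", "r2", "r3")))
  cv <- cv_profile(m)
  expect_equal(cv$per_site$cv_pct[cv$per_site$site == "a"], 10)
  expect_equal(cv$per_site$cv_pct[cv$per_site$site == "b"], 0)
  expect_false("c" %in% cv$per_site$site)   # single value: undefined, excluded
  expect_equal(unname(cv$median_cv), 5)

  # scale invariance: CV unchanged under positive scaling
  expect_equal(cv_profile(m * 37)$per_site$cv_pct, cv$per_site$cv_pct)
})

test_that("dilution linearity recovers exact proportional responses", {
  d <- dilution_design()
  m <- outer(c(site1 = 1000, site2 = 500), d$runs$amount)
  colnames(m) <- d$runs$run
  fit <- dilution_linearity(m, d)
  expect_equal(fit$slope, c(1000, 500), tolerance = 1e-9)
  expect_equal(fit$r_squared, c(1, 1), tolerance = 1e-12)

  # constant abundance: R^2 defined as 0
  mc <- matrix(100, 1, nrow(d$runs), dimnames = list("flat", d$runs$run))
  expect_equal(dilution_linearity(mc, d)$r_squared, 0)

  # a site observed at only two levels is skipped with a reason
  m2 <- m
  m2["site2", d$runs$run[d$runs$level > 2]] <- NA
  fit2 <- dilution_linearity(m2, d)
  expect_false("site2" %in% fit2$site)
  expect_equal(attr(fit2, "skipped")$site, "site2")
})

test_that("ratio accuracy is exact on noiseless data and robust to missingness", {
  d <- dilution_design()
  m <- outer(stats::setNames(c(1000, 500, 80), paste0("s", 1:3)), d$runs$amount)
  colnames(m) <- d$runs$run
  ra <- ratio_accuracy(m, d)
  expect_equal(ra$medians$median_ratio, c(1, 2, 4, 10, 20), tolerance = 1e-12)
  # exact per site, not just in the median
  expect_true(all(abs(ra$per_site$ratio - ra$per_site$expected) < 1e-9))

  # a site missing at one level drops out of that level's median only
  m2 <- m
  m2["s3", d$runs$run[d$runs$level == 5]] <- NA
  ra2 <- ratio_accuracy(m2, d)
  expect_equal(ra2$medians$n_sites, c(3L, 3L, 3L, 3L, 2L))
})

test_that("missing-value profiles concentrate and partition correctly", {
  # 6 sites x 3 runs; 2 missing cells planted in the lowest-abundance tertile
  m <- matrix(rep(c(1, 2, 10, 20, 100, 200), 3), nrow = 6,
              dimnames = list(paste0("s", 1:6), paste0("r", 1:3)))
  m[1, 1] <- NA; m[2, 3] <- NA
  mv <- missing_value_profile(m, n_groups = 3)
  expect_equal(mv$pct_missing_cells, c(2 / 6 * 100, 0, 0))
  expect_equal(mv$n_sites, c(2L, 2L, 2L))

  # completeness percentages partition to 100 in every group
  sums <- mv$pct_complete + mv$pct_partial + mv$pct_single + mv$pct_none
  expect_equal(sums, rep(100, 3))

  # all-complete matrix: no missingness anywhere
  mv2 <- missing_value_profile(matrix(1, 9, 3,
                                      dimnames = list(paste0("s", 1:9),
                                                      paste0("r", 1:3))))
  expect_true(all(mv2$pct_missing_cells == 0))
  expect_true(all(mv2$pct_complete == 100))

  # group sizes differ by at most 1 when n is not divisible
  mv3 <- missing_value_profile(matrix(1:20, 10, 2,
                                      dimnames = list(paste0("s", 1:10),
                                                      c("r1", "r2"))))
  expect_true(max(mv3$n_sites) - min(mv3$n_sites) <= 1L)
})

test_that("simulated dropout above the lowest level concentrates missingness
           in the low-abundance tertile", {
  prot <- simulate_proteins(40, seed = 21)
  panel <- simulate_panel(prot, counts = c(60, 0, 0), seed = 22)
  # midpoint set above the lowest dilution's typical log10 abundance
  sim <- simulate_dilution_report(panel, noise_cv = 0.05,
                                  dropout = list(midpoint = 4.3, steepness = 3),
                                  seed = 23)
  expect_gt(sim$truth$n_dropped, 0)
  sm <- rollup_phosphosites(sim$report, prot)
  mv <- missing_value_profile(sm, n_groups = 3)
  expect_gt(mv$pct_missing_cells[1], mv$pct_missing_cells[2])
  expect_gte(mv$pct_missing_cells[2], mv$pct_missing_cells[3])
})

test_that("benchmark_report bundles the four metric families", {
  prot <- simulate_proteins(30, seed = 31)
  panel <- simulate_panel(prot, counts = c(30, 0, 0), seed = 32)
  d <- dilution_design()
  sim <- simulate_dilution_report(panel, noise_cv = 0.05, seed = 33)
  sm <- rollup_phosphosites(sim$report, prot)
  br <- benchmark_report(sm, d)
  expect_s3_class(br, "benchmark_report")
  expect_named(br$cv$median_cv, d$labels)
  expect_equal(br$ratios$medians$expected, c(1, 2, 4, 10, 20))
  expect_true(all(br$linearity$r_squared > 0.9))
  expect_output(print(br), "median CV%")
})
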