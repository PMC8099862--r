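# Fragment filtering, PSM QC, iRT calibration and hybrid merging.

make_entry <- function(modseq = "AS(ph)GLKPVDER", charge = 2L, irt = 50,
                       source = "DDA", score = 1, n_frag = 6,
                       mz = NULL, intensity = NULL, n_residues = NULL) {
  if (is.null(mz)) mz <- seq(350, 900, length.out = n_frag)
  if (is.null(intensity)) intensity <- seq(1, 0.2, length.out = length(mz))
  if (is.null(n_residues)) n_residues <- rep(5L, length(mz))
  library_entry(modseq, charge, irt,
                data.frame(series = "y", index = seq_along(mz), charge = 1L,
                           neutral_loss = 0, mz = mz,
                           n_residues = n_residues,
                           rel_intensity = intensity),
                source = source, score = score, proteins = "SIM1")
}

test_that("fragment filtering applies the m/z, intensity, length and top-15 rules", {
  e <- make_entry(mz = c(250, 400, 500, 1900, 600, 700),
                  intensity = c(1, 0.04, 0.8, 0.9, 0.6, 0.5),
                  n_residues = c(5, 5, 5, 5, 2, 5))
  f <- filter_fragments(e)
  # dropped: 250 (below 300), 1900 (above 1800), 4% intensity, 2 residues
  expect_equal(sort(f$fragments$mz), c(500, 700))

  # top-15 by intensity, ties broken by ascending m/z
  e2 <- make_entry(mz = 300 + seq_len(20) * 10,
                   intensity = c(rep(1, 16), 0.9, 0.8, 0.7, 0.6),
                   n_residues = rep(5L, 20))
  f2 <- filter_fragments(e2)
  expect_equal(nrow(f2$fragments), 15L)
  # the 16 tied top-intensity fragments: the 15 with lowest m/z survive
  expect_equal(sort(f2$fragments$mz), 300 + seq_len(15) * 10)

  # neutral-loss fragments are retained
  e3 <- make_entry(mz = c(400, 500), intensity = c(1, 0.9))
  e3$fragments$neutral_loss <- c(97.9769, 0)
  expect_equal(nrow(filter_fragments(e3)$fragments), 2L)

  # a fully filtered entry warns
  expect_warning(filter_fragments(make_entry(mz = c(250, 260),
                                             intensity = c(1, 0.5))),
                 "no fragment")
})

test_that("fragment filtering is idempotent", {
  set.seed(11)
  for (i in 1:10) {
    n <- sample(5:30, 1)
    e <- make_entry(mz = runif(n, 200, 2000), intensity = runif(n, 0.01, 1),
                    n_residues = sample(1:10, n, replace = TRUE))
    f1 <- tryCatch(filter_fragments(e), warning = function(w) NULL)
    if (is.null(f1)) next
    f2 <- filter_fragments(f1)
    expect_equal(f2$fragments, f1$fragments)
  }
})

test_that("PSM QC keeps only records meeting all four inclusive thresholds", {
  recs <- data.frame(
    score = c(39, 40, 100, 50, 45, NA),
    delta_score = c(10, 8, 7.9, 9, 8, 9),
    intensity = c(500, 100, 500, 99, 500, 500),
    sequence = c("PEPTIDEK", "PEPTIDEK", "PEPTIDEK", "PEPTIDEK", "PEPTID", "PEPTIDEK"))
  out <- qc_filter_psms(recs)
  expect_equal(nrow(out), 1L)           # only row 2 passes everything
  expect_equal(out$score, 40)
  rej <- attr(out, "rejected")
  expect_setequal(rej$row, c(1, 3, 4, 5, 6))
  expect_equal(rej$reason[rej$row == 6], "missing field")
  expect_equal(rej$reason[rej$row == 1], "score below threshold")
  expect_equal(rej$reason[rej$row == 5], "peptide too short")
})

test_that("iRT calibration recovers exact linear fits and round trips", {
  irt <- seq(0, 100, by = 5)
  rt <- 0.5 * irt + 10
  cal <- fit_irt_calibration(irt, rt)
  expect_equal(cal$slope, 0.5, tolerance = 1e-12)
  expect_equal(cal$intercept, 10, tolerance = 1e-12)
  expect_equal(cal$r_squared, 1, tolerance = 1e-12)
  expect_equal(predict(cal, 0), 10)
  # round trip: predict then invert is the identity
  expect_equal(predict(cal, predict(cal, irt), invert = TRUE), irt,
               tolerance = 1e-9)

  expect_error(fit_irt_calibration(1, 2), "at least 2")
  expect_error(fit_irt_calibration(c(5, 5, 5), c(1, 2, 3)), "degenerate")

  # segmented: piecewise-linear data recovered segment by segment
  irt2 <- seq(0, 100, by = 2)
  rt2 <- ifelse(irt2 <= 50, irt2, 50 + 2 * (irt2 - 50))
  cal2 <- fit_irt_calibration(irt2, rt2, n_segments = 2)
  expect_equal(cal2$slope, c(1, 2), tolerance = 0.05)
  expect_gt(cal2$r_squared, 0.999)
})

test_that("hybrid merge unions archives, keeps best spectra and counts provenance", {
  a <- make_entry("AS(ph)GLKPVDER", source = "DDA", score = 10)
  b_dda <- make_entry("PES(ph)TLHKR", source = "DDA", score = 5)
  b_dia <- make_entry("PES(ph)TLHKR", source = "DIA", score = 8)
  c_dia <- make_entry("TS(ph)AAGGKR", source = "DIA", score = 3)
  lib <- merge_hybrid(list(a, b_dda), list(b_dia, c_dia))
  expect_length(lib$entries, 3L)
  expect_equal(unname(lib$counts), c(1, 1, 1))
  shared <- lib$entries[["PES(ph)TLHKR/2"]]
  expect_equal(shared$source, "both")
  expect_equal(shared$score, 8)  # higher-scoring DIA spectrum kept

  # empty DIA archive: library = DDA side
  expect_length(merge_hybrid(list(a), list())$entries, 1L)

  # same sequence at two charges stays two entries
  lib2 <- merge_hybrid(list(make_entry(charge = 2L), make_entry(charge = 3L)),
                       list())
  expect_length(lib2$entries, 2L)

  # content commutes; size obeys inclusion-exclusion
  lib_ab <- merge_hybrid(list(a, b_dda), list(b_dia, c_dia))
  lib_ba <- merge_hybrid(list(b_dia, c_dia), list(a, b_dda))
  expect_setequal(names(lib_ab$entries), names(lib_ba$entries))
  expect_equal(length(lib_ab$entries), 2L + 2L - 1L)
})

test_that("library summary counts sites, proteins and the pS/pT/pY split", {
  entries <- list(
    make_entry("AS(ph)GLKPVDER"),            # pS
    make_entry("PES(ph)TLHKR"),              # pS
    make_entry("PEST(ph)LHKR"),              # pT
    make_entry("ADGY(ph)LKR"))               # pY
  lib <- merge_hybrid(entries, list())
  s <- library_summary(lib)
  expect_equal(s$n_precursors, 4L)
  expect_equal(s$n_phosphosites, 4L)
  expect_equal(unname(s$psty_fraction), c(0.5, 0.25, 0.25))

  # class-1 counting at the 0.75 cutoff
  s2 <- library_summary(lib, site_probabilities = c(0.8, 0.7), cutoff = 0.75)
  expect_equal(s2$n_class1, 1L)

  empty <- library_summary(merge_hybrid(list(), list()))
  expect_equal(empty$n_precursors, 0L)
})
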