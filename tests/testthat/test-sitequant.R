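# Peptide-to-protein site mapping, phosphosite/protein roll-up and
# cross-run normalization.

# Small deterministic fixture: two proteins, four precursors over two runs.
quant_fixture <- function() {
  proteins <- c(P1 = "MKAASGLKPVDERGSHQISLDNPDYQQDFFPKTTR",
                P2 = "MSSTYKLRPEPTIDEK")
  report <- data.frame(
    run = c("r1", "r1", "r1", "r2", "r2"),
    modified_sequence = c("GS(ph)HQISLDNPDYQQDFFPK",
                          "GS(ph)HQISLDNPDYQQDFFPK",
                          "GSHQISLDNPDY(ph)QQDFFPK",
                          "GS(ph)HQISLDNPDYQQDFFPK",
                          "AAS(ph)GLK"),
    charge = c(2L, 3L, 2L, 2L, 2L),
    protein_group = c("P1", "P1", "P1", "P1", "P1;P2"),
    area = c(100, 50, 80, 70, 40),
    rt = 10,
    site_probs = c("S2: 0.9", "S2: 0.8", "Y12: 0.6", "S2: 1", ""),
    mode = "libDIA")
  list(proteins = proteins, report = report)
}

test_that("peptide phospho positions map to protein coordinates", {
  fx <- quant_fixture()
  # peptide starts at offset 14 in P1; peptide position 2 -> protein 15
  m <- map_sites_to_protein("GS(ph)HQISLDNPDYQQDFFPK", fx$proteins[["P1"]], "P1")
  expect_equal(m$position, 15L)
  expect_equal(m$site_key, "P1-S15")
  expect_false(m$multi_mapping)

  m2 <- map_sites_to_protein("GSHQISLDNPDY(ph)QQDFFPK", fx$proteins[["P1"]], "P1")
  expect_equal(m2$position, 25L)
  expect_equal(m2$residue, "Y")

  # identity offset: peptide at protein start maps position 1 to 1
  m3 <- map_sites_to_protein("MS(ph)STYK", "MSSTYKLR", "X")
  expect_equal(m3$position, 2L)

  expect_error(map_sites_to_protein("GS(ph)HHHHHH", fx$proteins[["P1"]], "P1"),
               "not found in protein P1")
})

test_that("site roll-up sums qualifying precursor areas per run", {
  fx <- quant_fixture()
  sm <- rollup_phosphosites(fx$report, fx$proteins, cutoff = 0.75)
  m <- sm$abundance
  # S14 in r1: 100 + 50 (both probs >= 0.75); Y24 excluded at 0.6
  expect_equal(m["P1-S15", "r1"], 150)
  expect_false("P1-Y25" %in% rownames(m))
  # missing is NA, never 0: S5 only observed in r2
  expect_equal(m["P1-S15", "r2"], 70)
  expect_true(is.na(m["P1-S5", "r1"]))
  expect_equal(m["P1-S5", "r2"], 40)  # blank probability string -> prob 1
  # first accession of the group string keys the site
  expect_equal(sm$sites$protein_group[sm$sites$site_key == "P1-S5"], "P1;P2")
})

test_that("precursors below the cutoff are excluded and multi-phospho
           precursors contribute full area to every class-1 site", {
  proteins <- c(P1 = "MKAASGLKPVDERGSHQISLDNPDYQQDFFPKTTR")
  rep2 <- data.frame(
    run = "r1",
    modified_sequence = "GS(ph)HQISLDNPDY(ph)QQDFFPK",
    charge = 2L, protein_group = "P1", area = 80, rt = 1,
    site_probs = "S2: 0.95; Y12: 0.9", mode = "libDIA")
  sm <- rollup_phosphosites(rep2, proteins, cutoff = 0.75)
  expect_equal(sm$abundance["P1-S15", "r1"], 80)
  expect_equal(sm$abundance["P1-Y25", "r1"], 80)

  # prob 0.6 at cutoff 0.75: excluded entirely
  rep3 <- rep2
  rep3$site_probs <- "S2: 0.6; Y12: 0.9"
  sm3 <- rollup_phosphosites(rep3, proteins, cutoff = 0.75)
  expect_false("P1-S15" %in% rownames(sm3$abundance))
})

test_that("mono-phospho roll-up conserves total class-1 area per run and is
           order-invariant", {
  prot <- simulate_proteins(30, seed = 5)
  panel <- simulate_panel(prot, counts = c(40, 0, 0), seed = 6)
  sim <- simulate_dilution_report(panel, noise_cv = 0.05, seed = 7)
  sm <- rollup_phosphosites(sim$report, prot)
  for (r in colnames(sm$abundance)) {
    expect_equal(sum(sm$abundance[, r], na.rm = TRUE),
                 sum(sim$report$area[sim$report$run == r]),
                 tolerance = 1e-9)
  }
  shuffled <- sim$report[sample(nrow(sim$report)), ]
  sm2 <- rollup_phosphosites(shuffled, prot)
  expect_equal(sm2$abundance[rownames(sm$abundance), colnames(sm$abundance)],
               sm$abundance)
})

test_that("protein roll-up averages precursors per stripped peptide then sums", {
  fx <- quant_fixture()
  pm <- rollup_proteins(fx$report)
  # r1: stripped GSHQISLDNPDYQQDFFPK has areas 100, 50, 80 -> mean 76.666...
  expect_equal(pm["P1", "r1"], mean(c(100, 50, 80)))
  # r2: two stripped peptides, 70 and 40 -> protein sum 110
  expect_equal(pm["P1", "r2"], 70 + 40)
  # no precursor for P2-keyed group in r1 -> missing
  expect_true(all(rownames(pm) == "P1"))
})

test_that("median normalization equalizes run medians and is idempotent
           in its factors", {
  m <- matrix(c(10, 20, 40, 20, 40, 80), nrow = 3,
              dimnames = list(c("a", "b", "c"), c("r1", "r2")))
  out <- normalize_runs(m)
  expect_equal(attr(out, "factors")[["r1"]] / attr(out, "factors")[["r2"]], 2)
  expect_equal(out[, "r1"], out[, "r2"])

  # already centered: factors all 1
  out2 <- normalize_runs(out)
  expect_equal(unname(attr(out2, "factors")), c(1, 1), tolerance = 1e-9)

  # missing markers survive normalization untouched as NA
  m2 <- m; m2["b", "r2"] <- NA
  out3 <- normalize_runs(m2)
  expect_true(is.na(out3["b", "r2"]))

  m3 <- matrix(c(1, NA, NA, 2), 2, dimnames = list(c("a", "b"), c("r1", "r2")))
  expect_error(normalize_runs(m3), "no rows complete")
})
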