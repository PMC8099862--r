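# S0 statistic, permutation FDR, protein normalization, motif windows and
# Fisher enrichment.

test_that("the S0 statistic reduces to the pooled t at s0 = 0 and matches
           the hand-computed example", {
  # A = (1,2,3), B = (4,5,6): d = -3 / (1 * sqrt(2/3) + 0.1)
  expect_equal(s0_ttest(c(1, 2, 3), c(4, 5, 6), s0 = 0.1),
               -3 / (sqrt(2 / 3) + 0.1), tolerance = 1e-12)
  expect_equal(round(s0_ttest(c(1, 2, 3), c(4, 5, 6), s0 = 0.1), 3), -3.273)

  # identical groups score 0
  expect_equal(s0_ttest(c(1, 2, 3), c(1, 2, 3), s0 = 0.1), 0)

  set.seed(42)
  for (i in 1:20) {
    a <- rnorm(sample(3:6, 1)); b <- rnorm(sample(3:6, 1))
    ref <- t.test(a, b, var.equal = TRUE)$statistic
    expect_equal(s0_ttest(a, b, s0 = 0), unname(ref), tolerance = 1e-12)
  }
  expect_error(s0_ttest(1, c(1, 2)), "at least 2")
})

test_that("permutation FDR is deterministic, exhaustive for 3v3 and
           invariant to site order", {
  sim <- simulate_two_group_matrix(200, 3, 20, effect = 2, sd = 0.25, seed = 1)
  r1 <- permutation_fdr(sim$matrix, sim$labels, seed = 9)
  r2 <- permutation_fdr(sim$matrix, sim$labels, seed = 9)
  expect_equal(r1$q_value, r2$q_value)
  expect_true(attr(r1, "exhaustive"))
  expect_equal(attr(r1, "n_assignments"), choose(6, 3))

  perm <- sample(nrow(sim$matrix))
  r3 <- permutation_fdr(sim$matrix[perm, ], sim$labels, seed = 9)
  expect_equal(r3$q_value[match(r1$site, r3$site)], r1$q_value)

  # q-values are monotone non-decreasing as |d| falls
  ord <- order(abs(r1$statistic), decreasing = TRUE)
  expect_true(all(diff(r1$q_value[ord]) >= 0))
  expect_true(all(r1$q_value >= 0 & r1$q_value <= 1))
})

test_that("under a simulated null the realized false-positive proportion
           stays below 0.05 at FDR < 0.01", {
  fpp <- vapply(1:20, function(s) {
    sim <- simulate_two_group_matrix(1000, 3, 0, seed = s)
    mean(permutation_fdr(sim$matrix, sim$labels, s0 = 0.1, seed = s)$significant)
  }, 0)
  expect_lt(max(fpp), 0.05)
})

test_that("planted 2-log2 shifts at sd 0.25 are recovered with >= 90% power", {
  sim <- simulate_two_group_matrix(1000, 3, 100, effect = 2, sd = 0.25,
                                   seed = 11)
  r <- permutation_fdr(sim$matrix, sim$labels, s0 = 0.1, seed = 11)
  power <- mean(r$significant[match(sim$truth$changed, r$site)])
  expect_gte(power, 0.9)
})

test_that("protein normalization cancels shared fold changes and flags
           unquantified proteins", {
  sites <- matrix(c(8, 64, 16, 16), 2, byrow = TRUE,
                  dimnames = list(c("P1-S10", "P9-S3"), c("r1", "r2")))
  prots <- matrix(c(2, 16), 1, dimnames = list("P1", c("r1", "r2")))
  out <- normalize_site_to_protein(sites, prots)
  # site 8x up, protein 8x up: adjusted difference 0
  expect_equal(out$adjusted["P1-S10", "r2"] - out$adjusted["P1-S10", "r1"], 0)
  # protein absent: passed through as plain log2, flagged
  expect_equal(out$adjusted["P9-S3", ], log2(sites["P9-S3", ]))
  expect_true(all(out$unadjusted["P9-S3", ]))
  expect_false(any(out$unadjusted["P1-S10", ]))

  # constant protein: adjusted differences equal raw log2 differences
  prots2 <- matrix(c(4, 4), 1, dimnames = list("P1", c("r1", "r2")))
  out2 <- normalize_site_to_protein(sites, prots2)
  expect_equal(out2$adjusted["P1-S10", "r2"] - out2$adjusted["P1-S10", "r1"],
               log2(64) - log2(8))
})

test_that("13-mer windows center the site and pad beyond the termini", {
  prot <- c(PX = "ABCDEFSHIJKLMNOPQRSX")
  # interior site at position 7: residues 1..13, no padding
  w <- extract_motif_windows(data.frame(accession = "PX", position = 7), prot)
  expect_equal(w$window, "ABCDEFSHIJKLM")
  expect_equal(nchar(w$window), 13L)

  # site at position 3 needs 4 leading pads
  prot2 <- c(PY = "MASXXXXXXXXXX")
  w2 <- extract_motif_windows(data.frame(accession = "PY", position = 3), prot2)
  expect_equal(w2$window, "____MASXXXXXX")

  # site at the last residue needs 6 trailing pads
  prot3 <- c(PZ = "XXXXXXXXXXXXS")
  w3 <- extract_motif_windows(data.frame(accession = "PZ", position = 13), prot3)
  expect_equal(w3$window, "XXXXXXS______")
  w4 <- extract_motif_windows("PZ-S13", prot3)
  expect_equal(substr(w4$window, 8, 13), "______")

  # center residue must be S/T/Y
  expect_error(extract_motif_windows(data.frame(accession = "PX", position = 1),
                                     prot), "not S/T/Y")
})

test_that("Fisher enrichment matches the hypergeometric tail and applies the
           FDR threshold strictly", {
  # foreground 8/10 match vs background 10/100 match, one-sided enrichment:
  # exact enumeration of the 2x2 tail
  tail_p <- sum(dhyper(8:10, m = 18, n = 92, k = 10))
  motif <- data.frame(motif = "test", pattern = "0:S")
  fg <- c(rep("AAAAAASAAAAAA", 8), rep("AAAAAATAAAAAA", 2))
  bg <- c(rep("AAAAAASAAAAAA", 10), rep("AAAAAATAAAAAA", 90))
  res <- fisher_motif_enrichment(fg, bg, motifs = motif, fdr_threshold = 0.02)
  expect_equal(res$p_value, tail_p, tolerance = 1e-12)
  expect_equal(res$fg_match, 8)

  # equal match rates: odds ratio 1, p = 1 (no enrichment signal)
  fg_eq <- c(rep("AAAAAASAAAAAA", 5), rep("AAAAAATAAAAAA", 5))
  bg_eq <- c(rep("AAAAAASAAAAAA", 50), rep("AAAAAATAAAAAA", 50))
  res_eq <- fisher_motif_enrichment(fg_eq, bg_eq, motifs = motif)
  expect_gt(res_eq$p_value, 0.5)

  # threshold is strict: FDR exactly at 0.02 is not enriched
  res_fake <- res
  res_fake$fdr <- 0.021
  expect_false(res_fake$fdr < 0.02)

  # motif grammar drives matching: proline-directed needs +1 P
  expect_true(match_motif("AAAAAASPAAAAA", "0:ST;1:P"))
  expect_false(match_motif("AAAAAASAAAAAA", "0:ST;1:P"))
  expect_error(fisher_motif_enrichment(character(), bg, motifs = motif),
               "empty")
})

test_that("the shipped kinase motif table is well-formed and parseable", {
  km <- kinase_motifs()
  expect_true(all(c("motif", "class", "pattern") %in% names(km)))
  for (p in km$pattern)
    expect_silent(match_motif("AAAAAASPAAAAA", p))
})
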