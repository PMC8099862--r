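# Shared fixtures and independent oracles.

# The EGFR tryptic peptide spanning protein residues 1161-1179; its S/T/Y
# candidates sit at peptide positions 2 (S1162), 6 (S1166) and 12 (Y1172).
EGFR_PEP <- "GSHQISLDNPDYQQDFFPK"

# Standard monoisotopic residue table, re-keyed independently of the package
# internals for oracle arithmetic.
ORACLE_AA <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)

# Brute-force oracle: site-determining ion indices found by computing both
# full singly-charged ladders and comparing m/z elementwise.
oracle_site_determining <- function(sequence, config_a, config_b) {
  ladder_of <- function(cfg) {
    mods <- if (length(cfg)) data.frame(position = cfg, label = "ph") else NULL
    fragment_ladder(peptidoform(sequence, mods))
  }
  la <- ladder_of(config_a); lb <- ladder_of(config_b)
  differs <- abs(la$mz - lb$mz) > 1e-9
  list(b = la$index[la$series == "b" & differs],
       y = la$index[la$series == "y" & differs])
}

# Random peptide containing at least min_sty S/T/Y residues.
random_peptide <- function(len, min_sty = 1L) {
  repeat {
    s <- paste(sample(names(ORACLE_AA), len, replace = TRUE), collapse = "")
    if (lengths(regmatches(s, gregexpr("[STY]", s))) >= min_sty) return(s)
  }
}

# Peak data.frame holding exactly the singly-charged b/y ions of one
# configuration, at unit intensity.
peaks_for_config <- function(sequence, positions, intensity = 100) {
  mods <- if (length(positions)) data.frame(position = positions, label = "ph")
          else NULL
  fl <- fragment_ladder(peptidoform(sequence, mods))
  data.frame(mz = sort(fl$mz), intensity = intensity)
}
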