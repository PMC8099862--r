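# phosphoDIA

Site-resolved quantification is the hard part of phosphoproteomics by
data-independent acquisition (DIA) mass spectrometry: a phosphopeptide with
several serine/threonine/tyrosine candidates is only as useful as the
confidence with which the phosphate can be placed on one of them, and
abundances measured per precursor still have to be aggregated to the
biological unit of interest — the phosphosite on a protein. phosphoDIA is
an R toolkit for that workflow, aimed at computational proteomics
developers and methods benchmarkers. It provides:

- **Mass arithmetic** — peptidoform parsing (`"GS(ph)HQISLDNPDYQQDFFPK"`),
  monoisotopic masses, precursor m/z, b/y fragment ladders with phospho
  neutral loss (−97.9769 Da).
- **Phosphosite localization** — positional-isomer enumeration,
  site-determining fragment ions, Ascore-style cumulative-binomial scoring
  of peak lists, per-site probabilities and class-1 calls
  (≥ 0.75 for DDA/libDIA, ≥ 0.99 for dirDIA). For a spectrum matched
  against $k$-phospho isomers with $j$ of $n$ theoretical ions hit, the
  score is $-10\log_{10} P(X \ge j)$, $X \sim \mathrm{Binomial}(n, p)$,
  $p = \mathrm{depth}\cdot 2\cdot\mathrm{tolerance}/100$; isomer weights
  $10^{s/10}$ marginalize into site probabilities that sum to $k$.
- **Hybrid spectral libraries** — fragment filtering (m/z 300–1800, ≥ 5%
  relative intensity, ≥ 3 residues, top 15), PSM quality control (score
  ≥ 40, delta ≥ 8, intensity ≥ 100, length ≥ 7), segmented iRT calibration,
  DDA+DIA archive merging with provenance counts.
- **Site roll-up** — a phosphosite's abundance per run is the summed area
  of every precursor containing that site at class-1 localization; protein
  abundance is the sum of mean precursor areas per stripped peptide;
  log2-median cross-run normalization.
- **Benchmarking** — CV% profiles, dilution linearity, measured-vs-expected
  fold ratios, and abundance-ranked missing-value profiles for spike-in
  dilution series.
- **Differential statistics** — SAM-style S0-moderated t-test
  ($s_0 = 0.1$) with permutation FDR, protein-level normalization of site
  abundances, 13-mer motif windows and Fisher's-exact kinase-motif
  enrichment (FDR < 0.02).
- **Simulators** — proteins, spike-in phosphopeptide panels (default
  139 mono / 21 di / 6 tri = 166 entries), dilution-series precursor
  reports with lognormal noise and logistic dropout, isomer spectra with
  known true sites, and two-group matrices with planted effects — all pure
  functions of (parameters, seed) with ground truth attached.

## Worked example

Simulate the spike-in benchmark — a 166-peptide panel spiked at five
amounts (2, 1, 0.5, 0.2, 0.1 units) in triplicate with 5% multiplicative
noise — then roll up to sites and benchmark:

```r
library(phosphoDIA)

proteins <- simulate_proteins(60, seed = 1)
panel <- simulate_panel(proteins, seed = 2)
panel
#> Phosphopeptide panel: 166 entries ( 139 mono / 21 di / 6 tri ) on 153 unique sequences

sim <- simulate_dilution_report(panel, noise_cv = 0.05, seed = 3)
sites <- rollup_phosphosites(sim$report, proteins, mode = "libDIA")
sites
#> Site abundance matrix: 193 site(s) x 15 run(s); 0 missing cell(s)

benchmark_report(sites, dilution_design())
#> Dilution-series benchmark
#>   median CV% per level:
#>   L2   L1 L0.5 L0.2 L0.1
#> 4.25 4.40 4.30 3.97 3.75
#>   median measured vs expected ratios:
#>  label expected median_ratio n_sites
#>     L2        1     1.000000     193
#>     L1        2     2.015514     193
#>   L0.5        4     4.001959     193
#>   L0.2       10     9.957941     193
#>   L0.1       20    19.821271     193
#>   per-site linearity: median R^2 = 0.9997 over 193 site(s)
```

The measured medians track the design's expected 1-, 2-, 4-, 10- and
20-fold ratios to within a fraction of a percent, and the ~4% median CV is
the expected recovery of a 5% multiplicative noise CV through the
three-replicate sample estimator. Localizing a simulated spectrum of the
EGFR peptide `GSHQISLDNPDYQQDFFPK` (S/T/Y candidates at positions 2, 6
and 12) phosphorylated at position 6:

```r
spec <- simulate_isomer_spectrum("GSHQISLDNPDYQQDFFPK", 6, seed = 4)
localize_spectrum(spec$peaks, "GSHQISLDNPDYQQDFFPK", k = 1)
#> Localization over 3 configuration(s), k = 1
#>  site probability class1
#>     6           1   TRUE
#>     2           0  FALSE
#>    12           0  FALSE
```

With full fragment coverage the discriminating b6–b11 and y8–y13 ions pin
the site unambiguously. A command-line interface covering the same
pipeline (`simulate`, `build-library`, `localize`, `quant-sites`,
`benchmark`, `diffexp`, `motif`) is available through
`phosphodia_cli()` / `inst/cli/phosphodia`.

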