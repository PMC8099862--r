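---
title: "phosphoDIA: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phosphoDIA: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

phosphoDIA is a desk-scale toolkit for DIA phosphoproteomics built around
four analytical steps — phosphosite localization from fragment-ion evidence,
hybrid spectral-library assembly, precursor-to-phosphosite abundance
roll-up, and spike-in benchmarking with differential statistics — plus a
synthetic-data generator that emulates a dilution-series spike-in benchmark
with known ground truth. This vignette explains the underlying models, the
parameters that matter, and the design choices made where more than one
defensible construction existed.

## Mass arithmetic

Peptide masses are sums of standard monoisotopic residue masses (hard-coded
at 5-decimal precision) plus one water (18.01056 Da) plus modification
deltas: phospho +79.96633 Da on S/T/Y, methionine oxidation +15.99491 Da,
cysteine carbamidomethylation +57.02146 Da, acetylation +42.01057 Da. The
proton mass is 1.007276 Da, so a precursor at charge $z$ sits at
$(M + z \cdot 1.007276)/z$. Fragment ladders enumerate all $b_1..b_{n-1}$
and $y_1..y_{n-1}$ ions; a fragment carries the deltas of the residues it
contains. The only neutral loss modeled is phosphoric acid (H$_3$PO$_4$,
97.9769 Da) from phospho-containing fragments: b/y ions with and without
that loss are what site-level evidence in this workflow rests on, and
adding water/ammonia losses would dilute the binomial match model below
without adding localization information. Fragment charges default to 1 and
are configurable.

## Phosphosite localization

Positional isomers of a peptide with $k$ phospho groups are the
$\binom{n_{STY}}{k}$ ways of placing them on its S/T/Y residues. Two
isomers differ at a fragment exactly when they put different numbers of
phospho groups inside it — all phospho deltas being equal — which is how
`site_determining_ions()` computes discriminating indices; the test suite
checks this against a brute-force comparison of the full ladders.

Scoring is an Ascore-style cumulative binomial. The peak list is reduced to
the `depth` most intense peaks per 100 Th (default 10); each configuration's
singly charged b/y ions are matched within `tolerance` (default 0.05 Da, the
conventional fragment tolerance of the upstream search); with $j$ of $n$
ions matched the score is $-10\log_{10} P(X \ge j)$ for
$X \sim \mathrm{Binomial}(n, p)$, $p = \mathrm{depth} \cdot 2 \cdot
\mathrm{tolerance}/100$ — the chance of a random match in the retained
spectrum. Configuration weights $10^{\mathrm{score}/10}$ are normalized into
configuration probabilities, and a site's probability marginalizes over the
configurations containing it, so site probabilities always sum to $k$.
Scoring whole configurations rather than sites independently keeps
multi-phospho peptides coherent; ties collapse to equal weights, so a
spectrum stripped of every discriminating ion yields the symmetric
$k/n_{STY}$ per site. Neutral-loss ions are excluded from the match count by
default to keep $n$ well defined.

A site is "class 1" when its probability meets the mode's cutoff: 0.75 for
DDA and library-based DIA, 0.99 for library-free DIA; both cutoffs are
inclusive. The binomial model is a reconstruction of what integrated
localization tools in commercial DIA software do, not a reimplementation of
any of them: its absolute probabilities will not numerically match theirs,
which is why the package's own recovery properties (below) are stated
against simulated spectra with known truth.

## Hybrid spectral libraries

Library entries are filtered by the standard fragment rules: m/z within
300–1800, relative intensity at least 5%, at least three residues, at most
the 15 most intense survivors (intensity ties broken by ascending m/z);
neutral-loss fragments are retained. Surviving intensities are rescaled to
base peak 1, which makes the filter idempotent. PSM-level quality control
keeps records with identification score ≥ 40, delta score ≥ 8, intensity
≥ 100 and peptide length ≥ 7, all inclusive. Upstream 1% FDR filtering is
treated as a property of the input, not recomputed — search-engine decoy
machinery is out of scope.

Retention-time calibration regresses measured RT on library iRT by least
squares, per segment, with knots at iRT quantiles; the default is a single
segment (ordinary least squares), since the proprietary "precision iRT"
function is not published and a linear map is the documented baseline. Each
segment requires at least three points; prediction works in both
directions.

DDA and DIA archives merge keyed by (modified sequence, charge). A
precursor present in both keeps its higher-scoring single spectrum and is
marked `both`; building a consensus spectrum would be the main alternative,
but keeping the best single spectrum is the simplest defensible reading of
how commercial archive merging behaves and keeps provenance unambiguous.

## Site-level quantification

Peptide phospho positions map to protein coordinates through the first
occurrence of the stripped sequence (`offset + position - 1`, both
1-based); additional occurrences set a multi-mapping flag. Site keys are
`"ACC-S123"` style, emitted against the first accession of a record's
protein group to avoid double counting shared peptides; the full group
string is kept as metadata.

The abundance of a phosphosite in a run is the *sum* of the areas of every
precursor — any charge, any co-modification, any phospho multiplicity —
whose localization probability for that site meets the class-1 cutoff.
Multi-phospho precursors therefore contribute their full area to each of
their qualifying sites; no splitting is attempted, since a di-phospho
precursor genuinely measures both sites. Records without an explicit
per-site probability (single-candidate peptides) are taken as fully
localized (probability 1). Sites with no qualifying precursor in a run are
*missing*, never zero, and the missing marker survives every downstream
operation. For mono-phospho-only data this roll-up conserves mass: per run,
the summed site abundances equal the summed qualifying precursor areas.

Protein abundance is the sum over the protein's stripped peptide sequences
of the *mean* precursor area per sequence. Cross-run normalization is
global median-centering in log2 space computed on rows complete in all
runs; a local, RT-dependent normalization is not reconstructable from the
description it emulates, and median centering is the standard conservative
stand-in.

## Benchmarking metrics

The default dilution design is five spike amounts (2, 1, 0.5, 0.2, 0.1
units) in triplicate, with the largest amount as the reference level, so
expected fold ratios are 1, 2, 4, 10 and 20. CV% is
$100 \cdot s/\bar{x}$ with the $n-1$ sample standard deviation on raw
abundances (log-space CV behind a flag); sites with fewer than two observed
replicates are excluded. Note that at $n = 3$ the sample CV is biased low —
its median is about $0.83\sigma$ — so a 5% simulated noise CV is typically
recovered as a median per-site CV near 4.2%, not 5%; this is a property of
the estimator, not a calibration error. Linearity regresses per-level mean
abundance on spike amount with an intercept on linear axes (log-log as an
option), reporting $R^2$ as the squared Pearson correlation; sites seen at
fewer than three levels are skipped. Ratio accuracy averages replicate
abundances per level first and then forms reference/level ratios — the
alternative (ratio per replicate, then average) is not distinguishable from
the description being emulated, and level means are the more stable choice
at triplicate depth. Missing-value profiles rank sites by mean observed
abundance, split them into near-equal groups (G1 lowest), and report per
group the fraction of missing cells plus the complete/partial/single/none
site partition, which sums to 100%.

## Differential statistics

The test statistic is the SAM-style fudged t:
$d = (\bar{x}_A - \bar{x}_B)/(s_p\sqrt{1/n_A + 1/n_B} + s_0)$ with pooled
variance on $n_A + n_B - 2$ degrees of freedom and $s_0 = 0.1$ by default;
$s_0 = 0$ recovers the classical pooled t exactly. FDR is permutation
based: the null pools $|d|$ recomputed under distinct relabelings of the
samples — exhaustive when $\binom{n}{n_A}$ does not exceed the permutation
budget (default 250), otherwise that many distinct sampled assignments
under the mandatory seed. The observed assignment and its complement are
excluded from the null pool: they reproduce the real effects, and with
small designs (3 vs 3 has only 20 assignments) their inclusion places a
floor of roughly $2/20$ on every q-value, making any FDR threshold below
that unattainable regardless of effect size. The q-value is the mean
per-permutation count of null $|d|$ at or above the observed $|d|$ divided
by the observed count at or above it, clipped to $[0,1]$ and monotonized
along decreasing $|d|$; significance is strict ($q <$ threshold, default
0.01). Benjamini–Hochberg is available as an alternative through the motif
module's machinery but the SAM-style estimator is the default throughout.

Protein-normalized site abundances are $\log_2(\mathrm{site}) -
\log_2(\mathrm{protein})$ per run, with sites lacking protein
quantification passed through as plain $\log_2$ and flagged.

Motif analysis extracts 13-mer windows centered on the phosphosite,
underscore-padded beyond protein termini. Enrichment is a one-sided
Fisher's exact test per motif pattern (match/non-match × foreground/
background), BH-adjusted, enriched strictly below FDR 0.02. One-sided
testing against the universe of all quantified sites is the documented
choice where sidedness and background were ambiguous. The shipped motif
table covers the canonical basophilic, proline-directed and acidophilic
kinase classes in a small `"offset:RESIDUES"` grammar and is meant to be
edited or replaced.

## The synthetic-data generator

The generator defines the study conditions the package is validated under.
Proteins are uniform-random sequences (isoleucine excluded in favor of
leucine, the pair being isobaric) guaranteed one S/T/Y. Panels draw
tryptic-like peptides — cleavage after K/R, no proline rule, no missed
cleavages, length 7–25, K/R C-terminus — and assign true phospho
configurations with multiplicity counts defaulting to 139 mono-, 21 di- and
6 tri-phosphopeptides (166 entries), the composition of the spike-in
benchmark being emulated; sequences may recur across entries with
different configurations, as in that benchmark.

Dilution reports draw per-precursor base intensities from a lognormal
(meanlog $\ln 10^5$, sdlog 1), scale by the level's spike amount, and
multiply by lognormal noise with $\sigma = \sqrt{\ln(1 + CV^2)}$ so the
multiplicative CV equals the requested `noise_cv` (default 0.05). Dropout,
when enabled, retains an observation with probability
$\mathrm{plogis}(\mathrm{steepness} \cdot (\log_{10}(\mathrm{area}) -
\mathrm{midpoint}))$, concentrating missingness in the low-abundance
tertile as real DIA/DDA comparisons show. Isomer spectra contain the true
configuration's singly charged b/y ions at a chosen coverage with lognormal
intensities, optional uniform noise peaks, and optionally with every
discriminating ion removed to construct deliberately ambiguous spectra.
Two-group matrices are normal in log2 with per-site baselines
$\mathcal{N}(20, 2)$, within-group sd 0.25 by default and a planted
`effect` shift on a chosen number of sites. Every simulator is a pure
function of (parameters, seed) and returns its ground truth alongside the
data.

What the generator does *not* emulate: chromatographic peak shapes,
co-fragmentation interference, intensity-dependent mass error, shared-ion
ambiguity between co-eluting isomers, and realistic protein sequence
composition. Passing the recovery properties below therefore demonstrates
the internal consistency and calibration of the algorithms on clean,
well-specified inputs — not performance on instrument data.

## Problem sizes and numerical choices

The validation suite runs at deliberately modest scale: 60 proteins,
166-entry panels, 150-site mono-phospho designs, 500 localization spectra,
1000-site two-group matrices over 20 seeds. These sizes make every check
reproducible in well under a minute or two apiece while keeping Monte-Carlo
noise far smaller than the tolerances being asserted.

Degenerate inputs are handled explicitly: empty peak lists score 0 for
every configuration (binomial tail at zero matches is 1); a single
calibration point or identical iRT values are errors; sites observed once
are excluded from CV; sites missing the reference level are excluded from
ratios; a normalization call with no complete rows errors rather than
silently imputing. Ties are deterministic everywhere: fragment-intensity
ties break by ascending m/z, abundance-rank ties by site key, and
configuration-score ties collapse to equal probabilities.
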