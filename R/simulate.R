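# Synthetic-data generators: proteins, spike-in phosphopeptide panels,
# dilution-series precursor reports with noise and dropout, isomer spectra
# with known true sites, and two-group matrices with planted effects.
# Every generator is a pure function of (parameters, seed).

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so simulators are pure functions of their arguments.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Simulate protein sequences
#'
#' Random amino-acid sequences with uniform residue frequencies, each
#' guaranteed to contain at least one S/T/Y residue, with accessions
#' `SIM1..SIMn` (UniProt-style headers `sp|SIMi|SIMi_TEST` when written with
#' [write_fasta()]).
#'
#' @param n Number of proteins.
#' @param length_range Inclusive sequence-length range (default 80-400).
#' @param seed Integer seed (mandatory).
#' @return Named character vector (accession -> sequence).
#' @export
simulate_proteins <- function(n, length_range = c(80L, 400L), seed) {
  stopifnot(n >= 1L, length(length_range) == 2L,
            length_range[1] >= 7L, length_range[1] <= length_range[2])
  aa <- names(.AA_MONO)[names(.AA_MONO) != "I"]  # I/L isobaric; keep L only
  with_seed(seed, {
    rng <- seq(length_range[1], length_range[2])
    lens <- rng[sample.int(length(rng), n, replace = TRUE)]
    seqs <- vapply(lens, function(L) {
      repeat {
        s <- paste(sample(aa, L, replace = TRUE), collapse = "")
        if (grepl("[STY]", s)) return(s)
      }
    }, "")
    stats::setNames(seqs, paste0("SIM", seq_len(n)))
  })
}

# Tryptic-like digest: cleave after K/R (no proline rule, 0 missed
# cleavages). Returns data.frame(accession, start, sequence).
.digest_tryptic <- function(proteins, min_length = 7L, max_length = 25L) {
  out <- lapply(names(proteins), function(acc) {
    s <- proteins[[acc]]
    cut_after <- gregexpr("[KR]", s)[[1]]
    bounds <- c(0L, if (cut_after[1] == -1L) integer() else cut_after,
                nchar(s))
    bounds <- unique(bounds[bounds <= nchar(s)])
    starts <- utils::head(bounds, -1) + 1L
    ends <- bounds[-1]
    keep <- (ends - starts + 1L) >= min_length &
      (ends - starts + 1L) <= max_length
    if (!any(keep)) return(NULL)
    data.frame(accession = acc, start = starts[keep],
               sequence = substring(s, starts[keep], ends[keep]))
  })
  do.call(rbind, out)
}

#' Simulate a spike-in phosphopeptide panel
#'
#' Draws tryptic-like peptides (length 7-25, K/R C-terminus, cleavage after
#' K/R) from the proteins and assigns each panel entry a true phospho
#' configuration. Default multiplicity counts are 139 mono-, 21 di- and 6
#' tri-phosphopeptides (166 entries); peptide sequences may recur across
#' entries with different configurations, but (sequence, configuration)
#' pairs are unique.
#'
#' @param proteins Named character vector from [simulate_proteins()] or
#'   [read_fasta()].
#' @param counts Integer vector `c(mono, di, tri)` of entries per phospho
#'   multiplicity.
#' @param seed Integer seed (mandatory).
#' @param charge Precursor charge assigned to every panel entry (default 2).
#' @return Object of class `phospho_panel`: a `data.frame` with peptide_id,
#'   accession, start, sequence, n_phospho, sites (peptide-local,
#'   `"+"`-joined), modified_sequence, charge. Attribute `truth` records the
#'   generating seed and true configurations.
#' @export
simulate_panel <- function(proteins, counts = c(mono = 139, di = 21, tri = 6),
                           seed, charge = 2L) {
  stopifnot(length(counts) == 3L, all(counts >= 0L), sum(counts) >= 1L)
  peptides <- .digest_tryptic(proteins)
  if (!is.null(peptides))   # synthetic panel peptides keep a K/R C-terminus
    peptides <- peptides[grepl("[KR]$", peptides$sequence), , drop = FALSE]
  if (is.null(peptides) || nrow(peptides) == 0L)
    stop("no tryptic-like candidate peptides")
  peptides$n_sty <- vapply(peptides$sequence,
                           function(s) length(.sty_positions(s)), 0L,
                           USE.NAMES = FALSE)
  with_seed(seed, {
    rows <- list()
    seen <- new.env(parent = emptyenv())
    for (k in 3:1) {
      pool <- which(peptides$n_sty >= k)
      if (length(pool) == 0L && counts[k] > 0L)
        stop("no candidate peptide with >= ", k, " S/T/Y residues")
      made <- 0L
      guard <- 0L
      while (made < counts[k]) {
        guard <- guard + 1L
        if (guard > 200L * max(1L, counts[k]))
          stop("insufficient candidate peptides for multiplicity ", k)
        i <- pool[sample.int(length(pool), 1L)]
        sty <- .sty_positions(peptides$sequence[i])
        cfg <- sort(sty[sample.int(length(sty), k)])
        key <- paste(peptides$sequence[i], .config_label(cfg))
        if (!is.null(seen[[key]])) next
        seen[[key]] <- TRUE
        made <- made + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          accession = peptides$accession[i], start = peptides$start[i],
          sequence = peptides$sequence[i], n_phospho = k,
          sites = .config_label(cfg))
      }
    }
    panel <- do.call(rbind, rows)
    panel <- panel[order(panel$n_phospho, panel$sequence, panel$sites), ,
                   drop = FALSE]
    panel$peptide_id <- paste0("PAN", seq_len(nrow(panel)))
    panel$modified_sequence <- vapply(seq_len(nrow(panel)), function(i) {
      pos <- as.integer(strsplit(panel$sites[i], "+", fixed = TRUE)[[1]])
      format_modified_sequence(
        peptidoform(panel$sequence[i],
                    data.frame(position = pos, label = "ph")))
    }, "")
    panel$charge <- as.integer(charge)
    rownames(panel) <- NULL
    panel <- panel[c("peptide_id", "accession", "start", "sequence",
                     "n_phospho", "sites", "modified_sequence", "charge")]
    attr(panel, "truth") <- list(seed = seed, counts = counts,
                                 configurations = stats::setNames(
                                   panel$sites, panel$peptide_id))
    class(panel) <- c("phospho_panel", "data.frame")
    panel
  })
}

#' @export
print.phospho_panel <- function(x, ...) {
  cat("Phosphopeptide panel:", nrow(x), "entries (",
      sum(x$n_phospho == 1), "mono /", sum(x$n_phospho == 2), "di /",
      sum(x$n_phospho == 3), "tri ) on",
      length(unique(x$sequence)), "unique sequences\n")
  invisible(x)
}

#' Simulate a dilution-series precursor report
#'
#' Emits one precursor-report row per panel entry, dilution level and
#' replicate: area = base intensity x spike amount x multiplicative
#' lognormal noise with `sigma = sqrt(log(1 + cv^2))` so the expected
#' coefficient of variation equals `noise_cv`. Optional abundance-dependent
#' dropout retains each observation with probability
#' `plogis(steepness * (log10(area) - midpoint))`, concentrating missingness
#' in the lowest dilutions. Localization probabilities are emitted as 1 for
#' every true site.
#'
#' @param panel A [simulate_panel()] result.
#' @param design A [dilution_design()] (default: 2, 1, 0.5, 0.2, 0.1 units
#'   in triplicate).
#' @param noise_cv Multiplicative noise CV (default 0.05; 0 = noiseless).
#' @param dropout `NULL` (no dropout) or `list(midpoint=, steepness=)` on the
#'   log10-abundance scale.
#' @param seed Integer seed (mandatory).
#' @param base_meanlog,base_sdlog Lognormal parameters of per-precursor base
#'   intensities (defaults log(1e5) and 1).
#' @return List with `report` (precursor-report `data.frame` ready for
#'   [write_precursor_report()]) and `truth` (base abundances, expected
#'   areas, dropout events, seed).
#' @export
simulate_dilution_report <- function(panel, design = dilution_design(),
                                     noise_cv = 0.05, dropout = NULL,
                                     seed, base_meanlog = log(1e5),
                                     base_sdlog = 1) {
  stopifnot(noise_cv >= 0)
  with_seed(seed, {
    n <- nrow(panel)
    base <- stats::rlnorm(n, base_meanlog, base_sdlog)
    sigma <- sqrt(log(1 + noise_cv^2))
    irt <- stats::runif(n, 0, 100)
    runs <- design$runs
    grid <- expand.grid(entry = seq_len(n), run_i = seq_len(nrow(runs)))
    expected <- base[grid$entry] * runs$amount[grid$run_i]
    noise <- if (sigma > 0) stats::rlnorm(nrow(grid), 0, sigma) else 1
    area <- expected * noise
    kept <- if (is.null(dropout)) rep(TRUE, nrow(grid)) else
      stats::runif(nrow(grid)) <
        stats::plogis(dropout$steepness * (log10(area) - dropout$midpoint))
    probs <- vapply(seq_len(n), function(i) {
      pos <- as.integer(strsplit(panel$sites[i], "+", fixed = TRUE)[[1]])
      res <- strsplit(panel$sequence[i], "")[[1]][pos]
      paste(sprintf("%s%d: 1", res, pos), collapse = "; ")
    }, "")
    report <- data.frame(
      run = runs$run[grid$run_i],
      modified_sequence = panel$modified_sequence[grid$entry],
      charge = panel$charge[grid$entry],
      protein_group = panel$accession[grid$entry],
      area = area,
      rt = irt[grid$entry] + stats::rnorm(nrow(grid), 0, 0.1),
      site_probs = probs[grid$entry],
      mode = "libDIA")[kept, , drop = FALSE]
    rownames(report) <- NULL
    list(report = report,
         truth = list(seed = seed, noise_cv = noise_cv,
                      base_abundance = stats::setNames(base, panel$peptide_id),
                      design_amounts = design$amounts,
                      dropout = dropout,
                      n_dropped = sum(!kept)))
  })
}

#' Simulate a fragment spectrum for a known phospho configuration
#'
#' Theoretical singly charged b/y ions of the true configuration, sampled at
#' `coverage`, plus uniform random noise peaks; intensities lognormal. Ions
#' that discriminate the true configuration from any competing isomer of the
#' same multiplicity are flagged in the ground truth and can be excluded to
#' construct deliberately ambiguous spectra.
#'
#' @param sequence Stripped peptide sequence.
#' @param true_positions Integer vector of true phospho positions.
#' @param coverage Fraction of theoretical ions present (default 1).
#' @param n_noise Number of uniform noise peaks (default 0).
#' @param seed Integer seed (mandatory).
#' @param exclude_discriminating Drop every site-determining ion, leaving
#'   only evidence shared by all isomers (default `FALSE`).
#' @return List with `peaks` (`data.frame(mz, intensity)` sorted by m/z),
#'   and `truth` (true configuration, flagged discriminating ions, seed).
#' @export
simulate_isomer_spectrum <- function(sequence, true_positions, coverage = 1,
                                     n_noise = 0L, seed,
                                     exclude_discriminating = FALSE) {
  stopifnot(coverage >= 0, coverage <= 1)
  k <- length(true_positions)
  configs <- enumerate_isomers(sequence, k)
  ladder <- .config_ladder(sequence, true_positions)
  others <- Filter(function(cfg) !identical(sort(cfg), sort(true_positions)),
                   configs)
  disc <- rep(FALSE, nrow(ladder))
  for (cfg in others) {
    sd_ions <- site_determining_ions(sequence, true_positions, cfg)
    for (s in names(sd_ions))
      disc <- disc | (ladder$series == s & ladder$index %in% sd_ions[[s]])
  }
  with_seed(seed, {
    pool <- if (exclude_discriminating) which(!disc) else seq_len(nrow(ladder))
    n_keep <- round(coverage * length(pool))
    keep <- if (n_keep >= length(pool)) pool else
      sort(sample(pool, n_keep))
    peaks <- data.frame(mz = ladder$mz[keep],
                        intensity = stats::rlnorm(length(keep), log(1e4), 0.5))
    if (n_noise > 0L) {
      lim <- max(ladder$mz) + 100
      peaks <- rbind(peaks, data.frame(
        mz = stats::runif(n_noise, 100, lim),
        intensity = stats::rlnorm(n_noise, log(1e3), 0.5)))
    }
    peaks <- peaks[order(peaks$mz), , drop = FALSE]
    rownames(peaks) <- NULL
    list(peaks = peaks,
         truth = list(seed = seed, sequence = sequence,
                      true_positions = sort(true_positions),
                      discriminating = ladder[disc, c("series", "index")],
                      n_theoretical = nrow(ladder), n_present = length(keep)))
  })
}

#' Simulate a two-group log2 site matrix with planted effects
#'
#' Per-site baselines are normal around `baseline_mean`; within-group values
#' are normal with standard deviation `sd`; the first `n_changed` sites get a
#' `+effect` log2 shift in group A. Row keys are `"SIMi-S<i>"`-style
#' synthetic site keys; columns `A_r1..`, `B_r1..`.
#'
#' @param n_sites Number of sites.
#' @param n_per_group Samples per group (default 3).
#' @param n_changed Number of sites with a planted shift (default 0).
#' @param effect Planted shift in log2 units (default 2).
#' @param sd Within-group standard deviation in log2 units (default 0.25).
#' @param seed Integer seed (mandatory).
#' @param baseline_mean,baseline_sd Per-site baseline distribution
#'   (defaults 20 and 2, log2 scale).
#' @return List with `matrix` (log2 values), `labels` (group factor) and
#'   `truth` (changed site keys, effect, seed).
#' @export
simulate_two_group_matrix <- function(n_sites, n_per_group = 3L,
                                      n_changed = 0L, effect = 2,
                                      sd = 0.25, seed,
                                      baseline_mean = 20, baseline_sd = 2) {
  stopifnot(n_changed <= n_sites, n_per_group >= 2L)
  with_seed(seed, {
    mu <- stats::rnorm(n_sites, baseline_mean, baseline_sd)
    m <- matrix(stats::rnorm(n_sites * 2L * n_per_group, mean = mu, sd = sd),
                n_sites, 2L * n_per_group)
    if (n_changed > 0L)
      m[seq_len(n_changed), seq_len(n_per_group)] <-
        m[seq_len(n_changed), seq_len(n_per_group)] + effect
    rownames(m) <- sprintf("SIM%d-S%d", seq_len(n_sites), seq_len(n_sites))
    colnames(m) <- c(paste0("A_r", seq_len(n_per_group)),
                     paste0("B_r", seq_len(n_per_group)))
    labels <- factor(rep(c("A", "B"), each = n_per_group))
    list(matrix = m, labels = labels,
         truth = list(seed = seed, effect = effect, sd = sd,
                      changed = rownames(m)[seq_len(n_changed)]))
  })
}

#' Annotate precursors with DIA isolation windows
#'
#' Assigns each precursor m/z to 10-Th isolation windows with 1-Th overlap
#' spanning 500-1000 Th (descriptive metadata only).
#'
#' @param mz Numeric precursor m/z values.
#' @param window_width,overlap,mz_range Scheme parameters (defaults 10, 1,
#'   c(500, 1000)).
#' @return Integer window index (1-based), `NA` outside the scanned range.
#' @export
dia_window_index <- function(mz, window_width = 10, overlap = 1,
                             mz_range = c(500, 1000)) {
  step <- window_width - overlap
  idx <- floor((mz - mz_range[1]) / step) + 1L
  n_win <- ceiling((mz_range[2] - mz_range[1] - window_width) / step) + 1L
  idx[mz < mz_range[1] | mz > mz_range[2] | idx > n_win] <- NA_integer_
  as.integer(idx)
}
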