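# Differential phosphosite statistics: S0-moderated two-sample t-test with
# SAM-style permutation FDR, protein-level normalization, 13-mer motif
# windows and Fisher's-exact motif enrichment.

#' S0-moderated two-sample t statistic
#'
#' SAM-style fudge-factor statistic
#' `d = (meanA - meanB) / (s_pooled * sqrt(1/nA + 1/nB) + s0)` with pooled
#' variance on `nA + nB - 2` degrees of freedom. With `s0 = 0` this is the
#' classical pooled two-sample t statistic; a positive `s0` damps the
#' significance of low-variance small effects.
#'
#' @param a,b Numeric vectors of log2 abundances (>= 2 values each).
#' @param s0 Fudge factor added to the denominator (default 0.1).
#' @return The statistic (positive when `mean(a) > mean(b)`).
#' @export
s0_ttest <- function(a, b, s0 = 0.1) {
  stopifnot(s0 >= 0)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values")
  na <- length(a); nb <- length(b)
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
               (na + nb - 2))
  (mean(a) - mean(b)) / (sp * sqrt(1 / na + 1 / nb) + s0)
}

# Row-wise S0 statistic for a complete log2 matrix (no NA handling: callers
# subset complete rows first). Vectorized for the permutation loop.
.s0_tstat_rows <- function(m, idx_a, idx_b, s0) {
  na <- length(idx_a); nb <- length(idx_b)
  ma <- rowMeans(m[, idx_a, drop = FALSE])
  mb <- rowMeans(m[, idx_b, drop = FALSE])
  va <- rowSums((m[, idx_a, drop = FALSE] - ma)^2) / (na - 1)
  vb <- rowSums((m[, idx_b, drop = FALSE] - mb)^2) / (nb - 1)
  sp <- sqrt(((na - 1) * va + (nb - 1) * vb) / (na + nb - 2))
  (ma - mb) / (sp * sqrt(1 / na + 1 / nb) + s0)
}

#' Two-group differential test with permutation FDR
#'
#' Computes the observed S0 statistic per site, builds a null by recomputing
#' it under permutations of the group labels (exhaustive when the number of
#' distinct assignments does not exceed `n_permutations`, otherwise that many
#' distinct sampled assignments; the observed assignment and its complement
#' reproduce the real effects and are kept out of the null pool), and
#' estimates a SAM-style q-value per site:
#' the mean per-permutation count of null `|d|` at or above the site's
#' observed `|d|`, divided by the observed count at or above it, clipped to
#' `[0, 1]` and monotonized along decreasing `|d|`.
#'
#' @param x Log2 abundance matrix (sites x samples) or [site_matrix] holding
#'   log2 values. Sites with missing values or fewer than 2 values per group
#'   are skipped.
#' @param labels Factor/character of length `ncol(x)` with exactly two levels;
#'   the first level is group A.
#' @param s0 Fudge factor (default 0.1).
#' @param n_permutations Permutation budget (default 250).
#' @param seed Seed for permutation sampling; required when not exhaustive.
#' @param fdr_threshold Significance threshold on the q-value (default 0.01;
#'   strict inequality `q < threshold`).
#' @return Object of class `diffexp_result`: a `data.frame` with site, group
#'   means, difference (A - B, log2), statistic, q_value, significant;
#'   attributes `n_permutations_used` and `exhaustive`.
#' @export
permutation_fdr <- function(x, labels, s0 = 0.1, n_permutations = 250L,
                            seed = NULL, fdr_threshold = 0.01) {
  m <- .abundance_of(x)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L)
    stop("labels must define exactly two groups")
  stopifnot(length(labels) == ncol(m))
  idx_a <- which(labels == levels(labels)[1])
  idx_b <- which(labels == levels(labels)[2])
  if (length(idx_a) < 2L || length(idx_b) < 2L)
    stop("each group needs at least 2 samples")
  ok <- stats::complete.cases(m)
  m <- m[ok, , drop = FALSE]
  if (nrow(m) == 0L) stop("no complete rows to test")

  n <- ncol(m); na <- length(idx_a)
  total <- choose(n, na)
  exhaustive <- total <= n_permutations
  # The observed assignment and (when the design is |d|-symmetric) its
  # complement reproduce the real effects and are excluded from the null.
  obs_key <- paste(sort(idx_a), collapse = ",")
  mirror_key <- paste(sort(idx_b), collapse = ",")
  assignments <- if (exhaustive) {
    utils::combn(n, na, simplify = FALSE)
  } else {
    if (is.null(seed)) stop("seed required for sampled permutations")
    with_seed(seed, {
      seen <- new.env(parent = emptyenv())
      out <- list()
      budget <- min(n_permutations, total - 1L - (na == n - na))
      while (length(out) < budget) {
        cand <- sort(sample.int(n, na))
        key <- paste(cand, collapse = ",")
        if (key %in% c(obs_key, mirror_key)) next
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          out[[length(out) + 1L]] <- cand
        }
      }
      out
    })
  }
  n_assignments <- length(assignments)
  null_set <- Filter(function(ia)
    !(paste(ia, collapse = ",") %in% c(obs_key, mirror_key)), assignments)

  d_obs <- .s0_tstat_rows(m, idx_a, idx_b, s0)
  abs_obs <- abs(d_obs)
  null_pool <- unlist(lapply(null_set, function(ia)
    abs(.s0_tstat_rows(m, ia, setdiff(seq_len(n), ia), s0))),
    use.names = FALSE)
  null_sorted <- sort(null_pool)
  obs_sorted <- sort(abs_obs)
  n_perm <- length(null_set)
  # counts of values >= t, inclusive (left.open counts strictly below t)
  null_ge <- length(null_sorted) -
    findInterval(abs_obs, null_sorted, left.open = TRUE)
  obs_ge <- length(obs_sorted) -
    findInterval(abs_obs, obs_sorted, left.open = TRUE)
  q_raw <- pmin(1, (null_ge / n_perm) / obs_ge)
  ord <- order(abs_obs, decreasing = TRUE)
  q <- numeric(length(q_raw))
  q[ord] <- cummax(q_raw[ord])   # monotone non-decreasing as |d| falls

  res <- data.frame(
    site = rownames(m),
    mean_a = rowMeans(m[, idx_a, drop = FALSE]),
    mean_b = rowMeans(m[, idx_b, drop = FALSE]),
    statistic = d_obs, q_value = q,
    significant = q < fdr_threshold)
  res$difference <- res$mean_a - res$mean_b
  rownames(res) <- NULL
  structure(res, class = c("diffexp_result", "data.frame"),
            n_assignments = n_assignments, n_permutations_used = n_perm,
            exhaustive = exhaustive, s0 = s0, fdr_threshold = fdr_threshold)
}

#' @export
print.diffexp_result <- function(x, ...) {
  cat("Differential test:", nrow(x), "site(s),", sum(x$significant),
      "significant at q <", attr(x, "fdr_threshold"),
      if (attr(x, "exhaustive")) "(exhaustive permutations)" else
        sprintf("(%d sampled permutations)", attr(x, "n_permutations_used")),
      "\n")
  NextMethod()
}

#' Normalize site abundances to protein expression
#'
#' Per run, the adjusted value is `log2(site) - log2(protein)` for the site's
#' protein (accession taken from the `"ACC-S123"` site key). Sites whose
#' protein is not quantified in a run are passed through unadjusted and
#' flagged.
#'
#' @param sites A [site_matrix] or abundance matrix (linear scale) with
#'   `"ACC-S123"` row keys.
#' @param proteins Protein abundance matrix (linear scale) from
#'   [rollup_proteins()], runs as columns.
#' @return List with `adjusted` (log2 matrix) and `unadjusted` (logical
#'   matrix flagging cells passed through as plain log2 site abundance).
#' @export
normalize_site_to_protein <- function(sites, proteins) {
  m <- .abundance_of(sites)
  acc <- sub("-[STY][0-9]+$", "", rownames(m))
  adj <- log2(m)
  flag <- matrix(FALSE, nrow(m), ncol(m), dimnames = dimnames(m))
  hit <- match(acc, rownames(proteins))
  run_hit <- match(colnames(m), colnames(proteins))
  for (i in seq_len(nrow(m))) {
    if (is.na(hit[i])) { flag[i, !is.na(m[i, ])] <- TRUE; next }
    p <- proteins[hit[i], run_hit]
    usable <- !is.na(p) & p > 0 & !is.na(m[i, ])
    adj[i, usable] <- log2(m[i, usable]) - log2(p[usable])
    flag[i, !usable & !is.na(m[i, ])] <- TRUE
  }
  list(adjusted = adj, unadjusted = flag)
}

#' Extract 13-mer motif windows around phosphosites
#'
#' For each site, the window is `protein[pos-6 .. pos+6]` with `"_"` padding
#' beyond the protein termini, so the phosphorylated residue sits at
#' position 7 of a 13-character string.
#'
#' @param sites `data.frame` with columns `accession` and `position`, or a
#'   character vector of `"ACC-S123"` site keys.
#' @param proteins Named character vector of protein sequences.
#' @param width Window width (odd; default 13).
#' @return `data.frame` with site_key, window, center_residue.
#' @export
extract_motif_windows <- function(sites, proteins, width = 13L) {
  stopifnot(width %% 2L == 1L)
  half <- (width - 1L) %/% 2L
  if (is.character(sites)) {
    acc <- sub("-[STY][0-9]+$", "", sites)
    pos <- as.integer(sub("^.*-[STY]", "", sites))
    sites <- data.frame(accession = acc, position = pos)
  }
  out <- lapply(seq_len(nrow(sites)), function(i) {
    acc <- sites$accession[i]; pos <- sites$position[i]
    seqn <- proteins[[acc]]
    if (is.null(seqn)) stop("accession ", acc, " not in protein sequences")
    if (pos < 1L || pos > nchar(seqn))
      stop("site position ", pos, " outside protein ", acc)
    center <- substr(seqn, pos, pos)
    if (!center %in% c("S", "T", "Y"))
      stop("site ", acc, "-", pos, " is ", center, ", not S/T/Y")
    lo <- max(1L, pos - half); hi <- min(nchar(seqn), pos + half)
    window <- paste0(strrep("_", lo - (pos - half)),
                     substr(seqn, lo, hi),
                     strrep("_", (pos + half) - hi))
    data.frame(site_key = paste0(acc, "-", center, pos),
               window = window, center_residue = center)
  })
  do.call(rbind, out)
}

#' Canonical kinase motif patterns
#'
#' A small editable table of linear kinase motifs over 13-mer windows. The
#' pattern grammar is `"offset:RESIDUES"` pairs joined by `";"`, offsets
#' relative to the central phosphorylated residue (position 0); `0:ST`
#' constrains the center itself.
#'
#' @return `data.frame` with columns `motif`, `class`, `pattern`.
#' @export
kinase_motifs <- function() {
  data.frame(
    motif = c("Proline-directed (ERK/CDK)", "CDK full (K at +3)",
              "PKA (R at -3)", "PKA/PKC (R at -3, R at -2)",
              "AKT (RxRxxS/T)", "CAMK2 (R at -3, hydrophobic +1)",
              "CK2 acidophilic (D/E at +3)", "CK1 (D/E at -3)",
              "ATM/ATR (Q at +1)", "GSK3 (S/T at +4)"),
    class = c("proline-directed", "proline-directed", "basophilic",
              "basophilic", "basophilic", "basophilic", "acidophilic",
              "acidophilic", "other", "other"),
    pattern = c("0:ST;1:P", "0:ST;1:P;3:KR", "0:ST;-3:R", "0:ST;-3:R;-2:R",
                "0:ST;-5:R;-3:R", "0:ST;-3:R;1:LIVFM", "0:ST;3:DE",
                "0:ST;-3:DE", "0:ST;1:Q", "0:ST;4:ST"))
}

.parse_motif_pattern <- function(pattern) {
  parts <- strsplit(pattern, ";", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^(-?[0-9]+):([A-Z]+)$", parts))
  if (any(vapply(m, length, 0L) != 3L))
    stop("malformed motif pattern: ", pattern)
  data.frame(offset = as.integer(vapply(m, `[`, "", 2L)),
             residues = vapply(m, `[`, "", 3L))
}

#' Match 13-mer windows against a motif pattern
#'
#' @param windows Character vector of fixed-width windows (center at the
#'   middle position).
#' @param pattern Pattern string in the `"offset:RESIDUES"` grammar.
#' @return Logical vector.
#' @export
match_motif <- function(windows, pattern) {
  .match_motif_windows(windows, pattern)
}

#' Fisher's-exact motif enrichment
#'
#' Per motif pattern, a 2x2 table of match/non-match in foreground vs
#' background windows is tested one-sided (enrichment of the motif in the
#' foreground) with Fisher's exact test; p-values are Benjamini-Hochberg
#' adjusted and a motif is called enriched when its FDR is strictly below
#' the threshold (default 0.02).
#'
#' @param foreground,background Character vectors of 13-mer windows; the
#'   background should contain the candidate universe.
#' @param motifs Motif table as from [kinase_motifs()] (columns `motif`,
#'   `pattern`).
#' @param fdr_threshold Enrichment FDR threshold (default 0.02).
#' @return `data.frame`: motif, fg_match, fg_total, bg_match, bg_total,
#'   odds_ratio, p_value, fdr, enriched.
#' @export
fisher_motif_enrichment <- function(foreground, background,
                                    motifs = kinase_motifs(),
                                    fdr_threshold = 0.02) {
  if (length(foreground) == 0L || length(background) == 0L)
    stop("empty foreground or background window set")
  rows <- lapply(seq_len(nrow(motifs)), function(i) {
    fg <- .match_motif_windows(foreground, motifs$pattern[i])
    bg <- .match_motif_windows(background, motifs$pattern[i])
    tab <- matrix(c(sum(fg), sum(!fg), sum(bg), sum(!bg)), 2,
                  dimnames = list(c("match", "nomatch"), c("fg", "bg")))
    ft <- stats::fisher.test(tab, alternative = "greater")
    data.frame(motif = motifs$motif[i], fg_match = sum(fg),
               fg_total = length(fg), bg_match = sum(bg),
               bg_total = length(bg),
               odds_ratio = unname(ft$estimate), p_value = ft$p.value)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out$enriched <- out$fdr < fdr_threshold
  out[order(out$p_value), ]
}

# Position-wise motif matching on fixed-width windows.
.match_motif_windows <- function(windows, pattern) {
  if (length(windows) == 0L) return(logical(0))
  width <- nchar(windows[1])
  center <- (width + 1L) %/% 2L
  spec <- .parse_motif_pattern(pattern)
  out <- rep(TRUE, length(windows))
  for (j in seq_len(nrow(spec))) {
    p <- center + spec$offset[j]
    if (p < 1L || p > width) return(rep(FALSE, length(windows)))
    allowed <- strsplit(spec$residues[j], "")[[1]]
    out <- out & substr(windows, p, p) %in% allowed
  }
  out
}
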