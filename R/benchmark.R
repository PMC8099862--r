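# Spike-in benchmarking of a site abundance matrix: CV profiles, dilution
# linearity, ratio accuracy against the design, and missing-value profiles.

#' Define a spike-in dilution design
#'
#' Levels are listed from the largest spike amount down; the reference level
#' for expected ratios defaults to the largest amount, so the default design
#' (2, 1, 0.5, 0.2, 0.1 units in triplicate) expects ratios 1, 2, 4, 10, 20.
#'
#' @param amounts Strictly decreasing positive spike amounts.
#' @param replicates Replicates per level (default 3).
#' @param labels Level labels; default `"L<amount>"`.
#' @param reference Index of the reference level (default 1, the largest).
#' @return Object of class `dilution_design` with a `runs` table mapping run
#'   ids (`"<label>_r<rep>"`) to levels.
#' @export
dilution_design <- function(amounts = c(2, 1, 0.5, 0.2, 0.1), replicates = 3L,
                            labels = NULL, reference = 1L) {
  stopifnot(length(amounts) >= 1L, all(amounts > 0))
  if (is.unsorted(rev(amounts), strictly = TRUE))
    stop("amounts must be strictly decreasing")
  if (is.null(labels)) labels <- paste0("L", amounts)
  stopifnot(length(labels) == length(amounts), replicates >= 1L)
  runs <- expand.grid(rep = seq_len(replicates), level = seq_along(amounts))
  runs <- data.frame(run = paste0(labels[runs$level], "_r", runs$rep),
                     level = runs$level, label = labels[runs$level],
                     amount = amounts[runs$level])
  structure(list(amounts = amounts, labels = labels,
                 replicates = as.integer(replicates),
                 reference = as.integer(reference), runs = runs),
            class = "dilution_design")
}

#' @export
print.dilution_design <- function(x, ...) {
  cat("Dilution design:", length(x$amounts), "levels x", x$replicates,
      "replicates\n  amounts:", paste(x$amounts, collapse = ", "),
      "\n  expected ratios vs reference:",
      paste(expected_ratios(x), collapse = ", "), "\n")
  invisible(x)
}

#' Expected fold ratios of a dilution design
#'
#' Reference amount divided by each level amount, derived from the design
#' alone.
#'
#' @param design A [dilution_design].
#' @return Named numeric vector, one ratio per level.
#' @export
expected_ratios <- function(design) {
  stats::setNames(design$amounts[design$reference] / design$amounts,
                  design$labels)
}

.design_columns <- function(design, run_ids) {
  lapply(split(design$runs$run, design$runs$level),
         function(r) intersect(r, run_ids))
}

#' Per-site coefficient of variation
#'
#' CV% = 100 * sample standard deviation (n-1 denominator) / mean, computed
#' on raw abundances over the given replicate columns (or in log2 space with
#' `log_space = TRUE`). Sites with fewer than two observed values in a group
#' are excluded from that group.
#'
#' @param x A [site_matrix] or abundance matrix.
#' @param groups Named list of replicate column sets; default: all columns as
#'   one group.
#' @param log_space Compute CV on log2 abundances instead of raw.
#' @return List with `per_site` (data.frame of site, group, cv_pct) and
#'   `median_cv` (named numeric, median CV% per group).
#' @export
cv_profile <- function(x, groups = NULL, log_space = FALSE) {
  m <- .abundance_of(x)
  if (is.null(groups)) groups <- list(all = colnames(m))
  if (log_space) m <- log2(m)
  per <- do.call(rbind, lapply(names(groups), function(g) {
    sub <- m[, groups[[g]], drop = FALSE]
    n_obs <- rowSums(!is.na(sub))
    keep <- n_obs >= 2L
    if (!any(keep)) return(NULL)
    mu <- rowMeans(sub[keep, , drop = FALSE], na.rm = TRUE)
    sdv <- apply(sub[keep, , drop = FALSE], 1, stats::sd, na.rm = TRUE)
    data.frame(site = rownames(m)[keep], group = g, cv_pct = 100 * sdv / mu)
  }))
  med <- if (is.null(per)) stats::setNames(numeric(0), character(0)) else
    vapply(split(per$cv_pct, per$group), stats::median, 0)[names(groups)]
  list(per_site = per, median_cv = med)
}

#' Per-site dilution linearity
#'
#' For each site, replicate abundances are averaged per level (observed
#' values only) and regressed on the spike amount by least squares, on linear
#' axes by default or log-log with `log_log = TRUE`. Sites quantified at
#' fewer than three levels are skipped with a reason.
#'
#' @param x A [site_matrix] or abundance matrix whose columns follow the
#'   design's run ids.
#' @param design A [dilution_design].
#' @param log_log Fit log2(abundance) on log2(amount).
#' @return `data.frame` with site, slope, intercept, r_squared, n_levels;
#'   attribute `skipped` lists excluded sites.
#' @export
dilution_linearity <- function(x, design, log_log = FALSE) {
  m <- .abundance_of(x)
  cols <- .design_columns(design, colnames(m))
  level_means <- sapply(seq_along(design$amounts), function(l) {
    sub <- m[, cols[[as.character(l)]], drop = FALSE]
    rowMeans(sub, na.rm = TRUE)
  })
  if (is.null(dim(level_means)))
    level_means <- matrix(level_means, nrow = nrow(m))
  level_means[is.nan(level_means)] <- NA
  amounts <- design$amounts
  fit_one <- function(y) {
    ok <- !is.na(y)
    if (sum(ok) < 3L) return(NULL)
    xx <- amounts[ok]; yy <- y[ok]
    if (log_log) { xx <- log2(xx); yy <- log2(yy) }
    f <- stats::lm(yy ~ xx)
    r2 <- if (stats::var(yy) == 0) 0 else stats::cor(xx, yy)^2
    c(slope = unname(stats::coef(f)[2]), intercept = unname(stats::coef(f)[1]),
      r_squared = r2, n_levels = sum(ok))
  }
  fits <- apply(level_means, 1, fit_one, simplify = FALSE)
  ok <- !vapply(fits, is.null, TRUE)
  out <- if (any(ok))
    data.frame(site = rownames(m)[ok], do.call(rbind, fits[ok])) else
    data.frame(site = character(), slope = numeric(), intercept = numeric(),
               r_squared = numeric(), n_levels = integer())
  rownames(out) <- NULL
  attr(out, "skipped") <- data.frame(
    site = rownames(m)[!ok],
    reason = if (any(!ok)) "quantified at fewer than 3 levels" else character())
  out
}

#' Measured vs expected fold ratios per dilution level
#'
#' Per site, replicate abundances are averaged per level; the measured ratio
#' at each level is the reference-level mean divided by the level mean. The
#' per-level median over sites is reported next to the design's expected
#' ratio. Sites lacking the reference level are excluded; a site missing at
#' a level is excluded from that level's median only.
#'
#' @inheritParams dilution_linearity
#' @return List with `per_site` (long data.frame: site, label, ratio,
#'   expected) and `medians` (data.frame: label, amount, expected,
#'   median_ratio, n_sites).
#' @export
ratio_accuracy <- function(x, design) {
  m <- .abundance_of(x)
  cols <- .design_columns(design, colnames(m))
  level_means <- sapply(seq_along(design$amounts), function(l)
    rowMeans(m[, cols[[as.character(l)]], drop = FALSE], na.rm = TRUE))
  if (is.null(dim(level_means)))
    level_means <- matrix(level_means, nrow = nrow(m))
  level_means[is.nan(level_means)] <- NA
  ref <- level_means[, design$reference]
  expected <- expected_ratios(design)
  per <- do.call(rbind, lapply(seq_along(design$amounts), function(l) {
    ok <- !is.na(ref) & !is.na(level_means[, l]) & level_means[, l] > 0
    if (!any(ok)) return(NULL)
    data.frame(site = rownames(m)[ok], label = design$labels[l],
               ratio = ref[ok] / level_means[ok, l],
               expected = unname(expected[l]))
  }))
  medians <- data.frame(
    label = design$labels, amount = design$amounts,
    expected = unname(expected),
    median_ratio = vapply(design$labels, function(lb) {
      r <- per$ratio[per$label == lb]
      if (length(r) == 0L) NA_real_ else stats::median(r)
    }, 0),
    n_sites = vapply(design$labels, function(lb)
      sum(per$label == lb), 0L))
  rownames(medians) <- NULL
  list(per_site = per, medians = medians)
}

#' Missing-value profile by abundance rank
#'
#' Sites are ranked by mean abundance over observed values and split into
#' `n_groups` nearly equal groups, G1 the least abundant. Per group the
#' fraction of missing cells and the site-level completeness partition
#' (observed in all / some / exactly one / no replicate) are reported; the
#' four completeness percentages sum to 100 within each group.
#'
#' @param x A [site_matrix] or abundance matrix.
#' @param n_groups Number of abundance-rank groups (default 3, tertiles).
#' @param replicates Columns to profile (default all).
#' @return `data.frame`: group, n_sites, pct_missing_cells, pct_complete,
#'   pct_partial, pct_single, pct_none.
#' @export
missing_value_profile <- function(x, n_groups = 3L, replicates = NULL) {
  m <- .abundance_of(x)
  if (!is.null(replicates)) m <- m[, replicates, drop = FALSE]
  if (ncol(m) < 2L) stop("profile needs >= 2 replicate columns")
  mu <- rowMeans(m, na.rm = TRUE)
  mu[is.nan(mu)] <- -Inf     # never-observed sites rank lowest
  ord <- order(mu, rownames(m))   # ties broken by stable site-key order
  grp_sizes <- rep(nrow(m) %/% n_groups, n_groups)
  extra <- nrow(m) %% n_groups
  if (extra > 0) grp_sizes[seq_len(extra)] <- grp_sizes[seq_len(extra)] + 1L
  grp <- integer(nrow(m))
  grp[ord] <- rep(seq_len(n_groups), grp_sizes)
  n_obs <- rowSums(!is.na(m))
  do.call(rbind, lapply(seq_len(n_groups), function(g) {
    sel <- grp == g
    no <- n_obs[sel]
    data.frame(group = paste0("G", g), n_sites = sum(sel),
               pct_missing_cells = 100 * sum(is.na(m[sel, , drop = FALSE])) /
                 (sum(sel) * ncol(m)),
               pct_complete = 100 * mean(no == ncol(m)),
               pct_partial = 100 * mean(no > 1L & no < ncol(m)),
               pct_single = 100 * mean(no == 1L),
               pct_none = 100 * mean(no == 0L))
  }))
}

#' Full benchmark report for a dilution series
#'
#' Bundles [cv_profile()] (per level), [dilution_linearity()],
#' [ratio_accuracy()] and [missing_value_profile()] for a site matrix
#' measured under a dilution design.
#'
#' @inheritParams dilution_linearity
#' @return Object of class `benchmark_report`.
#' @export
benchmark_report <- function(x, design) {
  m <- .abundance_of(x)
  cols <- .design_columns(design, colnames(m))
  names(cols) <- design$labels
  structure(list(
    cv = cv_profile(x, groups = cols),
    linearity = dilution_linearity(x, design),
    ratios = ratio_accuracy(x, design),
    missingness = missing_value_profile(x),
    design = design), class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("Dilution-series benchmark\n")
  cat("  median CV% per level:\n")
  print(round(x$cv$median_cv, 2))
  cat("  median measured vs expected ratios:\n")
  print(x$ratios$medians[c("label", "expected", "median_ratio", "n_sites")],
        row.names = FALSE)
  med_r2 <- stats::median(x$linearity$r_squared)
  cat("  per-site linearity: median R^2 =", format(med_r2, digits = 4),
      "over", nrow(x$linearity), "site(s)\n")
  invisible(x)
}
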