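# Hybrid DDA+DIA spectral-library assembly: fragment filtering, PSM QC,
# segmented iRT calibration, archive merging, and composition summaries.

#' Construct a spectral-library entry
#'
#' One annotated fragment spectrum for a precursor: peptidoform, charge,
#' normalized retention time (iRT), relative-intensity fragment table,
#' provenance and identification score.
#'
#' @param peptidoform A [peptidoform] or modified-sequence string.
#' @param charge Precursor charge.
#' @param irt Normalized retention time (dimensionless).
#' @param fragments `data.frame` with columns `series`, `index`, `charge`,
#'   `neutral_loss`, `mz`, `n_residues`, `rel_intensity`.
#' @param source `"DDA"`, `"DIA"` or `"both"`.
#' @param score Identification score (higher is better).
#' @param proteins Protein accession string (`;`-separated group allowed).
#' @return Object of class `library_entry`. Fragments are sorted by
#'   descending relative intensity and scaled so the base peak is 1.
#' @export
library_entry <- function(peptidoform, charge, irt, fragments,
                          source = c("DDA", "DIA", "both"),
                          score = NA_real_, proteins = NA_character_) {
  pf <- .as_peptidoform(peptidoform)
  source <- match.arg(source)
  fragments <- as.data.frame(fragments)
  needed <- c("series", "index", "charge", "neutral_loss", "mz",
              "n_residues", "rel_intensity")
  missing_cols <- setdiff(needed, names(fragments))
  if (length(missing_cols) > 0L)
    stop("fragment table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(fragments) > 0L) {
    fragments <- fragments[order(-fragments$rel_intensity, fragments$mz), ,
                           drop = FALSE]
    fragments$rel_intensity <- fragments$rel_intensity /
      max(fragments$rel_intensity)
    rownames(fragments) <- NULL
  }
  structure(list(peptidoform = pf, charge = as.integer(charge), irt = irt,
                 fragments = fragments, source = source, score = score,
                 proteins = proteins),
            class = "library_entry")
}

.entry_key <- function(entry) {
  paste0(format_modified_sequence(entry$peptidoform), "/", entry$charge)
}

#' Filter library fragments by the standard quality rules
#'
#' Drops fragments outside the 300–1800 m/z range, below 5% relative
#' intensity, or spanning fewer than three residues; keeps at most the 15 most
#' intense survivors (ties broken by ascending m/z). Neutral-loss fragments
#' are retained. Surviving intensities are rescaled to base peak 1, which
#' makes the filter idempotent.
#'
#' @param entry A [library_entry].
#' @param min_mz,max_mz Fragment m/z window (default 300–1800, inclusive).
#' @param min_rel_intensity Minimum relative intensity (default 0.05).
#' @param min_residues Minimum residues per fragment (default 3).
#' @param max_fragments Fragments retained per precursor (default 15).
#' @return The filtered [library_entry]; warns when no fragment survives.
#' @export
filter_fragments <- function(entry, min_mz = 300, max_mz = 1800,
                             min_rel_intensity = 0.05, min_residues = 3L,
                             max_fragments = 15L) {
  fr <- entry$fragments
  keep <- fr$mz >= min_mz & fr$mz <= max_mz &
    fr$rel_intensity >= min_rel_intensity & fr$n_residues >= min_residues
  fr <- fr[keep, , drop = FALSE]
  fr <- fr[order(-fr$rel_intensity, fr$mz), , drop = FALSE]
  fr <- utils::head(fr, max_fragments)
  if (nrow(fr) == 0L)
    warning("no fragment survives filtering for ", .entry_key(entry))
  else
    fr$rel_intensity <- fr$rel_intensity / max(fr$rel_intensity)
  rownames(fr) <- NULL
  entry$fragments <- fr
  entry
}

#' Quality-filter peptide-spectrum matches
#'
#' Retains records meeting all four inclusive thresholds: identification
#' score >= 40, delta score >= 8, intensity >= 100 and peptide length >= 7.
#' Records with missing fields are rejected and the reasons reported in the
#' `rejected` attribute.
#'
#' @param records `data.frame` with columns `score`, `delta_score`,
#'   `intensity` and `sequence` (stripped).
#' @param min_score,min_delta,min_intensity,min_length Thresholds.
#' @return Filtered `data.frame`; attribute `rejected` is a `data.frame` of
#'   dropped row indices and reasons.
#' @export
qc_filter_psms <- function(records, min_score = 40, min_delta = 8,
                           min_intensity = 100, min_length = 7L) {
  records <- as.data.frame(records)
  needed <- c("score", "delta_score", "intensity", "sequence")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0L)
    stop("PSM table lacks column(s): ", paste(missing_cols, collapse = ", "))
  reason <- character(nrow(records))
  bad_field <- is.na(records$score) | is.na(records$delta_score) |
    is.na(records$intensity) | is.na(records$sequence)
  reason[bad_field] <- "missing field"
  ok <- !bad_field
  fail <- function(cond, why) {
    hit <- ok & cond
    reason[hit] <<- why
    ok <<- ok & !cond
  }
  fail(records$score < min_score, "score below threshold")
  fail(records$delta_score < min_delta, "delta score below threshold")
  fail(records$intensity < min_intensity, "intensity below threshold")
  fail(nchar(records$sequence) < min_length, "peptide too short")
  out <- records[ok, , drop = FALSE]
  attr(out, "rejected") <- data.frame(row = which(!ok), reason = reason[!ok])
  out
}

#' Fit a segmented iRT calibration
#'
#' Least-squares regression of measured retention time on library iRT, fit
#' per segment. Segment knots are placed at iRT quantiles; the default single
#' segment is ordinary least squares. The returned object predicts in both
#' directions.
#'
#' @param irt Library iRT values.
#' @param rt Measured retention times (same length).
#' @param n_segments Number of contiguous segments (default 1).
#' @return Object of class `irt_calibration`: per-segment boundaries, slopes,
#'   intercepts and the overall R-squared.
#' @export
fit_irt_calibration <- function(irt, rt, n_segments = 1L) {
  stopifnot(length(irt) == length(rt))
  ok <- !is.na(irt) & !is.na(rt)
  irt <- irt[ok]; rt <- rt[ok]
  if (length(irt) < 2L) stop("need at least 2 calibration points")
  if (length(unique(irt)) < 2L) stop("degenerate calibration: identical iRT values")
  if (n_segments < 1L) stop("n_segments must be >= 1")
  breaks <- stats::quantile(irt, probs = seq(0, 1, length.out = n_segments + 1L),
                            names = FALSE)
  breaks[1] <- -Inf; breaks[length(breaks)] <- Inf
  seg <- cut(irt, breaks, labels = FALSE, include.lowest = TRUE)
  tab <- tabulate(seg, n_segments)
  if (n_segments > 1L && any(tab < 3L))
    stop("each segment needs >= 3 points; got ", paste(tab, collapse = ", "))
  fits <- lapply(seq_len(n_segments), function(s) {
    stats::lm(rt ~ irt, data = data.frame(irt = irt[seg == s], rt = rt[seg == s]))
  })
  pred <- unlist(lapply(seq_len(n_segments), function(s)
    stats::predict(fits[[s]])), use.names = FALSE)
  fitted_all <- numeric(length(irt))
  fitted_all[order(seg)] <- pred
  ss_res <- sum((rt - fitted_all)^2)
  ss_tot <- sum((rt - mean(rt))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(list(breaks = breaks,
                 slope = vapply(fits, function(f) unname(stats::coef(f)[2]), 0),
                 intercept = vapply(fits, function(f) unname(stats::coef(f)[1]), 0),
                 r_squared = r2, n_segments = n_segments),
            class = "irt_calibration")
}

#' Predict measured RT from iRT (or back) with a fitted calibration
#'
#' @param object An `irt_calibration`.
#' @param irt iRT values to map to measured RT.
#' @param invert When `TRUE`, `irt` is interpreted as measured RT and mapped
#'   back to the iRT scale (per-segment inverse; segments chosen by predicted
#'   range).
#' @param ... Unused.
#' @return Numeric vector.
#' @export
predict.irt_calibration <- function(object, irt, invert = FALSE, ...) {
  if (!invert) {
    seg <- cut(irt, object$breaks, labels = FALSE, include.lowest = TRUE)
    object$intercept[seg] + object$slope[seg] * irt
  } else {
    rt_breaks <- object$intercept + object$slope *
      c(object$breaks[-c(1, length(object$breaks))], Inf)
    rt_breaks <- c(-Inf, utils::head(rt_breaks, -1), Inf)
    seg <- cut(irt, rt_breaks, labels = FALSE, include.lowest = TRUE)
    (irt - object$intercept[seg]) / object$slope[seg]
  }
}

#' @export
print.irt_calibration <- function(x, ...) {
  cat("iRT calibration:", x$n_segments, "segment(s), R^2 =",
      format(x$r_squared, digits = 6), "\n")
  invisible(x)
}

#' Merge DDA and DIA archives into a hybrid spectral library
#'
#' Union keyed by (modified sequence, charge). When a precursor occurs in
#' both archives, the higher-scoring spectrum is kept and the entry's source
#' is marked `"both"`. Provenance counts (DDA-only, DIA-only, shared) are
#' recorded.
#'
#' @param dda_entries,dia_entries Lists of [library_entry] objects.
#' @return Object of class `spectral_library`: `entries` (named list keyed by
#'   `"modseq/charge"`) and `counts`.
#' @export
merge_hybrid <- function(dda_entries, dia_entries) {
  dda <- stats::setNames(dda_entries, vapply(dda_entries, .entry_key, ""))
  dia <- stats::setNames(dia_entries, vapply(dia_entries, .entry_key, ""))
  shared <- intersect(names(dda), names(dia))
  entries <- dda
  for (k in names(dia)) {
    if (k %in% shared) {
      sa <- dda[[k]]$score; sb <- dia[[k]]$score
      best <- if (!is.na(sb) && (is.na(sa) || sb > sa)) dia[[k]] else dda[[k]]
      best$source <- "both"
      entries[[k]] <- best
    } else {
      entries[[k]] <- dia[[k]]
    }
  }
  structure(list(entries = entries,
                 counts = c(dda_only = length(dda) - length(shared),
                            dia_only = length(dia) - length(shared),
                            shared = length(shared))),
            class = "spectral_library")
}

#' @export
print.spectral_library <- function(x, ...) {
  cat("Hybrid spectral library:", length(x$entries), "precursor(s)\n")
  cat("  DDA-only", x$counts["dda_only"], "| DIA-only", x$counts["dia_only"],
      "| shared", x$counts["shared"], "\n")
  invisible(x)
}

#' Summarize spectral-library composition
#'
#' Counts precursors, modified peptides, phosphosites (as distinct
#' peptide-coordinate phospho positions per modified sequence), proteins, the
#' pS/pT/pY composition, and class-1 sites at the given cutoff when per-entry
#' site probabilities are supplied.
#'
#' @param lib A `spectral_library`.
#' @param site_probabilities Optional named numeric vector of localization
#'   probabilities keyed like `site_ids` in the result.
#' @param cutoff Class-1 probability cutoff (default 0.75).
#' @return List of counts and fractions.
#' @export
library_summary <- function(lib, site_probabilities = NULL, cutoff = 0.75) {
  entries <- lib$entries
  if (length(entries) == 0L)
    return(list(n_precursors = 0L, n_modified_peptides = 0L, n_phosphosites = 0L,
                n_proteins = 0L, psty_fraction = c(pS = 0, pT = 0, pY = 0),
                n_class1 = 0L))
  modseqs <- vapply(entries, function(e) format_modified_sequence(e$peptidoform), "")
  proteins <- unique(unlist(lapply(entries, function(e)
    strsplit(e$proteins, ";")[[1]])))
  proteins <- proteins[!is.na(proteins)]
  site_rows <- do.call(rbind, lapply(unique(modseqs), function(ms) {
    pf <- parse_modified_sequence(ms)
    ph <- pf$modifications[pf$modifications$label == "ph", , drop = FALSE]
    if (nrow(ph) == 0L) return(NULL)
    res <- strsplit(pf$sequence, "")[[1]][ph$position]
    data.frame(site_id = paste0(pf$sequence, "-", res, ph$position),
               residue = res)
  }))
  if (is.null(site_rows)) site_rows <- data.frame(site_id = character(),
                                                  residue = character())
  site_rows <- site_rows[!duplicated(site_rows$site_id), , drop = FALSE]
  res_tab <- table(factor(site_rows$residue, levels = c("S", "T", "Y")))
  frac <- if (nrow(site_rows) > 0L) as.numeric(res_tab) / nrow(site_rows)
          else c(0, 0, 0)
  n_class1 <- if (!is.null(site_probabilities))
    sum(site_probabilities >= cutoff) else NA_integer_
  list(n_precursors = length(entries),
       n_modified_peptides = length(unique(modseqs)),
       n_phosphosites = nrow(site_rows),
       n_proteins = length(proteins),
       psty_fraction = stats::setNames(frac, c("pS", "pT", "pY")),
       n_class1 = n_class1)
}
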