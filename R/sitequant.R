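# Peptide-to-protein site mapping and roll-up of precursor areas to
# phosphosite and protein abundances, with cross-run normalization.

#' Map peptide-level phospho positions to protein coordinates
#'
#' Locates the stripped sequence in the protein and converts each peptide
#' position to a protein position (`offset + position - 1`, both 1-based).
#' All occurrences are reported; the first is used for keying and a
#' multi-mapping flag set when there are several.
#'
#' @param pf A [peptidoform] or modified-sequence string; its `"ph"`
#'   positions are mapped. Alternatively supply `positions`.
#' @param protein Protein sequence string.
#' @param accession Protein accession used in site keys.
#' @param positions Optional explicit peptide-local positions to map instead
#'   of the peptidoform's phospho positions.
#' @return `data.frame` with columns `accession`, `residue`, `position`
#'   (protein, 1-based), `peptide_position`, `site_key` (`"ACC-S123"` style),
#'   `multi_mapping`.
#' @export
map_sites_to_protein <- function(pf, protein, accession,
                                 positions = NULL) {
  pf <- .as_peptidoform(pf)
  if (is.null(positions)) {
    ph <- pf$modifications[pf$modifications$label == "ph", , drop = FALSE]
    positions <- ph$position
  }
  offs <- gregexpr(pf$sequence, protein, fixed = TRUE)[[1]]
  if (offs[1] == -1L)
    stop("peptide ", pf$sequence, " not found in protein ", accession)
  residues <- strsplit(pf$sequence, "")[[1]]
  multi <- length(offs) > 1L
  if (length(positions) == 0L)
    return(data.frame(accession = character(), residue = character(),
                      position = integer(), peptide_position = integer(),
                      site_key = character(), multi_mapping = logical()))
  prot_pos <- offs[1] + positions - 1L
  res <- residues[positions]
  data.frame(accession = accession, residue = res, position = prot_pos,
             peptide_position = positions,
             site_key = paste0(accession, "-", res, prot_pos),
             multi_mapping = multi)
}

#' Site abundance matrix
#'
#' Container for phosphosites-by-runs abundances: `abundance` is a numeric
#' matrix with `NA` marking *missing* (never zero), rows keyed `"ACC-S123"`;
#' `sites` carries per-site metadata (best localization probability, class-1
#' flag, protein group).
#'
#' @param abundance Numeric matrix, site keys as rownames, run ids as colnames.
#' @param sites `data.frame` of per-site metadata aligned with the rows.
#' @return Object of class `site_matrix`.
#' @export
site_matrix <- function(abundance, sites = NULL) {
  stopifnot(is.matrix(abundance), !is.null(rownames(abundance)),
            !is.null(colnames(abundance)))
  if (any(abundance < 0, na.rm = TRUE)) stop("negative abundances")
  if (is.null(sites))
    sites <- data.frame(site_key = rownames(abundance))
  structure(list(abundance = abundance, sites = sites), class = "site_matrix")
}

#' @export
print.site_matrix <- function(x, ...) {
  cat("Site abundance matrix:", nrow(x$abundance), "site(s) x",
      ncol(x$abundance), "run(s);",
      sum(is.na(x$abundance)), "missing cell(s)\n")
  invisible(x)
}

#' @export
as.matrix.site_matrix <- function(x, ...) x$abundance

.abundance_of <- function(x) {
  if (inherits(x, "site_matrix")) x$abundance else as.matrix(x)
}

# Parse the peptide-local probability annotation of one record into
# data.frame(position, prob); a missing/empty annotation means every phospho
# position is taken as fully localized (probability 1).
.record_site_probs <- function(pf, probs_string) {
  ph <- pf$modifications[pf$modifications$label == "ph", , drop = FALSE]
  if (nrow(ph) == 0L) return(NULL)
  if (is.na(probs_string) || !nzchar(probs_string))
    return(data.frame(position = ph$position, prob = 1))
  parsed <- parse_site_probabilities(probs_string)
  prob <- rep(1, nrow(ph))
  hit <- match(ph$position, parsed$position)
  prob[!is.na(hit)] <- parsed$prob[hit[!is.na(hit)]]
  data.frame(position = ph$position, prob = prob)
}

#' Roll precursor areas up to phosphosite abundances
#'
#' The abundance of a phosphosite in a run is the summed area of every
#' precursor (any charge, any co-modification, any phospho multiplicity)
#' whose localization probability for that site meets the class-1 cutoff.
#' Multi-phospho precursors contribute their full area to every qualifying
#' constituent site. Sites with no qualifying precursor in a run are missing
#' (`NA`), not zero.
#'
#' @param records Precursor report `data.frame` as returned by
#'   [read_precursor_report()]: columns `run`, `modified_sequence`, `charge`,
#'   `protein_group`, `area`, `site_probs`.
#' @param proteins Named character vector of protein sequences (accession ->
#'   sequence), e.g. from [read_fasta()]. Site keys are emitted against the
#'   first accession of the record's protein group.
#' @param cutoff Localization probability cutoff; defaults to the mode's
#'   class-1 cutoff.
#' @param mode Class-1 mode (`"libDIA"`, `"DDA"`, `"dirDIA"`).
#' @return A [site_matrix].
#' @export
rollup_phosphosites <- function(records, proteins, cutoff = NULL,
                                mode = "libDIA") {
  if (is.null(cutoff)) cutoff <- class1_cutoff(mode)
  records <- as.data.frame(records)
  runs <- unique(records$run)
  acc <- vapply(strsplit(records$protein_group, ";"), `[`, "", 1L)

  rows <- vector("list", nrow(records))
  pf_cache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(records))) {
    ms <- records$modified_sequence[i]
    pf <- if (!is.null(pf_cache[[ms]])) pf_cache[[ms]] else
      (pf_cache[[ms]] <- parse_modified_sequence(ms))
    sp <- .record_site_probs(pf, records$site_probs[i])
    if (is.null(sp)) next
    keep <- sp$prob >= cutoff
    if (!any(keep)) next
    seqn <- proteins[[acc[i]]]
    if (is.null(seqn))
      stop("accession ", acc[i], " not present in the protein sequences")
    mapped <- map_sites_to_protein(pf, seqn, acc[i],
                                   positions = sp$position[keep])
    rows[[i]] <- data.frame(site_key = mapped$site_key, run = records$run[i],
                            area = records$area[i], prob = sp$prob[keep],
                            residue = mapped$residue,
                            protein_group = records$protein_group[i],
                            multi_mapping = mapped$multi_mapping)
  }
  contrib <- do.call(rbind, rows)
  if (is.null(contrib) || nrow(contrib) == 0L) {
    m <- matrix(numeric(), 0, length(runs), dimnames = list(NULL, runs))
    return(site_matrix(m))
  }
  keys <- sort(unique(contrib$site_key))
  m <- matrix(NA_real_, length(keys), length(runs),
              dimnames = list(keys, runs))
  agg <- stats::aggregate(area ~ site_key + run, contrib, sum)
  m[cbind(match(agg$site_key, keys), match(agg$run, runs))] <- agg$area
  best <- vapply(split(contrib$prob, contrib$site_key), max, 0)[keys]
  meta <- data.frame(
    site_key = keys,
    best_probability = unname(best),
    class1 = unname(best) >= class1_cutoff(mode),
    protein_group = vapply(split(contrib$protein_group, contrib$site_key),
                           `[`, "", 1L)[keys],
    multi_mapping = vapply(split(contrib$multi_mapping, contrib$site_key),
                           any, TRUE)[keys])
  rownames(meta) <- NULL
  site_matrix(m, meta)
}

#' Roll precursor areas up to protein abundances
#'
#' Per run, the area of a stripped peptide sequence is the mean of its
#' precursor areas; the abundance of a protein is the sum of its stripped
#' peptide areas. Proteins are keyed by the first accession of each record's
#' protein group.
#'
#' @inheritParams rollup_phosphosites
#' @return Numeric matrix proteins x runs with `NA` for missing.
#' @export
rollup_proteins <- function(records) {
  records <- as.data.frame(records)
  records$stripped <- vapply(records$modified_sequence, function(ms)
    parse_modified_sequence(ms)$sequence, "", USE.NAMES = FALSE)
  records$accession <- vapply(strsplit(records$protein_group, ";"), `[`, "", 1L)
  pep <- stats::aggregate(area ~ accession + stripped + run, records, mean)
  prot <- stats::aggregate(area ~ accession + run, pep, sum)
  runs <- unique(records$run)
  accs <- sort(unique(prot$accession))
  m <- matrix(NA_real_, length(accs), length(runs),
              dimnames = list(accs, runs))
  m[cbind(match(prot$accession, accs), match(prot$run, runs))] <- prot$area
  m
}

#' Cross-run median normalization
#'
#' Computes per-run scaling factors from the rows complete in all runs: run
#' medians of log2 abundance are equalized to their mean. Factors are linear
#' multipliers applied to the whole matrix, reported in the `factors`
#' attribute (all 1 on an already-centered matrix).
#'
#' @param x A [site_matrix] or plain abundance matrix with >= 2 columns.
#' @return Same type as the input, normalized; attribute `factors` on the
#'   abundance matrix.
#' @export
normalize_runs <- function(x) {
  m <- .abundance_of(x)
  if (ncol(m) < 2L) stop("normalization needs at least 2 runs")
  complete <- stats::complete.cases(m) & rowSums(m == 0, na.rm = TRUE) == 0
  if (!any(complete))
    stop("no rows complete in all runs; relax completeness or impute upstream")
  med <- apply(log2(m[complete, , drop = FALSE]), 2, stats::median)
  factors <- 2^(mean(med) - med)
  out <- sweep(m, 2, factors, `*`)
  attr(out, "factors") <- factors
  if (inherits(x, "site_matrix")) {
    x$abundance <- out
    x
  } else out
}
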