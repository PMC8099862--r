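# Readers and writers for the on-disk formats: precursor reports, FASTA,
# spectral-library tables, site matrices, MGF-like peak lists, ground truth.
# All tabular formats are tab-delimited UTF-8 with "." decimals; missing
# cells are empty strings, never "0" or "NA".

#' Default precursor-report column schema
#'
#' Maps canonical field names to the column headers of the long-format
#' precursor report dialect. Override entries to adapt other report
#' dialects.
#'
#' @return Named character vector (canonical -> column header).
#' @export
default_report_schema <- function() {
  c(run = "Run", modified_sequence = "ModifiedPeptide",
    charge = "PrecursorCharge", protein_group = "ProteinGroups",
    area = "PrecursorArea", rt = "RT", site_probs = "SiteProbabilities",
    mode = "Mode")
}

#' Read a precursor quantification report
#'
#' Tab-delimited long-format report, one row per precursor per run. Columns
#' are resolved through `schema`; unknown columns are preserved as
#' passthrough metadata. Rows are validated (non-negative area, parsable
#' modified sequence, probabilities in `[0, 1]`) and failures are reported
#' with their line numbers.
#'
#' @param path Report TSV path.
#' @param schema Canonical-to-header mapping (default
#'   [default_report_schema()]).
#' @return `data.frame` with canonical columns `run`, `modified_sequence`,
#'   `charge`, `protein_group`, `area`, `rt`, `site_probs`, `mode`, plus any
#'   passthrough columns.
#' @export
read_precursor_report <- function(path, schema = default_report_schema()) {
  raw <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character", na.strings = NULL)
  missing_cols <- setdiff(unname(schema), names(raw))
  if (length(missing_cols) > 0L)
    stop("report lacks mapped column(s): ", paste(missing_cols, collapse = ", "))
  out <- stats::setNames(raw[unname(schema)], names(schema))
  passthrough <- setdiff(names(raw), unname(schema))
  out <- cbind(out, raw[passthrough])
  out$charge <- as.integer(out$charge)
  out$area <- suppressWarnings(as.numeric(out$area))
  out$rt <- suppressWarnings(as.numeric(out$rt))
  bad <- which(is.na(out$area) | out$area < 0)
  if (length(bad) > 0L)
    stop("invalid area at line(s) ", paste(bad + 1L, collapse = ", "),
         " of ", path)
  for (i in seq_len(nrow(out))) {
    pf <- tryCatch(parse_modified_sequence(out$modified_sequence[i]),
                   error = function(e)
                     stop("line ", i + 1L, " of ", path, ": ",
                          conditionMessage(e), call. = FALSE))
    if (nzchar(out$site_probs[i])) {
      pr <- tryCatch(parse_site_probabilities(out$site_probs[i]),
                     error = function(e)
                       stop("line ", i + 1L, " of ", path, ": ",
                            conditionMessage(e), call. = FALSE))
      if (any(pr$prob < 0 | pr$prob > 1))
        stop("line ", i + 1L, " of ", path, ": probability outside [0, 1]")
      if (any(pr$position > nchar(pf$sequence)))
        stop("line ", i + 1L, " of ", path, ": site position outside peptide")
    }
  }
  out
}

#' Write a precursor quantification report
#'
#' @param records Canonical-column `data.frame` (see
#'   [read_precursor_report()]).
#' @param path Output TSV path.
#' @param schema Canonical-to-header mapping used for the written headers.
#' @return `path`, invisibly.
#' @export
write_precursor_report <- function(records, path,
                                   schema = default_report_schema()) {
  canon <- intersect(names(schema), names(records))
  extra <- setdiff(names(records), names(schema))
  out <- records[c(canon, extra)]
  names(out)[seq_along(canon)] <- unname(schema[canon])
  .write_tsv(out, path)
  invisible(path)
}

# Serialize numerics at full precision; NA as empty string.
.write_tsv <- function(df, path) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]))
      df[[j]] <- ifelse(is.na(df[[j]]), "", sprintf("%.15g", df[[j]]))
    else df[[j]] <- ifelse(is.na(df[[j]]), "", as.character(df[[j]]))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
}

#' Parse a site-probability annotation string
#'
#' Grammar: semicolon-separated `"RESIDUE<position>: prob"` pairs with
#' peptide-local 1-based positions, e.g. `"S2: 0.98; S6: 0.02"`.
#'
#' @param text Annotation string.
#' @return `data.frame` with columns `residue`, `position`, `prob`.
#' @export
parse_site_probabilities <- function(text) {
  parts <- trimws(strsplit(text, ";", fixed = TRUE)[[1]])
  parts <- parts[nzchar(parts)]
  m <- regmatches(parts, regexec("^([STY])([0-9]+):\\s*([0-9.eE+-]+)$", parts))
  if (length(parts) == 0L || any(vapply(m, length, 0L) != 4L))
    stop("malformed site-probability string: ", text)
  data.frame(residue = vapply(m, `[`, "", 2L),
             position = as.integer(vapply(m, `[`, "", 3L)),
             prob = as.numeric(vapply(m, `[`, "", 4L)))
}

#' Render a site-probability annotation string
#'
#' Inverse of [parse_site_probabilities()].
#'
#' @param probs `data.frame` with `residue`, `position`, `prob`.
#' @return Annotation string.
#' @export
format_site_probabilities <- function(probs) {
  paste(sprintf("%s%d: %s", probs$residue, probs$position,
                sprintf("%.15g", probs$prob)),
        collapse = "; ")
}

#' Read protein sequences from FASTA
#'
#' Accessions follow the UniProt convention: the second pipe-delimited token
#' of `sp|ACC|NAME` headers, otherwise the first whitespace token. Duplicate
#' accessions are an error.
#'
#' @param path FASTA path.
#' @return Named character vector (accession -> sequence).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("empty FASTA: ", path)
  headers <- names(set)
  first_tok <- vapply(strsplit(headers, "\\s+"), `[`, "", 1L)
  acc <- vapply(first_tok, function(h) {
    if (grepl("^[a-z]{2}\\|", h)) strsplit(h, "|", fixed = TRUE)[[1]][2] else h
  }, "", USE.NAMES = FALSE)
  if (anyDuplicated(acc))
    stop("duplicate accession(s): ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  stats::setNames(as.character(set), acc)
}

#' Write protein sequences to FASTA
#'
#' @param proteins Named character vector (accession -> sequence).
#' @param path Output path.
#' @param uniprot_headers Write `sp|ACC|ACC_TEST`-style headers (default);
#'   otherwise bare accessions.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, uniprot_headers = TRUE) {
  set <- Biostrings::AAStringSet(proteins)
  names(set) <- if (uniprot_headers)
    sprintf("sp|%s|%s_TEST", names(proteins), names(proteins))
  else names(proteins)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write a site abundance matrix
#'
#' First column `SiteKey`, one column per run; missing cells are empty.
#'
#' @param x A [site_matrix] or abundance matrix.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_site_matrix <- function(x, path) {
  m <- .abundance_of(x)
  df <- data.frame(SiteKey = rownames(m), as.data.frame(m, optional = TRUE),
                   check.names = FALSE)
  .write_tsv(df, path)
  invisible(path)
}

#' Read a site abundance matrix
#'
#' @param path TSV path written by [write_site_matrix()].
#' @return A [site_matrix] (empty cells become `NA`).
#' @export
read_site_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character", na.strings = NULL)
  if (names(df)[1] != "SiteKey") stop("expected first column 'SiteKey'")
  m <- as.matrix(df[-1])
  m[m == ""] <- NA
  storage.mode(m) <- "double"
  rownames(m) <- df$SiteKey
  site_matrix(m)
}

#' Write peak lists in an MGF-like text format
#'
#' Each spectrum is wrapped in `BEGIN IONS` / `END IONS` with optional
#' `TITLE=`, `PEPMASS=` and `CHARGE=` headers, followed by
#' tab-separated `mz intensity` lines.
#'
#' @param spectra A single peak `data.frame(mz, intensity)` or a (optionally
#'   named) list of them.
#' @param path Output path.
#' @param precursor_mz,precursor_charge Optional per-spectrum vectors.
#' @return `path`, invisibly.
#' @export
write_peak_list <- function(spectra, path, precursor_mz = NULL,
                            precursor_charge = NULL) {
  if (is.data.frame(spectra)) spectra <- list(spectra)
  lines <- character()
  for (i in seq_along(spectra)) {
    lines <- c(lines, "BEGIN IONS")
    title <- names(spectra)[i]
    if (!is.null(title) && nzchar(title))
      lines <- c(lines, paste0("TITLE=", title))
    if (!is.null(precursor_mz))
      lines <- c(lines, paste0("PEPMASS=", sprintf("%.15g", precursor_mz[i])))
    if (!is.null(precursor_charge))
      lines <- c(lines, paste0("CHARGE=", precursor_charge[i], "+"))
    p <- spectra[[i]]
    lines <- c(lines, paste(sprintf("%.15g", p$mz),
                            sprintf("%.15g", p$intensity), sep = "\t"),
               "END IONS")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read peak lists from the MGF-like text format
#'
#' @param path Path written by [write_peak_list()].
#' @return List of peak lists; each element is a `data.frame(mz, intensity)`
#'   with attributes `title`, `precursor_mz`, `precursor_charge` when
#'   present.
#' @export
read_peak_list <- function(path) {
  lines <- readLines(path)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends) || any(ends < begins))
    stop("unbalanced BEGIN IONS/END IONS in ", path)
  out <- lapply(seq_along(begins), function(i) {
    block <- lines[(begins[i] + 1L):(ends[i] - 1L)]
    headers <- grepl("^[A-Z]+=", block)
    peaks <- block[!headers]
    fields <- strsplit(peaks, "[\t ]+")
    df <- data.frame(mz = as.numeric(vapply(fields, `[`, "", 1L)),
                     intensity = as.numeric(vapply(fields, `[`, "", 2L)))
    hv <- block[headers]
    get_h <- function(key) {
      hit <- grep(paste0("^", key, "="), hv, value = TRUE)
      if (length(hit) == 0L) NULL else sub(paste0("^", key, "="), "", hit[1])
    }
    attr(df, "title") <- get_h("TITLE")
    pm <- get_h("PEPMASS")
    if (!is.null(pm)) attr(df, "precursor_mz") <- as.numeric(pm)
    ch <- get_h("CHARGE")
    if (!is.null(ch)) attr(df, "precursor_charge") <- as.integer(sub("\\+$", "", ch))
    df
  })
  titles <- vapply(out, function(d) {
    t <- attr(d, "title"); if (is.null(t)) "" else t
  }, "")
  if (any(nzchar(titles))) names(out) <- titles
  out
}

#' Write a spectral library as a long-format TSV
#'
#' One row per fragment with the columns ModifiedPeptide, StrippedSequence,
#' PrecursorCharge, PrecursorMz, iRT, ProteinAccessions, FragmentType,
#' FragmentNumber, FragmentCharge, FragmentMz, RelativeIntensity,
#' FragmentLossType, Source, Score.
#'
#' @param lib A `spectral_library` (see [merge_hybrid()]) or list of
#'   [library_entry] objects.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_library_tsv <- function(lib, path) {
  entries <- if (inherits(lib, "spectral_library")) lib$entries else lib
  rows <- lapply(entries, function(e) {
    fr <- e$fragments
    if (nrow(fr) == 0L) return(NULL)
    data.frame(
      ModifiedPeptide = format_modified_sequence(e$peptidoform),
      StrippedSequence = e$peptidoform$sequence,
      PrecursorCharge = e$charge,
      PrecursorMz = precursor_mz(e$peptidoform, e$charge),
      iRT = e$irt,
      ProteinAccessions = e$proteins,
      FragmentType = fr$series, FragmentNumber = fr$index,
      FragmentCharge = fr$charge, FragmentMz = fr$mz,
      RelativeIntensity = fr$rel_intensity,
      FragmentLossType = ifelse(fr$neutral_loss > 0, "H3PO4", "noloss"),
      Source = e$source, Score = e$score)
  })
  .write_tsv(do.call(rbind, rows), path)
  invisible(path)
}

#' Read a spectral library from a long-format TSV
#'
#' @param path TSV path (see [write_library_tsv()] for the columns).
#' @param schema Optional named vector remapping canonical headers to a
#'   different dialect's headers.
#' @return List of [library_entry] objects.
#' @export
read_library_tsv <- function(path, schema = NULL) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (!is.null(schema)) {
    hit <- match(unname(schema), names(df))
    if (anyNA(hit)) stop("library TSV lacks mapped column(s): ",
                         paste(schema[is.na(hit)], collapse = ", "))
    names(df)[hit] <- names(schema)
  }
  key <- paste0(df$ModifiedPeptide, "/", df$PrecursorCharge)
  lapply(split(df, factor(key, levels = unique(key))), function(d) {
    n <- nchar(d$StrippedSequence[1])
    library_entry(
      parse_modified_sequence(d$ModifiedPeptide[1]),
      charge = d$PrecursorCharge[1], irt = d$iRT[1],
      fragments = data.frame(
        series = d$FragmentType, index = d$FragmentNumber,
        charge = d$FragmentCharge,
        neutral_loss = ifelse(d$FragmentLossType == "H3PO4", .MASS_H3PO4, 0),
        mz = d$FragmentMz, n_residues = d$FragmentNumber,
        rel_intensity = d$RelativeIntensity),
      source = as.character(d$Source[1]), score = d$Score[1],
      proteins = as.character(d$ProteinAccessions[1]))
  })
}

#' Write simulation ground truth as JSON
#'
#' @param truth Ground-truth list from a simulator.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  # jsonlite drops the names of atomic vectors; lift them to objects
  lift <- function(x) {
    if (is.data.frame(x)) x
    else if (is.list(x)) lapply(x, lift)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  jsonlite::write_json(lift(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "columns")
  invisible(path)
}

#' Read simulation ground truth
#'
#' @param path JSON path from [write_ground_truth()].
#' @return List.
#' @export
read_ground_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
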