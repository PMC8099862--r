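# Monoisotopic mass arithmetic for peptides, precursors and b/y fragment ions.

# Standard monoisotopic residue masses (Da), 5-decimal precision.
.AA_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

.MASS_WATER  <- 18.01056
.MASS_PROTON <- 1.007276
# Phosphoric acid (H3PO4), the dominant neutral loss of phosphopeptides.
.MASS_H3PO4  <- 97.9769

# Variable-modification deltas (Da): phospho on S/T/Y, Met oxidation,
# Cys carbamidomethylation, acetylation.
.MOD_DELTAS <- c(ph = 79.96633, ox = 15.99491, cam = 57.02146, ac = 42.01057)

#' Construct a peptidoform
#'
#' A peptidoform is a stripped amino-acid sequence plus positioned mass
#' modifications and, optionally, a precursor charge. It is the unit of
#' identification throughout the package.
#'
#' @param sequence Uppercase amino-acid string over the 20 canonical residues.
#' @param modifications `data.frame` with columns `position` (1-based residue
#'   index), `label` (one of `"ph"`, `"ox"`, `"cam"`, `"ac"`) and optionally
#'   `delta` (Da; filled from the label when absent). May be `NULL`.
#' @param charge Positive integer precursor charge, or `NA` when unset.
#' @return An object of class `peptidoform`.
#' @examples
#' peptidoform("GSHQISLDNPDYQQDFFPK",
#'             data.frame(position = 2, label = "ph"))
#' @export
peptidoform <- function(sequence, modifications = NULL, charge = NA_integer_) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("empty peptide sequence")
  residues <- strsplit(sequence, "")[[1]]
  bad <- setdiff(residues, names(.AA_MONO))
  if (length(bad) > 0L)
    stop("non-canonical residue(s): ", paste(unique(bad), collapse = ", "))
  if (is.null(modifications)) {
    modifications <- data.frame(position = integer(), label = character(),
                                delta = numeric())
  } else {
    modifications <- as.data.frame(modifications)
    if (!all(c("position", "label") %in% names(modifications)))
      stop("modifications need 'position' and 'label' columns")
    if (is.null(modifications$delta)) {
      unknown <- setdiff(modifications$label, names(.MOD_DELTAS))
      if (length(unknown) > 0L)
        stop("unknown modification label(s): ", paste(unknown, collapse = ", "))
      modifications$delta <- unname(.MOD_DELTAS[modifications$label])
    }
    if (any(modifications$position < 1L |
            modifications$position > length(residues)))
      stop("modification position outside the peptide")
    if (anyDuplicated(modifications[c("position", "label")]))
      stop("duplicate (position, label) modification")
    ph <- modifications$label == "ph"
    if (any(ph) && !all(residues[modifications$position[ph]] %in% c("S", "T", "Y")))
      stop("'ph' modification on a non-S/T/Y residue")
    modifications <- modifications[order(modifications$position), , drop = FALSE]
    rownames(modifications) <- NULL
  }
  if (!is.na(charge) && charge < 1) stop("charge must be a positive integer")
  structure(list(sequence = sequence, modifications = modifications,
                 charge = as.integer(charge)),
            class = "peptidoform")
}

#' @export
print.peptidoform <- function(x, ...) {
  cat("Peptidoform:", format_modified_sequence(x))
  if (!is.na(x$charge)) cat(" (", x$charge, "+)", sep = "")
  cat("\n")
  invisible(x)
}

.as_peptidoform <- function(x) {
  if (inherits(x, "peptidoform")) x else parse_modified_sequence(x)
}

#' Parse a modified-sequence string
#'
#' Accepts the inline-code dialect used by common search engines: the stripped
#' sequence with parenthesized lowercase modification codes immediately after
#' the modified residue, e.g. `"GS(ph)HQISLDNPDYQQDFFPK"` or `"M(ox)AS(ph)K"`,
#' with optional flanking underscores.
#'
#' @param text Modified-sequence string.
#' @param charge Optional precursor charge carried on the result.
#' @return A [peptidoform].
#' @export
parse_modified_sequence <- function(text, charge = NA_integer_) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- gsub("^_+|_+$", "", text)
  if (!nzchar(s)) stop("empty modified sequence")
  tokens <- regmatches(s, gregexpr("[A-Z](\\([a-z]+\\))?", s))[[1]]
  if (sum(nchar(tokens)) != nchar(s))
    stop("cannot parse modified sequence: ", text)
  residues <- substr(tokens, 1L, 1L)
  codes <- sub("^[A-Z](\\(([a-z]+)\\))?$", "\\2", tokens)
  has_mod <- nzchar(codes)
  unknown <- setdiff(codes[has_mod], names(.MOD_DELTAS))
  if (length(unknown) > 0L)
    stop("unknown modification code(s): ", paste(unknown, collapse = ", "))
  mods <- if (any(has_mod)) {
    data.frame(position = which(has_mod), label = codes[has_mod],
               delta = unname(.MOD_DELTAS[codes[has_mod]]))
  } else NULL
  peptidoform(paste(residues, collapse = ""), mods, charge)
}

#' Render a peptidoform back to the inline-code dialect
#'
#' Inverse of [parse_modified_sequence()]: `parse` then `format` is the
#' identity on the dialect.
#'
#' @param pf A [peptidoform].
#' @return Modified-sequence string.
#' @export
format_modified_sequence <- function(pf) {
  pf <- .as_peptidoform(pf)
  residues <- strsplit(pf$sequence, "")[[1]]
  if (nrow(pf$modifications) > 0L) {
    ins <- vapply(split(pf$modifications$label, pf$modifications$position),
                  function(l) paste0("(", paste(l, collapse = ")("), ")"), "")
    pos <- as.integer(names(ins))
    residues[pos] <- paste0(residues[pos], ins)
  }
  paste(residues, collapse = "")
}

#' Peptide monoisotopic mass
#'
#' Sum of residue monoisotopic masses plus one water plus all modification
#' deltas (phospho +79.96633 Da, oxidation +15.99491 Da, carbamidomethyl
#' +57.02146 Da, acetyl +42.01057 Da).
#'
#' @param pf A [peptidoform] or a modified-sequence string.
#' @return Monoisotopic mass in Da.
#' @examples
#' peptide_mono_mass("GG")  # 132.05348
#' @export
peptide_mono_mass <- function(pf) {
  pf <- .as_peptidoform(pf)
  sum(.AA_MONO[strsplit(pf$sequence, "")[[1]]]) + .MASS_WATER +
    sum(pf$modifications$delta)
}

#' Precursor m/z
#'
#' `(M + z * 1.007276) / z` for monoisotopic mass `M` and charge `z`.
#'
#' @param pf A [peptidoform], modified-sequence string, or a bare monoisotopic
#'   mass in Da.
#' @param z Positive integer charge; defaults to the peptidoform's own charge.
#' @return m/z in Th.
#' @export
precursor_mz <- function(pf, z = NULL) {
  m <- if (is.numeric(pf)) pf else peptide_mono_mass(pf)
  if (is.null(z)) {
    if (is.numeric(pf)) stop("charge required for a bare mass")
    z <- .as_peptidoform(pf)$charge
    if (is.na(z)) stop("peptidoform carries no charge; supply z")
  }
  if (any(z < 1)) stop("charge must be >= 1")
  (m + z * .MASS_PROTON) / z
}

# Cumulative modification delta up to (b) or from (y) each residue,
# restricted to labels in `labels` (NULL = all).
.mod_prefix <- function(pf, labels = NULL) {
  n <- nchar(pf$sequence)
  d <- numeric(n)
  m <- pf$modifications
  if (!is.null(labels)) m <- m[m$label %in% labels, , drop = FALSE]
  if (nrow(m) > 0L)
    d[m$position] <- d[m$position] + m$delta
  d
}

#' Theoretical b/y fragment ladder
#'
#' Enumerates all `b1..b(n-1)` and/or `y1..y(n-1)` fragment ions of a
#' peptidoform at fragment charges `1..max_charge`, carrying the modification
#' deltas of the residues each fragment contains. With
#' `include_neutral_loss = TRUE` an additional -97.9769 Da (phosphoric acid)
#' variant is emitted for every fragment containing at least one phospho
#' residue.
#'
#' @param pf A [peptidoform] or modified-sequence string.
#' @param series Character subset of `c("b", "y")`.
#' @param max_charge Maximum fragment charge (default 1).
#' @param include_neutral_loss Emit H3PO4-loss variants of phospho-containing
#'   fragments.
#' @return `data.frame` with columns `series`, `index`, `charge`,
#'   `neutral_loss` (Da), `mz` (Th), `n_residues`.
#' @export
fragment_ladder <- function(pf, series = c("b", "y"), max_charge = 1L,
                            include_neutral_loss = FALSE) {
  pf <- .as_peptidoform(pf)
  series <- match.arg(series, c("b", "y"), several.ok = TRUE)
  n <- nchar(pf$sequence)
  if (n < 2L) stop("fragment ladder needs a peptide of length >= 2")
  res <- .AA_MONO[strsplit(pf$sequence, "")[[1]]] + .mod_prefix(pf)
  is_ph <- logical(n)
  ph <- pf$modifications[pf$modifications$label == "ph", , drop = FALSE]
  is_ph[ph$position] <- TRUE

  rows <- list()
  for (s in series) {
    idx <- seq_len(n - 1L)
    if (s == "b") {
      neutral <- cumsum(res)[idx]                    # residues 1..i
      n_ph <- cumsum(is_ph)[idx]
    } else {
      neutral <- rev(cumsum(rev(res)))[n - idx + 1L] + .MASS_WATER  # last i
      n_ph <- rev(cumsum(rev(is_ph)))[n - idx + 1L]
    }
    for (z in seq_len(max_charge)) {
      rows[[length(rows) + 1L]] <- data.frame(
        series = s, index = idx, charge = z, neutral_loss = 0,
        mz = (neutral + z * .MASS_PROTON) / z, n_residues = idx)
      if (include_neutral_loss && any(n_ph > 0L)) {
        keep <- n_ph > 0L
        rows[[length(rows) + 1L]] <- data.frame(
          series = s, index = idx[keep], charge = z, neutral_loss = .MASS_H3PO4,
          mz = (neutral[keep] - .MASS_H3PO4 + z * .MASS_PROTON) / z,
          n_residues = idx[keep])
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
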