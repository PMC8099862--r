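# Positional phospho-isomer enumeration, site-determining ions, and
# cumulative-binomial localization scoring with per-site probabilities.

.sty_positions <- function(sequence) {
  which(strsplit(sequence, "")[[1]] %in% c("S", "T", "Y"))
}

#' Enumerate positional phospho-isomers
#'
#' All ways of placing `k` phospho groups on the S/T/Y residues of a stripped
#' sequence, in deterministic lexicographic order.
#'
#' @param sequence Stripped peptide sequence.
#' @param k Number of phospho groups (>= 1).
#' @return List of sorted integer vectors of 1-based positions; attribute
#'   `candidates` holds the S/T/Y positions.
#' @export
enumerate_isomers <- function(sequence, k) {
  stopifnot(k >= 1)
  sty <- .sty_positions(sequence)
  if (k > length(sty))
    stop("k = ", k, " exceeds the ", length(sty), " S/T/Y candidate(s)")
  configs <- if (length(sty) == 1L) list(sty) else
    utils::combn(sty, k, simplify = FALSE)
  attr(configs, "candidates") <- sty
  configs
}

.config_label <- function(positions) paste(positions, collapse = "+")

# Singly-charged b/y m/z ladder of `sequence` phosphorylated at `positions`.
.config_ladder <- function(sequence, positions, series = c("b", "y"),
                           max_charge = 1L, include_neutral_loss = FALSE) {
  mods <- if (length(positions) > 0L)
    data.frame(position = positions, label = "ph") else NULL
  fragment_ladder(peptidoform(sequence, mods), series = series,
                  max_charge = max_charge,
                  include_neutral_loss = include_neutral_loss)
}

#' Site-determining fragment ions between two isomers
#'
#' The b/y indices whose theoretical m/z differs between two phospho
#' configurations of the same peptide. Because every phospho group carries the
#' same delta mass, an ion discriminates exactly when the two configurations
#' place different numbers of phospho groups inside the fragment; the
#' computation counts configuration members per prefix (b) and suffix (y).
#'
#' @param sequence Shared stripped peptide sequence.
#' @param config_a,config_b Integer vectors of phospho positions; equal length.
#' @param series Character subset of `c("b", "y")`.
#' @return Named list of sorted integer index vectors, one per series.
#' @export
site_determining_ions <- function(sequence, config_a, config_b,
                                  series = c("b", "y")) {
  series <- match.arg(series, c("b", "y"), several.ok = TRUE)
  n <- nchar(sequence)
  if (length(config_a) != length(config_b))
    stop("configurations must carry the same phospho count")
  if (any(c(config_a, config_b) < 1L) || any(c(config_a, config_b) > n))
    stop("configuration positions outside the peptide")
  idx <- seq_len(n - 1L)
  out <- list()
  for (s in series) {
    if (s == "b") {
      ca <- vapply(idx, function(i) sum(config_a <= i), 0L)
      cb <- vapply(idx, function(i) sum(config_b <= i), 0L)
    } else {
      ca <- vapply(idx, function(i) sum(config_a > n - i), 0L)
      cb <- vapply(idx, function(i) sum(config_b > n - i), 0L)
    }
    out[[s]] <- idx[ca != cb]
  }
  out
}

# Keep the `depth` most intense peaks per 100-Th window.
.filter_peak_depth <- function(peaks, depth) {
  if (nrow(peaks) == 0L) return(peaks)
  win <- floor(peaks$mz / 100)
  keep <- unlist(lapply(split(seq_len(nrow(peaks)), win), function(i) {
    i[order(peaks$intensity[i], decreasing = TRUE)][seq_len(min(depth, length(i)))]
  }), use.names = FALSE)
  peaks[sort(keep), , drop = FALSE]
}

#' Score phospho-isomer configurations against a peak list
#'
#' Ascore-style cumulative-binomial match scoring. The peak list is reduced to
#' the `depth` most intense peaks per 100-Th window; for each configuration the
#' singly charged theoretical b/y ions are matched within `tolerance` Da and
#' the score is `-10 * log10 P(X >= k)` for a Binomial(n, p) with
#' `p = depth * 2 * tolerance / 100` — the chance probability of matching a
#' random peak in the retained spectrum.
#'
#' @param peaks `data.frame` with columns `mz`, `intensity`.
#' @param sequence Stripped peptide sequence.
#' @param configurations List of phospho-position vectors
#'   (e.g. from [enumerate_isomers()]).
#' @param tolerance Fragment match tolerance in Da (default 0.05).
#' @param depth Peaks retained per 100 Th (default 10).
#' @return Named numeric vector of scores, one per configuration (names are
#'   `"+"`-joined positions).
#' @export
score_isomers <- function(peaks, sequence, configurations,
                          tolerance = 0.05, depth = 10L) {
  if (length(configurations) == 0L) stop("no configurations to score")
  stopifnot(tolerance > 0, depth >= 1)
  peaks <- as.data.frame(peaks)
  filtered <- .filter_peak_depth(peaks, depth)
  p <- min(1, depth * 2 * tolerance / 100)
  scores <- vapply(configurations, function(cfg) {
    theo <- .config_ladder(sequence, cfg)$mz
    n <- length(theo)
    k <- if (nrow(filtered) == 0L) 0L else
      sum(vapply(theo, function(t) any(abs(filtered$mz - t) <= tolerance), TRUE))
    if (k == 0L) return(0)
    -10 * stats::pbinom(k - 1L, n, p, lower.tail = FALSE, log.p = TRUE) / log(10)
  }, 0)
  names(scores) <- vapply(configurations, .config_label, "")
  scores
}

#' Per-site localization probabilities from configuration scores
#'
#' Configurations are weighted `10^(score/10)`; normalized weights are
#' configuration probabilities (they sum to 1) and the per-site probability
#' marginalizes over the configurations containing the site, so site
#' probabilities sum to the phospho count `k`.
#'
#' @param scores Named numeric vector from [score_isomers()].
#' @param configurations The matching list of position vectors.
#' @return List with `config_prob` (named numeric) and `site_prob` (numeric
#'   named by site position).
#' @export
site_probabilities <- function(scores, configurations) {
  stopifnot(length(scores) == length(configurations), length(scores) >= 1L)
  w <- 10^((scores - max(scores)) / 10)
  config_prob <- w / sum(w)
  sites <- sort(unique(unlist(configurations)))
  site_prob <- vapply(sites, function(s)
    sum(config_prob[vapply(configurations, function(cfg) s %in% cfg, TRUE)]), 0)
  names(site_prob) <- sites
  names(config_prob) <- names(scores)
  list(config_prob = config_prob, site_prob = site_prob)
}

#' Class-1 site classification
#'
#' A site is class 1 when its localization probability meets the mode's
#' cutoff: 0.75 for DDA and library-based DIA (`libDIA`), 0.99 for
#' library-free DIA (`dirDIA`). Cutoffs are inclusive.
#'
#' @param prob Numeric probabilities in `[0, 1]`.
#' @param mode `"libDIA"`, `"DDA"` or `"dirDIA"`.
#' @return Logical vector.
#' @export
classify_class1 <- function(prob, mode = c("libDIA", "DDA", "dirDIA")) {
  mode <- match.arg(mode)
  stopifnot(all(prob >= 0 & prob <= 1))
  prob >= class1_cutoff(mode)
}

#' @rdname classify_class1
#' @export
class1_cutoff <- function(mode = c("libDIA", "DDA", "dirDIA")) {
  mode <- match.arg(mode)
  if (mode == "dirDIA") 0.99 else 0.75
}

#' Localize phospho sites on one spectrum
#'
#' Convenience wrapper: enumerate the `k`-phospho isomers of `sequence`, score
#' them against `peaks`, and return configuration and per-site probabilities
#' with class-1 flags.
#'
#' @inheritParams score_isomers
#' @param k Phospho count.
#' @param mode Class-1 mode passed to [classify_class1()].
#' @return Object of class `localization_result`: list with `scores`,
#'   `config_prob`, `site_prob`, `class1`, `candidates`, `k`.
#' @export
localize_spectrum <- function(peaks, sequence, k, tolerance = 0.05,
                              depth = 10L, mode = "libDIA") {
  configs <- enumerate_isomers(sequence, k)
  scores <- score_isomers(peaks, sequence, configs,
                          tolerance = tolerance, depth = depth)
  pr <- site_probabilities(scores, configs)
  structure(list(scores = scores, config_prob = pr$config_prob,
                 site_prob = pr$site_prob,
                 class1 = classify_class1(pr$site_prob, mode),
                 candidates = attr(configs, "candidates"), k = k),
            class = "localization_result")
}

#' @export
print.localization_result <- function(x, ...) {
  cat("Localization over", length(x$scores), "configuration(s), k =", x$k, "\n")
  best <- order(x$site_prob, decreasing = TRUE)
  df <- data.frame(site = names(x$site_prob)[best],
                   probability = round(unname(x$site_prob[best]), 4),
                   class1 = unname(x$class1[best]))
  print(utils::head(df, 10), row.names = FALSE)
  invisible(x)
}
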