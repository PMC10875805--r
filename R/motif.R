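empty_logo_df <- function() {
  data.frame(offset = integer(0), residue = character(0),
             height = numeric(0), statistic = numeric(0),
             p_value = numeric(0), direction = character(0),
             stringsAsFactors = FALSE)
}

#' Tally residues per window position
#'
#' Counts how often each of the 20 amino acids occurs at each offset
#' (-6 ... +6) across a set of centralized peptides. Overhang placeholders
#' (`"J"`) are tallied separately per offset and never count toward any of
#' the 20 residues, so at every offset the residue counts plus the `J` count
#' equal the number of peptides.
#'
#' @param peptides Character vector of centralized 13-mers.
#' @return A list with `counts` (13x20 integer matrix, rows = offsets,
#'   columns = amino acids in canonical order), `j_counts` (J placeholders
#'   per offset) and `n` (number of peptides).
#' @export
count_matrix <- function(peptides) {
  if (length(peptides) == 0L)
    km_stop("kinamotif_empty", "cannot tally an empty peptide set")
  peptides <- vapply(peptides, validate_peptide, character(1), USE.NAMES = FALSE)
  mat <- do.call(rbind, strsplit(peptides, ""))
  counts <- empty_matrix()
  j_counts <- stats::setNames(integer(13), as.character(PEPTIDE_OFFSETS))
  for (j in 1:13) {
    tab <- table(factor(mat[, j], levels = c(AA_ALPHABET20, "J")))
    counts[j, ] <- tab[AA_ALPHABET20]
    j_counts[j] <- tab[["J"]]
  }
  list(counts = counts, j_counts = j_counts, n = length(peptides))
}

#' Background residue frequencies of a peptide dataset
#'
#' Computes the reference amino-acid distribution used by the chi-square
#' enrichment tests: the frequency of each residue over all flanking offsets
#' (offset 0 and `J` placeholders excluded) pooled across every peptide
#' supplied, floored at `1e-6` and renormalized so that no chi-square
#' expectation is ever zero.
#'
#' @param peptides Character vector of centralized 13-mers, typically the
#'   pooled peptides of every kinase in a dataset.
#' @return Named numeric vector of 20 probabilities summing to 1.
#' @export
background_from_dataset <- function(peptides) {
  cm <- count_matrix(peptides)
  flank <- cm$counts[as.character(PEPTIDE_OFFSETS[PEPTIDE_OFFSETS != 0L]), , drop = FALSE]
  tot <- colSums(flank)
  if (sum(tot) == 0)
    km_stop("kinamotif_empty", "no usable flanking residues to estimate a background from")
  b <- tot / sum(tot)
  b <- pmax(b, 1e-6)
  b / sum(b)
}

#' Uniform background over the 20 amino acids
#' @return Named numeric vector, each entry 0.05.
#' @export
uniform_background <- function() {
  stats::setNames(rep(1 / 20, 20), AA_ALPHABET20)
}

#' Position-specific probability matrix
#'
#' Converts residue counts to per-position probabilities
#' `p(i,j) = (counts(i,j) + pseudocount) / (effective_n(j) + 20 * pseudocount)`,
#' where `effective_n(j)` is the number of peptides minus the `J`
#' placeholders at offset `j`. Offsets observed only as `J`
#' (`effective_n = 0`) yield an all-zero column flagged unusable rather than
#' a uniform one.
#'
#' @param counts Result of [count_matrix()].
#' @param pseudocount Non-negative smoothing constant added to every cell;
#'   default 0 keeps small profiles faithful to the observed tallies.
#' @return A list with `p` (13x20 matrix; usable rows sum to 1),
#'   `effective_n` (per offset) and `usable` (logical per offset).
#' @export
probability_matrix <- function(counts, pseudocount = 0) {
  if (pseudocount < 0)
    km_stop("kinamotif_argument", "pseudocount must be >= 0, got %g", pseudocount)
  eff <- counts$n - counts$j_counts
  p <- empty_matrix()
  usable <- eff > 0
  for (j in which(usable))
    p[j, ] <- (counts$counts[j, ] + pseudocount) / (eff[j] + 20 * pseudocount)
  list(p = p, effective_n = eff, usable = usable)
}

#' Shannon information content of one position
#'
#' `R = log2(20) - H` where `H = -sum p_i log2 p_i` (with `0 log2 0 = 0`) is
#' the Shannon entropy of the position's residue distribution, in bits.
#' `R` is 0 for a uniform position and `log2(20) ~ 4.32` bits for an
#' invariant one. An all-zero (unusable) column returns 0. No small-sample
#' entropy correction is applied.
#'
#' @param p_column Numeric vector of 20 probabilities summing to 1, or all
#'   zero for an unusable position.
#' @param tol Tolerance on the column sum.
#' @return Information content in bits.
#' @examples
#' position_information(c(1, rep(0, 19)))   # log2(20)
#' position_information(rep(0.05, 20))      # 0
#' @export
position_information <- function(p_column, tol = 1e-6) {
  if (length(p_column) != 20L)
    km_stop("kinamotif_argument", "a probability column has 20 entries")
  s <- sum(p_column)
  if (s == 0) return(0)
  if (abs(s - 1) > tol)
    km_stop("kinamotif_argument", "probability column sums to %.9f, not 1", s)
  nz <- p_column[p_column > 0]
  H <- -sum(nz * log2(nz))
  log2(20) - H
}

#' Per-cell chi-square enrichment test
#'
#' One-degree-of-freedom goodness-of-fit test on the dichotomy
#' \{residue i, not residue i\} at one window position: with expectation
#' `e = effective_n * b_i`, the statistic is
#' `(observed - e)^2 / e + (observed - e)^2 / (effective_n - e)`
#' (no continuity correction), compared against the chi-square distribution
#' with 1 degree of freedom. The direction records whether the residue is
#' enriched (`observed > e`) or depleted (`observed < e`) relative to the
#' background.
#'
#' @param observed Observed count of the residue at the position.
#' @param effective_n Peptides contributing a residue at that position.
#' @param b_i Background probability of the residue, strictly in (0, 1).
#' @return A list with `statistic`, `p_value` and `direction`
#'   (`"enriched"`, `"depleted"` or `"none"`).
#' @examples
#' chisq_cell(30, 30, 0.05)  # statistic 570, p << 1e-4, enriched
#' @export
chisq_cell <- function(observed, effective_n, b_i) {
  if (effective_n < 1)
    km_stop("kinamotif_argument", "effective_n must be >= 1")
  if (b_i <= 0 || b_i >= 1)
    km_stop("kinamotif_argument", "background probability must be in (0, 1)")
  if (observed < 0 || observed > effective_n)
    km_stop("kinamotif_argument",
            "observed count %g outside [0, effective_n = %g]", observed, effective_n)
  e <- effective_n * b_i
  d <- observed - e
  statistic <- d^2 / e + d^2 / (effective_n - e)
  p_value <- stats::pchisq(statistic, df = 1, lower.tail = FALSE)
  direction <- if (d > 0) "enriched" else if (d < 0) "depleted" else "none"
  list(statistic = statistic, p_value = p_value, direction = direction)
}

#' Chi-square-filtered logo and anti-logo
#'
#' Runs [chisq_cell()] for every (flanking offset, amino acid) cell of a
#' count matrix against the background. Cells significantly enriched at
#' level `alpha` enter the logo with letter height
#' `h(i,j) = p(i,j) * R(j)` (probability times position information, in
#' bits). Cells significantly depleted enter the anti-logo with depletion
#' height `d(i,j) = ((e - o) / effective_n(j)) * R_dep(j)`, where `R_dep(j)`
#' is the Shannon information of the column's positive-deficit distribution
#' normalized over depleted cells -- a convention, since only the set of
#' depleted residues (not their absolute heights) is identified by the
#' significance filter. The phosphoacceptor position (offset 0) is excluded
#' from both.
#'
#' @param counts Result of [count_matrix()].
#' @param background Named 20-vector of background probabilities.
#' @param alpha Raw per-cell significance level (default `1e-4`); no
#'   multiple-testing correction is applied.
#' @return A list of class `logo_model` with data.frames `logo` and
#'   `antilogo` (columns `offset`, `residue`, `height`, `statistic`,
#'   `p_value`, `direction`) and the `alpha` used.
#' @export
build_logo <- function(counts, background, alpha = 1e-4) {
  if (alpha <= 0 || alpha >= 1)
    km_stop("kinamotif_argument", "alpha must be in (0, 1), got %g", alpha)
  pm <- probability_matrix(counts, pseudocount = 0)
  logo <- empty_logo_df()
  antilogo <- empty_logo_df()
  for (j in which(pm$usable)) {
    off <- PEPTIDE_OFFSETS[j]
    if (off == 0L) next
    eff <- pm$effective_n[j]
    Rj <- position_information(pm$p[j, ])
    e <- eff * background
    o <- counts$counts[j, ]
    cells <- lapply(AA_ALPHABET20, function(a) chisq_cell(o[[a]], eff, background[[a]]))
    pvals <- vapply(cells, `[[`, numeric(1), "p_value")
    stat <- vapply(cells, `[[`, numeric(1), "statistic")
    dir <- vapply(cells, `[[`, character(1), "direction")
    sig_en <- which(pvals < alpha & dir == "enriched")
    sig_de <- which(pvals < alpha & dir == "depleted")
    if (length(sig_en)) {
      logo <- rbind(logo, data.frame(
        offset = off, residue = AA_ALPHABET20[sig_en],
        height = pm$p[j, sig_en] * Rj, statistic = stat[sig_en],
        p_value = pvals[sig_en], direction = "enriched",
        stringsAsFactors = FALSE))
    }
    if (length(sig_de)) {
      # deficit distribution over the significantly depleted residues
      deficit <- rep(0, 20)
      deficit[sig_de] <- pmax(e[sig_de] - o[sig_de], 0)
      R_dep <- if (sum(deficit) > 0) position_information(deficit / sum(deficit)) else 0
      antilogo <- rbind(antilogo, data.frame(
        offset = off, residue = AA_ALPHABET20[sig_de],
        height = (e[sig_de] - o[sig_de]) / eff * R_dep, statistic = stat[sig_de],
        p_value = pvals[sig_de], direction = "depleted",
        stringsAsFactors = FALSE))
    }
  }
  rownames(logo) <- rownames(antilogo) <- NULL
  structure(list(logo = logo, antilogo = antilogo, alpha = alpha),
            class = "logo_model")
}

#' Classify a kinase as serine/threonine or tyrosine directed
#'
#' A peptide set is classed `"Y"` when strictly more than half of its center
#' residues are tyrosine, otherwise `"ST"` (ties favor the majority class of
#' the kinome). Rankings are restricted to the class matching a query's
#' center residue.
#'
#' @param peptides Character vector of centralized 13-mers.
#' @return `"ST"` or `"Y"`.
#' @export
kinase_class <- function(peptides) {
  if (length(peptides) == 0L)
    km_stop("kinamotif_empty", "cannot classify an empty peptide set")
  centers <- substr(toupper(peptides), CENTER_IDX, CENTER_IDX)
  if (sum(centers == "Y") > length(centers) / 2) "Y" else "ST"
}

#' Build a complete kinase profile from its peptide set
#'
#' Assembles the full per-kinase model: residue counts, position-specific
#' probabilities (pseudocount 0), the Shannon information matrix of letter
#' heights `h(i,j) = p(i,j) * R(j)`, and the chi-square-filtered
#' logo/anti-logo. The information matrix is left unfiltered -- the
#' significance filter affects only the displayed logo model, while the
#' dense heights matrix (including offset 0) is what the kinase ranker dots
#' queries against.
#'
#' @param kinase Kinase name.
#' @param peptides Character vector of centralized 13-mers.
#' @param background Named 20-vector of background probabilities (e.g. from
#'   [background_from_dataset()] or [uniform_background()]).
#' @param alpha Chi-square significance level for the logo filter.
#' @param min_n Minimum peptides required for a profile (default 30).
#' @param pseudocount Smoothing for the probability matrix (default 0).
#' @return An object of class `kinase_profile`.
#' @export
build_profile <- function(kinase, peptides, background = uniform_background(),
                          alpha = 1e-4, min_n = 30, pseudocount = 0) {
  n <- length(peptides)
  if (n < min_n)
    km_stop("kinamotif_too_few",
            "kinase '%s' has %d peptides; a profile requires at least %d",
            kinase, n, min_n, data = list(n = n, min_n = min_n))
  cm <- count_matrix(peptides)
  pm <- probability_matrix(cm, pseudocount = pseudocount)
  R <- vapply(1:13, function(j)
    if (pm$usable[j]) position_information(pm$p[j, ]) else 0, numeric(1))
  names(R) <- as.character(PEPTIDE_OFFSETS)
  heights <- pm$p * R  # row-wise scaling: h(i,j) = p(i,j) * R(j)
  lm <- build_logo(cm, background, alpha = alpha)
  structure(list(
    kinase = kinase, n = n, class = kinase_class(peptides), alpha = alpha,
    counts = cm$counts, j_counts = cm$j_counts,
    effective_n = pm$effective_n, probabilities = pm$p, R = R,
    heights = heights, logo = lm$logo, antilogo = lm$antilogo
  ), class = "kinase_profile")
}

#' @export
print.kinase_profile <- function(x, ...) {
  cat(sprintf("Kinase profile: %s (%s class, n = %d peptides)\n",
              x$kinase, x$class, x$n))
  cat(sprintf("  total information: %.2f bits over 13 positions\n", sum(x$R)))
  cat(sprintf("  logo: %d enriched cells; anti-logo: %d depleted cells (alpha = %g)\n",
              nrow(x$logo), nrow(x$antilogo), x$alpha))
  invisible(x)
}
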