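#' Fit kinase substrate-preference profiles from phosphosite data
#'
#' The main modelling entry point. Takes a kinase-to-phosphosite table plus
#' substrate sequences, extracts the centralized 13-mer window around every
#' site (with `J` padding at protein termini), and builds one profile per
#' kinase: residue counts, position-specific probabilities, the Shannon
#' information matrix whose letter heights `h(i,j) = p(i,j) * R(j)` are the
#' scoring matrix, and the chi-square-filtered logo/anti-logo of favored and
#' disfavored residues.
#'
#' Rows that cannot be resolved (unknown accession, position beyond the
#' sequence, site residue not S/T/Y) are skipped and tallied; kinases with
#' fewer than `min_n` usable peptides are dropped and recorded. The fit
#' fails only if no kinase reaches `min_n`.
#'
#' @param sites Site table: a data.frame with columns `kinase`, `accession`,
#'   `position` and/or `peptide`, or a path to a TSV/CSV read via
#'   [read_site_table()].
#' @param sequences Substrate sequences: a data.frame from [read_fasta()], a
#'   named character vector, or a FASTA path. Not needed when every row
#'   carries a pre-centralized peptide.
#' @param alpha Chi-square significance level for the logo filter
#'   (default 0.0001).
#' @param min_n Minimum peptides per kinase (default 30).
#' @param pseudocount Probability-matrix smoothing (default 0).
#' @param background `"dataset"` (pooled flanking-residue frequencies across
#'   all kinases, the default), `"uniform"`, or a named numeric 20-vector.
#' @return An object of class `kinase_profiles`: a list with `profiles`
#'   (named list of `kinase_profile`), `background`, `dropped` (named
#'   integer vector, peptide counts of kinases below `min_n`), `skipped`
#'   (row-skip tally), and the settings used. Methods: `print`, `summary`,
#'   `coef`, `predict`, `plot`, `simulate`, `residuals`.
#' @examples
#' bench <- make_benchmark(k = 3, n_per_kinase = 30, seed = 42)
#' fit <- fit_kinase_profiles(bench$sites, bench$fasta)
#' summary(fit)
#' predict(fit, consensus_peptide(bench$pwms[[1]]))
#' @export
fit_kinase_profiles <- function(sites, sequences = NULL, alpha = 1e-4,
                                min_n = 30, pseudocount = 0,
                                background = "dataset") {
  cl <- match.call()
  if (is.character(sites) && length(sites) == 1L) sites <- read_site_table(sites)
  if (is.character(sequences) && length(sequences) == 1L &&
      is.null(names(sequences)) && file.exists(sequences))
    sequences <- read_fasta(sequences)
  built <- build_substrate_sets(sites, sequences)
  sets <- built$sets
  if (length(sets) == 0L)
    km_stop("kinamotif_empty", "no phosphosites could be resolved into peptides")
  bg <- resolve_background(background, unlist(sets, use.names = FALSE))
  ns <- vapply(sets, length, integer(1))
  eligible <- names(sets)[ns >= min_n]
  dropped <- ns[ns < min_n]
  if (length(eligible) == 0L)
    km_stop("kinamotif_too_few",
            "no kinase reached the minimum of %d peptides (max observed: %d)",
            min_n, max(ns))
  profiles <- lapply(eligible, function(k)
    build_profile(k, sets[[k]], background = bg, alpha = alpha,
                  min_n = min_n, pseudocount = pseudocount))
  names(profiles) <- eligible
  structure(list(
    profiles = profiles, background = bg, dropped = dropped,
    skipped = built$skipped, alpha = alpha, min_n = min_n,
    pseudocount = pseudocount, call = cl
  ), class = "kinase_profiles")
}

resolve_background <- function(background, all_peptides) {
  if (is.numeric(background)) {
    if (length(background) != 20L)
      km_stop("kinamotif_argument", "a background vector must have 20 entries")
    if (any(background <= 0) || abs(sum(background) - 1) > 1e-9)
      km_stop("kinamotif_argument",
              "background probabilities must be positive and sum to 1")
    return(stats::setNames(as.numeric(background), AA_ALPHABET20))
  }
  switch(match.arg(background, c("dataset", "uniform")),
         dataset = background_from_dataset(all_peptides),
         uniform = uniform_background())
}

#' @export
print.kinase_profiles <- function(x, ...) {
  cat(sprintf("Kinase substrate-preference profiles: %d kinases (%d ST, %d Y)\n",
              length(x$profiles),
              sum(vapply(x$profiles, `[[`, character(1), "class") == "ST"),
              sum(vapply(x$profiles, `[[`, character(1), "class") == "Y")))
  cat(sprintf("  settings: alpha = %g, min_n = %d, pseudocount = %g\n",
              x$alpha, x$min_n, x$pseudocount))
  if (length(x$dropped))
    cat(sprintf("  dropped below min_n: %s\n",
                paste(sprintf("%s (%d)", names(x$dropped), x$dropped),
                      collapse = ", ")))
  if (any(x$skipped > 0))
    cat(sprintf("  skipped rows: %s\n",
                paste(sprintf("%s %d", names(x$skipped), x$skipped),
                      collapse = ", ")))
  invisible(x)
}

#' Summarize a kinase-profiles fit
#'
#' @param object A `kinase_profiles` fit.
#' @param ... Unused.
#' @return A data.frame with one row per kinase: class, peptide count, total
#'   information across positions (bits), the most informative flanking
#'   offset, and logo/anti-logo cell counts.
#' @export
summary.kinase_profiles <- function(object, ...) {
  rows <- lapply(object$profiles, function(p) {
    flank <- p$R[as.character(PEPTIDE_OFFSETS[PEPTIDE_OFFSETS != 0])]
    data.frame(kinase = p$kinase, class = p$class, n = p$n,
               total_bits = sum(p$R),
               top_offset = as.integer(names(which.max(flank))),
               logo_cells = nrow(p$logo), antilogo_cells = nrow(p$antilogo),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(-out$total_bits), ]
}

#' Extract scoring matrices from a fit
#'
#' Returns the dense information-content matrix (letter heights, bits) that
#' queries are scored against.
#'
#' @param object A `kinase_profiles` fit.
#' @param kinase Kinase name; if `NULL`, a named list of all matrices.
#' @param ... Unused.
#' @return A 13x20 matrix, or a named list of them.
#' @export
coef.kinase_profiles <- function(object, kinase = NULL, ...) {
  if (is.null(kinase)) return(lapply(object$profiles, `[[`, "heights"))
  get_profile(object, kinase)$heights
}

get_profile <- function(object, kinase) {
  if (!kinase %in% names(object$profiles))
    km_stop("kinamotif_unknown_kinase",
            "unknown kinase '%s'; available: %s", kinase,
            paste(names(object$profiles), collapse = ", "))
  object$profiles[[kinase]]
}

#' Rank kinases for query phosphopeptides
#'
#' @param object A `kinase_profiles` fit.
#' @param peptide One or more centralized 13-mer queries.
#' @param restrict `"auto"` (restrict to the class of each query's center
#'   residue) or `"all"`.
#' @param ... Unused.
#' @return A `kinase_ranking` data.frame for a single query; a named list of
#'   them for several.
#' @export
predict.kinase_profiles <- function(object, peptide, restrict = "auto", ...) {
  if (length(peptide) == 1L)
    return(rank_kinases(peptide, object$profiles, restrict = restrict))
  stats::setNames(
    lapply(peptide, rank_kinases, profiles = object$profiles, restrict = restrict),
    peptide)
}

#' Simulate peptides from fitted profiles
#'
#' Draws centralized 13-mers from a fitted kinase's position-specific
#' probability matrix (offsets observed only as `J` in the training data
#' are emitted as `J`).
#'
#' @param object A `kinase_profiles` fit.
#' @param nsim Number of peptides per kinase.
#' @param seed Optional integer seed; the caller's RNG state is preserved.
#' @param kinase Kinase name; if `NULL`, simulates for every kinase.
#' @param ... Unused.
#' @return Character vector of peptides, or a named list of them.
#' @export
simulate.kinase_profiles <- function(object, nsim = 1, seed = NULL,
                                     kinase = NULL, ...) {
  if (is.null(kinase)) {
    return(with_seed(seed, stats::setNames(
      lapply(object$profiles, simulate_profile, nsim = nsim),
      names(object$profiles))))
  }
  with_seed(seed, simulate_profile(get_profile(object, kinase), nsim))
}

simulate_profile <- function(p, nsim) {
  draws <- vapply(1:13, function(j) {
    if (sum(p$probabilities[j, ]) == 0) rep("J", nsim)
    else sample(AA_ALPHABET20, nsim, replace = TRUE, prob = p$probabilities[j, ])
  }, character(nsim))
  if (nsim == 1L) draws <- matrix(draws, nrow = 1)
  apply(draws, 1, paste, collapse = "")
}

#' Pearson residuals of observed counts against the background
#'
#' For one kinase, `(observed - expected) / sqrt(expected)` per
#' (offset, residue) cell with `expected = effective_n * b`, the same
#' comparison the chi-square logo filter tests. Positive cells are
#' candidate logo residues, negative cells candidate anti-logo residues.
#'
#' @param object A `kinase_profiles` fit.
#' @param kinase Kinase name.
#' @param ... Unused.
#' @return A 13x20 numeric matrix.
#' @export
residuals.kinase_profiles <- function(object, kinase, ...) {
  p <- get_profile(object, kinase)
  e <- outer(p$effective_n, object$background)
  r <- empty_matrix()
  ok <- p$effective_n > 0
  r[ok, ] <- (p$counts[ok, , drop = FALSE] - e[ok, , drop = FALSE]) /
    sqrt(e[ok, , drop = FALSE])
  r
}
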