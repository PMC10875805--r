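#' One-hot (Boolean) encoding of a centralized peptide
#'
#' Encodes a 13-mer as the Boolean 13 x 20 matrix `x` with `x(i,j) = 1` iff
#' the residue at offset `j` is amino acid `i`; rows for `J` placeholders
#' are all zero, so each row carries at most a single 1.
#'
#' @param peptide Centralized 13-mer string.
#' @return A 13x20 numeric 0/1 matrix (rows = offsets -6..6, columns =
#'   amino acids in canonical order).
#' @export
encode_onehot <- function(peptide) {
  peptide <- validate_peptide(peptide)
  chars <- peptide_chars(peptide)
  x <- empty_matrix()
  for (j in 1:13) if (chars[j] != "J") x[j, chars[j]] <- 1
  x
}

#' Dot-product match score of a query against one kinase
#'
#' The kinase-match scalar is the sum of products of the corresponding
#' elements of the query's Boolean encoding and the kinase's
#' information-content matrix over all 13 positions -- equivalently, the sum
#' over non-`J` offsets of the profile's letter height at the query's
#' residue. Scores are in bits; `J` offsets contribute exactly 0.
#'
#' @param x 13x20 Boolean matrix from [encode_onehot()].
#' @param profile A `kinase_profile`.
#' @return Non-negative numeric score.
#' @export
score_kinase <- function(x, profile) {
  h <- profile$heights
  if (!identical(dim(x), dim(h)))
    km_stop("kinamotif_argument", "query encoding and profile matrix dimensions differ")
  sum(x * h)
}

#' Rank kinases for a query phosphopeptide
#'
#' Scores a centralized 13-mer against every kinase profile and returns the
#' rank-ordered list of kinases with their dot-product scores. With
#' `restrict = "auto"` (the default) only profiles whose class matches the
#' query's center residue are scored: an S/T-centered query is ranked
#' against serine/threonine kinases only, a Y-centered query against
#' tyrosine kinases. Ties are broken lexicographically by kinase name so
#' the ordering is deterministic; ranks are dense 1..K.
#'
#' @param peptide Centralized 13-mer query.
#' @param profiles Named list of `kinase_profile` objects, or a
#'   `kinase_profiles` fit.
#' @param restrict `"auto"` (class of the query center) or `"all"`.
#' @return A data.frame of class `kinase_ranking` with columns `rank`,
#'   `kinase`, `class`, `n`, `score`, plus attributes `query` and
#'   `restricted_class`.
#' @export
rank_kinases <- function(peptide, profiles, restrict = c("auto", "all")) {
  restrict <- match.arg(restrict)
  if (inherits(profiles, "kinase_profiles")) profiles <- profiles$profiles
  if (inherits(profiles, "kinase_profile")) profiles <- list(profiles)
  if (length(profiles) == 0L)
    km_stop("kinamotif_empty", "no kinase profiles supplied")
  peptide <- validate_peptide(peptide)
  center <- substr(peptide, CENTER_IDX, CENTER_IDX)
  query_class <- if (center == "Y") "Y" else "ST"
  classes <- vapply(profiles, `[[`, character(1), "class")
  keep <- if (restrict == "auto") classes == query_class else rep(TRUE, length(profiles))
  restricted_class <- if (restrict == "auto") query_class else "all"
  if (!any(keep))
    km_stop("kinamotif_empty",
            "no eligible kinases: query center '%s' implies class '%s' but no profile matches",
            center, query_class)
  profiles <- profiles[keep]
  x <- encode_onehot(peptide)
  scores <- vapply(profiles, function(p) score_kinase(x, p), numeric(1))
  kin <- vapply(profiles, `[[`, character(1), "kinase")
  ord <- order(-scores, kin, method = "radix")
  out <- data.frame(
    rank = seq_along(ord),
    kinase = kin[ord],
    class = vapply(profiles, `[[`, character(1), "class")[ord],
    n = vapply(profiles, function(p) as.integer(p$n), integer(1))[ord],
    score = scores[ord],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "query") <- peptide
  attr(out, "restricted_class") <- restricted_class
  class(out) <- c("kinase_ranking", "data.frame")
  out
}

#' @export
print.kinase_ranking <- function(x, n = 10, ...) {
  cat(sprintf("Kinase ranking for query %s (class restriction: %s; %d kinases)\n",
              attr(x, "query"), attr(x, "restricted_class"), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), n), row.names = FALSE,
                   digits = 6)
  if (nrow(x) > n) cat(sprintf("  ... and %d more\n", nrow(x) - n))
  invisible(x)
}

csv_field <- function(v) {
  needs <- grepl('[",\n]', v)
  v[needs] <- paste0('"', gsub('"', '""', v[needs]), '"')
  v
}

#' Export a kinase ranking as CSV
#'
#' Writes the ranked list with header `rank,kinase,class,n,score`, one row
#' per kinase in rank order, scores rendered with 6 significant digits.
#' Fields containing commas or quotes are quoted per CSV convention.
#'
#' @param result A `kinase_ranking` from [rank_kinases()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_csv <- function(result, path) {
  if (!is.data.frame(result) || nrow(result) == 0L)
    km_stop("kinamotif_empty", "cannot export an empty ranking")
  lines <- c("rank,kinase,class,n,score",
             sprintf("%d,%s,%s,%d,%s",
                     result$rank, csv_field(result$kinase),
                     csv_field(result$class), result$n,
                     formatC(result$score, digits = 6, format = "g")))
  con <- tryCatch(file(path, "w"),
                  error = function(e)
                    km_stop("kinamotif_io", "cannot write to '%s'", path))
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
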