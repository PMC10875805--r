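#' Read substrate protein sequences from a FASTA file
#'
#' Reads a FASTA file of substrate sequences and returns one record per
#' entry. The accession is the first whitespace-delimited token of the
#' header; UniProt-style pipe-delimited headers (`sp|P12345|NAME`) yield the
#' second pipe field. Sequences are uppercased and must consist only of the
#' 20 canonical amino-acid codes.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `accession` and `sequence`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">sp|P01234|TEST", "MS", "TY"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path))
    km_stop("kinamotif_io", "FASTA file not found: %s", path)
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L)
    km_stop("kinamotif_io", "FASTA file '%s' contains no records", path)
  headers <- names(seqs)
  acc <- vapply(headers, function(h) {
    tok <- strsplit(h, "[[:space:]]+")[[1]][1]
    parts <- strsplit(tok, "|", fixed = TRUE)[[1]]
    if (length(parts) >= 2L) parts[2] else tok
  }, character(1), USE.NAMES = FALSE)
  sq <- toupper(as.character(seqs))
  ok_chars <- paste0("^[", paste(AA_ALPHABET20, collapse = ""), "]+$")
  for (i in seq_along(sq)) {
    if (!nzchar(sq[i]))
      km_stop("kinamotif_invalid_sequence", "record '%s' has an empty sequence", acc[i])
    if (!grepl(ok_chars, sq[i])) {
      bad <- setdiff(unique(strsplit(sq[i], "")[[1]]), AA_ALPHABET20)
      km_stop("kinamotif_invalid_sequence",
              "record '%s' contains non-canonical character(s): %s",
              acc[i], paste(bad, collapse = ", "),
              data = list(accession = acc[i], characters = bad))
    }
  }
  data.frame(accession = acc, sequence = sq, stringsAsFactors = FALSE)
}

#' Read a kinase phosphosite table
#'
#' Reads a delimited table mapping kinases to phosphosites. The delimiter is
#' sniffed from the file extension (`.csv` means comma, anything else tab),
#' falling back to whichever of tab/comma occurs in the header line. The
#' header must contain either `kinase`, `accession` and `position` columns
#' (1-based site position within the substrate), or `kinase` and `peptide`
#' columns carrying pre-centralized 13-mers.
#'
#' @param path Path to the TSV/CSV site table.
#' @return A data.frame with columns `kinase`, `accession`, `position`,
#'   `peptide` (`NA` where a column was absent).
#' @export
read_site_table <- function(path) {
  if (!file.exists(path))
    km_stop("kinamotif_io", "site table not found: %s", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L)
    km_stop("kinamotif_io", "site table '%s' is empty", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  if (!grepl(sep, first, fixed = TRUE)) {
    sep <- if (grepl(",", first, fixed = TRUE)) "," else "\t"
  }
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          quote = "\"", comment.char = "", stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  has_pos <- all(c("kinase", "accession", "position") %in% names(df))
  has_pep <- all(c("kinase", "peptide") %in% names(df))
  if (!has_pos && !has_pep)
    km_stop("kinamotif_io",
            "site table needs columns kinase+accession+position or kinase+peptide; found: %s",
            paste(names(df), collapse = ", "))
  out <- data.frame(
    kinase = df$kinase,
    accession = if ("accession" %in% names(df)) df$accession else NA_character_,
    position = NA_integer_,
    peptide = if ("peptide" %in% names(df)) toupper(df$peptide) else NA_character_,
    stringsAsFactors = FALSE
  )
  if ("position" %in% names(df)) {
    pos <- suppressWarnings(as.integer(df$position))
    bad <- which(is.na(pos) & !is.na(df$position) & nzchar(df$position))
    if (length(bad))
      km_stop("kinamotif_io", "non-integer position on data row(s): %s",
              paste(utils::head(bad, 5), collapse = ", "))
    if (any(!is.na(pos) & pos < 1L))
      km_stop("kinamotif_io", "1-based site positions must be >= 1 (row %d)",
              which(pos < 1L)[1])
    out$position <- pos
  }
  # pre-centralized peptides must satisfy the 13-mer invariants up front
  for (i in which(!is.na(out$peptide) & nzchar(out$peptide)))
    out$peptide[i] <- validate_peptide(out$peptide[i])
  out
}

#' Extract the centralized 13-mer window around a phosphosite
#'
#' Returns the 13-residue window `sequence[position - 6 ... position + 6]`
#' around a 1-based site position, with every offset falling outside the
#' protein replaced by the placeholder `"J"` (terminal overhang padding).
#' The site residue must be a phosphoacceptor (S, T or Y).
#'
#' @param sequence Amino-acid string.
#' @param position 1-based position of the phosphoacceptor.
#' @return A centralized 13-mer string.
#' @examples
#' centralize("STY", 1)  # "JJJJJJSTYJJJJ"
#' @export
centralize <- function(sequence, position) {
  sequence <- toupper(sequence)
  len <- nchar(sequence)
  position <- as.integer(position)
  if (is.na(position) || position < 1L || position > len)
    km_stop("kinamotif_position", "position %s is outside sequence of length %d",
            position, len)
  center <- substr(sequence, position, position)
  if (!center %in% ACCEPTORS)
    km_stop("kinamotif_invalid_center",
            "residue '%s' at position %d is not a phosphoacceptor (S/T/Y)",
            center, position, data = list(residue = center))
  chars <- strsplit(sequence, "")[[1]]
  idx <- position + PEPTIDE_OFFSETS
  win <- ifelse(idx >= 1L & idx <= len, chars[pmax(pmin(idx, len), 1L)], "J")
  paste(win, collapse = "")
}

#' Group centralized peptides by kinase
#'
#' Joins a phosphosite table against substrate sequences, centralizes each
#' site into a 13-mer and groups the peptides by kinase. Rows carrying a
#' pre-centralized `peptide` bypass the sequence lookup. Rows that cannot be
#' resolved -- unknown accession, position beyond the sequence, or a site
#' residue that is not S/T/Y -- are skipped and tallied rather than aborting
#' the build, since large curated tables routinely contain isoform and
#' sequence-version mismatches. Duplicate observations of the same site are
#' retained as separate counts.
#'
#' @param rows Site table data.frame as returned by [read_site_table()].
#' @param records Sequence data.frame as returned by [read_fasta()], or a
#'   named character vector of sequences. May be `NULL` when every row
#'   carries a peptide.
#' @return A list with `sets` (named list: kinase -> character vector of
#'   13-mers) and `skipped` (named integer vector of skip counts by reason:
#'   `unresolved_accession`, `position_out_of_range`, `not_acceptor`).
#' @export
build_substrate_sets <- function(rows, records = NULL) {
  seqmap <- character(0)
  if (!is.null(records)) {
    if (is.data.frame(records)) {
      seqmap <- stats::setNames(records$sequence, records$accession)
    } else {
      seqmap <- stats::setNames(toupper(as.character(records)), names(records))
    }
  }
  skipped <- c(unresolved_accession = 0L, position_out_of_range = 0L,
               not_acceptor = 0L)
  sets <- list()
  for (i in seq_len(nrow(rows))) {
    pep <- rows$peptide[i]
    if (is.na(pep) || !nzchar(pep)) {
      acc <- rows$accession[i]
      if (is.na(acc) || !acc %in% names(seqmap)) {
        skipped["unresolved_accession"] <- skipped["unresolved_accession"] + 1L
        next
      }
      pep <- tryCatch(
        centralize(seqmap[[acc]], rows$position[i]),
        kinamotif_position = function(e) {
          skipped["position_out_of_range"] <<- skipped["position_out_of_range"] + 1L
          NULL
        },
        kinamotif_invalid_center = function(e) {
          skipped["not_acceptor"] <<- skipped["not_acceptor"] + 1L
          NULL
        })
      if (is.null(pep)) next
    }
    k <- rows$kinase[i]
    sets[[k]] <- c(sets[[k]], pep)
  }
  list(sets = sets, skipped = skipped)
}

PROFILE_FORMAT_VERSION <- 1L

# reals are serialized as %.17g strings: 17 significant digits round-trip
# IEEE doubles exactly, which plain JSON number formatting does not
num_out <- function(x) {
  s <- sprintf("%.17g", x)
  if (is.matrix(x)) dim(s) <- dim(x)
  s
}
num_in <- function(x) as.numeric(unlist(x))

logo_out <- function(d) {
  d$height <- sprintf("%.17g", d$height)
  d$statistic <- sprintf("%.17g", d$statistic)
  d$p_value <- sprintf("%.17g", d$p_value)
  d
}

profile_to_store <- function(p) {
  list(
    kinase = p$kinase,
    n = p$n,
    class = p$class,
    alpha = sprintf("%.17g", p$alpha),
    counts = unname(p$counts),
    j_counts = unname(p$j_counts),
    effective_n = unname(p$effective_n),
    probabilities = num_out(unname(p$probabilities)),
    R = num_out(unname(p$R)),
    information_matrix = num_out(unname(p$heights)),
    logo = logo_out(p$logo),
    antilogo = logo_out(p$antilogo)
  )
}

# `s` is a non-simplified jsonlite list: matrices arrive as lists of rows
store_to_profile <- function(s) {
  as_mat <- function(m) {
    m <- do.call(rbind, lapply(m, num_in))
    if (!identical(dim(m), c(13L, 20L)))
      km_stop("kinamotif_io", "profile matrix is not 13x20")
    dimnames(m) <- list(as.character(PEPTIDE_OFFSETS), AA_ALPHABET20)
    m
  }
  as_logo_df <- function(d) {
    if (is.null(d) || length(d) == 0) return(empty_logo_df())
    out <- empty_logo_df()
    for (row in d) {
      out <- rbind(out, data.frame(
        offset = as.integer(row$offset), residue = row$residue,
        height = as.numeric(row$height), statistic = as.numeric(row$statistic),
        p_value = as.numeric(row$p_value), direction = row$direction,
        stringsAsFactors = FALSE))
    }
    rownames(out) <- NULL
    out
  }
  offs <- as.character(PEPTIDE_OFFSETS)
  structure(list(
    kinase = s$kinase,
    n = as.integer(s$n),
    class = s$class,
    alpha = as.numeric(s$alpha),
    counts = as_mat(s$counts),
    j_counts = stats::setNames(as.integer(unlist(s$j_counts)), offs),
    effective_n = stats::setNames(as.integer(unlist(s$effective_n)), offs),
    probabilities = as_mat(s$probabilities),
    R = stats::setNames(num_in(s$R), offs),
    heights = as_mat(s$information_matrix),
    logo = as_logo_df(s$logo),
    antilogo = as_logo_df(s$antilogo)
  ), class = "kinase_profile")
}

#' Write kinase profiles to a JSON store
#'
#' Serializes a list of kinase profiles to a single JSON document. Real
#' numbers are written at full precision so that [read_profiles()] restores
#' every matrix element bit-for-bit.
#'
#' @param profiles A `kinase_profiles` fit, or a (possibly named) list of
#'   `kinase_profile` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_profiles()]
#' @export
write_profiles <- function(profiles, path) {
  if (inherits(profiles, "kinase_profiles")) profiles <- profiles$profiles
  if (inherits(profiles, "kinase_profile")) profiles <- list(profiles)
  if (length(profiles) == 0L)
    km_stop("kinamotif_io", "refusing to write an empty profile store")
  doc <- list(
    format_version = PROFILE_FORMAT_VERSION,
    alphabet = paste(AA_ALPHABET20, collapse = ""),
    offsets = PEPTIDE_OFFSETS,
    profiles = lapply(unname(profiles), profile_to_store)
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, na = "null")
  writeLines(json, path)
  invisible(path)
}

#' Read kinase profiles from a JSON store
#'
#' @param path Path to a store written by [write_profiles()].
#' @return A named list of `kinase_profile` objects.
#' @export
read_profiles <- function(path) {
  if (!file.exists(path))
    km_stop("kinamotif_io", "profile store not found: %s", path)
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    km_stop("kinamotif_io", "malformed profile store '%s': %s",
                            path, conditionMessage(e)))
  if (!identical(doc$alphabet, paste(AA_ALPHABET20, collapse = "")))
    km_stop("kinamotif_io",
            "profile store alphabet '%s' does not match the canonical order",
            doc$alphabet)
  if (!identical(as.integer(unlist(doc$offsets)), PEPTIDE_OFFSETS))
    km_stop("kinamotif_io", "profile store offset range is not -6..6")
  profs <- lapply(doc$profiles, store_to_profile)
  stats::setNames(profs, vapply(profs, `[[`, character(1), "kinase"))
}
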