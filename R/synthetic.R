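# run code with a private RNG stream, leaving the caller's untouched
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

new_pwm <- function(name, probs, center_class, signal) {
  dimnames(probs) <- list(as.character(PEPTIDE_OFFSETS), AA_ALPHABET20)
  structure(list(name = name, probs = probs, center_class = center_class,
                 signal = signal), class = "generator_pwm")
}

uniform_column <- function() rep(1 / 20, 20)

#' Preset position weight matrices for classic kinase archetypes
#'
#' Builds a generator PWM emulating one of the classic substrate-preference
#' archetypes: `"basophilic"` (basic R/K at -3 and -2, the PKA pattern),
#' `"proline_directed"` (P at +1, the CDK/MAPK pattern), `"acidophilic"`
#' (acidic D/E at +1 and +3, the CK2 pattern) and `"tyrosine_acidic"`
#' (Y acceptor with D/E across -3..+3, an EGFR-like tyrosine kinase).
#' At each signal offset a fraction `sharpness` of the column's mass sits on
#' the signature residue(s) (split equally within a pair), the remainder
#' uniform over the 20 amino acids; non-signal columns are uniform. The
#' acceptor column splits its mass over S/T for the serine/threonine
#' presets and is all-Y for the tyrosine preset.
#'
#' @param name Preset name.
#' @param sharpness Signal mass in (0, 1].
#' @return A `generator_pwm` with fields `name`, `probs` (13x20, columns sum
#'   to 1 within each offset row), `center_class` and `signal` (data.frame
#'   of planted (offset, residue) cells).
#' @export
preset_pwm <- function(name = c("basophilic", "proline_directed",
                                "acidophilic", "tyrosine_acidic"),
                       sharpness = 0.9) {
  name <- match.arg(name)
  if (sharpness <= 0 || sharpness > 1)
    km_stop("kinamotif_argument",
            "sharpness must be in (0, 1]; %g degenerates to background", sharpness)
  spots <- switch(name,
    basophilic      = list(offsets = c(-3L, -2L), residues = c("R", "K")),
    proline_directed = list(offsets = 1L, residues = "P"),
    acidophilic     = list(offsets = c(1L, 3L), residues = c("D", "E")),
    tyrosine_acidic = list(offsets = c(-3L, -2L, -1L, 1L, 2L, 3L),
                           residues = c("D", "E")))
  center_class <- if (name == "tyrosine_acidic") "Y" else "ST"
  probs <- matrix(rep(uniform_column(), each = 13), nrow = 13)
  dimnames(probs) <- list(as.character(PEPTIDE_OFFSETS), AA_ALPHABET20)
  for (off in spots$offsets) {
    j <- as.character(off)
    probs[j, ] <- (1 - sharpness) / 20
    probs[j, spots$residues] <- probs[j, spots$residues] +
      sharpness / length(spots$residues)
  }
  probs["0", ] <- 0
  if (center_class == "Y") probs["0", "Y"] <- 1
  else probs["0", c("S", "T")] <- 0.5
  signal <- expand.grid(offset = spots$offsets, residue = spots$residues,
                        stringsAsFactors = FALSE)
  new_pwm(name, probs, center_class, signal)
}

#' Random sharp position weight matrix
#'
#' Draws a PWM with `n_signal` randomly chosen flanking offsets, each
#' carrying probability `sharpness + (1 - sharpness)/20` on one randomly
#' chosen dominant residue; all other columns are uniform. Uses the current
#' RNG stream (set a seed beforehand for reproducibility). Used to emulate a
#' panel of distinct kinases in self-ranking benchmarks.
#'
#' @param name PWM name.
#' @param sharpness Signal mass in (0, 1].
#' @param n_signal Number of signal offsets (1-12).
#' @param center_class `"ST"` or `"Y"`.
#' @return A `generator_pwm`.
#' @export
random_pwm <- function(name, sharpness = 0.9, n_signal = 3,
                       center_class = c("ST", "Y")) {
  center_class <- match.arg(center_class)
  if (sharpness <= 0 || sharpness > 1)
    km_stop("kinamotif_argument", "sharpness must be in (0, 1]")
  if (n_signal < 1 || n_signal > 12)
    km_stop("kinamotif_argument", "n_signal must be between 1 and 12")
  probs <- matrix(rep(uniform_column(), each = 13), nrow = 13)
  dimnames(probs) <- list(as.character(PEPTIDE_OFFSETS), AA_ALPHABET20)
  offs <- sample(PEPTIDE_OFFSETS[PEPTIDE_OFFSETS != 0L], n_signal)
  res <- sample(AA_ALPHABET20, n_signal, replace = TRUE)
  for (i in seq_len(n_signal)) {
    j <- as.character(offs[i])
    probs[j, ] <- (1 - sharpness) / 20
    probs[j, res[i]] <- probs[j, res[i]] + sharpness
  }
  probs["0", ] <- 0
  if (center_class == "Y") probs["0", "Y"] <- 1
  else probs["0", c("S", "T")] <- 0.5
  new_pwm(name, probs, center_class,
          data.frame(offset = offs, residue = res, stringsAsFactors = FALSE))
}

#' Consensus peptide of a generator PWM
#'
#' The 13-mer taking the highest-probability residue at every offset
#' (ties resolved toward the canonical alphabet order).
#'
#' @param pwm A `generator_pwm`.
#' @return A centralized 13-mer string.
#' @export
consensus_peptide <- function(pwm) {
  paste(AA_ALPHABET20[apply(pwm$probs, 1, which.max)], collapse = "")
}

#' Sample centralized peptides from a generator PWM
#'
#' Draws `n` independent peptides, one residue per offset from that offset's
#' column distribution. All outputs are valid centralized peptides: the
#' acceptor column guarantees an S/T or Y center, and sampled peptides never
#' contain `J`.
#'
#' @param pwm A `generator_pwm`.
#' @param n Number of peptides (>= 1).
#' @param seed Optional integer seed for reproducibility; the caller's RNG
#'   state is preserved.
#' @return Character vector of `n` 13-mers.
#' @export
sample_peptides <- function(pwm, n, seed = NULL) {
  if (n < 1)
    km_stop("kinamotif_argument", "n must be >= 1")
  with_seed(seed, {
    draws <- vapply(1:13, function(j)
      sample(AA_ALPHABET20, n, replace = TRUE, prob = pwm$probs[j, ]),
      character(n))
    if (n == 1L) draws <- matrix(draws, nrow = 1)
    apply(draws, 1, paste, collapse = "")
  })
}

#' Generate an end-to-end benchmark dataset
#'
#' Emits a complete synthetic study: `k` kinases, each with
#' `n_per_kinase` phosphosites. With `pwm_set = "mixed"` (the default) the
#' kinases cycle through the four archetype presets and continue with random
#' sharp PWMs; `"random"` draws `k` i.i.d. sharp three-signal PWMs (the
#' composition used for self-ranking benchmarks -- archetype pairs split
#' their signal mass over two residues and carry too few bits for a fair
#' consensus-recovery contest against sharp single-residue decoys);
#' `"presets"` cycles the archetypes only. Every sampled peptide is spliced into a
#' random 50-residue host protein at a random acceptor position -- including
#' near-terminal positions, so window extraction must reproduce the `J`
#' padding -- and written out in exactly the formats the readers consume: a
#' TSV site table (kinase, accession, position), a FASTA of host proteins,
#' and a JSON truth map recording each site's generating PWM and expected
#' centralized peptide.
#'
#' @param k Number of kinases (>= 2).
#' @param n_per_kinase Sites per kinase.
#' @param seed Integer seed; the caller's RNG state is preserved.
#' @param dir Output directory (created if needed).
#' @param sharpness Signal mass of the generating PWMs.
#' @param pwm_set `"mixed"`, `"random"` or `"presets"` (see above).
#' @return Invisibly, a list with `sites` (path), `fasta` (path), `truth`
#'   (path), `truth_df` (data.frame: kinase, accession, position, peptide,
#'   pwm) and `pwms` (named list of `generator_pwm`).
#' @export
make_benchmark <- function(k, n_per_kinase, seed = 1L, dir = tempfile("bench"),
                           sharpness = 0.9,
                           pwm_set = c("mixed", "random", "presets")) {
  pwm_set <- match.arg(pwm_set)
  if (k < 2)
    km_stop("kinamotif_argument", "a benchmark needs at least 2 kinases")
  if (n_per_kinase < 1)
    km_stop("kinamotif_argument", "n_per_kinase must be >= 1")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  host_len <- 50L
  with_seed(seed, {
    presets <- c("basophilic", "proline_directed", "acidophilic", "tyrosine_acidic")
    pwms <- lapply(seq_len(k), function(i) {
      use_preset <- switch(pwm_set,
                           mixed = i <= length(presets),
                           presets = TRUE,
                           random = FALSE)
      if (use_preset) {
        nm <- presets[(i - 1L) %% length(presets) + 1L]
        pw <- preset_pwm(nm, sharpness = sharpness)
        pw$name <- sprintf("KIN%02d_%s", i, nm)
        pw
      } else {
        random_pwm(sprintf("KIN%02d_random", i), sharpness = sharpness)
      }
    })
    names(pwms) <- vapply(pwms, `[[`, character(1), "name")
    rows <- vector("list", k * n_per_kinase)
    fasta <- character(k * n_per_kinase)
    idx <- 0L
    for (pw in pwms) {
      peps <- sample_peptides(pw, n_per_kinase)
      for (pep in peps) {
        idx <- idx + 1L
        acc <- sprintf("SYN%05d", idx)
        host <- sample(AA_ALPHABET20, host_len, replace = TRUE)
        pos <- sample.int(host_len, 1L)
        chars <- peptide_chars(pep)
        expected <- chars
        for (d in 1:13) {
          at <- pos + PEPTIDE_OFFSETS[d]
          if (at >= 1L && at <= host_len) host[at] <- chars[d]
          else expected[d] <- "J"
        }
        rows[[idx]] <- data.frame(kinase = pw$name, accession = acc,
                                  position = pos,
                                  peptide = paste(expected, collapse = ""),
                                  pwm = pw$name, stringsAsFactors = FALSE)
        fasta[idx] <- paste(host, collapse = "")
        names(fasta)[idx] <- acc
      }
    }
    truth_df <- do.call(rbind, rows)
    sites_path <- file.path(dir, "sites.tsv")
    utils::write.table(truth_df[, c("kinase", "accession", "position")],
                       sites_path, sep = "\t", quote = FALSE, row.names = FALSE)
    fasta_path <- file.path(dir, "substrates.fasta")
    Biostrings::writeXStringSet(Biostrings::AAStringSet(fasta), fasta_path)
    truth_path <- file.path(dir, "truth.json")
    jsonlite::write_json(truth_df, truth_path, auto_unbox = TRUE, digits = NA)
    invisible(list(sites = sites_path, fasta = fasta_path, truth = truth_path,
                   truth_df = truth_df, pwms = pwms))
  })
}
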