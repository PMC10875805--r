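# Independent oracles kept deliberately separate from the implementation.

# brute-force dot product over all 13 x 20 cells
oracle_score <- function(x, heights) {
  s <- 0
  for (j in 1:13) for (i in 1:20) s <- s + x[j, i] * heights[j, i]
  s
}

# chi-square(df = 1) survival function via the normal tail:
# a chi-square(1) variate is the square of a standard normal
oracle_chisq_sf <- function(stat) 2 * stats::pnorm(-sqrt(stat))

# random valid centralized peptide, possibly with terminal J padding
random_peptide <- function(n_j_prefix = 0, n_j_suffix = 0) {
  chars <- sample(kinamotif::AA_ALPHABET20, 13, replace = TRUE)
  chars[7] <- sample(c("S", "T", "Y"), 1)
  if (n_j_prefix > 0) chars[seq_len(n_j_prefix)] <- "J"
  if (n_j_suffix > 0) chars[(13 - n_j_suffix + 1):13] <- "J"
  paste(chars, collapse = "")
}

# random non-negative heights matrix
random_heights <- function() {
  m <- matrix(stats::runif(13 * 20, 0, 4.5), nrow = 13,
              dimnames = list(as.character(-6:6), kinamotif::AA_ALPHABET20))
  m
}

# minimal profile wrapper around a heights matrix for scoring tests
fake_profile <- function(name, heights, class = "ST", n = 30L) {
  structure(list(kinase = name, n = n, class = class, heights = heights),
            class = "kinase_profile")
}
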