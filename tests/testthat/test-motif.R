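test_that("count_matrix tallies residues and J placeholders per offset", {
  cm <- count_matrix(c("JJJJJJSTYJJJJ", "JJJJJJSTYJJJJ"))
  expect_equal(cm$counts["0", "S"], 2)
  expect_equal(cm$counts["1", "T"], 2)
  expect_equal(cm$counts["2", "Y"], 2)
  expect_equal(sum(cm$counts), 6)
  expect_equal(unname(cm$j_counts["-6"]), 2L)
  expect_equal(unname(cm$j_counts["2"]), 0L)
  # residue counts + J count = n at every offset
  expect_equal(unname(rowSums(cm$counts) + cm$j_counts), rep(2, 13))

  one <- count_matrix("ACDEFGSIKLMNP")
  expect_equal(unname(rowSums(one$counts)), rep(1, 13))
  expect_error(count_matrix(character(0)), class = "kinamotif_empty")
})

test_that("background pools flanking residues, excludes center and J, floors at 1e-6", {
  b1 <- background_from_dataset(rep("AAAAAASAAAAAA", 5))
  expect_gt(b1[["A"]], 0.999)
  expect_true(all(b1 > 0))
  expect_equal(sum(b1), 1, tolerance = 1e-12)
  # S appears only at the center here, so its mass is just the floor
  expect_lt(b1[["S"]], 2e-6)

  b2 <- background_from_dataset(c("AAAAAASAAAAAA", "CCCCCCSCCCCCC"))
  expect_equal(b2[["A"]], b2[["C"]])
  expect_equal(b2[["A"]], 0.5, tolerance = 1e-4)
})

test_that("uniform synthetic background converges to 0.05 per residue", {
  pwm <- random_pwm("flat", sharpness = 1e-9, n_signal = 1)
  pwm$probs[] <- 1 / 20  # exactly uniform everywhere, center included
  peps <- sample_peptides(pwm, 2000, seed = 33)
  # centers are uniform too, so class/center handling is irrelevant here:
  # force valid centers to satisfy peptide invariants
  substr(peps, 7, 7) <- "S"
  b <- background_from_dataset(peps)
  se <- sqrt(0.05 * 0.95 / (2000 * 12))
  expect_true(all(abs(b - 0.05) < 3 * se + 1e-6))
})

test_that("probability_matrix normalizes per usable offset", {
  cm <- count_matrix("ACDEFGSIKLMNP")
  pm <- probability_matrix(cm)
  expect_equal(unname(rowSums(pm$p)), rep(1, 13))
  expect_equal(pm$p["0", "S"], 1)
  expect_equal(sum(pm$p == 1), 13)

  # arithmetic: 15 of 30 -> 0.5
  peps <- c(rep("AAARAASAAAAAA", 15), rep("AAAGAASAAAAAA", 15))
  pm2 <- probability_matrix(count_matrix(peps))
  expect_equal(pm2$p["-3", "R"], 0.5)

  # an offset observed only as J is unusable even with a pseudocount
  pm3 <- probability_matrix(count_matrix(rep("JJJJJJSTYAAAA", 30)),
                            pseudocount = 1)
  expect_false(pm3$usable[["-6"]])
  expect_equal(unname(pm3$p["-6", ]), rep(0, 20))
  expect_error(probability_matrix(cm, pseudocount = -1),
               class = "kinamotif_argument")
})

test_that("position information matches closed forms", {
  expect_equal(position_information(c(1, rep(0, 19))), log2(20),
               tolerance = 1e-9)
  expect_equal(position_information(rep(0.05, 20)), 0, tolerance = 1e-9)
  expect_equal(position_information(c(0.5, 0.5, rep(0, 18))), log2(20) - 1,
               tolerance = 1e-9)
  expect_equal(position_information(rep(0, 20)), 0)  # unusable column
  expect_error(position_information(c(0.9, rep(0, 19))),
               class = "kinamotif_argument")
})

test_that("chisq_cell matches hand arithmetic and an independent oracle", {
  r <- chisq_cell(30, 30, 0.05)
  expect_equal(r$statistic, 570)
  expect_equal(r$direction, "enriched")
  expect_lt(r$p_value, 1e-4)

  r2 <- chisq_cell(2, 30, 0.05)
  expect_equal(r2$statistic, 0.5^2 / 1.5 + 0.5^2 / 28.5, tolerance = 1e-12)
  expect_equal(r2$statistic, 0.1754, tolerance = 1e-3)
  expect_equal(r2$direction, "enriched")
  expect_gt(r2$p_value, 1e-4)

  r3 <- chisq_cell(3, 60, 0.05)  # observed equals expected
  expect_equal(r3$statistic, 0)
  expect_equal(r3$p_value, 1)
  expect_equal(r3$direction, "none")

  # p-values agree with the squared-normal survival oracle across a grid
  for (n in c(10, 30, 100, 500)) for (b in c(0.01, 0.05, 0.2, 0.5))
    for (o in unique(round(c(0, n * b, n * b * 2, n / 2, n)))) {
      if (o > n) next
      r <- chisq_cell(o, n, b)
      expect_equal(r$p_value, oracle_chisq_sf(r$statistic),
                   tolerance = 1e-10)
    }
  expect_error(chisq_cell(31, 30, 0.05), class = "kinamotif_argument")
})

test_that("chisq_cell statistic is zero iff observed = expected and grows with |o - e|", {
  n <- 100; b <- 0.2; e <- n * b
  stats_above <- vapply(20:60, function(o) chisq_cell(o, n, b)$statistic,
                        numeric(1))
  expect_equal(stats_above[1], 0)
  expect_true(all(diff(stats_above) > 0))
  stats_below <- vapply(20:0, function(o) chisq_cell(o, n, b)$statistic,
                        numeric(1))
  expect_true(all(diff(stats_below) > 0))
})

test_that("build_logo keeps only significant cells and never offset 0", {
  peps <- rep("RRRRRRSAAAAAA", 30)
  lm <- build_logo(count_matrix(peps), uniform_background(), alpha = 1e-4)
  expect_setequal(
    paste(lm$logo$offset, lm$logo$residue),
    c(paste(-6:-1, "R"), paste(1:6, "A")))
  expect_false(0 %in% lm$logo$offset)
  expect_false(0 %in% lm$antilogo$offset)
  # every enriched cell exceeds its expectation
  expect_true(all(lm$logo$direction == "enriched"))
  # heights are p * R: invariant columns give log2(20)
  expect_equal(lm$logo$height, rep(log2(20), 12), tolerance = 1e-9)

  # uniform peptides produce no significant cells
  pwm <- random_pwm("flat", sharpness = 1e-9)
  pwm$probs[] <- 1 / 20
  peps2 <- sample_peptides(pwm, 30, seed = 5)
  substr(peps2, 7, 7) <- "S"
  lm2 <- build_logo(count_matrix(peps2), uniform_background(), alpha = 1e-4)
  expect_equal(nrow(lm2$logo), 0)
  expect_equal(nrow(lm2$antilogo), 0)

  expect_error(build_logo(count_matrix(peps), uniform_background(), alpha = 0),
               class = "kinamotif_argument")
})

test_that("logo and antilogo are disjoint with opposite directions", {
  set.seed(77)
  for (rep in 1:10) {
    pwm <- random_pwm(sprintf("r%d", rep), sharpness = 0.8, n_signal = 3)
    peps <- sample_peptides(pwm, 120)
    lm <- build_logo(count_matrix(peps), uniform_background())
    key <- function(d) paste(d$offset, d$residue)
    expect_length(intersect(key(lm$logo), key(lm$antilogo)), 0)
    expect_true(all(lm$antilogo$direction == "depleted"))
    expect_true(all(lm$antilogo$height >= 0))
  }
})

test_that("kinase_class follows the center-residue majority with ST ties", {
  expect_equal(kinase_class(c("AAAAAASAAAAAA", "AAAAAASAAAAAA", "AAAAAATAAAAAA")), "ST")
  expect_equal(kinase_class(rep("AAAAAAYAAAAAA", 3)), "Y")
  expect_equal(kinase_class(c("AAAAAASAAAAAA", "AAAAAAYAAAAAA")), "ST")
})

test_that("build_profile assembles matrices and enforces the minimum n", {
  peps <- rep("ACDEFGSIKLMNP", 30)
  p <- build_profile("K", peps, uniform_background())
  expect_s3_class(p, "kinase_profile")
  expect_equal(p$n, 30)
  expect_equal(p$class, "ST")
  # identical peptides: every observed cell carries log2(20) bits
  expect_equal(p$heights["0", "S"], log2(20), tolerance = 1e-9)
  expect_equal(sum(p$heights > 0), 13)
  expect_equal(unname(p$heights[p$heights > 0]), rep(log2(20), 13),
               tolerance = 1e-9)

  err <- expect_error(build_profile("K", peps[1:29], uniform_background()),
                      class = "kinamotif_too_few")
  expect_equal(err$n, 29)
  expect_equal(err$min_n, 30)
})

test_that("profile matrices satisfy the information-theoretic invariants", {
  set.seed(99)
  for (rep in 1:8) {
    pwm <- random_pwm(sprintf("k%d", rep), sharpness = runif(1, 0.3, 0.95),
                      n_signal = sample(1:5, 1))
    peps <- sample_peptides(pwm, sample(30:150, 1))
    p <- build_profile("K", peps, uniform_background())
    expect_equal(unname(rowSums(p$probabilities)), rep(1, 13), tolerance = 1e-9)
    expect_true(all(p$R >= 0 & p$R <= log2(20) + 1e-12))
    # letter heights at each offset sum to that offset's information
    expect_equal(unname(rowSums(p$heights)), unname(p$R), tolerance = 1e-9)
  }
})

test_that("profiles recover planted motifs from sampled peptide sets", {
  presets <- c("basophilic", "proline_directed", "acidophilic")
  seeds <- c(201, 202, 203)
  for (i in seq_along(presets)) {
    pwm <- preset_pwm(presets[i], sharpness = 0.9)
    peps <- sample_peptides(pwm, 200, seed = seeds[i])
    p <- build_profile(pwm$name, peps, uniform_background())
    logo_cells <- paste(p$logo$offset, p$logo$residue)
    for (r in seq_len(nrow(pwm$signal))) {
      cell <- pwm$signal[r, ]
      expect_true(paste(cell$offset, cell$residue) %in% logo_cells)
      # the top-height residue at each signal offset is the PWM argmax
      j <- as.character(cell$offset)
      top <- names(which.max(p$heights[j, ]))
      expect_true(top %in% pwm$signal$residue[pwm$signal$offset == cell$offset])
    }
  }
  # dominant single residue: argmax of heights lands on it
  set.seed(204)
  pwm <- random_pwm("sharp", sharpness = 0.9, n_signal = 1)
  pwm$signal <- data.frame(offset = -3L, residue = "R")
  pwm$probs["-3", ] <- 0.1 / 20
  pwm$probs["-3", "R"] <- 0.9 + 0.1 / 20
  peps <- sample_peptides(pwm, 200, seed = 205)
  p <- build_profile("sharp", peps, uniform_background())
  expect_equal(names(which.max(p$heights["-3", ])), "R")
})
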