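# residue colors by side-chain class: basic blue, acidic red, hydrophobic
# green, aromatic black, polar/uncharged magenta, no side chain orange
residue_color <- function(aa) {
  cols <- c(R = "blue", K = "blue", H = "blue",
            D = "red", E = "red",
            A = "darkgreen", V = "darkgreen", L = "darkgreen",
            I = "darkgreen", M = "darkgreen", P = "darkgreen", C = "darkgreen",
            F = "black", W = "black", Y = "black",
            S = "magenta", T = "magenta", N = "magenta", Q = "magenta",
            G = "orange")
  unname(cols[aa])
}

#' Plot a kinase sequence logo or anti-logo
#'
#' Draws the chi-square-filtered logo (favored residues, letter height =
#' probability x position information in bits) or anti-logo (disfavored
#' residues, depletion height) for one fitted kinase as stacked letters,
#' colored by side-chain class (basic blue, acidic red, hydrophobic green,
#' aromatic black, polar/uncharged magenta, glycine orange). The
#' phosphoacceptor position (offset 0) carries no letters by construction.
#'
#' @param x A `kinase_profiles` fit.
#' @param kinase Kinase name (defaults to the first fitted kinase).
#' @param type `"logo"` or `"antilogo"`.
#' @param ... Passed to [graphics::plot.default()].
#' @return `x`, invisibly.
#' @export
plot.kinase_profiles <- function(x, kinase = names(x$profiles)[1],
                                 type = c("logo", "antilogo"), ...) {
  type <- match.arg(type)
  p <- get_profile(x, kinase)
  cells <- if (type == "logo") p$logo else p$antilogo
  ymax <- max(c(0.1, vapply(split(cells$height, cells$offset), sum, numeric(1))))
  graphics::plot(NULL, xlim = c(-6.5, 6.5), ylim = c(0, ymax * 1.05),
                 xlab = "position relative to phosphoacceptor",
                 ylab = if (type == "logo") "information (bits)" else "depletion (bits)",
                 main = sprintf("%s %s (n = %d, alpha = %g)",
                                kinase, type, p$n, p$alpha),
                 xaxt = "n", ...)
  graphics::axis(1, at = PEPTIDE_OFFSETS)
  graphics::abline(v = 0, col = "grey80", lty = 2)
  for (off in unique(cells$offset)) {
    sub <- cells[cells$offset == off, ]
    sub <- sub[order(sub$height), ]
    y0 <- 0
    for (i in seq_len(nrow(sub))) {
      h <- sub$height[i]
      if (h <= 0) next
      # letter scaled to fill its stack slice
      cex <- max(0.3, min(4, h / ymax * 12))
      graphics::text(off, y0 + h / 2, sub$residue[i],
                     col = residue_color(sub$residue[i]), cex = cex, font = 2)
      y0 <- y0 + h
    }
  }
  invisible(x)
}
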