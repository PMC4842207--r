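# Straight-line reference implementation of the directional machinery,
# written with plain loops directly from the defining formulas and kept
# independent of the package's stacked computational path.

oracle_freqs <- function(d) {
  pops <- levels(d$pop)
  lapply(seq_along(d$loci), function(l) {
    alleles <- sort(unique(as.vector(d$geno[, l, ])))
    alleles <- alleles[!is.na(alleles)]
    m <- matrix(0, length(alleles), length(pops),
                dimnames = list(as.character(alleles), pops))
    for (p in pops) {
      copies <- as.vector(d$geno[d$pop == p, l, ])
      copies <- copies[!is.na(copies)]
      if (length(copies) == 0L) next
      for (k in seq_along(alleles))
        m[k, p] <- sum(copies == alleles[k]) / length(copies)
    }
    m
  })
}

# b_ij = E(a_i, f(a_i, a_j)) combined across usable loci; Gst as ratio
# of summed Dst and Ht, D from locus-averaged Ht and Hs. Ht written via
# the mean-frequency form 1 - |(a+f)/2|^2 (an independent algebraic
# route). Loci with an empty pool enter with f = 0 and, for Gst,
# Dst = Ht.
oracle_directional <- function(d, stat) {
  frl <- if (inherits(d, "allele_freq_set")) d$freqs else oracle_freqs(d)
  pops <- if (inherits(d, "allele_freq_set")) d$populations else levels(d$pop)
  P <- length(pops)
  B <- matrix(NA_real_, P, P, dimnames = list(pops, pops))
  for (i in seq_len(P)) {
    for (j in seq_len(P)) {
      if (i == j) next
      hts <- c(); hss <- c(); dsts <- c()
      for (l in seq_along(frl)) {
        a <- frl[[l]][, i]
        b <- frl[[l]][, j]
        if (sum(a) == 0 || sum(b) == 0) next
        g <- sqrt(a * b)
        f <- if (sum(g) > 0) g / sum(g) else g * 0
        ht <- 1 - sum(((a + f) / 2)^2)
        hs <- 1 - (sum(a^2) + sum(f^2)) / 2
        dst <- if (sum(g) == 0) ht else ht - hs
        hts <- c(hts, ht); hss <- c(hss, hs); dsts <- c(dsts, dst)
      }
      B[i, j] <- if (stat == "gst") sum(dsts) / sum(hts)
                 else 2 * (mean(hts) - mean(hss)) / (1 - mean(hss))
    }
  }
  B
}

oracle_relative <- function(B, stat, eps = 1e-6) {
  bc <- pmax(B, eps)
  raw <- if (stat == "gst") (1 / bc - 1) / 4 else (1 - bc) / bc
  diag(raw) <- NA
  raw / max(raw, na.rm = TRUE)
}
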