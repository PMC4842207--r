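# Directional differentiation via the hypothetical pool of migrants.
#
# For an ordered pair (i, j) the pool f(a_i, a_j) has frequencies equal
# to the normalized geometric means of the two populations' frequencies.
# The directional statistic b_ij = E(a_i, f(a_i, a_j)) (E = Gst or
# Jost's D) measures how far population i is from the pool it shares
# with j; low values mean a high potential for gene flow i -> j. The
# matrix of b_ij is generally asymmetric even though E itself is
# symmetric.

#' Hypothetical pool of migrants for two populations
#'
#' Frequencies of the pool are the normalized geometric means
#' `f_i = sqrt(a_i * b_i) / sum(sqrt(a * b))`. When the two populations
#' share no alleles the pool is empty: an all-zero vector flagged with
#' `attr(, "empty")`, and downstream differentiation from either
#' population is set to 1.
#'
#' @param a,b aligned allele frequency vectors (see [align_pair()]).
#' @return Numeric vector over the same allele space, summing to 1
#'   unless empty; attribute `empty` is `TRUE` when no alleles are
#'   shared.
#' @export
pool_frequencies <- function(a, b) {
  .check_pair(a, b)
  .check_freq_vector(a)
  .check_freq_vector(b)
  g <- sqrt(a * b)
  s <- sum(g)
  if (s > 0) {
    f <- g / s
    empty <- FALSE
  } else {
    f <- g * 0
    empty <- TRUE
  }
  names(f) <- names(a)
  attr(f, "empty") <- empty
  f
}

#' Is a pool vector empty (no shared alleles)?
#' @param f a vector from [pool_frequencies()].
#' @return Logical scalar.
#' @export
is_empty_pool <- function(f) isTRUE(attr(f, "empty")) || all(f == 0)

#' Align a pair of populations at one locus
#'
#' Returns the two frequency vectors over the union of alleles observed
#' in either population at the locus, zero-filled and ordered by
#' ascending allele code. All pairwise statistics are invariant to the
#' extra all-zero rows of the full allele space, so this restriction is
#' a convenience, not a correction.
#'
#' @param freqs an `allele_freq_set`.
#' @param i,j population labels or indices.
#' @param locus locus name or index.
#' @return List with aligned vectors `a` and `b`.
#' @export
align_pair <- function(freqs, i, j, locus) {
  stopifnot(inherits(freqs, "allele_freq_set"))
  if (is.character(locus) && !locus %in% freqs$loci)
    stop("unknown locus: ", locus)
  A <- freqs$freqs[[locus]]
  if (is.null(A)) stop("unknown locus: ", locus)
  a <- A[, i]
  b <- A[, j]
  keep <- a > 0 | b > 0
  list(a = a[keep], b = b[keep])
}

# --- stacked internal representation -----------------------------------
# All loci concatenated row-wise so per-locus sums reduce to differences
# of cumulative sums; this is the single computational engine shared by
# directional_matrix(), the simulation experiments, and the bootstrap.

.stack_freqs <- function(freqs) {
  nr <- vapply(freqs$freqs, nrow, 0L)
  ends <- cumsum(nr)
  starts <- c(1L, head(ends, -1L) + 1L)
  Fm <- do.call(rbind, freqs$freqs)
  if (is.null(Fm)) stop("empty frequency set")
  list(F = Fm, starts = as.integer(starts), ends = as.integer(ends),
       L = length(nr), usable = freqs$sample_sizes > 0,
       populations = freqs$populations, loci = freqs$loci)
}

.locsum <- function(x, starts, ends) {
  cs <- c(0, cumsum(x))
  cs[ends + 1L] - cs[starts]
}

# Multilocus directional statistics for one ordered pair on the stacked
# representation. fa = focal population's frequencies, fb = partner's;
# usable = logical over loci (both populations have data).
#
# Multilocus combination: Gst = sum(Dst_l) / sum(Ht_l) (Nei's ratio of
# sums); D = 2 (mean Ht - mean Hs) / (1 - mean Hs), i.e. the Jost
# formula on locus-averaged heterozygosities. Averaging before the
# ratio keeps loci with zero differentiation from the pool (common by
# construction: any locus monomorphic in the focal population has pool
# == focal frequencies exactly) from annihilating the statistic, which
# a harmonic mean across loci would do.
#
# Per-locus empty pools (no shared alleles) contribute differentiation
# 1: for D this falls out of the formulas with f = 0; for Gst the locus
# is entered with Dst_l = Ht_l.
.pair_stat_stacked <- function(fa, fb, starts, ends, usable) {
  g <- sqrt(fa * fb)
  sg <- .locsum(g, starts, ends)
  scale <- ifelse(sg > 0, 1 / sg, 0)
  f <- g * rep.int(scale, ends - starts + 1L)
  d1 <- .locsum((fa - f)^2, starts, ends)
  s2 <- .locsum((fa + f)^2, starts, ends)
  na2 <- .locsum(fa * fa, starts, ends)
  nf2 <- .locsum(f * f, starts, ends)
  ht <- 1 - s2 / 4
  hs <- 1 - (na2 + nf2) / 2
  dst <- d1 / 4
  empty <- sg <= 0 & na2 > 0
  if (any(empty)) {
    # f is the all-zero vector here already, so ht/hs carry the f = 0
    # forms; only Gst needs the forced Dst = Ht entry
    dst[empty] <- ht[empty]
  }
  ht <- ht[usable]
  hs <- hs[usable]
  dst <- dst[usable]
  gst <- if (sum(ht) > 0) sum(dst) / sum(ht) else 0
  mhs <- mean(hs)
  d <- if (mhs < 1) 2 * (mean(ht) - mhs) / (1 - mhs) else 0
  c(gst = gst, d = min(max(d, 0), 1))
}

.as_freq_set <- function(x) {
  if (inherits(x, "genotype_dataset")) return(allele_frequencies(x))
  if (inherits(x, "allele_freq_set")) return(x)
  stop("expected a genotype_dataset or allele_freq_set")
}

#' Directional differentiation matrix
#'
#' Computes, for every ordered pair of populations (i, j), the chosen
#' multilocus differentiation statistic between population i and the
#' hypothetical pool of migrants it shares with j. Entry (i, j) is an
#' indicator of the potential for gene flow from i to j: low values mean
#' high potential. The diagonal is undefined (`NA`). Loci where either
#' member of a pair has no observed alleles are dropped for that pair.
#'
#' @param x a `genotype_dataset` or `allele_freq_set`.
#' @param stat `"d"` (Jost's D) or `"gst"` (Nei's Gst).
#' @return A `directional_matrix`: square matrix with `NA` diagonal,
#'   off-diagonal entries in `[0, 1]`, and attribute `stat`.
#' @export
directional_matrix <- function(x, stat = c("d", "gst")) {
  stat <- match.arg(stat)
  freqs <- .as_freq_set(x)
  st <- .stack_freqs(freqs)
  P <- length(st$populations)
  B <- matrix(NA_real_, P, P, dimnames = list(st$populations, st$populations))
  for (i in seq_len(P)) {
    for (j in seq_len(P)) {
      if (i == j) next
      us <- st$usable[, i] & st$usable[, j]
      if (!any(us))
        stop(sprintf("no usable loci for population pair %s -> %s",
                     st$populations[i], st$populations[j]))
      B[i, j] <- .pair_stat_stacked(st$F[, i], st$F[, j],
                                    st$starts, st$ends, us)[[stat]]
    }
  }
  structure(B, stat = stat, class = c("directional_matrix", class(B)))
}

.print_popmatrix <- function(x, digits) {
  m <- round(unclass(x), digits)
  attributes(m) <- list(dim = dim(x), dimnames = dimnames(x))
  print(m, na.print = "")
}

#' @export
print.directional_matrix <- function(x, digits = 4L, ...) {
  cat(sprintf("directional differentiation (%s); entry (i, j) = %s between\n",
              toupper(attr(x, "stat")), toupper(attr(x, "stat"))))
  cat("population i and the pool shared with j (low = high flow i -> j)\n")
  .print_popmatrix(x, digits)
  invisible(x)
}

#' Directional relative migration matrix
#'
#' Transforms directional differentiation into directional relative
#' migration under island-model assumptions: for Gst the effective
#' number of migrants `(1/Gst - 1)/4`, for Jost's D the scaled migration
#' rate `(1 - D)/D`. The matrix is then normalized by its largest
#' off-diagonal value so entries lie in `[0, 1]`; values are relative,
#' never absolute, rates. A directional statistic of exactly 0 is
#' clamped at `eps` before inversion, so the zero-differentiation
#' direction maps to the matrix maximum (relative migration 1) while the
#' arithmetic stays finite.
#'
#' @param x a `genotype_dataset`, `allele_freq_set`, or a
#'   `directional_matrix` (whose `stat` attribute then governs the
#'   transform).
#' @param stat `"d"` or `"gst"`; ignored when `x` already is a
#'   `directional_matrix`.
#' @param eps clamp for zero differentiation before inversion.
#' @return A `relative_migration` matrix (`NA` diagonal, maximum
#'   off-diagonal entry 1) with attributes `stat`, `eps` and `raw` (the
#'   unnormalized values).
#' @export
relative_migration <- function(x, stat = c("d", "gst"), eps = 1e-6) {
  if (inherits(x, "directional_matrix")) {
    B <- x
    stat <- attr(x, "stat")
  } else {
    stat <- match.arg(stat)
    B <- directional_matrix(x, stat)
  }
  if (eps <= 0 || eps >= 1) stop("`eps` must lie in (0, 1)")
  bc <- pmax(unclass(B), eps)
  raw <- if (stat == "gst") (1 / bc - 1) / 4 else (1 - bc) / bc
  diag(raw) <- NA_real_
  mx <- suppressWarnings(max(raw, na.rm = TRUE))
  if (!is.finite(mx) || mx <= 0) {
    warning("all directional differentiation is 1 (no shared alleles); ",
            "relative migration is 0 everywhere")
    C <- raw * 0
  } else {
    C <- raw / mx
  }
  structure(C, stat = stat, eps = eps, raw = raw,
            class = c("relative_migration", class(C)))
}

#' @export
print.relative_migration <- function(x, digits = 4L, ...) {
  cat(sprintf("directional relative migration (from %s), normalized to [0, 1];\n",
              toupper(attr(x, "stat"))))
  cat("entry (i, j) = relative migration from population i to j\n")
  .print_popmatrix(x, digits)
  invisible(x)
}
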