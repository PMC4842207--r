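# Heterozygosity and differentiation in vector form. For two aligned
# allele frequency vectors a and b:
#   H(a)      = 1 - |a|^2
#   Ht(a, b)  = 1 - |a + b|^2 / 4
#   Hs(a, b)  = 1 - (|a|^2 + |b|^2) / 2
#   Dst       = Ht - Hs = |a - b|^2 / 4
#   Gst       = Dst / Ht = |a - b|^2 / (4 - |a + b|^2)
#   D (Jost)  = 2 Dst / (1 - Hs) = |a - b|^2 / (|a|^2 + |b|^2)
# These are the plug-in (biased) estimators, computed per locus and only
# then combined across loci.

.check_freq_vector <- function(a, allow_empty = TRUE) {
  if (!is.numeric(a)) stop("frequency vectors must be numeric")
  if (length(a) < 1L) stop("frequency vectors must be non-empty")
  if (any(a < -1e-12) || any(a > 1 + 1e-12))
    stop("allele frequencies must lie in [0, 1]")
  s <- sum(a)
  if (abs(s - 1) > 1e-9 && !(allow_empty && s == 0))
    stop("frequency vector must sum to 1 (or be the all-zero empty vector)")
  invisible(a)
}

.check_pair <- function(a, b) {
  if (length(a) != length(b))
    stop("frequency vectors must be aligned to a common allele space ",
         "(lengths ", length(a), " and ", length(b), ")")
  invisible(NULL)
}

#' Expected heterozygosity of one frequency vector
#' @param a allele frequency vector (entries in `[0,1]` summing to 1).
#' @return `1 - sum(a^2)`.
#' @export
expected_het <- function(a) {
  .check_freq_vector(a, allow_empty = FALSE)
  1 - sum(a * a)
}

#' Pairwise heterozygosity and differentiation statistics
#'
#' All functions take two allele frequency vectors over a shared, ordered
#' allele space (see [align_pair()]) and return a scalar. `ht_pair` and
#' `hs_pair` are the unweighted two-population total and mean
#' within-population heterozygosities; `dst_pair`, `gst_pair` and
#' `d_pair` are the corresponding differentiation measures.
#'
#' @param a,b aligned allele frequency vectors.
#' @return A scalar; `gst_pair` and `d_pair` lie in `[0, 1]`.
#' @name pairwise_stats
NULL

#' @rdname pairwise_stats
#' @export
ht_pair <- function(a, b) {
  .check_pair(a, b)
  1 - sum((a + b)^2) / 4
}

#' @rdname pairwise_stats
#' @export
hs_pair <- function(a, b) {
  .check_pair(a, b)
  1 - (sum(a * a) + sum(b * b)) / 2
}

#' @rdname pairwise_stats
#' @export
dst_pair <- function(a, b) {
  .check_pair(a, b)
  sum((a - b)^2) / 4
}

#' @rdname pairwise_stats
#' @export
gst_pair <- function(a, b) {
  .check_pair(a, b)
  num <- sum((a - b)^2)
  if (num == 0) return(0)
  den <- 4 - sum((a + b)^2)
  num / den
}

#' @rdname pairwise_stats
#' @export
d_pair <- function(a, b) {
  .check_pair(a, b)
  den <- sum(a * a) + sum(b * b)
  if (den == 0)
    stop("Jost's D is undefined for two all-zero frequency vectors")
  sum((a - b)^2) / den
}

#' All pairwise statistics for one locus
#' @param a,b aligned allele frequency vectors.
#' @return One-row data frame with columns `ht`, `hs`, `dst`, `gst`, `d`.
#' @export
pair_stats <- function(a, b) {
  data.frame(ht = ht_pair(a, b), hs = hs_pair(a, b), dst = dst_pair(a, b),
             gst = gst_pair(a, b), d = d_pair(a, b))
}

#' Combine per-locus statistics into a multilocus value
#'
#' Multilocus Gst is the ratio of sums `sum(Dst_l) / sum(Ht_l)` (Nei).
#' Multilocus Jost's D offers two methods: `"harmonic"`, the harmonic
#' mean of the per-locus values (Crawford), and `"average"`, the Jost
#' formula applied to locus-averaged heterozygosities,
#' `2 (mean Ht - mean Hs) / (1 - mean Hs)`. Under `"harmonic"` a
#' per-locus D of exactly 0 drives the mean to its limit 0; by default
#' that limit is returned with a warning, or zero loci can be excluded
#' with `zero_action = "drop"`. The directional machinery
#' ([directional_matrix()]) uses the `"average"` form, which is robust
#' to the exact zeros that pool comparisons produce at loci monomorphic
#' in the focal population.
#'
#' @param per_locus data frame of per-locus statistics (rows = usable
#'   loci) with columns `ht` and `dst` (for Gst) or `d`/`ht`/`hs` (for
#'   D), as produced by [pair_stats()].
#' @param stat `"gst"` or `"d"`.
#' @param method multilocus D method, `"harmonic"` or `"average"`.
#' @param zero_action harmonic-mean treatment of per-locus D values of
#'   0: `"limit"` (return 0) or `"drop"` (exclude those loci).
#' @return Multilocus scalar.
#' @export
multilocus_combine <- function(per_locus, stat = c("gst", "d"),
                               method = c("harmonic", "average"),
                               zero_action = c("limit", "drop")) {
  stat <- match.arg(stat)
  method <- match.arg(method)
  zero_action <- match.arg(zero_action)
  if (is.null(nrow(per_locus)) || nrow(per_locus) < 1L)
    stop("no usable loci to combine")
  if (stat == "gst") {
    sht <- sum(per_locus$ht)
    if (sht <= 0) return(0)
    return(sum(per_locus$dst) / sht)
  }
  if (method == "average") {
    mhs <- mean(per_locus$hs)
    if (mhs >= 1) return(0)
    return(min(max(2 * (mean(per_locus$ht) - mhs) / (1 - mhs), 0), 1))
  }
  v <- per_locus$d
  if (any(v == 0)) {
    if (zero_action == "drop") {
      v <- v[v > 0]
      if (length(v) == 0L) {
        warning("all per-locus D values are 0; multilocus D is 0")
        return(0)
      }
    } else {
      warning("per-locus D of 0 encountered; harmonic mean taken at its limit 0")
      return(0)
    }
  }
  length(v) / sum(1 / v)
}
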