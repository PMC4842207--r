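# Bootstrap test for significant asymmetry of directional gene flow.
# Individuals (whole multilocus genotypes) are resampled with
# replacement within each population, preserving the original sample
# sizes; the directional statistic is recomputed for both directions of
# every pair; percentile confidence intervals that do not overlap flag
# the pair as significantly asymmetric.

# Per-population count matrices on the stacked allele space: one row per
# individual, one column per (locus, allele) row of the stacked
# frequency matrix. Bootstrap frequencies are then column sums over a
# resampled set of rows.
.boot_counts <- function(d, freqs, st) {
  pops <- levels(d$pop)
  L <- length(d$loci)
  R <- nrow(st$F)
  lapply(pops, function(p) {
    inds <- which(d$pop == p)
    M <- matrix(0, length(inds), R)
    for (l in seq_len(L)) {
      al <- suppressWarnings(as.integer(rownames(freqs$freqs[[l]])))
      if (length(al) == 0L) next
      off <- st$starts[l] - 1L
      for (k in 1:2) {
        m <- match(d$geno[inds, l, k], al)
        ok <- which(!is.na(m))
        if (length(ok)) {
          ij <- cbind(ok, off + m[ok])
          M[ij] <- M[ij] + 1
        }
      }
    }
    M
  })
}

#' Bootstrap test for asymmetric gene flow
#'
#' For each bootstrap replicate, individuals are resampled with
#' replacement within each population (original sample sizes preserved);
#' allele frequencies, hypothetical pools, and the multilocus
#' directional statistic are recomputed for both directions of every
#' population pair. Percentile confidence intervals at level `alpha`
#' (quantile method) are formed per direction; a pair is significantly
#' asymmetric when the two intervals do not overlap. Results are
#' deterministic given `seed`.
#'
#' @param d a [genotype_dataset()]; every population needs at least 2
#'   individuals.
#' @param stat `"d"` or `"gst"`.
#' @param n_boot number of bootstrap replicates (>= 2; the default 1000
#'   matches common practice for this test).
#' @param alpha confidence level complement in (0, 1); 0.05 gives 95%
#'   intervals with probabilities 0.025 and 0.975.
#' @param seed optional integer seed.
#' @return An `asymmetry_result`: list with `pairs` (data frame of
#'   ordered pairs: `from`, `to`, `estimate`, `lower`, `upper`,
#'   `significant`), the point/lower/upper matrices, and the call
#'   parameters.
#' @export
bootstrap_asymmetry <- function(d, stat = c("d", "gst"), n_boot = 1000L,
                                alpha = 0.05, seed = NULL) {
  stopifnot(inherits(d, "genotype_dataset"))
  stat <- match.arg(stat)
  if (!is.numeric(n_boot) || n_boot < 2L)
    stop("`n_boot` must be at least 2")
  n_boot <- as.integer(n_boot)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)")
  sizes <- tabulate(d$pop)
  if (any(sizes < 2L))
    stop("every population needs at least 2 individuals to resample")
  if (!is.null(seed)) set.seed(seed)

  freqs <- allele_frequencies(d)
  st <- .stack_freqs(freqs)
  P <- length(st$populations)
  point <- unclass(directional_matrix(freqs, stat))
  counts <- .boot_counts(d, freqs, st)

  boot <- array(NA_real_, c(n_boot, P, P))
  redraws <- 0L
  Fm <- matrix(0, nrow(st$F), P)
  us <- matrix(FALSE, st$L, P)
  for (r in seq_len(n_boot)) {
    for (p in seq_len(P)) {
      ok <- FALSE
      for (try in seq_len(100L)) {
        idx <- sample.int(sizes[p], sizes[p], replace = TRUE)
        cnt <- colSums(counts[[p]][idx, , drop = FALSE])
        tot <- .locsum(cnt, st$starts, st$ends)
        if (any(tot > 0)) { ok <- TRUE; break }
        redraws <- redraws + 1L
      }
      if (!ok)
        stop("population ", st$populations[p],
             " repeatedly lost all data in resampling")
      f <- cnt * rep.int(ifelse(tot > 0, 1 / tot, 0),
                         st$ends - st$starts + 1L)
      Fm[, p] <- f
      us[, p] <- tot > 0
    }
    for (i in seq_len(P)) {
      for (j in seq_len(P)) {
        if (i == j) next
        u <- us[, i] & us[, j]
        if (any(u))
          boot[r, i, j] <- .pair_stat_stacked(Fm[, i], Fm[, j],
                                              st$starts, st$ends, u)[[stat]]
      }
    }
  }

  qs <- function(prob) apply(boot, c(2L, 3L), quantile, probs = prob,
                             na.rm = TRUE, names = FALSE)
  lower <- qs(alpha / 2)
  upper <- qs(1 - alpha / 2)
  dimnames(lower) <- dimnames(upper) <- dimnames(point)
  diag(lower) <- diag(upper) <- NA_real_

  sig <- matrix(FALSE, P, P, dimnames = dimnames(point))
  for (i in seq_len(P - 1L)) {
    for (j in seq(i + 1L, P)) {
      disjoint <- upper[i, j] < lower[j, i] || upper[j, i] < lower[i, j]
      sig[i, j] <- sig[j, i] <- isTRUE(disjoint)
    }
  }

  ij <- which(row(point) != col(point), arr.ind = TRUE)
  ij <- ij[order(ij[, 1L], ij[, 2L]), , drop = FALSE]
  pairs <- data.frame(
    from = st$populations[ij[, 1L]],
    to = st$populations[ij[, 2L]],
    estimate = point[ij],
    lower = lower[ij],
    upper = upper[ij],
    significant = sig[ij],
    stringsAsFactors = FALSE)

  structure(list(pairs = pairs, point = point, lower = lower, upper = upper,
                 significant = sig, stat = stat, n_boot = n_boot,
                 alpha = alpha, seed = seed, redraws = redraws,
                 populations = st$populations),
            class = "asymmetry_result")
}

#' @export
print.asymmetry_result <- function(x, ...) {
  cat(sprintf("bootstrap asymmetry test (%s, %d replicates, %.0f%% CIs)\n",
              toupper(x$stat), x$n_boot, 100 * (1 - x$alpha)))
  nsig <- sum(x$significant[upper.tri(x$significant)])
  cat(sprintf("%d of %d population pairs significantly asymmetric\n",
              nsig, choose(length(x$populations), 2)))
  print(x$pairs, digits = 4)
  invisible(x)
}

#' Export an asymmetry result as CSV
#' @param x an `asymmetry_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_asymmetry_csv <- function(x, path) {
  stopifnot(inherits(x, "asymmetry_result"))
  write.csv(x$pairs, path, row.names = FALSE)
  invisible(path)
}

#' Mask of significant directed edges
#'
#' For every significantly asymmetric population pair, keeps only the
#' direction with the larger relative migration; non-significant pairs
#' are masked entirely. Ties leave both directions masked.
#'
#' @param res an `asymmetry_result`.
#' @param c a `relative_migration` matrix over the same populations.
#' @return Logical matrix; `TRUE` marks directed edges to retain.
#' @export
significant_edge_mask <- function(res, c) {
  stopifnot(inherits(res, "asymmetry_result"))
  cm <- unclass(c)
  if (!is.matrix(cm) || !identical(dim(cm), dim(res$point)))
    stop("population sets of the test and the migration matrix differ")
  if (!is.null(rownames(cm)) && !identical(rownames(cm), res$populations))
    stop("population sets of the test and the migration matrix differ")
  P <- length(res$populations)
  mask <- matrix(FALSE, P, P, dimnames = dimnames(res$point))
  for (i in seq_len(P - 1L)) {
    for (j in seq(i + 1L, P)) {
      if (!res$significant[i, j]) next
      if (cm[i, j] > cm[j, i]) mask[i, j] <- TRUE
      else if (cm[j, i] > cm[i, j]) mask[j, i] <- TRUE
    }
  }
  mask
}
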