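test_that("pool frequencies satisfy the four defining requirements", {
  set.seed(405)
  for (rep in 1:40) {
    n <- sample(2:6, 1)
    a <- random_simplex(n)
    b <- random_simplex(n)
    # zero out a random subset of entries to vary the supports
    a[sample(n, sample(0:(n - 1), 1))] <- 0
    b[sample(n, sample(0:(n - 1), 1))] <- 0
    if (sum(a) == 0 || sum(b) == 0) next
    a <- a / sum(a); b <- b / sum(b)
    f <- pool_frequencies(a, b)
    # 1: symmetry in the two parents
    expect_identical(unname(unclass(f)), unname(unclass(pool_frequencies(b, a))))
    # 2: support only where both parents are nonzero
    expect_true(all(f[a == 0 | b == 0] == 0))
    # 4: normalization (unless the pool is empty)
    if (!is_empty_pool(f)) expect_equal(sum(f), 1) else expect_true(all(f == 0))
  }
})

test_that("pool preserves allele proportions under one-way-flow structure", {
  # b proportional to a on the shared support, plus a private allele in b
  set.seed(406)
  for (rep in 1:20) {
    a3 <- random_simplex(3)
    kappa <- runif(1, 0.2, 0.8)
    a <- c(a3, 0)
    b <- c(kappa * a3, 1 - kappa)
    f <- pool_frequencies(a, b)
    shared <- which(a > 0 & b > 0)
    for (i in shared[-1]) {
      expect_equal(f[[i]] / f[[shared[1]]], a[i] / a[shared[1]])
    }
  }
})

test_that("pool of the worked example equals the source population's frequencies", {
  a <- c(0.4, 0.6, 0.0)
  b <- c(0.2, 0.3, 0.5)
  expect_equal(as.vector(pool_frequencies(a, b)), a)
  expect_equal(as.vector(pool_frequencies(a, a)), a)
})

test_that("disjoint populations give an empty pool and differentiation 1 both ways", {
  f <- pool_frequencies(c(1, 0), c(0, 1))
  expect_true(is_empty_pool(f))
  fs <- allele_freq_set(list(
    L1 = matrix(c(1, 0, 0, 1), 2, dimnames = list(1:2, c("A", "B")))))
  for (s in c("gst", "d")) {
    B <- directional_matrix(fs, s)
    expect_equal(unname(B[1, 2]), 1)
    expect_equal(unname(B[2, 1]), 1)
  }
  expect_warning(C <- relative_migration(fs, "d"),
                 "relative migration is 0")
  expect_equal(unname(C[1, 2]), 0)
  expect_equal(unname(C[2, 1]), 0)
})

test_that("align_pair returns zero-filled vectors over the observed union, in order", {
  geno <- array(NA_integer_, c(4L, 1L, 2L))
  geno[, 1, ] <- rbind(c(7, 7), c(2, 2), c(2, 9), c(9, 9))
  d <- genotype_dataset(geno, c("X", "X", "Y", "Y"), loci = "locZ")
  fr <- allele_frequencies(d)
  al <- align_pair(fr, "X", "Y", "locZ")
  expect_equal(names(al$a), c("2", "7", "9"))       # ascending allele codes
  expect_equal(unname(al$a), c(0.5, 0.5, 0))        # zero-fill for 9 in X
  expect_equal(unname(al$b), c(0.25, 0, 0.75))
  expect_error(align_pair(fr, "X", "Y", "nope"), "unknown locus")
})

test_that("the worked example pins the direction convention of the matrix", {
  fs <- table1_freqs()
  Bg <- directional_matrix(fs, "gst")
  Bd <- directional_matrix(fs, "d")
  # A is the source: zero differentiation from the pool in the A row
  expect_equal(unname(Bg["A", "B"]), 0)
  expect_equal(unname(Bd["A", "B"]), 0)
  expect_equal(round(unname(Bg["B", "A"]), 2), 0.15)
  expect_equal(round(unname(Bd["B", "A"]), 2), 0.42)
  expect_true(all(is.na(diag(Bg))))
})

test_that("identical populations yield zero differentiation everywhere", {
  p <- random_simplex(4)
  fs <- allele_freq_set(list(L1 = cbind(A = p, B = p, C = p)))
  for (s in c("gst", "d")) {
    B <- directional_matrix(fs, s)
    expect_true(all(B[!is.na(B)] == 0))
  }
})

test_that("relabelling populations permutes rows and columns consistently", {
  set.seed(407)
  d <- random_dataset(P = 3L, n_per_pop = 8L, L = 3L)
  fr <- allele_frequencies(d)
  B <- directional_matrix(fr, "d")
  perm <- c(3L, 1L, 2L)
  fr2 <- fr
  fr2$freqs <- lapply(fr$freqs, function(m) m[, perm, drop = FALSE])
  fr2$sample_sizes <- fr$sample_sizes[, perm, drop = FALSE]
  fr2$populations <- fr$populations[perm]
  B2 <- directional_matrix(fr2, "d")
  expect_equal(unclass(B2), unclass(B)[perm, perm], ignore_attr = TRUE)
})

test_that("directional matrices equal the straight-line oracle on random instances", {
  set.seed(408)
  for (rep in 1:20) {
    d <- random_dataset(P = sample(2:3, 1), n_per_pop = sample(4:7, 1),
                        L = sample(2:3, 1), n_alleles = sample(2:4, 1),
                        miss = sample(c(0, 0.15), 1))
    fr <- try(allele_frequencies(d), silent = TRUE)
    if (inherits(fr, "try-error")) next  # a population lost all data
    for (s in c("gst", "d")) {
      B <- directional_matrix(fr, s)
      O <- oracle_directional(d, s)
      expect_lt(max(abs(unclass(B) - O), na.rm = TRUE), 1e-12)
    }
  }
})

test_that("relative migration applies the island-model transforms and normalizes", {
  fs <- table1_freqs()
  C <- relative_migration(fs, "d", eps = 1e-6)
  raw <- attr(C, "raw")
  # B -> A: (1 - 0.4222) / 0.4222; A -> B capped at (1 - eps)/eps
  expect_equal(unname(raw["B", "A"]), (1 - 0.4222222) / 0.4222222,
               tolerance = 1e-6)
  expect_equal(unname(raw["A", "B"]), (1 - 1e-6) / 1e-6)
  expect_equal(unname(C["A", "B"]), 1)
  expect_equal(unname(C["B", "A"]), unname(raw["B", "A"] / raw["A", "B"]))
  Cg <- relative_migration(fs, "gst")
  expect_equal(unname(Cg["A", "B"]), 1)
  # both statistics agree on which direction dominates
  expect_gt(Cg["A", "B"], Cg["B", "A"])
  expect_gt(C["A", "B"], C["B", "A"])
})

test_that("relative migration of a symmetric matrix is symmetric with max 1", {
  p <- random_simplex(3); q <- random_simplex(3)
  fs <- allele_freq_set(list(L1 = cbind(A = p, B = q)))
  B <- directional_matrix(fs, "gst")
  # force exact symmetry for a clean check
  Bsym <- B; Bsym[1, 2] <- Bsym[2, 1] <- mean(B[!is.na(B)])
  C <- relative_migration(Bsym)
  if (Bsym[1, 2] > 0) {
    expect_equal(unname(C[1, 2]), 1)
    expect_equal(unname(C[2, 1]), 1)
  }
})

test_that("island-model transforms are strictly decreasing on (0, 1]", {
  x <- seq(0.01, 1, by = 0.01)
  gst_t <- (1 / x - 1) / 4
  d_t <- (1 - x) / x
  expect_true(all(diff(gst_t) < 0))
  expect_true(all(diff(d_t) < 0))
})
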