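test_that("a toy GENEPOP file parses with populations, loci and genotypes", {
  path <- write_toy_genepop()
  d <- read_genepop(path)
  expect_s3_class(d, "genotype_dataset")
  expect_equal(levels(d$pop), c("PopA", "PopB"))
  expect_equal(d$loci, c("locA", "locB", "locC"))
  expect_equal(dim(d$geno), c(5L, 3L, 2L))
  expect_equal(d$geno[1, 1, ], c(1L, 1L))   # 0101
  expect_equal(d$geno[4, 1, ], c(3L, 3L))   # 0303
  expect_equal(d$geno[3, 3, ], c(2L, 1L))   # 0201
})

test_that("0000 half-genotypes become missing alleles", {
  d <- read_genepop(write_toy_genepop())
  expect_true(all(is.na(d$geno[2, 2, ])))   # A2 has 0000 at locB
  expect_false(anyNA(d$geno[2, c(1, 3), ]))
})

test_that("malformed GENEPOP files are rejected with diagnostics", {
  lines <- toy_genepop_lines()
  nopop <- tempfile(); writeLines(lines[!grepl("^POP$", lines)], nopop)
  expect_error(read_genepop(nopop), "POP")

  onepop <- tempfile(); writeLines(lines[1:7], onepop)
  expect_error(read_genepop(onepop), "2 POP blocks")

  mixed <- lines; mixed[5] <- "A1 , 010101 010102 010101"
  f <- tempfile(); writeLines(mixed, f)
  expect_error(read_genepop(f), "mixed")

  raggedline <- lines; raggedline[5] <- "A1 , 010101 0102 0101"
  f3 <- tempfile(); writeLines(raggedline, f3)
  expect_error(read_genepop(f3), "line 5")

  short <- lines; short[6] <- "A2 , 0102 0000"
  f2 <- tempfile(); writeLines(short, f2)
  expect_error(read_genepop(f2), "line 6")
})

test_that("population labels follow the last-individual convention and can be overridden", {
  path <- write_toy_genepop()
  expect_equal(levels(read_genepop(path)$pop), c("PopA", "PopB"))
  d <- read_genepop(path, pop_names = c("north", "south"))
  expect_equal(levels(d$pop), c("north", "south"))
  expect_error(read_genepop(path, pop_names = "onlyone"), "one label per POP")
})

test_that("write + re-read round-trips the dataset", {
  d1 <- read_genepop(write_toy_genepop())
  f <- tempfile(fileext = ".gen")
  write_genepop(d1, f)
  d2 <- read_genepop(f)
  expect_identical(d2$geno, d1$geno)
  expect_identical(levels(d2$pop), levels(d1$pop))
  expect_identical(d2$loci, d1$loci)
  # a second serialization round-trip is a fixed point, ids included
  f2 <- tempfile(fileext = ".gen")
  write_genepop(d2, f2)
  expect_identical(read_genepop(f2), d2)
})

test_that("allele frequencies are plug-in counts over observed copies", {
  geno <- array(NA_integer_, c(4L, 1L, 2L))
  geno[, 1, ] <- rbind(c(1, 1), c(1, 2), c(3, 3), c(3, 3))
  d <- genotype_dataset(geno, c("X", "X", "Y", "Y"))
  fr <- allele_frequencies(d)
  expect_equal(unname(fr$freqs[[1]][, "X"]), c(0.75, 0.25, 0))
  # allele private to Y still gets a (zero) row for X
  expect_equal(rownames(fr$freqs[[1]]), c("1", "2", "3"))
  expect_equal(unname(fr$freqs[[1]][, "Y"]), c(0, 0, 1))
  expect_equal(unname(fr$sample_sizes[1, ]), c(4L, 4L))
})

test_that("missing data: half genotypes count one copy; empty columns are flagged", {
  geno <- array(NA_integer_, c(4L, 2L, 2L))
  geno[, 1, ] <- rbind(c(1, NA), c(1, 2), c(1, 1), c(2, 2))
  geno[, 2, ] <- rbind(c(NA, NA), c(NA, NA), c(5, 5), c(5, 6))
  d <- genotype_dataset(geno, c("X", "X", "Y", "Y"))
  fr <- allele_frequencies(d)
  expect_equal(unname(fr$sample_sizes[1, "X"]), 3L)  # one half-missing genotype
  expect_equal(unname(fr$freqs[[1]][, "X"]), c(2 / 3, 1 / 3))
  # X has no data at locus 2: all-zero column, sample size 0
  expect_equal(unname(fr$sample_sizes[2, "X"]), 0L)
  expect_true(all(fr$freqs[[2]][, "X"] == 0))
  expect_equal(sum(fr$freqs[[2]][, "Y"]), 1)
})

test_that("a population with no data at any locus is an error naming it", {
  geno <- array(NA_integer_, c(4L, 1L, 2L))
  geno[, 1, ] <- rbind(c(1, 1), c(1, 2), c(NA, NA), c(NA, NA))
  d <- genotype_dataset(geno, c("X", "X", "ghost", "ghost"))
  expect_error(allele_frequencies(d), "ghost")
})

test_that("frequency columns sum to one and are invariant to individual order", {
  set.seed(401)
  for (rep in 1:5) {
    d <- random_dataset(P = 3L, n_per_pop = 5L, L = 4L, miss = 0.1)
    fr <- allele_frequencies(d)
    for (l in seq_along(fr$freqs)) {
      cs <- colSums(fr$freqs[[l]])
      expect_true(all(abs(cs - 1) < 1e-12 | cs == 0))
      expect_true(all(fr$freqs[[l]] >= 0 & fr$freqs[[l]] <= 1))
    }
    perm <- sample(dim(d$geno)[1])        # reorder individuals globally
    d2 <- genotype_dataset(d$geno[perm, , , drop = FALSE],
                           as.character(d$pop)[perm])
    fr2 <- allele_frequencies(d2)
    # same populations may now appear in a different order; compare matched
    for (l in seq_along(fr$freqs))
      expect_equal(fr2$freqs[[l]][, colnames(fr$freqs[[l]])], fr$freqs[[l]])
  }
})

test_that("matrix CSV export writes an empty diagonal and round-trips", {
  m <- matrix(c(NA, 0.123456789, 1.3684215, NA), 2, 2,
              dimnames = list(c("A", "B"), c("A", "B")))
  f <- tempfile(fileext = ".csv")
  write_matrix_csv(m, f)
  lines <- readLines(f)
  expect_equal(lines[1], ",A,B")
  expect_match(lines[2], "^A,,")
  m2 <- read_matrix_csv(f)
  expect_true(all(abs(m2[!is.na(m)] - m[!is.na(m)]) < 1e-9))
  expect_true(all(is.na(diag(m2))))
})

test_that("matrix CSV export validates shape and labels", {
  expect_error(write_matrix_csv(matrix(1, 1, 1), tempfile()), "at least 2")
  expect_error(write_matrix_csv(matrix(1, 2, 3), tempfile()), "square")
  expect_error(write_matrix_csv(matrix(1, 2, 2), tempfile(), labels = "x"),
               "mismatch")
  expect_error(write_matrix_csv(matrix(1, 2, 2), tempfile()), "labels")
})
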