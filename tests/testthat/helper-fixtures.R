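# Fixtures are generated in code at test time.

random_simplex <- function(n) {
  x <- stats::rexp(n)
  x / sum(x)
}

# Small random genotype dataset; `miss` = per-allele missing probability.
random_dataset <- function(P = 2L, n_per_pop = 6L, L = 3L, n_alleles = 4L,
                           miss = 0) {
  n <- P * n_per_pop
  geno <- array(sample.int(n_alleles, n * L * 2L, replace = TRUE),
                c(n, L, 2L))
  if (miss > 0) {
    drop <- which(stats::runif(length(geno)) < miss)
    geno[drop] <- NA_integer_
  }
  genotype_dataset(geno, rep(sprintf("P%d", seq_len(P)), each = n_per_pop))
}

# Two populations, one locus, with exactly the frequencies of the
# worked thought-experiment table: a = (0.4, 0.6, 0.0), b = (0.2, 0.3, 0.5)
table1_freqs <- function() {
  allele_freq_set(list(
    T1 = matrix(c(0.4, 0.6, 0.0, 0.2, 0.3, 0.5), nrow = 3,
                dimnames = list(1:3, c("A", "B")))))
}

# Genotype dataset realizing the same frequencies from 5 diploids per
# population (10 allele copies: A = 4/6/0, B = 2/3/5)
table1_dataset <- function() {
  gA <- rbind(c(1, 1), c(1, 1), c(2, 2), c(2, 2), c(2, 2))
  gB <- rbind(c(1, 1), c(2, 2), c(2, 3), c(3, 3), c(3, 3))
  geno <- array(NA_integer_, c(10L, 1L, 2L))
  geno[, 1L, ] <- rbind(gA, gB)
  genotype_dataset(geno, rep(c("A", "B"), each = 5L), loci = "T1")
}

toy_genepop_lines <- function() {
  c("Toy dataset",
    "locA",
    "locB, locC",
    "POP",
    "A1 , 0101 0102 0101",
    "A2 , 0102 0000 0102",
    "PopA , 0101 0102 0201",
    "POP",
    "B1 , 0303 0101 0102",
    "PopB , 0303 0202 0101")
}

write_toy_genepop <- function(path = tempfile(fileext = ".gen")) {
  writeLines(toy_genepop_lines(), path)
  path
}

# GENEPOP file realizing the worked-example frequencies
write_table1_genepop <- function(path = tempfile(fileext = ".gen")) {
  write_genepop(table1_dataset(), path, title = "worked example")
  path
}
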