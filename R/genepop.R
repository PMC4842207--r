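#' Construct a multilocus genotype dataset
#'
#' Container for diploid codominant genotypes with population labels.
#' Allele codes are positive integers; missing alleles are `NA` (never
#' code 0, which is the GENEPOP missing sentinel and is translated on
#' input).
#'
#' @param geno integer array of dimension `individuals x loci x 2`
#'   holding the two allele codes of each genotype; `NA` marks a missing
#'   allele. A half-missing genotype keeps its observed allele.
#' @param pop character or factor of length `nrow(geno)` assigning each
#'   individual to a population; population order follows first
#'   appearance.
#' @param loci optional character vector of locus names.
#' @param ids optional character vector of individual identifiers.
#' @return An object of class `genotype_dataset` with elements `geno`,
#'   `pop`, `loci` and `ids`.
#' @seealso [read_genepop()], [allele_frequencies()]
#' @export
genotype_dataset <- function(geno, pop, loci = NULL, ids = NULL) {
  if (length(dim(geno)) != 3L || dim(geno)[3] != 2L)
    stop("`geno` must be an individuals x loci x 2 array of allele codes")
  n <- dim(geno)[1L]
  L <- dim(geno)[2L]
  if (n < 1L) stop("at least one individual is required")
  if (L < 1L) stop("at least one locus is required")
  storage.mode(geno) <- "integer"
  if (any(geno[!is.na(geno)] < 1L))
    stop("allele codes must be positive integers; use NA for missing alleles")
  if (length(pop) != n)
    stop("`pop` must assign every individual to exactly one population")
  pop <- factor(as.character(pop), levels = unique(as.character(pop)))
  if (nlevels(pop) < 2L)
    stop("at least 2 populations are required")
  if (is.null(loci)) loci <- sprintf("loc%d", seq_len(L))
  if (length(loci) != L) stop("`loci` must name every locus")
  if (is.null(ids)) ids <- sprintf("ind%d", seq_len(n))
  if (length(ids) != n) stop("`ids` must name every individual")
  structure(list(geno = geno, pop = pop, loci = as.character(loci),
                 ids = as.character(ids)),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d individuals, %d loci, %d populations\n",
              dim(x$geno)[1L], length(x$loci), nlevels(x$pop)))
  cat("populations:", paste(sprintf("%s (n=%d)", levels(x$pop),
                                    tabulate(x$pop)), collapse = ", "), "\n")
  invisible(x)
}

#' Population labels of a dataset or frequency set
#' @param x a `genotype_dataset` or `allele_freq_set`.
#' @return Character vector of population labels, in order.
#' @export
populations <- function(x) {
  if (inherits(x, "genotype_dataset")) return(levels(x$pop))
  if (inherits(x, "allele_freq_set")) return(x$populations)
  stop("no population labels for this object")
}

#' Read a GENEPOP file
#'
#' Parses the common GENEPOP dialect: a title line, locus names (one per
#' line or comma-separated), and populations delimited by lines equal to
#' `POP` (any case). Genotypes are 4-digit (2-digit allele codes) or
#' 6-digit (3-digit codes) strings; `00`/`000` denotes a missing allele.
#' Mixing 2- and 3-digit coding within one file is rejected.
#'
#' @param path path to a GENEPOP text file (UTF-8).
#' @param pop_names optional character vector overriding the population
#'   labels; by default the identifier of the last individual in each
#'   `POP` block is used, following the usual GENEPOP convention.
#' @return A [genotype_dataset()].
#' @export
read_genepop <- function(path, pop_names = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- sub("\r$", "", readLines(path, warn = FALSE, encoding = "UTF-8"))
  is_pop <- toupper(trimws(lines)) == "POP"
  pop_at <- which(is_pop)
  if (length(pop_at) == 0L)
    stop("not a GENEPOP file: no POP delimiter found")
  if (length(pop_at) < 2L)
    stop("at least 2 POP blocks are required, found ", length(pop_at))
  if (pop_at[1L] < 3L) stop("no locus names found before the first POP line")
  loci <- trimws(unlist(strsplit(lines[2:(pop_at[1L] - 1L)], ",", fixed = TRUE)))
  loci <- loci[nzchar(loci)]
  if (length(loci) == 0L) stop("no locus names found")
  L <- length(loci)

  blocks <- Map(function(from, to) {
    ln <- seq(from + 1L, to)
    ln[nzchar(trimws(lines[ln]))]
  }, pop_at, c(pop_at[-1L] - 1L, length(lines)))
  if (any(lengths(blocks) == 0L)) stop("empty POP block in GENEPOP file")

  width <- NULL
  parse_line <- function(ln) {
    line <- lines[ln]
    cpos <- regexpr(",", line, fixed = TRUE)
    if (cpos < 0L)
      stop(sprintf("line %d: expected 'id , genotypes'", ln))
    id <- trimws(substr(line, 1L, cpos - 1L))
    toks <- strsplit(trimws(substring(line, cpos + 1L)), "[ \t]+")[[1L]]
    toks <- toks[nzchar(toks)]
    if (length(toks) != L)
      stop(sprintf("line %d: %d genotypes found but %d loci declared",
                   ln, length(toks), L))
    if (!all(grepl("^[0-9]+$", toks)))
      stop(sprintf("line %d: non-numeric genotype", ln))
    w <- unique(nchar(toks))
    if (length(w) != 1L || !(w %in% c(4L, 6L)))
      stop(sprintf("line %d: genotypes must all be 4- or 6-digit strings", ln))
    if (is.null(width)) width <<- w / 2L
    else if (w / 2L != width)
      stop(sprintf("line %d: mixed 2- and 3-digit allele coding in one file", ln))
    a1 <- as.integer(substr(toks, 1L, width))
    a2 <- as.integer(substr(toks, width + 1L, 2L * width))
    a1[a1 == 0L] <- NA_integer_
    a2[a2 == 0L] <- NA_integer_
    list(id = id, a1 = a1, a2 = a2)
  }

  parsed <- lapply(blocks, function(b) lapply(b, parse_line))
  labs <- vapply(parsed, function(b) b[[length(b)]]$id, "")
  if (!is.null(pop_names)) {
    if (length(pop_names) != length(parsed))
      stop("`pop_names` must have one label per POP block")
    labs <- as.character(pop_names)
  }
  if (anyDuplicated(labs)) labs <- make.unique(labs)

  n <- sum(lengths(parsed))
  geno <- array(NA_integer_, c(n, L, 2L))
  ids <- character(n)
  popv <- character(n)
  i <- 0L
  for (b in seq_along(parsed)) {
    for (ind in parsed[[b]]) {
      i <- i + 1L
      geno[i, , 1L] <- ind$a1
      geno[i, , 2L] <- ind$a2
      ids[i] <- ind$id
      popv[i] <- labs[b]
    }
  }
  ds <- genotype_dataset(geno, popv, loci = loci, ids = ids)
  attr(ds, "allele_digits") <- as.integer(width)
  ds
}

#' Write a dataset as a GENEPOP file
#'
#' Writes the 3-digit dialect by default. Every individual in a block is
#' given its population label as identifier, so the last-individual
#' labelling convention round-trips the population names. Allele codes
#' outside `1 .. 10^digits - 1` are shifted (per locus) to fit; this
#' preserves all frequencies and all stepwise distances.
#'
#' @param x a [genotype_dataset()].
#' @param path output file path.
#' @param title title line for the file.
#' @param digits allele code width, 2 or 3.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(x, path, title = "dirmig dataset", digits = 3L) {
  stopifnot(inherits(x, "genotype_dataset"))
  if (!digits %in% c(2L, 3L)) stop("`digits` must be 2 or 3")
  top <- 10L^digits - 1L
  fmt <- paste0("%0", digits, "d")
  geno <- x$geno
  for (l in seq_along(x$loci)) {
    al <- geno[, l, ]
    rng <- range(al, na.rm = TRUE)
    if (is.finite(rng[1L]) && (rng[1L] < 1L || rng[2L] > top)) {
      shift <- 1L - rng[1L]
      if (rng[2L] + shift > top) {
        # dense re-code by rank; stepwise distances are not preserved but
        # identity of alleles (all that the statistics use) is
        codes <- sort(unique(al[!is.na(al)]))
        geno[, l, ] <- match(al, codes)
      } else {
        geno[, l, ] <- al + shift
      }
    }
  }
  enc <- function(a) ifelse(is.na(a), strrep("0", digits), sprintf(fmt, a))
  out <- c(title, x$loci)
  for (p in levels(x$pop)) {
    out <- c(out, "POP")
    for (i in which(x$pop == p)) {
      g <- paste0(enc(geno[i, , 1L]), enc(geno[i, , 2L]))
      out <- c(out, paste(p, ",", paste(g, collapse = " ")))
    }
  }
  writeLines(out, path, useBytes = FALSE)
  invisible(path)
}

#' Per-locus allele frequencies
#'
#' Plug-in (biased) frequency estimates: the count of copies of each
#' allele divided by the total number of observed copies, per locus and
#' population. Missing alleles contribute to neither numerator nor
#' denominator; a half-missing genotype contributes its one observed
#' allele. The allele space of a locus is the union of alleles observed
#' in any population, ordered by ascending numeric code, so columns are
#' directly comparable across populations.
#'
#' @param d a [genotype_dataset()].
#' @return An object of class `allele_freq_set`: a list with `freqs` (one
#'   alleles-by-populations matrix per locus; each column sums to 1, or
#'   is all zero when the population has no data at that locus),
#'   `sample_sizes` (loci-by-populations matrix of observed allele-copy
#'   counts), `loci` and `populations`.
#' @export
allele_frequencies <- function(d) {
  stopifnot(inherits(d, "genotype_dataset"))
  pops <- levels(d$pop)
  P <- length(pops)
  L <- length(d$loci)
  pp <- factor(rep(as.character(d$pop), 2L), levels = pops)
  freqs <- vector("list", L)
  names(freqs) <- d$loci
  ss <- matrix(0L, L, P, dimnames = list(d$loci, pops))
  for (l in seq_len(L)) {
    av <- c(d$geno[, l, 1L], d$geno[, l, 2L])
    keep <- !is.na(av)
    alleles <- sort(unique(av[keep]))
    cnt <- table(factor(av[keep], levels = alleles), pp[keep])
    cnt <- matrix(as.numeric(cnt), nrow = length(alleles),
                  dimnames = list(as.character(alleles), pops))
    n <- colSums(cnt)
    f <- cnt
    if (any(n > 0)) f[, n > 0] <- sweep(cnt[, n > 0, drop = FALSE], 2L, n[n > 0], "/")
    ss[l, ] <- as.integer(n)
    freqs[[l]] <- f
  }
  dead <- colSums(ss) == 0L
  if (any(dead))
    stop("population(s) with no observed alleles at any locus: ",
         paste(pops[dead], collapse = ", "))
  structure(list(freqs = freqs, sample_sizes = ss, loci = d$loci,
                 populations = pops),
            class = "allele_freq_set")
}

#' Assemble an allele frequency set from raw matrices
#'
#' Entry point for users who have per-locus allele frequency matrices
#' rather than genotypes (rows = alleles, columns = populations; each
#' column summing to 1, or all zero where a population has no data).
#'
#' @param freqs named list of numeric matrices, one per locus, all with
#'   the same set of population columns.
#' @param sample_sizes optional loci-by-populations matrix of observed
#'   allele-copy counts; defaults to 1 wherever a column carries data.
#' @return An `allele_freq_set`.
#' @export
allele_freq_set <- function(freqs, sample_sizes = NULL) {
  if (!is.list(freqs) || length(freqs) < 1L)
    stop("`freqs` must be a non-empty list of matrices")
  if (is.null(names(freqs))) names(freqs) <- sprintf("loc%d", seq_along(freqs))
  pops <- colnames(freqs[[1L]])
  if (is.null(pops)) pops <- sprintf("pop%d", ncol(freqs[[1L]]))
  P <- length(pops)
  if (P < 2L) stop("at least 2 populations are required")
  freqs <- lapply(freqs, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != P) stop("all loci must cover the same populations")
    colnames(m) <- pops
    if (is.null(rownames(m))) rownames(m) <- as.character(seq_len(nrow(m)))
    cs <- colSums(m)
    if (any(m < -1e-12) || any(m > 1 + 1e-12))
      stop("allele frequencies must lie in [0, 1]")
    if (any(abs(cs - 1) > 1e-9 & cs != 0))
      stop("each column must sum to 1 (or be all zero)")
    m
  })
  if (is.null(sample_sizes)) {
    sample_sizes <- t(vapply(freqs, function(m) as.integer(colSums(m) > 0),
                             integer(P)))
    dimnames(sample_sizes) <- list(names(freqs), pops)
  }
  structure(list(freqs = freqs, sample_sizes = sample_sizes,
                 loci = names(freqs), populations = pops),
            class = "allele_freq_set")
}

#' @export
print.allele_freq_set <- function(x, ...) {
  cat(sprintf("allele_freq_set: %d loci, %d populations\n",
              length(x$loci), length(x$populations)))
  cat("populations:", paste(x$populations, collapse = ", "), "\n")
  na <- vapply(x$freqs, nrow, 0L)
  cat(sprintf("alleles per locus: min %d, median %s, max %d\n",
              min(na), format(stats::median(na)), max(na)))
  invisible(x)
}

#' Write a population-by-population matrix as CSV
#'
#' Row label = source population, column label = target population; the
#' diagonal is written as an empty cell.
#'
#' @param m square numeric matrix with at least 2 rows.
#' @param path output path.
#' @param labels population labels; defaults to `rownames(m)`.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(m, path, labels = rownames(m)) {
  m <- unclass(m)
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("`m` must be a square matrix")
  if (nrow(m) < 2L) stop("at least 2 populations are required")
  if (is.null(labels)) stop("population labels are required")
  if (length(labels) != nrow(m))
    stop("label/dimension mismatch: ", length(labels), " labels for ",
         nrow(m), " populations")
  if (any(grepl(",", labels, fixed = TRUE)))
    stop("population labels must not contain commas")
  body <- matrix(sprintf("%.12g", m), nrow(m))
  body[!is.finite(m)] <- ""
  diag(body) <- ""
  lines <- c(paste(c("", labels), collapse = ","),
             vapply(seq_len(nrow(m)),
                    function(i) paste(c(labels[i], body[i, ]), collapse = ","),
                    ""))
  writeLines(lines, path)
  invisible(path)
}

#' Read a matrix written by [write_matrix_csv()]
#' @param path CSV path.
#' @return Square numeric matrix with `NA` on the diagonal.
#' @export
read_matrix_csv <- function(path) {
  df <- read.csv(path, row.names = 1L, check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  m
}
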