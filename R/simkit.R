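# Coalescent simulation of stepwise-mutation microsatellites under an
# n-deme migration matrix, and the percent-correct-direction power
# experiments used to validate the directional method.
#
# Migration rates follow the backward convention (the probability per
# generation that a gene copy's parent resided in another deme), the
# same convention coalescent simulators use. Note the reversal: forward
# gene flow FROM deme q TO deme p means lineages sampled in p trace
# back into q, i.e. migration[p, q] = m. The experiment helpers below
# take *gene-flow* patterns and build the backward matrix internally.

#' Simulation configuration
#'
#' @param n_demes number of demes (>= 2).
#' @param migration `n_demes x n_demes` matrix of backward migration
#'   rates: entry (i, j) is the per-generation probability that a
#'   lineage in deme i traces its parent to deme j (row = receiving
#'   deme, in the forward sense). Diagonal is ignored; off-diagonal row
#'   sums must stay below 1.
#' @param deme_size diploid deme size N (default 1000, so 2N = 2000 gene
#'   copies per deme).
#' @param mu mutation rate per locus per generation (default 5e-4, a
#'   typical vertebrate microsatellite rate).
#' @param n_loci number of independent loci.
#' @param sample_size diploid individuals sampled per deme.
#' @param seed optional integer seed.
#' @param deme_names optional labels (default `A`, `B`, ... for up to 26
#'   demes).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_demes, migration, deme_size = 1000, mu = 5e-4,
                       n_loci = 50L, sample_size = 50L, seed = NULL,
                       deme_names = NULL) {
  if (n_demes < 2L) stop("`n_demes` must be at least 2")
  migration <- as.matrix(migration)
  if (!identical(dim(migration), c(as.integer(n_demes), as.integer(n_demes))))
    stop("`migration` must be an n_demes x n_demes matrix")
  if (any(migration < 0) || any(migration > 1))
    stop("migration rates must lie in [0, 1]")
  diag(migration) <- 0
  if (any(rowSums(migration) >= 1))
    stop("off-diagonal migration row sums must be below 1")
  if (deme_size < 2) stop("`deme_size` must be at least 2")
  if (mu <= 0 || mu >= 1) stop("`mu` must lie in (0, 1)")
  if (n_loci < 1L) stop("`n_loci` must be at least 1")
  if (sample_size < 1L) stop("`sample_size` must be at least 1")
  if (is.null(deme_names)) {
    deme_names <- if (n_demes <= 26L) LETTERS[seq_len(n_demes)]
                  else sprintf("Pop%d", seq_len(n_demes))
  }
  if (length(deme_names) != n_demes) stop("one name per deme is required")
  structure(list(n_demes = as.integer(n_demes), migration = migration,
                 deme_size = deme_size, mu = mu, n_loci = as.integer(n_loci),
                 sample_size = as.integer(sample_size), seed = seed,
                 deme_names = as.character(deme_names)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("sim_config: %d demes of N = %g diploids, mu = %g, ",
                     "%d loci, %d individuals sampled per deme\n"),
              x$n_demes, x$deme_size, x$mu, x$n_loci, x$sample_size))
  cat("backward migration matrix (row = receiving deme):\n")
  print(x$migration)
  invisible(x)
}

#' Backward migration matrix for a two-deme gene-flow pattern
#'
#' Builds the 2x2 backward matrix for demes (A, B) under the three
#' canonical patterns, with `m` the total gene-flow rate:
#' `"unidirectional"` puts all flow B -> A; `"symmetric"` splits it
#' `m/2` each way; `"asymmetric"` puts `m/4` A -> B and `3m/4` B -> A.
#'
#' @param pattern one of `"unidirectional"`, `"symmetric"`,
#'   `"asymmetric"`.
#' @param m total gene-flow rate per generation.
#' @return 2x2 backward migration matrix labelled A, B.
#' @export
two_deme_migration <- function(pattern = c("unidirectional", "symmetric",
                                           "asymmetric"), m) {
  pattern <- match.arg(pattern)
  if (m < 0 || m >= 1) stop("`m` must lie in [0, 1)")
  # forward flow B->A at rate r means backward migration[A, B] = r
  ba <- switch(pattern, unidirectional = m, symmetric = m / 2,
               asymmetric = 3 * m / 4)
  ab <- switch(pattern, unidirectional = 0, symmetric = m / 2,
               asymmetric = m / 4)
  matrix(c(0, ba, ab, 0), 2L, 2L, byrow = TRUE,
         dimnames = list(c("A", "B"), c("A", "B")))
}

#' Backward migration matrix of a directed ring
#'
#' Circular stepping-stone with unidirectional forward flow
#' `1 -> 2 -> ... -> n -> 1` at rate `m`; the backward matrix therefore
#' has `migration[i, i-1] = m` (deme i receives from its predecessor),
#' one nonzero off-diagonal entry per row.
#'
#' @param n_demes number of demes (>= 3).
#' @param m per-generation migration rate along each ring edge.
#' @return `n_demes x n_demes` backward migration matrix.
#' @export
ring_migration <- function(n_demes, m) {
  if (n_demes < 3L) stop("a ring needs at least 3 demes")
  if (m < 0 || m >= 1) stop("`m` must lie in [0, 1)")
  mig <- matrix(0, n_demes, n_demes)
  for (i in seq_len(n_demes)) {
    from <- if (i == 1L) n_demes else i - 1L
    mig[i, from] <- m
  }
  mig
}

#' Simulate one microsatellite locus
#'
#' Samples a genealogy of the requested gene copies under the structured
#' coalescent, then drops stepwise mutations (repeat count +/- 1 with
#' equal probability) as a Poisson process along branches. When some
#' sampled demes can never exchange migrants, their subtrees are joined
#' at deeply separated times (gap `5000/mu` generations) so they carry
#' effectively unrelated alleles, and a `forced_join` flag is set.
#'
#' @param n_copies integer vector: gene copies to sample per deme.
#' @param deme_size diploid deme size N.
#' @param migration backward migration matrix.
#' @param mu mutation rate per locus per generation.
#' @param root_allele repeat count at the root (arbitrary offset).
#' @param max_events cap on coalescence + migration events.
#' @return List with `alleles` (integer repeat counts, deme-block
#'   order), `tmrca`, `tree_length`, `forced_join`.
#' @export
simulate_locus <- function(n_copies, deme_size, migration, mu,
                           root_allele = 100L, max_events = 5e7) {
  migration <- as.matrix(migration)
  diag(migration) <- 0
  .sim_locus_cpp(as.integer(n_copies), 2 * deme_size, migration, mu,
                 as.integer(root_allele), 5e3 / mu, max_events)
}

#' Simulate a multilocus genotype dataset
#'
#' Loci are independent draws from the structured coalescent at
#' stationarity; diploid genotypes are formed by random pairing of the
#' sampled gene copies within each deme. Deterministic given
#' `cfg$seed`. A warning is raised when isolated demes forced deep
#' joins (effectively infinite divergence).
#'
#' @param cfg a [sim_config()].
#' @return A [genotype_dataset()] with populations named by
#'   `cfg$deme_names`.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  nc <- rep(2L * cfg$sample_size, cfg$n_demes)
  n <- cfg$sample_size * cfg$n_demes
  geno <- array(NA_integer_, c(n, cfg$n_loci, 2L))
  any_forced <- FALSE
  for (l in seq_len(cfg$n_loci)) {
    sim <- simulate_locus(nc, cfg$deme_size, cfg$migration, cfg$mu)
    any_forced <- any_forced || sim$forced_join
    al <- sim$alleles
    if (min(al) < 1L) al <- al - min(al) + 1L
    odd <- seq(1L, length(al), by = 2L)
    geno[, l, 1L] <- al[odd]
    geno[, l, 2L] <- al[odd + 1L]
  }
  if (any_forced)
    warning("some demes cannot exchange migrants; their divergence is ",
            "effectively infinite")
  genotype_dataset(geno, rep(cfg$deme_names, each = cfg$sample_size),
                   loci = sprintf("L%03d", seq_len(cfg$n_loci)))
}

#' Island-model differentiation anchor
#'
#' Expected equilibrium differentiation under Wright's infinite island
#' model, `Fst = 1 / (4 N m + 1)`; links the simulated migration rates
#' to divergence levels (m = 0.00025, 0.005, 0.05 at N = 1000 give
#' 0.5, ~0.05, ~0.005).
#'
#' @param N diploid deme size.
#' @param m migration rate per generation.
#' @return Expected Fst.
#' @export
island_fst <- function(N, m) 1 / (4 * N * m + 1)

#' Equilibrium heterozygosity under the stepwise mutation model
#'
#' For a panmictic population with scaled mutation rate `theta = 4 N mu`
#' the expected heterozygosity is `1 - 1/sqrt(1 + 2 theta)`; used as a
#' closed-form sanity check of the simulator.
#'
#' @param theta scaled mutation rate `4 N mu`.
#' @return Expected heterozygosity.
#' @export
smm_equilibrium_het <- function(theta) 1 - 1 / sqrt(1 + 2 * theta)

# directional statistics for both stats and both directions of a
# two-deme dataset; returns matrix [stat x direction] of b values
.two_deme_b <- function(dat) {
  fr <- allele_frequencies(dat)
  st <- .stack_freqs(fr)
  us <- st$usable[, 1L] & st$usable[, 2L]
  bAB <- .pair_stat_stacked(st$F[, 1L], st$F[, 2L], st$starts, st$ends, us)
  bBA <- .pair_stat_stacked(st$F[, 2L], st$F[, 1L], st$starts, st$ends, us)
  cbind(AB = bAB, BA = bBA)
}

#' Percent-correct-direction experiment
#'
#' Replicates the two-deme validation design: simulate `n_replicates`
#' datasets under a gene-flow pattern, compute directional relative
#' migration from both Jost's D and Gst, and record how often the
#' method ranks the B -> A direction higher (`c(B->A) > c(A->B)`,
#' equivalently lower directional differentiation out of B). Under the
#' unidirectional and asymmetric patterns B -> A is the simulated
#' dominant direction, so this is the percent of correct calls; under
#' the symmetric pattern the expectation is 50%. Ties count as
#' incorrect.
#'
#' @param pattern `"unidirectional"`, `"symmetric"` or `"asymmetric"`
#'   (see [two_deme_migration()]).
#' @param m total gene-flow rate.
#' @param sample_size diploid individuals sampled per deme.
#' @param n_loci loci per dataset.
#' @param n_replicates simulated datasets (>= 1).
#' @param deme_size,mu demography (defaults N = 1000, mu = 5e-4).
#' @param seed optional integer seed.
#' @return A `scenario_result`: scenario descriptors plus a data frame
#'   `results` with `statistic`, `percent_correct` and `n_ties`.
#' @export
run_direction_experiment <- function(pattern = c("unidirectional",
                                                 "symmetric", "asymmetric"),
                                     m, sample_size, n_loci, n_replicates,
                                     deme_size = 1000, mu = 5e-4,
                                     seed = NULL) {
  pattern <- match.arg(pattern)
  if (n_replicates < 1L) stop("`n_replicates` must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  cfg <- sim_config(2L, two_deme_migration(pattern, m), deme_size = deme_size,
                    mu = mu, n_loci = n_loci, sample_size = sample_size,
                    deme_names = c("A", "B"))
  hits <- c(gst = 0L, d = 0L)
  ties <- c(gst = 0L, d = 0L)
  for (r in seq_len(n_replicates)) {
    b <- .two_deme_b(simulate_dataset(cfg))
    for (s in c("gst", "d")) {
      if (b[s, "BA"] < b[s, "AB"]) hits[[s]] <- hits[[s]] + 1L
      else if (b[s, "BA"] == b[s, "AB"]) ties[[s]] <- ties[[s]] + 1L
    }
  }
  structure(list(pattern = pattern, m = m, sample_size = sample_size,
                 n_loci = n_loci, n_replicates = as.integer(n_replicates),
                 results = data.frame(
                   statistic = c("gst", "d"),
                   percent_correct = 100 * as.vector(hits) / n_replicates,
                   n_ties = as.vector(ties),
                   stringsAsFactors = FALSE)),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("%s gene flow, m = %g, s = %d, %d loci, %d replicates\n",
              x$pattern, x$m, x$sample_size, x$n_loci, x$n_replicates))
  cat("percent of replicates ranking B -> A higher:\n")
  print(x$results, row.names = FALSE)
  invisible(x)
}

#' Simulate a directed-ring (circular stepping stone) dataset
#'
#' Five demes connected `1 -> 2 -> 3 -> 4 -> 5 -> 1` by default, with
#' unidirectional migration at rate `m` along each edge.
#'
#' @param n_demes number of demes (>= 3).
#' @param m migration rate along each ring edge (default 5e-4).
#' @param deme_size,mu,n_loci,sample_size,seed as in [sim_config()].
#' @return A [genotype_dataset()].
#' @export
ring_scenario <- function(n_demes = 5L, m = 5e-4, deme_size = 1000,
                          mu = 5e-4, n_loci = 50L, sample_size = 50L,
                          seed = NULL) {
  if (m == 0) warning("m = 0 disconnects the ring; demes will be isolated")
  cfg <- sim_config(n_demes, ring_migration(n_demes, m),
                    deme_size = deme_size, mu = mu, n_loci = n_loci,
                    sample_size = sample_size, seed = seed)
  simulate_dataset(cfg)
}

#' Read a scenario sweep configuration
#'
#' YAML file with a `scenarios` list; each entry gives `pattern`, `m`,
#' `sample_size`, `n_loci`, `n_replicates` and optionally `deme_size`,
#' `mu`. A top-level `seed` seeds the whole sweep.
#'
#' @param path YAML file path.
#' @return List with `seed` and `scenarios`.
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$scenarios) || !length(cfg$scenarios))
    stop("config must contain a non-empty `scenarios` list")
  req <- c("pattern", "m", "sample_size", "n_loci", "n_replicates")
  for (i in seq_along(cfg$scenarios)) {
    miss <- setdiff(req, names(cfg$scenarios[[i]]))
    if (length(miss))
      stop(sprintf("scenario %d: missing field(s) %s", i,
                   paste(miss, collapse = ", ")))
  }
  cfg
}

#' Run a sweep of direction experiments
#' @param cfg list from [read_scenario_config()].
#' @return Data frame with one row per scenario and statistic.
#' @export
run_scenario_sweep <- function(cfg) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  out <- lapply(cfg$scenarios, function(sc) {
    res <- run_direction_experiment(
      pattern = sc$pattern, m = sc$m, sample_size = sc$sample_size,
      n_loci = sc$n_loci, n_replicates = sc$n_replicates,
      deme_size = if (is.null(sc$deme_size)) 1000 else sc$deme_size,
      mu = if (is.null(sc$mu)) 5e-4 else sc$mu)
    cbind(data.frame(pattern = res$pattern, m = res$m,
                     sample_size = res$sample_size, n_loci = res$n_loci,
                     n_replicates = res$n_replicates),
          res$results)
  })
  do.call(rbind, out)
}
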