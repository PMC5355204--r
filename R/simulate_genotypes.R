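# Simulator for two-population diploid microsatellite panels: per-locus
# allele frequencies drawn for each species, pure individuals sampled at
# Hardy-Weinberg proportions, optional F1 hybrids drawing one allele from
# each species at every locus, and per-locus missing data.

#' Parameters for the genotype simulator
#'
#' @param n_loci Number of microsatellite loci.
#' @param alleles_per_locus Number of allele states per locus (>= 2).
#' @param divergence Dirichlet concentration for per-locus species allele
#'   frequencies, drawn independently for the two species. Small values
#'   produce near-fixed, strongly diverged loci; large values push both
#'   species toward the same uniform frequencies; `Inf` makes the two
#'   species' frequencies identical (uniform), i.e. no assignment signal.
#' @param n_per_species Length-2 vector: pure individuals per species.
#' @param n_f1 Number of F1 hybrids (one parent from each species).
#' @param missing_rate Probability an individual's locus is unscored
#'   (both allele copies missing).
#' @param diagnostic If `TRUE`, the two species use disjoint halves of the
#'   allele set at every locus (fully diagnostic loci); requires
#'   `alleles_per_locus >= 2`.
#' @param seed Integer seed.
#' @return An object of class `sim_genotype_params`.
#' @export
sim_genotype_params <- function(n_loci = 9,
                                alleles_per_locus = 6,
                                divergence = 0.2,
                                n_per_species = c(25, 25),
                                n_f1 = 0,
                                missing_rate = 0.05,
                                diagnostic = FALSE,
                                seed = 1L) {
  if (alleles_per_locus < 2) {
    stop("alleles_per_locus must be at least 2", call. = FALSE)
  }
  stopifnot(n_loci >= 1, divergence > 0, length(n_per_species) == 2,
            all(n_per_species >= 0), n_f1 >= 0,
            missing_rate >= 0, missing_rate < 1)
  structure(list(
    n_loci = as.integer(n_loci),
    alleles_per_locus = as.integer(alleles_per_locus),
    divergence = divergence,
    n_per_species = as.integer(n_per_species),
    n_f1 = as.integer(n_f1),
    missing_rate = missing_rate,
    diagnostic = isTRUE(diagnostic),
    seed = as.integer(seed)), class = "sim_genotype_params")
}

#' Simulate two-population diploid genotypes with optional F1 hybrids
#'
#' Pure individuals are drawn at Hardy-Weinberg proportions from their
#' species' per-locus allele frequencies; F1 hybrids draw one allele copy
#' from each species' frequency vector at every locus. Missing loci are
#' coded `NA` in the array (and -9 on export).
#'
#' @param params A [sim_genotype_params()] object.
#' @return A list of class `sim_genotypes` with elements `genotypes`
#'   (individuals x loci x 2 integer allele array, `NA` = missing),
#'   `truth` (data frame `id`, `origin` in A/B/F1), and `freqs`
#'   (list of per-locus allele-frequency matrices, rows = species).
#' @export
simulate_genotypes <- function(params) {
  stopifnot(inherits(params, "sim_genotype_params"))
  p <- params
  set.seed(p$seed)
  J <- p$alleles_per_locus

  freqs <- vector("list", p$n_loci)
  for (l in seq_len(p$n_loci)) {
    if (p$diagnostic) {
      half <- floor(J / 2)
      fa <- c(rep(1 / half, half), rep(0, J - half))
      fb <- c(rep(0, half), rep(1 / (J - half), J - half))
    } else if (is.infinite(p$divergence)) {
      fa <- fb <- rep(1 / J, J)
    } else {
      fa <- rdirichlet1(rep(p$divergence, J))
      fb <- rdirichlet1(rep(p$divergence, J))
    }
    freqs[[l]] <- rbind(A = fa, B = fb)
  }

  n_tot <- sum(p$n_per_species) + p$n_f1
  origin <- c(rep("A", p$n_per_species[1]), rep("B", p$n_per_species[2]),
              rep("F1", p$n_f1))
  geno <- array(NA_integer_, dim = c(n_tot, p$n_loci, 2))
  for (i in seq_len(n_tot)) {
    for (l in seq_len(p$n_loci)) {
      f <- freqs[[l]]
      geno[i, l, ] <- switch(origin[i],
        A = sample.int(J, 2, replace = TRUE, prob = f["A", ]),
        B = sample.int(J, 2, replace = TRUE, prob = f["B", ]),
        F1 = c(sample.int(J, 1, prob = f["A", ]),
               sample.int(J, 1, prob = f["B", ])))
    }
  }
  if (p$missing_rate > 0 && n_tot > 0) {
    miss <- matrix(runif(n_tot * p$n_loci) < p$missing_rate, n_tot, p$n_loci)
    for (i in seq_len(n_tot)) {
      geno[i, miss[i, ], ] <- NA_integer_
    }
  }
  structure(list(
    genotypes = geno,
    truth = data.frame(id = sprintf("IND%03d", seq_len(max(n_tot, 0))),
                       origin = origin, stringsAsFactors = FALSE),
    freqs = freqs), class = "sim_genotypes")
}
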