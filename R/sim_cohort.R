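#' Simulate a diploid two-population cohort under a demographic scenario
#'
#' Event-driven structured-coalescent simulation with piecewise-constant
#' population sizes and symmetric migration, following the scenario's
#' backward-time epoch table. Each of the scenario's `n_loci` loci gets an
#' independent genealogy; mutations fall on branches as a Poisson process
#' under the infinite-sites approximation and are polarized (the ancestral
#' allele is known by construction).
#'
#' Time is in units of `2 * N_ref` generations, so the pairwise coalescence
#' rate inside a population of relative size `nu` is `1 / nu` and the
#' per-lineage migration rate is the scaled rate `M`.
#'
#' @param scenario a [demography_scenario()].
#' @param seed integer seed; identical seeds give identical cohorts.
#' @param mean_depth mean simulated per-sample sequencing depth at variant
#'   sites (Poisson).
#' @return An object of class `synthetic_cohort`: a list with
#'   \describe{
#'     \item{sites}{data.frame `scaffold`, `pos` (1-based), `anc`, `der`.}
#'     \item{hap}{0/1 derived-allele matrix, sites x haploids.}
#'     \item{geno}{derived-allele dosage matrix (0/1/2), sites x diploids.}
#'     \item{depth}{per-sample depth matrix, sites x diploids.}
#'     \item{pop}{population label per diploid individual.}
#'     \item{truth}{list with the scenario and seed.}
#'   }
#' @export
simulate_two_pop_cohort <- function(scenario, seed, mean_depth = 20) {
  stopifnot(inherits(scenario, "demography_scenario"))
  if (mean_depth <= 0) stop_field("mean_depth", "must be > 0")
  set.seed(as.integer(seed))

  ns <- scenario$sample_sizes
  n_hap <- sum(ns)
  hap_pop <- rep(seq_along(ns), ns)
  locus_len <- floor(scenario$sequence_length / scenario$n_loci)
  theta_locus <- scenario$theta_site * locus_len

  ep <- scenario$epochs
  ep_mat <- cbind(ep$t0, ep$t1, ep$nu1,
                  ifelse(is.na(ep$nu2), 1, ep$nu2), ep$M,
                  as.numeric(ep$merged))
  res <- .sim_cohort_cpp(ep_mat, as.integer(hap_pop),
                         scenario$n_loci, theta_locus, locus_len)
  ord <- order(res$locus, res$pos)
  hap <- res$hap[ord, , drop = FALSE]
  sites <- data.frame(scaffold = sprintf("scf%d", res$locus[ord]),
                      pos = res$pos[ord],
                      anc = rep("A", length(ord)),
                      der = rep("G", length(ord)),
                      stringsAsFactors = FALSE)

  n_ind <- n_hap %/% 2L
  ind_pop <- hap_pop[seq(1, n_hap, by = 2)]
  geno <- hap[, seq(1, n_hap, by = 2), drop = FALSE] +
    hap[, seq(2, n_hap, by = 2), drop = FALSE]
  colnames(geno) <- sprintf("ind%d", seq_len(n_ind))
  depth <- matrix(rpois(nrow(geno) * n_ind, mean_depth),
                  nrow = nrow(geno), ncol = n_ind,
                  dimnames = list(NULL, colnames(geno)))

  structure(list(
    sites = sites, hap = hap, geno = geno, depth = depth,
    pop = factor(sprintf("pop%d", ind_pop)),
    truth = list(scenario = scenario, seed = as.integer(seed))
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d segregating sites, %d diploids (%s)\n",
              nrow(x$sites), ncol(x$geno),
              paste(table(x$pop), collapse = " + ")))
  invisible(x)
}

#' Watterson's estimator of the per-site scaled mutation rate
#'
#' `theta_W = S / (a_n * L)` with `a_n` the harmonic number for `n - 1`.
#'
#' @param n_segregating number of segregating sites.
#' @param n_haploids haploid sample size.
#' @param length_bp sequence length surveyed.
#' @return estimate of theta per site.
#' @export
watterson_theta <- function(n_segregating, n_haploids, length_bp) {
  if (n_haploids < 2) stop_field("n_haploids", "must be >= 2")
  n_segregating / (sum(1 / seq_len(n_haploids - 1)) * length_bp)
}

#' Mean pairwise nucleotide diversity of a cohort
#'
#' Average number of pairwise differences between haplotypes, per site.
#'
#' @param cohort a `synthetic_cohort`.
#' @return nucleotide diversity per bp.
#' @export
pairwise_diversity <- function(cohort) {
  n <- ncol(cohort$hap)
  if (nrow(cohort$hap) == 0) return(0)
  k <- rowSums(cohort$hap)
  sum(k * (n - k)) / choose(n, 2) / cohort$truth$scenario$sequence_length
}
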