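#' Demographic scenarios for one- and two-population histories
#'
#' A scenario couples a demographic model (piecewise-constant population
#' sizes, a population split, optional symmetric migration) with the
#' mutational and sampling parameters needed to simulate a cohort or to
#' compute an expected allele-frequency spectrum.
#'
#' Parameters are scaled the way diffusion-based AFS inference scales them:
#' population sizes `nu` are diploid sizes relative to the ancestral
#' (reference) size, epoch durations `tau` are in units of `2 * N_ref`
#' generations, and the migration rate `M = 2 * N_ref * m` where `m` is the
#' per-lineage per-generation migration probability.
#'
#' Supported models:
#' \describe{
#'   \item{CONST}{A single constant-size population (used for neutral-limit
#'     checks and as the null in nested comparisons).}
#'   \item{IM}{The ancestral population splits `tau_split` ago into two
#'     subpopulations of relative sizes `nu1`, `nu2` exchanging migrants
#'     symmetrically at scaled rate `M`.}
#'   \item{BIM}{The ancestral population passes through a bottleneck of
#'     relative size `nu_b` lasting `tau_b`, then splits into sizes
#'     `nu1`, `nu2` for `tau_split` (no migration).}
#'   \item{SBR}{Split `tau_split + tau_b + tau_r` ago at ancestral size;
#'     each subpopulation then bottlenecks to `nu1_b`/`nu2_b` for `tau_b`
#'     and recovers to `nu1_r`/`nu2_r` for the final `tau_r`.}
#'   \item{ISB}{The ancestral population changes size to `nu_growth` for
#'     `tau_growth`, splits `tau_split` ago, and each subpopulation
#'     independently bottlenecks to `nu1_b`/`nu2_b` starting `tau_b1`/
#'     `tau_b2` ago (both at most `tau_split`), lasting to the present.}
#' }
#'
#' @param model_id one of `"CONST"`, `"IM"`, `"BIM"`, `"SBR"`, `"ISB"`.
#' @param params named list of scaled model parameters (see Details).
#' @param ancestral_size ancestral (reference) diploid population size.
#' @param mutation_rate mutation rate per site, interpreted according to
#'   `mutation_rate_units`.
#' @param mutation_rate_units `"per_year"` (converted internally to a
#'   per-generation rate via `generation_time`) or `"per_generation"`.
#' @param generation_time generation time in years.
#' @param sequence_length total sequence length in bp, split evenly across
#'   `n_loci` independently segregating loci.
#' @param n_loci number of freely recombining loci the sequence is split
#'   into (coalescent simulation treats loci as independent).
#' @param sample_sizes haploid sample sizes; one element for `CONST`, two
#'   for the two-population models. Each must be an even number of at
#'   least 2 (haploids are paired into diploid individuals).
#'
#' @return An object of class `demography_scenario`: a list with the input
#'   fields, the per-generation mutation rate `mu_gen`, the per-site scaled
#'   mutation rate `theta_site = 4 * N_ref * mu_gen`, and `epochs`, a
#'   backward-time epoch table with columns `t0`, `t1` (scaled time, present
#'   = 0), `nu1`, `nu2`, `M` and `merged`.
#' @export
#' @examples
#' sc <- demography_scenario("IM",
#'   params = list(nu1 = 1, nu2 = 0.5, tau_split = 0.2, M = 0.5),
#'   sample_sizes = c(8, 6))
#' sc$epochs
demography_scenario <- function(model_id = c("CONST", "IM", "BIM", "SBR", "ISB"),
                                params = list(),
                                ancestral_size = 10000,
                                mutation_rate = 0.3e-8,
                                mutation_rate_units = c("per_year", "per_generation"),
                                generation_time = 3,
                                sequence_length = 1e6,
                                n_loci = 100,
                                sample_sizes = c(8, 6)) {
  model_id <- match.arg(model_id)
  mutation_rate_units <- match.arg(mutation_rate_units)

  if (!is.numeric(ancestral_size) || ancestral_size <= 0)
    stop_field("ancestral_size", "must be > 0")
  if (!is.numeric(mutation_rate) || mutation_rate < 0)
    stop_field("mutation_rate", "must be >= 0")
  if (generation_time <= 0) stop_field("generation_time", "must be > 0")
  if (sequence_length <= 0) stop_field("sequence_length", "must be > 0")
  if (n_loci < 1 || n_loci > sequence_length)
    stop_field("n_loci", "must be in [1, sequence_length]")

  n_pops <- if (model_id == "CONST") length(sample_sizes) else 2L
  if (model_id != "CONST" && length(sample_sizes) != 2L)
    stop_field("sample_sizes", "two-population models need two sample sizes")
  if (any(sample_sizes < 2)) stop_field("sample_sizes", "must all be >= 2")
  if (any(sample_sizes %% 2 != 0))
    stop_field("sample_sizes", "haploid sample sizes must be even (diploids)")

  epochs <- build_epochs(model_id, params)

  mu_gen <- if (mutation_rate_units == "per_year")
    mutation_rate * generation_time else mutation_rate

  structure(list(
    model_id = model_id,
    params = params,
    ancestral_size = ancestral_size,
    mu_gen = mu_gen,
    generation_time = generation_time,
    sequence_length = sequence_length,
    n_loci = as.integer(n_loci),
    sample_sizes = as.integer(sample_sizes),
    theta_site = 4 * ancestral_size * mu_gen,
    epochs = epochs
  ), class = "demography_scenario")
}

# Backward-time epoch table for each model. Epochs are ordered from the
# present (t0 = 0) into the past; the final epoch is the merged ancestral
# population at relative size 1 extending to t1 = Inf.
build_epochs <- function(model_id, p) {
  need <- function(names) {
    for (nm in names) {
      if (is.null(p[[nm]]) || !is.numeric(p[[nm]]))
        stop_field(nm, sprintf("missing numeric parameter for model %s", model_id))
    }
  }
  pos <- function(nm) if (p[[nm]] <= 0) stop_field(nm, "must be > 0")
  nonneg <- function(nm) if (p[[nm]] < 0) stop_field(nm, "must be >= 0")

  # columns assembled as plain vectors; one data.frame built at the end
  # (this sits on the hot path of every likelihood evaluation)
  cols <- switch(model_id,
    CONST = list(0, Inf, 1, NA, 0, TRUE),
    IM = {
      need(c("nu1", "nu2", "tau_split", "M"))
      pos("nu1"); pos("nu2"); nonneg("tau_split"); nonneg("M")
      list(c(0, p$tau_split), c(p$tau_split, Inf),
           c(p$nu1, 1), c(p$nu2, NA), c(p$M, 0), c(FALSE, TRUE))
    },
    BIM = {
      need(c("nu_b", "tau_b", "nu1", "nu2", "tau_split"))
      pos("nu_b"); pos("nu1"); pos("nu2"); nonneg("tau_b"); nonneg("tau_split")
      ts <- p$tau_split; tb <- ts + p$tau_b
      list(c(0, ts, tb), c(ts, tb, Inf),
           c(p$nu1, p$nu_b, 1), c(p$nu2, NA, NA),
           c(0, 0, 0), c(FALSE, TRUE, TRUE))
    },
    SBR = {
      need(c("tau_split", "nu1_b", "nu2_b", "tau_b", "nu1_r", "nu2_r", "tau_r"))
      for (nm in c("nu1_b", "nu2_b", "nu1_r", "nu2_r")) pos(nm)
      for (nm in c("tau_split", "tau_b", "tau_r")) nonneg(nm)
      t1 <- p$tau_r; t2 <- t1 + p$tau_b; t3 <- t2 + p$tau_split
      list(c(0, t1, t2, t3), c(t1, t2, t3, Inf),
           c(p$nu1_r, p$nu1_b, 1, 1), c(p$nu2_r, p$nu2_b, 1, NA),
           c(0, 0, 0, 0), c(FALSE, FALSE, FALSE, TRUE))
    },
    ISB = {
      need(c("nu_growth", "tau_growth", "tau_split", "nu1_b", "nu2_b",
             "tau_b1", "tau_b2"))
      pos("nu_growth"); pos("nu1_b"); pos("nu2_b")
      for (nm in c("tau_growth", "tau_split", "tau_b1", "tau_b2")) nonneg(nm)
      if (p$tau_b1 > p$tau_split) stop_field("tau_b1", "must be <= tau_split")
      if (p$tau_b2 > p$tau_split) stop_field("tau_b2", "must be <= tau_split")
      cuts <- sort(unique(c(0, p$tau_b1, p$tau_b2, p$tau_split)))
      t0 <- cuts[-length(cuts)]
      t1 <- cuts[-1]
      nu1 <- ifelse(t1 <= p$tau_b1, p$nu1_b, p$nu_growth)
      nu2 <- ifelse(t1 <= p$tau_b2, p$nu2_b, p$nu_growth)
      tg <- p$tau_split + p$tau_growth
      list(c(t0, p$tau_split, tg), c(t1, tg, Inf),
           c(nu1, p$nu_growth, 1), c(nu2, NA, NA),
           rep(0, length(t0) + 2),
           c(rep(FALSE, length(t0)), TRUE, TRUE))
    }
  )
  keep <- cols[[2]] > cols[[1]]   # drop zero-length epochs (tau = 0)
  tab <- data.frame(t0 = cols[[1]][keep], t1 = cols[[2]][keep],
                    nu1 = cols[[3]][keep], nu2 = cols[[4]][keep],
                    M = cols[[5]][keep], merged = cols[[6]][keep])
  if (any(diff(tab$t0) < 0)) stop_field("epoch_params", "times must be ordered")
  tab
}

#' @export
print.demography_scenario <- function(x, ...) {
  cat(sprintf("<demography_scenario> model %s, N_ref = %g, theta/site = %g\n",
              x$model_id, x$ancestral_size, x$theta_site))
  cat(sprintf("  L = %g bp over %d loci; haploid samples: %s\n",
              x$sequence_length, x$n_loci,
              paste(x$sample_sizes, collapse = " + ")))
  print(x$epochs)
  invisible(x)
}

#' Convert scaled epoch times to years before present
#'
#' @param scenario a [demography_scenario()].
#' @param tau scaled times (units of `2 * N_ref` generations).
#' @return times in years.
#' @export
tau_to_years <- function(scenario, tau) {
  tau * 2 * scenario$ancestral_size * scenario$generation_time
}
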