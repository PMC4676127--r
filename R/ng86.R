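#' Nei-Gojobori (1986) pairwise synonymous/nonsynonymous counting
#'
#' Counts synonymous and nonsynonymous sites and differences between two
#' in-frame coding sequences by the NG86 scheme: per-codon synonymous site
#' fractions from single-nucleotide neighbour enumeration (changes to stop
#' codons excluded), multi-step codon differences averaged over all
#' minimal pathways that avoid stop codons, and (optionally) Jukes-Cantor
#' correction of the proportions into rates.
#'
#' @param seq_a,seq_b in-frame nucleotide sequences of equal length with
#'   no internal stop codons (character strings, or character vectors of
#'   codons).
#' @param jc_correction apply the Jukes-Cantor correction
#'   `d = -3/4 * log(1 - 4 p / 3)` to `pN` and `pS`.
#' @return list with `Nd`, `Sd` (difference counts), `N`, `S` (site
#'   totals, averaged over the two sequences), `pN`, `pS`, `dN`, `dS`,
#'   `omega` (`dN/dS`) and `omega_defined` (FALSE when `dS` is 0 or a
#'   correction is out of range).
#' @export
ng86_pair <- function(seq_a, seq_b, jc_correction = TRUE) {
  ca <- if (length(seq_a) > 1) toupper(seq_a) else split_codons(seq_a)
  cb <- if (length(seq_b) > 1) toupper(seq_b) else split_codons(seq_b)
  if (length(ca) != length(cb))
    stop("sequences have unequal codon lengths")
  codon_universe()
  if (any(.codon_env$aa[ca] == "*") || any(.codon_env$aa[cb] == "*"))
    stop("internal stop codon in input")

  sites <- codon_site_counts()
  pd <- codon_pair_diffs()
  S <- (sum(sites[ca]) + sum(sites[cb])) / 2
  N <- 3 * length(ca) - S
  idx <- cbind(match(ca, codon_universe()), match(cb, codon_universe()))
  Nd <- sum(pd$nd[idx])
  Sd <- sum(pd$sd[idx])

  pN <- if (N > 0) Nd / N else 0
  pS <- if (S > 0) Sd / S else 0
  jc <- function(p) if (p < 0.75) -0.75 * log(1 - 4 * p / 3) else NA_real_
  dN <- if (jc_correction) jc(pN) else pN
  dS <- if (jc_correction) jc(pS) else pS
  defined <- !is.na(dN) && !is.na(dS) && dS > 0
  list(Nd = Nd, Sd = Sd, N = N, S = S, pN = pN, pS = pS,
       dN = dN, dS = dS,
       omega = if (defined) dN / dS else NA_real_,
       omega_defined = defined)
}
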