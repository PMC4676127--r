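#' Detect runs of homozygosity with a PLINK-style scanning rule
#'
#' For one individual, slides windows of `window_snp` consecutive SNVs
#' along each scaffold; a window is a hit when it contains at most
#' `het_allowance` heterozygous genotypes. A SNV is in ROH state when the
#' proportion of windows overlapping it that are hits exceeds
#' `hit_proportion`. Maximal runs of ROH-state SNVs become candidate
#' segments, kept when the bp span is at least `min_kb` kbp and the
#' segment carries at least one SNV per `density_kb_per_snp` kbp.
#'
#' @param sites data.frame with `scaffold`, `pos` (1-based, sorted within
#'   scaffold) and `gt` (allele dosage 0/1/2; 1 = heterozygous).
#' @param window_snp SNVs per scanning window.
#' @param density_kb_per_snp maximum kbp per SNV inside a segment.
#' @param min_kb minimum segment length in kbp.
#' @param het_allowance heterozygotes tolerated per window.
#' @param hit_proportion window-hit proportion above which a SNV is in
#'   ROH state.
#' @return list with `segments` (data.frame `scaffold`, `start_pos`,
#'   `end_pos`, `span_bp`, `n_snvs`, `n_het`) and `median_length_bp`.
#' @export
detect_roh <- function(sites, window_snp = 20, density_kb_per_snp = 50,
                       min_kb = 10, het_allowance = 1,
                       hit_proportion = 0.05) {
  stopifnot(all(c("scaffold", "pos", "gt") %in% names(sites)))
  segs <- list()
  for (nm in unique(sites$scaffold)) {
    s <- sites[sites$scaffold == nm, , drop = FALSE]
    if (is.unsorted(s$pos, strictly = FALSE))
      stop(sprintf("sites not sorted by position on scaffold %s", nm))
    n <- nrow(s)
    het <- as.integer(s$gt == 1)
    if (n < window_snp) next
    # window w covers SNVs w .. w + window_snp - 1
    n_win <- n - window_snp + 1
    csum <- cumsum(c(0, het))
    hits <- (csum[(window_snp + 1):(n + 1)] - csum[1:n_win]) <= het_allowance
    # per-SNV: windows covering SNV i are max(1, i - window_snp + 1) .. min(i, n_win)
    hcs <- cumsum(c(0, as.integer(hits)))
    lo <- pmax(1, seq_len(n) - window_snp + 1)
    hi <- pmin(seq_len(n), n_win)
    cover <- hi - lo + 1
    nhit <- hcs[hi + 1] - hcs[lo]
    in_state <- cover > 0 & (nhit / cover) > hit_proportion
    r <- rle(in_state)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      i0 <- starts[k]; i1 <- ends[k]
      span <- s$pos[i1] - s$pos[i0] + 1
      n_snv <- i1 - i0 + 1
      if (span < min_kb * 1000) next
      if (n_snv < span / (density_kb_per_snp * 1000)) next
      segs[[length(segs) + 1]] <- data.frame(
        scaffold = nm, start_pos = s$pos[i0], end_pos = s$pos[i1],
        span_bp = span, n_snvs = n_snv, n_het = sum(het[i0:i1]),
        stringsAsFactors = FALSE)
    }
  }
  segments <- if (length(segs)) do.call(rbind, segs) else
    data.frame(scaffold = character(), start_pos = integer(),
               end_pos = integer(), span_bp = integer(), n_snvs = integer(),
               n_het = integer(), stringsAsFactors = FALSE)
  rownames(segments) <- NULL
  list(segments = segments,
       median_length_bp = if (nrow(segments)) median(segments$span_bp) else NA_real_)
}

#' Per-individual ROH site stream from a variant set
#'
#' @param vs variant set.
#' @param individual column index or name.
#' @return data.frame `scaffold`, `pos`, `gt` suitable for [detect_roh()].
#' @export
roh_sites <- function(vs, individual = 1) {
  check_variant_set(vs)
  data.frame(scaffold = vs$sites$scaffold, pos = vs$sites$pos,
             gt = vs$geno[, individual], stringsAsFactors = FALSE)
}
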