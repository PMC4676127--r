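# Genomic diversity battery ----------------------------------------------
#
# These functions operate on a variant set: any list with components
# `sites` (data.frame `scaffold`, `pos` 1-based), `geno` (derived- or
# alt-allele dosage matrix 0/1/2, sites x individuals) and, where needed,
# `depth` (same shape). A `synthetic_cohort` is a variant set.

check_variant_set <- function(vs, need_depth = FALSE) {
  stopifnot(is.list(vs), !is.null(vs$sites), !is.null(vs$geno))
  if (need_depth && is.null(vs$depth))
    stop("variant set has no per-sample depth")
  invisible(vs)
}

subset_sites <- function(vs, keep) {
  vs$sites <- vs$sites[keep, , drop = FALSE]
  vs$geno <- vs$geno[keep, , drop = FALSE]
  if (!is.null(vs$depth)) vs$depth <- vs$depth[keep, , drop = FALSE]
  if (!is.null(vs$hap)) vs$hap <- vs$hap[keep, , drop = FALSE]
  rownames(vs$sites) <- NULL
  vs
}

#' Filter variant sites by per-sample read depth
#'
#' Keeps sites at which every sample's depth lies inside
#' `[min_depth, max_depth]` (bounds inclusive). Sites with a missing depth
#' in any sample are dropped and counted in the filter log.
#'
#' @param vs variant set (see package docs) with a `depth` matrix.
#' @param min_depth,max_depth inclusive per-sample depth bounds.
#' @return filtered variant set, with attribute `filter_log` (list with
#'   `n_input`, `n_kept`, `n_dropped_range`, `n_dropped_missing`).
#' @export
filter_by_depth <- function(vs, min_depth = 5, max_depth = 30) {
  check_variant_set(vs, need_depth = TRUE)
  d <- vs$depth
  miss <- rowSums(is.na(d)) > 0
  ok <- !miss & rowSums(d < min_depth | d > max_depth) == 0
  out <- subset_sites(vs, which(ok))
  attr(out, "filter_log") <- list(
    n_input = nrow(d), n_kept = sum(ok),
    n_dropped_range = sum(!ok & !miss), n_dropped_missing = sum(miss))
  out
}

#' Filter variant sites against a repeat/gap mask
#'
#' A site at 1-based position `pos` is removed iff some mask interval
#' (0-based half-open `[start, end)`) satisfies `start < pos <= end`,
#' i.e. the usual VCF-point-in-BED-interval rule. Mask intervals on
#' scaffolds absent from the variant set are ignored with a warning.
#'
#' @param vs variant set.
#' @param mask data.frame `scaffold`, `start`, `end` (0-based half-open).
#' @return list with `kept` and `removed` variant sets and
#'   `retention_percent` (see [retention_percent()]).
#' @export
filter_by_mask <- function(vs, mask) {
  check_variant_set(vs)
  unknown <- setdiff(unique(mask$scaffold), unique(vs$sites$scaffold))
  if (length(unknown) > 0) {
    warning(sprintf("mask scaffolds not in variant set ignored: %s",
                    paste(unknown, collapse = ", ")))
    mask <- mask[!mask$scaffold %in% unknown, , drop = FALSE]
  }
  n <- nrow(vs$sites)
  inside <- rep(FALSE, n)
  for (nm in unique(mask$scaffold)) {
    iv <- iv_to_iranges(mask[mask$scaffold == nm, , drop = FALSE])
    rows <- which(vs$sites$scaffold == nm)
    if (length(rows) == 0) next
    hits <- IRanges::countOverlaps(
      IRanges::IRanges(vs$sites$pos[rows], width = 1L), iv)
    inside[rows] <- hits > 0
  }
  list(kept = subset_sites(vs, which(!inside)),
       removed = subset_sites(vs, which(inside)),
       retention_percent = retention_percent(sum(!inside), n))
}

#' Percent of SNVs retained by a filter
#'
#' `100 * n_kept / n_total`, rounded to the reporting precision.
#'
#' @param n_kept,n_total site counts.
#' @param digits decimal places of the reported percentage.
#' @return retention percent.
#' @export
retention_percent <- function(n_kept, n_total, digits = 0) {
  if (n_total <= 0) stop_field("n_total", "must be > 0")
  round(100 * n_kept / n_total, digits)
}

#' Per-individual SNV rate
#'
#' Number of sites at which the individual carries at least one
#' non-reference allele, divided by the genome length.
#'
#' @param vs variant set.
#' @param genome_length genome length in bp.
#' @return named vector of per-individual rates (per bp).
#' @export
snv_rate <- function(vs, genome_length) {
  check_variant_set(vs)
  if (genome_length <= 0) stop_field("genome_length", "must be > 0")
  colSums(vs$geno > 0, na.rm = TRUE) / genome_length
}

#' SNV density in fixed non-overlapping windows
#'
#' Scaffolds shorter than the window contribute no windows; qualifying
#' scaffolds are tiled from position 0 in full windows, the trailing
#' partial window being dropped. Counts use all (cohort segregating)
#' sites in the variant set.
#'
#' @param vs variant set.
#' @param scaffold_lengths named vector of scaffold lengths (bp).
#' @param window window width in bp.
#' @return data.frame `scaffold`, `start`, `end`, `snv_count`, with
#'   attributes `genome_fraction` (window bp over total scaffold bp) and
#'   `n_excluded_scaffolds`.
#' @export
window_density <- function(vs, scaffold_lengths, window = 50000) {
  check_variant_set(vs)
  stopifnot(!is.null(names(scaffold_lengths)))
  out <- list()
  for (nm in names(scaffold_lengths)) {
    L <- scaffold_lengths[[nm]]
    n_win <- L %/% window
    if (n_win == 0) next
    start <- (seq_len(n_win) - 1) * window
    pos <- vs$sites$pos[vs$sites$scaffold == nm]
    pos <- pos[pos <= n_win * window]
    cnt <- tabulate((pos - 1) %/% window + 1, nbins = n_win)
    out[[nm]] <- data.frame(scaffold = nm, start = start,
                            end = start + window, snv_count = cnt,
                            stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(scaffold = character(), start = numeric(), end = numeric(),
               snv_count = integer(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "genome_fraction") <- sum(res$end - res$start) / sum(scaffold_lengths)
  attr(res, "n_excluded_scaffolds") <- sum(scaffold_lengths < window)
  res
}

#' Classify windows as heterozygous or homozygous
#'
#' Counts one individual's heterozygous SNVs in fixed non-overlapping
#' windows and labels a window heterozygous iff the count is strictly
#' greater than `threshold`.
#'
#' @param vs variant set.
#' @param individual column index or name of the individual.
#' @param scaffold_lengths named vector of scaffold lengths.
#' @param window window width in bp.
#' @param threshold heterozygous-SNV count above which a window is
#'   heterozygous.
#' @return data.frame of windows with `het_count` and `label`, plus
#'   attributes `percent_homozygous` (share of classified windows) and
#'   `percent_homozygous_genome` (homozygous-window bp over total
#'   scaffold bp, the alternative denominator including short scaffolds).
#' @export
classify_het_hom <- function(vs, individual = 1, scaffold_lengths,
                             window = 100000, threshold = 40) {
  check_variant_set(vs)
  het <- vs$geno[, individual] == 1
  het[is.na(het)] <- FALSE
  hvs <- subset_sites(vs, which(het))
  win <- window_density(hvs, scaffold_lengths, window)
  names(win)[names(win) == "snv_count"] <- "het_count"
  win$label <- ifelse(win$het_count > threshold, "heterozygous", "homozygous")
  n_hom <- sum(win$label == "homozygous")
  attr(win, "percent_homozygous") <-
    if (nrow(win) > 0) 100 * n_hom / nrow(win) else NA_real_
  attr(win, "percent_homozygous_genome") <-
    100 * n_hom * window / sum(scaffold_lengths)
  win
}

#' Per-individual heterozygous-site rate
#'
#' Percent of callable positions at which the individual is heterozygous.
#'
#' @param vs variant set.
#' @param callable_length callable genome length in bp.
#' @return named vector of percentages.
#' @export
heterozygosity_rate <- function(vs, callable_length) {
  check_variant_set(vs)
  if (callable_length <= 0) stop_field("callable_length", "must be > 0")
  100 * colSums(vs$geno == 1, na.rm = TRUE) / callable_length
}

#' Classify tandem-repeat records
#'
#' Each record is labeled
#' \describe{
#'   \item{microsatellite}{monomer length < 5 bp;}
#'   \item{complex}{monomer > 4 bp, array GC between 20 and 80 percent,
#'     array longer than 100 bp, entropy above 1.76, copy-number length
#'     variation above 4 bp, and imperfect array organisation;}
#'   \item{large}{assembled arrays subgrouped by array length at 1, 3 and
#'     10 kbp.}
#' }
#' The complex and large labels are not mutually exclusive; both flags are
#' retained. Records missing a needed field are flagged unclassifiable.
#'
#' @param records data.frame with columns `monomer_len`, `array_len`,
#'   `copy_number`, `gc` (percent), `entropy`, `perfect` (logical),
#'   `cn_variation_bp`.
#' @return the records with logical `microsatellite`, `complex`,
#'   `large_class` (`NA`, `"1kb"`, `"3kb"`, `"10kb"`) and
#'   `unclassifiable` columns added.
#' @export
classify_tandem_repeats <- function(records) {
  need <- c("monomer_len", "array_len", "copy_number", "gc", "entropy",
            "perfect", "cn_variation_bp")
  missing_col <- setdiff(need, names(records))
  for (m in missing_col) records[[m]] <- NA
  bad <- Reduce(`|`, lapply(need, function(f) is.na(records[[f]])))
  records$microsatellite <- !bad & records$monomer_len < 5
  records$complex <- !bad &
    records$monomer_len > 4 &
    records$gc >= 20 & records$gc <= 80 &
    records$array_len > 100 &
    records$entropy > 1.76 &
    records$cn_variation_bp > 4 &
    !records$perfect
  records$large_class <- ifelse(bad | records$array_len < 1000, NA,
    ifelse(records$array_len >= 10000, "10kb",
      ifelse(records$array_len >= 3000, "3kb", "1kb")))
  records$unclassifiable <- bad
  records
}
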