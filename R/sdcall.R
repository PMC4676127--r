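# Read-depth segmental-duplication calling --------------------------------
#
# Pipeline: mask preparation (repeats + gaps + over-represented k-mers +
# 36-bp padding), windows of exactly 1 kbp of unmasked sequence, read-depth
# assignment, iterative control-region statistics, copy-number estimation
# (CN = 2 * RD / mean control RD) and duplication-block calling.

iv_to_iranges <- function(df) {
  IRanges::IRanges(start = df$start + 1L, end = df$end)  # 0-based half-open in
}

#' Mask over-represented k-mers
#'
#' Partitions each scaffold into k-mers of `k` bp with adjacent k-mers
#' overlapping by `overlap` bp (sampling step `k - overlap`) and counts
#' each sampled k-mer's exact forward-strand occurrences in the unmasked
#' assembly. Sampled k-mers seen `min_hits` or more times have their
#' source interval reported for additional masking.
#'
#' @param reference `Biostrings::DNAStringSet`.
#' @param k k-mer length (bp).
#' @param overlap overlap between adjacent sampled k-mers (bp).
#' @param min_hits occurrence count (including the source) at which a
#'   k-mer counts as over-represented.
#' @param mask optional data.frame (`scaffold`, `start`, `end`, 0-based
#'   half-open) of already-masked intervals; masked positions are excluded
#'   from both sampling and occurrence counting.
#' @return data.frame `scaffold`, `start`, `end` (0-based half-open) of
#'   intervals to add to the mask.
#' @export
kmer_overmask <- function(reference, k = 36, overlap = 5, min_hits = 3,
                          mask = NULL) {
  stopifnot(k > overlap)
  step <- k - overlap
  # hard-mask already-masked text so it neither seeds nor attracts hits
  masked_ref <- reference
  if (!is.null(mask) && nrow(mask) > 0) {
    for (nm in unique(mask$scaffold)) {
      if (!nm %in% names(masked_ref)) next
      iv <- IRanges::reduce(iv_to_iranges(mask[mask$scaffold == nm, ]))
      masked_ref[[nm]] <- Biostrings::replaceAt(
        masked_ref[[nm]], iv,
        Biostrings::DNAStringSet(strrep("N", IRanges::width(iv))))
    }
  }

  sampled <- list()
  for (nm in names(masked_ref)) {
    L <- length(masked_ref[[nm]])
    if (L < k) {
      warning(sprintf("scaffold %s shorter than k = %d; skipped", nm, k))
      next
    }
    starts <- seq(1L, L - k + 1L, by = step)
    km <- Biostrings::extractAt(
      masked_ref[[nm]], IRanges::IRanges(starts, width = k))
    keep <- !grepl("N", as.character(km), fixed = TRUE)
    if (!any(keep)) next
    sampled[[nm]] <- data.frame(scaffold = nm, start = starts[keep] - 1L,
                                kmer = as.character(km)[keep],
                                stringsAsFactors = FALSE)
  }
  if (length(sampled) == 0)
    return(data.frame(scaffold = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  tab <- do.call(rbind, sampled)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(tab$kmer))
  counts <- rowSums(vapply(seq_along(masked_ref), function(i)
    Biostrings::countPDict(pd, masked_ref[[i]]),
    integer(nrow(tab))))
  hit <- counts >= min_hits
  out <- data.frame(scaffold = tab$scaffold[hit],
                    start = tab$start[hit],
                    end = tab$start[hit] + k,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Prepare a masked reference for read-depth analysis
#'
#' Unions the repeat/tandem/k-mer masks, adds `pad` bp of padding on each
#' flank of every masked segment (clipped at scaffold bounds), treats
#' assembly gaps as masked, and excludes scaffolds shorter than
#' `min_scaffold_bp` or listed as putative sex scaffolds.
#'
#' @param features a [planted_genome()], or any list with `reference`
#'   (`DNAStringSet`), `mask` and `gaps` interval data.frames.
#' @param extra_mask optional additional intervals (e.g. from
#'   [kmer_overmask()]).
#' @param pad padding width in bp added to each masked-segment flank.
#' @param min_scaffold_bp scaffolds shorter than this are dropped.
#' @param sex_scaffolds character vector of scaffold names to drop.
#' @return object of class `masked_reference`: list with `lengths`,
#'   per-scaffold `masked` (`IRanges`, padding and gaps included),
#'   `gaps` (`IRanges`), and `excluded` scaffold names.
#' @export
prepare_masked_reference <- function(features, extra_mask = NULL, pad = 36,
                                     min_scaffold_bp = 10000,
                                     sex_scaffolds = character()) {
  lens <- Biostrings::width(features$reference)
  names(lens) <- names(features$reference)
  excluded <- names(lens)[lens < min_scaffold_bp | names(lens) %in% sex_scaffolds]
  keep <- setdiff(names(lens), excluded)

  mask_df <- features$mask[, c("scaffold", "start", "end")]
  if (!is.null(extra_mask) && nrow(extra_mask) > 0)
    mask_df <- rbind(mask_df, extra_mask[, c("scaffold", "start", "end")])

  masked <- list(); gaps <- list()
  for (nm in keep) {
    L <- lens[[nm]]
    iv <- iv_to_iranges(mask_df[mask_df$scaffold == nm, , drop = FALSE])
    if (length(iv) > 0) {
      iv <- IRanges::IRanges(pmax(IRanges::start(iv) - pad, 1L),
                             pmin(IRanges::end(iv) + pad, L))
    }
    gv <- iv_to_iranges(features$gaps[features$gaps$scaffold == nm, ,
                                      drop = FALSE])
    masked[[nm]] <- IRanges::reduce(c(iv, gv))
    gaps[[nm]] <- IRanges::reduce(gv)
  }
  structure(list(lengths = lens[keep], masked = masked, gaps = gaps,
                 excluded = excluded, pad = pad),
            class = "masked_reference")
}

#' Build windows of exactly 1 kbp of unmasked sequence
#'
#' Accumulates unmasked positions left to right into consecutive groups of
#' exactly `unmasked_bp`; the trailing deficient group is dropped. A
#' window's genomic span runs from its first to its last unmasked position
#' and may exceed `unmasked_bp` where it straddles masked sequence.
#'
#' @param masked_ref a [prepare_masked_reference()] result.
#' @param unmasked_bp unmasked positions per window.
#' @return object of class `rd_windows`: list with `windows` (data.frame
#'   `scaffold`, `start`, `end` 0-based half-open, `win`) and `index`
#'   (per-scaffold unmasked positions and their window assignment).
#' @export
build_windows <- function(masked_ref, unmasked_bp = 1000) {
  wins <- list(); index <- list()
  for (nm in names(masked_ref$lengths)) {
    L <- masked_ref$lengths[[nm]]
    is_masked <- rep(FALSE, L)
    iv <- masked_ref$masked[[nm]]
    if (length(iv) > 0)
      for (r in seq_along(iv))
        is_masked[IRanges::start(iv)[r]:IRanges::end(iv)[r]] <- TRUE
    pos <- which(!is_masked)
    n_win <- length(pos) %/% unmasked_bp
    if (n_win == 0) next
    pos <- pos[seq_len(n_win * unmasked_bp)]
    win <- rep(seq_len(n_win), each = unmasked_bp)
    first <- pos[seq(1, length(pos), by = unmasked_bp)]
    last <- pos[seq(unmasked_bp, length(pos), by = unmasked_bp)]
    wins[[nm]] <- data.frame(scaffold = nm, start = first - 1L, end = last,
                             win = seq_len(n_win), stringsAsFactors = FALSE)
    index[[nm]] <- list(pos = pos, win = win)
  }
  windows <- if (length(wins)) do.call(rbind, wins) else
    data.frame(scaffold = character(), start = integer(), end = integer(),
               win = integer(), stringsAsFactors = FALSE)
  rownames(windows) <- NULL
  structure(list(windows = windows, index = index,
                 unmasked_bp = unmasked_bp), class = "rd_windows")
}

#' Assign read depth to windows
#'
#' Window read depth `RD` is the sum of per-position read-start counts over
#' the window's unmasked positions.
#'
#' @param rdw an [build_windows()] result.
#' @param depth_track data.frame `scaffold`, `pos` (1-based), `depth`.
#' @return the `rd_windows` object with an `RD` column added.
#' @export
assign_depth <- function(rdw, depth_track) {
  stopifnot(inherits(rdw, "rd_windows"))
  rdw$windows$RD <- NA_real_
  for (nm in names(rdw$index)) {
    tr <- depth_track[depth_track$scaffold == nm, , drop = FALSE]
    if (nrow(tr) == 0)
      stop(sprintf("depth track has no positions for scaffold %s", nm))
    dvec <- numeric(max(tr$pos))
    dvec[tr$pos] <- tr$depth
    idx <- rdw$index[[nm]]
    if (max(idx$pos) > length(dvec))
      stop(sprintf("depth track shorter than scaffold %s", nm))
    rd <- rowsum(dvec[idx$pos], idx$win)
    rows <- which(rdw$windows$scaffold == nm)
    rdw$windows$RD[rows] <- rd[as.character(rdw$windows$win[rows]), 1]
  }
  rdw
}

#' Iterative control-region read-depth statistics
#'
#' Starting from all windows, repeatedly drops windows whose RD deviates
#' from the current mean by more than `trim_sd` standard deviations, until
#' the control set is unchanged, the mean moves less than `tol`, or
#' `max_iter` is reached.
#'
#' @param rdw windows with RD ([assign_depth()]).
#' @param trim_sd trimming threshold in standard deviations.
#' @param tol convergence tolerance on the control mean.
#' @param max_iter iteration cap.
#' @return object of class `control_stats`: list with `mean`, `sd`,
#'   `control` (window row indices), `iterations`.
#' @export
estimate_controls <- function(rdw, trim_sd = 3, tol = 1e-6, max_iter = 50) {
  rd <- rdw$windows$RD
  if (length(rd) < 20) stop("need at least 20 windows for control estimation")
  ctrl <- seq_along(rd)
  it <- 0
  repeat {
    it <- it + 1
    m <- mean(rd[ctrl]); s <- sd(rd[ctrl])
    keep <- ctrl[is.na(s) | s == 0 | abs(rd[ctrl] - m) <= trim_sd * s]
    if (length(keep) == 0)
      stop(sprintf(
        "control set became empty (iteration %d, mean %.3g, sd %.3g)", it, m, s))
    changed <- length(keep) != length(ctrl)
    m_new <- mean(rd[keep])
    ctrl <- keep
    if (!changed || abs(m_new - m) < tol || it >= max_iter) break
  }
  structure(list(mean = mean(rd[ctrl]), sd = sd(rd[ctrl]), control = ctrl,
                 iterations = it), class = "control_stats")
}

#' Copy-number estimation from window read depth
#'
#' `CN = 2 * RD / mean(RD in control regions)`; control windows therefore
#' average CN 2 by construction.
#'
#' @param rdw windows with RD.
#' @param controls a [estimate_controls()] result.
#' @return `rd_windows` with a `CN` column; attribute `control_mean_cn`
#'   gives the mean CN over control windows.
#' @export
compute_cn <- function(rdw, controls) {
  if (controls$mean <= 0) stop("control mean RD must be > 0")
  rdw$windows$CN <- 2 * rdw$windows$RD / controls$mean
  attr(rdw, "control_mean_cn") <- mean(rdw$windows$CN[controls$control])
  rdw
}

#' Call duplication blocks from copy-number windows
#'
#' Scans each scaffold for maximal runs of consecutive windows with CN
#' above the soft threshold (control mean CN + `soft_sd` standard
#' deviations of control CN). A run is called a duplication block iff it
#' has at least `min_windows` windows, at most `soft_allowance` of them at
#' or below the hard threshold (mean + `hard_sd` sd), a genomic span of at
#' least `min_span_bp`, and no member CN above `cn_ceiling`. Assembly gaps
#' are subtracted from reported spans.
#'
#' @param rdw windows with CN ([compute_cn()]).
#' @param controls a [estimate_controls()] result.
#' @param min_windows minimum windows per block.
#' @param hard_sd,soft_sd thresholds in control-CN standard deviations.
#' @param soft_allowance windows allowed between soft and hard thresholds.
#' @param min_span_bp minimum genomic span.
#' @param cn_ceiling absolute CN above which a region is excluded.
#' @param gaps optional per-scaffold `IRanges` list (defaults to the ones
#'   recorded at window building if present).
#' @param sample_id label recorded on the calls.
#' @return data.frame of blocks: `sample`, `scaffold`, `start`, `end`,
#'   `n_windows`, `mean_cn`, `gap_trimmed`.
#' @export
call_blocks <- function(rdw, controls, min_windows = 5, hard_sd = 3,
                        soft_sd = 2, soft_allowance = 1,
                        min_span_bp = 10000, cn_ceiling = 100,
                        gaps = NULL, sample_id = "sample1") {
  w <- rdw$windows
  cn_ctrl <- w$CN[controls$control]
  mu <- mean(cn_ctrl); s <- sd(cn_ctrl)
  hard <- mu + hard_sd * s
  soft <- mu + soft_sd * s

  out <- list()
  for (nm in unique(w$scaffold)) {
    ws <- w[w$scaffold == nm, , drop = FALSE]
    ws <- ws[order(ws$win), , drop = FALSE]
    above <- ws$CN > soft
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      rows <- ws[starts[k]:ends[k], , drop = FALSE]
      if (nrow(rows) < min_windows) next
      if (sum(rows$CN <= hard) > soft_allowance) next
      span_start <- rows$start[1]
      span_end <- rows$end[nrow(rows)]
      if (span_end - span_start < min_span_bp) next
      if (any(rows$CN > cn_ceiling)) next
      span <- IRanges::IRanges(span_start + 1L, span_end)
      gv <- gaps[[nm]] %||% NULL
      trimmed <- FALSE
      if (!is.null(gv) && length(gv) > 0) {
        kept <- IRanges::setdiff(span, gv)
        trimmed <- sum(IRanges::width(kept)) < IRanges::width(span)
        span <- kept
      }
      for (p in seq_along(span)) {
        out[[length(out) + 1]] <- data.frame(
          sample = sample_id, scaffold = nm,
          start = IRanges::start(span)[p] - 1L,
          end = IRanges::end(span)[p],
          n_windows = nrow(rows), mean_cn = mean(rows$CN),
          gap_trimmed = trimmed, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(sample = character(), scaffold = character(),
                      start = integer(), end = integer(),
                      n_windows = integer(), mean_cn = numeric(),
                      gap_trimmed = logical(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Base-pair intersection of duplication calls across samples
#'
#' @param per_sample_blocks list of [call_blocks()] data.frames, one per
#'   sample (at least two).
#' @return list with `shared` (data.frame of intervals present in every
#'   sample), `union`, `per_sample_bp` and `shared_bp`.
#' @export
shared_blocks <- function(per_sample_blocks) {
  if (length(per_sample_blocks) < 2) stop("need blocks from at least 2 samples")
  by_sample <- lapply(per_sample_blocks, function(df) {
    sp <- split(df, df$scaffold)
    lapply(sp, iv_to_iranges)
  })
  scaffolds <- unique(unlist(lapply(by_sample, names)))
  shared <- list(); un <- list()
  for (nm in scaffolds) {
    ivs <- lapply(by_sample, function(x)
      IRanges::reduce(x[[nm]] %||% IRanges::IRanges()))
    inter <- Reduce(IRanges::intersect, ivs)
    uni <- IRanges::reduce(do.call(c, ivs))
    if (length(inter) > 0)
      shared[[nm]] <- data.frame(scaffold = nm,
                                 start = IRanges::start(inter) - 1L,
                                 end = IRanges::end(inter),
                                 stringsAsFactors = FALSE)
    if (length(uni) > 0)
      un[[nm]] <- data.frame(scaffold = nm,
                             start = IRanges::start(uni) - 1L,
                             end = IRanges::end(uni),
                             stringsAsFactors = FALSE)
  }
  empty <- data.frame(scaffold = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  shared_df <- if (length(shared)) do.call(rbind, shared) else empty
  union_df <- if (length(un)) do.call(rbind, un) else empty
  rownames(shared_df) <- rownames(union_df) <- NULL
  list(shared = shared_df, union = union_df,
       per_sample_bp = vapply(per_sample_blocks, function(df)
         sum(width_of(df)), numeric(1)),
       shared_bp = sum(width_of(shared_df)))
}

width_of <- function(df) if (nrow(df) == 0) 0 else df$end - df$start

#' Genes overlapped by shared duplications
#'
#' A gene is reported iff at least `min_fraction` of its length overlaps
#' the shared duplication intervals.
#'
#' @param shared data.frame of intervals (`scaffold`, `start`, `end`).
#' @param genes data.frame with `gene_id`, `scaffold`, `start`, `end`
#'   (0-based half-open).
#' @param min_fraction required overlap fraction of the gene length.
#' @return data.frame `gene_id`, `overlap_bp`, `fraction` for reported
#'   genes.
#' @export
gene_overlap <- function(shared, genes, min_fraction = 0.60) {
  res <- list()
  for (g in seq_len(nrow(genes))) {
    giv <- IRanges::IRanges(genes$start[g] + 1L, genes$end[g])
    siv <- iv_to_iranges(shared[shared$scaffold == genes$scaffold[g], ,
                                drop = FALSE])
    ov <- sum(IRanges::width(IRanges::intersect(giv, IRanges::reduce(siv))))
    frac <- ov / IRanges::width(giv)
    if (frac >= min_fraction)
      res[[length(res) + 1]] <- data.frame(gene_id = genes$gene_id[g],
                                           overlap_bp = ov, fraction = frac,
                                           stringsAsFactors = FALSE)
  }
  if (length(res) == 0)
    return(data.frame(gene_id = character(), overlap_bp = numeric(),
                      fraction = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, res)
}
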