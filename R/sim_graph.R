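#' Simulate an all-vs-all bit-score graph with planted gene families
#'
#' Generates self hits plus pairwise records whose Hscore (100 times the
#' bit score over the larger self score) falls in `within_hscore` for
#' same-family pairs and `between_hscore` for cross-family pairs. Aligned
#' fractions are drawn above the edge-filter threshold so that family
#' recovery is governed by the Hscore ranges alone.
#'
#' @param n_families number of planted families.
#' @param sizes integer vector of family sizes (recycled to
#'   `n_families`).
#' @param within_hscore,between_hscore Hscore ranges (length-2 vectors).
#' @param species optional character vector of species labels assigned
#'   round-robin within each family.
#' @param seed integer seed.
#' @return list with `records` (data.frame `query`, `target`, `bitscore`,
#'   `qalnfrac`, `talnfrac`), `truth` (named family id per gene),
#'   `species` (named species per gene or NULL) and `overlap_warning`
#'   (TRUE when the two Hscore ranges overlap).
#' @export
simulate_similarity_graph <- function(n_families, sizes,
                                      within_hscore = c(40, 90),
                                      between_hscore = c(0, 3),
                                      species = NULL, seed = 1) {
  if (n_families < 1) stop_field("n_families", "must be >= 1")
  sizes <- rep_len(sizes, n_families)
  if (any(sizes < 1)) stop_field("sizes", "must be >= 1")
  set.seed(as.integer(seed))

  overlap <- max(between_hscore) >= min(within_hscore)
  if (overlap)
    warning("within and between Hscore ranges overlap; truth partition may not be recoverable")

  genes <- unlist(lapply(seq_len(n_families), function(f)
    sprintf("fam%d_g%d", f, seq_len(sizes[f]))))
  fam <- rep(seq_len(n_families), sizes)
  names(fam) <- genes
  self_score <- setNames(runif(length(genes), 200, 400), genes)

  sp <- NULL
  if (!is.null(species)) {
    sp <- unlist(lapply(sizes, function(n) rep_len(species, n)))
    names(sp) <- genes
  }

  recs <- list()
  for (g in genes)
    recs[[length(recs) + 1]] <- data.frame(
      query = g, target = g, bitscore = self_score[[g]],
      qalnfrac = 1, talnfrac = 1, stringsAsFactors = FALSE)
  if (length(genes) > 1) {
    pairs <- utils::combn(genes, 2)
    for (k in seq_len(ncol(pairs))) {
      a <- pairs[1, k]; b <- pairs[2, k]
      rng <- if (fam[[a]] == fam[[b]]) within_hscore else between_hscore
      h <- runif(1, rng[1], rng[2])
      sc <- h / 100 * max(self_score[[a]], self_score[[b]])
      if (sc <= 0) next
      recs[[length(recs) + 1]] <- data.frame(
        query = a, target = b, bitscore = sc,
        qalnfrac = runif(1, 0.5, 1), talnfrac = runif(1, 0.5, 1),
        stringsAsFactors = FALSE)
    }
  }
  list(records = do.call(rbind, recs), truth = fam, species = sp,
       overlap_warning = overlap)
}
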