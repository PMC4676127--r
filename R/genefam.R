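# Hscore similarity graph and gene-family clustering ---------------------

#' Build an Hscore-weighted similarity graph from bit-score records
#'
#' An edge connects two genes when strictly more than
#' `min_aligned_fraction` of each gene aligned. Its weight is
#' `Hscore = 100 * sc(G1, G2) / max(sc(G1, G1), sc(G2, G2))`, clamped to
#' `[0, 100]`, where `sc` is the bit score. Self scores come from self
#' hits; for genes without one the maximum observed score involving the
#' gene is used as a fallback (counted in attribute
#' `n_self_fallback`).
#'
#' @param records data.frame with `query`, `target`, `bitscore`,
#'   `qalnfrac`, `talnfrac`.
#' @param min_aligned_fraction aligned-fraction threshold (strict).
#' @return data.frame of edges `gene1`, `gene2`, `bitscore`, `hscore`,
#'   with attributes `genes` (all gene ids seen) and `n_self_fallback`.
#' @export
build_graph <- function(records, min_aligned_fraction = 1 / 3) {
  stopifnot(all(c("query", "target", "bitscore", "qalnfrac", "talnfrac")
                %in% names(records)))
  genes <- sort(unique(c(records$query, records$target)))
  selfs <- records[records$query == records$target, , drop = FALSE]
  self_score <- setNames(rep(NA_real_, length(genes)), genes)
  self_score[selfs$query] <- selfs$bitscore
  fallback <- is.na(self_score)
  if (any(fallback)) {
    for (g in genes[fallback]) {
      hit <- records$query == g | records$target == g
      self_score[g] <- max(records$bitscore[hit])
    }
  }

  pairs <- records[records$query != records$target, , drop = FALSE]
  keep <- pairs$qalnfrac > min_aligned_fraction &
    pairs$talnfrac > min_aligned_fraction
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs) > 0) {
    g1 <- pmin(pairs$query, pairs$target)
    g2 <- pmax(pairs$query, pairs$target)
    key <- paste(g1, g2)
    # keep the best-scoring record per unordered pair
    best <- tapply(pairs$bitscore, key, max)
    first <- !duplicated(key)
    edges <- data.frame(gene1 = g1[first], gene2 = g2[first],
                        bitscore = as.numeric(best[key[first]]),
                        stringsAsFactors = FALSE)
    edges$hscore <- pmin(pmax(100 * edges$bitscore /
                                pmax(self_score[edges$gene1],
                                     self_score[edges$gene2]), 0), 100)
  } else {
    edges <- data.frame(gene1 = character(), gene2 = character(),
                        bitscore = numeric(), hscore = numeric(),
                        stringsAsFactors = FALSE)
  }
  rownames(edges) <- NULL
  attr(edges, "genes") <- genes
  attr(edges, "n_self_fallback") <- sum(fallback)
  edges
}

#' Cluster genes into families by constrained average-linkage
#'
#' Agglomerates over the similarity graph: at each step the cluster pair
#' with the highest average inter-cluster Hscore (absent edges count 0)
#' is merged, refusing merges whose average Hscore is not strictly above
#' `min_hscore`, whose merged edge density (edges present over possible
#' pairs) is not strictly above `min_density`, whose merged size exceeds
#' `max_size`, or which would grow a cluster that already contains an
#' outgroup gene (a lone outgroup gene may still be absorbed, after which
#' its family stops growing). Ties are broken by the lexicographically
#' smallest member gene. Isolated genes come out as singletons.
#'
#' @param edges [build_graph()] output.
#' @param min_hscore minimum average Hscore for a merge (strict).
#' @param min_density minimum edge density of a merged family (strict).
#' @param max_size maximum family size.
#' @param outgroup character vector of outgroup gene ids.
#' @param genes optional complete gene universe (defaults to the graph's
#'   genes attribute).
#' @return data.frame with one row per family: `family`, `size`,
#'   `genes` (comma-separated), `density`, `contains_outgroup`; attribute
#'   `membership` maps gene to family id.
#' @export
cluster_families <- function(edges, min_hscore = 5, min_density = 1 / 3,
                             max_size = 500, outgroup = character(),
                             genes = NULL) {
  genes <- genes %||% attr(edges, "genes")
  if (is.null(genes)) genes <- sort(unique(c(edges$gene1, edges$gene2)))
  n <- length(genes)
  idx <- setNames(seq_len(n), genes)
  S <- matrix(0, n, n)           # hscore (0 = no edge)
  A <- matrix(FALSE, n, n)       # adjacency
  if (nrow(edges) > 0) {
    i <- idx[edges$gene1]; j <- idx[edges$gene2]
    S[cbind(i, j)] <- S[cbind(j, i)] <- edges$hscore
    A[cbind(i, j)] <- A[cbind(j, i)] <- TRUE
  }
  is_out <- genes %in% outgroup

  members <- as.list(seq_len(n))
  alive <- rep(TRUE, n)
  min_gene <- genes

  repeat {
    live <- which(alive)
    if (length(live) < 2) break
    best <- NULL; best_avg <- min_hscore
    for (ai in seq_along(live)) for (bi in seq_len(ai - 1)) {
      a <- live[ai]; b <- live[bi]
      ma <- members[[a]]; mb <- members[[b]]
      # outgroup stop rule: a multi-gene cluster containing an outgroup
      # gene accepts no further merges
      if ((any(is_out[ma]) && length(ma) > 1) ||
          (any(is_out[mb]) && length(mb) > 1)) next
      if (length(ma) + length(mb) > max_size) next
      avg <- mean(S[ma, mb, drop = FALSE])
      if (avg <= best_avg - 1e-12) next
      merged <- c(ma, mb)
      dens <- sum(A[merged, merged]) / 2 / choose(length(merged), 2)
      if (dens <= min_density) next
      cand_key <- min(min_gene[a], min_gene[b])
      if (is.null(best) || avg > best_avg + 1e-12 ||
          (abs(avg - best_avg) <= 1e-12 && cand_key < best$key)) {
        best <- list(a = a, b = b, key = cand_key)
        best_avg <- avg
      }
    }
    if (is.null(best)) break
    members[[best$a]] <- c(members[[best$a]], members[[best$b]])
    min_gene[best$a] <- min(min_gene[best$a], min_gene[best$b])
    alive[best$b] <- FALSE
  }

  fams <- members[alive]
  ord <- order(vapply(fams, function(m) min(genes[m]), character(1)))
  fams <- fams[ord]
  out <- data.frame(
    family = sprintf("family%d", seq_along(fams)),
    size = vapply(fams, length, integer(1)),
    genes = vapply(fams, function(m) paste(sort(genes[m]), collapse = ","),
                   character(1)),
    density = vapply(fams, function(m)
      if (length(m) < 2) 1 else sum(A[m, m]) / 2 / choose(length(m), 2),
      numeric(1)),
    contains_outgroup = vapply(fams, function(m) any(is_out[m]), logical(1)),
    stringsAsFactors = FALSE)
  membership <- setNames(rep(out$family, out$size),
                         unlist(lapply(fams, function(m) sort(genes[m]))))
  attr(out, "membership") <- membership[genes]
  out
}

#' Cross-species sharing counts of gene families
#'
#' For each queried species combination, counts families whose species
#' set equals the combination exactly (`exclusive`) and families whose
#' species set contains it (`inclusive`).
#'
#' @param families [cluster_families()] output (or a list of gene-id
#'   vectors).
#' @param species_map named character vector gene -> species.
#' @param combinations list of character vectors of species; default all
#'   distinct observed species sets.
#' @return data.frame `combination`, `exclusive`, `inclusive`.
#' @export
sharing_summary <- function(families, species_map, combinations = NULL) {
  fam_genes <- if (is.data.frame(families))
    strsplit(families$genes, ",", fixed = TRUE) else families
  all_genes <- unlist(fam_genes)
  unknown <- setdiff(all_genes, names(species_map))
  if (length(unknown) > 0)
    stop("genes without species label: ", paste(head(unknown, 5), collapse = ", "))
  sets <- lapply(fam_genes, function(g) sort(unique(species_map[g])))
  keys <- vapply(sets, paste, character(1), collapse = "+")
  if (is.null(combinations))
    combinations <- lapply(unique(keys), function(k)
      strsplit(k, "+", fixed = TRUE)[[1]])
  res <- lapply(combinations, function(cmb) {
    cmb <- sort(unique(cmb))
    key <- paste(cmb, collapse = "+")
    data.frame(combination = key,
               exclusive = sum(keys == key),
               inclusive = sum(vapply(sets, function(s) all(cmb %in% s),
                                      logical(1))),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
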