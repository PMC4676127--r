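# Branch-specific Dn/Ds from parsimony-reconstructed ancestors -----------

#' Branch-specific Dn/Ds on a fixed species tree
#'
#' Reconstructs ancestral sequences by Fitch parsimony, then accumulates
#' NG86 synonymous/nonsynonymous differences between each branch's parent
#' and child sequences. Site totals (`N`, `S`) are counted on the child
#' sequence, so `N + S = 3 * codons` on every branch.
#'
#' @param alignment named vector of in-frame, gap-free, equal-length
#'   coding sequences covering all tips.
#' @param tree rooted `ape::phylo`; default [five_taxon_tree()].
#' @param jc_correction Jukes-Cantor-correct the rates.
#' @param per_column also return per-codon-column contribution arrays
#'   (used by the bootstrap and permutation machinery).
#' @return data.frame with one row per branch (named by child node):
#'   `branch`, `Nd`, `Sd`, `N`, `S`, `dN`, `dS`, `omega`,
#'   `omega_defined`; attribute `ancestral` holds the reconstruction.
#'   With `per_column = TRUE`, attribute `columns` is a list of
#'   `ncodon x nbranch` matrices `nd`, `sd`, `n`, `s`.
#' @export
branch_dnds <- function(alignment, tree = five_taxon_tree(),
                        jc_correction = TRUE, per_column = FALSE) {
  anc <- ancestral_codons(alignment, tree)
  labs <- node_names(tree)
  seq_of <- function(v)
    if (v <= length(tree$tip.label)) alignment[[labs[v]]] else
      anc$ancestors[[labs[v]]]

  codon_universe()
  sites <- codon_site_counts()
  pd <- codon_pair_diffs()
  codons <- codon_universe()

  edges <- tree$edge
  n_branch <- nrow(edges)
  branch <- labs[edges[, 2]]
  ncod <- nchar(alignment[[tree$tip.label[1]]]) / 3

  nd <- sd_ <- nmat <- smat <- matrix(0, ncod, n_branch,
                                      dimnames = list(NULL, branch))
  for (r in seq_len(n_branch)) {
    cp <- split_codons(seq_of(edges[r, 1]))
    cc <- split_codons(seq_of(edges[r, 2]))
    idx <- cbind(match(cp, codons), match(cc, codons))
    nd[, r] <- pd$nd[idx]
    sd_[, r] <- pd$sd[idx]
    s_child <- sites[cc]
    s_child[is.na(s_child)] <- 0
    smat[, r] <- s_child
    nmat[, r] <- 3 - s_child
  }

  out <- summarize_branch_counts(colSums(nd), colSums(sd_), colSums(nmat),
                                 colSums(smat), branch, jc_correction)
  attr(out, "ancestral") <- anc
  if (per_column)
    attr(out, "columns") <- list(nd = nd, sd = sd_, n = nmat, s = smat)
  out
}

summarize_branch_counts <- function(Nd, Sd, N, S, branch, jc_correction) {
  jc <- function(p) ifelse(p < 0.75, -0.75 * log(pmax(1 - 4 * p / 3, 1e-300)),
                           NA_real_)
  pN <- ifelse(N > 0, Nd / N, 0)
  pS <- ifelse(S > 0, Sd / S, 0)
  dN <- if (jc_correction) jc(pN) else pN
  dS <- if (jc_correction) jc(pS) else pS
  defined <- !is.na(dN) & !is.na(dS) & dS > 0
  data.frame(branch = branch, Nd = Nd, Sd = Sd, N = N, S = S,
             dN = dN, dS = dS,
             omega = ifelse(defined, dN / dS, NA_real_),
             omega_defined = defined,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Concatenate gene alignments into a supergene
#'
#' @param alignments list of named sequence vectors sharing taxa.
#' @return single named vector of concatenated sequences.
#' @export
concat_supergene <- function(alignments) {
  if (!is.list(alignments) || length(alignments) == 0)
    stop("alignments must be a non-empty list")
  taxa <- Reduce(intersect, lapply(alignments, names))
  if (length(taxa) == 0) stop("alignments share no taxa")
  setNames(vapply(taxa, function(tx)
    paste(vapply(alignments, function(a) a[[tx]], character(1)),
          collapse = ""), character(1)), taxa)
}

#' Bootstrap distributions of branch-specific Dn/Ds
#'
#' Concatenates the gene alignments into one supergene, resamples codon
#' columns with replacement `B` times, and recomputes every branch's
#' Dn/Ds per replicate (the ancestral reconstruction is per-column, so
#' per-column substitution attributions are resampled directly).
#'
#' @param alignments list of alignments (or a single named vector).
#' @param tree rooted `ape::phylo`.
#' @param B bootstrap replicates (at least 2).
#' @param seed integer seed.
#' @param jc_correction Jukes-Cantor-correct the rates.
#' @param foreground optional branch label; when given, pooled
#'   foreground/background omegas are also computed per replicate
#'   (pooling the substitution and site counts over the branch sets,
#'   which is stable even for short individual branches).
#' @return list with `point` (the supergene branch table), `boot_omega`
#'   (`B x branch` matrix), `quantiles` (2.5/50/97.5 percent per branch,
#'   `NA`-removed), and with `foreground`: `boot_fg`, `boot_bg`.
#' @export
supergene_bootstrap <- function(alignments, tree = five_taxon_tree(),
                                B = 500, seed = 1, jc_correction = TRUE,
                                foreground = NULL) {
  if (B < 2) stop_field("B", "must be >= 2")
  aln <- if (is.list(alignments)) concat_supergene(alignments) else alignments
  point <- branch_dnds(aln, tree, jc_correction, per_column = TRUE)
  cols <- attr(point, "columns")
  ncod <- nrow(cols$nd)
  branches <- colnames(cols$nd)
  fg <- if (is.null(foreground)) integer() else which(branches == foreground)
  bg <- setdiff(seq_along(branches), fg)
  set.seed(as.integer(seed))
  boot <- matrix(NA_real_, B, length(branches),
                 dimnames = list(NULL, branches))
  boot_fg <- boot_bg <- rep(NA_real_, B)
  pooled <- function(take, idx) {
    tab <- summarize_branch_counts(
      sum(cols$nd[take, idx]), sum(cols$sd[take, idx]),
      sum(cols$n[take, idx]), sum(cols$s[take, idx]),
      "pooled", jc_correction)
    tab$omega
  }
  for (b in seq_len(B)) {
    take <- sample.int(ncod, ncod, replace = TRUE)
    tab <- summarize_branch_counts(
      colSums(cols$nd[take, , drop = FALSE]),
      colSums(cols$sd[take, , drop = FALSE]),
      colSums(cols$n[take, , drop = FALSE]),
      colSums(cols$s[take, , drop = FALSE]),
      branches, jc_correction)
    boot[b, ] <- tab$omega
    if (length(fg) > 0) {
      boot_fg[b] <- pooled(take, fg)
      boot_bg[b] <- pooled(take, bg)
    }
  }
  qs <- apply(boot, 2, function(v)
    if (all(is.na(v))) c(NA_real_, NA_real_, NA_real_) else
      quantile(v, c(0.025, 0.5, 0.975), na.rm = TRUE))
  rownames(qs) <- c("q2.5", "q50", "q97.5")
  out <- list(point = point, boot_omega = boot, quantiles = qs)
  if (length(fg) > 0) {
    out$boot_fg <- boot_fg
    out$boot_bg <- boot_bg
  }
  out
}

pooled_omega <- function(nd, sd_, n, s, cols_idx, branches, jc_correction,
                         pseudocount) {
  Nd <- sum(nd[cols_idx, branches])
  Sd <- sum(sd_[cols_idx, branches])
  N <- sum(n[cols_idx, branches])
  S <- sum(s[cols_idx, branches])
  if (Sd == 0) Sd <- Sd + pseudocount
  pN <- if (N > 0) Nd / N else 0
  pS <- if (S > 0) Sd / S else 0
  if (jc_correction) {
    if (pN >= 0.75 || pS >= 0.75) return(NA_real_)
    pN <- -0.75 * log(1 - 4 * pN / 3)
    pS <- -0.75 * log(1 - 4 * pS / 3)
  }
  if (pS == 0) return(NA_real_)
  pN / pS
}

#' Test for elevated Dn/Ds on a foreground branch
#'
#' Statistic `T = omega_foreground - omega_background`, the background
#' pooling substitution and site counts over all non-foreground branches.
#'
#' With `method = "codon_bootstrap"` (default) the test inverts a
#' percentile codon-column bootstrap: columns are resampled with
#' replacement, the statistic is recomputed, and the one-sided p-value is
#' `(1 + #{T* <= 0}) / (B + 1)` — the position of zero in the bootstrap
#' distribution of the elevation. The percentile form is robust to the
#' right-skew that small synonymous counts induce in omega ratios, and it
#' preserves each branch's length and count structure.
#'
#' With `method = "permutation"` the branch labels of each codon column's
#' substitution attributions are permuted independently per column
#' (per-branch site totals stay in place). This variant is exact when
#' branch lengths are equal but runs anticonservative for very unequal
#' branch lengths, because permuted foreground columns inherit the longer
#' branches' counts; it is retained for comparison.
#'
#' Branches with zero synonymous differences are handled by a synonymous
#' pseudocount (`ds_zero = "pseudocount"`, default 0.5) or by returning an
#' undefined result (`ds_zero = "exclude"`); the choice is recorded.
#'
#' @param alignment named vector of coding sequences.
#' @param tree rooted `ape::phylo`.
#' @param foreground tip (or internal node) label of the tested branch.
#' @param B resampling replicates.
#' @param seed integer seed.
#' @param jc_correction Jukes-Cantor-correct the rates.
#' @param method null-distribution construction (see Details).
#' @param ds_zero zero-synonymous handling policy.
#' @param pseudocount synonymous pseudocount used by the policy.
#' @param gene_id label copied into the result.
#' @return list (`gene_test` class) with `gene_id`, `omega_fg`,
#'   `omega_bg`, `stat`, `p`, `foreground_max` (foreground omega exceeds
#'   every other branch), `method`, `B`, `ds_zero`.
#' @export
foreground_test <- function(alignment, tree = five_taxon_tree(),
                            foreground = "cheetah", B = 200, seed = 1,
                            jc_correction = TRUE,
                            method = c("codon_bootstrap", "permutation"),
                            ds_zero = c("pseudocount", "exclude"),
                            pseudocount = 0.5, gene_id = NA_character_) {
  method <- match.arg(method)
  ds_zero <- match.arg(ds_zero)
  tab <- branch_dnds(alignment, tree, jc_correction, per_column = TRUE)
  cols <- attr(tab, "columns")
  branches <- colnames(cols$nd)
  if (!foreground %in% branches)
    stop_field("foreground", "not a branch of the tree")
  fg <- which(branches == foreground)
  bg <- setdiff(seq_along(branches), fg)
  ncod <- nrow(cols$nd)
  all_rows <- seq_len(ncod)

  pc <- if (ds_zero == "pseudocount") pseudocount else 0
  stat_of <- function(nd, sd_) {
    om_f <- pooled_omega(nd, sd_, cols$n, cols$s, all_rows, fg,
                         jc_correction, pc)
    om_b <- pooled_omega(nd, sd_, cols$n, cols$s, all_rows, bg,
                         jc_correction, pc)
    if (is.na(om_f) || is.na(om_b)) return(NA_real_)
    om_f - om_b
  }

  om_fg <- pooled_omega(cols$nd, cols$sd, cols$n, cols$s, all_rows, fg,
                        jc_correction, pc)
  om_bg <- pooled_omega(cols$nd, cols$sd, cols$n, cols$s, all_rows, bg,
                        jc_correction, pc)
  t_obs <- stat_of(cols$nd, cols$sd)

  no_subs <- sum(cols$nd) + sum(cols$sd) == 0
  if (ds_zero == "exclude" && (is.na(om_fg) || is.na(om_bg))) {
    p <- NA_real_
  } else if (no_subs || is.na(t_obs)) {
    p <- 1
  } else if (method == "codon_bootstrap") {
    set.seed(as.integer(seed))
    t_boot <- numeric(B)
    for (b in seq_len(B)) {
      take <- sample.int(ncod, ncod, replace = TRUE)
      om_f <- pooled_omega(cols$nd, cols$sd, cols$n, cols$s, take, fg,
                           jc_correction, pc)
      om_b <- pooled_omega(cols$nd, cols$sd, cols$n, cols$s, take, bg,
                           jc_correction, pc)
      t_boot[b] <- if (is.na(om_f) || is.na(om_b)) NA_real_ else om_f - om_b
    }
    p <- (1 + sum(t_boot <= 0, na.rm = TRUE)) / (B + 1)
  } else {
    set.seed(as.integer(seed))
    nb <- length(branches)
    t_perm <- numeric(B)
    for (b in seq_len(B)) {
      nd_p <- cols$nd; sd_p <- cols$sd
      for (cc in which(rowSums(cols$nd) + rowSums(cols$sd) > 0)) {
        pm <- sample.int(nb)
        nd_p[cc, ] <- cols$nd[cc, pm]
        sd_p[cc, ] <- cols$sd[cc, pm]
      }
      t_perm[b] <- stat_of(nd_p, sd_p)
    }
    p <- (1 + sum(t_perm >= t_obs, na.rm = TRUE)) / (B + 1)
  }

  per_branch <- tab$omega
  names(per_branch) <- tab$branch
  structure(list(
    gene_id = gene_id,
    omega_fg = om_fg, omega_bg = om_bg,
    omega_branches = per_branch,
    stat = t_obs, p = p,
    foreground_max = {
      others <- per_branch[tab$branch != foreground]
      !all(is.na(others)) && isTRUE(om_fg > max(others, na.rm = TRUE))
    },
    method = method, B = B, ds_zero = ds_zero
  ), class = "gene_test")
}

#' Run the foreground test over many genes with multiplicity adjustment
#'
#' @param alignments named list of gene alignments.
#' @param ... passed to [foreground_test()].
#' @param alpha significance level applied to BH-adjusted p-values.
#' @return data.frame with per-gene omegas, p, BH-adjusted q and decision.
#' @export
foreground_scan <- function(alignments, ..., alpha = 0.05) {
  res <- lapply(names(alignments), function(g)
    foreground_test(alignments[[g]], gene_id = g, ...))
  df <- data.frame(
    gene_id = vapply(res, `[[`, character(1), "gene_id"),
    omega_fg = vapply(res, `[[`, numeric(1), "omega_fg"),
    omega_bg = vapply(res, `[[`, numeric(1), "omega_bg"),
    stat = vapply(res, `[[`, numeric(1), "stat"),
    p = vapply(res, `[[`, numeric(1), "p"),
    foreground_max = vapply(res, `[[`, logical(1), "foreground_max"),
    stringsAsFactors = FALSE)
  df$q <- p.adjust(df$p, "BH")
  df$significant <- !is.na(df$q) & df$q < alpha
  df
}
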