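# Parsimony ancestral reconstruction ------------------------------------

#' Default five-taxon species tree
#'
#' Rooted topology with the dog as outgroup, then human, then the felid
#' clade with the cheetah sister to (cat, tiger). Branch lengths are in
#' expected substitutions per codon and are used by the codon simulator;
#' reconstruction uses only the topology.
#'
#' @param branch_lengths optional named vector of branch lengths keyed by
#'   the child node of each branch (leaves and internal labels `anc_ct`,
#'   `anc_felid`, `anc_fh`).
#' @return an `ape::phylo` tree with node labels.
#' @export
five_taxon_tree <- function(branch_lengths = NULL) {
  default <- c(cheetah = 0.02, cat = 0.015, tiger = 0.015,
               anc_ct = 0.01, anc_felid = 0.06, human = 0.12,
               anc_fh = 0.04, dog = 0.18)
  bl <- default
  if (!is.null(branch_lengths)) bl[names(branch_lengths)] <- branch_lengths
  txt <- sprintf(
    "(((cheetah:%g,(cat:%g,tiger:%g)anc_ct:%g)anc_felid:%g,human:%g)anc_fh:%g,dog:%g)root;",
    bl["cheetah"], bl["cat"], bl["tiger"], bl["anc_ct"], bl["anc_felid"],
    bl["human"], bl["anc_fh"], bl["dog"])
  ape::read.tree(text = txt)
}

node_names <- function(tree) {
  n_tip <- length(tree$tip.label)
  labs <- c(tree$tip.label,
            tree$node.label %||% sprintf("node%d", seq_len(tree$Nnode) + n_tip))
  if (length(labs) < n_tip + tree$Nnode)
    labs <- c(labs, sprintf("node%d", seq_len(n_tip + tree$Nnode - length(labs))))
  labs
}

#' Fitch parsimony reconstruction of ancestral sequences
#'
#' Per nucleotide column: bottom-up Fitch state sets, then top-down
#' assignment taking the parent state when possible and otherwise the
#' first state in the fixed base order A < C < G < T. Columns whose
#' assignment involved such an arbitrary choice are counted in the
#' reported tie fraction. Non-ACGT characters are treated as fully
#' ambiguous.
#'
#' @param alignment named character vector (or list) of equal-length
#'   sequences covering every tip of `tree`.
#' @param tree rooted binary `ape::phylo` (default [five_taxon_tree()]).
#' @return list with `ancestors` (named character vector of internal-node
#'   sequences, including `root`), `mutation_count` (parsimony score),
#'   `tie_fraction` (fraction of columns with an arbitrary tie-break) and
#'   `tie_columns`.
#' @export
ancestral_codons <- function(alignment, tree = five_taxon_tree()) {
  alignment <- unlist(alignment)
  miss <- setdiff(tree$tip.label, names(alignment))
  if (length(miss) > 0)
    stop("alignment is missing taxa: ", paste(miss, collapse = ", "))
  L <- unique(nchar(alignment[tree$tip.label]))
  if (length(L) != 1) stop("sequences have unequal lengths")

  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  bases <- c(A = 1L, C = 2L, G = 4L, T = 8L)
  # state sets as bitmasks, nodes x columns
  sets <- matrix(0L, n_node, L)
  for (k in seq_len(n_tip)) {
    chars <- strsplit(toupper(alignment[[tree$tip.label[k]]]), "")[[1]]
    m <- unname(bases[chars])
    m[is.na(m)] <- 15L
    sets[k, ] <- m
  }

  tre_po <- ape::reorder.phylo(tree, "postorder")
  mutations <- integer(L)
  # bottom-up: combine children into parents edge by edge; postorder
  # guarantees a child's subtree is complete before its own edge appears
  filled <- logical(n_node)
  filled[seq_len(n_tip)] <- TRUE
  for (r in seq_len(nrow(tre_po$edge))) {
    p <- tre_po$edge[r, 1]; ch <- tre_po$edge[r, 2]
    s_ch <- sets[ch, ]
    if (!filled[p]) {
      sets[p, ] <- s_ch
      filled[p] <- TRUE
    } else {
      inter <- bitwAnd(sets[p, ], s_ch)
      un <- bitwOr(sets[p, ], s_ch)
      add <- inter == 0L
      mutations <- mutations + add
      sets[p, ] <- ifelse(add, un, inter)
    }
  }

  first_base <- function(mask) {
    # lowest set bit in A < C < G < T order
    b <- integer(length(mask))
    for (v in c(1L, 2L, 4L, 8L)) {
      hit <- b == 0L & bitwAnd(mask, v) > 0L
      b[hit] <- v
    }
    b
  }

  assign_state <- matrix(0L, n_node, L)
  root <- n_tip + 1L
  tie <- logical(L)
  root_pick <- first_base(sets[root, ])
  tie <- tie | bitwAnd(sets[root, ], sets[root, ] - 1L) > 0L  # >1 bit set
  assign_state[root, ] <- root_pick
  pre <- tre_po$edge[rev(seq_len(nrow(tre_po$edge))), , drop = FALSE]
  for (r in seq_len(nrow(pre))) {
    p <- pre[r, 1]; ch <- pre[r, 2]
    inherit <- bitwAnd(sets[ch, ], assign_state[p, ]) > 0L
    pick <- ifelse(inherit, assign_state[p, ], first_base(sets[ch, ]))
    tie <- tie | (!inherit & bitwAnd(sets[ch, ], sets[ch, ] - 1L) > 0L)
    assign_state[ch, ] <- pick
  }

  inv <- setNames(names(bases), bases)
  labs <- node_names(tree)
  internal <- (n_tip + 1L):n_node
  ancestors <- vapply(internal, function(v)
    paste(inv[as.character(assign_state[v, ])], collapse = ""), character(1))
  names(ancestors) <- labs[internal]
  list(ancestors = ancestors,
       mutation_count = sum(mutations),
       tie_fraction = mean(tie),
       tie_columns = which(tie))
}
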