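#' Specification for simulating codon alignments with branch-specific omega
#'
#' Describes a Goldman-Yang-style codon substitution process on a rooted
#' tree: single-nucleotide codon exchanges at rate proportional to the
#' target codon frequency, multiplied by `kappa` for transitions and by
#' the branch's `omega` for nonsynonymous changes. Stop codons are
#' excluded from the state space, so none can be emitted. Branch lengths
#' are in expected substitutions per codon (at that branch's omega).
#'
#' @param tree rooted `ape::phylo` with branch lengths
#'   (default [five_taxon_tree()]).
#' @param omega per-branch Dn/Ds; a single number, or a named vector
#'   keyed by child-node label (unnamed branches fall back to
#'   `default_omega`).
#' @param default_omega omega for branches not named in `omega`.
#' @param kappa transition/transversion rate ratio.
#' @param codon_freqs equilibrium codon frequencies over the 61 sense
#'   codons (default uniform); must sum to 1.
#' @param n_codons alignment length in codons.
#' @return object of class `codon_sim_spec`.
#' @export
codon_sim_spec <- function(tree = five_taxon_tree(), omega = 0.2,
                           default_omega = 0.2, kappa = 2,
                           codon_freqs = NULL, n_codons = 1000) {
  codon_universe()
  sense <- .codon_env$sense
  codon_freqs <- codon_freqs %||% setNames(rep(1 / length(sense),
                                               length(sense)), sense)
  if (abs(sum(codon_freqs) - 1) > 1e-8)
    stop_field("codon_freqs", "must sum to 1")
  if (any(codon_freqs < 0)) stop_field("codon_freqs", "must be >= 0")
  if (kappa <= 0) stop_field("kappa", "must be > 0")
  if (n_codons < 1) stop_field("n_codons", "must be >= 1")
  labs <- node_names(tree)
  branch <- labs[tree$edge[, 2]]
  om <- setNames(rep(default_omega, length(branch)), branch)
  if (length(omega) == 1 && is.null(names(omega))) om[] <- omega
  else om[names(omega)] <- omega
  if (any(om < 0)) stop_field("omega", "must be >= 0")
  structure(list(tree = tree, omega = om, kappa = kappa,
                 codon_freqs = codon_freqs, n_codons = as.integer(n_codons)),
            class = "codon_sim_spec")
}

# rate matrix over sense codons for one omega; scaled to one expected
# substitution per codon per unit time at equilibrium
codon_rate_matrix <- function(kappa, omega, codon_freqs) {
  sense <- .codon_env$sense
  ns <- length(sense)
  aa <- .codon_env$aa
  Q <- matrix(0, ns, ns, dimnames = list(sense, sense))
  chars <- strsplit(sense, "")
  for (i in seq_len(ns)) for (j in seq_len(ns)) {
    if (i == j) next
    d <- which(chars[[i]] != chars[[j]])
    if (length(d) != 1) next
    r <- codon_freqs[sense[j]]
    if (is_transition(chars[[i]][d], chars[[j]][d])) r <- r * kappa
    if (aa[sense[i]] != aa[sense[j]]) r <- r * omega
    Q[i, j] <- r
  }
  diag(Q) <- -rowSums(Q)
  scale <- -sum(codon_freqs[sense] * diag(Q))
  Q / scale
}

#' Simulate a codon alignment along a tree with branch-specific omega
#'
#' Gillespie simulation of the codon process of a [codon_sim_spec()]:
#' the root sequence is drawn from the equilibrium codon frequencies and
#' evolved down every branch, recording each realized substitution as
#' synonymous or nonsynonymous.
#'
#' @param spec a [codon_sim_spec()].
#' @param seed integer seed.
#' @return list with `alignment` (named vector of tip sequences),
#'   `ancestors` (true internal-node sequences), and `truth`
#'   (data.frame per branch: realized `n_syn`, `n_nonsyn` substitution
#'   counts and the branch's `omega` and length).
#' @export
simulate_codon_alignment <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "codon_sim_spec"))
  set.seed(as.integer(seed))
  codon_universe()
  sense <- .codon_env$sense
  aa <- .codon_env$aa
  tree <- spec$tree
  labs <- node_names(tree)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode

  # per-omega transition machinery, cached per unique omega value
  machinery <- list()
  get_machinery <- function(om) {
    key <- sprintf("%.12g", om)
    if (is.null(machinery[[key]])) {
      Q <- codon_rate_matrix(spec$kappa, om, spec$codon_freqs)
      leave <- -diag(Q)
      P <- Q
      diag(P) <- 0
      P <- P / ifelse(leave > 0, leave, 1)
      machinery[[key]] <<- list(leave = leave, Pcum = t(apply(P, 1, cumsum)))
    }
    machinery[[key]]
  }

  root <- n_tip + 1L
  seqs <- matrix(NA_integer_, n_node, spec$n_codons)
  seqs[root, ] <- sample.int(length(sense), spec$n_codons, replace = TRUE,
                             prob = spec$codon_freqs[sense])

  truth <- data.frame(branch = labs[tree$edge[, 2]],
                      omega = unname(spec$omega[labs[tree$edge[, 2]]]),
                      length = tree$edge.length,
                      n_syn = 0L, n_nonsyn = 0L, stringsAsFactors = FALSE)

  tre_pre <- ape::reorder.phylo(tree, "cladewise")
  pre <- tre_pre$edge
  for (r in seq_len(nrow(pre))) {
    p <- pre[r, 1]; ch <- pre[r, 2]
    len <- tre_pre$edge.length[r]
    om <- spec$omega[labs[ch]]
    mach <- get_machinery(om)
    s <- seqs[p, ]
    n_s <- 0L; n_n <- 0L
    if (len > 0) {
      # codons with no allowed exchange (e.g. TGG under omega = 0) never move
      t_ev <- rep(Inf, spec$n_codons)
      movable <- mach$leave[s] > 0
      t_ev[movable] <- rexp(sum(movable), mach$leave[s][movable])
      active <- which(t_ev < len)
      for (site in active) {
        t <- t_ev[site]
        cur <- s[site]
        while (t < len) {
          cur_new <- findInterval(runif(1), mach$Pcum[cur, ]) + 1L
          if (aa[sense[cur_new]] == aa[sense[cur]]) n_s <- n_s + 1L
          else n_n <- n_n + 1L
          cur <- cur_new
          lv <- mach$leave[cur]
          if (lv <= 0) break
          t <- t + rexp(1, lv)
        }
        s[site] <- cur
      }
    }
    seqs[ch, ] <- s
    row <- which(truth$branch == labs[ch])
    truth$n_syn[row] <- n_s
    truth$n_nonsyn[row] <- n_n
  }

  to_string <- function(v) paste(sense[v], collapse = "")
  alignment <- setNames(vapply(seq_len(n_tip), function(k)
    to_string(seqs[k, ]), character(1)), tree$tip.label)
  ancestors <- setNames(vapply((n_tip + 1L):n_node, function(k)
    to_string(seqs[k, ]), character(1)), labs[(n_tip + 1L):n_node])
  list(alignment = alignment, ancestors = ancestors, truth = truth,
       spec = spec, seed = as.integer(seed))
}
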