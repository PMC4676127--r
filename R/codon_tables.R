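# Codon bookkeeping shared by the NG86 counters and the codon simulator.
# All tables are built lazily once per session and cached.

.codon_env <- new.env(parent = emptyenv())

codon_universe <- function() {
  if (!is.null(.codon_env$codons)) return(.codon_env$codons)
  b <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  gc <- Biostrings::GENETIC_CODE
  .codon_env$codons <- all64
  .codon_env$aa <- gc[all64]
  .codon_env$stops <- all64[gc[all64] == "*"]
  .codon_env$sense <- all64[gc[all64] != "*"]
  all64
}

codon_aa <- function(codon) {
  codon_universe()
  .codon_env$aa[codon]
}

is_transition <- function(a, b) {
  (a %in% c("A", "G") && b %in% c("A", "G")) ||
    (a %in% c("C", "T") && b %in% c("C", "T"))
}

# NG86 site counts: per codon, the fraction of the three possible changes
# at each position that are synonymous, excluding changes to stop codons
# from both numerator and denominator; each position contributes one site.
codon_site_counts <- function() {
  if (!is.null(.codon_env$sites)) return(.codon_env$sites)
  codons <- codon_universe()
  aa <- .codon_env$aa
  b <- c("A", "C", "G", "T")
  S <- setNames(numeric(64), codons)
  for (c0 in codons) {
    if (aa[c0] == "*") { S[c0] <- NA; next }
    chars <- strsplit(c0, "")[[1]]
    s_tot <- 0
    for (p in 1:3) {
      syn <- 0; valid <- 0
      for (nt in setdiff(b, chars[p])) {
        c1 <- chars; c1[p] <- nt
        c1 <- paste(c1, collapse = "")
        if (aa[c1] == "*") next
        valid <- valid + 1
        if (aa[c1] == aa[c0]) syn <- syn + 1
      }
      if (valid > 0) s_tot <- s_tot + syn / valid
    }
    S[c0] <- s_tot
  }
  .codon_env$sites <- S
  S
}

# NG86 pathway-averaged synonymous/nonsynonymous difference counts for
# every ordered codon pair. Multi-step differences average over all
# orderings of the changed positions; pathways passing through a stop
# codon are excluded (if every pathway hits a stop, all pathways are used
# with steps into/out of stops counted as nonsynonymous).
codon_pair_diffs <- function() {
  if (!is.null(.codon_env$pair_nd)) {
    return(list(nd = .codon_env$pair_nd, sd = .codon_env$pair_sd))
  }
  codons <- codon_universe()
  aa <- .codon_env$aa
  nd <- matrix(0, 64, 64, dimnames = list(codons, codons))
  sdm <- matrix(0, 64, 64, dimnames = list(codons, codons))
  split_c <- strsplit(codons, "")
  names(split_c) <- codons
  for (a in codons) for (b2 in codons) {
    if (a == b2) next
    ca <- split_c[[a]]; cb <- split_c[[b2]]
    pos <- which(ca != cb)
    paths <- if (length(pos) == 1) list(pos) else
      apply(perms(length(pos)), 1, function(o) pos[o], simplify = FALSE)
    tally <- function(path, allow_stops) {
      cur <- ca; n_s <- 0; n_n <- 0
      for (p in path) {
        nxt <- cur; nxt[p] <- cb[p]
        aa_cur <- aa[paste(cur, collapse = "")]
        aa_nxt <- aa[paste(nxt, collapse = "")]
        if (aa_nxt == "*" && !allow_stops) return(NULL)
        if (aa_cur != "*" && aa_cur == aa_nxt) n_s <- n_s + 1 else n_n <- n_n + 1
        cur <- nxt
      }
      c(n_s, n_n)
    }
    res <- Filter(Negate(is.null), lapply(paths, tally, allow_stops = FALSE))
    if (length(res) == 0)
      res <- lapply(paths, tally, allow_stops = TRUE)
    m <- do.call(rbind, res)
    sdm[a, b2] <- mean(m[, 1])
    nd[a, b2] <- mean(m[, 2])
  }
  .codon_env$pair_nd <- nd
  .codon_env$pair_sd <- sdm
  list(nd = nd, sd = sdm)
}

# all permutations of 1..n (n <= 3 here)
perms <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

split_codons <- function(seq) {
  seq <- toupper(gsub("\\s", "", seq))
  if (nchar(seq) %% 3 != 0) stop("sequence length is not a multiple of 3")
  substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
}
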