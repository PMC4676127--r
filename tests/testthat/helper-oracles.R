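# Independent brute-force oracles used across the suite. These
# deliberately re-derive results from first principles with the simplest
# possible code, sharing nothing with the package implementation paths
# they check.

# --- NG86 oracle: direct enumeration with its own genetic code ----------

oracle_genetic_code <- function() {
  stds <- Biostrings::GENETIC_CODE
  stds
}

oracle_codon_sites <- function(codon) {
  gc <- oracle_genetic_code()
  nts <- c("A", "C", "G", "T")
  ch <- strsplit(codon, "")[[1]]
  s <- 0
  for (p in 1:3) {
    syn <- 0; valid <- 0
    for (nt in nts[nts != ch[p]]) {
      mut <- ch; mut[p] <- nt
      mut <- paste(mut, collapse = "")
      if (gc[mut] == "*") next
      valid <- valid + 1
      if (gc[mut] == gc[codon]) syn <- syn + 1
    }
    if (valid > 0) s <- s + syn / valid
  }
  s
}

oracle_pair_counts <- function(ca, cb) {
  gc <- oracle_genetic_code()
  a <- strsplit(ca, "")[[1]]; b <- strsplit(cb, "")[[1]]
  pos <- which(a != b)
  if (length(pos) == 0) return(c(0, 0))
  enumerate <- function(order_idx, allow_stop) {
    cur <- a; ns <- 0; nn <- 0
    for (p in order_idx) {
      nxt <- cur; nxt[p] <- b[p]
      c_cur <- paste(cur, collapse = ""); c_nxt <- paste(nxt, collapse = "")
      if (gc[c_nxt] == "*" && !allow_stop) return(NULL)
      if (gc[c_cur] != "*" && gc[c_cur] == gc[c_nxt]) ns <- ns + 1 else nn <- nn + 1
      cur <- nxt
    }
    c(ns, nn)
  }
  orders <- if (length(pos) == 1) list(pos) else {
    perm_all <- function(v) {
      if (length(v) == 1) return(list(v))
      out <- list()
      for (k in seq_along(v))
        for (rest in perm_all(v[-k])) out[[length(out) + 1]] <- c(v[k], rest)
      out
    }
    perm_all(pos)
  }
  res <- Filter(Negate(is.null), lapply(orders, enumerate, allow_stop = FALSE))
  if (length(res) == 0) res <- lapply(orders, enumerate, allow_stop = TRUE)
  rowMeans(do.call(cbind, res))  # c(mean Sd, mean Nd)
}

oracle_ng86 <- function(seq_a, seq_b) {
  split3 <- function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  ca <- split3(seq_a); cb <- split3(seq_b)
  S <- (sum(vapply(ca, oracle_codon_sites, 0)) +
          sum(vapply(cb, oracle_codon_sites, 0))) / 2
  N <- 3 * length(ca) - S
  counts <- rowSums(vapply(seq_along(ca), function(i)
    oracle_pair_counts(ca[i], cb[i]), numeric(2)))
  list(Sd = counts[1], Nd = counts[2], S = S, N = N)
}

# --- random sense-codon sequences ---------------------------------------

random_coding_seq <- function(n_codons) {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# --- SD-calling rule oracle: direct scan of a CN track ------------------

oracle_call_runs <- function(cn, starts, ends, soft, hard, min_windows,
                             soft_allowance, min_span, cn_ceiling) {
  above <- cn > soft
  out <- list()
  i <- 1
  n <- length(cn)
  while (i <= n) {
    if (!above[i]) { i <- i + 1; next }
    j <- i
    while (j < n && above[j + 1]) j <- j + 1
    run <- i:j
    ok <- length(run) >= min_windows &&
      sum(cn[run] <= hard) <= soft_allowance &&
      (ends[j] - starts[i]) >= min_span &&
      all(cn[run] <= cn_ceiling)
    if (ok) out[[length(out) + 1]] <- c(start = starts[i], end = ends[j])
    i <- j + 1
  }
  if (length(out) == 0)
    return(data.frame(start = numeric(), end = numeric()))
  as.data.frame(do.call(rbind, out))
}

# --- Fitch parsimony oracle: exhaustive assignment over internal nodes --

oracle_parsimony_score <- function(tree, tip_chars) {
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  bases <- c("A", "C", "G", "T")
  combos <- expand.grid(rep(list(bases), n_int), stringsAsFactors = FALSE)
  best <- Inf
  for (r in seq_len(nrow(combos))) {
    state <- c(tip_chars[tree$tip.label], unlist(combos[r, ]))
    cost <- sum(state[tree$edge[, 1]] != state[tree$edge[, 2]])
    best <- min(best, cost)
  }
  best
}

# --- misc ----------------------------------------------------------------

const_scenario <- function(L = 2e5, n = 8, N = 10000, mu = 1e-8,
                           n_loci = 50) {
  demography_scenario("CONST", sample_sizes = n, ancestral_size = N,
                      mutation_rate = mu,
                      mutation_rate_units = "per_generation",
                      sequence_length = L, n_loci = n_loci)
}
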