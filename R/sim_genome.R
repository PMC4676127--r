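#' Generate a reference genome with planted features
#'
#' Builds random scaffold sequences and plants the feature classes the
#' depth-based duplication caller has to cope with: tandem repeats
#' (repeated short motifs) and interspersed repeats (a small library of
#' elements, each copied to several locations so k-mer over-masking sees
#' genuinely repeated text), assembly gaps (`N` runs), and copy-number
#' gains recorded with their true integer copy number (depth simulation
#' reads the gains from the truth record).
#'
#' @param scaffold_lengths named or unnamed integer vector of scaffold
#'   lengths in bp (names default to `scf1`, `scf2`, ...).
#' @param repeat_fraction approximate fraction of each scaffold covered by
#'   planted repeats (half tandem, half interspersed).
#' @param duplications `NULL` or a data.frame with columns `scaffold`,
#'   `start`, `end` (0-based half-open) and `cn` (true copy number >= 3).
#' @param gap_fraction approximate fraction covered by assembly gaps.
#' @param roh `NULL` or a data.frame of planted runs of homozygosity
#'   (`scaffold`, `start`, `end`), carried through for truth bookkeeping.
#' @param seed integer seed.
#' @return object of class `planted_genome`: list with `reference`
#'   (`Biostrings::DNAStringSet`), `mask` (data.frame `scaffold`, `start`,
#'   `end`, `class` in `interspersed`/`tandem`), `gaps`, `duplications`,
#'   `roh` and `seed`.
#' @export
planted_genome <- function(scaffold_lengths = c(scf1 = 100000L),
                           repeat_fraction = 0.1,
                           duplications = NULL,
                           gap_fraction = 0,
                           roh = NULL,
                           seed = 1) {
  set.seed(as.integer(seed))
  if (is.null(names(scaffold_lengths)))
    names(scaffold_lengths) <- sprintf("scf%d", seq_along(scaffold_lengths))
  if (any(scaffold_lengths < 1)) stop_field("scaffold_lengths", "must be >= 1")
  if (!is.null(duplications)) {
    stopifnot(all(c("scaffold", "start", "end", "cn") %in% names(duplications)))
    if (any(duplications$cn < 3)) stop_field("cn", "planted CN must be >= 3")
  }

  bases <- c("A", "C", "G", "T")
  seqs <- character(length(scaffold_lengths))
  mask <- list(); gaps <- list()

  for (s in seq_along(scaffold_lengths)) {
    L <- scaffold_lengths[s]
    nm <- names(scaffold_lengths)[s]
    chars <- sample(bases, L, replace = TRUE)

    # interspersed elements are drawn from a small per-scaffold library so
    # each element occurs at several locations (real repeated text)
    library_elements <- replicate(3, sample(bases, sample(300:800, 1),
                                            replace = TRUE), simplify = FALSE)
    plant <- function(fraction, tandem) {
      placed <- list()
      covered <- 0
      guard <- 0
      while (covered < fraction * L && guard < 1000) {
        guard <- guard + 1
        if (tandem) {
          len <- sample(300:2000, 1)
          if (len >= L) break
          motif <- sample(bases, sample(5:20, 1), replace = TRUE)
          unit <- rep_len(motif, len)
        } else {
          unit <- library_elements[[sample.int(length(library_elements), 1)]]
          len <- length(unit)
          if (len >= L) break
        }
        start <- sample.int(L - len, 1) - 1L   # 0-based
        chars[(start + 1):(start + len)] <<- unit
        placed[[length(placed) + 1]] <- data.frame(
          scaffold = nm, start = start, end = start + len,
          class = if (tandem) "tandem" else "interspersed",
          stringsAsFactors = FALSE)
        covered <- covered + len
      }
      placed
    }
    mask <- c(mask, plant(repeat_fraction / 2, tandem = TRUE),
              plant(repeat_fraction / 2, tandem = FALSE))

    if (gap_fraction > 0) {
      n_gaps <- max(1L, round(gap_fraction * L / 500))
      for (g in seq_len(n_gaps)) {
        len <- sample(100:500, 1)
        if (len >= L) next
        start <- sample.int(L - len, 1) - 1L
        chars[(start + 1):(start + len)] <- "N"
        gaps[[length(gaps) + 1]] <- data.frame(
          scaffold = nm, start = start, end = start + len,
          stringsAsFactors = FALSE)
      }
    }
    seqs[s] <- paste(chars, collapse = "")
  }

  empty_iv <- data.frame(scaffold = character(), start = integer(),
                         end = integer(), stringsAsFactors = FALSE)
  structure(list(
    reference = Biostrings::DNAStringSet(setNames(seqs, names(scaffold_lengths))),
    mask = if (length(mask)) do.call(rbind, mask) else
      cbind(empty_iv, class = character()),
    gaps = if (length(gaps)) do.call(rbind, gaps) else empty_iv,
    duplications = duplications %||% cbind(empty_iv, cn = numeric()),
    roh = roh %||% empty_iv,
    seed = as.integer(seed)
  ), class = "planted_genome")
}

#' Simulate a per-position read-start depth track
#'
#' Depth at each position is Poisson (or negative binomial when
#' `dispersion > 0`) with mean `mean_depth * cn / 2`, where `cn` is the
#' true local copy number (2 outside planted duplications). Assembly gaps
#' get exactly zero depth.
#'
#' @param features a [planted_genome()].
#' @param mean_depth mean read starts per position on copy-number-2
#'   sequence.
#' @param dispersion negative-binomial overdispersion; the variance is
#'   `mean * (1 + dispersion)`. Zero gives Poisson counts.
#' @param seed integer seed.
#' @return data.frame `scaffold`, `pos` (1-based), `depth`.
#' @export
simulate_depth_track <- function(features, mean_depth, dispersion = 0,
                                 seed = 1) {
  stopifnot(inherits(features, "planted_genome"))
  if (mean_depth <= 0) stop_field("mean_depth", "must be > 0")
  if (dispersion < 0) stop_field("dispersion", "must be >= 0")
  set.seed(as.integer(seed))

  lens <- Biostrings::width(features$reference)
  names(lens) <- names(features$reference)
  out <- vector("list", length(lens))
  for (s in seq_along(lens)) {
    nm <- names(lens)[s]
    L <- lens[s]
    cn <- rep(2, L)
    dups <- features$duplications[features$duplications$scaffold == nm, ,
                                  drop = FALSE]
    for (d in seq_len(nrow(dups)))
      cn[(dups$start[d] + 1):dups$end[d]] <- dups$cn[d]
    mu <- mean_depth * cn / 2
    depth <- if (dispersion > 0)
      rnbinom(L, size = mu / dispersion, mu = mu)
    else rpois(L, mu)
    gaps <- features$gaps[features$gaps$scaffold == nm, , drop = FALSE]
    for (g in seq_len(nrow(gaps)))
      depth[(gaps$start[g] + 1):gaps$end[g]] <- 0L
    out[[s]] <- data.frame(scaffold = nm, pos = seq_len(L), depth = depth,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
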