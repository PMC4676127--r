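#' Build the joint allele-frequency spectrum of two populations
#'
#' Tallies polarized sites into a `(n1+1) x (n2+1)` matrix `X` whose entry
#' `x[i, j]` counts SNVs with derived-allele count `i` in population 1 and
#' `j` in population 2. The fixed corner cells `(0, 0)` and `(n1, n2)` are
#' masked (they carry no information about segregating variation).
#'
#' Sites with missing genotypes are either dropped (`missing = "drop"`) or
#' projected down to `(n1, n2)` by hypergeometric averaging over the
#' observed chromosomes (`missing = "project"`), in which case entries are
#' fractional.
#'
#' @param geno derived-allele dosage matrix (sites x diploid individuals),
#'   values 0/1/2 or `NA` for missing genotypes.
#' @param pop factor/vector of population labels per individual (exactly
#'   two levels).
#' @param n1,n2 haploid spectrum dimensions; default twice the number of
#'   individuals in each population.
#' @param missing policy for sites with missing genotypes.
#' @return object of class `joint_afs`: the count matrix with attribute
#'   `mask` and `sample_sizes`.
#' @export
build_joint_afs <- function(geno, pop, n1 = NULL, n2 = NULL,
                            missing = c("drop", "project")) {
  missing <- match.arg(missing)
  pop <- factor(pop)
  if (nlevels(pop) != 2L) stop_field("pop", "exactly two populations required")
  if (ncol(geno) != length(pop)) stop_field("pop", "one label per individual")
  i1 <- which(pop == levels(pop)[1])
  i2 <- which(pop == levels(pop)[2])
  n1 <- n1 %||% (2L * length(i1))
  n2 <- n2 %||% (2L * length(i2))

  X <- matrix(0, n1 + 1, n2 + 1)
  if (nrow(geno) > 0) {
    g1 <- geno[, i1, drop = FALSE]
    g2 <- geno[, i2, drop = FALSE]
    miss <- rowSums(is.na(g1)) + rowSums(is.na(g2)) > 0
    d1 <- rowSums(g1[!miss, , drop = FALSE])
    d2 <- rowSums(g2[!miss, , drop = FALSE])
    if (any(d1 > n1) || any(d2 > n2))
      stop("derived count exceeds sample size; corrupt input")
    full <- table(factor(d1, levels = 0:n1), factor(d2, levels = 0:n2))
    X <- X + unclass(full)
    if (missing == "project" && any(miss)) {
      g1m <- g1[miss, , drop = FALSE]
      g2m <- g2[miss, , drop = FALSE]
      for (s in seq_len(nrow(g1m))) {
        a1 <- g1m[s, !is.na(g1m[s, ])]
        a2 <- g2m[s, !is.na(g2m[s, ])]
        m1 <- 2L * length(a1); m2 <- 2L * length(a2)
        if (m1 < n1 || m2 < n2) {
          if (m1 < 1 || m2 < 1) next
          # project observed counts down to (n1, n2) only if enough
          # chromosomes were seen; otherwise the site is dropped
          if (m1 < n1 || m2 < n2) next
        }
        w1 <- dhyper(0:n1, sum(a1), m1 - sum(a1), n1)
        w2 <- dhyper(0:n2, sum(a2), m2 - sum(a2), n2)
        X <- X + outer(w1, w2)
      }
    }
  }
  mask <- matrix(FALSE, n1 + 1, n2 + 1)
  mask[1, 1] <- TRUE
  mask[n1 + 1, n2 + 1] <- TRUE
  X[mask] <- 0
  dimnames(X) <- list(0:n1, 0:n2)
  structure(X, mask = mask, sample_sizes = c(n1, n2), class = "joint_afs")
}

#' Joint AFS of a synthetic cohort
#'
#' Convenience wrapper around [build_joint_afs()] using the cohort's
#' genotypes and population labels.
#'
#' @param cohort a `synthetic_cohort`.
#' @param ... passed to [build_joint_afs()].
#' @export
cohort_joint_afs <- function(cohort, ...) {
  build_joint_afs(cohort$geno, cohort$pop, ...)
}

#' Fold a one-dimensional allele-frequency spectrum
#'
#' Folded class `i` (minor-allele count) sums the derived classes `i` and
#' `n - i`; the central class of an even spectrum is not double-counted.
#'
#' @param eta unfolded spectrum `eta[0..n]` (vector of length `n + 1`).
#' @return folded spectrum of length `floor(n / 2) + 1`.
#' @export
fold_afs <- function(eta) {
  n <- length(eta) - 1L
  half <- n %/% 2L
  vapply(0:half, function(i) {
    if (i == n - i) eta[i + 1] else eta[i + 1] + eta[n - i + 1]
  }, numeric(1))
}

#' Project an AFS to smaller sample sizes
#'
#' Hypergeometric down-projection of a 1D spectrum or 2D joint spectrum.
#'
#' @param afs vector `eta[0..n]` or matrix `(n1+1) x (n2+1)`.
#' @param to new haploid sample size(s).
#' @return projected spectrum of the same kind.
#' @export
project_afs <- function(afs, to) {
  if (is.matrix(afs)) {
    n1 <- nrow(afs) - 1L; n2 <- ncol(afs) - 1L
    stopifnot(length(to) == 2L, to[1] <= n1, to[2] <= n2)
    out <- projection_matrix(n1, to[1]) %*% afs %*% t(projection_matrix(n2, to[2]))
    dimnames(out) <- list(0:to[1], 0:to[2])
    out
  } else {
    n <- length(afs) - 1L
    stopifnot(length(to) == 1L, to <= n)
    out <- as.vector(projection_matrix(n, to) %*% afs)
    names(out) <- 0:to
    out
  }
}
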