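# Expected allele-frequency spectra under piecewise-constant demographies.
#
# The engine propagates the expected density of segregating sites over a
# discrete population-frequency grid 0..G by a Wright-Fisher binomial
# resampling chain. For an epoch of relative size `nu` the chain takes
# steps of scaled duration dtau with an effective binomial size
# G_eff = nu / dtau (interpolated back onto the grid), so drift accrues at
# rate 1/nu per unit time. New mutations are injected into the singleton
# class at rate theta/2 per unit scaled time (mass theta * G * dtau / 2
# per step, i.e. the flux that keeps a constant-size population at the
# classical stationary density theta/i). Migration is the deterministic
# first-moment map x1 <- x1 + M * dtau * (x2 - x1), applied by linear
# redistribution of cell mass. The present-day grid density is projected
# to the sample sizes hypergeometrically.

# one-step transition matrix on grid 0..G for binomial size g_eff
wf_transition <- function(G, g_eff) {
  key <- sprintf("T_%d_%d", G, g_eff)
  hit <- .afs_cache[[key]]
  if (!is.null(hit)) return(hit)
  freqs <- (0:G) / G
  B <- outer(freqs, 0:g_eff, function(x, c) dbinom(c, g_eff, x))
  # interpolate counts c/g_eff back onto the G-grid
  W <- matrix(0, g_eff + 1, G + 1)
  idx <- (0:g_eff) / g_eff * G
  lo <- pmin(floor(idx), G - 1)
  w <- idx - lo
  W[cbind(seq_len(g_eff + 1), lo + 1)] <- 1 - w
  W[cbind(seq_len(g_eff + 1), lo + 2)] <- W[cbind(seq_len(g_eff + 1), lo + 2)] + w
  T1 <- B %*% W
  .afs_cache[[key]] <- T1
  T1
}

# quantized ladder of effective binomial sizes, so transition matrices can
# be cached across likelihood evaluations
g_ladder <- function(G) {
  key <- sprintf("ladder_%d", G)
  hit <- .afs_cache[[key]]
  if (!is.null(hit)) return(hit)
  lad <- unique(as.integer(round(4 * 1.05^(0:300))))
  lad <- lad[lad <= max(4L * G * G, 4L)]
  .afs_cache[[key]] <- lad
  lad
}

# steps, per-step duration and effective binomial size for an epoch of
# duration tau at relative size nu: total drift tau/nu is split into n
# steps of a cached binomial of quantized size g (g ~ n * nu / tau)
epoch_chain <- function(G, tau, nu, max_steps = 20000L) {
  D <- tau / nu
  n <- max(1L, min(max_steps, ceiling(G * D)))
  g_target <- max(4, min(n / D, 4 * G * G))
  lad <- g_ladder(G)
  g <- lad[which.min(abs(log(lad / g_target)))]
  n <- max(1L, min(max_steps, as.integer(round(D * g))))
  list(n = n, dtau = tau / n, g = g)
}

# steps and per-step duration for an epoch (shared-step migration path)
epoch_steps <- function(G, tau, nu_min, max_steps = 20000L) {
  n <- max(1L, min(max_steps, ceiling(G * tau / nu_min)))
  list(n = as.integer(n), dtau = tau / n)
}

matrix_power <- function(M, n) {
  P <- diag(nrow(M))
  while (n > 0) {
    if (n %% 2 == 1) P <- P %*% M
    M <- M %*% M
    n <- n %/% 2
  }
  P
}

# P = A^n and S = sum_{k=0}^{n-1} A^k v, by binary doubling
power_sum <- function(A, n, v) {
  if (n == 0) return(list(P = diag(nrow(A)), S = numeric(length(v))))
  if (n %% 2 == 1) {
    h <- power_sum(A, n - 1, v)
    list(P = A %*% h$P, S = v + as.vector(A %*% h$S))
  } else {
    h <- power_sum(A, n %/% 2, v)
    list(P = h$P %*% h$P, S = h$S + as.vector(h$P %*% h$S))
  }
}

# equilibrium density (theta = 1) of the constant-size chain, cached per G
.afs_cache <- new.env(parent = emptyenv())

wf_equilibrium <- function(G, tol = 1e-10, max_iter = NULL) {
  key <- as.character(G)
  if (!is.null(.afs_cache[[key]])) return(.afs_cache[[key]])
  max_iter <- max_iter %||% (200L * G)
  T1 <- wf_transition(G, G)
  A <- t(T1)
  phi <- numeric(G + 1)
  inj <- 1 / 2                      # theta = 1: G * dtau / 2 with dtau = 1/G
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    phi_new <- as.vector(A %*% phi)
    phi_new[1] <- 0; phi_new[G + 1] <- 0   # absorbed mass leaves the system
    phi_new[2] <- phi_new[2] + inj
    if (max(abs(phi_new - phi)) < tol * max(phi_new)) {
      phi <- phi_new; converged <- TRUE; break
    }
    phi <- phi_new
  }
  if (!converged)
    stop(sprintf(
      "ancestral equilibration did not converge at grid %d after %d iterations (tol %g)",
      G, max_iter, tol))
  .afs_cache[[key]] <- phi
  phi
}

# run the chain through one 1D epoch (merged population). The boundary
# classes are absorbing, so absorbed mass is simply discarded at the end.
run_epoch_1d <- function(phi, G, tau, nu, theta) {
  st <- epoch_chain(G, tau, nu)
  A <- t(wf_transition(G, st$g))
  inj <- theta * G * st$dtau / 2
  e1 <- numeric(G + 1); e1[2] <- 1
  ps <- power_sum(A, st$n, e1)
  phi <- as.vector(ps$P %*% phi) + inj * ps$S
  phi[1] <- 0; phi[G + 1] <- 0
  phi
}

# deterministic migration shift on the joint density: each population's
# frequency moves toward the other's by M * dtau * (x_other - x_self);
# cell mass is redistributed linearly between the flanking grid classes.
# Returned as a sparse operator on vec(Phi) (column-major), built once per
# epoch and applied every step.
migration_operator <- function(G, Mdt) {
  m <- G + 1
  x <- (0:G) / G
  one_direction <- function(tgt) {
    tgt <- pmin(pmax(tgt, 0), G)
    lo <- pmin(floor(tgt), G - 1)
    w <- tgt - lo
    cols <- rep(seq_len(m) - 1L, each = m) * m    # column-major cell index base
    src <- seq_len(m * m)
    Matrix::sparseMatrix(
      i = c(as.integer(lo) + 1L + cols, as.integer(lo) + 2L + cols),
      j = c(src, src),
      x = c(1 - as.vector(w), as.vector(w)),
      dims = c(m * m, m * m))
  }
  # pop1: row coordinate i moves toward x_j; target row index per (i, j)
  tgt1 <- outer((1 - Mdt) * x, Mdt * x, `+`) * G
  S1 <- one_direction(tgt1)
  # pop2: column coordinate j moves toward x_i; operate on the transposed
  # layout, i.e. conjugate the same construction by the vec-transpose
  perm <- as.vector(matrix(seq_len(m * m), m, m, byrow = TRUE))
  P <- Matrix::sparseMatrix(i = seq_len(m * m), j = perm, x = 1,
                            dims = c(m * m, m * m))
  S2 <- Matrix::t(P) %*% S1 %*% P
  S2 %*% S1
}

# run the joint density through one 2D epoch
run_epoch_2d <- function(Phi, G, tau, nu1, nu2, M, theta) {
  e1 <- numeric(G + 1); e1[2] <- 1

  if (M > 0) {
    # migration couples the populations, so both use a shared time step;
    # step count and effective binomial size are capped to keep extreme
    # parameter corners affordable (accuracy there matters only in
    # regions the search rejects anyway)
    st <- epoch_steps(G, tau, min(nu1, nu2), max_steps = 1000L)
    lad <- g_ladder(G)
    pick_g <- function(nu) lad[which.min(abs(log(lad / max(4, min(nu / st$dtau,
                                                                  4 * G * G)))))]
    A1 <- t(wf_transition(G, pick_g(nu1)))
    T2 <- wf_transition(G, pick_g(nu2))
    S <- migration_operator(G, M * st$dtau)
    inj <- theta * G * st$dtau / 2
    m <- G + 1
    for (k in seq_len(st$n)) {
      Phi <- matrix(as.vector(S %*% as.vector(Phi)), m, m)
      Phi <- A1 %*% Phi %*% T2
      Phi[1, 2] <- Phi[1, 2] + inj
      Phi[2, 1] <- Phi[2, 1] + inj
      Phi[1, 1] <- 0; Phi[m, m] <- 0
    }
    return(Phi)
  }
  # without migration the two populations evolve independently, so each
  # takes its own steps (effective binomial size ~ G). Mass injected into
  # a private class stays at frequency 0 in the other population, so the
  # accumulated injections are rank-one updates on the first row/column.
  st1 <- epoch_chain(G, tau, nu1)
  st2 <- epoch_chain(G, tau, nu2)
  A1 <- t(wf_transition(G, st1$g))
  A2 <- t(wf_transition(G, st2$g))
  ps1 <- power_sum(A1, st1$n, e1)
  ps2 <- power_sum(A2, st2$n, e1)
  Phi <- ps1$P %*% Phi %*% t(ps2$P)
  Phi[, 1] <- Phi[, 1] + theta * G * st1$dtau / 2 * ps1$S
  Phi[1, ] <- Phi[1, ] + theta * G * st2$dtau / 2 * ps2$S
  Phi[1, 1] <- 0; Phi[G + 1, G + 1] <- 0
  Phi
}

# hypergeometric down-projection matrix from from_n to to_n chromosomes
projection_matrix <- function(from_n, to_n) {
  outer(0:to_n, 0:from_n, function(a, i) dhyper(a, i, from_n - i, to_n))
}

#' Expected allele-frequency spectrum under a demographic scenario
#'
#' Computes the expected (Poisson-mean) AFS by propagating the density of
#' segregating sites over a Wright-Fisher frequency grid through the
#' scenario's epochs and projecting to the sample sizes. For a single
#' population (`CONST`, or `sample_sizes` of length 1) the result is a
#' vector `eta[0..n]`; for two populations a `(n1+1) x (n2+1)` matrix with
#' the fixed corner cells `(0,0)` and `(n1,n2)` masked.
#'
#' @param scenario a [demography_scenario()].
#' @param sample_sizes haploid sample sizes; defaults to the scenario's.
#' @param grid_size population-frequency grid size `G`; must be at least
#'   `4 * max(sample_sizes)`. Default `max(60, 4 * max(sample_sizes))`.
#' @param theta total scaled mutation rate `4 N_ref mu L`; defaults to the
#'   scenario's `theta_site * sequence_length`. The spectrum is linear in
#'   `theta`.
#' @return numeric vector or matrix of expected site counts, with
#'   attributes `theta` and `grid_size`; for two populations the masked
#'   corners carry attribute `mask` (logical matrix).
#' @export
expected_afs <- function(scenario, sample_sizes = scenario$sample_sizes,
                         grid_size = NULL, theta = NULL) {
  stopifnot(inherits(scenario, "demography_scenario"))
  n_max <- max(sample_sizes)
  G <- grid_size %||% max(60L, 4L * n_max)
  if (G < 4L * n_max)
    stop_field("grid_size", sprintf("must be >= %d (4 x max sample size)", 4L * n_max))
  theta <- theta %||% (scenario$theta_site * scenario$sequence_length)
  if (theta < 0) stop_field("theta", "must be >= 0")

  ep <- scenario$epochs
  # forward order: oldest finite epoch first; infinite ancestral epoch is
  # the stationary initial condition
  fin <- ep[is.finite(ep$t1), , drop = FALSE]
  fwd <- fin[rev(seq_len(nrow(fin))), , drop = FALSE]

  phi <- theta * wf_equilibrium(G)
  two_pop <- length(sample_sizes) == 2L
  Phi <- NULL
  split_done <- FALSE

  if (nrow(fwd) > 0) {
    for (r in seq_len(nrow(fwd))) {
      e <- fwd[r, ]
      tau <- e$t1 - e$t0
      if (e$merged) {
        phi <- run_epoch_1d(phi, G, tau, e$nu1, theta)
      } else {
        if (!split_done) {
          Phi <- matrix(0, G + 1, G + 1)
          Phi[cbind(seq_len(G + 1), seq_len(G + 1))] <- phi
          split_done <- TRUE
        }
        Phi <- run_epoch_2d(Phi, G, tau, e$nu1, e$nu2, e$M, theta)
      }
    }
  }

  if (!two_pop) {
    n <- sample_sizes[1]
    eta <- as.vector(projection_matrix(G, n) %*% phi)
    eta[eta < 0] <- 0
    names(eta) <- 0:n
    attr(eta, "theta") <- theta
    attr(eta, "grid_size") <- G
    return(eta)
  }

  if (!split_done) {
    # two samples from a never-split population: joint frequencies identical
    Phi <- matrix(0, G + 1, G + 1)
    Phi[cbind(seq_len(G + 1), seq_len(G + 1))] <- phi
  }
  n1 <- sample_sizes[1]; n2 <- sample_sizes[2]
  M_exp <- projection_matrix(G, n1) %*% Phi %*% t(projection_matrix(G, n2))
  M_exp[M_exp < 0] <- 0
  mask <- matrix(FALSE, n1 + 1, n2 + 1)
  mask[1, 1] <- TRUE
  mask[n1 + 1, n2 + 1] <- TRUE
  M_exp[mask] <- 0
  dimnames(M_exp) <- list(0:n1, 0:n2)
  attr(M_exp, "theta") <- theta
  attr(M_exp, "grid_size") <- G
  attr(M_exp, "mask") <- mask
  M_exp
}
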