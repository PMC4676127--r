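# Small, fast fits: tiny samples and coarse grids keep these cheap while
# still exercising the full optimization path.

sim_poisson_afs <- function(sc, grid_size, theta, seed) {
  M <- expected_afs(sc, grid_size = grid_size, theta = theta)
  set.seed(seed)
  X <- matrix(rpois(length(M), unclass(M)), nrow(M), ncol(M))
  structure(X, mask = attr(M, "mask"),
            sample_sizes = dim(M) - 1L, class = "joint_afs")
}

test_that("refitting from the optimum does not decrease the likelihood", {
  sc <- demography_scenario("IM", params = list(nu1 = 1, nu2 = 0.6,
                                                tau_split = 0.2, M = 1),
                            sample_sizes = c(4, 4))
  X <- sim_poisson_afs(sc, 16, 3000, seed = 1)
  f1 <- fit_model(X, "IM", n_starts = 2, n_candidates = 10, seed = 1,
                  grid_size = 16, maxit = 200)
  f2 <- fit_model(X, "IM", n_starts = 1, n_candidates = 1, seed = 2,
                  grid_size = 16, maxit = 200,
                  starts = matrix(unlist(f1$par[c("nu1", "nu2", "tau_split",
                                                  "M")]),
                                  1, dimnames = list(NULL,
                                                     c("nu1", "nu2",
                                                       "tau_split", "M"))))
  expect_gte(f2$LL, f1$LL - 1e-6)
})

test_that("model comparison ranks by likelihood and refuses undeclared LRTs", {
  f_a <- structure(list(model_id = "IM", LL = -100, n_par = 4),
                   class = "afs_fit")
  f_b <- structure(list(model_id = "BIM", LL = -90, n_par = 5),
                   class = "afs_fit")
  cmp <- compare_models(list(IM = f_a, BIM = f_b))
  expect_equal(cmp$ranking$model[1], "BIM")
  expect_null(cmp$lrt)

  cmp2 <- compare_models(list(IM = f_a, BIM = f_b),
                         data.frame(full = "BIM", restricted = "IM", df = 1))
  expect_equal(cmp2$lrt$stat, 20)
  expect_equal(cmp2$lrt$p, pchisq(20, 1, lower.tail = FALSE))

  # identical fits: zero statistic, p = 1
  cmp3 <- compare_models(list(a = f_a, b = f_a),
                         data.frame(full = "a", restricted = "b", df = 2))
  expect_equal(cmp3$lrt$stat, 0)
  expect_equal(cmp3$lrt$p, 1)

  expect_error(compare_models(list(IM = f_a, BIM = f_b),
                              data.frame(full = "BIM", restricted = "IM",
                                         df = NA)),
               "refused")
})

test_that("a full model never fits worse than its restriction", {
  sc <- demography_scenario("IM", params = list(nu1 = 1, nu2 = 1,
                                                tau_split = 0.15, M = 0.001),
                            sample_sizes = c(4, 4))
  X <- sim_poisson_afs(sc, 16, 2000, seed = 3)
  restr <- fit_model(X, "IM", n_starts = 2, n_candidates = 10, seed = 1,
                     grid_size = 16, maxit = 200,
                     fixed = list(M = 1e-4))
  # seed the full model with the restricted optimum so the numerical
  # optimum respects the nesting
  st <- matrix(c(unlist(restr$par[c("nu1", "nu2", "tau_split")]), 1e-4), 1,
               dimnames = list(NULL, c("nu1", "nu2", "tau_split", "M")))
  full <- fit_model(X, "IM", n_starts = 2, n_candidates = 10, seed = 1,
                    grid_size = 16, maxit = 200, starts = st)
  expect_gte(full$LL, restr$LL - 1e-6)
})

test_that("block bootstrap handles degenerate and identical-block cases", {
  # 12 identical blocks: every resample reproduces the same AFS
  sites <- data.frame(scaffold = rep(sprintf("c%d", 1:12), each = 5),
                      pos = rep(seq(1e5, 5e5, length.out = 5), 12))
  geno <- do.call(rbind, replicate(12, rbind(
    c(1, 0, 0, 0), c(0, 1, 1, 0), c(2, 2, 0, 1), c(1, 1, 1, 1),
    c(0, 0, 1, 2)), simplify = FALSE))
  cohort <- list(sites = sites, geno = geno,
                 pop = factor(c("a", "a", "b", "b")))
  b1 <- bootstrap_variance(cohort, "IM", block_bp = 1e6, B = 1, seed = 1,
                           n_starts = 1, n_candidates = 2, grid_size = 16,
                           maxit = 60)
  expect_true(b1$degenerate)
  expect_true(all(b1$par_var == 0))

  b3 <- bootstrap_variance(cohort, "IM", block_bp = 1e6, B = 3, seed = 1,
                           n_starts = 1, n_candidates = 2, grid_size = 16,
                           maxit = 60)
  expect_false(b3$degenerate)
  expect_true(all(b3$par_var < 1e-10))
  expect_lt(b3$LL_var, 1e-10)

  expect_error(bootstrap_variance(list(sites = sites[1:5, ],
                                       geno = geno[1:5, ],
                                       pop = cohort$pop),
                                  "IM", block_bp = 1e6, B = 2),
               "at least 10")
})

test_that("bootstrap parameter variances shrink with more data", {
  sc <- demography_scenario("IM", params = list(nu1 = 1, nu2 = 0.7,
                                                tau_split = 0.2, M = 0.5),
                            sample_sizes = c(4, 4), ancestral_size = 10000,
                            mutation_rate = 1e-8,
                            mutation_rate_units = "per_generation",
                            sequence_length = 2e6, n_loci = 400)
  sc_big <- sc; sc_big$sequence_length <- 8e6; sc_big$n_loci <- 1600L
  st <- matrix(c(1, 0.7, 0.2, 0.5), 1,
               dimnames = list(NULL, c("nu1", "nu2", "tau_split", "M")))
  med_var <- function(scn, seeds) median(vapply(seeds, function(s) {
    co <- simulate_two_pop_cohort(scn, s)
    bv <- bootstrap_variance(co, "IM", block_bp = 2e4, B = 5, seed = s,
                             n_starts = 1, n_candidates = 1, grid_size = 16,
                             maxit = 80, starts = st)
    median(bv$par_var / unlist(bv$boot_par[1, ])^2)  # relative scale
  }, numeric(1)))
  expect_lt(med_var(sc_big, 1:3), med_var(sc, 1:3))
})

test_that("likelihood-ratio test of a true interior null is chi-square calibrated", {
  # Data are Poisson draws from the null expectation, so sites are
  # independent and the composite likelihood is a true likelihood. The
  # null fixes tau_split at its true (interior) value; the alternative
  # frees it, giving a regular 1-df likelihood-ratio test.
  truth <- c(nu1 = 1, nu2 = 0.7, tau_split = 0.2, M = 0.5)
  sc0 <- demography_scenario("IM", params = as.list(truth),
                             sample_sizes = c(4, 4))
  n_rep <- 100
  stats <- numeric(n_rep)
  st1 <- matrix(truth, 1, dimnames = list(NULL, names(truth)))
  for (r in seq_len(n_rep)) {
    X <- sim_poisson_afs(sc0, 16, 4000, seed = 100 + r)
    f0 <- fit_model(X, "IM", n_starts = 1, n_candidates = 1, seed = r,
                    grid_size = 16, maxit = 300,
                    fixed = list(tau_split = 0.2),
                    starts = st1[, c("nu1", "nu2", "M"), drop = FALSE])
    # seed the alternative with the null optimum so the statistic is the
    # genuine improvement from freeing tau_split
    st_full <- matrix(c(unlist(f0$par[c("nu1", "nu2", "M")]),
                        tau_split = 0.2), 1,
                      dimnames = list(NULL, c("nu1", "nu2", "M",
                                              "tau_split")))
    f1 <- fit_model(X, "IM", n_starts = 1, n_candidates = 1, seed = r,
                    grid_size = 16, maxit = 300, starts = st_full)
    stats[r] <- max(0, 2 * (f1$LL - f0$LL))
  }
  rej <- mean(pchisq(stats, df = 1, lower.tail = FALSE) < 0.05)
  expect_gte(rej, 0.02)
  expect_lte(rej, 0.10)
})
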