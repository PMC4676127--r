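# Model fitting by maximum Poisson composite likelihood ------------------

# Free parameters, bounds and random-start windows per model. ISB epoch
# times inside the split are fitted as fractions of tau_split so the
# constraint tau_b <= tau_split holds throughout the search.
model_param_table <- function(model_id) {
  p <- function(name, lower, upper, s_lo, s_hi)
    data.frame(name = name, lower = lower, upper = upper,
               s_lo = s_lo, s_hi = s_hi, stringsAsFactors = FALSE)
  nu <- function(n) p(n, 1e-3, 100, 0.05, 5)
  tau <- function(n) p(n, 1e-4, 5, 0.01, 1)
  frac <- function(n) p(n, 1e-3, 1, 0.1, 0.95)
  switch(model_id,
    IM = rbind(nu("nu1"), nu("nu2"), tau("tau_split"),
               p("M", 1e-4, 20, 0.01, 5)),
    BIM = rbind(nu("nu_b"), tau("tau_b"), nu("nu1"), nu("nu2"),
                tau("tau_split")),
    SBR = rbind(tau("tau_split"), nu("nu1_b"), nu("nu2_b"), tau("tau_b"),
                nu("nu1_r"), nu("nu2_r"), tau("tau_r")),
    ISB = rbind(nu("nu_growth"), tau("tau_growth"), tau("tau_split"),
                nu("nu1_b"), nu("nu2_b"), frac("f_b1"), frac("f_b2")),
    stop_field("model_id", "must be one of IM, BIM, SBR, ISB")
  )
}

# deterministic coverage starts spanning the no-/moderate-/deep-bottleneck
# regimes; always screened alongside the random candidates
default_starts <- function(model_id) {
  rows <- switch(model_id,
    IM = list(c(nu1 = 1, nu2 = 1, tau_split = 0.2, M = 0.5),
              c(nu1 = 0.3, nu2 = 0.3, tau_split = 0.1, M = 0.05)),
    BIM = list(c(nu_b = 0.3, tau_b = 0.1, nu1 = 1, nu2 = 1, tau_split = 0.2),
               c(nu_b = 0.05, tau_b = 0.05, nu1 = 0.5, nu2 = 0.5,
                 tau_split = 0.1)),
    SBR = list(c(tau_split = 0.3, nu1_b = 0.3, nu2_b = 0.3, tau_b = 0.1,
                 nu1_r = 0.8, nu2_r = 0.8, tau_r = 0.1),
               c(tau_split = 0.1, nu1_b = 0.05, nu2_b = 0.05, tau_b = 0.05,
                 nu1_r = 0.3, nu2_r = 0.3, tau_r = 0.05)),
    ISB = list(c(nu_growth = 1.5, tau_growth = 0.3, tau_split = 0.2,
                 nu1_b = 0.3, nu2_b = 0.3, f_b1 = 0.6, f_b2 = 0.6),
               c(nu_growth = 1, tau_growth = 0.1, tau_split = 0.1,
                 nu1_b = 0.05, nu2_b = 0.05, f_b1 = 0.4, f_b2 = 0.4),
               c(nu_growth = 3, tau_growth = 0.5, tau_split = 0.3,
                 nu1_b = 0.15, nu2_b = 0.1, f_b1 = 0.7, f_b2 = 0.4)))
  do.call(rbind, rows)
}

# natural-scale named parameters -> demography_scenario (theta handled
# separately by the analytic profile scale)
params_to_scenario <- function(model_id, par) {
  par <- as.list(par)
  if (model_id == "ISB") {
    par$tau_b1 <- par$f_b1 * par$tau_split
    par$tau_b2 <- par$f_b2 * par$tau_split
    par$f_b1 <- NULL; par$f_b2 <- NULL
  }
  demography_scenario(model_id, params = par, sample_sizes = c(2, 2))
}

#' Fit a two-population demographic model to a joint AFS
#'
#' Maximizes the Poisson composite likelihood over the model's scaled
#' parameters by multi-start Nelder-Mead search in log10-parameter space.
#' The overall mutation-rate scale `theta` is profiled out analytically at
#' every evaluation, so only shape parameters are searched.
#'
#' @param X observed joint AFS ([build_joint_afs()]).
#' @param model_id one of `"IM"`, `"BIM"`, `"SBR"`, `"ISB"`.
#' @param n_starts number of Nelder-Mead starts actually run; candidates
#'   are pre-screened by a single likelihood evaluation.
#' @param n_candidates random candidate starting points screened before
#'   optimization (cheap: one evaluation each).
#' @param seed integer seed controlling the random starts (deterministic).
#' @param grid_size frequency grid for [expected_afs()]; default
#'   `4 * max(sample sizes)`.
#' @param maxit Nelder-Mead iteration cap per start.
#' @param starts optional matrix of natural-scale starting values (one row
#'   per start, named columns), added to the screened candidate pool;
#'   useful for seeding a rich model from a simpler model's optimum.
#' @param fixed optional named list of parameters to hold fixed.
#' @param n_hops basin-hopping rounds after the multi-start phase: the
#'   incumbent optimum is perturbed by a log-normal factor (sd `hop_sd`
#'   in log10 units) per parameter and re-optimized, keeping improvements.
#'   Useful for likelihood surfaces with competing bottleneck basins.
#' @param hop_sd perturbation scale of a hop, in log10 units.
#' @return object of class `afs_fit`: list with `model_id`, `par` (natural
#'   scale; for ISB also the derived `tau_b1`/`tau_b2`), `LL`,
#'   `theta_hat`, `grid_size` and per-start diagnostics `starts`.
#' @export
fit_model <- function(X, model_id, n_starts = 4, n_candidates = 40,
                      seed = 1, grid_size = NULL, maxit = 400,
                      starts = NULL, fixed = NULL, n_hops = 0,
                      hop_sd = 0.3) {
  info <- model_param_table(model_id)
  ns <- attr(X, "sample_sizes") %||% (dim(X) - 1L)
  n1 <- ns[1]; n2 <- ns[2]
  G <- grid_size %||% (4L * max(n1, n2))

  fixed <- fixed %||% list()
  free <- setdiff(info$name, names(fixed))
  if (length(free) == 0) stop("no free parameters to fit")
  fi <- info[match(free, info$name), ]

  assemble <- function(lp) {
    par <- as.list(10^lp)
    names(par) <- free
    c(par, fixed)[info$name]
  }

  objective <- function(lp) {
    if (any(lp < log10(fi$lower)) || any(lp > log10(fi$upper)))
      return(1e10 + sum(pmax(lp - log10(fi$upper), 0)^2 +
                        pmax(log10(fi$lower) - lp, 0)^2) * 1e10)
    par <- assemble(lp)
    sc <- try(params_to_scenario(model_id, par), silent = TRUE)
    if (inherits(sc, "try-error")) return(1e10)
    M <- try(expected_afs(sc, sample_sizes = c(n1, n2), grid_size = G,
                          theta = 1), silent = TRUE)
    if (inherits(M, "try-error")) return(1e10)
    ll <- suppressWarnings(composite_loglik(X, M, scale_theta = TRUE))
    if (!is.finite(ll)) return(1e10)
    -as.numeric(ll)
  }

  set.seed(as.integer(seed))
  n_candidates <- max(n_candidates, n_starts)
  cand <- matrix(
    10^(runif(n_candidates * nrow(fi), log10(fi$s_lo), log10(fi$s_hi))),
    nrow = n_candidates, byrow = TRUE, dimnames = list(NULL, fi$name))
  if (!is.null(starts)) {
    starts <- as.matrix(starts)[, fi$name, drop = FALSE]
    cand <- rbind(cand, starts)
  }
  cand <- rbind(cand, default_starts(model_id)[, fi$name, drop = FALSE])
  # screen candidates with a single evaluation; optimize from the best,
  # always including the best deterministic coverage start
  n_default <- nrow(default_starts(model_id))
  cand_lp <- log10(pmin(pmax(cand, fi$lower), fi$upper))
  screen <- apply(cand_lp, 1, function(lp)
    tryCatch(objective(lp), error = function(e) Inf))
  keep_n <- min(n_starts, nrow(cand))
  def_idx <- nrow(cand) - n_default + seq_len(n_default)
  take_idx <- unique(c(order(screen)[seq_len(keep_n)],
                       def_idx[which.min(screen[def_idx])]))
  start_mat <- cand[take_idx, , drop = FALSE]

  # each Nelder-Mead run is restarted (fresh simplex at its own optimum)
  # until it stops improving: a single pass rarely converges in 5-7
  # dimensions
  run_nm <- function(lp0, rounds = 3) {
    best <- NULL
    for (round in seq_len(rounds)) {
      o <- optim(lp0, objective, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-9))
      if (!is.null(best) && -o$value <= best$LL + 1e-6) break
      best <- list(ok = TRUE, LL = -o$value, par = o$par,
                   convergence = o$convergence)
      lp0 <- o$par
    }
    best
  }

  runs <- vector("list", nrow(start_mat))
  for (k in seq_len(nrow(start_mat))) {
    lp0 <- log10(pmin(pmax(start_mat[k, ], fi$lower), fi$upper))
    runs[[k]] <- tryCatch(run_nm(lp0),
                          error = function(e)
                            list(ok = FALSE, error = conditionMessage(e)))
  }

  ok <- vapply(runs, function(r) isTRUE(r$ok) && is.finite(r$LL) &&
                 r$LL > -1e9, logical(1))
  if (!any(ok)) {
    status <- vapply(seq_along(runs), function(k)
      sprintf("start %d: %s", k,
              if (isTRUE(runs[[k]]$ok)) sprintf("LL=%g", runs[[k]]$LL)
              else runs[[k]]$error), character(1))
    stop("all optimization starts failed:\n", paste(status, collapse = "\n"))
  }
  best <- runs[[which.max(vapply(runs, function(r)
    if (isTRUE(r$ok)) r$LL else -Inf, numeric(1)))]]
  # basin hopping: coordinated log-scale jumps escape the ridge-shaped
  # competing optima that bottleneck likelihoods are prone to
  for (h in seq_len(n_hops)) {
    prop <- best$par + rnorm(length(best$par), 0, hop_sd)
    prop <- pmin(pmax(prop, log10(fi$lower)), log10(fi$upper))
    o <- tryCatch(run_nm(prop, rounds = 2), error = function(e) NULL)
    if (!is.null(o) && o$LL > best$LL + 1e-6) best <- o
  }
  # polish: restarting Nelder-Mead re-expands the simplex at the optimum
  repeat {
    pol <- optim(best$par, objective, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-10))
    if (-pol$value > best$LL + 1e-6) {
      best <- list(ok = TRUE, LL = -pol$value, par = pol$par,
                   convergence = pol$convergence)
    } else break
  }

  par <- assemble(best$par)
  if (model_id == "ISB") {
    par$tau_b1 <- par$f_b1 * par$tau_split
    par$tau_b2 <- par$f_b2 * par$tau_split
  }
  sc <- params_to_scenario(model_id, par[info$name])
  M <- expected_afs(sc, sample_sizes = c(n1, n2), grid_size = G, theta = 1)
  ll <- composite_loglik(X, M, scale_theta = TRUE)

  structure(list(
    model_id = model_id,
    par = par,
    n_par = length(free),
    LL = as.numeric(ll),
    theta_hat = attr(ll, "theta_hat"),
    grid_size = G,
    expected = M * attr(ll, "theta_hat"),
    starts = lapply(runs, function(r)
      r[intersect(names(r), c("ok", "LL", "convergence", "error"))])
  ), class = "afs_fit")
}

#' @export
print.afs_fit <- function(x, ...) {
  cat(sprintf("<afs_fit> model %s  LL = %.2f  (theta_hat = %.4g)\n",
              x$model_id, x$LL, x$theta_hat))
  print(unlist(x$par))
  invisible(x)
}

#' Rank demographic model fits and run likelihood-ratio tests
#'
#' Ranks fits by log composite likelihood. For pairs declared nested in
#' `nesting_map` (columns `full`, `restricted`, `df`) the statistic
#' `2 * (LL_full - LL_restricted)` is compared to a chi-square with `df`
#' degrees of freedom. Undeclared or df-less pairs are refused.
#'
#' @param fits named list of [fit_model()] results.
#' @param nesting_map optional data.frame declaring nested pairs.
#' @return list with `ranking` (data.frame) and `lrt` (data.frame or NULL).
#' @export
compare_models <- function(fits, nesting_map = NULL) {
  stopifnot(length(fits) >= 1, !is.null(names(fits)))
  LL <- vapply(fits, function(f) f$LL, numeric(1))
  ranking <- data.frame(
    model = names(fits),
    LL = LL,
    n_par = vapply(fits, function(f) f$n_par, numeric(1)),
    rank = rank(-LL, ties.method = "first"),
    row.names = NULL
  )
  ranking <- ranking[order(ranking$rank), ]
  lrt <- NULL
  if (!is.null(nesting_map)) {
    if (!all(c("full", "restricted", "df") %in% names(nesting_map)))
      stop("nesting_map needs columns full, restricted, df")
    rows <- lapply(seq_len(nrow(nesting_map)), function(r) {
      fl <- nesting_map$full[r]; rs <- nesting_map$restricted[r]
      df <- nesting_map$df[r]
      if (is.na(df) || df < 1)
        stop(sprintf("pair (%s, %s) is not declared nested (df missing); LRT refused",
                     fl, rs))
      if (!fl %in% names(fits) || !rs %in% names(fits))
        stop(sprintf("fits for pair (%s, %s) not supplied", fl, rs))
      stat <- 2 * (fits[[fl]]$LL - fits[[rs]]$LL)
      data.frame(full = fl, restricted = rs, df = df,
                 stat = stat,
                 p = pchisq(max(stat, 0), df, lower.tail = FALSE))
    })
    lrt <- do.call(rbind, rows)
  }
  list(ranking = ranking, lrt = lrt)
}

#' Block-bootstrap variance of demographic parameter estimates
#'
#' Partitions the genome into blocks of `block_bp`, resamples blocks with
#' replacement `B` times, rebuilds the joint AFS and refits the model,
#' reporting per-parameter and log-likelihood variances. Block (rather
#' than per-site) resampling respects linkage within blocks.
#'
#' @param cohort a `synthetic_cohort` (or any list with `geno`, `pop` and
#'   `sites` of the same layout).
#' @param model_id model to refit.
#' @param block_bp block length in bp.
#' @param B number of bootstrap replicates.
#' @param seed integer seed.
#' @param ... further arguments to [fit_model()] (e.g. `n_starts`,
#'   `grid_size`, `maxit`, `starts`).
#' @return list with `par_var`, `LL_var`, `boot_par` (replicate matrix),
#'   `boot_LL`, `B` and `degenerate` (TRUE when `B < 2`).
#' @export
bootstrap_variance <- function(cohort, model_id, block_bp = 1e6, B = 100,
                               seed = 1, ...) {
  if (B < 1) stop_field("B", "must be >= 1")
  block <- paste(cohort$sites$scaffold,
                 (cohort$sites$pos - 1) %/% block_bp)
  ids <- unique(block)
  if (length(ids) < 10)
    stop(sprintf("only %d blocks of %g bp; need at least 10", length(ids), block_bp))
  set.seed(as.integer(seed))
  rows_by_block <- split(seq_along(block), block)
  boot <- vector("list", B)
  for (b in seq_len(B)) {
    take <- sample(ids, length(ids), replace = TRUE)
    rows <- unlist(rows_by_block[take], use.names = FALSE)
    Xb <- build_joint_afs(cohort$geno[rows, , drop = FALSE], cohort$pop)
    # a fixed fit seed keeps the optimizer deterministic across replicates,
    # so bootstrap variance reflects resampling only
    fit <- fit_model(Xb, model_id, seed = seed, ...)
    boot[[b]] <- c(unlist(fit$par), LL = fit$LL)
  }
  bm <- do.call(rbind, boot)
  degenerate <- B < 2
  v <- if (degenerate) setNames(rep(0, ncol(bm)), colnames(bm)) else
    apply(bm, 2, stats::var)
  list(par_var = v[setdiff(names(v), "LL")],
       LL_var = unname(v["LL"]),
       boot_par = bm[, setdiff(colnames(bm), "LL"), drop = FALSE],
       boot_LL = bm[, "LL"],
       B = B, degenerate = degenerate)
}
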