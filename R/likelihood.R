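mask_of <- function(X) {
  m <- attr(X, "mask")
  if (is.null(m)) {
    m <- matrix(FALSE, nrow(as.matrix(X)), ncol(as.matrix(X)))
    m[1, 1] <- TRUE
    m[nrow(m), ncol(m)] <- TRUE
  }
  m
}

#' Poisson composite log-likelihood of an observed joint AFS
#'
#' Treats unmasked AFS cells as independent Poisson observations with
#' means given by the expected spectrum:
#' `LL = sum x_ij * ln(m_ij) - m_ij - ln(x_ij!)`.
#' With `scale_theta = TRUE` the expected spectrum is first multiplied by
#' the analytic optimum `theta_hat = sum(x) / sum(m)`, which profiles the
#' overall mutation-rate scale out of the model parameters.
#'
#' @param X observed spectrum ([build_joint_afs()] output or plain matrix).
#' @param M expected spectrum ([expected_afs()] output or plain matrix).
#' @param scale_theta rescale `M` by the analytic theta optimum.
#' @param eps floor applied (with a warning) to expected cells that are 0
#'   where the observation is positive.
#' @return log composite likelihood (attribute `theta_hat` when scaled).
#' @export
composite_loglik <- function(X, M, scale_theta = TRUE, eps = 1e-12) {
  x <- unclass(as.matrix(X)); m <- unclass(as.matrix(M))
  if (!all(dim(x) == dim(m))) stop("observed and expected AFS shapes differ")
  keep <- !(mask_of(X) | mask_of(M))
  x <- x[keep]; m <- m[keep]
  theta_hat <- 1
  if (scale_theta) {
    if (sum(m) <= 0) stop("expected AFS has zero total mass")
    theta_hat <- sum(x) / sum(m)
    m <- m * theta_hat
  }
  bad <- m <= 0 & x > 0
  if (any(bad)) {
    warning(sprintf("%d expected cells floored at eps = %g", sum(bad), eps))
    m[bad] <- eps
  }
  pos <- x > 0
  ll <- sum(x[pos] * log(m[pos]) - lgamma(x[pos] + 1)) - sum(m)
  attr(ll, "theta_hat") <- theta_hat
  ll
}

#' Pearson residuals and goodness of fit for an AFS model
#'
#' Signed residuals `r_ij = (x_ij - m_ij) / sqrt(m_ij)` on unmasked cells
#' (positive where the model predicts too few sites) and the Pearson
#' statistic `sum r_ij^2`.
#'
#' @inheritParams composite_loglik
#' @param scale_theta rescale `M` by the analytic theta optimum first.
#' @return list with `residuals` (matrix, `NA` at masked cells),
#'   `pearson` and `theta_hat`.
#' @export
residuals_and_gof <- function(X, M, scale_theta = FALSE, eps = 1e-12) {
  x <- unclass(as.matrix(X)); m <- unclass(as.matrix(M))
  if (!all(dim(x) == dim(m))) stop("observed and expected AFS shapes differ")
  keep <- !(mask_of(X) | mask_of(M))
  theta_hat <- 1
  if (scale_theta) {
    theta_hat <- sum(x[keep]) / sum(m[keep])
    m <- m * theta_hat
  }
  mf <- pmax(m, eps)
  r <- (x - mf) / sqrt(mf)
  r[!keep] <- NA_real_
  list(residuals = r,
       pearson = sum(r[keep]^2),
       theta_hat = theta_hat)
}
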