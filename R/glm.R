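#' Poisson regression fit with log link and log offset
#'
#' Maximum-likelihood fit of the covariate-only model
#' \eqn{Y \sim Pois(u\,e^{x\cdot\beta})} on the flattened cells, by
#' iteratively reweighted least squares (via [stats::glm.fit()], convergence
#' when the relative deviance change is below `1e-8`, at most 100
#' iterations). The returned covariance is the inverse Fisher information at
#' the optimum; it seeds the fixed component of the adaptive Metropolis
#' proposal, and the coefficient estimate is the sampler's starting value.
#'
#' @param data a [count_tensor()]. The design is the covariate array as
#'   provided (include an explicit intercept column if one is wanted).
#' @return A list with `beta_hat` (length `P`), `cov_hat` (`P x P`, symmetric
#'   positive definite), `loglik`, `deviance` and `converged`.
#' @export
glm_poisson_fit <- function(data) {
  stopifnot(inherits(data, "count_tensor"))
  X <- ct_design(data)
  colnames(X) <- data$labels$covariates
  y <- as.vector(data$counts)
  off <- log(as.vector(data$offsets))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  fit <- suppressWarnings(glm.fit(
    x = X, y = y, family = poisson(), offset = off,
    control = glm.control(epsilon = 1e-8, maxit = 100)))
  if (!fit$converged)
    warning("IRLS did not converge in 100 iterations; returning last iterate")
  # unscaled covariance = (X' W X)^{-1} from the final weighted QR
  Rm <- qr.R(fit$qr)
  piv <- fit$qr$pivot
  cov_hat <- chol2inv(Rm)
  cov_hat[piv, piv] <- cov_hat
  dimnames(cov_hat) <- list(colnames(X), colnames(X))
  beta_hat <- fit$coefficients
  mu <- exp(pmin(pmax(drop(X %*% beta_hat) + off, -.ETA_CLAMP), .ETA_CLAMP))
  list(beta_hat = beta_hat,
       cov_hat = (cov_hat + t(cov_hat)) / 2,
       loglik = sum(dpois(y, mu, log = TRUE)),
       deviance = fit$deviance,
       converged = fit$converged)
}
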