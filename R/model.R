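#' Prior specification
#'
#' Independent gamma priors on the three core blocks and independent
#' zero-mean normal priors on the regression coefficients:
#' \deqn{\lambda^{(1)}_{i,h_1} \sim Ga(\alpha_a, \alpha_b),\quad
#'   \lambda^{(2)}_{t,h_1,h_2} \sim Ga(\gamma_a, \gamma_b),\quad
#'   \lambda^{(3)}_{k,h_2} \sim Ga(\epsilon_a, \epsilon_b),\quad
#'   \beta_p \sim N(0, \sigma^2).}
#' The gamma priors are conjugate to the Poisson likelihood after
#' latent-count augmentation; the normal prior on \eqn{\beta} is not, hence
#' the Metropolis step. The defaults are the hyperparameters used in the
#' rank-5 parameter-recovery study.
#'
#' @param alpha_a,alpha_b gamma shape/rate for strata loadings.
#' @param gamma_a,gamma_b gamma shape/rate for time cores.
#' @param eps_a,eps_b gamma shape/rate for cause loadings.
#' @param sigma2 normal prior variance for each coefficient.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(alpha_a = 1, alpha_b = 1, gamma_a = 1, gamma_b = 2,
                       eps_a = 1, eps_b = 1, sigma2 = 0.1) {
  v <- c(alpha_a, alpha_b, gamma_a, gamma_b, eps_a, eps_b, sigma2)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("all prior hyperparameters must be positive and finite")
  structure(list(alpha_a = alpha_a, alpha_b = alpha_b,
                 gamma_a = gamma_a, gamma_b = gamma_b,
                 eps_a = eps_a, eps_b = eps_b, sigma2 = sigma2),
            class = "prior_spec")
}

#' Model state: regression coefficients plus rate cores
#'
#' @param beta numeric coefficient vector, aligned with the covariate columns
#'   of the data (the first entry is the intercept when the first covariate
#'   column is all ones).
#' @param cores a [tt_cores()] or [cp_cores()] object.
#' @return An object of class `model_state`.
#' @export
model_state <- function(beta, cores) {
  stopifnot(is.numeric(beta), all(is.finite(beta)),
            inherits(cores, "tt_cores") || inherits(cores, "cp_cores"))
  structure(list(beta = as.numeric(beta), cores = cores),
            class = "model_state")
}

# u * exp(clamp(X beta)) as an N x T x K array
offset_factor <- function(data, beta) {
  eta <- clamp_eta(drop(ct_design(data) %*% beta))
  w <- data$offsets * array(exp(eta), dim(data))
  w
}

#' Cellwise Poisson mean under the model
#'
#' The observation model is
#' \deqn{Y_{itk} \sim Pois(u_{itk}\, e^{x_{itk}\cdot\beta}\, \lambda^*_{itk}),}
#' the classical Poisson regression with offset, multiplied by the residual
#' rate \eqn{\lambda^*} reconstructed from the cores. The linear predictor is
#' clamped to \eqn{[-700, 700]} before exponentiation as an overflow guard
#' (with a warning when the clamp activates).
#'
#' @param data a [count_tensor()].
#' @param state a [model_state()].
#' @return A positive array `N x T x K`.
#' @export
poisson_mean <- function(data, state) {
  stopifnot(inherits(data, "count_tensor"), inherits(state, "model_state"))
  if (length(state$beta) != ct_nvar(data))
    stop("length(beta) must match the number of covariate columns")
  mu <- offset_factor(data, state$beta) * tt_rate(state$cores)
  bad <- which(!is.finite(mu))
  if (length(bad))
    stop(sprintf("non-finite Poisson mean at cell %d", bad[1]))
  mu
}

#' Poisson log-likelihood of a model state
#'
#' \eqn{\sum_{itk} [Y \log\mu - \mu - \log Y!]} with
#' \eqn{\mu = } [poisson_mean()]. The \eqn{\log Y!} constant is retained so
#' absolute values are comparable across models and software. Returns
#' `-Inf` (with a message) if any cell has `mu == 0` with a positive count.
#'
#' @inheritParams poisson_mean
#' @return A scalar.
#' @export
log_likelihood <- function(data, state) {
  mu <- poisson_mean(data, state)
  ll <- sum(dpois(data$counts, mu, log = TRUE))
  if (!is.finite(ll)) message("log-likelihood is -Inf: zero mean with positive count")
  ll
}

#' Poisson deviance goodness-of-fit
#'
#' \eqn{2\sum_{itk}[Y\log(Y/\mu) - (Y-\mu)]} with the convention
#' \eqn{Y\log(Y/\mu) = 0} for \eqn{Y = 0}; equals twice the gap between the
#' saturated and model log-likelihoods, and is non-negative.
#'
#' @inheritParams poisson_mean
#' @return A non-negative scalar.
#' @export
deviance_gof <- function(data, state) {
  mu <- poisson_mean(data, state)
  y <- data$counts
  term <- ifelse(y > 0, y * log(y / mu), 0)
  2 * sum(term - (y - mu))
}

#' Log posterior density (unnormalized, constants retained)
#'
#' Log-likelihood plus gamma log prior densities of every core entry and
#' normal log prior densities of the coefficients. For CP cores only the
#' (structurally free) diagonal middle-core entries carry prior mass.
#'
#' @inheritParams poisson_mean
#' @param priors a [prior_spec()].
#' @return A scalar.
#' @export
log_posterior <- function(data, state, priors) {
  stopifnot(inherits(priors, "prior_spec"))
  cores <- state$cores
  l2 <- if (inherits(cores, "cp_cores")) cores$lambda2_diag else cores$lambda2
  if (any(cores$lambda1 <= 0) || any(l2 <= 0) || any(cores$lambda3 <= 0))
    stop("core entries must be strictly positive")
  lp <- log_likelihood(data, state) +
    sum(dgamma(cores$lambda1, priors$alpha_a, priors$alpha_b, log = TRUE)) +
    sum(dgamma(l2, priors$gamma_a, priors$gamma_b, log = TRUE)) +
    sum(dgamma(cores$lambda3, priors$eps_a, priors$eps_b, log = TRUE)) +
    sum(dnorm(state$beta, 0, sqrt(priors$sigma2), log = TRUE))
  lp
}

#' Simulate a count tensor from the model
#'
#' Draws each cell independently from `Pois(poisson_mean)`; reproducible
#' given `seed`.
#'
#' @param offsets positive array `N x T x K`.
#' @param covariates array `N x T x K x P`.
#' @param state a [model_state()].
#' @param seed optional integer seed.
#' @param labels optional axis labels, as in [count_tensor()].
#' @return A [count_tensor()].
#' @export
simulate_counts <- function(offsets, covariates, state, seed = NULL,
                            labels = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- dim(as.array(offsets))
  shell <- count_tensor(array(0L, d), offsets, covariates, labels)
  mu <- poisson_mean(shell, state)
  if (any(mu > .Machine$integer.max / 4))
    stop(sprintf("Poisson mean overflow at cell %d", which.max(mu)))
  y <- rpois(length(mu), mu)
  count_tensor(array(y, d), offsets, covariates, labels)
}
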