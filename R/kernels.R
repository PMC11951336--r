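#' Multinomial thinning of observed counts into latent components
#'
#' The augmentation behind the conjugate gamma updates: each cell count is
#' split over the `H1 x H2` latent components as
#' \deqn{(Y^{1,1}_{itk},\dots,Y^{H_1,H_2}_{itk}) \sim
#'   Multi\big(Y_{itk},\ \pi^{h_1,h_2}_{itk}\big),\qquad
#'   \pi^{h_1,h_2}_{itk} = \lambda^{(1)}_{i,h_1}\lambda^{(2)}_{t,h_1,h_2}
#'   \lambda^{(3)}_{k,h_2} / \lambda^*_{itk},}
#' and only the three marginal sums of the split counts are retained, since
#' those are all the full conditionals need. Cells with `Y = 0` contribute
#' nothing and are skipped; each marginal sums exactly to the total observed
#' count. In CP mode the split runs over the `H` diagonal components only.
#'
#' This is the plain-R reference implementation used by the correctness
#' tests; [run_chain()] uses an equivalent compiled kernel.
#'
#' @param data a [count_tensor()].
#' @param state a [model_state()].
#' @param seed optional integer seed.
#' @return A list of class `latent_marginals` with `m1` (`N x H1`), `m2`
#'   (`T x H1 x H2`, or `T x H` in CP mode) and `m3` (`K x H2`).
#' @export
thin_latent_counts <- function(data, state, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cores <- state$cores
  cp <- inherits(cores, "cp_cores")
  d <- dim(data); N <- d[1]; Tt <- d[2]
  l1 <- cores$lambda1; l3 <- cores$lambda3
  H1 <- ncol(l1); H2 <- ncol(l3)
  rate <- tt_rate(cores)
  m1 <- matrix(0L, N, H1)
  m3 <- matrix(0L, d[3], H2)
  m2 <- if (cp) matrix(0L, Tt, H1) else array(0L, c(Tt, H1, H2))
  for (cell in data$nonzero) {
    i <- (cell - 1L) %% N + 1L
    t <- ((cell - 1L) %/% N) %% Tt + 1L
    k <- (cell - 1L) %/% (N * Tt) + 1L
    y <- data$counts[cell]
    if (cp) {
      p <- l1[i, ] * cores$lambda2_diag[t, ] * l3[k, ]
    } else {
      p <- as.vector(l1[i, ] * cores$lambda2[t, , ]) * rep(l3[k, ], each = H1)
    }
    tot <- sum(p)
    if (!is.finite(tot) || tot <= 0)
      stop(sprintf("degenerate split probabilities at cell %d", cell))
    if (abs(sum(p / rate[cell]) - 1) > 1e-10)
      stop(sprintf("split probabilities inconsistent with the rate at cell %d",
                   cell))
    yl <- drop(rmultinom(1L, y, p))
    if (cp) {
      m1[i, ] <- m1[i, ] + yl
      m2[t, ] <- m2[t, ] + yl
      m3[k, ] <- m3[k, ] + yl
    } else {
      ym <- matrix(yl, H1, H2)
      m1[i, ] <- m1[i, ] + as.integer(rowSums(ym))
      m2[t, , ] <- m2[t, , ] + ym
      m3[k, ] <- m3[k, ] + as.integer(colSums(ym))
    }
  }
  structure(list(m1 = m1, m2 = m2, m3 = m3, cp = cp),
            class = "latent_marginals")
}

# shared contraction: A[(t,k), h1] = sum_h2 lambda2[t,h1,h2] lambda3[k,h2]
contract_23 <- function(l2, l3) {
  Tt <- dim(l2)[1]; H1 <- dim(l2)[2]; H2 <- dim(l2)[3]; K <- nrow(l3)
  A <- matrix(l2, Tt * H1, H2) %*% t(l3)  # (t,h1) x k
  dim(A) <- c(Tt, H1, K)
  A
}

#' Conjugate gamma full-conditional updates of the core blocks
#'
#' Given the latent marginals, each core entry has a gamma full conditional:
#' the shape is the prior shape plus the matching latent marginal count, and
#' the rate is the prior rate plus the accumulated exposure
#' \eqn{u_{itk} e^{x_{itk}\cdot\beta}} weighted by the complementary cores,
#' summed over the indices the entry does not carry. For the strata loadings:
#' \deqn{\lambda^{(1)}_{i,h_1}\mid\cdot \sim Ga\Big(\alpha_a + Y^{h_1,\cdot}_{i,\cdot,\cdot},\
#'   \alpha_b + \textstyle\sum_{t,k,h_2} u_{itk} e^{x_{itk}\cdot\beta}
#'   \lambda^{(2)}_{t,h_1,h_2}\lambda^{(3)}_{k,h_2}\Big),}
#' and analogously for the time cores and cause loadings. In CP mode only
#' the diagonal middle-core entries are updated; off-diagonals are
#' structurally zero.
#'
#' These are the plain-R reference kernels; [run_chain()] uses compiled
#' equivalents.
#'
#' @param marginals a `latent_marginals` object from [thin_latent_counts()].
#' @param data a [count_tensor()].
#' @param state a [model_state()] holding the conditioning values.
#' @param priors a [prior_spec()].
#' @param seed optional integer seed.
#' @return The updated core block (`lambda1`/`lambda3`: a matrix; `lambda2`:
#'   a `T x H1 x H2` array, or a `T x H` matrix in CP mode).
#' @name gamma_updates
NULL

#' @rdname gamma_updates
#' @export
update_lambda1 <- function(marginals, data, state, priors, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  r <- fc_rate_lambda1(data, state)
  shape <- priors$alpha_a + marginals$m1
  rate <- priors$alpha_b + r
  if (any(rate <= 0)) stop("non-positive full-conditional rate")
  matrix(rgamma(length(shape), shape = shape, rate = rate), nrow(r), ncol(r))
}

#' @rdname gamma_updates
#' @export
update_lambda2 <- function(marginals, data, state, priors, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  r <- fc_rate_lambda2(data, state)
  shape <- priors$gamma_a + marginals$m2
  rate <- priors$gamma_b + r
  if (any(rate <= 0)) stop("non-positive full-conditional rate")
  out <- rgamma(length(shape), shape = shape, rate = rate)
  if (inherits(state$cores, "cp_cores")) matrix(out, dim(r)[1], dim(r)[2])
  else array(out, dim(r))
}

#' @rdname gamma_updates
#' @export
update_lambda3 <- function(marginals, data, state, priors, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  r <- fc_rate_lambda3(data, state)
  shape <- priors$eps_a + marginals$m3
  rate <- priors$eps_b + r
  if (any(rate <= 0)) stop("non-positive full-conditional rate")
  matrix(rgamma(length(shape), shape = shape, rate = rate), nrow(r), ncol(r))
}

# deterministic full-conditional rate terms (exclusive of the prior rate);
# exposed internally so the compiled path can be pinned against them
fc_rate_lambda1 <- function(data, state) {
  W <- offset_factor(data, state$beta)
  cores <- as_tt(state$cores)
  d <- dim(data)
  A <- contract_23(cores$lambda2, cores$lambda3)       # t x h1 x k
  A <- aperm(A, c(1, 3, 2))                            # t x k x h1
  H1 <- dim(A)[3]
  matrix(W, d[1], d[2] * d[3]) %*% matrix(A, d[2] * d[3], H1)
}

fc_rate_lambda2 <- function(data, state) {
  W <- offset_factor(data, state$beta)
  d <- dim(data); cp <- inherits(state$cores, "cp_cores")
  cores <- as_tt(state$cores)
  l1 <- cores$lambda1; l3 <- cores$lambda3
  H1 <- ncol(l1); H2 <- ncol(l3)
  V <- crossprod(l1, matrix(W, d[1], d[2] * d[3]))     # h1 x (t,k)
  dim(V) <- c(H1, d[2], d[3])
  V <- aperm(V, c(2, 1, 3))                            # t x h1 x k
  out <- matrix(V, d[2] * H1, d[3]) %*% l3             # (t,h1) x h2
  out <- array(out, c(d[2], H1, H2))
  if (cp) {
    diag_out <- matrix(0, d[2], H1)
    for (h in seq_len(H1)) diag_out[, h] <- out[, h, h]
    diag_out
  } else out
}

fc_rate_lambda3 <- function(data, state) {
  W <- offset_factor(data, state$beta)
  d <- dim(data)
  cores <- as_tt(state$cores)
  l1 <- cores$lambda1; l2 <- cores$lambda2
  H1 <- ncol(l1); H2 <- dim(l2)[3]
  V <- crossprod(l1, matrix(W, d[1], d[2] * d[3]))     # h1 x (t,k)
  dim(V) <- c(H1, d[2], d[3])
  V <- aperm(V, c(2, 1, 3))                            # t x h1 x k
  crossprod(matrix(V, d[2] * H1, d[3]), matrix(l2, d[2] * H1, H2))  # k x h2
}

as_tt <- function(cores) {
  if (inherits(cores, "cp_cores")) cp_to_tt(cores, eps = 0) else cores
}

#' Adaptive Metropolis state
#'
#' Running mean and covariance of the coefficient draws (Welford recursion
#' over the whole run), plus the fixed covariance seeding the safe proposal
#' component. The `n`-step proposal is the two-component mixture
#' \deqn{Q_n(\beta,\cdot) = (1-p)\,N(\beta, 2.38^2\Sigma_n/d) +
#'   p\,N(\beta, 0.1^2\Sigma/d),}
#' with `p = p_fixed` a small constant, \eqn{\Sigma_n} the empirical
#' covariance of the draws so far, \eqn{\Sigma} the fixed (GLM) covariance
#' and `d` the coefficient dimension. During warm-up (`n <= n0` draws seen)
#' only the fixed component is used, since \eqn{\Sigma_n} is rank-deficient
#' early on.
#'
#' @param sigma_fixed fixed `d x d` covariance, typically `cov_hat` from
#'   [glm_poisson_fit()].
#' @param p_fixed mixture weight of the fixed component, in (0, 1).
#' @param n0 warm-up length; defaults to `2 * d`.
#' @return An object of class `adapt_state`.
#' @export
adapt_state <- function(sigma_fixed, p_fixed = 0.05, n0 = NULL) {
  sigma_fixed <- as.matrix(sigma_fixed)
  d <- nrow(sigma_fixed)
  stopifnot(ncol(sigma_fixed) == d, p_fixed > 0, p_fixed < 1)
  structure(list(mean = rep(0, d), M2 = matrix(0, d, d), n = 0L,
                 d = d, sigma_fixed = sigma_fixed, p_fixed = p_fixed,
                 n0 = as.integer(n0 %||% (2L * d))),
            class = "adapt_state")
}

#' @describeIn adapt_state fold one coefficient draw into the running mean
#'   and covariance; `cov_n(adapt)` recovers \eqn{\Sigma_n} (the batch
#'   empirical covariance of the draws seen, zero matrix while `n < 2`).
#' @param adapt an `adapt_state`.
#' @param beta_draw one coefficient vector.
#' @export
update_adaptation <- function(adapt, beta_draw) {
  n1 <- adapt$n + 1L
  delta <- beta_draw - adapt$mean
  adapt$mean <- adapt$mean + delta / n1
  adapt$M2 <- adapt$M2 + outer(delta, beta_draw - adapt$mean)
  adapt$n <- n1
  adapt
}

#' @rdname adapt_state
#' @export
cov_n <- function(adapt) {
  if (adapt$n < 2L) matrix(0, adapt$d, adapt$d) else adapt$M2 / (adapt$n - 1L)
}

# One Metropolis step against an arbitrary log target with the mixture
# random-walk proposal. Both mixture components are centred at the current
# point, so the proposal is symmetric and the Hastings correction cancels;
# the acceptance probability is min(1, exp(lp' - lp)).
# RNG order (fixed contract shared with the compiled path): one uniform for
# the component choice, d standard normals, one uniform for the accept step.
mh_step <- function(beta, log_post, adapt, lp_current = NULL) {
  d <- adapt$d
  u_comp <- runif(1)
  use_fixed <- (adapt$n <= adapt$n0) || (u_comp < adapt$p_fixed)
  scale2 <- if (use_fixed) 0.1^2 / d else 2.38^2 / d
  S <- if (use_fixed) adapt$sigma_fixed else cov_n(adapt)
  L <- tryCatch(chol(scale2 * S), error = function(e) NULL)
  if (is.null(L)) {
    warning("proposal covariance not positive definite; using fixed component")
    L <- chol(0.1^2 / d * adapt$sigma_fixed)
  }
  z <- rnorm(d)
  prop <- beta + drop(crossprod(L, z))
  lp0 <- lp_current %||% log_post(beta)
  lp1 <- log_post(prop)
  u_acc <- runif(1)
  if (is.finite(lp1) && log(u_acc) < lp1 - lp0) {
    list(beta = prop, accepted = TRUE, lp = lp1)
  } else {
    list(beta = beta, accepted = FALSE, lp = lp0)
  }
}

#' Adaptive Metropolis update of the regression coefficients
#'
#' One step of the mixture random-walk described in [adapt_state()], with
#' the full conditional of \eqn{\beta} (likelihood times its normal prior)
#' as the target. The coefficient vector is proposed and accepted as one
#' block. Reference implementation; [run_chain()] uses a compiled
#' equivalent.
#'
#' @param data a [count_tensor()].
#' @param state a [model_state()].
#' @param priors a [prior_spec()].
#' @param adapt an [adapt_state()].
#' @param seed optional integer seed.
#' @return A list with the updated `beta`, logical `accepted`, and `lp` (log
#'   full-conditional at the returned point, constants dropped).
#' @export
mh_update_beta <- function(data, state, priors, adapt, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rate <- tt_rate(state$cores)
  y <- as.vector(data$counts)
  X <- ct_design(data)
  log_off <- log(as.vector(data$offsets)) + log(as.vector(rate))
  log_post <- function(b) {
    eta <- pmin(pmax(drop(X %*% b), -.ETA_CLAMP), .ETA_CLAMP)
    mu <- exp(eta + log_off)
    sum(y * (eta + log_off) - mu) - 0.5 * sum(b^2) / priors$sigma2
  }
  mh_step(state$beta, log_post, adapt)
}

#' One full Gibbs sweep (reference implementation)
#'
#' Executes, in order: latent-count thinning, the three gamma
#' full-conditional updates (each conditioning on the blocks already
#' refreshed this sweep), the adaptive Metropolis coefficient update, and
#' the adaptation update. This mirrors one iteration of [run_chain()] and
#' exists so the transition kernel can be tested in isolation (conservation,
#' conjugacy, prior-preservation).
#'
#' @inheritParams mh_update_beta
#' @return A list with the new `state`, `adapt`, `accepted` and `marginals`.
#' @export
gibbs_sweep <- function(data, state, priors, adapt, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cp <- inherits(state$cores, "cp_cores")
  marg <- thin_latent_counts(data, state)
  cores <- state$cores
  cores$lambda1 <- update_lambda1(marg, data, state, priors)
  state$cores <- cores
  if (cp) cores$lambda2_diag <- update_lambda2(marg, data, state, priors)
  else cores$lambda2 <- update_lambda2(marg, data, state, priors)
  state$cores <- cores
  cores$lambda3 <- update_lambda3(marg, data, state, priors)
  state$cores <- cores
  mh <- mh_update_beta(data, state, priors, adapt)
  state$beta <- mh$beta
  adapt <- update_adaptation(adapt, mh$beta)
  list(state = state, adapt = adapt, accepted = mh$accepted, marginals = marg)
}
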