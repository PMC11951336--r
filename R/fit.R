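#' MCMC configuration
#'
#' @param n_iter total iterations.
#' @param burn_in iterations discarded from the front (`0 <= burn_in <
#'   n_iter`).
#' @param thin keep every `thin`-th post-burn-in coefficient draw.
#' @param seed integer seed; the whole chain is reproducible from it.
#' @param p_fixed mixture weight of the fixed proposal component (see
#'   [adapt_state()]). The default 0.05 gives the empirical component the
#'   0.95 sampling probability used in the recovery studies.
#' @param n0 adaptation warm-up (draws before the empirical covariance is
#'   trusted); default `2 * d`.
#' @param core_thin_mult core draws are stored every `thin * core_thin_mult`
#'   iterations to bound memory (cores are much larger than `beta`).
#' @return An object of class `mcmc_control`.
#' @export
mcmc_control <- function(n_iter = 10000, burn_in = 3000, thin = 1, seed = 1,
                         p_fixed = 0.05, n0 = NULL, core_thin_mult = 5) {
  stopifnot(burn_in >= 0, burn_in < n_iter, thin >= 1,
            p_fixed > 0, p_fixed < 1, core_thin_mult >= 1)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed),
                 p_fixed = p_fixed, n0 = n0,
                 core_thin_mult = as.integer(core_thin_mult)),
            class = "mcmc_control")
}

init_cores_from_prior <- function(d, ranks, priors, cp) {
  H1 <- ranks[1]; H2 <- ranks[2]
  l1 <- matrix(rgamma(d[1] * H1, priors$alpha_a, priors$alpha_b), d[1], H1)
  if (cp) {
    l2 <- matrix(rgamma(d[2] * H1, priors$gamma_a, priors$gamma_b), d[2], H1)
    l3 <- matrix(rgamma(d[3] * H1, priors$eps_a, priors$eps_b), d[3], H1)
    cp_cores(l1, l2, l3)
  } else {
    l2 <- array(rgamma(d[2] * H1 * H2, priors$gamma_a, priors$gamma_b),
                c(d[2], H1, H2))
    l3 <- matrix(rgamma(d[3] * H2, priors$eps_a, priors$eps_b), d[3], H2)
    tt_cores(l1, l2, l3)
  }
}

cores_from_flat <- function(v1, v2, v3, d, ranks, cp) {
  H1 <- ranks[1]; H2 <- ranks[2]
  if (cp) {
    l2full <- array(v2, c(d[2], H1, H2))
    diag2 <- matrix(0, d[2], H1)
    for (h in seq_len(H1)) diag2[, h] <- l2full[, h, h]
    cp_cores(matrix(v1, d[1], H1), diag2, matrix(v3, d[3], H1))
  } else {
    tt_cores(matrix(v1, d[1], H1), array(v2, c(d[2], H1, H2)),
             matrix(v3, d[3], H2))
  }
}

#' Run the adaptive Metropolis-within-Gibbs chain
#'
#' Per iteration: multinomial latent-count thinning, the three conjugate
#' gamma core updates (strata, time, cause), one block adaptive Metropolis
#' update of the coefficients, and the adaptation update. The coefficient
#' vector is initialized at the Poisson-GLM estimate and the cores at
#' independent prior draws; the fixed proposal covariance is the GLM
#' covariance. The chain is fully reproducible from `control$seed`.
#'
#' In CP mode (`mode = "cp"`, `ranks` a single integer `H`) the middle cores
#' are constrained diagonal: off-diagonal entries are structurally zero and
#' never sampled, which is exactly the CP comparator model.
#'
#' @param data a [count_tensor()].
#' @param priors a [prior_spec()].
#' @param control an [mcmc_control()].
#' @param ranks `c(H1, H2)` in tensor-train mode, a single `H` in CP mode.
#' @param mode `"tt"` or `"cp"`.
#' @param init_state optional [model_state()] to start from. By default the
#'   coefficients start at the GLM estimate and the cores at independent
#'   prior draws. The tensor-train likelihood is invariant to relabeling the
#'   latent classes, so the posterior has one symmetric mode per labeling;
#'   parameter-recovery experiments that compare draws elementwise against a
#'   known truth should warm-start at that truth so the chain samples the
#'   matching mode (see the methods vignette).
#' @return An object of class `bprttd_fit`; see [tidy.bprttd_fit()],
#'   [glance.bprttd_fit()], [summarize_beta()], [fitted_trajectories()].
#' @export
run_chain <- function(data, priors = prior_spec(), control = mcmc_control(),
                      ranks = c(6, 6), mode = c("tt", "cp"),
                      init_state = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(data, "count_tensor"), inherits(priors, "prior_spec"),
            inherits(control, "mcmc_control"))
  cp <- mode == "cp"
  if (cp) {
    if (length(ranks) != 1L) stop("CP mode takes a single rank H")
    ranks <- c(ranks, ranks)
  } else if (length(ranks) != 2L) {
    stop("tensor-train mode takes ranks c(H1, H2)")
  }
  ranks <- as.integer(ranks)
  d <- dim(data); P <- ct_nvar(data)

  glm0 <- glm_poisson_fit(data)
  set.seed(control$seed)
  if (is.null(init_state)) {
    cores0 <- init_cores_from_prior(d, ranks, priors, cp)
    beta0 <- glm0$beta_hat
  } else {
    stopifnot(inherits(init_state, "model_state"))
    cores0 <- init_state$cores
    beta0 <- init_state$beta
    if (inherits(cores0, "cp_cores") != cp)
      stop("init_state core type disagrees with `mode`")
  }
  l2flat <- if (cp) cp_to_tt(cores0, 0)$lambda2 else cores0$lambda2
  n0 <- as.integer(control$n0 %||% (2L * P))

  t0 <- proc.time()[["elapsed"]]
  res <- .cpp_run_chain(
    counts = as.integer(data$counts), offsets = as.numeric(data$offsets),
    X = ct_design(data), N = d[1], T = d[2], K = d[3],
    H1 = ranks[1], H2 = ranks[2], cp = cp,
    l1 = cores0$lambda1, l2 = as.numeric(l2flat), l3 = cores0$lambda3,
    beta = beta0, sigma_fixed = glm0$cov_hat,
    prior = c(priors$alpha_a, priors$alpha_b, priors$gamma_a, priors$gamma_b,
              priors$eps_a, priors$eps_b, priors$sigma2),
    p_fixed = control$p_fixed, n0 = n0,
    n_iter = control$n_iter, burn_in = control$burn_in, thin = control$thin,
    core_mult = control$core_thin_mult)
  elapsed <- proc.time()[["elapsed"]] - t0

  beta_draws <- res$beta_draws
  colnames(beta_draws) <- data$labels$covariates
  core_draws <- lapply(seq_len(nrow(res$l1_draws)), function(s) {
    cores_from_flat(res$l1_draws[s, ], res$l2_draws[s, ], res$l3_draws[s, ],
                    d, ranks, cp)
  })
  structure(list(
    beta_draws = beta_draws,
    log_lik_trace = res$loglik_trace,
    acceptance_rate = res$accept_rate,
    core_draws = core_draws,
    core_beta_row = res$core_beta_row,
    beta_postmean = stats::setNames(res$beta_postmean,
                                    data$labels$covariates),
    core_postmean = cores_from_flat(res$l1_postmean, res$l2_postmean,
                                    res$l3_postmean, d, ranks, cp),
    glm = glm0,
    mode = mode, ranks = if (cp) ranks[1] else ranks,
    priors = priors, control = control,
    dims = d, labels = data$labels,
    elapsed = elapsed
  ), class = "bprttd_fit")
}

#' Fit the tensor-train model
#'
#' `bprttd()` fits the Poisson regression with tensor-train factorized
#' residual rate; `bprcpd()` fits the CP-decomposition comparator (diagonal
#' middle cores). Both are thin wrappers over [run_chain()].
#'
#' @inheritParams run_chain
#' @param rank CP rank `H` for `bprcpd()`.
#' @return A `bprttd_fit` object.
#' @export
bprttd <- function(data, ranks = c(6, 6), priors = prior_spec(),
                   control = mcmc_control(), init_state = NULL) {
  run_chain(data, priors, control, ranks = ranks, mode = "tt",
            init_state = init_state)
}

#' @rdname bprttd
#' @export
bprcpd <- function(data, rank = 6, priors = prior_spec(),
                   control = mcmc_control(), init_state = NULL) {
  run_chain(data, priors, control, ranks = rank, mode = "cp",
            init_state = init_state)
}

#' @export
print.bprttd_fit <- function(x, ...) {
  cat(sprintf("<bprttd_fit> %s mode, ranks %s\n", x$mode,
              paste(x$ranks, collapse = "x")))
  cat(sprintf("  %d x %d x %d tensor, %d covariates\n",
              x$dims[1], x$dims[2], x$dims[3], ncol(x$beta_draws)))
  cat(sprintf("  %d stored draws (%d iterations, %d burn-in), acceptance %.2f\n",
              nrow(x$beta_draws), x$control$n_iter, x$control$burn_in,
              x$acceptance_rate))
  invisible(x)
}

# One compiled transition-kernel sweep, preserving state and adaptation;
# consumed by the prior-preservation test and kernel unit tests.
chain_sweep <- function(data, state, priors, adapt) {
  d <- dim(data)
  cp <- inherits(state$cores, "cp_cores")
  ranks <- ranks_of(state$cores)
  l2flat <- if (cp) cp_to_tt(state$cores, 0)$lambda2 else state$cores$lambda2
  res <- .cpp_sweep(
    counts = as.integer(data$counts), offsets = as.numeric(data$offsets),
    X = ct_design(data), N = d[1], T = d[2], K = d[3],
    H1 = ranks[1], H2 = ranks[2], cp = cp,
    l1 = state$cores$lambda1, l2 = as.numeric(l2flat),
    l3 = state$cores$lambda3, beta = state$beta,
    sigma_fixed = adapt$sigma_fixed,
    prior = c(priors$alpha_a, priors$alpha_b, priors$gamma_a, priors$gamma_b,
              priors$eps_a, priors$eps_b, priors$sigma2),
    p_fixed = adapt$p_fixed, n0 = adapt$n0,
    amean = adapt$mean, aM2 = adapt$M2, an = adapt$n)
  state$cores <- cores_from_flat(res$l1, res$l2, res$l3, d, ranks, cp)
  state$beta <- res$beta
  adapt$mean <- res$adapt_mean
  adapt$M2 <- matrix(res$adapt_M2, adapt$d, adapt$d)
  adapt$n <- res$adapt_n
  list(state = state, adapt = adapt, accepted = res$accepted == 1,
       loglik = res$loglik,
       marginals = list(m1 = matrix(res$m1, d[1], ranks[1]),
                        m2 = array(res$m2, c(d[2], ranks[1], ranks[2])),
                        m3 = matrix(res$m3, d[3], ranks[2])))
}
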