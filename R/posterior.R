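#' Coefficient summaries and effect classification
#'
#' Posterior mean, sd, and equal-tailed 95% credible interval from the
#' empirical 2.5%/97.5% quantiles of the stored draws, plus a sign
#' classification: `positive` iff the lower bound is strictly above 0,
#' `negative` iff the upper bound is strictly below 0, otherwise `none`
#' (an interval touching 0 classifies as `none`).
#'
#' @param fit a `bprttd_fit`.
#' @param level credible level (default 0.95, equal-tailed).
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`, `effect`.
#' @export
summarize_beta <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "bprttd_fit"), level > 0, level < 1)
  if (nrow(fit$beta_draws) < 100)
    warning("fewer than 100 stored draws; interval endpoints are noisy")
  a <- (1 - level) / 2
  draws <- fit$beta_draws
  lo <- apply(draws, 2, quantile, probs = a, names = FALSE)
  hi <- apply(draws, 2, quantile, probs = 1 - a, names = FALSE)
  tibble::tibble(
    term = colnames(draws),
    estimate = unname(colMeans(draws)),
    std.error = unname(apply(draws, 2, sd)),
    conf.low = unname(lo),
    conf.high = unname(hi),
    effect = dplyr::case_when(lo > 0 ~ "positive",
                              hi < 0 ~ "negative",
                              TRUE ~ "none"))
}

#' @describeIn summarize_beta broom-style alias.
#' @param x a `bprttd_fit`.
#' @param ... passed on to [summarize_beta()].
#' @export
tidy.bprttd_fit <- function(x, ...) summarize_beta(x, ...)

#' One-row model summary
#'
#' Plug-in log-likelihood and deviance at the posterior means of the
#' coefficients and cores, together with chain health quantities.
#'
#' @param x a `bprttd_fit`.
#' @param data the [count_tensor()] the model was fitted to.
#' @param ... unused.
#' @return A one-row tibble.
#' @export
glance.bprttd_fit <- function(x, data, ...) {
  state <- model_state(x$beta_postmean, x$core_postmean)
  tibble::tibble(
    logLik = log_likelihood(data, state),
    deviance = deviance_gof(data, state),
    logLik_glm = x$glm$loglik,
    deviance_glm = x$glm$deviance,
    acceptance_rate = x$acceptance_rate,
    n_iter = x$control$n_iter,
    n_draws = nrow(x$beta_draws),
    elapsed = x$elapsed)
}

#' Fitted trajectories with credible bands for one (stratum, cause) pair
#'
#' For each stored core draw (paired with its coefficient draw) the cellwise
#' Poisson mean \eqn{\mu_{itk}} along the time axis is computed; the
#' pointwise mean and equal-tailed band over draws are returned together
#' with the covariate-only GLM fitted line \eqn{\hat\mu = u\,
#' e^{x\cdot\hat\beta_{GLM}}} and the observed counts.
#'
#' @param data the [count_tensor()] the model was fitted to.
#' @param fit a `bprttd_fit`.
#' @param stratum,cause stratum and cause, by index or label.
#' @param level credible level of the band.
#' @return A tibble of class `bprttd_trajectory` with one row per time
#'   point: `time`, `observed`, `estimate`, `conf.low`, `conf.high`,
#'   `glm_estimate`.
#' @export
fitted_trajectories <- function(data, fit, stratum, cause, level = 0.95) {
  stopifnot(inherits(data, "count_tensor"), inherits(fit, "bprttd_fit"))
  i <- if (is.character(stratum)) match(stratum, data$labels$strata) else
    as.integer(stratum)
  k <- if (is.character(cause)) match(cause, data$labels$cause) else
    as.integer(cause)
  d <- dim(data)
  if (is.na(i) || i < 1 || i > d[1]) stop("unknown stratum")
  if (is.na(k) || k < 1 || k > d[3]) stop("unknown cause")
  Tt <- d[2]
  u <- data$offsets[i, , k]
  X <- matrix(data$covariates[i, , k, ], Tt, ct_nvar(data))
  mu_draws <- vapply(seq_along(fit$core_draws), function(s) {
    cores <- fit$core_draws[[s]]
    beta <- fit$beta_draws[fit$core_beta_row[s], ]
    tt <- as_tt(cores)
    H1 <- ncol(tt$lambda1); H2 <- ncol(tt$lambda3)
    lam <- vapply(seq_len(Tt), function(t)
      sum(tt$lambda1[i, ] *
            (matrix(tt$lambda2[t, , ], H1, H2) %*% tt$lambda3[k, ])),
      numeric(1))
    eta <- pmin(pmax(drop(X %*% beta), -.ETA_CLAMP), .ETA_CLAMP)
    u * exp(eta) * lam
  }, numeric(Tt))
  a <- (1 - level) / 2
  eta_glm <- pmin(pmax(drop(X %*% fit$glm$beta_hat), -.ETA_CLAMP), .ETA_CLAMP)
  out <- tibble::tibble(
    time = data$labels$time,
    observed = data$counts[i, , k],
    estimate = rowMeans(mu_draws),
    conf.low = apply(mu_draws, 1, quantile, probs = a, names = FALSE),
    conf.high = apply(mu_draws, 1, quantile, probs = 1 - a, names = FALSE),
    glm_estimate = u * exp(eta_glm))
  class(out) <- c("bprttd_trajectory", class(out))
  attr(out, "stratum") <- data$labels$strata[i]
  attr(out, "cause") <- data$labels$cause[k]
  out
}

#' Compare the fitted model with the covariate-only Poisson regression
#'
#' Log-likelihood and deviance of the covariate-only GLM (residual rate
#' \eqn{\lambda^* \equiv 1}, coefficients at the GLM estimate) and of the
#' fitted model evaluated at the posterior means of coefficients and cores
#' (a plug-in convention).
#'
#' @param data the [count_tensor()] the model was fitted to.
#' @param fit a `bprttd_fit`.
#' @return A two-row tibble with columns `model`, `logLik`, `deviance`.
#' @export
compare_models <- function(data, fit) {
  stopifnot(inherits(data, "count_tensor"), inherits(fit, "bprttd_fit"))
  d <- dim(data); P <- ct_nvar(data)
  unit <- tt_cores(matrix(1, d[1], 1), array(1, c(d[2], 1, 1)),
                   matrix(1, d[3], 1))
  glm_state <- model_state(fit$glm$beta_hat, unit)
  fit_state <- model_state(fit$beta_postmean, fit$core_postmean)
  tibble::tibble(
    model = c("glm", if (fit$mode == "cp") "bprcpd" else "bprttd"),
    logLik = c(log_likelihood(data, glm_state),
               log_likelihood(data, fit_state)),
    deviance = c(deviance_gof(data, glm_state),
                 deviance_gof(data, fit_state)))
}

#' Rearrange posterior-mean strata loadings by demographic grouping
#'
#' Pivots the posterior-mean strata loadings \eqn{\hat\lambda^{(1)}_{i,h_1}}
#' into a `regions x (sex * age * H1)` matrix: each region row concatenates
#' the loadings of its (sex, age) strata over the latent classes. Column
#' order is fixed and documented: sex varies slowest, then age, then the
#' latent class index; sexes and ages appear in their order of first
#' appearance in `grouping`. The result feeds directly into any clustering
#' routine (the published analysis used partitioning around medoids).
#'
#' @param fit a `bprttd_fit`.
#' @param grouping a data frame with columns `stratum`, `region`, `sex`,
#'   `age` covering every stratum exactly once;
#'   strata count must equal regions x sexes x ages.
#' @return A tibble with a `region` column followed by `sex.age.h<h1>`
#'   loading columns.
#' @export
rearrange_strata_loadings <- function(fit, grouping) {
  stopifnot(inherits(fit, "bprttd_fit"))
  need <- c("stratum", "region", "sex", "age")
  if (!all(need %in% names(grouping)))
    stop("grouping needs columns: ", paste(need, collapse = ", "))
  strata <- fit$labels$strata
  if (anyDuplicated(grouping$stratum))
    stop("grouping maps some stratum more than once")
  if (!setequal(grouping$stratum, strata))
    stop("grouping must cover every stratum exactly once")
  regions <- unique(grouping$region)
  sexes <- unique(grouping$sex)
  ages <- unique(grouping$age)
  if (length(strata) != length(regions) * length(sexes) * length(ages))
    stop("strata count must equal regions x sexes x ages")
  l1 <- fit$core_postmean$lambda1
  H1 <- ncol(l1)
  idx <- match(grouping$stratum, strata)
  out <- matrix(NA_real_, length(regions),
                length(sexes) * length(ages) * H1)
  colnames(out) <- as.vector(vapply(sexes, function(s)
    vapply(ages, function(a) paste(s, a, paste0("h", seq_len(H1)), sep = "."),
           character(H1)), character(H1 * length(ages))))
  for (r in seq_len(nrow(grouping))) {
    ri <- match(grouping$region[r], regions)
    si <- match(grouping$sex[r], sexes)
    ai <- match(grouping$age[r], ages)
    off <- ((si - 1L) * length(ages) + (ai - 1L)) * H1
    out[ri, off + seq_len(H1)] <- l1[idx[r], ]
  }
  if (anyNA(out)) stop("grouping does not fill the region x sex x age grid")
  dplyr::bind_cols(tibble::tibble(region = regions),
                   tibble::as_tibble(out))
}

#' Plot methods
#'
#' `autoplot.bprttd_fit()` shows the post-burn-in log-likelihood trace;
#' `autoplot.bprttd_trajectory()` draws the fitted trajectory with its
#' credible ribbon, the GLM line and the observed counts, the layout used
#' to inspect where the factorized residual rate corrects the GLM fit.
#'
#' @param object a `bprttd_fit` or the result of [fitted_trajectories()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot bprttd_fit
#' @export
autoplot.bprttd_fit <- function(object, ...) {
  df <- tibble::tibble(draw = seq_along(object$log_lik_trace),
                       logLik = object$log_lik_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$draw, y = .data$logLik)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "stored draw", y = "log-likelihood",
                  title = "Post-burn-in log-likelihood trace")
}

#' @rdname autoplot.bprttd_fit
#' @method autoplot bprttd_trajectory
#' @export
autoplot.bprttd_trajectory <- function(object, ...) {
  df <- dplyr::mutate(object, t = seq_len(nrow(object)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf.low,
                                      ymax = .data$conf.high),
                         fill = "firebrick", alpha = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$estimate),
                       colour = "firebrick") +
    ggplot2::geom_line(ggplot2::aes(y = .data$glm_estimate),
                       colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), size = 0.8) +
    ggplot2::labs(x = "time", y = "count",
                  title = sprintf("%s / %s: fitted (red), GLM (blue), observed",
                                  attr(object, "stratum"),
                                  attr(object, "cause")))
}
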