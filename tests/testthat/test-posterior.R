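fake_fit <- function(draws, labels = paste0("x", seq_len(ncol(draws)))) {
  colnames(draws) <- labels
  structure(list(beta_draws = draws), class = "bprttd_fit")
}

test_that("effect classification follows the credible-interval rule", {
  # constant draws: degenerate interval, positive
  f <- fake_fit(matrix(1, 200, 1))
  s <- summarize_beta(f)
  expect_identical(s$effect, "positive")
  expect_equal(c(s$conf.low, s$conf.high), c(1, 1))

  # symmetric draws around zero: none
  set.seed(3)
  f2 <- fake_fit(matrix(c(rnorm(500), -rnorm(500)), ncol = 1))
  expect_identical(summarize_beta(f2)$effect, "none")

  # interval with lower bound exactly zero classifies as none
  x <- c(rep(0, 100), 0.5 + runif(100))
  f3 <- fake_fit(matrix(x, ncol = 1))
  s3 <- summarize_beta(f3)
  expect_identical(s3$conf.low, 0)
  expect_identical(s3$effect, "none")

  # strictly negative draws: negative
  f4 <- fake_fit(matrix(-1 - abs(rnorm(200)), ncol = 1))
  expect_identical(summarize_beta(f4)$effect, "negative")
})

test_that("summary quantiles match a sort-based oracle", {
  set.seed(5)
  draws <- matrix(rnorm(1000, 0.2, 1.3), ncol = 1)
  s <- summarize_beta(fake_fit(draws))
  expect_equal(s$conf.low, quantile(draws, 0.025, names = FALSE),
               tolerance = 1e-12)
  expect_equal(s$conf.high, quantile(draws, 0.975, names = FALSE),
               tolerance = 1e-12)
  expect_equal(s$estimate, mean(draws), tolerance = 1e-12)
  expect_equal(s$std.error, sd(draws), tolerance = 1e-12)
  # tidy() is the same table
  expect_identical(tidy(fake_fit(draws)), s)
})

test_that("credible bands are monotone in the level and glance is consistent", {
  d <- tiny_tensor(N = 3, T = 5, K = 2, P = 2, seed = 15, mean_scale = 3)
  f <- bprttd(d, ranks = c(2, 2),
              control = mcmc_control(n_iter = 700, burn_in = 200, seed = 6))
  tr95 <- fitted_trajectories(d, f, stratum = 1, cause = 2, level = 0.95)
  tr90 <- fitted_trajectories(d, f, stratum = 1, cause = 2, level = 0.90)
  expect_true(all(tr90$conf.low >= tr95$conf.low - 1e-12))
  expect_true(all(tr90$conf.high <= tr95$conf.high + 1e-12))
  g <- glance(f, d)
  cm <- compare_models(d, f)
  expect_equal(g$logLik, cm$logLik[2], tolerance = 1e-12)
  expect_equal(g$deviance, cm$deviance[2], tolerance = 1e-12)
  expect_equal(cm$deviance[1],
               deviance_gof(d, model_state(f$glm$beta_hat,
                                           tt_cores(matrix(1, 3, 1),
                                                    array(1, c(5, 1, 1)),
                                                    matrix(1, 2, 1)))),
               tolerance = 1e-12)
})

test_that("a single stored draw collapses the band to the point estimate", {
  d <- tiny_tensor(N = 2, T = 4, K = 2, P = 2, seed = 25, mean_scale = 3)
  f <- bprttd(d, ranks = c(1, 1),
              control = mcmc_control(n_iter = 21, burn_in = 20, seed = 2))
  expect_length(f$core_draws, 1)
  tr <- fitted_trajectories(d, f, stratum = 2, cause = 1)
  expect_equal(tr$conf.low, tr$estimate, tolerance = 1e-12)
  expect_equal(tr$conf.high, tr$estimate, tolerance = 1e-12)
})

test_that("unit cores at the GLM coefficients reproduce the GLM line", {
  d <- tiny_tensor(N = 2, T = 4, K = 2, P = 2, seed = 35, mean_scale = 3)
  f <- bprttd(d, ranks = c(1, 1),
              control = mcmc_control(n_iter = 40, burn_in = 20, seed = 2))
  glm0 <- glm_poisson_fit(d)
  unit <- tt_cores(matrix(1, 2, 1), array(1, c(4, 1, 1)), matrix(1, 2, 1))
  f$core_draws <- list(unit)
  f$core_beta_row <- 1L
  f$beta_draws[1, ] <- glm0$beta_hat
  tr <- fitted_trajectories(d, f, stratum = 1, cause = 1)
  expect_equal(tr$estimate, tr$glm_estimate, tolerance = 1e-10)
})

test_that("strata-loading rearrangement matches a loop oracle and is label-keyed", {
  d <- tiny_tensor(N = 8, T = 3, K = 2, P = 2, seed = 45, mean_scale = 2)
  f <- bprttd(d, ranks = c(2, 2),
              control = mcmc_control(n_iter = 60, burn_in = 20, seed = 3))
  grouping <- tidyr::expand_grid(region = c("r1", "r2"),
                                 sex = c("m", "f"),
                                 age = c("young", "old"))
  grouping$stratum <- f$labels$strata
  out <- rearrange_strata_loadings(f, grouping)
  expect_identical(dim(out), as.integer(c(2, 1 + 2 * 2 * 2)))
  # loop oracle
  l1 <- f$core_postmean$lambda1
  for (r in seq_len(nrow(grouping))) {
    ri <- match(grouping$region[r], unique(grouping$region))
    col <- paste(grouping$sex[r], grouping$age[r], "h1", sep = ".")
    expect_equal(out[[col]][ri], l1[r, 1], tolerance = 1e-12)
    col2 <- paste(grouping$sex[r], grouping$age[r], "h2", sep = ".")
    expect_equal(out[[col2]][ri], l1[r, 2], tolerance = 1e-12)
  }
  # permuting the grouping rows leaves the result invariant (keys, not order)
  out2 <- rearrange_strata_loadings(f, grouping[sample(nrow(grouping)), ])
  expect_equal(out2[order(out2$region), names(out)],
               out[order(out$region), ], tolerance = 1e-12,
               ignore_attr = TRUE)
  # 1 region x 1 sex x 1 age: a single row holding that stratum's loadings
  d1 <- tiny_tensor(N = 1, T = 3, K = 2, P = 2, seed = 46, mean_scale = 2)
  f1 <- bprttd(d1, ranks = c(2, 2),
               control = mcmc_control(n_iter = 60, burn_in = 20, seed = 3))
  g1 <- tibble::tibble(stratum = f1$labels$strata, region = "r",
                       sex = "f", age = "a")
  out1 <- rearrange_strata_loadings(f1, g1)
  expect_equal(unname(unlist(out1[1, -1])),
               unname(f1$core_postmean$lambda1[1, ]), tolerance = 1e-12)
  # broken groupings fail validation
  expect_error(rearrange_strata_loadings(f, grouping[-1, ]), "cover")
})

test_that("autoplot methods return ggplot objects", {
  d <- tiny_tensor(N = 2, T = 4, K = 2, P = 2, seed = 55, mean_scale = 3)
  f <- bprttd(d, ranks = c(1, 1),
              control = mcmc_control(n_iter = 60, burn_in = 20, seed = 2))
  expect_s3_class(ggplot2::autoplot(f), "ggplot")
  tr <- fitted_trajectories(d, f, 1, 1)
  expect_s3_class(ggplot2::autoplot(tr), "ggplot")
})
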