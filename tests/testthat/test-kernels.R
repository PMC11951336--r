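make_state <- function(d, H1, H2, beta = NULL, seed = 1) {
  set.seed(seed)
  model_state(beta %||% rnorm(dim(d$covariates)[4], 0, 0.3),
              random_cores(dim(d)[1], dim(d)[2], dim(d)[3], H1, H2))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("latent-count thinning conserves the total count in every marginal", {
  for (seed in 1:4) {
    d <- tiny_tensor(N = 4, T = 3, K = 3, P = 2, seed = seed, mean_scale = 2)
    st <- make_state(d, 2, 3, seed = seed + 100)
    m <- thin_latent_counts(d, st, seed = seed)
    expect_identical(sum(m$m1), sum(d$counts))
    expect_identical(sum(m$m2), sum(d$counts))
    expect_identical(sum(m$m3), sum(d$counts))
  }
  # all-zero data: all marginals zero
  d0 <- count_tensor(array(0L, c(2, 2, 2)), array(1, c(2, 2, 2)),
                     array(1, c(2, 2, 2, 1)))
  st0 <- make_state(d0, 2, 2, beta = 0)
  m0 <- thin_latent_counts(d0, st0)
  expect_true(all(m0$m1 == 0) && all(m0$m2 == 0) && all(m0$m3 == 0))
})

test_that("degenerate single-component split routes everything to h1 = h2 = 1", {
  d <- tiny_tensor(N = 3, T = 2, K = 2, P = 1, seed = 5, mean_scale = 3)
  st <- make_state(d, 1, 1, seed = 6)
  m <- thin_latent_counts(d, st)
  expect_identical(m$m1[, 1], vapply(1:3, function(i) sum(d$counts[i, , ]),
                                     integer(1)))
})

test_that("one-cell split fractions match the multinomial probabilities", {
  # one cell with a very large count: the empirical split fractions must sit
  # within binomial Monte-Carlo error of the component probabilities
  y <- 100000L
  d <- count_tensor(array(y, c(1, 1, 1)), array(1, c(1, 1, 1)),
                    array(1, c(1, 1, 1, 1)))
  set.seed(8)
  cores <- random_cores(1, 1, 1, 2, 2)
  st <- model_state(0, cores)
  p <- as.vector(cores$lambda1[1, ] * cores$lambda2[1, , ]) *
    rep(cores$lambda3[1, ], each = 2)
  p <- p / sum(p)
  m <- thin_latent_counts(d, st, seed = 9)
  frac1 <- m$m1[1, ] / y  # marginal over h2
  p1 <- rowSums(matrix(p, 2, 2))
  expect_true(all(abs(frac1 - p1) < 4 * sqrt(p1 * (1 - p1) / y)))
})

test_that("gamma full conditionals use shape = prior + marginal and the conjugate rate", {
  d <- tiny_tensor(N = 3, T = 3, K = 2, P = 2, seed = 11, mean_scale = 2)
  st <- make_state(d, 2, 2, seed = 12)
  pri <- prior_spec()
  m <- thin_latent_counts(d, st, seed = 13)

  # conjugate closed form: with all marginals zero the draw is
  # Gamma(alpha_a, alpha_b + S); check the Monte-Carlo mean
  m0 <- m; m0$m1 <- m$m1 * 0L
  S <- bprttd:::fc_rate_lambda1(d, st)
  set.seed(14)
  draws <- replicate(4000, update_lambda1(m0, d, st, pri)[1, 1])
  mu_exact <- pri$alpha_a / (pri$alpha_b + S[1, 1])
  sd_exact <- sqrt(pri$alpha_a) / (pri$alpha_b + S[1, 1])
  expect_lt(abs(mean(draws) - mu_exact), 4 * sd_exact / sqrt(4000))
})

test_that("time slices with identical data get identical full conditionals", {
  # duplicate one time slice: equal data + equal offsets => equal shape/rate
  set.seed(15)
  N <- 3; K <- 2
  counts1 <- matrix(rpois(N * K, 4), N, K)
  off1 <- matrix(rgamma(N * K, 5, 1), N, K)
  counts <- array(0L, c(N, 2, K)); off <- array(0, c(N, 2, K))
  counts[, 1, ] <- counts1; counts[, 2, ] <- counts1
  off[, 1, ] <- off1; off[, 2, ] <- off1
  x <- array(1, c(N, 2, K, 1))
  d <- count_tensor(counts, off, x)
  st <- make_state(d, 2, 2, beta = 0.2, seed = 16)
  r2 <- bprttd:::fc_rate_lambda2(d, st)
  expect_equal(r2[1, , ], r2[2, , ], tolerance = 1e-12)
})

test_that("single-cell full conditionals match the quadrature posterior", {
  # N=T=K=1, H1=H2=1: the exact posterior of each core entry given the rest
  # is computable by numeric integration of gamma prior x Poisson likelihood
  y <- 7L
  u <- 2.3; x <- 0.4; beta <- 0.5
  d <- count_tensor(array(y, c(1, 1, 1)), array(u, c(1, 1, 1)),
                    array(x, c(1, 1, 1, 1)))
  cores <- tt_cores(matrix(0.8, 1, 1), array(1.4, c(1, 1, 1)),
                    matrix(0.6, 1, 1))
  st <- model_state(beta, cores)
  pri <- prior_spec(alpha_a = 1.5, alpha_b = 1.2, gamma_a = 2, gamma_b = 2,
                    eps_a = 1, eps_b = 1)
  w <- u * exp(x * beta)
  marg <- list(m1 = matrix(y, 1, 1), m2 = array(y, c(1, 1, 1)),
               m3 = matrix(y, 1, 1), cp = FALSE)

  post_mean_quad <- function(a, b, coef) {
    # posterior for lambda given the others: prior Ga(a,b), lik Pois(coef*lambda)
    f <- function(l) dgamma(l, a, b) * dpois(y, coef * l)
    z <- stats::integrate(f, 0, Inf)$value
    stats::integrate(function(l) l * f(l), 0, Inf)$value / z
  }

  # lambda1 block
  coef1 <- w * cores$lambda2[1, 1, 1] * cores$lambda3[1, 1]
  q1 <- post_mean_quad(pri$alpha_a, pri$alpha_b, coef1)
  expect_equal((pri$alpha_a + y) / (pri$alpha_b + coef1), q1,
               tolerance = 1e-6)
  set.seed(17)
  mc1 <- replicate(4000, update_lambda1(marg, d, st, pri)[1, 1])
  se1 <- sqrt(pri$alpha_a + y) / (pri$alpha_b + coef1) / sqrt(4000)
  expect_lt(abs(mean(mc1) - q1), 3 * se1)

  # lambda2 block
  coef2 <- w * cores$lambda1[1, 1] * cores$lambda3[1, 1]
  q2 <- post_mean_quad(pri$gamma_a, pri$gamma_b, coef2)
  mc2 <- replicate(4000, update_lambda2(marg, d, st, pri)[1, 1, 1])
  se2 <- sqrt(pri$gamma_a + y) / (pri$gamma_b + coef2) / sqrt(4000)
  expect_lt(abs(mean(mc2) - q2), 3 * se2)

  # lambda3 block
  coef3 <- w * cores$lambda1[1, 1] * cores$lambda2[1, 1, 1]
  q3 <- post_mean_quad(pri$eps_a, pri$eps_b, coef3)
  mc3 <- replicate(4000, update_lambda3(marg, d, st, pri)[1, 1])
  se3 <- sqrt(pri$eps_a + y) / (pri$eps_b + coef3) / sqrt(4000)
  expect_lt(abs(mean(mc3) - q3), 3 * se3)
})

test_that("CP-mode updates touch only the diagonal middle-core entries", {
  d <- tiny_tensor(N = 3, T = 3, K = 3, P = 2, seed = 21, mean_scale = 2)
  set.seed(22)
  st <- model_state(c(0.1, 0.1), random_cp_cores(3, 3, 3, H = 2))
  m <- thin_latent_counts(d, st, seed = 23)
  expect_identical(dim(m$m2), c(3L, 2L))  # diagonal storage only
  l2 <- update_lambda2(m, d, st, prior_spec(), seed = 24)
  expect_identical(dim(l2), c(3L, 2L))
  expect_true(all(l2 > 0))
  # embedding into full tensor-train form keeps off-diagonals at zero
  st$cores$lambda2_diag <- l2
  full <- cp_to_tt(st$cores, eps = 0)
  for (h1 in 1:2) for (h2 in 1:2) if (h1 != h2)
    expect_true(all(full$lambda2[, h1, h2] == 0))
})

test_that("running mean and covariance match batch recomputation", {
  set.seed(31)
  draws <- matrix(rnorm(40 * 3), 40, 3)
  ad <- adapt_state(diag(3))
  for (r in seq_len(nrow(draws))) ad <- update_adaptation(ad, draws[r, ])
  expect_equal(ad$mean, colMeans(draws), tolerance = 1e-12)
  expect_equal(cov_n(ad), cov(draws), tolerance = 1e-12,
               ignore_attr = TRUE)
  # two identical draws: zero covariance
  ad2 <- adapt_state(diag(2))
  ad2 <- update_adaptation(ad2, c(1, 2))
  ad2 <- update_adaptation(ad2, c(1, 2))
  expect_equal(cov_n(ad2), matrix(0, 2, 2))
})

test_that("the Metropolis kernel samples a known Gaussian target", {
  # target: independent standard normals in 2 dimensions (likelihood stubbed)
  set.seed(41)
  ad <- adapt_state(diag(2) * 50, p_fixed = 0.05, n0 = 10)
  log_post <- function(b) -0.5 * sum(b^2)
  b <- c(0, 0)
  lp <- log_post(b)
  n <- 50000
  keep <- matrix(0, n, 2)
  for (it in seq_len(n)) {
    stp <- bprttd:::mh_step(b, log_post, ad, lp_current = lp)
    b <- stp$beta; lp <- stp$lp
    ad <- update_adaptation(ad, b)
    keep[it, ] <- b
  }
  keep <- keep[-(1:5000), ]
  expect_lt(max(abs(colMeans(keep))), 0.05)
  expect_lt(max(abs(apply(keep, 2, var) - 1)), 0.1)
})

test_that("proposal mixture degenerates correctly", {
  # p_fixed ~ 1: every proposal comes from the fixed component, whose scale
  # we can detect through the step-size distribution
  set.seed(51)
  ad <- adapt_state(diag(2) * 1e-8, p_fixed = 1 - 1e-12, n0 = 0)
  # feed adaptation draws with huge spread: if the empirical component were
  # ever used, steps would be enormous
  for (r in 1:50) ad <- update_adaptation(ad, rnorm(2, sd = 100))
  b <- c(0, 0)
  log_post <- function(bb) 0  # flat target: all proposals accepted
  steps <- replicate(200, {
    stp <- bprttd:::mh_step(b, log_post, ad)
    sqrt(sum((stp$beta - b)^2))
  })
  expect_lt(max(steps), 1e-2)
  expect_true(all(steps > 0))
})

test_that("compiled full-conditional rates agree with the reference kernels", {
  for (seed in 1:3) {
    d <- tiny_tensor(N = 4, T = 3, K = 5, P = 3, seed = seed, mean_scale = 1)
    st <- make_state(d, 2, 3, seed = seed + 30)
    cpp <- bprttd:::.cpp_fc_rates(
      offsets = as.numeric(d$offsets), X = bprttd:::ct_design(d),
      N = 4, T = 3, K = 5, H1 = 2, H2 = 3,
      l1 = st$cores$lambda1, l2 = as.numeric(st$cores$lambda2),
      l3 = st$cores$lambda3, beta = st$beta)
    expect_equal(cpp$rate1, bprttd:::fc_rate_lambda1(d, st),
                 tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(as.vector(cpp$rate2),
                 as.vector(bprttd:::fc_rate_lambda2(d, st)),
                 tolerance = 1e-10)
    expect_equal(cpp$rate3, bprttd:::fc_rate_lambda3(d, st),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("compiled sweep conserves latent counts across both split branches", {
  # counts straddling the small-count/large-count split algorithms
  set.seed(61)
  N <- 3; Tt <- 3; K <- 2
  counts <- array(rpois(N * Tt * K, 30), c(N, Tt, K))  # straddles 32
  counts[1, 1, 1] <- 500L
  off <- array(rgamma(N * Tt * K, 5, 1), c(N, Tt, K))
  x <- array(0, c(N, Tt, K, 2)); x[, , , 1] <- 1
  x[, , , 2] <- rnorm(N * Tt * K)
  d <- count_tensor(counts, off, x)
  st <- make_state(d, 2, 2, seed = 62)
  ad <- adapt_state(glm_poisson_fit(d)$cov_hat)
  set.seed(63)
  sw <- bprttd:::chain_sweep(d, st, prior_spec(), ad)
  expect_identical(sum(sw$marginals$m1), sum(d$counts))
  expect_identical(sum(sw$marginals$m2), sum(d$counts))
  expect_identical(sum(sw$marginals$m3), sum(d$counts))
  expect_true(all(sw$state$cores$lambda1 > 0))
})

test_that("one reference sweep and one compiled sweep leave the same invariants", {
  # both sweeps draw valid positive cores, update adaptation identically in
  # count, and report finite log-densities
  d <- tiny_tensor(N = 3, T = 3, K = 2, P = 2, seed = 71, mean_scale = 2)
  pri <- prior_spec()
  st <- make_state(d, 2, 2, seed = 72)
  ad <- adapt_state(glm_poisson_fit(d)$cov_hat)
  set.seed(73)
  r <- gibbs_sweep(d, st, pri, ad)
  set.seed(73)
  cxx <- bprttd:::chain_sweep(d, st, pri, ad)
  expect_identical(r$adapt$n, 1L)
  expect_identical(as.integer(cxx$adapt$n), 1L)
  expect_true(all(r$state$cores$lambda2 > 0))
  expect_true(all(cxx$state$cores$lambda2 > 0))
  expect_identical(sum(r$marginals$m1), sum(d$counts))
  expect_identical(sum(cxx$marginals$m1), sum(d$counts))
})
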