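# fixtures are built in code; nothing is read from disk

random_cores <- function(N, T, K, H1, H2, shape = 1, rate = 2) {
  tt_cores(
    matrix(rgamma(N * H1, shape, rate), N, H1),
    array(rgamma(T * H1 * H2, shape, rate), c(T, H1, H2)),
    matrix(rgamma(K * H2, shape, rate), K, H2))
}

random_cp_cores <- function(N, T, K, H, shape = 1, rate = 2) {
  cp_cores(
    matrix(rgamma(N * H, shape, rate), N, H),
    matrix(rgamma(T * H, shape, rate), T, H),
    matrix(rgamma(K * H, shape, rate), K, H))
}

# a small random dataset with intercept + (P-1) standard-normal covariates
tiny_tensor <- function(N = 3, T = 4, K = 2, P = 2, seed = 1,
                        offset_shape = 5, mean_scale = 1) {
  set.seed(seed)
  covariates <- array(0, c(N, T, K, P))
  covariates[, , , 1] <- 1
  if (P > 1) covariates[, , , -1] <- rnorm(N * T * K * (P - 1))
  offsets <- array(rgamma(N * T * K, offset_shape, 1), c(N, T, K))
  counts <- array(rpois(N * T * K, mean_scale * offsets), c(N, T, K))
  count_tensor(counts, offsets, covariates)
}

# brute-force reconstruction of the factorized rate, scalar loops only
tt_rate_bruteforce <- function(cores) {
  l1 <- cores$lambda1; l2 <- cores$lambda2; l3 <- cores$lambda3
  N <- nrow(l1); Tt <- dim(l2)[1]; K <- nrow(l3)
  H1 <- ncol(l1); H2 <- ncol(l3)
  out <- array(0, c(N, Tt, K))
  for (i in seq_len(N)) for (t in seq_len(Tt)) for (k in seq_len(K)) {
    s <- 0
    for (h1 in seq_len(H1)) for (h2 in seq_len(H2))
      s <- s + l1[i, h1] * l2[t, h1, h2] * l3[k, h2]
    out[i, t, k] <- s
  }
  out
}

# effective sample size via initial-positive-sequence autocorrelations
ess <- function(x, max_lag = 100) {
  n <- length(x)
  v <- stats::var(x)
  if (v == 0) return(n)
  rho <- stats::acf(x, lag.max = min(max_lag, n - 1), plot = FALSE)$acf[-1]
  s <- 0
  for (r in rho) {
    if (r <= 0) break
    s <- s + r
  }
  n / (1 + 2 * s)
}

geweke_z <- function(x, mu_true) {
  (mean(x) - mu_true) / (stats::sd(x) / sqrt(ess(x)))
}
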