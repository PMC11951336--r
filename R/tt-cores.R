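#' Tensor-train cores for the residual rate
#'
#' The residual Poisson rate \eqn{\lambda^*_{itk}} is factorized as
#' \deqn{\lambda^*_{itk} = \sum_{h_1=1}^{H_1} \lambda^{(1)}_{i,h_1}
#'   \sum_{h_2=1}^{H_2} \lambda^{(2)}_{t,h_1,h_2} \lambda^{(3)}_{k,h_2}
#'   = \lambda^{(1)\prime}_i \Lambda^{(2)}_t \lambda^{(3)}_k,}
#' a three-way tensor-train factorization with ranks \eqn{(H_1, H_2)}. All
#' core entries are strictly positive (they carry gamma priors). Mode order
#' is fixed as (strata, time, cause): the middle core chains the strata
#' classes \eqn{h_1} to the cause classes \eqn{h_2} through time, and the API
#' does not permit permuting modes.
#'
#' @param lambda1 positive matrix `N x H1` of strata loadings.
#' @param lambda2 positive array `T x H1 x H2` of time cores.
#' @param lambda3 positive matrix `K x H2` of cause loadings.
#' @return An object of class `tt_cores`.
#' @export
tt_cores <- function(lambda1, lambda2, lambda3) {
  lambda1 <- as.matrix(lambda1); lambda3 <- as.matrix(lambda3)
  lambda2 <- as.array(lambda2)
  if (length(dim(lambda2)) != 3L) stop("`lambda2` must be a 3-way array")
  H1 <- ncol(lambda1); H2 <- ncol(lambda3)
  if (!identical(dim(lambda2)[2:3], c(H1, H2)))
    stop("core shapes inconsistent: lambda2 must be T x H1 x H2")
  if (any(lambda1 <= 0) || any(lambda2 < 0) || any(lambda3 <= 0))
    stop("core entries must be strictly positive")
  structure(list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
                 ranks = c(H1 = H1, H2 = H2)),
            class = "tt_cores")
}

#' @describeIn tt_cores the CP (canonical polyadic) special case: diagonal
#'   middle cores, a single rank `H`. Used by the [bprcpd()] comparator.
#' @param lambda2_diag positive matrix `T x H`: the diagonal of each
#'   \eqn{\Lambda^{(2)}_t}.
#' @export
cp_cores <- function(lambda1, lambda2_diag, lambda3) {
  lambda1 <- as.matrix(lambda1); lambda3 <- as.matrix(lambda3)
  lambda2_diag <- as.matrix(lambda2_diag)
  H <- ncol(lambda1)
  if (ncol(lambda2_diag) != H || ncol(lambda3) != H)
    stop("all CP factors must share the rank H")
  if (any(lambda1 <= 0) || any(lambda2_diag <= 0) || any(lambda3 <= 0))
    stop("core entries must be strictly positive")
  structure(list(lambda1 = lambda1, lambda2_diag = lambda2_diag,
                 lambda3 = lambda3, rank = H),
            class = "cp_cores")
}

#' Reconstruct the residual rate tensor from its cores
#'
#' @param cores a [tt_cores()] or [cp_cores()] object.
#' @return A positive array `N x T x K` with entries
#'   \eqn{\lambda^{(1)\prime}_i \Lambda^{(2)}_t \lambda^{(3)}_k}.
#' @export
tt_rate <- function(cores) UseMethod("tt_rate")

#' @export
tt_rate.tt_cores <- function(cores) {
  l1 <- cores$lambda1; l2 <- cores$lambda2; l3 <- cores$lambda3
  N <- nrow(l1); Tt <- dim(l2)[1]; K <- nrow(l3)
  H1 <- ncol(l1); H2 <- ncol(l3)
  # A[t, h1, k] = sum_h2 lambda2[t,h1,h2] * lambda3[k,h2]
  A <- matrix(l2, Tt * H1, H2) %*% t(l3)        # (t,h1) x k
  dim(A) <- c(Tt, H1, K)
  A <- aperm(A, c(2, 1, 3))                     # h1 x t x k
  out <- l1 %*% matrix(A, H1, Tt * K)           # i x (t,k)
  array(out, c(N, Tt, K))
}

#' @export
tt_rate.cp_cores <- function(cores) {
  l1 <- cores$lambda1; l2 <- cores$lambda2_diag; l3 <- cores$lambda3
  N <- nrow(l1); Tt <- nrow(l2); K <- nrow(l3); H <- cores$rank
  out <- array(0, c(N, Tt, K))
  for (h in seq_len(H)) {
    out <- out + outer(outer(l1[, h], l2[, h]), l3[, h])
  }
  out
}

#' Embed CP cores into tensor-train form
#'
#' A CP factorization is the tensor-train special case with diagonal middle
#' cores. Because the sampler's core entries must be strictly positive, the
#' structurally-zero off-diagonal entries are set to a machine floor
#' `eps >= 0` on export; `eps = 0` (the default) gives exact equality
#' between [tt_rate()] of the result and the CP sum.
#'
#' @param cp a [cp_cores()] object.
#' @param eps non-negative floor for off-diagonal middle-core entries.
#' @return A [tt_cores()] object with `H1 = H2 = H`.
#' @export
cp_to_tt <- function(cp, eps = 0) {
  stopifnot(inherits(cp, "cp_cores"), eps >= 0)
  Tt <- nrow(cp$lambda2_diag); H <- cp$rank
  l2 <- array(eps, c(Tt, H, H))
  for (h in seq_len(H)) l2[, h, h] <- cp$lambda2_diag[, h]
  structure(list(lambda1 = cp$lambda1, lambda2 = l2, lambda3 = cp$lambda3,
                 ranks = c(H1 = H, H2 = H)),
            class = "tt_cores")
}

#' Number of free parameters in the tensor-train subspace
#'
#' The saturated rate tensor has `N*T*K` free parameters; the tensor-train
#' factorization reduces this to `N*H1 + T*H1*H2 + K*H2`.
#'
#' @param N,T,K tensor dimensions (strata, time points, causes).
#' @param H1,H2 tensor-train ranks.
#' @return The integer `N*H1 + T*H1*H2 + K*H2`.
#' @export
count_subspace_params <- function(N, T, K, H1, H2) {
  args <- c(N = N, T = T, K = K, H1 = H1, H2 = H2)
  if (any(args < 1) || any(args != round(args)))
    stop("all arguments must be positive integers")
  as.integer(N * H1 + T * H1 * H2 + K * H2)
}

ranks_of <- function(cores) {
  if (inherits(cores, "cp_cores")) c(cores$rank, cores$rank) else
    unname(cores$ranks)
}
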