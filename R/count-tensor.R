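#' Three-way count tensors with offsets and covariates
#'
#' A `count_tensor` holds observed counts \eqn{Y_{itk}} on a strata
#' \eqn{\times} time \eqn{\times} cause grid, together with strictly positive
#' exposures (offsets) \eqn{u_{itk}} and a covariate vector \eqn{x_{itk}} per
#' cell. It is the observed-data container for [bprttd()] and [bprcpd()].
#'
#' Internally the fields are dense arrays; the first covariate column is
#' conventionally an all-ones intercept, but any full-rank design is accepted.
#' An index of non-zero cells is built at construction time (the latent-count
#' thinning step of the sampler only visits non-zero cells) and is always
#' consistent with `counts`.
#'
#' @param counts non-negative integer array, `N x T x K`.
#' @param offsets strictly positive array, `N x T x K`.
#' @param covariates numeric array `N x T x K x P`.
#' @param labels optional list with character vectors `strata`, `time`,
#'   `cause`, `covariates` naming the axes.
#' @return An object of class `count_tensor`.
#' @seealso [read_long_table()], [write_long_table()], [as_count_tensor()]
#' @export
count_tensor <- function(counts, offsets, covariates, labels = NULL) {
  counts <- as.array(counts); offsets <- as.array(offsets)
  covariates <- as.array(covariates)
  if (length(dim(counts)) != 3L) stop("`counts` must be a 3-way array")
  d <- dim(counts)
  if (!identical(dim(offsets), d))
    stop("`offsets` dimensions disagree with `counts`")
  if (length(dim(covariates)) != 4L || !identical(dim(covariates)[1:3], d))
    stop("`covariates` must be N x T x K x P matching `counts`")
  if (anyNA(counts) || anyNA(offsets) || anyNA(covariates))
    stop("missing values are not supported")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (any(offsets <= 0)) stop("all offsets must be strictly positive")
  P <- dim(covariates)[4L]
  labels <- complete_labels(labels, d, P)
  x <- list(
    counts = array(as.integer(round(counts)), d),
    offsets = offsets,
    covariates = covariates,
    labels = labels,
    nonzero = which(counts > 0L)
  )
  structure(x, class = "count_tensor")
}

complete_labels <- function(labels, d, P) {
  labels <- labels %||% list()
  list(
    strata = labels$strata %||% paste0("s", seq_len(d[1])),
    time = labels$time %||% paste0("t", seq_len(d[2])),
    cause = labels$cause %||% paste0("c", seq_len(d[3])),
    covariates = labels$covariates %||% paste0("x", seq_len(P))
  )
}

#' @export
dim.count_tensor <- function(x) dim(x$counts)

ct_nvar <- function(x) dim(x$covariates)[4L]

# flattened design matrix, rows in cell order (stratum fastest, then time,
# then cause) -- the canonical cell order used throughout the package
ct_design <- function(x) {
  d <- dim(x)
  matrix(x$covariates, nrow = prod(d), ncol = ct_nvar(x))
}

#' @export
print.count_tensor <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<count_tensor> %d strata x %d times x %d causes, %d covariates\n",
    d[1], d[2], d[3], ct_nvar(x)))
  cat(sprintf("  total count %d; %d/%d non-zero cells\n",
              sum(x$counts), length(x$nonzero), prod(d)))
  invisible(x)
}

#' Coerce a long-format data frame to a count tensor
#'
#' Expects one row per cell with columns `stratum`, `time`, `cause`, `count`,
#' `offset` and covariate columns `x1 ... xP`. Every (stratum, time, cause)
#' combination must appear exactly once; axis ordering follows first
#' appearance in the file.
#'
#' @param df a data frame in the long format described above.
#' @return A [count_tensor()].
#' @export
as_count_tensor <- function(df) {
  need <- c("stratum", "time", "cause", "count", "offset")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "))
  xcols <- grep("^x[0-9]+$", names(df), value = TRUE)
  if (!length(xcols)) stop("no covariate columns x1..xP found")
  xcols <- xcols[order(as.integer(sub("^x", "", xcols)))]

  ls <- unique(as.character(df$stratum))
  lt <- unique(as.character(df$time))
  lk <- unique(as.character(df$cause))
  N <- length(ls); T <- length(lt); K <- length(lk)

  i <- match(as.character(df$stratum), ls)
  t <- match(as.character(df$time), lt)
  k <- match(as.character(df$cause), lk)
  cell <- i + N * (t - 1L) + N * T * (k - 1L)

  dup <- which(duplicated(cell))
  if (length(dup))
    stop(sprintf("duplicate cell at row %d (stratum=%s, time=%s, cause=%s)",
                 dup[1], df$stratum[dup[1]], df$time[dup[1]], df$cause[dup[1]]))
  if (nrow(df) != N * T * K) {
    have <- logical(N * T * K); have[cell] <- TRUE
    m <- which(!have)[1]
    mi <- (m - 1L) %% N + 1L
    mt <- ((m - 1L) %/% N) %% T + 1L
    mk <- (m - 1L) %/% (N * T) + 1L
    stop(sprintf("missing cell: stratum=%s, time=%s, cause=%s",
                 ls[mi], lt[mt], lk[mk]))
  }
  bad <- which(df$count < 0 | df$count != round(df$count))
  if (length(bad))
    stop(sprintf("non-integer or negative count at row %d", bad[1]))
  bad <- which(df$offset <= 0)
  if (length(bad))
    stop(sprintf("non-positive offset at row %d", bad[1]))

  counts <- offsets <- array(0, c(N, T, K))
  counts[cell] <- df$count
  offsets[cell] <- df$offset
  P <- length(xcols)
  covariates <- array(0, c(N, T, K, P))
  for (p in seq_len(P)) {
    sl <- array(0, c(N, T, K)); sl[cell] <- df[[xcols[p]]]
    covariates[, , , p] <- sl
  }
  count_tensor(counts, offsets, covariates,
               labels = list(strata = ls, time = lt, cause = lk,
                             covariates = xcols))
}

#' @describeIn as_count_tensor the inverse coercion: one row per cell, in the
#'   canonical cell order.
#' @param x a `count_tensor`.
#' @param ... unused.
#' @export
as_tibble.count_tensor <- function(x, ...) {
  d <- dim(x); lab <- x$labels
  grid <- expand.grid(i = seq_len(d[1]), t = seq_len(d[2]), k = seq_len(d[3]),
                      KEEP.OUT.ATTRS = FALSE)
  out <- tibble::tibble(
    stratum = lab$strata[grid$i],
    time = lab$time[grid$t],
    cause = lab$cause[grid$k],
    count = as.integer(x$counts),
    offset = as.vector(x$offsets)
  )
  X <- ct_design(x)
  for (p in seq_len(ncol(X))) out[[paste0("x", p)]] <- X[, p]
  out
}

#' Read / write a count tensor as a long-format delimited file
#'
#' The on-disk format is a CSV with header columns `stratum`, `time`,
#' `cause`, `count`, `offset`, `x1 ... xP` and one row per cell. Labels
#' containing delimiter characters are quoted by the writer and survive a
#' round trip; numeric fields are written at full precision.
#'
#' @param path file path.
#' @return `read_long_table()` returns a validated [count_tensor()];
#'   `write_long_table()` returns `path` invisibly.
#' @export
read_long_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          stratum = readr::col_character(),
                          time = readr::col_character(),
                          cause = readr::col_character(),
                          .default = readr::col_double()))
  as_count_tensor(df)
}

#' @rdname read_long_table
#' @param data a [count_tensor()].
#' @export
write_long_table <- function(data, path) {
  stopifnot(inherits(data, "count_tensor"))
  readr::write_csv(as_tibble.count_tensor(data), path, progress = FALSE)
  invisible(path)
}
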