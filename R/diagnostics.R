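# FFT-based autocovariance (biased, divisor n), demeaned
autocov_fft <- function(x) {
  n <- length(x)
  xc <- x - mean(x)
  m <- stats::nextn(2L * n)
  f <- stats::fft(c(xc, rep(0, m - n)))
  Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / (m * n)
}

# split each chain in half along iterations: [iter, chain] -> [iter/2, 2*chain]
split_chains <- function(x) {
  n <- nrow(x)
  h <- n %/% 2L
  cbind(x[seq_len(h), , drop = FALSE],
        x[(n - h + 1L):n, , drop = FALSE])
}

# rank-normalization across all chains jointly (blended ranks)
zscale <- function(x) {
  r <- rank(x, ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (length(x) + 1 / 4))
  array(z, dim = dim(x))
}

rhat_basic <- function(x) {
  n <- nrow(x)
  m <- ncol(x)
  cm <- colMeans(x)
  cv <- apply(x, 2L, var)
  W <- mean(cv)
  B <- n * var(cm)
  if (!is.finite(W) || W <= 0) return(NaN)
  sqrt(((n - 1) / n * W + B / n) / W)
}

ess_basic <- function(x) {
  n <- nrow(x)
  m <- ncol(x)
  if (n < 4L) return(NaN)
  acov <- apply(x, 2L, autocov_fft)
  chain_var <- acov[1L, ] * n / (n - 1)
  W <- mean(chain_var)
  vhat <- (n - 1) / n * W + var(colMeans(x))
  if (!is.finite(vhat) || vhat <= 0) return(NaN)
  rho <- 1 - (W - rowMeans(acov)) / vhat
  rho[1L] <- 1
  # Geyer initial monotone positive sequence on paired sums
  # P_k = rho_{2k} + rho_{2k+1}, k = 0, 1, ...; truncate at the first
  # negative pair, then enforce monotone non-increase; tau = -1 + 2 sum P_k
  pairs <- numeric(0)
  t <- 0L
  while (t + 2L <= n) {
    p <- rho[t + 1L] + rho[t + 2L]
    if (p < 0) break
    pairs <- c(pairs, p)
    t <- t + 2L
  }
  if (length(pairs) == 0L) pairs <- rho[1L]
  pairs <- cummin(pairs)
  tau <- max(-1 + 2 * sum(pairs), 1 / log10(n * m + 10))
  min(n * m / tau, n * m)
}

ess_tail_basic <- function(x) {
  q <- quantile(x, c(0.05, 0.95), names = FALSE)
  min(ess_basic(array(as.numeric(x <= q[1L]), dim = dim(x))),
      ess_basic(array(as.numeric(x <= q[2L]), dim = dim(x))))
}

#' Split-Rhat of one parameter
#'
#' Rank-normalized split-Rhat: chains are split in half, draws are
#' rank-normalized jointly, and the classical potential-scale-reduction
#' statistic is computed on the result.  Values near 1 indicate convergence
#' (1.01 is the conventional threshold); constant chains give `NaN`.
#'
#' @param x Draws matrix `[iteration, chain]` (or a vector of one chain,
#'   which errors: at least 2 chains are required).
#' @return Scalar Rhat.
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("Rhat requires at least 2 chains")
  if (diff(range(x)) == 0) return(NaN)
  rhat_basic(split_chains(zscale(x)))
}

#' Bulk and tail effective sample size of one parameter
#'
#' Bulk ESS is computed on rank-normalized split chains via the
#' autocovariance (Geyer initial monotone sequence); tail ESS is the
#' minimum ESS of the 5% and 95% exceedance indicators.
#'
#' @inheritParams split_rhat
#' @return Named vector `c(ess_bulk, ess_tail)`.
#' @export
ess_draws <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("ESS requires at least 2 chains")
  if (diff(range(x)) == 0) return(c(ess_bulk = NaN, ess_tail = NaN))
  c(ess_bulk = ess_basic(split_chains(zscale(x))),
    ess_tail = ess_tail_basic(split_chains(x)))
}

#' Convergence diagnostics for all stored parameters
#'
#' Computes split-Rhat and bulk/tail effective sample sizes for every
#' parameter of a fit (or any draws array `[iteration, chain, parameter]`)
#' and flags parameters with Rhat > 1.01 (`"nonconverged"`) or
#' zero-variance chains (`"degenerate"`).
#'
#' @param draws An `lba_fit` object or a 3-d draws array.
#' @param rhat_threshold Flagging threshold (default 1.01).
#' @return data.frame with columns `parameter`, `rhat`, `ess_bulk`,
#'   `ess_tail`, `flag`.
#' @export
convergence_diagnostics <- function(draws, rhat_threshold = 1.01) {
  a <- if (inherits(draws, "lba_fit")) draws$draws else draws
  stopifnot(length(dim(a)) == 3L)
  if (dim(a)[2] < 2L) stop("Rhat requires at least 2 chains")
  pn <- dimnames(a)[[3]]
  if (is.null(pn)) pn <- paste0("param", seq_len(dim(a)[3]))
  res <- lapply(seq_len(dim(a)[3]), function(j) {
    x <- a[, , j, drop = TRUE]
    r <- split_rhat(x)
    e <- ess_draws(x)
    data.frame(parameter = pn[j], rhat = r, ess_bulk = e[[1]],
               ess_tail = e[[2]])
  })
  out <- do.call(rbind, res)
  out$flag <- ifelse(is.nan(out$rhat), "degenerate",
                     ifelse(out$rhat > rhat_threshold, "nonconverged", "ok"))
  rownames(out) <- NULL
  out
}
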