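#' Map unconstrained parameter vectors to the constrained (model) scale
#'
#' Drift rates and boosts are unconstrained (identity transform).  The
#' remaining parameters are constrained by construction: `A = exp(u_A) > 0`,
#' `b = A + exp(u_b) > A`, and `t0 = 0.150 + exp(u_t0)` seconds, so the
#' non-decision time always respects the 150 ms lower bound.  All transforms
#' are smooth, bijective and order-preserving.
#'
#' @param u Numeric matrix (rows = parameter vectors) or a single numeric
#'   vector of length 17, on the unconstrained scale.
#' @return Object of the same shape on the constrained scale.
#' @seealso [unconstrain_params()] for the inverse map.
#' @export
constrain_params <- function(u) {
  vec <- is.null(dim(u))
  if (vec) u <- matrix(u, nrow = 1L)
  stopifnot(ncol(u) == 17L)
  p <- u
  p[, 15L] <- exp(u[, 15L])
  p[, 16L] <- p[, 15L] + exp(u[, 16L])
  p[, 17L] <- 0.150 + exp(u[, 17L])
  colnames(p) <- lba_param_names()
  if (vec) p[1L, ] else p
}

#' Inverse of [constrain_params()]
#'
#' @param p Constrained parameter matrix or vector (length 17); requires
#'   `A > 0`, `b > A`, `t0 > 0.150`.
#' @return Unconstrained parameters of the same shape.
#' @export
unconstrain_params <- function(p) {
  vec <- is.null(dim(p))
  if (vec) p <- matrix(p, nrow = 1L)
  stopifnot(ncol(p) == 17L)
  if (any(p[, 15L] <= 0) || any(p[, 16L] <= p[, 15L]) || any(p[, 17L] <= 0.150))
    stop("parameters violate constraints (need A > 0, b > A, t0 > 0.150 s)")
  u <- p
  u[, 15L] <- log(p[, 15L])
  u[, 16L] <- log(p[, 16L] - p[, 15L])
  u[, 17L] <- log(p[, 17L] - 0.150)
  colnames(u) <- lba_param_names()
  if (vec) u[1L, ] else u
}

validate_constrained <- function(p) {
  p <- if (is.null(dim(p))) matrix(p, nrow = 1L) else p
  ok <- p[, 15L] > 0 & p[, 16L] > p[, 15L] & p[, 17L] >= 0.150
  if (!all(ok)) stop("invalid constrained parameters: need A > 0, b > A, t0 >= 0.150 s")
  invisible(TRUE)
}
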