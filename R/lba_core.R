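#' First-passage CDF of a single LBA accumulator
#'
#' Probability that an accumulator with start point uniform on `(0, A)`,
#' drift rate drawn from `N(v, s)` per trial, and threshold `b > A` reaches
#' threshold by decision time `t`.  As `t` grows the CDF approaches
#' `pnorm(v / s)`, the probability of a positive drift draw (the density is
#' "defective": a negative-drift accumulator never finishes).
#'
#' @param t Decision times in seconds (non-negative).
#' @param A Start-point upper bound (> 0).
#' @param b Response threshold (> A).
#' @param v Mean drift rate (any real).
#' @param s Between-trial drift SD (the model's scaling constraint fixes
#'   this to 1 for all free accumulators).
#' @return Vector of probabilities, monotone non-decreasing in `t`.
#' @export
lba_cdf <- function(t, A, b, v, s = 1) {
  stopifnot(A > 0, b > A, s > 0)
  if (any(t < 0)) stop("t must be non-negative")
  .lba_cdf_cpp(as.numeric(t), A, b, v, s)
}

#' First-passage density of a single LBA accumulator
#'
#' Derivative of [lba_cdf()]; returns 0 for `t <= 0`.
#'
#' @inheritParams lba_cdf
#' @return Density values (1/seconds), non-negative.
#' @export
lba_pdf <- function(t, A, b, v, s = 1) {
  stopifnot(A > 0, b > A, s > 0)
  .lba_pdf_cpp(as.numeric(t), A, b, v, s)
}

#' Log defective density of the four-way LBA race
#'
#' Joint log density of responding with option `response` at decision time
#' `t`: the winner's first-passage density times the survival functions of
#' the three competitors.  Integrating `exp()` of this over `t` for each
#' response gives the choice probabilities, which sum to the probability
#' that at least one accumulator finishes (no renormalization over the
#' all-fail event is applied).
#'
#' @param t Decision times (seconds); values `<= 0` give `-Inf`.
#' @param response Response index 1..4 or label in
#'   `c("correct","semantic","phonetic","neither")` (recycled).
#' @param drifts Numeric 4-vector of effective drift means, or an
#'   `length(t) x 4` matrix for row-wise evaluation.
#' @inheritParams lba_cdf
#' @return Log densities.
#' @export
race_log_density <- function(t, response, drifts, A, b, s = 1) {
  stopifnot(A > 0, b > A, s > 0)
  if (is.character(response))
    response <- match(response, response_levels())
  if (anyNA(response) || any(response < 1 | response > 4))
    stop("response must index the four options")
  if (is.null(dim(drifts))) drifts <- matrix(drifts, nrow = 1L)
  stopifnot(ncol(drifts) == 4L)
  .race_log_density_cpp(as.numeric(t), as.integer(response), drifts, A, b, s)
}

#' Effective drift rates for one keyword observation
#'
#' Applies the serial-dependency boosts to the correct-response accumulator
#' only: keyword 2 receives `boost_kw2` if keyword 1 of the same sentence
#' was answered correctly; keyword 3 receives `boost_kw3` if both preceding
#' keywords were correct.  Error drifts are never modified, and keyword 1 is
#' never boosted.
#'
#' @param params Constrained parameter vector (length 17, see
#'   [lba_param_names()]).
#' @param mode Presentation mode label or index 1..3.
#' @param keyword_index Keyword position within the sentence, 1..3.
#' @param kw1_correct,kw2_correct Context flags: was keyword 1 (resp. 2) of
#'   this sentence answered correctly?  `kw2_correct` only matters for
#'   keyword 3.
#' @return Named drift 4-vector (correct, semantic, phonetic, neither).
#' @export
effective_drifts <- function(params, mode, keyword_index,
                             kw1_correct = FALSE, kw2_correct = FALSE) {
  if (is.character(mode)) mode <- match(mode, mode_levels())
  stopifnot(mode %in% 1:3, keyword_index %in% 1:3, length(params) == 17L)
  v <- params[(4L * (mode - 1L)) + 1:4]
  if (keyword_index == 2L && isTRUE(kw1_correct)) v[1L] <- v[1L] + params[13L]
  if (keyword_index == 3L && isTRUE(kw1_correct) && isTRUE(kw2_correct))
    v[1L] <- v[1L] + params[14L]
  names(v) <- response_levels()
  v
}

#' Mixture log likelihood of a single keyword observation
#'
#' With probability `1 - lambda` the observation comes from the LBA race
#' (density evaluated at `rt - t0`); with probability `lambda` it is a
#' contaminant, uniform over the four response options and uniform in RT on
#' `(0, t_max)`.  The contaminant component keeps the likelihood finite for
#' any `rt` in `(0, t_max]`, including responses faster than the
#' non-decision time.
#'
#' @param rt Response time in seconds (from stimulus onset, including `t0`).
#' @param response Response index 1..4 or label.
#' @param params Constrained 17-parameter vector.
#' @param mode,keyword_index,kw1_correct,kw2_correct As in
#'   [effective_drifts()].
#' @param lambda Contaminant proportion in `[0, 1]`.
#' @param t_max Upper bound of the contaminant RT distribution (seconds),
#'   the maximum observed RT when fitting.
#' @return Log likelihood (finite; floored at -745 as a numerical guard).
#' @export
trial_log_likelihood <- function(rt, response, params, mode, keyword_index,
                                 kw1_correct = FALSE, kw2_correct = FALSE,
                                 lambda, t_max) {
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  if (any(rt > t_max)) stop("rt exceeds t_max")
  validate_constrained(params)
  if (is.character(response)) response <- match(response, response_levels())
  v <- effective_drifts(params, mode, keyword_index, kw1_correct, kw2_correct)
  race <- exp(race_log_density(rt - params[17L], response, v,
                               A = params[15L], b = params[16L], s = 1))
  race[rt - params[17L] <= 0] <- 0
  pmax(log((1 - lambda) * race + lambda * 0.25 / t_max), -745)
}

#' Summed mixture log likelihood of a trial table
#'
#' Vectorized evaluation over all rows of a trial table; the sum is
#' invariant to row order.  Optionally returns per-row values.
#'
#' @param data Trial table as produced by [simulate_dataset()] or
#'   [read_trials()].
#' @param params Constrained parameter matrix, one row per participant
#'   (rows in the order of `sort(unique(data$participant_id))`), or a single
#'   vector applied to all participants.
#' @param lambda Contaminant proportion.
#' @param t_max Contaminant RT upper bound; defaults to `max(data$rt_seconds)`.
#' @param per_row Return per-row log likelihoods as well?
#' @return Scalar log likelihood, or a list with `total` and `per_row`.
#' @export
dataset_log_likelihood <- function(data, params, lambda,
                                   t_max = max(data$rt_seconds),
                                   per_row = FALSE) {
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  if (any(data$rt_seconds > t_max)) stop("rt exceeds t_max")
  enc <- encode_trials(data)
  if (is.null(dim(params))) params <- matrix(params, nrow = 1L)[rep(1L, enc$n), , drop = FALSE]
  validate_constrained(params)
  out <- .dataset_loglik_cpp(enc$rt, enc$resp, enc$mode, enc$kw, enc$kw1c,
                             enc$kw2c, enc$pid, params, lambda, t_max, per_row)
  if (per_row) {
    pr <- numeric(length(enc$order))
    pr[enc$order] <- out$per_row
    list(total = out$total, per_row = pr)
  } else out$total
}

# integer-encode a trial table for the compiled likelihood / sampler.
# Rows are sorted by participant; `order` maps sorted rows back to input rows.
encode_trials <- function(data) {
  pid_levels <- sort(unique(as.character(data$participant_id)))
  pid <- match(as.character(data$participant_id), pid_levels)
  ord <- order(pid)
  resp <- match(as.character(data$response), response_levels())
  mode <- match(as.character(data$mode), mode_levels())
  if (anyNA(resp)) stop("unknown response category")
  if (anyNA(mode)) stop("unknown presentation mode")
  kw1c <- as.integer(!is.na(data$kw1_correct) & data$kw1_correct)
  kw2c <- as.integer(!is.na(data$kw2_correct) & data$kw2_correct)
  grp <- vapply(pid_levels, function(p) {
    as.character(data$group[match(p, as.character(data$participant_id))])
  }, character(1))
  list(rt = as.numeric(data$rt_seconds)[ord], resp = resp[ord],
       mode = mode[ord], kw = as.integer(data$keyword_index)[ord],
       kw1c = kw1c[ord], kw2c = kw2c[ord], pid = pid[ord],
       row_start = c(0L, cumsum(tabulate(pid, length(pid_levels)))),
       participants = pid_levels, group = grp, n = length(pid_levels),
       order = ord)
}
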