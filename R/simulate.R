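# vectorized LBA race: one row per simulated observation.
# drifts: m x 4 matrix of effective drift means; A, b, t0 scalars or
# length-m vectors.  Rows where no accumulator finishes in finite time
# (all four drift draws non-positive) are redrawn; with a finite t_max the
# redraw extends to races slower than the window (used only where a
# timeout cannot be represented otherwise).
simulate_race <- function(drifts, A, b, t0, s = 1, t_max = Inf) {
  m <- nrow(drifts)
  draw_rows <- function(rows) {
    mm <- length(rows)
    k <- matrix(rnorm(mm * 4L, as.vector(drifts[rows, , drop = FALSE]), s),
                mm, 4L)
    start <- matrix(runif(mm * 4L, 0, rep_len(A, m)[rows]), mm, 4L)
    tt <- (rep_len(b, m)[rows] - start) / k
    tt[k <= 0] <- Inf
    win <- max.col(-tt, ties.method = "first")
    list(win = win, t = tt[cbind(seq_len(mm), win)])
  }
  response <- integer(m)
  rt <- rep(Inf, m)
  todo <- seq_len(m)
  for (tries in 1:1000) {
    d <- draw_rows(todo)
    response[todo] <- d$win
    rt[todo] <- rep_len(t0, m)[todo] + d$t
    todo <- todo[!(is.finite(rt[todo]) & rt[todo] <= t_max)]
    if (!length(todo)) break
  }
  if (length(todo)) stop("race simulation failed to finish within t_max")
  list(response = response, rt = rt)
}

#' Simulate keyword responses from the LBA race with contaminant lapses
#'
#' With probability `1 - lambda` the response and RT come from the LBA race
#' (per-accumulator start uniform on `(0, A)`, drift normal around the
#' effective drift with SD 1, winner = first accumulator to reach `b`;
#' RT = non-decision time + winning finishing time).  With probability
#' `lambda` the observation is a lapse: response uniform over the four
#' options and RT uniform on `(0, t_max)`.
#'
#' @param params Constrained parameter vector (length 17).
#' @param mode,keyword_index,kw1_correct,kw2_correct Trial context, see
#'   [effective_drifts()].
#' @param lambda Contaminant proportion.
#' @param t_max Response window (seconds): the contaminant RT upper bound,
#'   and also the horizon within which a simulated race must finish (slower
#'   races are redrawn; truncated mass is negligible at realistic
#'   parameters).
#' @param n Number of independent replicates to draw.
#' @param seed Optional integer seed.
#' @return data.frame with `response` (factor) and `rt_seconds`.
#' @export
simulate_trial <- function(params, mode, keyword_index,
                           kw1_correct = FALSE, kw2_correct = FALSE,
                           lambda = 0, t_max = 10, n = 1L, seed = NULL) {
  validate_constrained(params)
  stopifnot(lambda >= 0, lambda <= 1, t_max > 0)
  v <- effective_drifts(params, mode, keyword_index, kw1_correct, kw2_correct)
  run <- function() {
    drifts <- matrix(v, n, 4L, byrow = TRUE)
    race <- simulate_race(drifts, params[15L], params[16L], params[17L])
    # with a contaminant arm, t_max acts as a response window: trials whose
    # race outlasts it become timeout guesses (uniform response and RT),
    # absorbed by the model's contaminant component; with lambda = 0 the
    # pure race is returned unmodified
    lapse <- runif(n) < lambda
    if (lambda > 0) lapse <- lapse | race$rt > t_max
    if (any(lapse)) {
      race$response[lapse] <- sample.int(4L, sum(lapse), replace = TRUE)
      race$rt[lapse] <- runif(sum(lapse), 0, t_max)
    }
    data.frame(response = factor(response_levels()[race$response],
                                 levels = response_levels()),
               rt_seconds = race$rt)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Simulate a full trial table from the generative model
#'
#' Expands the design via [build_design()], draws each participant's
#' parameter vector from the population, then simulates the three keywords
#' of every sentence sequentially so that the serial-dependency boosts act
#' on the simulated correctness of the preceding keywords (lapses included:
#' context is defined by the recorded response).  Context flags
#' `kw1_correct` / `kw2_correct` are written consistently with the response
#' column (`NA` where not meaningful: keyword 1 has no context, and
#' `kw2_correct` only applies to keyword 3).
#'
#' @param spec An [design_spec()] object (its seed drives the trial order).
#' @param pop An [true_population()] object.
#' @param seed Integer seed for parameters, races and lapses.
#' @return Trial table data.frame; attributes `truth` (population and
#'   per-participant parameters) and `t_max` record the generating process.
#' @export
simulate_dataset <- function(spec = design_spec(), pop = true_population(),
                             seed = 1L) {
  stopifnot(inherits(spec, "lba_design_spec"), inherits(pop, "lba_population"))
  design <- build_design(spec)
  with_seed(seed, {
    group_seeds <- sample.int(2^31 - 1, length(spec$groups))
    params <- lapply(seq_along(spec$groups), function(gi)
      draw_individual_parameters(pop, spec$groups[gi], spec$n_per_group,
                                 seed = group_seeds[gi]))
    names(params) <- spec$groups
    ids <- unique(design$participant_id)
    pmat <- do.call(rbind, lapply(params, `[[`, "constrained"))
    rownames(pmat) <- ids
    out <- simulate_responses(design, pmat, pop$contaminant_prop, pop$t_max)
    attr(out, "truth") <- list(population = pop, params = params,
                               participant_order = ids)
    attr(out, "t_max") <- pop$t_max
    out
  })
}

# simulate responses/RTs for every keyword slot of a design table, keyword
# by keyword so the boosts act on the simulated correctness of earlier
# keywords.  pmat: constrained parameter matrix with rownames matching
# design$participant_id.  Uses the current RNG stream (callers seed it).
simulate_responses <- function(design, pmat, lambda, t_max) {
  # keyword slots of one trial must stay aligned across keyword indices
  design <- design[order(design$participant_id, design$trial_id,
                         design$keyword_index), , drop = FALSE]
  rownames(design) <- NULL
  design$response <- factor(NA_character_, levels = response_levels())
  design$rt_seconds <- NA_real_
  design$kw1_correct <- NA
  design$kw2_correct <- NA
  prow <- match(design$participant_id, rownames(pmat))
  if (anyNA(prow)) stop("design participants missing from parameter matrix")
  mode_i <- match(design$mode, mode_levels())
  kw_max <- max(design$keyword_index)
  corr_prev <- NULL  # m x (kw-1) matrix of correctness of earlier keywords
  for (k in seq_len(kw_max)) {
    rows <- which(design$keyword_index == k)
    m <- length(rows)
    pk <- pmat[prow[rows], , drop = FALSE]
    drifts <- vapply(1:4, function(r)
      pk[cbind(seq_len(m), 4L * (mode_i[rows] - 1L) + r)], numeric(m))
    if (m == 1L) drifts <- matrix(drifts, 1L, 4L)
    if (k == 2L) {
      kw1c <- corr_prev[, 1L]
      drifts[, 1L] <- drifts[, 1L] + pk[, 13L] * kw1c
      design$kw1_correct[rows] <- as.logical(kw1c)
    } else if (k >= 3L) {
      kw1c <- corr_prev[, 1L]
      kw2c <- corr_prev[, 2L]
      drifts[, 1L] <- drifts[, 1L] + pk[, 14L] * (kw1c * kw2c)
      design$kw1_correct[rows] <- as.logical(kw1c)
      design$kw2_correct[rows] <- as.logical(kw2c)
    }
    race <- simulate_race(drifts, pk[, 15L], pk[, 16L], pk[, 17L])
    # response window: races outlasting t_max become timeout guesses
    # (uniform response/RT), handled by the contaminant arm; see
    # simulate_trial
    lapse <- runif(m) < lambda
    if (lambda > 0) lapse <- lapse | race$rt > t_max
    if (any(lapse)) {
      race$response[lapse] <- sample.int(4L, sum(lapse), replace = TRUE)
      race$rt[lapse] <- runif(sum(lapse), 0, t_max)
    }
    design$response[rows] <- response_levels()[race$response]
    design$rt_seconds[rows] <- race$rt
    this_corr <- as.numeric(race$response == 1L)
    corr_prev <- if (k == 1L) cbind(this_corr) else cbind(corr_prev, this_corr)
  }
  design
}

#' Simulate preference-vote counts
#'
#' Each group x conversation cell casts `n_per_group` independent votes
#' over the presentation modes with the given probabilities, so per-cell
#' counts are multinomial and always sum to `n_per_group`.
#'
#' @param vote_probs data.frame with columns `group`, `conversation`,
#'   `mode`, `prob`; probabilities must sum to 1 (within 1e-9) in every
#'   group x conversation cell.
#' @param n_per_group Voters per group.
#' @param seed Integer seed.
#' @return data.frame with columns `group`, `conversation`, `mode`, `count`.
#' @export
simulate_preferences <- function(vote_probs = default_vote_probs(),
                                 n_per_group = 50L, seed = 1L) {
  stopifnot(all(c("group", "conversation", "mode", "prob") %in% names(vote_probs)))
  key <- interaction(vote_probs$group, vote_probs$conversation, drop = TRUE)
  sums <- tapply(vote_probs$prob, key, sum)
  if (any(abs(sums - 1) > 1e-9))
    stop("vote probabilities must sum to 1 within each group x conversation cell")
  with_seed(seed, {
    out <- vote_probs
    out$count <- NA_integer_
    for (cell in levels(key)) {
      idx <- which(key == cell)
      out$count[idx] <- as.integer(rmultinom(1, n_per_group, vote_probs$prob[idx]))
    }
    out$prob <- NULL
    out
  })
}

#' @rdname simulate_preferences
#' @export
default_vote_probs <- function() {
  # Synthetic vote-share defaults: CI caption share 92/69/63% and AH video
  # share 64/80/72% across conversations A/B/C, remainders split plausibly.
  expand_cell <- function(group, conversation, probs)
    data.frame(group = group, conversation = conversation,
               mode = mode_levels(), prob = probs)
  rbind(
    expand_cell("AH", "A", c(0.07, 0.64, 0.29)),
    expand_cell("AH", "B", c(0.04, 0.80, 0.16)),
    expand_cell("AH", "C", c(0.06, 0.72, 0.22)),
    expand_cell("CI", "A", c(0.02, 0.06, 0.92)),
    expand_cell("CI", "B", c(0.05, 0.26, 0.69)),
    expand_cell("CI", "C", c(0.07, 0.30, 0.63)))
}
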