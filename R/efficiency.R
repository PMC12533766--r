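#' Listening efficiency from drift rates
#'
#' Listening efficiency is the drift rate toward the correct response minus
#' the mean of the drift rates toward the three error responses.  For a
#' random guesser (all drifts equal) it is exactly 0; it increases as
#' evidence accumulates faster toward the correct option.  Adding a common
#' constant to all four drifts leaves it unchanged.
#'
#' @param v_correct,v_semantic,v_phonetic,v_neither Drift rates
#'   (vectorized).
#' @return Efficiency in drift units.
#' @export
listening_efficiency <- function(v_correct, v_semantic, v_phonetic, v_neither) {
  v_correct - (v_semantic + v_phonetic + v_neither) / 3
}

#' Per-draw listening-efficiency posterior for each group x mode
#'
#' Computes listening efficiency from the group-level mean drift draws
#' (the group-level parameters, not averaged individual draws) for every
#' group x mode cell, and normalizes so that the reference group's mean
#' across modes equals exactly 1 within every draw.
#'
#' @param fit An `lba_fit` object.
#' @param reference_group Label of the normalization reference (default the
#'   first group, AH in the study design).
#' @return Object of class `efficiency_posterior`: list with `raw` and
#'   `normalized` arrays `[draw, group, mode]`, the per-draw normalization
#'   constants, and the count of flagged draws (non-positive reference
#'   mean).
#' @export
efficiency_posterior <- function(fit, reference_group = fit$groups[1L]) {
  stopifnot(inherits(fit, "lba_fit"))
  modes <- mode_levels()
  groups <- fit$groups
  pn <- dimnames(fit$draws)[[3]]
  n_draw <- dim(fit$draws)[1] * dim(fit$draws)[2]
  raw <- array(NA_real_, c(n_draw, length(groups), length(modes)),
               dimnames = list(NULL, groups, modes))
  for (g in groups) {
    for (m in modes) {
      cols <- paste0("mu_", g, "[v_", c("correct", "semantic", "phonetic",
                                        "neither"), "_", m, "]")
      idx <- match(cols, pn)
      v <- lapply(idx, function(j) as.vector(fit$draws[, , j]))
      raw[, g, m] <- listening_efficiency(v[[1]], v[[2]], v[[3]], v[[4]])
    }
  }
  normalize_to_reference(raw, reference_group)
}

#' Normalize efficiency draws to a reference group
#'
#' Within each posterior draw, every group x mode efficiency is divided by
#' the mean of the reference group's values across modes in that same
#' draw, so the reference group's mode-average is exactly 1 draw by draw.
#' Draws with a non-positive reference mean are flagged (count reported)
#' and normalized to `NA`.
#'
#' @param raw Array `[draw, group, mode]` of raw efficiency values.
#' @param reference_group Group label present in the array's dimnames.
#' @return An `efficiency_posterior` object.
#' @export
normalize_to_reference <- function(raw, reference_group) {
  if (inherits(raw, "efficiency_posterior")) raw <- raw$normalized
  if (!reference_group %in% dimnames(raw)[[2]])
    stop("reference group not present: ", reference_group)
  ref_mean <- rowMeans(raw[, reference_group, , drop = FALSE], dims = 1L)
  bad <- !(ref_mean > 0)
  normalized <- sweep(raw, 1L, ref_mean, "/")
  if (any(bad)) normalized[bad, , ] <- NA_real_
  structure(list(raw = raw, normalized = normalized,
                 reference_group = reference_group,
                 reference_mean = ref_mean, flagged_draws = sum(bad)),
            class = "efficiency_posterior")
}

#' @export
print.efficiency_posterior <- function(x, ...) {
  cat("Listening-efficiency posterior (normalized to",
      x$reference_group, "mode-average = 1)\n")
  med <- apply(x$normalized, c(2L, 3L), median, na.rm = TRUE)
  print(round(med, 3))
  if (x$flagged_draws > 0)
    cat("Flagged draws (non-positive reference mean):", x$flagged_draws, "\n")
  invisible(x)
}

#' Narrowest 95% highest-density interval of a sample
#'
#' Narrowest-window HDI over the sorted draws (assumes a unimodal
#' posterior, the typical case for these models).
#'
#' @param x Numeric draws.
#' @param prob Probability mass (default 0.95).
#' @return Numeric `c(lower, upper)`.
#' @export
hdi <- function(x, prob = 0.95) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n == 0L) return(c(NA_real_, NA_real_))
  k <- max(1L, ceiling(prob * n))
  if (k >= n) return(c(x[1L], x[n]))
  widths <- x[(k + 1L):n] - x[seq_len(n - k)]
  i <- which.min(widths)
  c(x[i], x[i + k])
}

#' Credibility and HDI summary of a paired posterior contrast
#'
#' Summarizes the per-draw difference `a - b`: posterior median, 95%
#' highest-density interval, and the credibility that the difference is
#' positive.  Ties count 0.5 so that comparing a posterior with itself
#' yields exactly 0.5.
#'
#' @param draws_a,draws_b Paired posterior draws (equal length).
#' @param label Contrast label carried in the output.
#' @param prob HDI mass.
#' @return data.frame with `contrast`, `median`, `hdi_lower`, `hdi_upper`,
#'   `credibility`.
#' @export
effect_credibility <- function(draws_a, draws_b, label = "a - b", prob = 0.95) {
  if (length(draws_a) != length(draws_b))
    stop("draws_a and draws_b must have equal length")
  diff <- draws_a - draws_b
  h <- hdi(diff, prob)
  data.frame(contrast = label, median = median(diff),
             hdi_lower = h[1L], hdi_upper = h[2L],
             credibility = mean((diff > 0) + 0.5 * (diff == 0)))
}

#' Posterior response caution
#'
#' Response caution summarizes the speed-accuracy trade-off as the distance
#' from the mean start point to the threshold, `b - A/2` (default), with
#' the threshold-to-start ratio `b/A` available as an alternative
#' definition.  Computed from the constrained group-level draws.
#'
#' @param fit An `lba_fit` object.
#' @param definition `"b_minus_half_A"` (default) or `"b_over_A"`.
#' @return Matrix `[draw, group]` of per-draw caution values.
#' @export
response_caution <- function(fit, definition = c("b_minus_half_A", "b_over_A")) {
  definition <- match.arg(definition)
  pn <- dimnames(fit$draws)[[3]]
  out <- sapply(fit$groups, function(g) {
    A <- as.vector(fit$draws[, , match(paste0("mu_", g, "[A]"), pn)])
    b <- as.vector(fit$draws[, , match(paste0("mu_", g, "[b]"), pn)])
    if (definition == "b_minus_half_A") b - A / 2 else b / A
  })
  colnames(out) <- fit$groups
  out
}

#' Descriptive accuracy and response-time summaries
#'
#' Per group x mode cell: number of keyword observations, accuracy (%),
#' response-time quantiles (0.1 / 0.5 / 0.9), and error-type counts.
#' Empty cells are reported as missing rather than raising an error.
#'
#' @param data Trial table.
#' @return data.frame with one row per group x mode cell.
#' @export
observed_summaries <- function(data) {
  if (nrow(data) == 0L) stop("empty trial table")
  groups <- sort(unique(as.character(data$group)))
  modes <- intersect(mode_levels(), unique(as.character(data$mode)))
  cells <- expand.grid(group = groups, mode = modes, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(cells)), function(i) {
    d <- data[data$group == cells$group[i] & data$mode == cells$mode[i], ]
    if (nrow(d) == 0L)
      return(data.frame(cells[i, ], n = 0L, accuracy_pct = NA_real_,
                        rt_q10 = NA_real_, rt_q50 = NA_real_,
                        rt_q90 = NA_real_, n_semantic = NA_integer_,
                        n_phonetic = NA_integer_, n_neither = NA_integer_))
    q <- quantile(d$rt_seconds, c(0.1, 0.5, 0.9), names = FALSE)
    tab <- table(factor(as.character(d$response), levels = response_levels()))
    data.frame(cells[i, ], n = nrow(d),
               accuracy_pct = 100 * mean(d$response == "correct"),
               rt_q10 = q[1L], rt_q50 = q[2L], rt_q90 = q[3L],
               n_semantic = as.integer(tab[["semantic"]]),
               n_phonetic = as.integer(tab[["phonetic"]]),
               n_neither = as.integer(tab[["neither"]]))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
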