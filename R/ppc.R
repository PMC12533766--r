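#' Posterior predictive simulation of replicated datasets
#'
#' For each of `n_datasets` posterior draws (sampled uniformly across
#' chains and iterations), simulates a full replicated dataset on the
#' observed design using that draw's individual-level constrained
#' parameters and contaminant proportion — the replicated-data contract for
#' posterior predictive checking of existing participants.
#'
#' @param fit An `lba_fit` object.
#' @param n_datasets Number of replicated datasets (0 gives an empty list).
#' @param seed Integer seed.
#' @return List of trial tables sharing the observed design.
#' @export
posterior_predictive_simulate <- function(fit, n_datasets = 50L, seed = 1L) {
  stopifnot(inherits(fit, "lba_fit"))
  if (n_datasets == 0L) return(list())
  d <- 17L
  n <- length(fit$participants)
  design <- fit$data[c("participant_id", "group", "trial_id", "mode",
                       "keyword_index")]
  lambda_col <- match("lambda", dimnames(fit$draws)[[3]])
  theta_cols <- match(as.vector(vapply(fit$participants, function(p)
    paste0("theta_", p, "[", fit$param_names, "]"), character(d))),
    dimnames(fit$draws)[[3]])
  with_seed(seed, {
    it <- sample.int(dim(fit$draws)[1], n_datasets, replace = TRUE)
    ch <- sample.int(dim(fit$draws)[2], n_datasets, replace = TRUE)
    lapply(seq_len(n_datasets), function(k) {
      pmat <- matrix(fit$draws[it[k], ch[k], theta_cols], n, d, byrow = TRUE,
                     dimnames = list(fit$participants, fit$param_names))
      simulate_responses(design, pmat, fit$draws[it[k], ch[k], lambda_col],
                         fit$t_max)
    })
  })
}

#' Accuracy gap between observed and replicated data
#'
#' Absolute difference, in percentage points, between observed accuracy and
#' the mean accuracy of posterior-replicated datasets, per group x mode
#' cell.  Used as the posterior predictive summary of model fit.
#'
#' @param observed Observed trial table.
#' @param replicated List of replicated trial tables sharing the observed
#'   design (see [posterior_predictive_simulate()]).
#' @return data.frame with per-cell observed and replicated accuracy (%)
#'   and `gap_points`.
#' @export
ppc_accuracy_gap <- function(observed, replicated) {
  stopifnot(length(replicated) >= 1L)
  cell_acc <- function(d) {
    agg <- aggregate(list(acc = d$response == "correct"),
                     by = list(group = d$group, mode = d$mode), FUN = mean)
    agg[order(agg$group, agg$mode), ]
  }
  obs <- cell_acc(observed)
  for (r in replicated) {
    if (nrow(r) != nrow(observed))
      stop("replicated dataset does not match the observed design")
    ra <- cell_acc(r)
    if (!identical(ra$group, obs$group) || !identical(ra$mode, obs$mode))
      stop("replicated dataset does not match the observed design")
  }
  rep_acc <- rowMeans(vapply(replicated, function(r) cell_acc(r)$acc,
                             numeric(nrow(obs))))
  data.frame(group = obs$group, mode = obs$mode,
             observed_pct = 100 * obs$acc, replicated_pct = 100 * rep_acc,
             gap_points = abs(100 * rep_acc - 100 * obs$acc))
}
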