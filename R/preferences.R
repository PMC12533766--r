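#' Fit a Bayesian Poisson log-linear model to preference counts
#'
#' Counts of preference votes are modelled as independent Poisson with a
#' log link and a full-factorial design matrix: `Counts ~ Mode x Group`
#' (two-way; counts summed over conversations) or
#' `Counts ~ Mode x Group x Conversation` (three-way, saturated for this
#' design).  Coefficients use treatment coding with audio / AH /
#' conversation A as reference levels and `N(0, 5^2)` priors on the log
#' scale.  Posterior sampling runs 4 chains with 2000 warmup and 2000
#' post-warmup iterations each (JAGS, glm module), deterministic given the
#' seed.
#'
#' @param counts Preference-count table: columns `group`, `conversation`,
#'   `mode`, `count` (complete factorial; zero counts allowed).
#' @param formula_order `"two_way"` or `"three_way"`.
#' @param chains,warmup,samples MCMC settings (defaults 4 / 2000 / 2000).
#' @param seed Integer seed.
#' @param coef_sd Prior SD of the log-scale coefficients.
#' @return Object of class `glm_posterior`: coefficient draws
#'   `[draw, coefficient]` (8000 rows by default), the cell table and
#'   design matrix, and per-coefficient Rhat.
#' @export
fit_poisson_model <- function(counts, formula_order = c("two_way", "three_way"),
                              chains = 4L, warmup = 2000L, samples = 2000L,
                              seed = 1L, coef_sd = 5) {
  formula_order <- match.arg(formula_order)
  validate_counts(counts, require_conversation = formula_order == "three_way")
  if (formula_order == "two_way") {
    cells <- aggregate(count ~ group + mode, data = counts, FUN = sum)
  } else {
    cells <- aggregate(count ~ group + conversation + mode, data = counts,
                       FUN = sum)
  }
  cells$mode <- factor(cells$mode,
                       levels = intersect(mode_levels(),
                                          unique(as.character(cells$mode))))
  cells$group <- factor(cells$group, levels = sort(unique(as.character(cells$group))))
  form <- if (formula_order == "two_way") ~ mode * group else {
    cells$conversation <- factor(cells$conversation)
    ~ mode * group * conversation
  }
  X <- stats::model.matrix(form, data = cells)

  model_str <- "
  model {
    for (i in 1:N) {
      count[i] ~ dpois(mu[i])
      log(mu[i]) <- inprod(X[i, ], beta[])
    }
    for (j in 1:P) { beta[j] ~ dnorm(0, prec) }
  }"
  inits <- lapply(seq_len(chains), function(ch)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer(seed + ch)))
  rjags::load.module("glm", quiet = TRUE)
  jm <- rjags::jags.model(textConnection(model_str),
                          data = list(count = cells$count, X = X,
                                      N = nrow(X), P = ncol(X),
                                      prec = 1 / coef_sd^2),
                          inits = inits, n.chains = chains,
                          n.adapt = min(1000L, warmup), quiet = TRUE)
  burn <- warmup - min(1000L, warmup)
  if (burn > 0) stats::update(jm, burn, progress.bar = "none")
  samp <- rjags::coda.samples(jm, "beta", n.iter = samples,
                              progress.bar = "none")
  beta <- do.call(rbind, lapply(samp, as.matrix))
  colnames(beta) <- colnames(X)
  rhat <- tryCatch(
    coda::gelman.diag(samp, autoburnin = FALSE, multivariate = FALSE)$psrf[, 1L],
    error = function(e) rep(NA_real_, ncol(X)))
  structure(list(beta = beta, X = X, cells = cells,
                 formula_order = formula_order, rhat = rhat,
                 chains = chains, seed = seed), class = "glm_posterior")
}

validate_counts <- function(counts, require_conversation = FALSE) {
  need <- c("group", "mode", "count")
  if (require_conversation) need <- c(need, "conversation")
  miss <- setdiff(need, names(counts))
  if (length(miss)) stop("counts table missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(counts$count < 0) || any(counts$count != round(counts$count)))
    stop("counts must be non-negative integers")
  by_cols <- intersect(c("group", "conversation"), names(counts))
  tab <- table(counts[c("mode", by_cols)])
  if (any(tab != 1L)) stop("counts table must be a complete factorial (one row per cell)")
  invisible(TRUE)
}

#' @export
print.glm_posterior <- function(x, ...) {
  cat("Bayesian Poisson model (", x$formula_order, "), ",
      nrow(x$beta), " draws, max Rhat ", round(max(x$rhat, na.rm = TRUE), 3),
      "\n", sep = "")
  print(round(apply(x$beta, 2L, quantile, c(0.025, 0.5, 0.975)), 3))
  invisible(x)
}

#' Conditional effects (predicted cell means) of a fitted count model
#'
#' Exponentiates the linear predictor of every factorial cell for each
#' posterior draw and summarizes across draws.
#'
#' @param posterior A `glm_posterior` from [fit_poisson_model()].
#' @param prob Credible-interval mass (central interval, default 95%).
#' @return data.frame of cells with observed count, posterior mean, median
#'   and credible-interval bounds.
#' @export
conditional_effects <- function(posterior, prob = 0.95) {
  stopifnot(inherits(posterior, "glm_posterior"))
  eta <- posterior$beta %*% t(posterior$X)
  mu <- exp(eta)
  a <- (1 - prob) / 2
  out <- posterior$cells
  out$predicted_mean <- colMeans(mu)
  out$predicted_median <- apply(mu, 2L, median)
  out$cri_lower <- apply(mu, 2L, quantile, a, names = FALSE)
  out$cri_upper <- apply(mu, 2L, quantile, 1 - a, names = FALSE)
  out
}

#' Preference percentages per group and conversation
#'
#' Converts counts to the percentage of each group's voters choosing each
#' mode within a conversation; percentages sum to 100 within each
#' group x conversation cell.
#'
#' @param counts Preference-count table (columns `group`, `conversation`,
#'   `mode`, `count`).
#' @return data.frame with an added `pct` column.
#' @export
percentage_table <- function(counts) {
  validate_counts(counts, require_conversation = TRUE)
  key <- interaction(counts$group, counts$conversation, drop = TRUE)
  totals <- tapply(counts$count, key, sum)[key]
  if (any(totals == 0)) stop("zero voters in a group x conversation cell")
  out <- counts
  out$pct <- 100 * counts$count / as.numeric(totals)
  out
}
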