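#' MCMC sampler configuration
#'
#' Defaults follow the analysis protocol: 4 independent chains, 1000 warmup
#' iterations and 2000 retained sampling iterations per chain (8000 retained
#' draws in total).
#'
#' @param chains Number of chains (>= 2 for convergence diagnostics).
#' @param warmup_iterations Warmup (adaptation) iterations per chain;
#'   adaptation of proposal scales and covariances happens only here.
#' @param sampling_iterations Retained iterations per chain.
#' @param seed Integer seed; all chains derive from it deterministically.
#' @param target_acceptance Target acceptance rate of the individual-level
#'   random-walk updates (0.234 is the classic high-dimensional optimum).
#' @param thin Transitions between retained draws (default 3): a
#'   Metropolis-within-Gibbs kernel needs more transitions per effective
#'   draw than gradient-based samplers, and thinning buys them without
#'   growing the stored output.
#' @param inner_sweeps Individual-parameter update sweeps per iteration.
#' @param lambda_steps Contaminant-proportion updates per iteration.
#' @return An object of class `sampler_config`.
#' @export
sampler_config <- function(chains = 4L, warmup_iterations = 1000L,
                           sampling_iterations = 2000L, seed = 1L,
                           target_acceptance = 0.234, thin = 3L,
                           inner_sweeps = 1L, lambda_steps = 5L) {
  stopifnot(chains >= 1, warmup_iterations >= 1, sampling_iterations >= 1,
            thin >= 1)
  structure(list(chains = as.integer(chains),
                 warmup_iterations = as.integer(warmup_iterations),
                 sampling_iterations = as.integer(sampling_iterations),
                 seed = as.integer(seed),
                 target_acceptance = target_acceptance,
                 thin = as.integer(thin),
                 inner_sweeps = as.integer(inner_sweeps),
                 lambda_steps = as.integer(lambda_steps)),
            class = "sampler_config")
}

#' Prior specification of the hierarchical model
#'
#' Weakly informative stand-ins on the unconstrained scale: group means
#' `N(0, 5^2)` componentwise; the shared between-subject covariance gets
#' the Huang-Wand (2013) prior with `nu = tau_df` and `A = tau_scale`,
#' under which every between-subject scale has an exact
#' half-Student-t(`tau_df`, 0, `tau_scale`) marginal and correlations are
#' marginally near-uniform; standardized individual offsets are `N(0, I)`;
#' the contaminant proportion is `Beta(1, 19)` (prior mean 5%).  The
#' Huang-Wand form admits exact conjugate Gibbs updates of the covariance.
#'
#' @param mu_sd SD of the normal prior on group means.
#' @param tau_df,tau_scale Half-Student-t parameters of the scale marginals
#'   (Huang-Wand `nu` and `A`).
#' @param lambda_a,lambda_b Beta prior on the contaminant proportion.
#' @return List of prior settings.
#' @export
lba_prior <- function(mu_sd = 5, tau_df = 3, tau_scale = 2.5,
                      lambda_a = 1, lambda_b = 19) {
  list(mu_sd = mu_sd, tau_df = tau_df, tau_scale = tau_scale,
       lambda_a = lambda_a, lambda_b = lambda_b)
}

half_t_log <- function(x, df, scale) {
  ifelse(x > 0, log(2) + dt(x / scale, df, log = TRUE) - log(scale), -Inf)
}

# log of the marginal Huang-Wand density of Sigma = diag(tau) C diag(tau)
# (auxiliary scales integrated out), plus the (tau, C) -> Sigma Jacobian
# so the value is a density over (tau, C); normalizing constant dropped.
hw_sigma_log <- function(tau, corr, nu, A) {
  d <- length(tau)
  Sigma <- diag(tau) %*% corr %*% diag(tau)
  Prec <- tryCatch(chol2inv(chol(Sigma)), error = function(e) NULL)
  if (is.null(Prec)) return(-Inf)
  logdet <- 2 * sum(log(diag(chol(Sigma))))
  -0.5 * (nu + 2 * d) * logdet -
    0.5 * (nu + d) * sum(log(nu * diag(Prec) + 1 / A^2)) +
    d * log(2) + d * sum(log(tau))
}

#' Joint log posterior density of the hierarchical model
#'
#' Non-centered parameterization: each individual's unconstrained vector is
#' `theta_i = mu[group(i)] + diag(tau) %*% L %*% z_i` with `L` the lower
#' Cholesky factor of the correlation matrix.  The log posterior is the sum
#' of the mixture trial log likelihoods (via the constrained parameters)
#' plus the priors of [lba_prior()]; the covariance prior is the
#' closed-form marginal Huang-Wand density evaluated at
#' `diag(tau) corr diag(tau)` (in (tau, corr) coordinates).
#'
#' @param data Trial table (may have zero rows, giving the log prior).
#' @param hyper List with elements `mu` (matrix, one row per group, ordered
#'   as `sort(unique(data$group))` or named), `tau` (positive 17-vector),
#'   `corr` (17 x 17 correlation matrix), `z` (participants x 17 matrix of
#'   standardized offsets, rows ordered as sorted participant ids), and
#'   `lambda`.
#' @param prior Prior settings from [lba_prior()].
#' @param t_max Contaminant RT bound; defaults to the maximum observed RT
#'   (must be supplied for zero-row data).
#' @return Scalar log density (`-Inf` outside the support).
#' @export
joint_log_posterior <- function(data, hyper, prior = lba_prior(),
                                t_max = NULL) {
  mu <- as.matrix(hyper$mu)
  tau <- hyper$tau
  corr <- hyper$corr
  z <- as.matrix(hyper$z)
  lambda <- hyper$lambda
  stopifnot(ncol(mu) == 17L, length(tau) == 17L, all(dim(corr) == 17L))
  if (any(tau <= 0) || lambda < 0 || lambda > 1) return(-Inf)
  L <- tryCatch(t(chol(corr)), error = function(e) NULL)
  if (is.null(L)) return(-Inf)

  lp <- sum(dnorm(mu, 0, prior$mu_sd, log = TRUE)) +
    hw_sigma_log(tau, corr, prior$tau_df, prior$tau_scale) +
    sum(dnorm(z, 0, 1, log = TRUE)) +
    dbeta(lambda, prior$lambda_a, prior$lambda_b, log = TRUE)

  if (nrow(data) > 0) {
    if (is.null(t_max)) t_max <- max(data$rt_seconds)
    enc <- encode_trials(data)
    grp_levels <- if (!is.null(rownames(mu))) rownames(mu) else sort(unique(enc$group))
    gi <- match(enc$group, grp_levels)
    if (anyNA(gi)) stop("group labels of data and hyper$mu do not match")
    if (nrow(z) != enc$n) stop("hyper$z must have one row per participant")
    theta_u <- mu[gi, , drop = FALSE] + z %*% t(diag(tau) %*% L)
    theta_c <- constrain_params(theta_u)
    ll <- .dataset_loglik_cpp(enc$rt, enc$resp, enc$mode, enc$kw, enc$kw1c,
                              enc$kw2c, enc$pid, theta_c, lambda, t_max, FALSE)
    lp <- lp + ll$total
  }
  lp
}

#' Fit the hierarchical LBA model
#'
#' Posterior sampling uses a blocked adaptive Metropolis-within-Gibbs
#' scheme written for this model.  Individual parameter vectors mix through
#' adaptive random-walk sweeps, slice-sampled line moves along the
#' principal axes of the stiff (A, b, t0) ridge, and conditional-prior
#' independence refreshes of each drift/boost component evaluated on the
#' rows it affects.  The group level mixes through exact conjugate Gibbs
#' draws of the mean vectors plus joint translation moves (full-vector
#' random walk and per-component slices) that move a group mean together
#' with its members.  The shared covariance has exact conjugate Gibbs
#' updates under the Huang-Wand prior, interleaved with joint scale moves
#' (a component of every individual, Sigma's row/column, and the
#' Huang-Wand auxiliary rescaled together) that eliminate the scale
#' funnel.  The contaminant proportion uses logit-scale random walks over
#' cached race densities.  All tuning happens during warmup and is frozen
#' afterwards; runs are deterministic given `config$seed`.
#'
#' @param data Trial table with both groups (or a declared subset) and the
#'   response/RT columns of [simulate_dataset()].
#' @param config A [sampler_config()].
#' @param prior A [lba_prior()].
#' @param init Initial-value strategy: `"random"` draws every unconstrained
#'   quantity uniformly from (-0.5, 0.5) per chain.
#' @return An object of class `lba_fit`: constrained draws array
#'   `[iteration, chain, parameter]` covering group-level parameters
#'   (constrained group means, scales, correlations, lambda) and
#'   individual-level constrained parameters, plus unconstrained states,
#'   acceptance rates, data encoding and metadata.
#' @export
fit_lba <- function(data, config = sampler_config(), prior = lba_prior(),
                    init = "random") {
  stopifnot(inherits(config, "sampler_config"))
  if (nrow(data) == 0) stop("cannot fit an empty trial table")
  enc <- encode_trials(data)
  grp_levels <- sort(unique(enc$group))
  if (length(grp_levels) > 2) stop("at most two groups are supported")
  gi <- match(enc$group, grp_levels) - 1L
  if (length(grp_levels) == 1L) gi <- rep(0L, enc$n)
  t_max <- max(enc$rt)
  d <- 17L
  n <- enc$n
  n_save <- config$sampling_iterations

  chains <- with_seed(config$seed, {
    lapply(seq_len(config$chains), function(ch) {
      init_state <- list(
        theta = matrix(runif(n * d, -0.5, 0.5), n, d),
        mu = matrix(runif(2 * d, -0.5, 0.5), 2, d),
        Sigma = diag(exp(runif(d, -0.5, 0.5))^2),
        lambda = plogis(runif(1, -0.5, 0.5)))
      .run_lba_chain_cpp(
        rows = enc[c("rt", "resp", "mode", "kw", "kw1c", "kw2c")],
        row_start = as.integer(enc$row_start), group = as.integer(gi),
        tmax = t_max, n_warmup = config$warmup_iterations,
        n_save = n_save, n_thin = config$thin, n_inner = config$inner_sweeps,
        n_lambda_steps = config$lambda_steps, init = init_state,
        prior = prior, target_accept = config$target_acceptance)
    })
  })

  pnames <- lba_param_names()
  grp_names <- c(grp_levels, setdiff(c("g1", "g2"), grp_levels))[1:2]
  mu_names <- as.vector(vapply(grp_names, function(g) paste0("mu_", g, "[", pnames, "]"),
                               character(d)))
  tau_names <- paste0("tau[", pnames, "]")
  corr_idx <- which(lower.tri(matrix(0, d, d)), arr.ind = TRUE)
  corr_idx <- corr_idx[order(corr_idx[, "col"], corr_idx[, "row"]), , drop = FALSE]
  corr_names <- paste0("corr[", pnames[corr_idx[, "row"]], ",",
                       pnames[corr_idx[, "col"]], "]")
  theta_names <- as.vector(vapply(enc$participants,
                                  function(p) paste0("theta_", p, "[", pnames, "]"),
                                  character(d)))

  # constrained group-level draws: transform mu through the constraint map
  n_chain <- length(chains)
  all_names <- c(mu_names, tau_names, corr_names, "lambda", theta_names)
  draws <- array(NA_real_, dim = c(n_save, n_chain, length(all_names)),
                 dimnames = list(NULL, paste0("chain", seq_len(n_chain)), all_names))
  unconstrained <- list(mu = array(NA_real_, c(n_save, n_chain, 2 * d)),
                        theta = array(NA_real_, c(n_save, n_chain, n * d)))
  for (ch in seq_len(n_chain)) {
    res <- chains[[ch]]
    mu_c <- cbind(constrain_params(res$mu[, 1:d, drop = FALSE]),
                  constrain_params(res$mu[, d + 1:d, drop = FALSE]))
    draws[, ch, seq_len(2 * d)] <- mu_c
    draws[, ch, 2 * d + seq_len(d)] <- res$tau
    draws[, ch, 3 * d + seq_len(nrow(corr_idx))] <- res$corr
    draws[, ch, 3 * d + nrow(corr_idx) + 1L] <- res$lambda
    th_c <- res$theta
    for (i in seq_len(n)) {
      cols <- (i - 1L) * d + seq_len(d)
      th_c[, cols] <- constrain_params(res$theta[, cols, drop = FALSE])
    }
    draws[, ch, 3 * d + nrow(corr_idx) + 1L + seq_len(n * d)] <- th_c
    unconstrained$mu[, ch, ] <- res$mu
    unconstrained$theta[, ch, ] <- res$theta
  }

  structure(list(
    draws = draws, unconstrained = unconstrained,
    accept = lapply(chains, `[[`, "accept"),
    groups = grp_levels, participants = enc$participants,
    participant_group = enc$group, t_max = t_max,
    config = config, prior = prior, data = data,
    group_param_names = c(mu_names, tau_names, "lambda"),
    param_names = pnames,
    data_hash = dataset_hash(data)), class = "lba_fit")
}

#' @export
print.lba_fit <- function(x, ...) {
  cat("Hierarchical LBA fit:", length(x$participants), "participants (",
      paste(x$groups, collapse = ", "), "),",
      dim(x$draws)[2], "chains x", dim(x$draws)[1], "retained draws\n")
  acc <- colMeans(do.call(rbind, lapply(x$accept, function(a)
    unlist(a, use.names = TRUE))))
  cat(sprintf("Mean acceptance: theta %.2f, sigma %.2f, lambda %.2f\n",
              acc["theta"], acc["sigma"], acc["lambda"]))
  invisible(x)
}

# lightweight content hash (sum-based; stable across sessions)
dataset_hash <- function(data) {
  v <- c(nrow(data), sum(as.numeric(data$rt_seconds)),
         sum(match(as.character(data$response), response_levels())))
  sprintf("%.0f-%.6f-%.0f", v[1], v[2], v[3])
}

#' Extract posterior draws of group-level parameters
#'
#' @param fit An `lba_fit` object.
#' @param which Subset of parameter names (defaults to all group-level
#'   names: constrained group means, scales, lambda).
#' @return Draws array `[iteration, chain, parameter]`.
#' @export
group_draws <- function(fit, which = fit$group_param_names) {
  fit$draws[, , which, drop = FALSE]
}

#' Reconstruct standardized individual offsets from stored draws
#'
#' Inverts the non-centered identity `theta_i = mu_g + diag(tau) L z_i`
#' draw by draw, returning the `z` offsets consistent with the stored
#' states.
#'
#' @param fit An `lba_fit` object.
#' @param iterations,chains Subsets to reconstruct (defaults: all).
#' @return Array `[iteration, chain, participant x parameter]`.
#' @export
reconstruct_offsets <- function(fit, iterations = NULL, chains = NULL) {
  d <- 17L
  n <- length(fit$participants)
  it <- if (is.null(iterations)) seq_len(dim(fit$draws)[1]) else iterations
  chs <- if (is.null(chains)) seq_len(dim(fit$draws)[2]) else chains
  gi <- match(fit$participant_group, fit$groups)
  corr_cols <- grep("^corr\\[", dimnames(fit$draws)[[3]])
  tau_cols <- grep("^tau\\[", dimnames(fit$draws)[[3]])
  out <- array(NA_real_, c(length(it), length(chs), n * d))
  for (ci in seq_along(chs)) {
    for (ii in seq_along(it)) {
      tau <- fit$draws[it[ii], chs[ci], tau_cols]
      C <- diag(d)
      C[lower.tri(C)] <- fit$draws[it[ii], chs[ci], corr_cols]
      C <- C + t(C) - diag(d)
      L <- t(chol(C))
      M <- diag(tau) %*% L
      mu <- matrix(fit$unconstrained$mu[it[ii], chs[ci], ], 2, d, byrow = TRUE)
      theta <- matrix(fit$unconstrained$theta[it[ii], chs[ci], ], n, d, byrow = TRUE)
      z <- t(forwardsolve(M, t(theta - matrix(mu[gi, ], n, d))))
      out[ii, ci, ] <- as.vector(t(z))
    }
  }
  out
}
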