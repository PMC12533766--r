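# small fit reused across tests in this file (2 participants/group,
# 4 trials/mode, short chains) — enough to exercise the whole machinery
fit_cache <- local({
  dat <- small_cohort(n_per_group = 2, trials_per_mode = 4, seed = 42)
  fit <- fit_lba(dat, sampler_config(chains = 2, warmup_iterations = 150,
                                     sampling_iterations = 150, thin = 1,
                                     seed = 99))
  list(dat = dat, fit = fit)
})

test_that("the joint log posterior obeys the empty-sum and additivity identities", {
  dat <- fit_cache$dat
  n <- length(unique(dat$participant_id))
  hyper <- list(mu = matrix(0, 2, 17, dimnames = list(c("AH", "CI"), NULL)),
                tau = rep(1, 17), corr = diag(17),
                z = matrix(0.1, n, 17), lambda = 0.05)
  empty <- dat[0, ]
  lp0 <- joint_log_posterior(empty, hyper, t_max = 10)
  expect_true(is.finite(lp0))
  lp1 <- joint_log_posterior(dat, hyper, t_max = 10)
  # duplicating every row doubles the likelihood term, prior unchanged
  dat2 <- rbind(dat, dat)
  lp2 <- joint_log_posterior(dat2, hyper, t_max = 10)
  expect_equal(lp2 - lp0, 2 * (lp1 - lp0), tolerance = 1e-8)
  # out-of-support hyperparameters give -Inf
  bad <- hyper; bad$tau[1] <- -1
  expect_identical(joint_log_posterior(dat, bad, t_max = 10), -Inf)
  bad2 <- hyper; bad2$lambda <- 1.5
  expect_identical(joint_log_posterior(dat, bad2, t_max = 10), -Inf)
})

test_that("the posterior stays finite for responses faster than the non-decision time", {
  dat <- fit_cache$dat[1:6, ]
  dat$rt_seconds[1] <- 0.05  # below any admissible t0 (>= 0.150 s)
  n <- length(unique(dat$participant_id))
  hyper <- list(mu = matrix(0, 2, 17, dimnames = list(c("AH", "CI"), NULL)),
                tau = rep(0.5, 17), corr = diag(17),
                z = matrix(0, n, 17), lambda = 0.02)
  expect_true(is.finite(joint_log_posterior(dat, hyper, t_max = 10)))
})

test_that("fits retain chains x sampling_iterations draws with t0 above 150 ms", {
  fit <- fit_cache$fit
  expect_equal(dim(fit$draws)[1:2], c(150L, 2L))
  pn <- dimnames(fit$draws)[[3]]
  t0_cols <- grep("\\[t0\\]$", pn[grep("^mu_|^theta_", pn)], value = TRUE)
  for (nm in t0_cols) expect_true(all(fit$draws[, , nm] >= 0.150))
  A_cols <- grep("^theta_.*\\[A\\]$", pn, value = TRUE)
  b_cols <- sub("\\[A\\]", "[b]", A_cols)
  for (k in seq_along(A_cols))
    expect_true(all(fit$draws[, , b_cols[k]] > fit$draws[, , A_cols[k]]))
})

test_that("fits are deterministic given the seed", {
  dat <- fit_cache$dat
  cfg <- sampler_config(chains = 2, warmup_iterations = 50,
                        sampling_iterations = 50, thin = 1, seed = 123)
  f1 <- fit_lba(dat, cfg)
  f2 <- fit_lba(dat, cfg)
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_lba(dat, sampler_config(chains = 2, warmup_iterations = 50,
                                    sampling_iterations = 50, thin = 1,
                                    seed = 124))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("stored draws satisfy the non-centered reconstruction identity", {
  fit <- fit_cache$fit
  z <- reconstruct_offsets(fit, iterations = c(1, 75, 150), chains = 1:2)
  gi <- match(fit$participant_group, fit$groups)
  d <- 17L
  n <- length(fit$participants)
  pn <- dimnames(fit$draws)[[3]]
  tau_cols <- grep("^tau\\[", pn)
  corr_cols <- grep("^corr\\[", pn)
  for (ci in 1:2) for (ii in seq_along(c(1, 75, 150))) {
    it <- c(1, 75, 150)[ii]
    tau <- fit$draws[it, ci, tau_cols]
    C <- diag(d); C[lower.tri(C)] <- fit$draws[it, ci, corr_cols]
    C <- C + t(C) - diag(d)
    L <- t(chol(C))
    mu_u <- matrix(fit$unconstrained$mu[it, ci, ], 2, d, byrow = TRUE)
    for (i in seq_len(n)) {
      zi <- z[ii, ci, (i - 1) * d + seq_len(d)]
      theta_u <- mu_u[gi[i], ] + as.vector(diag(tau) %*% L %*% zi)
      stored <- fit$draws[it, ci, paste0("theta_", fit$participants[i], "[",
                                         fit$param_names, "]")]
      expect_equal(unname(constrain_params(theta_u)), unname(stored),
                   tolerance = 1e-10)
    }
  }
})

test_that("prior-predictive hyperdraws simulate valid trial tables", {
  set.seed(404)
  gm <- list(AH = rnorm(17, 0, 1), CI = rnorm(17, 0, 1))
  # keep drifts plausible so races finish in finite time at test scale
  gm$AH[c(1, 5, 9)] <- abs(gm$AH[c(1, 5, 9)]) + 1
  gm$CI[c(1, 5, 9)] <- abs(gm$CI[c(1, 5, 9)]) + 1
  tau <- abs(2.5 * rt(17, 3)) / 5
  pop <- true_population(group_means = gm, scales = tau,
                         contaminant_prop = rbeta(1, 1, 19))
  dat <- simulate_dataset(design_spec(n_per_group = 2, trials_per_mode = 2),
                          pop, seed = 405)
  expect_false(anyNA(dat$rt_seconds))
  expect_true(all(dat$rt_seconds > 0))
  expect_false(anyNA(dat$response))
})

test_that("split-Rhat and ESS behave on null, shifted and degenerate chains", {
  set.seed(500)
  # independent draws: Rhat in [0.999, 1.005], ESS near the draw count
  x <- matrix(rnorm(4 * 2000), 2000, 4)
  expect_gt(split_rhat(x), 0.999)
  expect_lt(split_rhat(x), 1.005)
  e <- ess_draws(x)
  expect_gt(e[["ess_bulk"]], 0.5 * 8000)
  # one chain shifted by 5 SDs: flagged as non-converged
  y <- x; y[, 1] <- y[, 1] + 5
  expect_gt(split_rhat(y), 1.2)
  # constant chains: degenerate
  z <- matrix(1, 2000, 4)
  expect_true(is.nan(split_rhat(z)))
  a <- array(c(x, y, z), c(2000, 4, 3),
             dimnames = list(NULL, NULL, c("null", "shifted", "const")))
  dg <- convergence_diagnostics(a)
  expect_equal(dg$flag, c("ok", "nonconverged", "degenerate"))
  expect_error(convergence_diagnostics(a[, 1, , drop = FALSE]), "2 chains")
})

test_that("Rhat and ESS agree with the coda cross-check on autocorrelated chains", {
  set.seed(501)
  # AR(1) chains with known persistence
  ar <- function(n, rho) as.vector(arima.sim(list(ar = rho), n))
  x <- cbind(ar(2000, 0.8), ar(2000, 0.8), ar(2000, 0.8), ar(2000, 0.8))
  ml <- coda::mcmc.list(lapply(1:4, function(j) coda::mcmc(x[, j])))
  ours <- ess_draws(x)[["ess_bulk"]]
  theirs <- sum(coda::effectiveSize(ml))
  expect_lt(abs(ours - theirs) / theirs, 0.5)  # same order, both ~ n(1-rho)/(1+rho)
  expect_lt(split_rhat(x), 1.02)
  expect_lt(abs(split_rhat(x) -
                coda::gelman.diag(ml, autoburnin = FALSE)$psrf[1]), 0.02)
})

test_that("posterior predictive replication matches the observed design", {
  fit <- fit_cache$fit
  expect_identical(posterior_predictive_simulate(fit, 0), list())
  reps <- posterior_predictive_simulate(fit, 3, seed = 8)
  expect_length(reps, 3L)
  for (r in reps) {
    expect_equal(nrow(r), nrow(fit$data))
    expect_true(all(r$rt_seconds > 0))
    expect_identical(sort(unique(r$participant_id)),
                     sort(unique(fit$data$participant_id)))
  }
  gap <- ppc_accuracy_gap(fit$data, list(fit$data))
  expect_true(all(gap$gap_points == 0))
  # misspecified replicates are detected as a large accuracy gap
  bad <- fit$data
  bad$response <- factor("neither", levels = response_levels())
  expect_gt(max(ppc_accuracy_gap(fit$data, list(bad))$gap_points), 5)
  expect_error(ppc_accuracy_gap(fit$data, list(fit$data[1:10, ])),
               "does not match")
})
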