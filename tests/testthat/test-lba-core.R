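test_that("accumulator CDF has the correct boundary and limit behaviour", {
  expect_equal(lba_cdf(0, 0.5, 1, 1), 0)
  expect_equal(lba_cdf(1e-9, 0.5, 1, 1), 0, tolerance = 1e-6)
  # limit t -> Inf equals the probability of a positive drift draw
  expect_equal(lba_cdf(1e6, 0.5, 1, 1), pnorm(1), tolerance = 1e-6)
  expect_equal(lba_cdf(1e6, 0.8, 1.6, -0.5), pnorm(-0.5), tolerance = 1e-5)
  # monotone non-decreasing
  grid <- seq(0, 20, length.out = 400)
  expect_true(all(diff(lba_cdf(grid, 0.5, 1, 1)) >= -1e-12))
  expect_error(lba_cdf(-1, 0.5, 1, 1), "non-negative")
})

test_that("accumulator CDF matches the empirical CDF of simulated accumulators", {
  A <- 0.5; b <- 1; v <- 1
  set.seed(101)
  n <- 1e6
  start <- runif(n, 0, A)
  drift <- rnorm(n, v, 1)
  tt <- ifelse(drift > 0, (b - start) / drift, Inf)
  for (t0 in c(0.3, 1.0, 3.0))
    expect_lt(abs(lba_cdf(t0, A, b, v) - mean(tt <= t0)), 0.002)
})

test_that("accumulator PDF is the derivative of the CDF and integrates to Phi(v/s)", {
  A <- 0.5; b <- 1; v <- 1
  expect_equal(lba_pdf(0, A, b, v), 0)
  h <- 1e-5
  num <- (lba_cdf(1 + h, A, b, v) - lba_cdf(1 - h, A, b, v)) / (2 * h)
  expect_equal(lba_pdf(1, A, b, v), num, tolerance = 1e-5)
  total <- integrate(function(t) lba_pdf(t, A, b, v), 0, Inf)$value
  expect_equal(total, pnorm(1), tolerance = 1e-4)
  # derivative consistency on a grid, including a negative drift
  # (absolute bound: densities span orders of magnitude across the grid)
  for (vv in c(-0.5, 0.7, 2)) {
    ts <- c(0.2, 0.5, 1, 2, 5)
    num <- (lba_cdf(ts + h, A, b, vv) - lba_cdf(ts - h, A, b, vv)) / (2 * h)
    expect_lt(max(abs(lba_pdf(ts, A, b, vv) - num)), 1e-5)
  }
})

test_that("race defective densities are symmetric, dominated, and sum to P(finish)", {
  A <- 0.8; b <- 1.3
  # four identical accumulators: equal mass 1/4 of P(any finishes)
  drifts <- rep(1.2, 4)
  mass <- vapply(1:4, function(r)
    trapz_int(function(t) exp(race_log_density(t, r, drifts, A, b)), 1e-6, 60),
    numeric(1))
  expect_equal(max(mass) - min(mass), 0, tolerance = 1e-8)
  expect_lte(sum(mass), 1 + 1e-6)
  expect_equal(sum(mass), 1 - (1 - pnorm(1.2))^4, tolerance = 0.02)
  # dominance: one huge drift takes all the mass (its first-passage density
  # is concentrated near (b - A)/30, so integrate on a fine local grid)
  drifts2 <- c(30, 0.3, 0.3, 0.3)
  m1 <- trapz_int(function(t) exp(race_log_density(t, 1, drifts2, A, b)),
                  1e-6, 3, n = 20000)
  m2 <- trapz_int(function(t) exp(race_log_density(t, 2, drifts2, A, b)),
                  1e-6, 60, n = 20000)
  expect_equal(m1, 1, tolerance = 1e-3)
  expect_lt(m2, 1e-3)
  expect_identical(race_log_density(-1, 1, drifts, A, b), -Inf)
})

test_that("race choice probabilities match Monte-Carlo simulation within 0.01", {
  p <- flat_params(v_correct = 1.5, v_err = 0.6)
  drifts <- p[1:4]
  mass <- vapply(1:4, function(r)
    trapz_int(function(t) exp(race_log_density(t, r, drifts, p["A"], p["b"])),
              1e-6, 80), numeric(1))
  sim <- simulate_trial(p, "audio", 1, lambda = 0, t_max = 10, n = 1e5, seed = 7)
  props <- as.vector(table(sim$response)) / nrow(sim)
  # simulator redraws the all-fail event; renormalize the quadrature masses
  expect_equal(props, as.vector(mass / sum(mass)), tolerance = 0.01)
})

test_that("mixture likelihood handles contaminant limits exactly", {
  p <- flat_params()
  # pure contaminant: flat in response and rt
  expect_equal(trial_log_likelihood(0.5, "correct", p, "audio", 1,
                                    lambda = 1, t_max = 8), log(1 / (4 * 8)))
  expect_equal(trial_log_likelihood(5, "neither", p, "video", 1,
                                    lambda = 1, t_max = 8), log(1 / (4 * 8)))
  # rt below t0: only the contaminant carries mass
  expect_equal(trial_log_likelihood(0.2, "correct", p, "audio", 1,
                                    lambda = 0.02, t_max = 10),
               log(0.02 / (4 * 10)))
  # lambda = 0, rt > t0: equals the race density at rt - t0
  rt <- 1.1
  expect_equal(trial_log_likelihood(rt, "semantic", p, "captions", 1,
                                    lambda = 0, t_max = 10),
               race_log_density(rt - p["t0"], 2, p[9:12], p["A"], p["b"])[1])
  expect_error(trial_log_likelihood(11, "correct", p, "audio", 1,
                                    lambda = 0.02, t_max = 10), "t_max")
  expect_error(trial_log_likelihood(1, "correct", p, "audio", 1,
                                    lambda = 2, t_max = 10), "lambda")
})

test_that("dataset log likelihood is invariant to row order and matches per-trial sums", {
  dat <- small_cohort()
  p <- flat_params()
  ll1 <- dataset_log_likelihood(dat, p, lambda = 0.02, t_max = 10)
  perm <- sample(nrow(dat))
  ll2 <- dataset_log_likelihood(dat[perm, ], p, lambda = 0.02, t_max = 10)
  expect_equal(ll1, ll2, tolerance = 1e-10)
  rows <- dataset_log_likelihood(dat, p, lambda = 0.02, t_max = 10,
                                 per_row = TRUE)
  expect_equal(rows$total, sum(rows$per_row))
  manual <- sum(vapply(seq_len(nrow(dat)), function(i)
    trial_log_likelihood(dat$rt_seconds[i], as.character(dat$response[i]), p,
                         as.character(dat$mode[i]), dat$keyword_index[i],
                         isTRUE(dat$kw1_correct[i]), isTRUE(dat$kw2_correct[i]),
                         lambda = 0.02, t_max = 10), numeric(1)))
  expect_equal(ll1, manual, tolerance = 1e-8)
})

test_that("simulated response/RT distributions match the mixture density (KS < 0.01)", {
  # parameter sets keep the all-fail probability below ~0.4% so the
  # no-renormalization likelihood and the redrawing simulator agree to
  # within the KS tolerance; categories need >= 20,000 draws for the KS
  # noise floor (~0.87/sqrt(n)) to sit safely under 0.01
  par_sets <- list(
    flat_params(v_correct = 2.0, v_err = 0.5),
    flat_params(v_correct = 2.2, v_err = -0.4),   # negative error drift
    flat_params(v_correct = 3.0, v_err = 0.8, A = 0.4, b = 1.0, t0 = 0.2))
  lambda <- 0.02; t_max <- 10
  checked <- 0L
  for (si in seq_along(par_sets)) {
    p <- par_sets[[si]]
    sim <- simulate_trial(p, "audio", 1, lambda = lambda, t_max = t_max,
                          n = 2e5, seed = 300 + si)
    grid <- seq(1e-4, t_max, length.out = 6000)
    for (r in 1:4) {
      rts <- sim$rt_seconds[as.integer(sim$response) == r]
      if (length(rts) < 20000) next
      dens <- (1 - lambda) *
        exp(race_log_density(grid - p["t0"], r, p[1:4], p["A"], p["b"])) +
        lambda * 0.25 / t_max
      dens[grid <= p["t0"]] <- lambda * 0.25 / t_max
      cdf <- cumsum(c(0, (dens[-1] + dens[-length(dens)]) / 2 * diff(grid)))
      emp <- ecdf(rts)
      ks <- max(abs(emp(grid) - cdf / max(cdf)))
      expect_lt(ks, 0.01)
      checked <- checked + 1L
    }
  }
  expect_gte(checked, 4L)  # every set contributes at least its majority category
})

test_that("effective drifts apply boosts to the correct accumulator only", {
  p <- flat_params(v_correct = 2.0, v_err = 0.5, boost2 = 0.4, boost3 = 0.7)
  # keyword 2 after a correct keyword 1
  v <- effective_drifts(p, "audio", 2, kw1_correct = TRUE)
  expect_equal(unname(v), c(2.4, 0.5, 0.5, 0.5))
  # keyword 1 never boosted
  expect_equal(unname(effective_drifts(p, "video", 1)), c(2, 0.5, 0.5, 0.5))
  # keyword 3 needs both previous keywords correct
  expect_equal(unname(effective_drifts(p, "audio", 3, kw1_correct = TRUE,
                                       kw2_correct = FALSE)),
               c(2, 0.5, 0.5, 0.5))
  expect_equal(unname(effective_drifts(p, "audio", 3, kw1_correct = TRUE,
                                       kw2_correct = TRUE)),
               c(2.7, 0.5, 0.5, 0.5))
})

test_that("parameter constraints hold by construction and invert exactly", {
  u <- rnorm(17)
  p <- constrain_params(u)
  expect_gt(p["A"], 0)
  expect_gt(p["b"], p["A"])
  expect_gte(p["t0"], 0.150)
  expect_equal(unconstrain_params(p), setNames(u, lba_param_names()),
               tolerance = 1e-12)
  expect_length(lba_param_names(), 17L)
  expect_error(unconstrain_params(c(rep(0, 14), -1, 1, 0.3)), "constraints")
})
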