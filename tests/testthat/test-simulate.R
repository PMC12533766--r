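test_that("individual parameters follow the population distribution", {
  pop <- true_population()
  # degenerate: zero scales reproduce the group mean exactly
  pop0 <- true_population(scales = rep(0, 17))
  dr <- draw_individual_parameters(pop0, "CI", 5, seed = 1)
  for (i in 1:5)
    expect_equal(unname(dr$unconstrained[i, ]),
                 unname(pop0$group_means$CI), tolerance = 1e-12)
  # identity correlation: near-zero sample correlations at n = 10,000
  dr2 <- draw_individual_parameters(pop, "AH", 10000, seed = 2)
  for (pair in list(c(1, 2), c(3, 15), c(13, 17)))
    expect_lt(abs(cor(dr2$unconstrained[, pair[1]],
                      dr2$unconstrained[, pair[2]])), 0.05)
  # CLT: sample means within 3 SE of the group mean at n = 5,000
  dr3 <- draw_individual_parameters(pop, "CI", 5000, seed = 3)
  se <- pop$scales / sqrt(5000)
  dev <- abs(colMeans(dr3$unconstrained) - pop$group_means$CI)
  expect_true(all(dev <= 3 * se + 1e-12))
  # non-PD correlation is rejected
  badc <- diag(17); badc[1, 2] <- badc[2, 1] <- 1.2
  expect_error(true_population(correlation = badc), "positive definite")
})

test_that("pure-contaminant trials are uniform in response and RT", {
  p <- flat_params()
  sim <- simulate_trial(p, "audio", 1, lambda = 1, t_max = 6, n = 10000,
                        seed = 11)
  props <- as.vector(table(sim$response)) / nrow(sim)
  expect_gt(chisq.test(table(sim$response))$p.value, 0.01)
  expect_true(all(abs(props - 0.25) < 0.02))
  expect_gt(ks.test(sim$rt_seconds, "punif", 0, 6)$p.value, 0.01)
})

test_that("race trials respect the non-decision floor and drift symmetry", {
  p <- flat_params(v_correct = 1, v_err = 1)  # four equal drifts
  sim0 <- simulate_trial(p, "video", 1, lambda = 0, n = 2000, seed = 12)
  expect_true(all(sim0$rt_seconds > p["t0"]))
  sim <- simulate_trial(p, "video", 1, lambda = 0, n = 1e5, seed = 13)
  props <- as.vector(table(sim$response)) / nrow(sim)
  expect_true(all(abs(props - 0.25) < 0.01))
})

test_that("simulated accuracy is monotone in the correct drift", {
  acc <- vapply(c(1.0, 1.6, 2.2, 2.8), function(v) {
    sim <- simulate_trial(flat_params(v_correct = v), "audio", 1, lambda = 0,
                          n = 10000, seed = 14)
    mean(sim$response == "correct")
  }, numeric(1))
  expect_true(all(diff(acc) > 0))
})

test_that("the full default dataset has exactly 18,000 context-consistent rows", {
  dat <- simulate_dataset(design_spec(), true_population(), seed = 20)
  expect_equal(nrow(dat), 18000L)
  expect_true(all(dat$rt_seconds > 0))
  expect_false(anyNA(dat$response))
  # context consistency: kw2 flag == (keyword-1 response correct), always
  key <- paste(dat$participant_id, dat$trial_id)
  corr1 <- (dat$response == "correct")[dat$keyword_index == 1]
  names(corr1) <- key[dat$keyword_index == 1]
  k2 <- dat$keyword_index == 2
  expect_identical(dat$kw1_correct[k2], unname(corr1[key[k2]]))
  corr2 <- (dat$response == "correct")[dat$keyword_index == 2]
  names(corr2) <- key[dat$keyword_index == 2]
  k3 <- dat$keyword_index == 3
  expect_identical(dat$kw1_correct[k3], unname(corr1[key[k3]]))
  expect_identical(dat$kw2_correct[k3], unname(corr2[key[k3]]))
})

test_that("identical seeds reproduce the dataset byte for byte", {
  a <- simulate_dataset(design_spec(n_per_group = 3), true_population(), seed = 5)
  b <- simulate_dataset(design_spec(n_per_group = 3), true_population(), seed = 5)
  attr(a, "truth") <- attr(b, "truth") <- NULL
  expect_identical(a, b)
  c <- simulate_dataset(design_spec(n_per_group = 3), true_population(), seed = 6)
  expect_false(identical(a$rt_seconds, c$rt_seconds))
})

test_that("serial-dependency boosts raise keyword-2 accuracy after correct keyword 1", {
  nm <- lba_param_names()
  mk_pop <- function(b2) {
    gm <- default_group_means()
    gm$AH[13] <- gm$CI[13] <- b2
    gm$AH[14] <- gm$CI[14] <- 0
    true_population(group_means = gm, scales = rep(0, 17),
                    contaminant_prop = 0)
  }
  spec <- design_spec(n_per_group = 25, seed = 30)
  # very large boost: keyword-2 accuracy (given kw1 correct) >= keyword-1
  big <- simulate_dataset(spec, mk_pop(6), seed = 31)
  acc1 <- mean(big$response[big$keyword_index == 1] == "correct")
  acc2 <- mean(big$response[big$keyword_index == 2 & big$kw1_correct] == "correct")
  expect_gte(acc2, acc1)
  # zero boosts: keyword-2 accuracy independent of keyword-1 context
  none <- simulate_dataset(spec, mk_pop(0), seed = 32)
  k2 <- none[none$keyword_index == 2, ]
  tab <- table(k2$kw1_correct, k2$response == "correct")
  expect_gt(chisq.test(tab)$p.value, 0.001)
})

test_that("preference counts are multinomial with conserved totals", {
  # degenerate probabilities give a deterministic count vector
  vp <- data.frame(group = "CI", conversation = "A",
                   mode = c("audio", "video", "captions"),
                   prob = c(1, 0, 0))
  cnt <- simulate_preferences(vp, n_per_group = 50, seed = 1)
  expect_equal(cnt$count, c(50L, 0L, 0L))
  # totals are conserved in every cell
  counts <- simulate_preferences(default_vote_probs(), n_per_group = 50, seed = 2)
  totals <- tapply(counts$count, interaction(counts$group, counts$conversation),
                   sum)
  expect_true(all(totals == 50L))
  # long-run mean of the captions cell tracks its probability (0.92 * 50 = 46)
  vp2 <- data.frame(group = "CI", conversation = "A",
                    mode = c("captions", "video", "audio"),
                    prob = c(0.92, 0.06, 0.02))
  means <- vapply(1:200, function(s)
    simulate_preferences(vp2, 50, seed = s)$count[1], numeric(1))
  expect_equal(mean(means), 46, tolerance = 0.02)
  # invalid probabilities are rejected
  vp3 <- vp2; vp3$prob <- c(0.9, 0.2, 0.02)
  expect_error(simulate_preferences(vp3), "sum to 1")
})
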