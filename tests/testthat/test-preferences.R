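make_counts <- function(ci_captions = 46) {
  cnt <- expand.grid(mode = mode_levels(), group = c("AH", "CI"),
                     conversation = c("A", "B", "C"),
                     stringsAsFactors = FALSE)
  cnt$count <- 5L
  # conversation A, CI: a 46-of-50 captions majority
  cnt$count[cnt$group == "CI" & cnt$conversation == "A"] <-
    c(2L, 50L - ci_captions - 2L, ci_captions)
  cnt$count[cnt$group == "AH"] <- rep(c(4L, 32L, 14L), 3)
  cnt$count[cnt$group == "CI" & cnt$conversation != "A"] <-
    rep(c(3L, 13L, 34L), 2)
  cnt
}

test_that("percentage table converts counts to within-cell vote shares", {
  cnt <- make_counts()
  pt <- percentage_table(cnt)
  expect_equal(pt$pct[pt$group == "CI" & pt$conversation == "A" &
                      pt$mode == "captions"], 92)
  expect_equal(pt$pct[pt$group == "CI" & pt$conversation == "A" &
                      pt$mode == "audio"], 4)
  # shares sum to 100 in every cell
  sums <- tapply(pt$pct, interaction(pt$group, pt$conversation), sum)
  expect_true(all(abs(sums - 100) < 0.01))
  # boundary values
  cnt0 <- cnt; cnt0$count[cnt0$group == "CI" & cnt0$conversation == "B"] <- c(25L, 25L, 0L)
  pt0 <- percentage_table(cnt0)
  expect_equal(pt0$pct[pt0$group == "CI" & pt0$conversation == "B"],
               c(50, 50, 0))
})

test_that("count validation catches malformed tables", {
  cnt <- make_counts()
  expect_error(fit_poisson_model(cnt[-1, ], "three_way"), "complete factorial")
  bad <- cnt; bad$count[1] <- 2.5
  expect_error(fit_poisson_model(bad, "three_way"), "non-negative integers")
  bad2 <- cnt; bad2$count[1] <- -1L
  expect_error(fit_poisson_model(bad2, "three_way"), "non-negative integers")
})

test_that("the saturated model reproduces observed counts and their order", {
  cnt <- make_counts()
  post <- fit_poisson_model(cnt, "three_way", chains = 2, warmup = 1000,
                            samples = 1000, seed = 3)
  expect_equal(nrow(post$beta), 2000L)
  ce <- conditional_effects(post)
  big <- ce$count >= 10
  expect_true(all(abs(ce$predicted_median[big] - ce$count[big]) /
                  ce$count[big] < 0.15))
  # the 46-of-50 cell has a CrI containing 46
  cell <- ce[ce$group == "CI" & ce$conversation == "A" & ce$mode == "captions", ]
  expect_lt(cell$cri_lower, 46)
  expect_gt(cell$cri_upper, 46)
  # monotone: strictly larger observed counts get larger predicted medians
  for (i in seq_len(nrow(ce))) for (j in seq_len(nrow(ce)))
    if (ce$count[i] > ce$count[j])
      expect_gt(ce$predicted_median[i], ce$predicted_median[j])
})

test_that("equal counts give null coefficients; two-way pools conversations", {
  cnt <- make_counts()
  cnt$count <- 15L
  post <- fit_poisson_model(cnt, "two_way", chains = 2, warmup = 1000,
                            samples = 1000, seed = 4)
  med <- apply(post$beta[, -1, drop = FALSE], 2, median)
  expect_true(all(abs(med) < 0.1))
  # two-way model sums counts over conversations
  expect_equal(sort(unique(post$cells$count)), 45L)
})

test_that("saturated predictions approach observed counts as the prior widens", {
  cnt <- make_counts()
  narrow <- fit_poisson_model(cnt, "three_way", chains = 2, warmup = 600,
                              samples = 600, seed = 21, coef_sd = 1)
  wide <- fit_poisson_model(cnt, "three_way", chains = 2, warmup = 600,
                            samples = 600, seed = 21, coef_sd = 10)
  err <- function(post) {
    ce <- conditional_effects(post)
    big <- ce$count >= 10
    mean(abs(ce$predicted_median[big] - ce$count[big]))
  }
  expect_lt(err(wide), err(narrow))
})

test_that("fits are deterministic given the seed", {
  cnt <- make_counts()
  p1 <- fit_poisson_model(cnt, "two_way", chains = 2, warmup = 200,
                          samples = 200, seed = 9)
  p2 <- fit_poisson_model(cnt, "two_way", chains = 2, warmup = 200,
                          samples = 200, seed = 9)
  expect_identical(p1$beta, p2$beta)
})

test_that("coefficients of a known log-linear model are recovered", {
  # truth: intercept log(10), modevideo 0.8, groupCI -0.4, interaction 0.9
  cells <- expand.grid(mode = c("audio", "video"),
                       group = c("AH", "CI"), stringsAsFactors = FALSE)
  X <- model.matrix(~ mode * group, cells)
  beta_true <- c(log(10), 0.8, -0.4, 0.9)
  lambda <- exp(drop(X %*% beta_true))
  cover <- 0
  set.seed(11)
  for (r in 1:10) {
    cnt <- data.frame(cells, count = rpois(4, lambda))
    # two-mode factorial: fit with the same design matrix through JAGS
    post <- fit_poisson_model(
      data.frame(cnt, conversation = "A"), "two_way",
      chains = 2, warmup = 500, samples = 500, seed = 100 + r)
    keep <- colnames(post$beta) %in% colnames(X)
    ci <- apply(post$beta[, colnames(X)[-1]], 2, quantile, c(0.025, 0.975))
    cover <- cover + all(ci[1, ] <= beta_true[-1] & beta_true[-1] <= ci[2, ])
  }
  expect_gte(cover, 8)
})
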