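test_that("error_ratio follows the inclusive running-mean convention", {
  expect_identical(error_ratio(2, 1), 0)
  expect_identical(error_ratio(c(2, 2, 2), 3), 0)
  expect_identical(error_ratio(c(1, 3), 2), -0.5)
  # undefined current epoch and all-zero history degenerate to 0
  expect_identical(error_ratio(c(1, NA), 2), 0)
  expect_identical(error_ratio(c(0, 0), 2), 0)
  expect_error(error_ratio(c(1, 2), 3), "round 3")
})

test_that("error_ratio preceding-rounds variant excludes the current epoch", {
  expect_identical(error_ratio(c(1, 3), 2, running_mean = "preceding"), -2)
  # no history at round 1
  expect_identical(error_ratio(5, 1, running_mean = "preceding"), 0)
  # NA history is skipped
  expect_identical(error_ratio(c(NA, 2, 4), 3, running_mean = "preceding"), -1)
})

test_that("rewards peak at zero error ratio and decay with |er|", {
  expect_identical(ucb_reward(0, a = 8, b = 3), 8)
  expect_identical(ucb_reward(0, a = 8, b = 2, kind = "normal"), 8)
  # cosine argument clamps at pi/2: large deviations get zero, not rebound
  expect_identical(ucb_reward(2, a = 8, b = 1), 0)
  expect_identical(ucb_reward(-5, a = 8, b = 1), 0)
  ers <- seq(0, 4, by = 0.05)
  for (kind in c("cosine", "normal")) {
    rw <- ucb_reward(ers, a = 8, b = 0.5, kind = kind)
    expect_true(all(diff(rw) <= 1e-12))
    expect_true(all(rw >= 0 & rw <= 8))
    # symmetric in the sign of the error ratio
    expect_equal(ucb_reward(-ers, a = 8, b = 0.5, kind = kind), rw)
  }
})

test_that("ucb_bound adds the exploration bonus sqrt(2 log i)", {
  expect_identical(ucb_bound(7.3, 1, c = 5), 7.3)   # log(1) = 0
  expect_equal(ucb_bound(0, exp(2), c = 1), 2)
  expect_identical(ucb_bound(5, 1000, c = 0), 5)
  expect_error(ucb_bound(1, 0), ">= 1")
})

test_that("softmax weights normalize, stay positive, and are shift-stable", {
  expect_equal(softmax_weights(c(3, 3, 3)), rep(1 / 3, 3))
  expect_equal(softmax_weights(c(0, log(2))), c(1 / 3, 2 / 3))
  expect_equal(softmax_weights(c(1000, 1001)), softmax_weights(c(0, 1)))
  set.seed(55)
  for (i in 1:20) {
    u <- rnorm(sample(2:50, 1), sd = 10)
    w <- softmax_weights(u)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(w > 0))
    expect_equal(softmax_weights(u + 17.5), w)
  }
  expect_error(softmax_weights(numeric(0)), "non-empty")
  expect_error(softmax_weights(c(1, Inf)), "finite")
})

test_that("ucbmcsampen2d is zero on a constant image", {
  cst <- toy_image("constant", 32, 32)
  for (seed in c(1, 99)) {
    fit <- ucbmcsampen2d(cst, N0 = 16, N1 = 10, seed = seed)
    expect_identical(fit$entropy, 0)
    expect_equal(sum(fit$epochs$weight), 1, tolerance = 1e-12)
  }
})

test_that("with c = 0 and equal epoch entropies the UCB estimate is the MC estimate", {
  cst <- toy_image("constant", 32, 32)
  mc <- mcsampen2d(cst, N0 = 16, N1 = 8, seed = 4)
  ucb <- ucbmcsampen2d(cst, N0 = 16, N1 = 8, seed = 4, c = 0)
  expect_true(all(ucb$epochs$e == 0))
  expect_equal(ucb$epochs$weight, rep(1 / 8, 8))
  expect_identical(ucb$entropy, mc$entropy)
})

test_that("identical seeds give identical epoch records across both estimators", {
  u <- mix2d(0.5, 48, 48, binarize = TRUE, seed = 13)
  mc <- mcsampen2d(u, N0 = 48, N1 = 20, seed = 77)
  ucb <- ucbmcsampen2d(u, N0 = 48, N1 = 20, seed = 77)
  expect_identical(ucb$epochs[c("epoch", "A_tilde", "B_tilde", "e")],
                   mc$epochs[c("epoch", "A_tilde", "B_tilde", "e")])
})

test_that("no epoch's weight exceeds exp(ucb range) times the uniform weight", {
  u <- mix2d(0.9, 48, 48, binarize = TRUE, seed = 19)
  fit <- suppressWarnings(ucbmcsampen2d(u, N0 = 48, N1 = 60, seed = 5))
  wts <- fit$epochs$weight
  expect_equal(sum(wts), 1, tolerance = 1e-12)
  expect_true(all(wts > 0))
  bound <- exp(diff(range(fit$epochs$ucb))) / length(wts)
  expect_lte(max(wts), bound + 1e-12)
})

test_that("UCB and MC converge to the same exact limit on a fixed image", {
  u <- mix2d(0.5, 48, 48, binarize = TRUE, seed = 23)
  exact <- sampen2d_exact(u)$entropy
  seeds <- 1:10
  for (N1 in c(100, 1000)) {
    mc_est <- vapply(seeds, function(s)
      mcsampen2d(u, N0 = 64, N1 = N1, seed = 300 + s)$entropy, numeric(1))
    ucb_est <- vapply(seeds, function(s)
      suppressWarnings(ucbmcsampen2d(u, N0 = 64, N1 = N1,
                                     seed = 300 + s))$entropy, numeric(1))
    se <- sd(mc_est) / sqrt(length(seeds))
    expect_lt(abs(mean(ucb_est) - exact),
              abs(mean(mc_est) - exact) + 4 * se + sd(mc_est))
  }
})

test_that("undefined epochs get zero error ratio but keep their counts", {
  # matches exist only inside a constant block: epochs whose draw misses
  # the block see no m-matches at all
  u <- matrix(seq_len(576), 24, 24)
  u[1:12, 1:12] <- 0
  fit <- suppressWarnings(
    ucbmcsampen2d(u, r_value = 0.5, r_mode = "absolute", N0 = 6, N1 = 40,
                  seed = 11))
  undef <- is.na(fit$epochs$e)
  expect_gt(sum(undef), 0)
  expect_gt(sum(!undef), 0)
  expect_true(all(fit$epochs$er[undef] == 0))
  expect_equal(sum(fit$epochs$weight), 1, tolerance = 1e-12)
  # weighted sums still include the undefined epochs' (zero) counts
  expect_equal(fit$A, sum(fit$epochs$weight * fit$epochs$A_tilde))
  expect_warning(
    ucbmcsampen2d(u, r_value = 0.5, r_mode = "absolute", N0 = 6, N1 = 40,
                  seed = 11), "no m-matches")
})

test_that("prose and pseudocode running means are both available and differ", {
  u <- mix2d(0.5, 48, 48, binarize = TRUE, seed = 41)
  inc <- suppressWarnings(ucbmcsampen2d(u, N0 = 48, N1 = 30, seed = 9,
                                        running_mean = "inclusive"))
  pre <- suppressWarnings(ucbmcsampen2d(u, N0 = 48, N1 = 30, seed = 9,
                                        running_mean = "preceding"))
  expect_identical(inc$epochs$e, pre$epochs$e)
  expect_false(identical(inc$epochs$er, pre$epochs$er))
  # round 1 is pinned to zero error ratio under both conventions
  expect_identical(inc$epochs$er[1], 0)
  expect_identical(pre$epochs$er[1], 0)
})
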