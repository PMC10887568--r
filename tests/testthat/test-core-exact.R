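test_that("extract_template reads off the anchored submatrix", {
  u <- outer(1:4, 1:4, function(i, j) 10 * i + j)
  expect_equal(extract_template(u, c(1, 1), 2),
               matrix(c(11, 21, 12, 22), 2, 2))
  expect_equal(extract_template(u, c(2, 1), 2),
               matrix(c(21, 31, 22, 32), 2, 2))
  cst <- toy_image("constant", 6, 6)
  expect_equal(extract_template(cst, c(3, 2), 3), matrix(0.5, 3, 3))
})

test_that("extract_template rejects anchors outside the restricted range", {
  u <- outer(1:4, 1:4, function(i, j) 10 * i + j)
  # anchors for m = 2 run to h - m = 2 so the same coord admits both sizes
  expect_error(extract_template(u, c(3, 3), 2), "k = 3")
  expect_error(extract_template(u, c(1, 3), 2), "l = 3")
  expect_error(extract_template(u, c(0, 1), 2), "k = 0")
})

test_that("chebyshev_distance matches hand-computed values", {
  X <- matrix(c(1, 3, 2, 4), 2, 2)
  expect_identical(chebyshev_distance(X, X), 0)
  Y <- X; Y[1, 2] <- 1
  expect_identical(chebyshev_distance(X, Y), 1)
  expect_identical(chebyshev_distance(matrix(0, 2, 2),
                                      matrix(c(0.5, 0, -2, 0), 2, 2)), 2)
  expect_error(chebyshev_distance(matrix(0, 2, 2), matrix(0, 2, 3)), "shape")
})

test_that("chebyshev_distance behaves as a metric on random matrices", {
  set.seed(401)
  for (i in 1:25) {
    s <- sample(2:4, 1)
    X <- matrix(rnorm(s * s), s, s)
    Y <- matrix(rnorm(s * s), s, s)
    Z <- matrix(rnorm(s * s), s, s)
    expect_identical(chebyshev_distance(X, Y), chebyshev_distance(Y, X))
    expect_gte(chebyshev_distance(X, Y), 0)
    expect_lte(chebyshev_distance(X, Z),
               chebyshev_distance(X, Y) + chebyshev_distance(Y, Z) + 1e-12)
    expect_identical(chebyshev_distance(X, X), 0)
  }
})

test_that("count_matching_pairs counts unordered pairs, self-pairs excluded", {
  cst <- toy_image("constant", 4, 4)
  anchors <- oracle_anchors(4, 4, 2)  # the 4 valid anchors
  expect_identical(count_matching_pairs(cst, anchors, 2, 0.1), 6)
  # strictly distinct templates: no pair within a sub-unit tolerance
  u <- matrix(seq_len(36), 6, 6)
  expect_identical(count_matching_pairs(u, oracle_anchors(6, 6, 2), 2, 0.5), 0)
  # duplicated coordinates never match themselves
  dup <- rbind(c(1, 1), c(1, 1))
  expect_identical(count_matching_pairs(cst, dup, 2, 0.1), 0)
  expect_identical(count_matching_pairs(cst, NULL, 2, 0.1), 0)
  expect_error(count_matching_pairs(cst, rbind(c(4, 1)), 2, 0.1),
               "out of range")
})

test_that("count_matching_pairs equals the naive double loop on a seeded image", {
  u <- toy_image("random_int", 8, 8, seed = 83, max_int = 3)
  anchors <- oracle_anchors(8, 8, 2)
  for (r in c(0.5, 1, 1.5)) {
    expect_identical(count_matching_pairs(u, anchors, 2, r),
                     oracle_count_pairs(u, anchors, 2, r))
  }
})

test_that("phi_m matches closed forms and the per-anchor enumeration oracle", {
  expect_identical(phi_m(toy_image("constant", 8, 8), 2, 0.1), 1)
  expect_identical(phi_m(matrix(seq_len(64), 8, 8), 2, 0.5), 0)
  u <- toy_image("random_int", 8, 8, seed = 83, max_int = 3)
  expect_equal(phi_m(u, 2, 0.5), oracle_phi(u, 2, 0.5))
  expect_equal(phi_m(u, 3, 1.5), oracle_phi(u, 3, 1.5))
  expect_error(phi_m(toy_image("constant", 3, 3), 2, 0.1), "degenerate")
})

test_that("phi_m lies in [0, 1] and is monotone in the tolerance", {
  set.seed(402)
  for (i in 1:10) {
    u <- toy_image("random_int", 10, 10, seed = 500 + i, max_int = 4)
    rs <- sort(runif(3, 0, 3))
    ph <- vapply(rs, function(r) phi_m(u, 2, r), numeric(1))
    expect_true(all(ph >= 0 & ph <= 1))
    expect_true(all(diff(ph) >= 0))
  }
})

test_that("sampen2d_exact reproduces brute-force values on fixtures", {
  # constant image: every pair matches at both sizes
  expect_identical(sampen2d_exact(toy_image("constant", 16, 16), 2, 0.1,
                                  "absolute")$entropy, 0)
  # 2-periodic checkerboard: extending a matching pair never breaks it
  cb <- toy_image("checkerboard", 16, 16)
  expect_equal(sampen2d_exact(cb, 2, 0.5, "absolute")$entropy,
               oracle_sampen2d_vec(cb, 2, 0.5))
  # seeded binary MIX(0.5): hash-path exact vs direct enumeration oracle
  u <- mix2d(0.5, 64, 64, binarize = TRUE, seed = 77)
  r_eff <- 0.3 * sqrt(mean((u - mean(u))^2))
  fit <- sampen2d_exact(u, 2, 0.3, "sd_relative")
  expect_equal(fit$entropy, oracle_sampen2d_vec(u, 2, r_eff))
  expect_equal(fit$r_eff, r_eff)
})

test_that("identity-hash counting agrees with the Chebyshev scan", {
  # binary image, tolerance below the level gap: both paths must agree
  for (sd_ in c(11, 12, 13)) {
    u <- mix2d(0.7, 24, 24, binarize = TRUE, seed = sd_)
    r_eff <- effective_tolerance(u, 0.3)
    hash_A <- sampen2d:::.hash_pair_count(u, 2, r_eff, margin = 2)
    hash_B <- sampen2d:::.hash_pair_count(u, 3, r_eff, margin = 2)
    scan <- sampen2d:::exact_pair_counts_cpp(u, 2L, r_eff)
    expect_identical(c(hash_A, hash_B), c(scan[1], scan[2]))
  }
  # above the level gap the hash path must stand down
  u <- toy_image("random_int", 12, 12, seed = 9, max_int = 3)
  expect_null(sampen2d:::.hash_pair_count(u, 2, 1.5, margin = 2))
})

test_that("phi^(m+1) <= phi^m on the shared anchor set and entropy >= 0", {
  for (sd_ in 1:8) {
    u <- toy_image("random_int", 12, 12, seed = 700 + sd_, max_int = 1)
    anchors <- oracle_anchors(12, 12, 2)
    A <- count_matching_pairs(u, anchors, 2, 0.5)
    B <- count_matching_pairs(u, anchors, 3, 0.5)
    expect_lte(B, A)
    if (A > 0 && B > 0) expect_gte(-log(B / A), 0)
  }
})

test_that("sd-relative entropy is invariant to affine intensity rescaling", {
  u <- toy_image("random_int", 16, 16, seed = 21, max_int = 1)
  base <- sampen2d_exact(u, 2, 0.3)
  resc <- sampen2d_exact(137 + 42.5 * u, 2, 0.3)
  expect_identical(base$entropy, resc$entropy)
  expect_identical(base$A, resc$A)
})

test_that("degenerate inputs raise the documented errors", {
  expect_error(sampen2d_exact(matrix(seq_len(256), 16, 16), 2, 0.5,
                              "absolute"), "undefined entropy: no matches")
  expect_error(sampen2d_exact(toy_image("constant", 3, 3), 2, 0.1), "too small")
  expect_error(sampen2d_exact(matrix(c(1, NA, 3, 4), 2, 2), 1, 0.5),
               "non-finite")
})
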