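test_that("soft thresholding shrinks toward zero elementwise", {
  expect_equal(soft_threshold(c(2, -1, 0.5), 1), c(1, 0, 0))
  expect_equal(soft_threshold(c(-3, 3), 1.5), c(-1.5, 1.5))
  x <- c(0.3, -2, 5)
  expect_equal(soft_threshold(x, 0), x)
  expect_error(soft_threshold(x, -0.1), "non-negative")
})

test_that("the L1-constrained maximizer handles both constraint regimes", {
  # inactive bound: plain L2 normalization
  expect_equal(l1_constrained_unit(c(3, 4), 2), c(0.6, 0.8))
  # tight bound: vertex at the largest component
  expect_equal(l1_constrained_unit(c(3, 4), 1), c(0, 1), tolerance = 1e-6)
  # intermediate bound hits the L1 boundary exactly; closed form for
  # a = (2, 1), c = 1.2: threshold solves 1.12 t^2 - 3.36 t + 1.8 = 0
  u <- l1_constrained_unit(c(2, 1), 1.2)
  expect_equal(sum(abs(u)), 1.2, tolerance = 1e-5)
  t_star <- (3.36 - sqrt(3.36^2 - 4 * 1.12 * 1.8)) / (2 * 1.12)
  su <- c(2, 1) - t_star
  expect_equal(u, su / sqrt(sum(su^2)), tolerance = 1e-6)
  # c < 1 clamps to 1; with tied entries the bound is unattainable and
  # both conditions are reported
  w <- capture_warnings(u2 <- l1_constrained_unit(c(1, 1), 0.5))
  expect_match(w, "clamped", all = FALSE)
  expect_match(w, "could not attain", all = FALSE)
  expect_equal(u2, c(1, 1) / sqrt(2), tolerance = 1e-6)
  expect_error(l1_constrained_unit(c(0, 0), 1.5), "nonzero")
})

test_that("the constrained maximizer matches the threshold-grid oracle", {
  set.seed(12)
  for (i in 1:100) {
    m <- sample(3:12, 1)
    a <- rnorm(m)
    c <- runif(1, 1, sqrt(m))
    u <- l1_constrained_unit(a, c)
    ref <- l1_unit_oracle(a, c)
    expect_lt(max(abs(u - ref)), 1e-3)
    expect_lte(sum(abs(u)), c + 1e-4)
    expect_equal(sum(u^2), 1, tolerance = 1e-10)
  }
})

test_that("rank-one PMD reduces to the leading singular triplet when free", {
  f <- pmd_rank_one(diag(c(3, 1)), c = sqrt(2))
  expect_equal(f$d, 3, tolerance = 1e-8)
  expect_equal(abs(f$u), c(1, 0), tolerance = 1e-6)
  expect_equal(abs(f$v), c(1, 0), tolerance = 1e-6)

  set.seed(13)
  for (i in 1:50) {
    x <- matrix(rnorm(40), 10, 4)
    f <- pmd_rank_one(x, c = sqrt(10))
    expect_equal(f$d, svd(x)$d[1], tolerance = 1e-8)
  }
})

test_that("a tight L1 bound selects the dominant row", {
  f <- pmd_rank_one(rbind(c(3, 0), c(0, 4)), c = 1)
  expect_equal(f$d, 4, tolerance = 1e-6)
  expect_equal(abs(f$u), c(0, 1), tolerance = 1e-6)
})

test_that("every factor is feasible and the objective never decreases", {
  set.seed(14)
  for (i in 1:200) {
    p <- sample(5:20, 1)
    r <- sample(2:6, 1)
    x <- matrix(rnorm(p * r), p, r)
    c <- runif(1, 1, sqrt(p))
    f <- suppressWarnings(pmd_rank_one(x, c))
    expect_equal(sum(f$u^2), 1, tolerance = 1e-8)
    expect_lte(sum(abs(f$u)), c + 1e-6)
    expect_equal(sum(f$v^2), 1, tolerance = 1e-8)
    expect_gte(f$d, 0)
    if (length(f$objective) > 1L)
      expect_true(all(diff(f$objective) >= -1e-10))
  }
})

test_that("deflation recovers an exact SVD when the bound is inactive", {
  f <- pmd_rank_k(diag(c(3, 1)), c = sqrt(2), K = 2)
  expect_equal(f$d, c(3, 1), tolerance = 1e-6)
  expect_equal(abs(f$u), diag(2), tolerance = 1e-5, ignore_attr = TRUE)

  # K = 1 equals the rank-one fit
  set.seed(15)
  x <- matrix(rnorm(60), 12, 5)
  expect_equal(pmd_rank_k(x, c = 2, K = 1)$u[, 1],
               pmd_rank_one(x, c = 2)$u)

  # Frobenius identity at full rank with the bound inactive
  for (i in 1:5) {
    x <- matrix(rnorm(48), 12, 4)
    f <- pmd_rank_k(x, c = sqrt(12), K = 4)
    expect_equal(sum(f$d^2), sum(x^2), tolerance = 1e-6)
  }
})

test_that("sparsity grows with the L1 bound on a fixed matrix", {
  set.seed(16)
  x <- matrix(rnorm(200), 50, 4)
  nnz <- sapply(seq(0.15, 1, by = 0.05), function(gamma) {
    f <- suppressWarnings(pmd_rank_one(x, c = max(1, gamma * sqrt(50))))
    sum(f$u != 0)
  })
  expect_true(all(diff(nnz) >= 0))
})

test_that("deflation stops early on a numerically zero residual", {
  x <- tcrossprod(c(1, 0, 0, 0), c(1, 0))  # exact rank one
  expect_warning(f <- pmd_rank_k(x, c = sqrt(4), K = 3), "fewer")
  expect_lt(ncol(f$u), 3)
})
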