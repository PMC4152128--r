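test_that("class means and grand mean follow the sample-mean convention", {
  x <- cbind(c(1, 1), c(3, 3))
  dimnames(x) <- list(c("g1", "g2"), c("s1", "s2"))
  # single class needs a second one to pass validation; use 2+2 layout
  x2 <- cbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  dimnames(x2) <- list(c("g1", "g2"), paste0("s", 1:4))
  lab <- factor(c("A", "A", "B", "B"))
  names(lab) <- colnames(x2)
  st <- class_statistics(x2, lab)
  expect_equal(unname(st$class_means[, "A"]), c(1, 0))
  expect_equal(unname(st$class_means[, "B"]), c(0, 1))
  expect_equal(unname(st$grand_mean), c(0.5, 0.5))

  # one class of two identical-mean columns
  lab2 <- factor(c("A", "A", "B", "B"))
  names(lab2) <- paste0("s", 1:4)
  x3 <- cbind(c(1, 1), c(3, 3), c(0, 0), c(0, 0))
  dimnames(x3) <- list(c("g1", "g2"), paste0("s", 1:4))
  expect_equal(unname(class_statistics(x3, lab2)$class_means[, "A"]), c(2, 2))
})

test_that("means are invariant to joint permutation of samples and labels", {
  set.seed(3)
  f <- rand_labeled(6, 8, C = 2L)
  st <- class_statistics(f$x, f$labels)
  perm <- sample(ncol(f$x))
  st_p <- class_statistics(f$x[, perm], f$labels[perm])
  expect_equal(st_p$class_means, st$class_means)
  expect_equal(st_p$grand_mean, st$grand_mean)
})

test_that("factored scatter reproduces the dense definitional sums", {
  # fixed worked instance: two point-mass classes
  x <- cbind(c(1, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 1, 0))
  dimnames(x) <- list(paste0("g", 1:3), paste0("s", 1:4))
  lab <- factor(c("A", "A", "B", "B"))
  names(lab) <- colnames(x)
  sf <- scatter_factors(x, lab)
  Sb <- tcrossprod(sf$Hb)
  expect_equal(unname(Sb),
               rbind(c(1, -1, 0), c(-1, 1, 0), c(0, 0, 0)))
  expect_equal(sf$trace_b, 2)
  expect_equal(sf$trace_w, 0)

  # random instances against the double-loop oracle
  set.seed(4)
  for (i in 1:50) {
    p <- sample(2:10, 1)
    C <- sample(2:4, 1)
    n <- C * sample(2:3, 1)
    f <- rand_labeled(p, n, C)
    sf <- scatter_factors(f$x, f$labels)
    dn <- dense_scatter(f$x, f$labels)
    expect_lt(max(abs(tcrossprod(sf$Hb) - dn$Sb)), 1e-10)
    expect_lt(max(abs(tcrossprod(sf$Hw) - dn$Sw)), 1e-10)
    expect_equal(sf$trace_b, sum(diag(dn$Sb)), tolerance = 1e-12)
    expect_equal(sf$trace_w, sum(diag(dn$Sw)), tolerance = 1e-12)
  }
})

test_that("within-class factor columns sum to zero per class", {
  set.seed(5)
  f <- rand_labeled(7, 12, C = 3L)
  sf <- scatter_factors(f$x, f$labels)
  for (cl in levels(f$labels)) {
    expect_lt(max(abs(rowSums(sf$Hw[, f$labels == cl, drop = FALSE]))), 1e-12)
  }
  # degenerate: all samples identical
  x0 <- matrix(1, 4, 6, dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
  sf0 <- scatter_factors(x0, factor(rep(c("A", "B"), each = 3)))
  expect_equal(sf0$trace_b, 0)
  expect_equal(sf0$trace_w, 0)
})

test_that("scatter scales quadratically and splits the total scatter", {
  set.seed(6)
  f <- rand_labeled(8, 8, C = 2L)
  sf <- scatter_factors(f$x, f$labels)
  sf3 <- scatter_factors(3 * f$x, f$labels)
  expect_equal(sf3$trace_b, 9 * sf$trace_b)
  expect_equal(sf3$trace_w, 9 * sf$trace_w)
  expect_equal(compute_beta(sf3), compute_beta(sf))

  # S_b + S_w equals the total sample scatter around the grand mean
  total <- matrix(0, nrow(f$x), nrow(f$x))
  m <- rowMeans(f$x)
  for (j in seq_len(ncol(f$x))) total <- total + tcrossprod(f$x[, j] - m)
  expect_equal(tcrossprod(sf$Hb) + tcrossprod(sf$Hw), total,
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("beta modes behave as defined", {
  set.seed(7)
  f <- rand_labeled(5, 6, C = 2L)
  sf <- scatter_factors(f$x, f$labels)
  expect_equal(compute_beta(sf), sf$trace_b / sf$trace_w)
  expect_equal(compute_beta(sf, 1.7), 1.7)
  expect_error(compute_beta(sf, -1), "non-negative")

  x0 <- matrix(rep(c(1, 5), each = 2), 1, 4,
               dimnames = list("g1", paste0("s", 1:4)))
  sf0 <- scatter_factors(x0, factor(c("A", "A", "B", "B")))
  expect_error(compute_beta(sf0), "fixed beta")
})
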