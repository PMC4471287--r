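test_that("hypergeometric tail reproduces enumerable cases and rejects bad counts", {
  expect_equal(hypergeometric_tail(10, 4, 3, 0), 1)
  expect_equal(hypergeometric_tail(10, 4, 3, 2), 1 / 3)       # 40 of 120 draws
  expect_equal(hypergeometric_tail(5, 2, 3, 2), 0.3)          # C(2,2)C(3,1)/C(5,3)
  expect_error(hypergeometric_tail(5, 2, 3, 3), "exceeds K")
  expect_error(hypergeometric_tail(10, 4, 12, 2), "ordering")
  expect_error(hypergeometric_tail(10, 11, 3, 2), "ordering")
  expect_error(hypergeometric_tail(10, 4, 3, -1), "non-negative")
})

test_that("hypergeometric tail matches phyper and stays monotone in k", {
  set.seed(11)
  for (i in 1:50) {
    N <- sample(20:5000, 1)
    K <- sample.int(N, 1)
    n <- sample.int(N, 1)
    k <- sample.int(min(K, n), 1)
    expect_equal(hypergeometric_tail(N, K, n, k),
                 phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  # non-increasing in k, equal to 1 at k = 0
  tails <- vapply(0:10, function(k) hypergeometric_tail(60, 20, 10, k), 1)
  expect_equal(tails[1], 1)
  expect_true(all(diff(tails) <= 1e-15))
  # stable deep in the tail of a large pool
  expect_gt(hypergeometric_tail(1e5, 500, 500, 30), 0)
})

test_that("overlap test restricts to the pool and computes the exact tail", {
  ds <- function(ids) directional_set(ids, rep(1, length(ids)))
  pool <- paste0("g", 1:10)
  ov <- overlap_test(ds(c("g1", "g2")), ds(c("g2", "g3")), pool)
  expect_equal(ov$intersection_size, 1)
  expect_equal(ov$intersection_ids, "g2")
  expect_equal(ov$p_hyper, 1 - choose(8, 2) / choose(10, 2))  # 17/45
  ov2 <- overlap_test(ds("g1"), ds("g1"), paste0("g", 1:5))
  expect_equal(ov2$p_hyper, 0.2)
  ov3 <- overlap_test(ds(character(0)), ds(c("g1", "g2")), pool)
  expect_equal(ov3$intersection_size, 0)
  expect_equal(ov3$p_hyper, 1)
  # symmetry in A/B
  a <- ds(paste0("g", 1:4)); b <- ds(paste0("g", 3:7))
  expect_equal(overlap_test(a, b, pool)$p_hyper, overlap_test(b, a, pool)$p_hyper)
  # features outside the pool are dropped with a warning
  expect_warning(ov4 <- overlap_test(ds(c("g1", "zz")), ds("g1"), pool), "outside")
  expect_equal(ov4$set_a_size, 1)
  expect_error(overlap_test(a, b, character(0)), "non-empty")
})

test_that("directional concordance reports fractions, identity and Pearson r", {
  a <- directional_set("g1", 2)
  b <- directional_set("g1", 1)
  cc <- directional_concordance(a, b)
  expect_equal(cc$frac_a_in_b, 1)
  expect_equal(cc$frac_directionally_identical, 1)
  expect_false(cc$pearson_defined)  # fewer than 3 shared features

  a2 <- directional_set(c("g1", "g2"), c(1, -1))
  b2 <- directional_set(c("g1", "g3"), c(-1, 1))
  cc2 <- directional_concordance(a2, b2)
  expect_equal(cc2$frac_a_in_b, 0.5)
  expect_equal(cc2$frac_directionally_identical, 0)

  a3 <- directional_set(paste0("g", 1:4), c(1, 2, 3, 4))
  b3 <- directional_set(paste0("g", 1:4), c(1, 3, 2, 4))
  cc3 <- directional_concordance(a3, b3)
  expect_equal(cc3$pearson_r, 0.8)   # hand-computed covariance / sd ratio
  expect_true(cc3$pearson_defined)

  empty <- directional_set(character(0), numeric(0))
  cc4 <- directional_concordance(empty, b3)
  expect_equal(cc4$frac_a_in_b, 0)
  expect_true(cc4$a_empty)
})

test_that("directional_set enforces its invariants", {
  expect_error(directional_set(c("a", "a"), c(1, 2)), "unique")
  expect_error(directional_set("a", 1, direction = -1), "sign")
  expect_error(directional_set("a", 1, p = 1.5), "\\[0, 1\\]")
  s <- directional_set("a", 0, direction = -1)   # zero log2fc: any direction
  expect_equal(s$direction, -1)
})

test_that("welch_t matches the closed form, t.test, and degenerate rules", {
  a <- c(0.8, 0.7, 0.9, 0.8); b <- c(0.2, 0.3, 0.1, 0.2)
  w <- welch_t(a, b)
  expect_equal(w$t, 0.6 / sqrt(2 * var(a) / 4), tolerance = 1e-12)
  expect_equal(w$t, 10.392, tolerance = 1e-3)
  expect_equal(w$df, 6)
  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3))$t, 0)
  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3))$p, 1)
  deg <- welch_t(c(5, 5), c(5, 5))
  expect_true(deg$degenerate)
  expect_equal(deg$t, 0); expect_equal(deg$p, 1)
  deg2 <- welch_t(c(5, 5), c(4, 4))
  expect_true(deg2$degenerate)
  expect_equal(deg2$p, 0)

  set.seed(3)
  for (i in 1:25) {
    x <- rnorm(sample(3:9, 1)); y <- rnorm(sample(3:9, 1), sd = runif(1, 0.5, 2))
    ref <- t.test(x, y)
    w <- welch_t(x, y)
    expect_equal(w$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(w$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(w$p, ref$p.value, tolerance = 1e-10)
    ref2 <- t.test(x, y, var.equal = TRUE)
    w2 <- welch_t(x, y, var_equal = TRUE)
    expect_equal(w2$p, ref2$p.value, tolerance = 1e-10)
  }
})

test_that("row_welch agrees with welch_t row by row, including degenerate rows", {
  set.seed(4)
  x <- matrix(rnorm(40 * 8), 40, 8, dimnames = list(paste0("f", 1:40), paste0("s", 1:8)))
  x[1, ] <- 5                      # equal constants
  x[2, 1:4] <- 1; x[2, 5:8] <- 2   # unequal constants
  rw <- row_welch(x, paste0("s", 1:4), paste0("s", 5:8))
  for (i in seq_len(nrow(x))) {
    w <- welch_t(x[i, 1:4], x[i, 5:8])
    expect_equal(rw$t[i], w$t)
    expect_equal(rw$p[i], w$p)
  }
  expect_equal(rw$p[1], 1)
  expect_equal(rw$p[2], 0)
})

test_that("BH q-values follow the step-up rule and its invariants", {
  expect_equal(bh_fdr(0.05), 0.05)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_fdr(c(1, 1)), c(1, 1))
  expect_identical(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(5)
  p <- runif(200)^2
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  # re-adjusting can only move q-values up, never above 1
  q2 <- bh_fdr(q)
  expect_true(all(q2 >= q - 1e-15) && all(q2 <= 1))
})

test_that("geometric mean is exact on closed forms and rejects non-positives", {
  expect_equal(geometric_mean(c(2, 2)), 2)
  expect_equal(geometric_mean(c(1, 8)), sqrt(8))
  expect_equal(geometric_mean(5), 5)
  expect_error(geometric_mean(c(1, 0)), "positive")
  expect_error(geometric_mean(c(1, -2)), "positive")
})

test_that("pearson_with_p matches cor.test and flags undefined cases", {
  set.seed(6)
  x <- rnorm(20); y <- x + rnorm(20)
  ref <- cor.test(x, y)
  pw <- pearson_with_p(x, y)
  expect_equal(pw$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(pw$p, ref$p.value, tolerance = 1e-10)
  expect_false(pearson_with_p(c(1, 2), c(3, 4))$defined)
  expect_false(pearson_with_p(c(1, 1, 1), c(1, 2, 3))$defined)
})
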