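test_that("the r = 0.61, n = 59 worked example gives t = 5.81", {
  v <- vectors_with_r(0.61, 59)
  ct <- pearson_with_t(v$x, v$y)
  expect_equal(ct$r, 0.61, tolerance = 1e-12)
  expect_equal(ct$t, 5.81, tolerance = 0.01)
  expect_identical(ct$df, 57L)
  expect_lt(ct$p, 1e-4)
})

test_that("pearson_with_t matches cor.test and handles sentinels", {
  set.seed(31)
  x <- rnorm(30); y <- x + rnorm(30)
  ct <- pearson_with_t(x, y)
  ref <- stats::cor.test(x, y)
  expect_equal(ct$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(ct$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ct$p, ref$p.value, tolerance = 1e-12)

  perfect <- pearson_with_t(x, x)
  expect_identical(perfect$t, Inf)
  expect_identical(perfect$p, 0)

  orth <- pearson_with_t(c(1, -1, 1, -1, 1, -1), c(1, 1, -1, -1, 1, 1))
  expect_equal(orth$r, 0, tolerance = 1e-12)
  expect_equal(orth$t, 0, tolerance = 1e-12)
  expect_equal(orth$p, 1, tolerance = 1e-12)

  expect_error(pearson_with_t(rep(1, 10), rnorm(10)), "zero variance")
  expect_error(pearson_with_t(1:3, 1:3), "at least 4")
  expect_error(pearson_with_t(1:5, 1:4), "unequal")
})

test_that("pearson_with_t is affine-invariant with a sign flip", {
  set.seed(32)
  x <- rnorm(25); y <- rnorm(25)
  r0 <- pearson_with_t(x, y)$r
  expect_equal(pearson_with_t(3 * x + 7, y)$r, r0, tolerance = 1e-12)
  expect_equal(pearson_with_t(-2 * x + 1, y)$r, -r0, tolerance = 1e-12)
})

test_that("Hotelling t is null at equality and exactly antisymmetric", {
  h0 <- hotelling_dependent_t(0.5, 0.5, 0.3, 40)
  expect_identical(h0$t, 0)
  expect_equal(h0$p, 1)
  expect_identical(h0$df, 37L)

  a <- hotelling_dependent_t(0.61, 0.02, 0.40, 59)
  b <- hotelling_dependent_t(0.02, 0.61, 0.40, 59)
  expect_identical(a$t, -b$t)
  expect_identical(a$p, b$p)
})

test_that("Hotelling t matches the direct formula evaluation", {
  r12 <- 0.61; r13 <- 0.02; r23 <- 0.40; n <- 59
  detR <- 1 - r12^2 - r13^2 - r23^2 + 2 * r12 * r13 * r23
  t_direct <- (r12 - r13) * sqrt((n - 3) * (1 + r23)) / sqrt(2 * detR)
  h <- hotelling_dependent_t(r12, r13, r23, n)
  expect_equal(h$t, t_direct, tolerance = 1e-12)
  expect_equal(h$t, 5.3471, tolerance = 1e-4)  # frozen from the arithmetic
  expect_equal(h$p, 2 * stats::pt(-abs(t_direct), 56), tolerance = 1e-12)
})

test_that("Williams' variant behaves like a damped Hotelling t", {
  h <- hotelling_dependent_t(0.61, 0.02, 0.40, 59)
  w <- hotelling_dependent_t(0.61, 0.02, 0.40, 59, method = "williams")
  expect_identical(sign(w$t), sign(h$t))
  expect_false(isTRUE(all.equal(w$t, h$t)))
  expect_identical(hotelling_dependent_t(0.4, 0.4, 0.2, 30,
                                         method = "williams")$t, 0)
})

test_that("Hotelling rejects invalid correlation geometry", {
  expect_error(hotelling_dependent_t(0.9, -0.9, 0.9, 30),
               "not positive definite")
  expect_error(hotelling_dependent_t(0.5, 0.2, 0.1, 3), "n >= 4")
  expect_error(hotelling_dependent_t(1, 0.2, 0.1, 30), "inside")
})

test_that("chi-square matches hand arithmetic and its invariances", {
  expect_equal(chisq_2x2(10, 90, 20, 180)$chi2, 0, tolerance = 1e-9)

  a <- 30; b <- 70; cc <- 10; d <- 90
  n <- a + b + cc + d
  expected <- outer(c(a + b, cc + d), c(a + cc, b + d)) / n
  obs <- matrix(c(a, b, cc, d), 2, byrow = TRUE)
  chi_hand <- sum((obs - expected)^2 / expected)
  res <- chisq_2x2(a, b, cc, d)
  expect_equal(res$chi2, chi_hand, tolerance = 1e-12)
  expect_identical(res$df, 1L)

  # transpose and double-swap invariance
  expect_equal(chisq_2x2(a, cc, b, d)$chi2, res$chi2, tolerance = 1e-12)
  expect_equal(chisq_2x2(d, cc, b, a)$chi2, res$chi2, tolerance = 1e-12)

  # Yates correction shrinks the statistic
  expect_lt(chisq_2x2(a, b, cc, d, correct = TRUE)$chi2, res$chi2)

  expect_error(chisq_2x2(0, 0, 5, 5), "zero margin")
})

test_that("two-sample t covers identical, shifted and simulated groups", {
  x <- c(1.2, 3.4, 2.2, 5.0)
  expect_equal(two_sample_t(x, x)$t, 0, tolerance = 1e-12)

  # shifted copies: closed-form pooled t = d / (s * sqrt(2/n))
  d <- 2.5
  s <- sd(x)  # shifting preserves the common within-group sd
  expect_equal(two_sample_t(x, x + d)$t, -d / (s * sqrt(2 / length(x))),
               tolerance = 1e-12)

  ref <- stats::t.test(x, x + 1, var.equal = TRUE)
  mine <- two_sample_t(x, x + 1)
  expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  welch <- two_sample_t(x, c(x, 9) + 1, pooled = FALSE)
  refw <- stats::t.test(x, c(x, 9) + 1)
  expect_equal(welch$df, unname(refw$parameter), tolerance = 1e-9)

  expect_error(two_sample_t(rep(1, 3), rep(2, 3)), "zero pooled variance")
  expect_error(two_sample_t(1, 1:5), "at least 2")
})

test_that("group-mean separation at gradient-scale effects is detectable", {
  # two groups of A+T3-like values: means 5 points apart, sd 4.4 and 1.2,
  # n = 37 vs 17 (the shape of the real monkeys-vs-group-M comparison)
  set.seed(33)
  a <- rnorm(37, 65.4, 4.4)
  b <- rnorm(17, 70.4, 1.2)
  tt <- two_sample_t(a, b)
  expect_gt(abs(tt$t), 3)
  expect_lt(tt$p, 0.01)
})

test_that("amino-acid chi-square pools raw counts by default", {
  set.seed(34)
  g1 <- lapply(1:3, function(i) codon_counts(random_counts_vec(100 + i)))
  g2 <- lapply(1:3, function(i) codon_counts(random_counts_vec(200 + i)))
  res <- aa_content_chisq(g1, g2, "I")
  # reproduce by hand from pooled family counts
  fam <- genetic_code()$synonym_families
  tot <- function(g) sum(vapply(g, function(cc) {
    sum(cc$counts[unlist(fam[genetic_code()$degenerate_aa])])
  }, numeric(1)))
  ile <- function(g) sum(vapply(g, function(cc) sum(cc$counts[fam[["I"]]]),
                                numeric(1)))
  ref <- chisq_2x2(ile(g1), tot(g1) - ile(g1), ile(g2), tot(g2) - ile(g2))
  expect_equal(res$chi2, ref$chi2, tolerance = 1e-12)
  expect_error(aa_content_chisq(g1, g2, "M"), "degenerate-family")

  # the mean-of-percentages variant exists and differs in general
  res_mean <- aa_content_chisq(g1, g2, "I", pooling = "mean")
  expect_true(is.finite(res_mean$chi2))
})
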