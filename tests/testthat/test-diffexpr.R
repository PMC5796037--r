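test_that("log2 fold change is the difference of group means", {
  expect_equal(log2_fold_change(c(3, 3), c(3, 3)), 0.0)
  expect_equal(log2_fold_change(c(4, 4), c(3, 3)), 1.0)
  expect_equal(log2_fold_change(c(5.1, 4.9, 5.3), c(3.7, 4.1, 3.9)), 1.2)
  expect_error(log2_fold_change(numeric(), c(1)), "empty group")
})

test_that("pooled t-test matches the exact t distribution and stats::t.test", {
  expect_equal(student_t_test(c(1, 2, 3), c(1, 2, 3))[c("t", "p")],
               list(t = 0, p = 1))
  r <- student_t_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t, -3.6742, tolerance = 1e-4)
  expect_equal(r$df, 4)
  expect_equal(r$p, 0.02131, tolerance = 1e-4)
  set.seed(31)
  for (i in 1:25) {
    a <- rnorm(sample(3:12, 1)); b <- rnorm(sample(3:12, 1), sd = runif(1, .5, 2))
    for (ev in c(TRUE, FALSE)) {
      mine <- student_t_test(a, b, equal_variance = ev)
      ref <- t.test(a, b, var.equal = ev)
      expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-9)
      expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
    }
  }
})

test_that("degenerate zero-variance inputs follow the documented convention", {
  same <- student_t_test(c(2, 2, 2), c(2, 2))
  expect_equal(same[c("t", "p")], list(t = 0, p = 1))
  expect_true(same$degenerate)
  diff <- student_t_test(c(2, 2, 2), c(3, 3))
  expect_equal(diff$p, 0)
  expect_true(diff$degenerate)
  expect_error(student_t_test(1, c(1, 2)), "at least 2")
})

test_that("the test is antisymmetric under group swap and monotone in effect", {
  set.seed(8)
  a <- rnorm(6); b <- rnorm(7)
  f <- student_t_test(a, b); g <- student_t_test(b, a)
  expect_equal(f$t, -g$t); expect_equal(f$p, g$p)
  expect_equal(log2_fold_change(a, b), -log2_fold_change(b, a))
  # same residuals, growing mean separation: p never increases
  res_a <- a - mean(a); res_b <- b - mean(b)
  ps <- vapply(seq(0, 3, by = 0.25), function(d)
    student_t_test(res_a + d, res_b)$p, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("vectorized per-row tests agree with the scalar implementation", {
  set.seed(99)
  A <- matrix(rnorm(50 * 8), 50, 8); B <- matrix(rnorm(50 * 6), 50, 6)
  v <- mirpair:::row_t_test(A, B)
  for (i in sample(50, 10)) {
    s <- student_t_test(A[i, ], B[i, ])
    expect_equal(v$t[i], s$t, tolerance = 1e-12)
    expect_equal(v$p[i], s$p, tolerance = 1e-12)
  }
})

test_that("null p-values are uniform (KS at the 1% level)", {
  set.seed(2024)
  A <- matrix(rnorm(10000 * 10), 10000, 10)
  B <- matrix(rnorm(10000 * 10), 10000, 10)
  p <- mirpair:::row_t_test(A, B)$p
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
})

test_that("direction calling applies the class fold-change filter strictly", {
  # significant but |lfc| = 0.9 <= 1 for mRNA: no call
  set.seed(5)
  vals <- rbind(f1 = c(rnorm(10, 5.9, 0.05), rnorm(10, 5.0, 0.05)),
                f2 = c(rnorm(10, 8.0, 0.05), rnorm(10, 5.0, 0.05)))
  colnames(vals) <- sprintf("s%02d", 1:20)
  ds <- expression_dataset("d", vals, rep(c("tumor", "normal"), each = 10))
  de <- call_de(ds, de_thresholds(), "mrna")
  expect_identical(de$records$direction, c("none", "up"))
  # the same feature is called for the miRNA class (threshold 0)
  de_mi <- call_de(ds, de_thresholds(), "mirna")
  expect_identical(de_mi$records$direction, c("up", "up"))
  expect_error(call_de(expression_dataset(
    "d2", vals[, 1:3], c("tumor", "normal", "normal")), de_thresholds(), "mrna"),
    "2 samples per group")
})

test_that("overexpression filter uses inclusive bounds at 0.5849", {
  # scrambled baseline of 0 keeps the computed log2FC bit-exact at the bound
  tab <- data.frame(gene_id = c("at_bound", "inside", "up_gene", "flat"),
                    mimic = c(-0.5849, -0.5848, 0.60, 0),
                    scrambled = c(0, 0, 0, 0))
  res <- overexpression_filter(tab, de_thresholds())
  expect_identical(res$down, "at_bound")
  expect_identical(res$up, "up_gene")
  expect_error(overexpression_filter(tab[, 1:2], de_thresholds()),
               "missing column")
})
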