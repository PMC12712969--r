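test_that("ICC is 1 when columns agree perfectly and subjects differ", {
  x <- matrix(rep(c(1, 2, 3, 4, 5), 3), 5, 3)
  r <- icc(x)
  expect_equal(r$icc, 1)
  expect_lte(r$ci_low, 1)
  expect_equal(r$ci_high, 1, tolerance = 1e-9)
})

test_that("ICC matches the longhand sums-of-squares oracle", {
  set.seed(61)
  for (i in 1:20) {
    x <- matrix(rnorm(12, mean = 1.2, sd = 0.4), 6, 2) +
      rnorm(6, sd = 0.5)  # subject effect recycled by column
    expect_equal(icc(x)$icc, longhand_icc(x), tolerance = 1e-9)
  }
})

test_that("ICC point estimate and CI match an independent reference", {
  # reference values computed with pingouin.intraclass_corr (ICC(A,1)) on
  # this fixed table
  x <- matrix(c(2.304, 0.465, 1.655,
                0.913, 0.959, 1.054,
                0.399, 1.115, 0.861,
                2.993, 1.754, 1.523,
                1.251, 1.096, 0.941,
                0.892, 1.241, 0.953), 6, 3, byrow = TRUE)
  r <- icc(x)
  expect_equal(r$icc, 0.3063617265, tolerance = 1e-9)
  expect_lt(abs(r$ci_low - (-0.18)), 0.005)
  expect_lt(abs(r$ci_high - 0.83), 0.005)
  expect_true(r$ci_low <= r$icc && r$icc <= r$ci_high)
})

test_that("ICC near zero for subject-independent noise", {
  set.seed(17)
  vals <- replicate(200, icc(matrix(rnorm(150), 50, 3))$icc)
  expect_lt(abs(mean(vals)), 0.05)
})

test_that("ICC is invariant to shifts and positive scaling, CI covers estimate", {
  set.seed(3)
  for (i in 1:20) {
    x <- matrix(rnorm(18, sd = 0.3), 6, 3) + rnorm(6)
    r0 <- icc(x)
    expect_equal(icc(x + 7)$icc, r0$icc, tolerance = 1e-9)
    expect_equal(icc(x * 3.5)$icc, r0$icc, tolerance = 1e-9)
    expect_true(r0$ci_low <= r0$icc && r0$icc <= r0$ci_high)
  }
})

test_that("ICC errors on degenerate tables", {
  expect_error(icc(matrix(1, 4, 3)), class = "fna_undefined_icc")
  expect_error(icc(matrix(1:3, 1, 3)), class = "fna_bad_table")
  expect_error(icc(matrix(c(1, NA, 2, 3), 2, 2)), class = "fna_bad_table")
})

test_that("two-way ANOVA returns null results for identical cell means", {
  df <- expand.grid(gender = c("m", "f"), side = c("l", "r"),
                    rep = 1:6, KEEP.OUT.ATTRS = FALSE)
  # within-cell spread but every cell mean identical => all factor F = 0, p = 1
  df$value <- 2 + rep(c(-0.5, 0.5), each = nrow(df) / 2 / 2, length.out = nrow(df))
  df$value <- 2 + rep(c(-0.5, 0.5), length.out = nrow(df)) *
    rep(c(1, -1), each = 4, length.out = nrow(df))
  cellm <- tapply(df$value, interaction(df$gender, df$side), mean)
  df$value <- df$value - cellm[interaction(df$gender, df$side)] + 2
  r <- two_way_anova(df)
  expect_equal(r$terms$ss[1:3], rep(0, 3), tolerance = 1e-18)
  expect_equal(r$terms$F[1:3], rep(0, 3), tolerance = 1e-12)
  expect_equal(r$terms$p[1:3], rep(1, 3), tolerance = 1e-12)
})

test_that("a pure factor-A effect loads only on factor A", {
  df <- expand.grid(gender = c("m", "f"), side = c("l", "r"), rep = 1:6,
                    KEEP.OUT.ATTRS = FALSE)
  df$value <- ifelse(df$gender == "m", 1, 2)
  r <- two_way_anova(df)
  expect_gt(r$terms$ss[1], 0)
  expect_equal(r$terms$ss[2], 0, tolerance = 1e-18)
  expect_equal(r$terms$ss[3], 0, tolerance = 1e-18)
  expect_lt(r$terms$p[1], 1e-10)
})

test_that("balanced ANOVA matches the longhand cell-means oracle and conserves SS", {
  set.seed(29)
  for (i in 1:10) {
    df <- expand.grid(gender = c("m", "f"), side = c("l", "r"), rep = 1:12,
                      KEEP.OUT.ATTRS = FALSE)
    df$value <- rnorm(nrow(df), mean = 1.2, sd = 0.35)
    r <- two_way_anova(df)
    o <- longhand_anova_balanced(df)
    expect_equal(r$terms$ss[1], o$ss_a, tolerance = 1e-9)
    expect_equal(r$terms$ss[2], o$ss_b, tolerance = 1e-9)
    expect_equal(r$terms$ss[3], o$ss_ab, tolerance = 1e-9)
    expect_equal(r$terms$ss[4], o$ss_err, tolerance = 1e-9)
    expect_equal(sum(r$terms$ss), r$ss_total, tolerance = 1e-9)
  }
})

test_that("ANOVA design validation catches bad tables", {
  df <- data.frame(value = rnorm(6), gender = "m", side = rep(c("l", "r"), 3))
  expect_error(two_way_anova(df), class = "fna_bad_table")
  df2 <- data.frame(value = rnorm(6),
                    gender = c("m", "m", "m", "f", "f", "f"),
                    side = c("l", "l", "l", "r", "r", "r"))
  expect_error(two_way_anova(df2), class = "fna_bad_design")
  expect_error(two_way_anova(data.frame(x = 1)), class = "fna_bad_table")
})

test_that("reliability simulation: zero rater noise gives identical repetitions", {
  st <- simulate_reliability_study(n_cases = 3, n_reps = 3, sigma_rater = 0,
                                   seed = 12)
  expect_null(st$failed)
  expect_equal(st$table[, 1], st$table[, 2], tolerance = 1e-12)
  expect_equal(st$table[, 1], st$table[, 3], tolerance = 1e-12)
  expect_equal(icc(st$table)$icc, 1, tolerance = 1e-9)
})

test_that("reliability simulation shape matches the requested design", {
  st <- simulate_reliability_study(n_cases = 3, n_raters = 2, n_reps = 2,
                                   sigma_rater = 0.3, seed = 21)
  expect_equal(dim(st$table), c(3, 4))
  expect_equal(nrow(st$measurements), 12)
  expect_true(all(is.finite(st$table)))
  # between-case variance dominates: ICC high
  expect_gt(icc(st$table)$icc, 0.9)
})
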