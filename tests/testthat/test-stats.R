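# t-test, factorial ANOVA and noncentral-F power against formula oracles.

test_that("pooled t-test matches the formula and the reference routine", {
  withr::with_seed(1, {
    a <- rnorm(6, 10, 2)
    b <- rnorm(6, 11, 2)
  })
  res <- independent_t_test(a, b)
  expect_equal(res$df, 10)  # two groups of six
  # brute-force formula oracle
  sp <- sqrt(((5) * var(a) + (5) * var(b)) / 10)
  t_oracle <- (mean(a) - mean(b)) / (sp * sqrt(1 / 6 + 1 / 6))
  expect_equal(res$t, t_oracle, tolerance = 1e-12)
  expect_equal(res$mean_diff, mean(a) - mean(b))
  # independent cross-check against the reference implementation
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(res$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
  # identical groups: t = 0, p = 1
  same <- independent_t_test(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  expect_error(independent_t_test(rep(1, 4), rep(1, 5)),
               class = "degenerate_data_error")
})

test_that("t-test type-I error is calibrated at alpha = 0.05", {
  n_rep <- 10000
  withr::with_seed(2024, {
    xa <- matrix(rnorm(6 * n_rep), 6)
    xb <- matrix(rnorm(6 * n_rep), 6)
  })
  ma <- colMeans(xa)
  mb <- colMeans(xb)
  va <- apply(xa, 2, var)
  vb <- apply(xb, 2, var)
  tstat <- (ma - mb) / sqrt((5 * va + 5 * vb) / 10 * (2 / 6))
  p <- 2 * pt(-abs(tstat), 10)
  rate <- mean(p < 0.05)
  expect_gte(rate, 0.04)
  expect_lte(rate, 0.06)
})

# independent sums-of-squares oracle from group means (balanced designs)
anova_ss_oracle <- function(df) {
  n <- nrow(df)
  gm <- mean(df$y)
  ss_main <- function(f) {
    m <- aggregate(df$y, list(df[[f]]), mean)
    sum((m$x - gm)^2) * (n / nrow(m))
  }
  ssA <- ss_main("A"); ssB <- ss_main("B"); ssC <- ss_main("C")
  ss_two <- function(f1, f2) {
    m <- aggregate(df$y, list(df[[f1]], df[[f2]]), mean)
    sum((m$x - gm)^2) * (n / nrow(m)) - ss_main(f1) - ss_main(f2)
  }
  ssAB <- ss_two("A", "B"); ssAC <- ss_two("A", "C"); ssBC <- ss_two("B", "C")
  mABC <- aggregate(df$y, list(df$A, df$B, df$C), mean)
  ss_cells <- sum((mABC$x - gm)^2) * (n / nrow(mABC))
  ssABC <- ss_cells - ssA - ssB - ssC - ssAB - ssAC - ssBC
  ss_total <- sum((df$y - gm)^2)
  ss_res <- ss_total - ss_cells
  c(A = ssA, B = ssB, C = ssC, `A:B` = ssAB, `A:C` = ssAC, `B:C` = ssBC,
    `A:B:C` = ssABC, residual = ss_res, total = ss_total)
}

test_that("balanced 2x2x2 ANOVA agrees with the sums-of-squares oracle", {
  withr::with_seed(11, {
    df <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"),
                      C = c("c1", "c2"), rep = 1:3)
    df$y <- rnorm(nrow(df), 5, 1) + 10 * (df$A == "a2")
  })
  res <- three_factor_anova(df, "y", c("A", "B", "C"))
  oracle <- anova_ss_oracle(df)
  expect_equal(res$effects$df1, rep(1L, 7))
  for (i in seq_len(7)) {
    e <- res$effects$effect[i]
    ms_res <- res$residual_ss / res$residual_df
    expect_equal(res$effects$F[i], unname(oracle[e]) / ms_res,
                 tolerance = 1e-10)
    expect_equal(res$effects$sum_sq[i], unname(oracle[e]), tolerance = 1e-10)
  }
  # the constructed +10 effect on A dominates
  expect_gt(res$effects$F[res$effects$effect == "A"], 100)
  expect_lt(res$effects$p_value[res$effects$effect == "A"], 0.001)
  # decomposition identity to 1e-10 relative
  ss_sum <- sum(res$effects$sum_sq) + res$residual_ss
  expect_equal(ss_sum, res$total_ss, tolerance = 1e-10)
})

test_that("constant response yields F = 0 and p = 1 throughout", {
  df <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"),
                    C = c("c1", "c2"), rep = 1:3)
  df$y <- 7
  res <- three_factor_anova(df, "y", c("A", "B", "C"))
  expect_true(all(res$effects$F == 0))
  expect_true(all(res$effects$p_value == 1))
})

test_that("unbalanced data falls back to Type II with a warning", {
  withr::with_seed(12, {
    df <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"),
                      C = c("c1", "c2"), rep = 1:4)
    df$y <- rnorm(nrow(df)) + 3 * (df$B == "b2")
    df <- df[-(1:4), ]  # drop one replicate from four cells
  })
  expect_warning(res <- three_factor_anova(df, "y", c("A", "B", "C")),
                 "Type-II")
  expect_equal(res$type, "II")
  expect_equal(res$effects$df1, rep(1L, 7))
  expect_lt(res$effects$p_value[res$effects$effect == "B"], 0.001)
})

test_that("cell summaries give mean ± SD per cell and marginal", {
  df <- data.frame(y = c(1, 2, 3, 4, 5, 6),
                   A = rep(c("x", "z"), each = 3),
                   B = "b", C = "c")
  s <- summarize_cells(df, "y", c("A", "B", "C"))
  cell_x <- s$cells[s$cells$A == "x", ]
  expect_equal(cell_x$mean, 2)
  expect_equal(cell_x$sd, 1)
  expect_equal(cell_x$label, "2.000 ± 1.000")
  # marginal mean equals the weighted mean of its cells (balanced)
  mA <- s$marginals[s$marginals$factor == "A", ]
  expect_equal(mA$mean, c(2, 5))
  expect_equal(mean(mA$mean), mean(df$y))
})

test_that("noncentral-F power analysis reproduces the study minimum of 108", {
  expect_identical(anova_power_min_n(f = 0.40, alpha = 0.05, power = 0.85,
                                     groups = 8, df1 = 7), 108L)
  # boundary: power insufficient at 107, sufficient at 108
  expect_lt(anova_power(107, 0.40, 0.05, 8, 7), 0.85)
  expect_gte(anova_power(108, 0.40, 0.05, 8, 7), 0.85)
})

test_that("power routine agrees with a quadrature oracle over a grid", {
  quad_power <- function(n, f, a, k, df1) {
    df2 <- n - k
    fc <- qf(1 - a, df1, df2)
    integrate(function(x) df(x, df1, df2, ncp = f^2 * n), fc, Inf,
              rel.tol = 1e-9)$value
  }
  grid <- list(c(0.40, 0.05, 0.85, 8, 7), c(0.25, 0.05, 0.80, 4, 3),
               c(0.30, 0.01, 0.90, 6, 5), c(0.50, 0.10, 0.95, 2, 1))
  for (g in grid) {
    n_pf <- anova_power_min_n(g[1], g[2], g[3], g[4], g[5])
    # oracle: smallest N whose quadrature power reaches the target
    n_quad <- n_pf
    while (n_quad > g[4] + 1 &&
           quad_power(n_quad - 1, g[1], g[2], g[4], g[5]) >= g[3])
      n_quad <- n_quad - 1
    while (quad_power(n_quad, g[1], g[2], g[4], g[5]) < g[3])
      n_quad <- n_quad + 1
    expect_lte(abs(n_pf - n_quad), 1)
  }
})

test_that("minimum sample size is monotone in effect size, alpha and power", {
  base <- anova_power_min_n(0.40, 0.05, 0.85, 8, 7)
  expect_lte(anova_power_min_n(0.50, 0.05, 0.85, 8, 7), base)
  expect_lte(anova_power_min_n(0.40, 0.10, 0.85, 8, 7), base)
  expect_gte(anova_power_min_n(0.40, 0.05, 0.95, 8, 7), base)
  expect_gte(anova_power_min_n(0.30, 0.05, 0.85, 8, 7), base)
  # saturation: an extreme effect needs only the smallest viable design
  expect_identical(anova_power_min_n(10, 0.05, 0.85, 8, 7), 10L)
  expect_error(anova_power_min_n(1e-4, 0.05, 0.85, 8, 7, n_cap = 2000),
               class = "convergence_error")
})
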