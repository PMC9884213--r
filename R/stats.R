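# Study statistics: pooled-variance t-test, 2x2x2 factorial ANOVA with all
# interactions and Table-style cell summaries, and noncentral-F power /
# minimum-sample-size computation.

#' Independent two-sample t-test (pooled variance)
#'
#' Equal-variance form: `df = n1 + n2 - 2`, mean difference =
#' `mean(a) - mean(b)`.  The pooled form is the one matching integer degrees
#' of freedom for equal group sizes (two groups of 6 give df = 10).
#'
#' @param group_a,group_b numeric vectors (each n >= 2).
#' @return List: `t`, `df`, `mean_diff`, `p_value` (two-sided).
#' @export
independent_t_test <- function(group_a, group_b) {
  n1 <- length(group_a)
  n2 <- length(group_b)
  stopifnot(n1 >= 2, n2 >= 2)
  sp2 <- ((n1 - 1) * var(group_a) + (n2 - 1) * var(group_b)) / (n1 + n2 - 2)
  if (sp2 <= 0)
    stop_crownforge("zero pooled variance: t statistic undefined",
                    "degenerate_data_error")
  md <- mean(group_a) - mean(group_b)
  tstat <- md / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = tstat, df = df, mean_diff = md,
       p_value = 2 * stats::pt(-abs(tstat), df))
}

#' Three-factor fixed-effects ANOVA with all interactions
#'
#' For a balanced 2x2x2 design the sums of squares decompose exactly
#' (Type I = Type II = Type III); every effect has numerator df 1.  With
#' unbalanced data (e.g. after removing corrupted specimens) a Type-II
#' decomposition is used with a warning.
#'
#' @param table `data.frame` containing the response and three factor
#'   columns.
#' @param response name of the response column.
#' @param factors character length-3: the factor column names.
#' @return An `anova3_result`: `effects` (data.frame with `effect`, `F`,
#'   `df1`, `df2`, `p_value`, `sum_sq`), `residual_ss`, `residual_df`,
#'   `total_ss`, `cells` (see [summarize_cells()]), `balanced`, `type`.
#' @export
three_factor_anova <- function(table, response, factors) {
  stopifnot(is.data.frame(table), length(factors) == 3,
            all(c(response, factors) %in% names(table)))
  df <- table[, c(response, factors)]
  names(df) <- c(".y", "A", "B", "C")
  for (v in c("A", "B", "C")) df[[v]] <- factor(df[[v]])
  if (any(vapply(df[c("A", "B", "C")], nlevels, integer(1)) != 2))
    stop_crownforge("all three factors must have exactly 2 levels",
                    "design_error")
  counts <- table(df$A, df$B, df$C)
  if (any(counts == 0))
    stop_crownforge("empty design cells: effects are not estimable",
                    "design_error")
  if (any(counts < 2))
    stop_crownforge("need >= 2 replicates per cell for a residual term",
                    "design_error")
  balanced <- length(unique(as.vector(counts))) == 1
  eff_names <- c("A", "B", "C", "A:B", "A:C", "B:C", "A:B:C")
  if (balanced) {
    fit <- aov(.y ~ A * B * C, data = df)
    sm <- summary(fit)[[1]]
    rn <- trimws(rownames(sm))
    res_row <- which(rn == "Residuals")
    eff <- data.frame(effect = rn[-res_row], sum_sq = sm$`Sum Sq`[-res_row],
                      df1 = sm$Df[-res_row], F = sm$`F value`[-res_row],
                      p_value = sm$`Pr(>F)`[-res_row])
    residual_ss <- sm$`Sum Sq`[res_row]
    residual_df <- sm$Df[res_row]
    type <- "I (= II/III, balanced)"
  } else {
    warning("unbalanced design: using Type-II sums of squares")
    fit <- lm(.y ~ A * B * C, data = df,
              contrasts = list(A = "contr.sum", B = "contr.sum",
                               C = "contr.sum"))
    sm <- car::Anova(fit, type = 2)
    rn <- trimws(rownames(sm))
    res_row <- which(rn == "Residuals")
    eff <- data.frame(effect = rn[-res_row], sum_sq = sm$`Sum Sq`[-res_row],
                      df1 = sm$Df[-res_row], F = sm$`F value`[-res_row],
                      p_value = sm$`Pr(>F)`[-res_row])
    residual_ss <- sm$`Sum Sq`[res_row]
    residual_df <- sm$Df[res_row]
    type <- "II"
  }
  eff$df2 <- residual_df
  eff$effect <- gsub("A", factors[1],
                     gsub("B", factors[2], gsub("C", factors[3], eff$effect)))
  # a numerically constant response has no signal: define F = 0, p = 1
  # rather than returning the 0/0 floating-point noise ratio
  total_ss <- sum((df$.y - mean(df$.y))^2)
  if (total_ss <= 1e-12 * nrow(df) * (abs(mean(df$.y)) + 1)^2 ||
      any(!is.finite(eff$F))) {
    eff$F <- 0
    eff$p_value <- 1
    eff$sum_sq <- 0
  }
  structure(list(effects = eff[, c("effect", "F", "df1", "df2", "p_value",
                                   "sum_sq")],
                 residual_ss = residual_ss, residual_df = residual_df,
                 total_ss = total_ss,
                 cells = summarize_cells(table, response, factors),
                 balanced = balanced, type = type),
            class = "anova3_result")
}

#' @export
print.anova3_result <- function(x, ...) {
  cat(sprintf("3-factor ANOVA (%s sums of squares, n = %d)\n", x$type,
              x$residual_df + sum(x$effects$df1) + 1))
  e <- x$effects
  for (i in seq_len(nrow(e))) {
    cat(sprintf("  %-40s F(%d) = %8.3f, P %s\n", e$effect[i], e$df1[i],
                e$F[i], format_p(e$p_value[i])))
  }
  invisible(x)
}

# p-value formatting used in report tables ("< 0.001" style, 3 decimals)
format_p <- function(p) {
  ifelse(p < 0.001, "< 0.001", sprintf("= %.3f", p))
}

#' Cell and marginal mean +/- SD summaries
#'
#' Per-cell and per-marginal summaries of a factorial table, in the layout
#' used for factorial ANOVA reporting (`"mean ± sd"`).
#'
#' @inheritParams three_factor_anova
#' @return List: `cells` (data.frame of every factor combination with `n`,
#'   `mean`, `sd`, `label`), `marginals` (per factor level).
#' @export
summarize_cells <- function(table, response, factors) {
  stopifnot(nrow(table) > 0, all(c(response, factors) %in% names(table)))
  y <- table[[response]]
  fs <- lapply(table[factors], factor)
  agg <- aggregate(y, by = fs, FUN = function(v)
    c(n = length(v), mean = mean(v), sd = if (length(v) > 1) sd(v) else 0))
  cells <- cbind(agg[, seq_along(factors), drop = FALSE],
                 as.data.frame(agg$x))
  names(cells)[seq_along(factors)] <- factors
  cells$label <- sprintf("%.3f ± %.3f", cells$mean, cells$sd)
  marginals <- do.call(rbind, lapply(factors, function(f) {
    a <- aggregate(y, by = list(level = fs[[f]]), FUN = function(v)
      c(n = length(v), mean = mean(v), sd = if (length(v) > 1) sd(v) else 0))
    data.frame(factor = f, level = as.character(a$level),
               as.data.frame(a$x))
  }))
  marginals$label <- sprintf("%.3f ± %.3f", marginals$mean, marginals$sd)
  list(cells = cells, marginals = marginals)
}

#' Power of a fixed-effects ANOVA at a given total sample size
#'
#' Noncentral-F power: `P(F' > F_crit)` with `F' ~ F(df1, N - groups,
#' ncp = f^2 N)` and `F_crit` the central upper-alpha quantile.
#'
#' @param n total sample size.
#' @param f Cohen's effect size f.
#' @param alpha significance level.
#' @param groups number of cells/groups (error df = N - groups).
#' @param df1 numerator degrees of freedom.
#' @return Power in (0, 1).
#' @export
anova_power <- function(n, f, alpha = 0.05, groups = 8, df1 = groups - 1) {
  stopifnot(n > groups)
  df2 <- n - groups
  fcrit <- qf(1 - alpha, df1, df2)
  1 - pf(fcrit, df1, df2, ncp = f^2 * n)
}

#' Minimum total sample size for a target ANOVA power
#'
#' Smallest `N` such that the noncentral-F power reaches `power`.  The
#' default configuration is the omnibus fixed-effects test of the 2x2x2
#' design: 8 groups, numerator df 7.
#'
#' @param f Cohen's effect size f (> 0).
#' @param alpha significance level in (0, 1).
#' @param power target power in (0, 1).
#' @param groups number of groups.
#' @param df1 numerator degrees of freedom.
#' @param n_cap search cap on N.
#' @return Integer minimum total sample size.
#' @export
anova_power_min_n <- function(f = 0.40, alpha = 0.05, power = 0.85,
                              groups = 8, df1 = 7, n_cap = 100000L) {
  stopifnot(f > 0, alpha > 0, alpha < 1, power > 0, power < 1, groups >= 2,
            df1 >= 1)
  for (n in seq.int(groups + 1L, n_cap)) {
    if (anova_power(n, f, alpha, groups, df1) >= power) return(as.integer(n))
  }
  stop_crownforge(sprintf(
    "target power %.2f not reachable below N = %d at f = %g", power, n_cap, f),
    "convergence_error")
}
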