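# Statistical layer: one-way repeated-measures ANOVA with eta-squared and
# FDR-corrected follow-ups; two-sample t tests with automatic Welch
# correction; Cohen's d; Monte Carlo power/type-I checks.

#' Construct a statistical test result
#' @noRd
stat_result <- function(test_name, statistic, df, p_value, effect_size,
                        effect_size_name, correction = "none",
                        decisions = NULL) {
  structure(
    list(test_name = test_name, statistic = statistic, df = df,
         p_value = p_value, effect_size = effect_size,
         effect_size_name = effect_size_name, correction = correction,
         decisions = decisions),
    class = "stat_result"
  )
}

#' @export
print.stat_result <- function(x, digits = 4, ...) {
  df_txt <- paste(signif(x$df, 3), collapse = ", ")
  stat_letter <- if (grepl("ANOVA", x$test_name)) "F" else "t"
  cat(sprintf("%s: %s (%s) = %s, p = %s, %s = %s\n",
              x$test_name, stat_letter, df_txt,
              signif(x$statistic, digits), signif(x$p_value, digits),
              x$effect_size_name, signif(x$effect_size, digits)))
  if (x$correction != "none") cat(sprintf("  correction: %s\n", x$correction))
  if (!is.null(x$decisions) && length(x$decisions)) {
    cat("  assumption checks (p):",
        paste(sprintf("%s = %.3g", names(x$decisions), x$decisions),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Eta-squared for an F statistic
#'
#' The partial form `F * df1 / (F * df1 + df2)`, the effect size reported
#' alongside repeated-measures ANOVA results.
#'
#' @param f F statistic.
#' @param df1,df2 numerator and denominator degrees of freedom.
#' @return effect size in `[0, 1]`.
#' @export
eta_squared_from_f <- function(f, df1, df2) {
  stopifnot(df1 > 0, df2 > 0, f >= 0)
  if (!is.finite(f)) return(1)
  f * df1 / (f * df1 + df2)
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject decomposition of a complete subjects x conditions table:
#' `SS_total = SS_condition + SS_subject + SS_error`, with
#' `F = MS_condition / MS_error` on `(k - 1, (k - 1)(n - 1))` degrees of
#' freedom.  The effect size is [eta_squared_from_f()].  No sphericity
#' correction is applied by default; `gg_correction = TRUE` applies the
#' Greenhouse-Geisser epsilon to the degrees of freedom.
#'
#' @param values numeric matrix, rows = subjects (mice), columns =
#'   conditions (regions); must be complete.
#' @param gg_correction apply the Greenhouse-Geisser correction.
#' @return a `stat_result` with `effect_size_name = "eta_squared"`.
#' @export
rm_anova <- function(values, gg_correction = FALSE) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("missing cells: the matched-section rule should guarantee a complete table")
  n <- nrow(values); k <- ncol(values)
  if (n < 2L || k < 2L) stop("need at least 2 subjects and 2 conditions")
  grand <- mean(values)
  cond_means <- colMeans(values)
  subj_means <- rowMeans(values)
  ss_cond <- n * sum((cond_means - grand)^2)
  ss_subj <- k * sum((subj_means - grand)^2)
  ss_tot <- sum((values - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  ms_cond <- ss_cond / df1
  ms_err <- ss_err / df2
  f <- if (ms_err <= .Machine$double.eps * max(1, ms_cond)) {
    if (ss_cond <= 1e-12 * max(1, ss_tot)) 0 else Inf
  } else ms_cond / ms_err
  eps <- 1
  if (gg_correction && k > 2L) {
    # Greenhouse-Geisser epsilon from the double-centered covariance
    s <- stats::cov(values)
    dc <- s - outer(rowMeans(s), rep(1, k)) - outer(rep(1, k), colMeans(s)) +
      mean(s)
    eps <- sum(diag(dc))^2 / ((k - 1) * sum(dc^2))
    eps <- min(1, max(1 / (k - 1), eps))
  }
  p <- if (!is.finite(f)) 0 else if (f == 0) 1 else
    stats::pf(f, df1 * eps, df2 * eps, lower.tail = FALSE)
  stat_result(
    "one-way repeated-measures ANOVA", f, c(df1 * eps, df2 * eps), p,
    eta_squared_from_f(f, df1, df2), "eta_squared",
    correction = if (gg_correction) "greenhouse_geisser" else "none"
  )
}

#' FDR-controlling step-up decisions for follow-up comparisons
#'
#' `method = "two_stage"` (default) is the two-stage step-up procedure:
#' a first Benjamini-Hochberg pass at `q / (1 + q)` estimates the number
#' of true nulls, and a second pass at the inflated level
#' `q / (1 + q) * m / m0` makes the final decisions.  `method = "step_up"`
#' is the plain Benjamini-Hochberg step-up rule.
#'
#' @param p numeric vector of p-values.
#' @param q target false discovery rate.
#' @param method `"two_stage"` or `"step_up"`.
#' @return logical vector of discovery flags, aligned with `p`.
#' @export
fdr_followups <- function(p, q = 0.05, method = c("two_stage", "step_up")) {
  method <- match.arg(method)
  if (length(p) == 0L) stop("need at least one p-value")
  if (any(p < 0 | p > 1 | is.na(p))) stop("p-values must lie in [0, 1]")
  bh_reject <- function(p, level) {
    m <- length(p)
    ord <- order(p)
    ps <- p[ord]
    below <- which(ps <= seq_len(m) * level / m)
    out <- rep(FALSE, m)
    if (length(below)) out[ord[seq_len(max(below))]] <- TRUE
    out
  }
  if (method == "step_up") return(bh_reject(p, q))
  m <- length(p)
  q1 <- q / (1 + q)
  stage1 <- bh_reject(p, q1)
  r1 <- sum(stage1)
  if (r1 == 0L) return(stage1)
  if (r1 == m) return(stage1)
  bh_reject(p, q1 * m / (m - r1))
}

#' Pairwise paired t tests between conditions of a repeated-measures table
#'
#' Follow-up comparisons for [rm_anova()]: a two-tailed paired t test for
#' every pair of columns, plus FDR discovery flags from [fdr_followups()].
#'
#' @inheritParams rm_anova
#' @param q target false discovery rate for the follow-ups.
#' @param method FDR variant, see [fdr_followups()].
#' @return data frame with `a`, `b`, `t`, `df`, `p`, `cohens_d` (paired),
#'   `discovery`.
#' @export
rm_anova_followups <- function(values, q = 0.05,
                               method = c("two_stage", "step_up")) {
  values <- as.matrix(values)
  k <- ncol(values)
  cn <- colnames(values)
  if (is.null(cn)) cn <- paste0("cond", seq_len(k))
  pairs <- utils::combn(k, 2)
  res <- apply(pairs, 2, function(ij) {
    d <- values[, ij[1]] - values[, ij[2]]
    tt <- stats::t.test(d)
    c(t = unname(tt$statistic), df = unname(tt$parameter),
      p = tt$p.value, d = mean(d) / stats::sd(d))
  })
  out <- data.frame(
    a = cn[pairs[1, ]], b = cn[pairs[2, ]],
    t = res["t", ], df = res["df", ], p = res["p", ],
    cohens_d = res["d", ]
  )
  out$discovery <- fdr_followups(out$p, q = q, method = match.arg(method))
  out
}

#' Two-sample two-tailed t test with automatic Welch correction
#'
#' In `"auto"` mode an F test of variance equality (alpha = 0.05) decides
#' between the pooled Student test and Welch's unequal-variance test
#' (Satterthwaite degrees of freedom); Shapiro-Wilk normality checks are
#' recorded alongside the decision trail.  Cohen's d (pooled SD) is
#' attached as the effect size.
#'
#' @param x,y numeric samples (each of length >= 2).
#' @param mode `"auto"`, `"student"` or `"welch"`.
#' @return a `stat_result`; `decisions` carries the assumption-check
#'   p-values, `correction` is `"welch"` or `"none"`.
#' @export
two_sample_t <- function(x, y, mode = c("auto", "student", "welch")) {
  mode <- match.arg(mode)
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    if (isTRUE(all.equal(mean(x), mean(y))))
      stop("t undefined: both groups constant with equal means")
    return(stat_result("two-sample t test",
                       sign(mean(x) - mean(y)) * Inf,
                       length(x) + length(y) - 2, 0,
                       NA_real_, "cohens_d"))
  }
  decisions <- c(
    shapiro_x = if (length(x) >= 3L) stats::shapiro.test(x)$p.value else NA,
    shapiro_y = if (length(y) >= 3L) stats::shapiro.test(y)$p.value else NA,
    var_f = stats::var.test(x, y)$p.value
  )
  welch <- switch(mode,
    auto = decisions[["var_f"]] < 0.05,
    student = FALSE,
    welch = TRUE
  )
  tt <- stats::t.test(x, y, var.equal = !welch)
  stat_result(
    if (welch) "Welch two-sample t test" else "Student two-sample t test",
    unname(tt$statistic), unname(tt$parameter), tt$p.value,
    cohens_d(x, y), "cohens_d",
    correction = if (welch) "welch" else "none",
    decisions = decisions
  )
}

#' Cohen's d for two independent samples
#'
#' `d = (mean(x) - mean(y)) / s_pooled` with the pooled SD by default;
#' `method = "average_variance"` uses `sqrt((s_x^2 + s_y^2) / 2)` instead.
#'
#' @param x,y numeric samples.
#' @param method pooling convention for the denominator.
#' @return Cohen's d (signed).
#' @export
cohens_d <- function(x, y, method = c("pooled", "average_variance")) {
  method <- match.arg(method)
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 2L, n2 >= 2L)
  s2 <- switch(method,
    pooled = ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
      (n1 + n2 - 2),
    average_variance = (stats::var(x) + stats::var(y)) / 2
  )
  if (s2 <= 0) stop("pooled SD is zero: d undefined")
  (mean(x) - mean(y)) / sqrt(s2)
}

#' Cohen's d recovered from a pooled-variance t statistic
#'
#' `d = t * sqrt(1/n1 + 1/n2)`, the algebraic identity for the pooled
#' Student case; useful to recompute effect sizes from reported test
#' statistics and group sizes.
#'
#' @param t t statistic.
#' @param n1,n2 group sizes.
#' @return Cohen's d.
#' @export
cohens_d_from_t <- function(t, n1, n2) {
  stopifnot(is.finite(t), n1 >= 2L, n2 >= 2L)
  t * sqrt(1 / n1 + 1 / n2)
}

#' Monte Carlo rejection rate of the two-sample comparison
#'
#' Simulates cohorts of per-mouse densities with lognormal mouse-to-mouse
#' variation, scales one group by `effect_ratio`, and reports the fraction
#' of simulations where [two_sample_t()] (auto mode) rejects at
#' `alpha = 0.05`.  With `effect_ratio = 1` this measures the realized
#' type-I error; with a true effect it estimates power.
#'
#' @param effect_ratio ratio of group-2 to group-1 means (1 = null).
#' @param n_per_group mice per group.
#' @param noise_cv coefficient of variation of per-mouse values.
#' @param n_sim number of simulated cohorts (>= 100).
#' @param seed RNG seed.
#' @param alpha rejection level.
#' @return rejection rate in `[0, 1]`.
#' @export
power_check <- function(effect_ratio, n_per_group = 5L, noise_cv = 0.3,
                        n_sim = 1000L, seed = 1L, alpha = 0.05) {
  stopifnot(n_sim >= 100L, effect_ratio > 0, noise_cv > 0)
  s <- sqrt(log(1 + noise_cv^2))
  with_seed(seed, {
    rej <- logical(n_sim)
    for (i in seq_len(n_sim)) {
      g1 <- exp(stats::rnorm(n_per_group, -s^2 / 2, s))
      g2 <- effect_ratio * exp(stats::rnorm(n_per_group, -s^2 / 2, s))
      rej[i] <- two_sample_t(g1, g2)$p_value < alpha
    }
    mean(rej)
  })
}
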