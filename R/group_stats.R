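# Normality-gated two-group comparisons.
#
# The study procedure: test each group (or the paired differences) for
# normality with Shapiro-Wilk at alpha; if nothing rejects, use a t-test
# (Welch by default), otherwise the Wilcoxon test (rank-sum unpaired,
# signed-rank paired). Two-sided p-values throughout; t statistics are
# reported as |t|.

#' Shapiro-Wilk normality test
#'
#' In-package implementation of the standard W statistic and p-value
#' approximation (Royston's algorithm: Blom-score coefficients corrected at
#' the extremes, with the log-normal / log-log-normal null approximations
#' for the p-value). Valid for 3 <= n <= 5000.
#'
#' @param values numeric vector, 3 to 5000 finite values, not all equal.
#' @return list of class `shapiro_wilk` with `statistic` (W) and `p_value`.
#' @export
shapiro_wilk <- function(values) {
  x <- sort(as.numeric(values))
  n <- length(x)
  if (n < 3L || n > 5000L)
    stop("Shapiro-Wilk requires 3 <= n <= 5000", call. = FALSE)
  if (x[n] == x[1]) stop("all values identical: zero variance", call. = FALSE)

  m <- qnorm((seq_len(n) - 0.375) / (n + 0.25))
  u <- 1 / sqrt(n)
  if (n == 3L) {
    a <- c(-sqrt(0.5), 0, sqrt(0.5))
  } else {
    cn <- m / sqrt(sum(m^2))
    a_n <- cn[n] + 0.221157 * u - 0.147981 * u^2 - 2.071190 * u^3 +
      4.434685 * u^4 - 2.706056 * u^5
    if (n <= 5L) {
      phi <- (sum(m^2) - 2 * m[n]^2) / (1 - 2 * a_n^2)
      a <- m / sqrt(phi)
      a[c(1L, n)] <- c(-a_n, a_n)
    } else {
      a_n1 <- cn[n - 1L] + 0.042981 * u - 0.293762 * u^2 - 1.752461 * u^3 +
        5.682633 * u^4 - 3.582633 * u^5
      phi <- (sum(m^2) - 2 * m[n]^2 - 2 * m[n - 1L]^2) /
        (1 - 2 * a_n^2 - 2 * a_n1^2)
      a <- m / sqrt(phi)
      a[c(1L, 2L, n - 1L, n)] <- c(-a_n, -a_n1, a_n1, a_n)
    }
  }
  W <- sum(a * x)^2 / sum((x - mean(x))^2)
  W <- min(W, 1)

  if (n == 3L) {
    p <- (6 / pi) * (asin(sqrt(W)) - asin(sqrt(0.75)))
    p <- min(max(p, 0), 1)
  } else if (n <= 11L) {
    g <- -2.273 + 0.459 * n
    mu <- 0.5440 - 0.39978 * n + 0.025054 * n^2 - 0.0006714 * n^3
    sig <- exp(1.3822 - 0.77857 * n + 0.062767 * n^2 - 0.0020322 * n^3)
    z <- (-log(g - log1p(-W)) - mu) / sig
    p <- pnorm(z, lower.tail = FALSE)
  } else {
    ln <- log(n)
    mu <- -1.5861 - 0.31082 * ln - 0.083751 * ln^2 + 0.0038915 * ln^3
    sig <- exp(-0.4803 - 0.082676 * ln + 0.0030302 * ln^2)
    z <- (log1p(-W) - mu) / sig
    p <- pnorm(z, lower.tail = FALSE)
  }
  structure(list(statistic = W, p_value = p), class = "shapiro_wilk")
}

has_ties <- function(x) anyDuplicated(x) > 0L

# Wilcoxon wrapper: exact null for small tie-free samples, normal
# approximation with continuity correction otherwise (stats::wilcox.test
# switches automatically; warnings about ties/zeroes are expected and
# silenced).
run_wilcoxon <- function(a, b, paired, exact_max = 25L) {
  if (paired) {
    d <- a - b
    d <- d[d != 0]
    exact <- length(d) <= exact_max && !has_ties(abs(d))
  } else {
    exact <- (length(a) + length(b)) <= 2L * exact_max &&
      !has_ties(c(a, b))
  }
  suppressWarnings(
    wilcox.test(a, b, paired = paired, exact = exact, correct = TRUE))
}

#' Normality-gated two-group comparison
#'
#' Unpaired: if both groups pass Shapiro-Wilk at `alpha`, a two-sample
#' t-test (Welch by default); otherwise the Wilcoxon rank-sum test.
#' Paired: the gate runs on the differences; paired t-test vs Wilcoxon
#' signed-rank. A zero-variance group (or zero-variance differences), where
#' the normality test is undefined, routes to the nonparametric branch.
#' All paired differences zero is a degenerate no-signal case, flagged with
#' p = 1.
#'
#' @param a,b numeric vectors (paired: same length, matched order).
#' @param paired logical.
#' @param alpha normality-gate threshold (default 0.05).
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @param test `"auto"` (the normality gate, default) or a specific test
#'   to force: `"t"` or `"wilcoxon"`; normality p-values are still
#'   reported.
#' @param label optional comparison label carried into the result.
#' @return list of class `group_comparison`: `label`, `test_used` (one of
#'   `t_test`, `paired_t_test`, `wilcoxon_rank_sum`,
#'   `wilcoxon_signed_rank`, or `none` for the degenerate case),
#'   `statistic` (|t|, W or V), `p_value`, `degenerate`, `n_a`, `n_b`,
#'   `mean_a`, `sd_a`, `mean_b`, `sd_b`, `summary_a`, `summary_b`, and
#'   `normality_p_a`/`normality_p_b` (unpaired) or `normality_p_diff`
#'   (paired).
#' @export
compare_groups <- function(a, b, paired = FALSE, alpha = 0.05,
                           var_equal = FALSE,
                           test = c("auto", "t", "wilcoxon"), label = "") {
  test <- match.arg(test)
  a <- as.numeric(a); b <- as.numeric(b)
  if (anyNA(a) || anyNA(b)) stop("NA values in comparison", call. = FALSE)
  if (paired && length(a) != length(b))
    stop("paired comparison with unequal group sizes", call. = FALSE)
  if (length(a) < 3L || length(b) < 3L)
    stop("each group needs at least 3 values", call. = FALSE)

  base <- list(
    label = label, paired = paired, degenerate = FALSE,
    n_a = length(a), n_b = length(b),
    mean_a = mean(a), sd_a = sd(a), mean_b = mean(b), sd_b = sd(b),
    summary_a = summarize_values(a)$text,
    summary_b = summarize_values(b)$text)

  if (paired) {
    d <- a - b
    if (all(d == 0)) {
      out <- c(base, list(test_used = "none", statistic = NA_real_,
                          p_value = 1, normality_p_diff = NA_real_))
      out$degenerate <- TRUE
      class(out) <- "group_comparison"
      return(out)
    }
    p_norm <- if (var(d) == 0) NA_real_ else shapiro_wilk(d)$p_value
    use_t <- if (test == "auto") !is.na(p_norm) && p_norm >= alpha
             else test == "t"
    if (use_t) {
      tt <- t.test(a, b, paired = TRUE)
      out <- c(base, list(test_used = "paired_t_test",
                          statistic = abs(unname(tt$statistic)),
                          p_value = tt$p.value, normality_p_diff = p_norm))
    } else {
      wt <- run_wilcoxon(a, b, paired = TRUE)
      out <- c(base, list(test_used = "wilcoxon_signed_rank",
                          statistic = unname(wt$statistic),
                          p_value = wt$p.value, normality_p_diff = p_norm))
    }
  } else {
    p_a <- if (var(a) == 0) NA_real_ else shapiro_wilk(a)$p_value
    p_b <- if (var(b) == 0) NA_real_ else shapiro_wilk(b)$p_value
    use_t <- if (test == "auto")
      !is.na(p_a) && !is.na(p_b) && p_a >= alpha && p_b >= alpha
    else test == "t"
    if (use_t) {
      tt <- t.test(a, b, var.equal = var_equal)
      out <- c(base, list(test_used = "t_test",
                          statistic = abs(unname(tt$statistic)),
                          p_value = tt$p.value,
                          normality_p_a = p_a, normality_p_b = p_b))
    } else {
      wt <- run_wilcoxon(a, b, paired = FALSE)
      out <- c(base, list(test_used = "wilcoxon_rank_sum",
                          statistic = unname(wt$statistic),
                          p_value = wt$p.value,
                          normality_p_a = p_a, normality_p_b = p_b))
    }
  }
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s%s: %s, statistic = %.4g, p = %.4g (n = %d vs %d)\n",
              if (nzchar(x$label)) paste0(x$label, " ") else "",
              if (x$paired) "[paired]" else "[unpaired]",
              x$test_used,
              if (is.na(x$statistic)) NA else x$statistic,
              x$p_value, x$n_a, x$n_b))
  cat(sprintf("  group a: %s   group b: %s\n", x$summary_a, x$summary_b))
  invisible(x)
}

#' Mean and sample standard deviation, rendered "mean \eqn{\pm} sd"
#'
#' @param values numeric vector, n >= 2.
#' @param percent render on the x100 percent scale with a % sign.
#' @param digits decimals in the rendered text (default 2).
#' @return list with `mean`, `sd` and `text`.
#' @export
summarize_values <- function(values, percent = FALSE, digits = 2L) {
  if (length(values) < 2L)
    stop("summary needs at least 2 values", call. = FALSE)
  m <- mean(values); s <- sd(values)
  scale <- if (percent) 100 else 1
  unit <- if (percent) "%" else ""
  text <- sprintf("%.*f%s ± %.*f%s", digits, m * scale, unit,
                  digits, s * scale, unit)
  list(mean = m, sd = s, text = text)
}
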