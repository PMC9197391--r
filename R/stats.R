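# Exact small-sample nonparametric tests and group summaries.
#
# Both tests compute exact two-sided p-values for small samples by dynamic
# programming over the full permutation distribution (equivalent to
# enumerating all sign assignments / group assignments, including tied
# data via mid-ranks), and fall back to the normal approximation with tie
# correction and continuity correction for larger samples.  Two-sided p is
# 2 * min(lower tail, upper tail), capped at 1.

# distribution of 2*signed-rank statistic: counts over 0..sum(s2)
signed_rank_counts <- function(s2) {
  total <- sum(s2)
  counts <- numeric(total + 1)
  counts[1] <- 1
  for (s in s2) {
    shifted <- c(numeric(s), counts[seq_len(total + 1 - s)])
    counts <- counts + shifted
  }
  counts
}

#' Exact Wilcoxon signed-rank test
#'
#' Paired two-sided test on differences.  Zero differences are dropped
#' (classical convention); ties among |differences| use mid-ranks.  Exact
#' by full enumeration of the 2^n sign assignments (via dynamic
#' programming) for `n <= exact_max`, normal approximation with tie and
#' continuity correction above.
#'
#' @param x numeric vector of paired differences, or first sample if `y`
#'   given.
#' @param y optional second sample; differences are `x - y`.
#' @param exact_max largest n for the exact distribution (default 25).
#' @return A list of class `nonparam_test`: `p_value`, `statistic` (sum of
#'   positive signed ranks), `n` (non-zero differences), `method`,
#'   `exact`, `diagnostic`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_max = 25) {
  d <- if (is.null(y)) as.numeric(x) else as.numeric(x) - as.numeric(y)
  if (length(d) < 2) stop("wilcoxon_signed_rank: need n >= 2")
  d <- d[d != 0]
  diagnostic <- NULL
  if (length(d) == 0) {
    return(structure(list(p_value = 1, statistic = 0, n = 0,
                          method = "wilcoxon_signed_rank", exact = TRUE,
                          diagnostic = "all differences zero"),
                     class = "nonparam_test"))
  }
  if (length(d) < 2)
    diagnostic <- "only one non-zero difference"
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_max) {
    s2 <- as.integer(round(2 * r))
    counts <- signed_rank_counts(s2)
    total <- 2^n
    w2 <- as.integer(round(2 * W))
    lo <- sum(counts[seq_len(w2 + 1)]) / total          # P(W <= w)
    hi <- sum(counts[(w2 + 1):length(counts)]) / total  # P(W >= w)
    p <- min(1, 2 * min(lo, hi))
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
    exact <- FALSE
  }
  structure(list(p_value = p, statistic = W, n = n,
                 method = "wilcoxon_signed_rank", exact = exact,
                 diagnostic = diagnostic),
            class = "nonparam_test")
}

# counts of rank-sum values over all size-na subsets of scaled ranks s2
rank_sum_counts <- function(s2, na) {
  total <- sum(s2)
  # dp[k+1, w+1] = number of size-k subsets with scaled sum w
  dp <- matrix(0, na + 1, total + 1)
  dp[1, 1] <- 1
  for (s in s2) {
    for (k in na:1) {
      row <- dp[k, ]
      if (!any(row != 0)) next
      shifted <- c(numeric(s), row[seq_len(total + 1 - s)])
      dp[k + 1, ] <- dp[k + 1, ] + shifted
    }
  }
  dp[na + 1, ]
}

#' Exact Mann-Whitney (rank-sum) test
#'
#' Unpaired two-sided test.  Exact by enumeration of all group assignments
#' of the (mid-)ranks for `n_a + n_b <= exact_max`, normal approximation
#' with tie and continuity correction above.
#'
#' @param a,b numeric samples (both non-empty).
#' @param exact_max largest combined n for the exact distribution
#'   (default 20).
#' @return A list of class `nonparam_test`: `p_value`, `statistic`
#'   (rank sum of `a`), `n` (`c(n_a, n_b)`), `method`, `exact`.
#' @export
mann_whitney <- function(a, b, exact_max = 20) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0)
    stop("mann_whitney: both groups must be non-empty")
  na <- length(a); nb <- length(b); N <- na + nb
  r <- rank(c(a, b))
  W <- sum(r[seq_len(na)])
  if (N <= exact_max) {
    s2 <- as.integer(round(2 * r))
    counts <- rank_sum_counts(s2, na)
    total <- choose(N, na)
    w2 <- as.integer(round(2 * W))
    lo <- sum(counts[seq_len(w2 + 1)]) / total
    hi <- sum(counts[(w2 + 1):length(counts)]) / total
    p <- min(1, 2 * min(lo, hi))
    exact <- TRUE
  } else {
    mu <- na * (N + 1) / 2
    tie_tab <- table(r)
    sig2 <- na * nb / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
    exact <- FALSE
  }
  structure(list(p_value = p, statistic = W, n = c(na, nb),
                 method = "mann_whitney", exact = exact, diagnostic = NULL),
            class = "nonparam_test")
}

#' @export
print.nonparam_test <- function(x, ...) {
  cat(sprintf("<%s> W = %g, n = %s, p = %.5g (%s)%s\n",
              x$method, x$statistic, paste(x$n, collapse = "/"), x$p_value,
              if (x$exact) "exact" else "normal approximation",
              if (!is.null(x$diagnostic)) paste0(" [", x$diagnostic, "]")
              else ""))
  invisible(x)
}

#' Group summary: median and SEM
#'
#' Reports the sample median with a mean-based standard error
#' (`sd/sqrt(n)`), the "median +/- sem" convention.  A single observation
#' yields SEM 0 with a diagnostic attribute.
#'
#' @param values numeric vector, n >= 1.
#' @return `list(median, sem, n)`.
#' @export
summarize_group <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0) stop("summarize_group: empty input")
  out <- list(median = stats::median(values),
              sem = if (length(values) > 1) sd(values) / sqrt(length(values))
                    else 0,
              n = length(values))
  if (length(values) == 1) attr(out, "diagnostic") <- "single value; SEM 0 by convention"
  out
}

#' Two-group comparison with the appropriate nonparametric test
#'
#' @param a,b numeric samples; with `paired = TRUE` they must align by
#'   observation unit and the Wilcoxon signed-rank test is applied to
#'   `b - a`, otherwise the Mann-Whitney test compares the groups.
#' @param labels character pair naming the groups.
#' @param paired logical.
#' @return A list of class `group_comparison`: per-group `median`, `sem`,
#'   `n`, plus `test`, `p_value`, `paired`.
#' @export
group_comparison <- function(a, b, labels = c("a", "b"), paired = FALSE) {
  if (paired && length(a) != length(b))
    stop("group_comparison: paired groups must have equal n")
  test <- if (paired) wilcoxon_signed_rank(b, a) else mann_whitney(a, b)
  sa <- summarize_group(a); sb <- summarize_group(b)
  structure(list(labels = labels,
                 median = c(sa$median, sb$median),
                 sem = c(sa$sem, sb$sem),
                 n = c(sa$n, sb$n),
                 test = test$method, p_value = test$p_value,
                 paired = paired),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(paste0("<group_comparison> %s: %.3g +/- %.3g (n=%d) vs ",
                     "%s: %.3g +/- %.3g (n=%d); %s p = %.4g%s\n"),
              x$labels[1], x$median[1], x$sem[1], x$n[1],
              x$labels[2], x$median[2], x$sem[2], x$n[2],
              x$test, x$p_value, if (x$paired) " (paired)" else ""))
  invisible(x)
}
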