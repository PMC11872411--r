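#' Wilcoxon rank-sum test with an exact small-sample mode
#'
#' Two-sided rank-sum test using midranks for ties. For `length(x) +
#' length(y) <= 12` the null distribution is enumerated exactly over all
#' rank splits (ties handled by enumerating the observed midranks); larger
#' samples use the tie-corrected normal approximation with continuity
#' correction. The mode actually used is recorded in the result.
#'
#' @param x,y numeric vectors (each non-empty).
#' @param mode `"auto"` (exact when feasible), `"exact"`, or `"normal"`.
#' @return List with `statistic` (rank sum of `x`), `p_value`, `mode`.
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (length(x) < 1 || length(y) < 1) abort("both samples must be non-empty")
  m <- length(x); n <- length(y); N <- m + n
  r <- rank(c(x, y))
  w <- sum(r[seq_len(m)])
  if (mode == "auto") mode <- if (N <= 12) "exact" else "normal"
  if (mode == "exact") {
    if (choose(N, m) > 5e6) abort("exact mode infeasible for this sample size")
    splits <- combn(N, m)
    ws <- colSums(matrix(r[splits], nrow = m))
    # two-sided: double the smaller tail (capped), the convention matched by
    # the brute-force enumeration oracle
    p_lo <- mean(ws <= w + 1e-9)
    p_hi <- mean(ws >= w - 1e-9)
    p <- min(1, 2 * min(p_lo, p_hi))
  } else {
    mu <- m * (N + 1) / 2
    ties <- table(r)
    tie_corr <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- m * n / 12 * ((N + 1) - tie_corr)
    if (sigma2 <= 0) return(list(statistic = w, p_value = 1, mode = mode))
    z <- (abs(w - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-max(z, 0)))
  }
  list(statistic = w, p_value = p, mode = mode)
}

#' Statistical power of the one-sample t-test
#'
#' Power at sample size `n` for standardised effect size `d` and two-sided
#' significance level `alpha`, under the noncentral-t formulation:
#' the test statistic has a noncentral t distribution with `n - 1` degrees
#' of freedom and noncentrality `d * sqrt(n)`.
#'
#' @param n sample size (>= 2).
#' @param d standardised effect size (> 0).
#' @param alpha two-sided significance level in (0, 1).
#' @return Achieved power in (0, 1).
#' @export
power_at <- function(n, d, alpha = 0.05) {
  if (any(n < 2)) abort("n must be at least 2")
  if (d <= 0) abort("effect size d must be positive")
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  vapply(n, function(ni) {
    stats::power.t.test(n = ni, delta = d, sd = 1, sig.level = alpha,
                        type = "one.sample", strict = TRUE)$power
  }, 0)
}

#' Required sample size for target power
#'
#' Smallest integer `n` whose one-sample t-test power reaches `power`,
#' together with the un-rounded solution of the power equation.
#'
#' @param d standardised effect size (> 0).
#' @param alpha two-sided significance level in (0, 1).
#' @param power target power in (0, 1).
#' @return List with `n_exact` (un-rounded), `n_required` (integer) and
#'   `achieved_power` at `n_required`.
#' @export
power_sample_size <- function(d, alpha = 0.05, power = 0.8) {
  if (d <= 0) abort("effect size d must be positive")
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  if (power <= 0 || power >= 1) abort("power must be in (0, 1)")
  n_exact <- stats::power.t.test(delta = d, sd = 1, sig.level = alpha,
                                 power = power, type = "one.sample",
                                 strict = TRUE)$n
  n_required <- ceiling(n_exact - 1e-9)
  list(n_exact = n_exact, n_required = n_required,
       achieved_power = power_at(n_required, d, alpha))
}

# AUC as the normalised Mann-Whitney U statistic with half credit for ties.
# labels: logical/0-1, TRUE = positive class.
auc_mw <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) abort("both classes must be present")
  r <- rank(scores)
  u <- sum(r[labels]) - n1 * (n1 + 1) / 2
  u / (n1 * n0)
}
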