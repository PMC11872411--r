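#' ROC curve with Youden-index threshold and bootstrap CIs
#'
#' Computes the empirical ROC over all distinct score cuts, the AUC (by the
#' trapezoid rule, identical to the tie-corrected Mann-Whitney U statistic),
#' and the operating threshold maximising the Youden index
#' (sensitivity + specificity - 1). Ties among Youden maximisers are
#' resolved by a uniform random choice under the fixed seed; reported
#' thresholds follow the midpoint-between-adjacent-scores convention.
#' Percentile bootstrap confidence intervals (subject-level resampling,
#' stratified by class) are produced for AUC, threshold, sensitivity,
#' specificity and accuracy.
#'
#' @param data data frame with one row per subject.
#' @param score unquoted column with the score (higher = more disease-like).
#' @param label unquoted column with the class: logical, or 0/1 with 1 the
#'   event class.
#' @param n_boot number of bootstrap resamples (>= 1).
#' @param seed integer seed for tie-breaking and the bootstrap.
#' @param conf_level confidence level of the percentile intervals.
#' @return A `cgps_roc` object; see [tidy.cgps_roc()] and
#'   [glance.cgps_roc()].
#' @export
roc_with_youden <- function(data, score, label, n_boot = 2000, seed = 1,
                            conf_level = 0.95) {
  s <- dplyr::pull(data, {{ score }})
  l <- dplyr::pull(data, {{ label }})
  if (is.numeric(l)) {
    if (!all(l %in% c(0, 1))) abort("numeric labels must be 0/1")
    l <- l == 1
  }
  if (!is.logical(l)) abort("label column must be logical or 0/1")
  if (anyNA(s) || anyNA(l)) abort("missing scores or labels")
  if (length(unique(l)) < 2) abort("both classes must be present")
  if (n_boot < 1) abort("n_boot must be at least 1")
  set.seed(seed)

  fit <- .roc_fit(s, l)
  pick <- .youden_pick(fit)
  boot <- replicate(n_boot, {
    pos <- which(l); neg <- which(!l)
    idx <- c(pos[sample.int(length(pos), replace = TRUE)],
             neg[sample.int(length(neg), replace = TRUE)])
    bfit <- .roc_fit(s[idx], l[idx])
    bpick <- .youden_pick(bfit)
    c(auc = bfit$auc, threshold = bpick$threshold,
      sensitivity = bpick$sensitivity, specificity = bpick$specificity,
      accuracy = bpick$accuracy)
  })
  alpha <- (1 - conf_level) / 2
  ci <- as_tibble(t(apply(boot, 1, quantile, probs = c(alpha, 1 - alpha),
                          names = FALSE)), .name_repair = "minimal")
  names(ci) <- c("low", "high")
  ci$quantity <- rownames(boot)
  ci <- ci[, c("quantity", "low", "high")]

  structure(
    list(points = fit$points, auc = fit$auc,
         youden_threshold = pick$threshold,
         sensitivity = pick$sensitivity, specificity = pick$specificity,
         accuracy = pick$accuracy, ci = ci, conf_level = conf_level,
         n_boot = n_boot, tie_policy = "random", seed = seed,
         n = length(s), n_pos = sum(l), n_neg = sum(!l)),
    class = "cgps_roc"
  )
}

# ROC points over all achievable cuts; thresholds are midpoints between
# adjacent distinct scores (+-Inf at the ends).
.roc_fit <- function(s, l) {
  us <- sort(unique(s))
  cuts <- c(Inf, rev((us[-1] + us[-length(us)]) / 2), -Inf)
  n_pos <- sum(l); n_neg <- sum(!l)
  tpr <- vapply(cuts, function(cc) sum(s > cc & l) / n_pos, 0)
  fpr <- vapply(cuts, function(cc) sum(s > cc & !l) / n_neg, 0)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(points = tibble(threshold = cuts, fpr = fpr, tpr = tpr), auc = auc,
       n_pos = n_pos, n_neg = n_neg)
}

.youden_pick <- function(fit) {
  p <- fit$points
  j <- p$tpr + (1 - p$fpr) - 1
  best <- which(abs(j - max(j)) < 1e-12)
  k <- if (length(best) == 1) best else sample(best, 1)
  list(threshold = p$threshold[k], sensitivity = p$tpr[k],
       specificity = 1 - p$fpr[k],
       accuracy = (p$tpr[k] * fit$n_pos + (1 - p$fpr[k]) * fit$n_neg) /
         (fit$n_pos + fit$n_neg))
}

#' @export
print.cgps_roc <- function(x, ...) {
  cat(sprintf("<cgps_roc> AUC %.3f | Youden threshold %.3g | sens %.2f spec %.2f acc %.2f\n",
              x$auc, x$youden_threshold, x$sensitivity, x$specificity,
              x$accuracy))
  cat(sprintf("  %d subjects (%d/%d), %d bootstrap resamples, %g%% CIs\n",
              x$n, x$n_pos, x$n_neg, x$n_boot, 100 * x$conf_level))
  invisible(x)
}

#' Tidy an ROC result
#'
#' @param x a `cgps_roc`.
#' @param ... unused.
#' @return `tidy()`: the ROC points (threshold, fpr, tpr), one row per cut.
#'   `glance()`: a one-row summary with the AUC, the Youden threshold and
#'   its operating characteristics, each with bootstrap confidence bounds.
#' @method tidy cgps_roc
#' @export
tidy.cgps_roc <- function(x, ...) x$points

#' @rdname tidy.cgps_roc
#' @method glance cgps_roc
#' @export
glance.cgps_roc <- function(x, ...) {
  est <- c(auc = x$auc, threshold = x$youden_threshold,
           sensitivity = x$sensitivity, specificity = x$specificity,
           accuracy = x$accuracy)
  wide <- tibble(quantity = names(est), estimate = unname(est))
  out <- left_join(wide, x$ci, by = "quantity")
  tidyr::pivot_wider(out, names_from = "quantity",
                     values_from = c("estimate", "low", "high"),
                     names_glue = "{quantity}_{.value}") |>
    dplyr::rename_with(~ sub("_estimate$", "", .x))
}

#' @method autoplot cgps_roc
#' @export
autoplot.cgps_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8, colour = "#c0392b") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False-positive rate", y = "True-positive rate",
                  title = sprintf("AUC = %.2f, threshold = %.3g",
                                  object$auc, object$youden_threshold)) +
    ggplot2::theme_minimal()
}

#' Contingency evaluation of scored subjects against outcomes
#'
#' Splits subjects at a score threshold (the boundary value itself falls in
#' the low/below cell) and crosses the split with the observed outcome
#' events, giving the 2x2 table, event fractions with explicit
#' numerator/denominator, and a two-sided Fisher exact p-value (conventional
#' definition: sum of all tables with point probability at most that of the
#' observed table).
#'
#' @param records data frame with one row per subject.
#' @param threshold score cut; `score > threshold` is the high side.
#' @param score unquoted score column.
#' @param event unquoted logical column, `TRUE` when the outcome event
#'   (progression/activation) occurred.
#' @return A `cgps_contingency` object.
#' @export
contingency_eval <- function(records, threshold, score = score, event = event) {
  s <- dplyr::pull(records, {{ score }})
  ev <- dplyr::pull(records, {{ event }})
  if (length(s) == 0) abort("no records")
  if (!is.logical(ev)) abort("event column must be logical")
  if (anyNA(s) || anyNA(ev)) abort("missing scores or events")
  high <- s > threshold
  tab <- matrix(c(sum(high & ev), sum(high & !ev),
                  sum(!high & ev), sum(!high & !ev)),
                nrow = 2, byrow = TRUE,
                dimnames = list(side = c("high", "low"),
                                outcome = c("event", "no_event")))
  fractions <- tibble(
    side = c("high", "low"),
    events = unname(tab[, "event"]),
    total = unname(rowSums(tab)),
    fraction_pct = unname(ifelse(rowSums(tab) > 0,
                                 100 * tab[, "event"] / rowSums(tab), NA_real_))
  )
  fisher_p <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) 1
              else fisher.test(tab)$p.value
  structure(
    list(table = tab, fractions = fractions, fisher_p = fisher_p,
         threshold = threshold),
    class = "cgps_contingency"
  )
}

#' @export
print.cgps_contingency <- function(x, ...) {
  cat(sprintf("<cgps_contingency> split at score > %.4g | Fisher p = %.3g\n",
              x$threshold, x$fisher_p))
  print(x$table)
  invisible(x)
}

#' Tidy a contingency summary
#'
#' @param x a `cgps_contingency`.
#' @param ... unused.
#' @return `tidy()`: event fractions per side with numerator and
#'   denominator. `glance()`: one row with both fractions and the Fisher p.
#' @method tidy cgps_contingency
#' @export
tidy.cgps_contingency <- function(x, ...) x$fractions

#' @rdname tidy.cgps_contingency
#' @method glance cgps_contingency
#' @export
glance.cgps_contingency <- function(x, ...) {
  tibble(
    threshold = x$threshold,
    high_event_pct = x$fractions$fraction_pct[x$fractions$side == "high"],
    low_event_pct = x$fractions$fraction_pct[x$fractions$side == "low"],
    n = sum(x$table),
    fisher_p = x$fisher_p
  )
}
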