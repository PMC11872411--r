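# Independent brute-force oracles used to pin the statistical machinery.
# These deliberately share no code with the implementations they check.

# AUC by exhaustive pair counting: P(s_pos > s_neg) + 0.5 P(s_pos = s_neg)
oracle_auc_pairs <- function(scores, labels) {
  sp <- scores[as.logical(labels)]
  sn <- scores[!as.logical(labels)]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# two-sided Fisher exact by full hypergeometric enumeration
oracle_fisher_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  probs <- stats::dhyper(lo:hi, c1, n - c1, r1)
  obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# two-sided exact Wilcoxon rank-sum by enumerating every rank split
oracle_wilcoxon_exact <- function(x, y) {
  m <- length(x); N <- m + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(m)])
  ws <- apply(utils::combn(N, m), 2, function(ii) sum(r[ii]))
  p_lo <- mean(ws <= w_obs + 1e-9)
  p_hi <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(p_lo, p_hi))
}

# one-sample t-test power from the noncentral-t distribution directly
oracle_power_noncentral_t <- function(n, d, alpha) {
  df <- n - 1
  tc <- stats::qt(1 - alpha / 2, df)
  ncp <- d * sqrt(n)
  stats::pt(tc, df, ncp, lower.tail = FALSE) + stats::pt(-tc, df, ncp)
}

# nearest-centroid assignment, the oracle for well-separated blob clustering
oracle_nearest_centroid <- function(x, centroids) {
  d2 <- sapply(seq_len(nrow(centroids)), function(i) {
    rowSums(sweep(x, 2, centroids[i, ], "-")^2)
  })
  max.col(-d2)
}

# a small cohort for fast unit tests
tiny_cohort <- function(n_subjects = c(HD = 3, cGVHD_DP = 3),
                        cells_per_subject = 400, seed = 11, ...) {
  generate_cohort(sim_config(n_subjects = n_subjects,
                             cells_per_subject = cells_per_subject,
                             seed = seed, ...))
}

# minimal FCS 3.0 writer (float data, little-endian), independent of the
# package's reader; used to exercise FCS parsing without binary fixtures
write_tiny_fcs <- function(path, mat, channel_names = colnames(mat)) {
  n_par <- ncol(mat); n_tot <- nrow(mat)
  kw <- c("$MODE", "L", "$DATATYPE", "F", "$BYTEORD", "1,2,3,4",
          "$PAR", as.character(n_par), "$TOT", as.character(n_tot))
  for (i in seq_len(n_par)) {
    kw <- c(kw, paste0("$P", i, "N"), channel_names[i],
            paste0("$P", i, "B"), "32")
  }
  text <- paste0("/", paste(kw, collapse = "/"), "/")
  header_len <- 58
  text_start <- header_len
  text_end <- text_start + nchar(text) - 1
  data_start <- text_end + 1
  data_end <- data_start + 4 * n_par * n_tot - 1
  header <- sprintf("FCS3.0    %8d%8d%8d%8d%8d%8d",
                    text_start, text_end, data_start, data_end, 0, 0)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(text), con)
  writeBin(as.vector(t(mat)), con, size = 4, endian = "little")
  invisible(path)
}
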