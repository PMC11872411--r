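# healthy-donor reference with clean bimodality on the gate markers
gate_reference <- function(seed = 1, n = 4000, shift = 0) {
  set.seed(seed)
  pos_frac <- c(CD27 = 0.25, CD86 = 0.05, CD20 = 0.95, CD19 = 1.0)
  cells <- purrr::map_dfc(names(pos_frac), function(mk) {
    k <- rbinom(1, n, pos_frac[[mk]])
    tibble::tibble(!!mk := shift + c(rnorm(k, 3.0, 0.4), rnorm(n - k, 0.5, 0.4)))
  })
  cells$subject_id <- "hd_1"
  subjects <- tibble::tibble(subject_id = "hd_1", group = "HD", stratum = NA,
                             batch = "B1", outcome = NA, truth_freq = NA)
  new_cohort(cells, subjects, names(pos_frac), transformed = TRUE)
}

test_that("bimodal markers get a density-minimum cut between the modes", {
  gates <- fit_gates(gate_reference(), seed = 2)
  for (mk in c("CD27", "CD86", "CD20")) {
    row <- gates[gates$marker == mk, ]
    expect_false(row$fallback)
    expect_gt(row$cut, 1.0)
    expect_lt(row$cut, 2.5)
  }
})

test_that("unimodal markers fall back to a flagged percentile cut", {
  ref <- gate_reference()
  expect_message(gates <- fit_gates(ref, seed = 2), "fallback.*CD19")
  row <- gates[gates$marker == "CD19", ]
  expect_true(row$fallback)
  # the denominator gate keeps the bulk of (pan-positive) CD19 cells
  expect_lt(row$cut, stats::quantile(ref$cells$CD19, 0.05))
})

test_that("shifting all intensities shifts the fitted cuts by the same amount", {
  g0 <- fit_gates(gate_reference(seed = 5), seed = 2)
  g1 <- fit_gates(gate_reference(seed = 5, shift = 0.7), seed = 2)
  expect_equal(g1$cut, g0$cut + 0.7, tolerance = 1e-6)
})

test_that("gate fitting demands a healthy reference with enough cells", {
  small <- gate_reference(n = 50)
  expect_error(fit_gates(small), "100")
  ref <- gate_reference()
  ref$subjects$group <- "cGVHD"
  expect_error(fit_gates(ref), "healthy-donor")
})

manual_gates <- function() {
  g <- tibble::tibble(
    marker = c("CD19", "CD27", "CD86", "CD20"),
    side = c("+", "+", "+", "-"),
    role = c("b_cell", "subset", "subset", "subset"),
    cut = c(1.5, 2.0, 2.0, 1.5),
    fallback = FALSE)
  class(g) <- c("cgps_gates", class(g))
  g
}

test_that("gated frequency is the direct cell count ratio", {
  g <- manual_gates()
  s <- tibble::tibble(
    CD19 = rep(3, 10),                      # all 10 are B cells
    CD27 = c(rep(3, 5), rep(0.5, 5)),
    CD86 = c(rep(3, 3), rep(0.5, 7)),       # 3 of the CD27+ are CD86+
    CD20 = rep(0.5, 10))
  expect_equal(gated_frequency(s, g), 30)
  s$CD86 <- 0.5
  expect_equal(gated_frequency(s, g), 0)
  s$CD86 <- 3; s$CD27 <- 3
  expect_equal(gated_frequency(s, g), 100)
})

test_that("an empty B-cell denominator is an explicit error", {
  g <- manual_gates()
  s <- tibble::tibble(CD19 = rep(0.2, 5), CD27 = 3, CD86 = 3, CD20 = 0.2)
  expect_error(gated_frequency(s, g), "no B cells")
})

test_that("adding a gate-passing cell never decreases the frequency", {
  g <- manual_gates()
  s <- tibble::tibble(CD19 = rep(3, 8), CD27 = c(rep(3, 2), rep(0.5, 6)),
                      CD86 = c(rep(3, 2), rep(0.5, 6)), CD20 = 0.5)
  f0 <- gated_frequency(s, g)
  s2 <- dplyr::bind_rows(s, tibble::tibble(CD19 = 3, CD27 = 3, CD86 = 3, CD20 = 0.5))
  expect_gte(gated_frequency(s2, g), f0)
})

test_that("cGPS is the clamped monotone map of frequency", {
  expect_equal(cgps_score(0), 0)
  expect_equal(cgps_score(1.5), 1.5)
  expect_equal(cgps_score(100), 100)
  expect_error(cgps_score(-1), "0, 100")
  expect_error(cgps_score(101), "0, 100")
  # monotone transforms preserve order; clamping keeps [0, 100]
  f <- sort(runif(20, 0, 100))
  sc <- cgps_score(f, transform = function(x) 2 * x + 5)
  expect_true(all(diff(sc) >= 0))
  expect_true(all(sc >= 0 & sc <= 100))
})

test_that("risk classification uses context thresholds with a low boundary", {
  expect_equal(classify_risk(1.15, "nonGVHD"), "low")
  expect_equal(classify_risk(1.16, "nonGVHD"), "high")
  expect_equal(classify_risk(1.51, "cGVHD"), "low")
  expect_equal(classify_risk(1.52, "cGVHD"), "high")
  expect_equal(classify_risk(1.3, "cGVHD"), "low")
  expect_equal(classify_risk(1.3, "nonGVHD", threshold = 1.0), "high")
  expect_error(classify_risk(1, "bogus"))
  expect_error(classify_risk(150, "cGVHD"), "0, 100")
})

test_that("gated frequencies recover planted frequencies at Spearman 0.95", {
  # 20 subjects with planted frequencies spread over 0.5-20% of B cells,
  # 500 cells each: cell-sampling noise must not scramble the ranking
  ref <- generate_cohort(sim_config(n_subjects = c(HD = 10),
                                    cells_per_subject = 2000, seed = 34))
  gates <- suppressMessages(fit_gates(arcsinh_transform(ref)))
  means <- seq(0.5, 20, length.out = 20)
  dfq <- default_disease_freq()
  dfq$kappa <- Inf
  gated <- vapply(seq_along(means), function(i) {
    dfq$mean[dfq$stratum == "cGVHD_DP"] <- means[i]
    co <- generate_cohort(sim_config(n_subjects = c(cGVHD_DP = 1),
                                     cells_per_subject = 500,
                                     disease_freq = dfq, seed = 330 + i))
    gated_frequency(cohort_sample(arcsinh_transform(co),
                                  co$subjects$subject_id[1]), gates)
  }, 0)
  expect_gte(stats::cor(gated, means, method = "spearman"), 0.95)
})

test_that("cohort records carry bounded scores and context risk classes", {
  co <- generate_cohort(sim_config(
    n_subjects = c(HD = 4, nonGVHD_stable = 4, nonGVHD_active = 4, cGVHD_DP = 4),
    cells_per_subject = 500, seed = 33))
  ref <- generate_cohort(sim_config(n_subjects = c(HD = 10),
                                    cells_per_subject = 2000, seed = 34))
  gates <- suppressMessages(fit_gates(arcsinh_transform(ref)))
  rec <- cgps_records(arcsinh_transform(co), gates)
  expect_true(all(rec$score >= 0 & rec$score <= 100))
  expect_identical(rec$risk_class[rec$group == "nonGVHD"],
                   ifelse(rec$score[rec$group == "nonGVHD"] > 1.15, "high", "low"))
  expect_true(all(is.na(rec$risk_class[rec$group == "HD"])))
})
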