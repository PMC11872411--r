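test_that("combination enumeration counts match binomial coefficients", {
  cand <- paste0("M", 1:8)
  expect_length(enumerate_combos(cand, sizes = 2:3), 28 + 56)
  expect_length(enumerate_combos(cand, sizes = 2:8), 2^8 - 8 - 1)
  expect_error(enumerate_combos(cand, sizes = 9), "sizes")
  expect_error(enumerate_combos(cand, sizes = 1), "sizes")
  # deterministic lexicographic order
  first <- enumerate_combos(cand, sizes = 2)[[1]]
  expect_equal(first, c("M1", "M2"))
})

# screening cohort: disease cells separable from healthy cells on m1/m2,
# marker "noise" carries nothing
screen_cohort <- function(n = 400, seed = 3, separable = TRUE) {
  set.seed(seed)
  half <- n / 2
  shift <- if (separable) 3 else 0
  cells <- tibble::tibble(
    subject_id = rep(c("cg_1", "cg_2", "hd_1", "hd_2"), each = half / 2),
    m1 = c(rnorm(half, shift), rnorm(half)),
    m2 = c(rnorm(half, -shift), rnorm(half)),
    noise = rnorm(n))
  subjects <- tibble::tibble(
    subject_id = c("cg_1", "cg_2", "hd_1", "hd_2"),
    group = c("cGVHD", "cGVHD", "HD", "HD"),
    stratum = NA, batch = "B1", outcome = NA, truth_freq = NA)
  new_cohort(cells, subjects, c("m1", "m2", "noise"),
             transformed = TRUE, scaled = TRUE)
}

test_that("a separable subset screens above 0.95 and is deterministic under the seed", {
  co <- screen_cohort()
  cb <- screen_combo(co, c("m1", "m2"), seed = 5)
  expect_gte(cb$train_accuracy, 0.95)
  expect_true(cb$passed_stage1)
  cb2 <- screen_combo(co, c("m1", "m2"), seed = 5)
  expect_equal(cb$train_accuracy, cb2$train_accuracy)
  expect_identical(cb$model_hash, cb2$model_hash)
  expect_equal(cb$combo_class, "C2")
  expect_error(screen_combo(co, c("m1", "absent")), "absent")
})

test_that("labels carrying no signal screen near the majority-class rate", {
  co <- screen_cohort(n = 2000, separable = FALSE)
  cb <- screen_combo(co, c("m1", "m2"), seed = 9)
  expect_lt(abs(cb$train_accuracy - 0.5), 0.05)
  expect_false(cb$passed_stage1)
})

test_that("stage-1 filter is monotone in the accuracy cutoff", {
  co <- screen_cohort()
  strict <- screen_combo(co, c("m1", "m2"), seed = 5, accuracy_cutoff = 0.99)
  loose <- screen_combo(co, c("m1", "m2"), seed = 5, accuracy_cutoff = 0.5)
  expect_true(loose$passed_stage1 >= strict$passed_stage1)
  expect_equal(loose$train_accuracy, strict$train_accuracy)
})

test_that("validation freezes the model and aggregates per subject", {
  co1 <- screen_cohort(seed = 21)
  co2 <- screen_cohort(seed = 22)
  co2$cells$subject_id <- sub("_", "_v", co2$cells$subject_id)
  co2$subjects$subject_id <- sub("_", "_v", co2$subjects$subject_id)
  cb <- screen_combo(co1, c("m1", "m2"), seed = 1)
  out <- validate_combo(cb, co2)
  expect_equal(out$validation_auc, 1)
  expect_true(out$passed_stage2)
  expect_identical(out$model_hash, cb$model_hash)
  expect_equal(nrow(out$subject_scores), 4)
  # AUC equals the normalised Mann-Whitney U on the same subject scores
  expect_equal(out$validation_auc,
               oracle_auc_pairs(out$subject_scores$score,
                                out$subject_scores$group == "cGVHD"))
  # freeze-then-validate order is enforced
  failed <- cb; failed$passed_stage1 <- FALSE
  expect_error(validate_combo(failed, co2), "stage 1")
  tampered <- cb; tampered$model_hash <- "not-the-hash"
  expect_error(validate_combo(tampered, co2), "hash")
})

test_that("uninformative subject scores give AUC one half", {
  expect_equal(cgps:::auc_mw(rep(0.4, 8), rep(c(TRUE, FALSE), 4)), 0.5)
})

fake_combo <- function(markers, auc, passed = TRUE) {
  structure(list(markers = markers, validation_auc = auc,
                 passed_stage1 = TRUE, passed_stage2 = passed,
                 combo_class = sprintf("C%d", length(markers)),
                 train_accuracy = 0.95),
            class = "cgps_combo")
}

test_that("panel selection prefers fewest markers, then AUC, then name order", {
  a <- fake_combo(c("A", "B"), 0.92)
  b <- fake_combo(c("A", "B", "C"), 0.96)
  expect_equal(select_final_panel(list(a, b))$markers, c("A", "B"))
  c2 <- fake_combo(c("C", "D"), 0.95)
  expect_equal(select_final_panel(list(a, c2))$markers, c("C", "D"))
  tie <- fake_combo(c("A", "C"), 0.92)
  expect_equal(select_final_panel(list(tie, a))$markers, c("A", "B"))
  expect_error(select_final_panel(list(fake_combo(c("A", "B"), 0.5, passed = FALSE))),
               "no panel meets criteria")
})

test_that("combo summary table carries one row per combination", {
  tab <- combo_summary(list(fake_combo(c("A", "B"), 0.91),
                            fake_combo(c("A", "B", "C"), 0.95)))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$n_markers, c(2, 3))
})
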