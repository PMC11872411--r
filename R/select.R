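#' Enumerate marker subsets
#'
#' All subsets of the candidate markers at each requested size, in
#' deterministic lexicographic order (by the order of `candidates`).
#'
#' @param candidates character vector of candidate markers.
#' @param sizes integer set of subset sizes; each must lie in
#'   `2..length(candidates)`.
#' @return List of character vectors.
#' @export
#' @examples
#' length(enumerate_combos(letters[1:8], sizes = 2:3))  # 28 + 56 = 84
enumerate_combos <- function(candidates, sizes = 2:3) {
  sizes <- sort(unique(as.integer(sizes)))
  if (any(sizes < 2) || any(sizes > length(candidates))) {
    abort(sprintf("sizes must lie in 2..%d", length(candidates)))
  }
  unlist(lapply(sizes, function(k) {
    combn(candidates, k, simplify = FALSE)
  }), recursive = FALSE)
}

#' Screen one marker combination on the discovery cohort
#'
#' Restricts the cohort's cells to the marker subset, inherits a binary
#' cell label from the subject group (`disease_group` = 1, `"HD"` = 0),
#' trains a random forest on a 70/30 split and scores accuracy on the
#' held-out 30%. A combination passes stage 1 when accuracy exceeds
#' `accuracy_cutoff`; the trained model is frozen (content-hashed) and must
#' not be re-trained afterwards.
#'
#' The default split unit is the cell, which lets cells of one subject fall
#' on both sides of the split; `split_unit = "subject"` is the leakage-safe
#' alternative that splits whole subjects.
#'
#' @param cohort discovery `cgps_cohort`; must contain `disease_group` and
#'   `"HD"` subjects.
#' @param markers the marker subset.
#' @param split_fraction training fraction of the 70/30 split.
#' @param seed integer seed (split and forest).
#' @param disease_group subject group mapped to label 1.
#' @param accuracy_cutoff stage-1 accuracy filter.
#' @param split_unit `"cell"` or `"subject"`.
#' @param num_trees random-forest size.
#' @param n_candidates optional size of the candidate pool, used only to
#'   label the combination class (e.g. `"C82"` for a 2-subset of 8).
#' @return A `cgps_combo` object.
#' @export
screen_combo <- function(cohort, markers, split_fraction = 0.7, seed = 1,
                         disease_group = "cGVHD", accuracy_cutoff = 0.9,
                         split_unit = c("cell", "subject"), num_trees = 100,
                         n_candidates = NULL) {
  stopifnot(inherits(cohort, "cgps_cohort"))
  split_unit <- match.arg(split_unit)
  missing_mk <- setdiff(markers, cohort$markers)
  if (length(missing_mk) > 0) {
    abort(paste0("marker(s) absent from cohort: ",
                 paste(missing_mk, collapse = ", ")))
  }
  grp <- cohort$subjects$group[match(cohort$cells$subject_id,
                                     cohort$subjects$subject_id)]
  keep <- grp %in% c(disease_group, "HD")
  for (g in c(disease_group, "HD")) {
    if (!any(grp == g)) abort(paste0("no cells of group '", g, "' in cohort"))
  }
  x <- cohort$cells[keep, markers]
  y <- factor(as.integer(grp[keep] == disease_group), levels = c(0, 1))

  set.seed(seed)
  if (split_unit == "cell") {
    n <- nrow(x)
    train <- sort(sample.int(n, round(split_fraction * n)))
  } else {
    sids <- unique(cohort$cells$subject_id[keep])
    train_sid <- sample(sids, round(split_fraction * length(sids)))
    train <- which(cohort$cells$subject_id[keep] %in% train_sid)
  }
  test <- setdiff(seq_len(nrow(x)), train)
  if (length(test) == 0 || length(unique(y[train])) < 2) {
    abort("train/test split left a one-class partition")
  }
  # marker subsets are tiny (2-3 features): every split considers every
  # marker, otherwise trees blind to one marker mix neighbouring phenotypes
  fit <- ranger::ranger(
    x = x[train, , drop = FALSE], y = y[train],
    num.trees = num_trees, probability = TRUE, mtry = length(markers),
    min.node.size = 1, num.threads = 1, seed = seed
  )
  prob <- predict(fit, x[test, , drop = FALSE], num.threads = 1)$predictions[, "1"]
  acc <- mean((prob > 0.5) == (y[test] == 1))
  structure(
    list(markers = markers,
         combo_class = if (is.null(n_candidates)) sprintf("C%d", length(markers))
                       else sprintf("C%d%d", n_candidates, length(markers)),
         model = fit, model_hash = rlang::hash(fit$forest),
         train_accuracy = acc,
         passed_stage1 = acc > accuracy_cutoff,
         validation_auc = NA_real_, passed_stage2 = NA,
         seed = seed, num_trees = num_trees, split_unit = split_unit),
    class = "cgps_combo"
  )
}

#' @export
print.cgps_combo <- function(x, ...) {
  cat(sprintf("<cgps_combo> {%s} acc %.3f [stage1 %s]",
              paste(x$markers, collapse = ", "), x$train_accuracy,
              if (x$passed_stage1) "pass" else "fail"))
  if (!is.na(x$validation_auc)) {
    cat(sprintf(" | AUC %.3f [stage2 %s]", x$validation_auc,
                if (isTRUE(x$passed_stage2)) "pass" else "fail"))
  }
  cat("\n")
  invisible(x)
}

#' Validate a frozen combination on the independent cohort
#'
#' Scores every cell of the validation cohort with the stage-1 frozen model
#' (no re-training; the model content hash is checked), aggregates to one
#' score per subject as the mean predicted disease probability over that
#' subject's cells, and computes the subject-level AUC (disease versus
#' healthy). A combination passes stage 2 when AUC exceeds `auc_cutoff`.
#'
#' @param combo a `cgps_combo` that passed stage 1.
#' @param cohort2 validation `cgps_cohort`, subjects disjoint from the
#'   discovery cohort.
#' @param disease_group subject group treated as the positive class.
#' @param auc_cutoff stage-2 AUC filter.
#' @param cells_per_subject optional per-subject subsample used for
#'   scoring; the aggregate is a mean, so a per-subject subsample only adds
#'   binomial noise. `NULL` scores every cell.
#' @param seed seed for the scoring subsample.
#' @return The `cgps_combo` with `validation_auc`, `passed_stage2` and
#'   per-subject scores filled in.
#' @export
validate_combo <- function(combo, cohort2, disease_group = "cGVHD",
                           auc_cutoff = 0.9, cells_per_subject = NULL,
                           seed = 1) {
  stopifnot(inherits(combo, "cgps_combo"), inherits(cohort2, "cgps_cohort"))
  if (!isTRUE(combo$passed_stage1)) {
    abort("combo failed stage 1; freeze-then-validate order forbids validation")
  }
  if (!identical(rlang::hash(combo$model$forest), combo$model_hash)) {
    abort("frozen model hash mismatch: combo was altered after stage 1")
  }
  grp <- cohort2$subjects$group[match(cohort2$cells$subject_id,
                                      cohort2$subjects$subject_id)]
  keep <- which(grp %in% c(disease_group, "HD"))
  if (length(keep) == 0) abort("validation cohort has no disease/HD cells")
  if (!is.null(cells_per_subject)) {
    set.seed(seed)
    keep <- unlist(lapply(split(keep, cohort2$cells$subject_id[keep]),
                          function(ii) {
                            if (length(ii) <= cells_per_subject) ii
                            else sort(sample(ii, cells_per_subject))
                          }), use.names = FALSE)
  }
  prob <- predict(combo$model, cohort2$cells[keep, combo$markers],
                  num.threads = 1)$predictions[, "1"]
  scores <- tibble(
    subject_id = cohort2$cells$subject_id[keep],
    prob = prob
  ) |>
    group_by(.data$subject_id) |>
    summarise(score = mean(.data$prob), .groups = "drop") |>
    left_join(select(cohort2$subjects, "subject_id", "group"),
              by = "subject_id")
  auc <- auc_mw(scores$score, scores$group == disease_group)
  combo$validation_auc <- auc
  combo$passed_stage2 <- auc > auc_cutoff
  combo$subject_scores <- scores
  combo
}

#' Select the final minimal panel
#'
#' Among stage-2 survivors: fewest markers first, then highest validation
#' AUC, then lexicographic marker order (fully deterministic).
#'
#' @param results list of `cgps_combo` objects.
#' @return The winning `cgps_combo`.
#' @export
select_final_panel <- function(results) {
  ok <- purrr::keep(results, ~ isTRUE(.x$passed_stage2))
  if (length(ok) == 0) abort("no panel meets criteria (no stage-2 survivor)")
  key <- purrr::map(ok, function(cb) {
    list(size = length(cb$markers), auc = cb$validation_auc,
         lex = paste(cb$markers, collapse = "|"))
  })
  ord <- order(
    vapply(key, `[[`, 0, "size"),
    -vapply(key, `[[`, 0, "auc"),
    vapply(key, `[[`, "", "lex")
  )
  ok[[ord[1]]]
}

#' Summarise a list of combination results
#'
#' @param results list of `cgps_combo`.
#' @return Tibble: markers, combo_class, train_accuracy, validation_auc,
#'   passed_stage1, passed_stage2.
#' @export
combo_summary <- function(results) {
  purrr::map_dfr(results, function(cb) {
    tibble(
      markers = paste(cb$markers, collapse = "+"),
      n_markers = length(cb$markers),
      combo_class = cb$combo_class,
      train_accuracy = cb$train_accuracy,
      validation_auc = cb$validation_auc,
      passed_stage1 = cb$passed_stage1,
      passed_stage2 = cb$passed_stage2
    )
  })
}
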