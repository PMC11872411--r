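# stage-seed fan-out: every random stage consumes seed * 100 + stage index,
# so stages can be rerun in isolation reproducibly
.stage_seed <- function(seed, k) as.integer(seed) * 100L + k

.run_stage <- function(name, done, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("stage '%s' failed: %s [completed stages: %s]",
                  name, conditionMessage(e),
                  if (length(done) > 0) paste(done, collapse = ", ") else "none"))
  })
}

#' Run the discovery arm: cluster, rank, screen, validate, select
#'
#' Executes the full discovery workflow on a discovery/validation cohort
#' pair: arcsinh transform and per-cohort standardisation (with batch
#' regression when more than one batch is present), pooled-cell clustering,
#' disease-cluster identification, marker ranking, exhaustive combination
#' screening with a random forest, frozen-model validation on the
#' independent cohort, and minimal-panel selection.
#'
#' Screening input: cells of the disease-associated cluster together with
#' an equal-size sample of healthy-donor cells ("cluster-guided
#' screening"). Cell labels are still inherited from the subject group, but
#' restricting the disease side to the cluster is what gives the forest a
#' learnable cell-level signal when the disease subset is a small fraction
#' of each patient's B cells.
#'
#' @param cohort1 discovery `cgps_cohort` (raw scale; disease and HD
#'   subjects).
#' @param cohort2 validation `cgps_cohort`, disjoint subjects.
#' @param cofactor arcsinh cofactor.
#' @param k_neighbors,resolution clustering parameters, see
#'   [cluster_cells()].
#' @param cluster_cells_per_subject per-subject subsample for clustering.
#' @param disease_group,min_fraction see [identify_disease_cluster()].
#' @param alpha,effect_floor,top_n see [rank_cluster_markers()].
#' @param combo_sizes subset sizes to enumerate (default 2--3, the sizes
#'   eligible for final selection).
#' @param split_fraction,accuracy_cutoff,num_trees see [screen_combo()].
#' @param auc_cutoff stage-2 AUC filter.
#' @param validate_cells_per_subject per-subject subsample for stage-2
#'   scoring.
#' @param seed global seed; every random stage consumes a seed derived
#'   deterministically from it.
#' @return A `cgps_discovery` object: clustering result, disease cluster
#'   id, marker ranking, candidate markers, all combination results (list
#'   and table), the selected `panel`, and a `manifest` tibble recording
#'   stage, seed, size and a content hash per stage.
#' @export
run_discovery <- function(cohort1, cohort2, cofactor = 150,
                          k_neighbors = 20, resolution = 0.8,
                          cluster_cells_per_subject = 1000,
                          disease_group = "cGVHD", min_fraction = 0.75,
                          alpha = 1e-4, effect_floor = 0.5, top_n = 8,
                          combo_sizes = 2:3, split_fraction = 0.7,
                          accuracy_cutoff = 0.9, num_trees = 100,
                          auc_cutoff = 0.9, validate_cells_per_subject = 1000,
                          seed = 1) {
  stopifnot(inherits(cohort1, "cgps_cohort"), inherits(cohort2, "cgps_cohort"))
  overlap <- intersect(cohort1$subjects$subject_id, cohort2$subjects$subject_id)
  if (length(overlap) > 0) {
    abort(paste0("cohorts share subject(s): ", paste(head(overlap, 5), collapse = ", ")))
  }
  done <- character(); manifest <- list()
  note <- function(stage, sd, n, obj) {
    manifest[[stage]] <<- tibble(stage = stage, seed = sd, n = n,
                                 hash = rlang::hash(obj))
    done <<- c(done, stage)
  }

  c1t <- .run_stage("preprocess", done, {
    if (cohort1$transformed) cohort1 else arcsinh_transform(cohort1, cofactor)
  })
  c1 <- .run_stage("preprocess", done, {
    cv <- if (length(unique(c1t$subjects$batch)) > 1) "batch" else character()
    scale_and_regress(c1t, covariates = cv)
  })
  c2 <- .run_stage("preprocess", done, {
    c2 <- if (cohort2$transformed) cohort2 else arcsinh_transform(cohort2, cofactor)
    cv <- if (length(unique(c2$subjects$batch)) > 1) "batch" else character()
    scale_and_regress(c2, covariates = cv)
  })
  note("preprocess", NA_integer_, nrow(c1$cells) + nrow(c2$cells),
       list(c1$cells, c2$cells))

  clusters <- .run_stage("cluster", done,
    cluster_cells(c1, k_neighbors = k_neighbors, resolution = resolution,
                  seed = .stage_seed(seed, 1L),
                  cells_per_subject = cluster_cells_per_subject))
  note("cluster", .stage_seed(seed, 1L), nrow(clusters$labels), clusters$labels)

  disease_cluster <- .run_stage("identify_cluster", done,
    identify_disease_cluster(clusters, disease_group = disease_group,
                             min_fraction = min_fraction))
  note("identify_cluster", NA_integer_,
       sum(clusters$labels$cluster == disease_cluster), disease_cluster)

  # effect sizes are compared on the transformed (unscaled) axis: per-marker
  # z-scoring would weight a median shift by the marker's positivity rate
  ranking <- .run_stage("rank_markers", done,
    rank_cluster_markers(c1t, clusters, disease_cluster, alpha = alpha,
                         effect_floor = effect_floor, top_n = top_n))
  candidates <- sort(ranking$marker[ranking$selected])
  note("rank_markers", NA_integer_, length(candidates), ranking)

  combos <- .run_stage("screen", done, {
    lab <- clusters$labels
    in_cluster <- lab$.cell[lab$cluster == disease_cluster]
    grp <- c1$subjects$group[match(c1$cells$subject_id, c1$subjects$subject_id)]
    hd_pool <- setdiff(which(grp == "HD"), in_cluster)
    set.seed(.stage_seed(seed, 2L))
    # several healthy cells per disease-cluster cell, so rare healthy
    # subsets (plasmablasts and other confusable phenotypes) are
    # represented well enough for the forest to carve them out
    hd_draw <- sample(hd_pool, min(length(hd_pool), 4L * length(in_cluster)))
    rows <- c(in_cluster, hd_draw)
    extract <- new_cohort(c1$cells[rows, ], c1$subjects, c1$markers,
                          transformed = TRUE, scaled = TRUE)
    purrr::map(enumerate_combos(candidates, combo_sizes), function(mk) {
      screen_combo(extract, mk, split_fraction = split_fraction,
                   seed = .stage_seed(seed, 3L), disease_group = disease_group,
                   accuracy_cutoff = accuracy_cutoff, num_trees = num_trees,
                   n_candidates = length(candidates))
    })
  })
  note("screen", .stage_seed(seed, 3L), length(combos), combo_summary(combos))

  combos <- .run_stage("validate", done, {
    purrr::map(combos, function(cb) {
      if (!isTRUE(cb$passed_stage1)) return(cb)
      validate_combo(cb, c2, disease_group = disease_group,
                     auc_cutoff = auc_cutoff,
                     cells_per_subject = validate_cells_per_subject,
                     seed = .stage_seed(seed, 4L))
    })
  })
  note("validate", .stage_seed(seed, 4L),
       sum(purrr::map_lgl(combos, ~ isTRUE(.x$passed_stage1))),
       combo_summary(combos))

  panel <- .run_stage("select", done, select_final_panel(combos))
  note("select", NA_integer_, length(panel$markers), panel$markers)

  structure(
    list(clusters = clusters, disease_cluster = disease_cluster,
         ranking = ranking, candidates = candidates,
         combos = combos, combo_table = combo_summary(combos),
         panel = panel, seed = seed,
         manifest = bind_rows(manifest)),
    class = "cgps_discovery"
  )
}

#' @export
print.cgps_discovery <- function(x, ...) {
  cat(sprintf("<cgps_discovery> disease cluster %d | candidates: %s\n",
              x$disease_cluster, paste(x$candidates, collapse = ", ")))
  cat(sprintf("  selected panel: {%s} (validation AUC %.3f)\n",
              paste(x$panel$markers, collapse = ", "),
              x$panel$validation_auc))
  invisible(x)
}

#' Tidy a discovery result
#'
#' @param x a `cgps_discovery`.
#' @param ... unused.
#' @return The combination results table (one row per screened subset).
#' @method tidy cgps_discovery
#' @export
tidy.cgps_discovery <- function(x, ...) x$combo_table

#' Run the monitoring arm: score, classify, evaluate
#'
#' Scores every patient of a cohort with fitted gates, classifies risk at
#' the context threshold (1.15 for non-GVHD patients, 1.51 for cGVHD
#' patients, both overridable), and -- when outcome labels are present --
#' evaluates the classification with contingency tables (event = a
#' non-GVHD patient turning active, or a cGVHD patient progressing to DP).
#'
#' @param cohort transformed or raw `cgps_cohort` of patients to monitor
#'   (HD samples are scored but not risk-classified).
#' @param gates a `cgps_gates` from [fit_gates()].
#' @param thresholds named thresholds per context; overrides are recorded
#'   in the report.
#' @param transform cGPS transform, see [cgps_score()].
#' @param cofactor arcsinh cofactor applied when the cohort is raw.
#' @return A `cgps_monitoring` object: `records` (per-subject cGPS table),
#'   `contingency` (named list per context), `report` (markdown lines) and
#'   `manifest`.
#' @export
run_monitoring <- function(cohort, gates, thresholds = cgps_thresholds(),
                           transform = identity, cofactor = 150) {
  stopifnot(inherits(cohort, "cgps_cohort"))
  if (nrow(cohort$subjects) == 0) abort("empty cohort")
  bad <- cohort$subjects$subject_id[
    is.na(cohort$subjects$group) |
      !cohort$subjects$group %in% c("HD", names(thresholds))]
  if (length(bad) > 0) {
    abort(paste0("subject(s) without a monitoring context (nonGVHD/cGVHD): ",
                 paste(bad, collapse = ", ")))
  }
  if (!cohort$transformed) cohort <- arcsinh_transform(cohort, cofactor)
  records <- cgps_records(cohort, gates, transform = transform,
                          thresholds = thresholds)
  contingency <- list()
  for (ctx in names(thresholds)) {
    rec <- filter(records, .data$context == ctx, !is.na(.data$outcome))
    if (nrow(rec) == 0) next
    rec$event <- rec$outcome == (if (ctx == "nonGVHD") "active" else "DP")
    contingency[[ctx]] <- contingency_eval(rec, thresholds[[ctx]])
  }
  defaults <- cgps_thresholds()
  report <- c(
    "# cGPS monitoring report", "",
    sprintf("- subjects scored: %d", nrow(records)),
    vapply(names(thresholds), function(ctx) {
      override <- !(ctx %in% names(defaults)) ||
        thresholds[[ctx]] != defaults[[ctx]]
      sprintf("- %s threshold: %.4g%s", ctx, thresholds[[ctx]],
              if (override) " (override of default)" else "")
    }, ""),
    "",
    purrr::imap_chr(contingency, function(ct, ctx) {
      g <- glance(ct)
      sprintf("- %s: %d/%d events above threshold (%.2f%%), %d/%d below (%.2f%%), Fisher p = %.3g",
              ctx, ct$table["high", "event"], sum(ct$table["high", ]),
              g$high_event_pct, ct$table["low", "event"],
              sum(ct$table["low", ]), g$low_event_pct, g$fisher_p)
    })
  )
  structure(
    list(records = records, contingency = contingency, report = report,
         thresholds = thresholds,
         manifest = tibble(stage = c("score", "evaluate"),
                           seed = NA_integer_,
                           n = c(nrow(records), length(contingency)),
                           hash = c(rlang::hash(records),
                                    rlang::hash(contingency)))),
    class = "cgps_monitoring"
  )
}

#' @export
print.cgps_monitoring <- function(x, ...) {
  cat(x$report, sep = "\n")
  invisible(x)
}

#' Tidy a monitoring result
#'
#' @param x a `cgps_monitoring`.
#' @param ... unused.
#' @return The per-subject cGPS record table.
#' @method tidy cgps_monitoring
#' @export
tidy.cgps_monitoring <- function(x, ...) x$records
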