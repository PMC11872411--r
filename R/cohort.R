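#' Cohort container
#'
#' A `cgps_cohort` bundles the per-cell expression table of every sample in a
#' study arm with the subject-level clinical table. It is the unit that flows
#' through preprocessing, clustering, panel selection and scoring.
#'
#' @details
#' The cell table holds one row per cell: `subject_id`, then one numeric
#' column per marker (synthetic cohorts additionally carry a `.template`
#' column with the ground-truth population of each cell). The subject table
#' holds one row per subject: `subject_id`, `group` (one of `"HD"`,
#' `"nonGVHD"`, `"cGVHD"`), `stratum` (the generating frequency stratum for
#' synthetic data), `batch`, `outcome` (`"stable"`/`"active"` for non-GVHD,
#' `"DP"`/`"PR"`/`"CR"`/`"SD"` for cGVHD, `NA` for healthy donors) and
#' `truth_freq` (planted disease-subset frequency, percent of B cells, `NA`
#' for real data).
#'
#' Two flags track the state of the expression values: `transformed` (arcsinh
#' applied) and `scaled` (per-marker standardisation/batch regression
#' applied). Operations that require a particular state check it and refuse
#' to run twice.
#'
#' @param cells tibble of cells (see Details).
#' @param subjects tibble of subjects (see Details).
#' @param markers character vector of marker column names, in panel order.
#' @param transformed,scaled state flags.
#'
#' @return A `cgps_cohort` object.
#' @export
new_cohort <- function(cells, subjects, markers,
                       transformed = FALSE, scaled = FALSE) {
  cells <- as_tibble(cells)
  subjects <- as_tibble(subjects)
  missing_mk <- setdiff(markers, names(cells))
  if (length(missing_mk) > 0) {
    abort(paste0("cell table lacks marker column(s): ",
                 paste(missing_mk, collapse = ", ")))
  }
  if (!"subject_id" %in% names(cells) || !"subject_id" %in% names(subjects)) {
    abort("both tables need a 'subject_id' column")
  }
  if (anyDuplicated(subjects$subject_id)) {
    abort("one row per subject_id required in the subject table")
  }
  orphan <- setdiff(unique(cells$subject_id), subjects$subject_id)
  if (length(orphan) > 0) {
    abort(paste0("cells reference unknown subject(s): ",
                 paste(head(orphan, 5), collapse = ", ")))
  }
  if (anyNA(cells[markers])) abort("missing values in marker columns")
  structure(
    list(cells = cells, subjects = subjects, markers = markers,
         transformed = transformed, scaled = scaled),
    class = "cgps_cohort"
  )
}

#' @export
print.cgps_cohort <- function(x, ...) {
  state <- c(if (x$transformed) "arcsinh" else "raw",
             if (x$scaled) "scaled" else NULL)
  cat(sprintf("<cgps_cohort> %d cells | %d subjects | %d markers [%s]\n",
              nrow(x$cells), nrow(x$subjects), length(x$markers),
              paste(state, collapse = ", ")))
  print(count(x$subjects, .data$group))
  invisible(x)
}

#' Subset a cohort by subject
#'
#' @param cohort a `cgps_cohort`.
#' @param subject_ids subjects to keep.
#' @return A `cgps_cohort` restricted to the given subjects.
#' @export
cohort_subset <- function(cohort, subject_ids) {
  stopifnot(inherits(cohort, "cgps_cohort"))
  missing_id <- setdiff(subject_ids, cohort$subjects$subject_id)
  if (length(missing_id) > 0) {
    abort(paste0("unknown subject(s): ", paste(head(missing_id, 5), collapse = ", ")))
  }
  new_cohort(
    cells = filter(cohort$cells, .data$subject_id %in% subject_ids),
    subjects = filter(cohort$subjects, .data$subject_id %in% subject_ids),
    markers = cohort$markers,
    transformed = cohort$transformed, scaled = cohort$scaled
  )
}

#' Extract one sample's cell matrix
#'
#' Returns the cells of a single subject as a tibble of markers only, with
#' sample metadata in attributes -- the "one FCS file" view used by the
#' gating functions.
#'
#' @param cohort a `cgps_cohort`.
#' @param subject_id the subject to extract.
#' @return A tibble (cells x markers) with attributes `subject_id` and
#'   `transformed`.
#' @export
cohort_sample <- function(cohort, subject_id) {
  stopifnot(inherits(cohort, "cgps_cohort"))
  if (!subject_id %in% cohort$subjects$subject_id) {
    abort(paste0("unknown subject: ", subject_id))
  }
  out <- cohort$cells[cohort$cells$subject_id == subject_id, cohort$markers]
  attr(out, "subject_id") <- subject_id
  attr(out, "transformed") <- cohort$transformed
  out
}
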