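#' Arcsinh transform of raw intensities
#'
#' Elementwise `asinh(x / cofactor)`, the variance-stabilising transform
#' conventionally applied to fluorescence intensities before clustering or
#' gating. The transform is tracked with a flag and refuses to run twice.
#'
#' @param x a `cgps_cohort` or a sample tibble from [read_sample()] /
#'   [cohort_sample()].
#' @param cofactor positive scale divisor. 150 is a common choice for
#'   fluorescence-scale data; the value is configurable because upstream
#'   acquisition software may already have normalised the data.
#' @return Object of the same shape with transformed values and
#'   `transformed = TRUE`.
#' @export
arcsinh_transform <- function(x, cofactor = 150) {
  UseMethod("arcsinh_transform")
}

#' @export
arcsinh_transform.cgps_cohort <- function(x, cofactor = 150) {
  if (cofactor <= 0) abort("cofactor must be positive")
  if (x$transformed) abort("cohort is already arcsinh-transformed")
  x$cells[x$markers] <- lapply(x$cells[x$markers], function(v) asinh(v / cofactor))
  x$transformed <- TRUE
  x
}

#' @export
arcsinh_transform.data.frame <- function(x, cofactor = 150) {
  if (cofactor <= 0) abort("cofactor must be positive")
  if (isTRUE(attr(x, "transformed"))) abort("sample is already arcsinh-transformed")
  num <- vapply(x, is.numeric, TRUE)
  x[num] <- lapply(x[num], function(v) asinh(v / cofactor))
  attr(x, "transformed") <- TRUE
  x
}

#' Standardise markers and regress out batch covariates
#'
#' Per marker, fits a linear model of expression on the indicator columns of
#' the given subject-level covariates across all pooled cells of the cohort,
#' replaces values with the residuals, then centres to mean 0 and scales to
#' unit variance. With `covariates = character()` this is a plain
#' centre/scale. Constant-valued markers are set to zero (with a warning)
#' rather than producing NaN, so degenerate synthetic inputs do not abort a
#' run.
#'
#' @param cohort an arcsinh-transformed `cgps_cohort`.
#' @param covariates character vector of subject-table columns (e.g.
#'   `"batch"`) to regress out. Each must have at least two levels.
#' @return A new `cgps_cohort` with `scaled = TRUE`.
#' @export
scale_and_regress <- function(cohort, covariates = character()) {
  stopifnot(inherits(cohort, "cgps_cohort"))
  if (!cohort$transformed) abort("arcsinh-transform the cohort before scaling")
  if (cohort$scaled) abort("cohort is already scaled")
  y <- as.matrix(cohort$cells[cohort$markers])
  if (length(covariates) > 0) {
    missing_cv <- setdiff(covariates, names(cohort$subjects))
    if (length(missing_cv) > 0) {
      abort(paste0("covariate(s) not in subject table: ",
                   paste(missing_cv, collapse = ", ")))
    }
    cv <- cohort$subjects[match(cohort$cells$subject_id,
                                cohort$subjects$subject_id),
                          covariates, drop = FALSE]
    single <- covariates[vapply(cv, function(v) length(unique(v)) < 2, TRUE)]
    if (length(single) > 0) {
      abort(paste0("covariate with a single level (no contrast): ",
                   paste(single, collapse = ", ")))
    }
    cv[] <- lapply(cv, factor)
    design <- stats::model.matrix(~ ., data = cv)
    y <- qr.resid(qr(design), y)
  }
  y <- scale(y, center = TRUE, scale = FALSE)
  sds <- apply(y, 2, sd)
  flat <- sds < 1e-12
  if (any(flat)) {
    warn(paste0("constant-valued marker(s) set to zero: ",
                paste(cohort$markers[flat], collapse = ", ")))
    sds[flat] <- 1
    y[, flat] <- 0
  }
  y <- sweep(y, 2, sds, "/")
  cohort$cells[cohort$markers] <- as_tibble(y)
  cohort$scaled <- TRUE
  cohort
}
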