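#' Read one sample's cell matrix
#'
#' Reads a cells-by-markers expression matrix from CSV (header row of marker
#' names, one cell per row) or from an FCS 3.0/3.1 list-mode file. Values
#' are returned on the raw scale with `transformed = FALSE`; apply
#' [arcsinh_transform()] before gating or clustering.
#'
#' FCS parameter names are mapped to panel marker names through a
#' user-supplied channel map (two columns: `channel`, `marker`, either a
#' data frame or the path of such a CSV). When a map is supplied it must
#' cover every channel in the file and every mapped channel must be present.
#'
#' @param path file to read.
#' @param format `"csv"` or `"fcs"`.
#' @param channel_map optional channel-to-marker map (FCS only).
#' @param sample_id optional label stored as an attribute.
#' @return Tibble (cells x markers) with attributes `sample_id` and
#'   `transformed = FALSE`.
#' @export
read_sample <- function(path, format = c("csv", "fcs"), channel_map = NULL,
                        sample_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (file.size(path) == 0) abort(paste0("empty file: ", path))
  if (format == "csv") {
    out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    if (nrow(out) == 0) abort(paste0("no cells in file: ", path))
    bad <- names(out)[!vapply(out, is.numeric, TRUE)]
    if (length(bad) > 0) {
      abort(paste0("non-numeric marker column(s): ", paste(bad, collapse = ", ")))
    }
  } else {
    fcs <- read_fcs(path)
    channels <- colnames(fcs)
    if (!is.null(channel_map)) {
      if (is.character(channel_map) && length(channel_map) == 1) {
        channel_map <- readr::read_csv(channel_map, show_col_types = FALSE,
                                       progress = FALSE)
      }
      stopifnot(all(c("channel", "marker") %in% names(channel_map)))
      unmapped <- setdiff(channels, channel_map$channel)
      if (length(unmapped) > 0) {
        abort(paste0("channel(s) with no map entry: ",
                     paste(unmapped, collapse = ", ")))
      }
      missing_ch <- setdiff(channel_map$channel, channels)
      if (length(missing_ch) > 0) {
        abort(paste0("mapped channel(s) missing from FCS file: ",
                     paste(missing_ch, collapse = ", ")))
      }
      colnames(fcs) <- channel_map$marker[match(channels, channel_map$channel)]
    }
    out <- as_tibble(fcs)
  }
  if (anyNA(out)) abort(paste0("missing values in ", path))
  attr(out, "sample_id") <- sample_id %||% sub("\\.(csv|fcs)$", "", basename(path))
  attr(out, "transformed") <- FALSE
  out
}

#' Write one sample's cell matrix as CSV
#'
#' Comma-separated, UTF-8, header row of marker names, one cell per row.
#' Round-trips losslessly with [read_sample()] at full double precision.
#'
#' @param sample tibble of cells x markers.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sample <- function(sample, path) {
  readr::write_csv(as_tibble(sample), path)
  invisible(path)
}

# Minimal FCS 3.0/3.1 list-mode reader. No R package in the supported stack
# parses FCS, so the subset of the standard needed here (single data
# segment, $MODE L, $DATATYPE F/D/I, uniform $PnB) is implemented directly.
read_fcs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- rawToChar(readBin(con, "raw", 58))
  version <- substr(header, 1, 6)
  if (!version %in% c("FCS3.0", "FCS3.1")) {
    abort(paste0("unsupported FCS version: '", version, "'"))
  }
  off <- function(i) as.numeric(trimws(substr(header, 11 + (i - 1) * 8, 18 + (i - 1) * 8)))
  text_start <- off(1); text_end <- off(2)
  data_start <- off(3); data_end <- off(4)

  seek(con, text_start)
  text <- rawToChar(readBin(con, "raw", text_end - text_start + 1))
  delim <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  kw <- as.list(setNames(parts[seq(2, length(parts), 2)],
                         parts[seq(1, length(parts), 2)]))

  n_par <- as.integer(kw[["$PAR"]])
  n_tot <- as.integer(kw[["$TOT"]])
  dtype <- kw[["$DATATYPE"]]
  byteord <- kw[["$BYTEORD"]]
  endian <- if (startsWith(byteord, "1")) "little" else "big"
  bits <- unique(vapply(seq_len(n_par),
                        function(i) as.integer(kw[[paste0("$P", i, "B")]]), 0L))
  if (length(bits) != 1) abort("mixed $PnB widths are not supported")
  if (identical(kw[["$MODE"]], "C")) abort("correlated-mode FCS is not supported")
  if (data_start == 0 && !is.null(kw[["$BEGINDATA"]])) {
    data_start <- as.numeric(kw[["$BEGINDATA"]])
    data_end <- as.numeric(kw[["$ENDDATA"]])
  }
  seek(con, data_start)
  n_values <- n_par * n_tot
  values <- switch(dtype,
    "F" = readBin(con, "numeric", n_values, size = 4, endian = endian),
    "D" = readBin(con, "numeric", n_values, size = 8, endian = endian),
    "I" = readBin(con, "integer", n_values, size = bits / 8, endian = endian,
                  signed = bits > 16),
    abort(paste0("unsupported $DATATYPE: ", dtype))
  )
  if (length(values) < n_values) abort("truncated FCS data segment")
  mat <- matrix(values, nrow = n_tot, ncol = n_par, byrow = TRUE)
  nm <- vapply(seq_len(n_par), function(i) {
    kw[[paste0("$P", i, "S")]] %||% kw[[paste0("$P", i, "N")]]
  }, "")
  colnames(mat) <- nm
  mat
}

#' Write a cohort to disk as CSV
#'
#' One `cells.csv` per subject under `dir`, plus `subjects.csv` with the
#' clinical table.
#'
#' @param cohort a `cgps_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cgps_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sid in cohort$subjects$subject_id) {
    write_sample(cohort_sample(cohort, sid), file.path(dir, paste0(sid, ".csv")))
  }
  readr::write_csv(cohort$subjects, file.path(dir, "subjects.csv"))
  invisible(dir)
}
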