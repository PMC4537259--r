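#' Read a feature table from CSV
#'
#' Expects a header row `subject_id, group, <feature names...>`, optionally
#' followed by a domain line whose first field is `#domain` carrying one
#' domain tag per feature. Non-numeric cells in feature columns become
#' missing values and are counted in the validation summary.
#'
#' @param path Path to the CSV file.
#' @return A feature table tibble (`subject_id` character, `group` factor
#'   with the control level first, numeric features), with attributes
#'   `domains` (if present) and `n_missing` (count of non-numeric /
#'   missing feature cells).
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("cannot read '%s'", path))
  lines <- readLines(path, n = 2L)
  if (length(lines) < 2L) abort("file has no data rows")
  has_domains <- startsWith(lines[2], "#domain")
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  domains <- NULL
  if (has_domains) {
    dom_row <- as.character(raw[1, ])
    raw <- raw[-1, ]
    domains <- setNames(dom_row[-(1:2)], names(raw)[-(1:2)])
  }
  if (!all(c("subject_id", "group") %in% names(raw))) {
    abort("header must contain `subject_id` and `group`")
  }
  if (ncol(raw) < 3L) abort("no feature columns found")
  if (anyDuplicated(raw$subject_id)) abort("duplicate subject ids")
  if (length(unique(raw$group)) < 2L) abort("two groups required")

  feats <- names(raw)[-(1:2)]
  vals <- lapply(raw[feats], function(col) {
    suppressWarnings(as.numeric(col))
  })
  out <- tibble::tibble(subject_id = raw$subject_id,
                        group = as_group_factor(raw$group))
  out <- dplyr::bind_cols(out, tibble::as_tibble(vals))
  if (!is.null(domains)) attr(out, "domains") <- domains
  attr(out, "n_missing") <- sum(vapply(vals, function(v) sum(is.na(v)),
                                       integer(1)))
  out
}

#' Write a feature table to CSV
#'
#' Inverse of [read_feature_table()]: header row, optional `#domain` tag
#' line, then one row per subject. Round-trips bit-identically for tables
#' written and re-read by this pair.
#'
#' @param data A feature table.
#' @param path Output path.
#' @param domains Optional named domain tags; defaults to the table's
#'   `"domains"` attribute.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(data, path,
                                domains = attr(data, "domains")) {
  fc <- feature_cols(data)
  header <- paste(c("subject_id", "group", fc), collapse = ",")
  body <- do.call(paste, c(
    list(data$subject_id, as.character(data$group)),
    lapply(data[fc], format_num_csv),
    sep = ","
  ))
  lines <- c(header,
             if (!is.null(domains))
               paste(c("#domain", "", unname(domains[fc])), collapse = ","),
             body)
  writeLines(lines, path)
  invisible(path)
}

format_num_csv <- function(v) {
  out <- vapply(v, function(x) {
    if (is.na(x)) "NA" else format(x, digits = 17, scientific = FALSE)
  }, character(1))
  out
}

#' Read / write a gait table
#'
#' Plain CSV with columns `subject_id`, `group`, `speed`,
#' `stride_duration`, `stance_duration`, `body_weight`, `paw_area`.
#' All measurement columns must be numeric and strictly positive.
#'
#' @param path CSV path.
#' @return A gait table tibble.
#' @export
read_gait_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("cannot read '%s'", path))
  need <- c("subject_id", "group", "speed", "stride_duration",
            "stance_duration", "body_weight", "paw_area")
  raw <- readr::read_csv(path, show_col_types = FALSE)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    abort(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  }
  num <- need[-(1:2)]
  if (any(vapply(raw[num], function(v) any(!is.finite(v) | v <= 0),
                 logical(1)))) {
    abort("gait measurements must be strictly positive")
  }
  tibble::as_tibble(raw) |>
    dplyr::mutate(subject_id = as.character(.data$subject_id),
                  group = as_group_factor(.data$group))
}

#' @rdname read_gait_table
#' @param data A gait table.
#' @export
write_gait_table <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' Serialize a cohort spec to JSON
#'
#' Written alongside generated tables so every synthetic cohort is
#' reproducible from its provenance file.
#'
#' @param spec A [cohort_spec()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_spec <- function(spec, path) {
  stopifnot(inherits(spec, "cohort_spec"))
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(cohort_spec, x)
}
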