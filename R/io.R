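# CSV readers and writers for the three dataset layouts.
#
# Time columns carry an explicit unit tag in the header (`time_min` or
# `time_hours`); the internal canonical unit is minutes.

time_col_from_header <- function(nms, path) {
  hit <- grep("^time_(min|minutes|h|hr|hours)$", nms, value = TRUE)
  if (length(hit) != 1) {
    stop("expected exactly one time column named time_min/time_minutes or ",
         "time_h/time_hr/time_hours in ", path, call. = FALSE)
  }
  unit <- sub("^time_", "", hit)
  list(col = hit, factor = if (unit %in% c("min", "minutes")) 1 else 60)
}

read_validated_csv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- readr::read_csv(path, show_col_types = FALSE,
                       progress = FALSE, col_types = readr::cols())
  tc <- time_col_from_header(names(d), path)
  missing <- setdiff(required, names(d))
  if (length(missing)) {
    stop("missing column(s) in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  num_cols <- c(tc$col, intersect(c("percent", "rate_pct_per_h"), names(d)))
  for (cc in num_cols) {
    v <- d[[cc]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad)) {
        stop(sprintf("non-numeric value(s) in column %s, row(s) %s of %s",
                     cc, paste(bad, collapse = ", "), path), call. = FALSE)
      }
      d[[cc]] <- vn
    }
    if (anyNA(d[[cc]])) {
      stop(sprintf("missing value(s) in column %s of %s", cc, path),
           call. = FALSE)
    }
  }
  d$time <- d[[tc$col]] * tc$factor
  d
}

#' Read and write migration datasets
#'
#' Long-format CSV with columns `organ`, a unit-tagged time column
#' (`time_min` or `time_hours`) and `percent` (percent of injected label
#' recovered). Unknown organ labels and duplicate (organ, time) pairs are
#' rejected with the offending row numbers.
#'
#' @param path Path to a UTF-8 CSV file with a header.
#' @return A validated tibble with columns `organ`, `time` (minutes),
#'   `percent`.
#' @export
read_migration_csv <- function(path) {
  d <- read_validated_csv(path, required = "organ")
  if (!"percent" %in% names(d)) {
    stop("missing column(s) in ", path, ": percent", call. = FALSE)
  }
  bad <- which(!d$organ %in% recirc_organs())
  if (length(bad)) {
    stop(sprintf("unknown organ label(s) %s in row(s) %s of %s",
                 paste(unique(d$organ[bad]), collapse = ", "),
                 paste(bad, collapse = ", "), path), call. = FALSE)
  }
  out <- tibble::as_tibble(d[, c("organ", "time", "percent")])
  validate_migration_data(out, require_all_organs = FALSE)
  out
}

#' @rdname read_migration_csv
#' @param data Tibble with columns `organ`, `time` (minutes), `percent`.
#' @param time_unit Unit used for the written time column.
#' @export
write_migration_csv <- function(data, path,
                                time_unit = c("min", "hours")) {
  time_unit <- match.arg(time_unit)
  validate_migration_data(tibble::as_tibble(data), require_all_organs = FALSE)
  out <- tibble::tibble(
    organ = data$organ,
    time = if (time_unit == "min") data$time else data$time / 60,
    percent = data$percent
  )
  names(out)[2] <- paste0("time_", time_unit)
  readr::write_csv(out, path)
  invisible(path)
}

#' Read and write cannulation datasets
#'
#' CSV with a unit-tagged time column and `rate_pct_per_h`, the duct output
#' in percent of transferred cells per hour.
#'
#' @inheritParams read_migration_csv
#' @return A validated tibble with columns `time` (minutes), `rate`.
#' @export
read_cannulation_csv <- function(path) {
  d <- read_validated_csv(path, required = "rate_pct_per_h")
  out <- tibble::tibble(time = d$time, rate = d$rate_pct_per_h)
  validate_cannulation_data(out)
  out
}

#' @rdname read_cannulation_csv
#' @param data Tibble with columns `time` (minutes), `rate`.
#' @param time_unit Unit used for the written time column.
#' @export
write_cannulation_csv <- function(data, path,
                                  time_unit = c("min", "hours")) {
  time_unit <- match.arg(time_unit)
  validate_cannulation_data(data)
  out <- tibble::tibble(
    time = if (time_unit == "min") data$time else data$time / 60,
    rate_pct_per_h = data$rate
  )
  names(out)[1] <- paste0("time_", time_unit)
  readr::write_csv(out, path)
  invisible(path)
}

#' Read and write stimulated/control node datasets
#'
#' CSV with columns `node` (`stimulated`/`control`), a unit-tagged time
#' column and `percent`.
#'
#' @inheritParams read_migration_csv
#' @return A validated tibble with columns `node`, `time` (minutes),
#'   `percent`.
#' @export
read_node_csv <- function(path) {
  d <- read_validated_csv(path, required = "node")
  if (!"percent" %in% names(d)) {
    stop("missing column(s) in ", path, ": percent", call. = FALSE)
  }
  bad <- which(!d$node %in% c("stimulated", "control"))
  if (length(bad)) {
    stop(sprintf("unknown node label(s) %s in row(s) %s of %s",
                 paste(unique(d$node[bad]), collapse = ", "),
                 paste(bad, collapse = ", "), path), call. = FALSE)
  }
  if (anyDuplicated(d[, c("node", "time")])) {
    stop("at most one record per (node, time) pair in ", path, call. = FALSE)
  }
  tibble::as_tibble(d[, c("node", "time", "percent")])
}

#' @rdname read_node_csv
#' @param data Tibble with columns `node`, `time` (minutes), `percent`.
#' @param time_unit Unit used for the written time column.
#' @export
write_node_csv <- function(data, path, time_unit = c("min", "hours")) {
  time_unit <- match.arg(time_unit)
  out <- tibble::tibble(
    node = data$node,
    time = if (time_unit == "min") data$time else data$time / 60,
    percent = data$percent
  )
  names(out)[2] <- paste0("time_", time_unit)
  readr::write_csv(out, path)
  invisible(path)
}
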