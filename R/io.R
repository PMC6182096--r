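#' Read raw count data from CSV
#'
#' Reads a comma-separated file with header columns `sample_id`, `count`,
#' `volume_liters` and optional `tntc_threshold` (blank or `NA` on exact
#' counted rows). Malformed rows are reported with their line numbers.
#'
#' @param path Path to a CSV file.
#' @return A [count_data] table.
#' @export
read_counts <- function(path) {
  raw <- read_validated_csv(path, c("sample_id", "count", "volume_liters"))
  if (!"tntc_threshold" %in% names(raw)) raw$tntc_threshold <- NA_real_
  bad <- which(
    (is.na(raw$count) & is.na(raw$tntc_threshold)) |
      (!is.na(raw$count) & (raw$count < 0 | raw$count != round(raw$count))) |
      is.na(raw$volume_liters) | raw$volume_liters <= 0
  )
  if (length(bad)) {
    stop("invalid count rows (negative/non-integer count or non-positive ",
         "volume) at data line(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  count_data(sample_id = raw$sample_id, count = raw$count,
             volume = raw$volume_liters, tntc_threshold = raw$tntc_threshold)
}

#' Write raw count data to CSV
#'
#' Inverse of [read_counts()]: counts and volumes round-trip exactly
#' (volumes written at full precision).
#'
#' @param observations A [count_data] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(observations, path) {
  stopifnot(inherits(observations, "count_data"))
  out <- data.frame(
    sample_id = observations$sample_id,
    count = observations$count,
    volume_liters = format(observations$volume, digits = 17, trim = TRUE,
                           scientific = FALSE),
    tntc_threshold = observations$tntc_threshold
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read legacy reported concentrations from CSV
#'
#' Reads per-sample reported concentrations with header columns
#' `sample_id`, `reported`. The `reported` column holds either a numeric
#' concentration or a `"<x"` non-detect string whose `x` is the reporting
#' limit. The `units` flag states the scale of the file; values are
#' converted to organisms per liter internally.
#'
#' @param path Path to a CSV file.
#' @param units `"per_L"` or `"per_100L"` (e.g. protozoan data are
#'   conventionally reported per 100 L).
#' @return A [reported_data] table (always per liter).
#' @export
read_reported <- function(path, units = c("per_L", "per_100L")) {
  units <- match.arg(units)
  raw <- read_validated_csv(path, c("sample_id", "reported"),
                            colClasses = "character")
  txt <- trimws(raw$reported)
  nd <- startsWith(txt, "<")
  num <- suppressWarnings(as.numeric(ifelse(nd, substring(txt, 2), txt)))
  bad <- which(is.na(num) | num <= 0)
  if (length(bad)) {
    stop("unparseable or non-positive reported value at data line(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  scale <- if (units == "per_100L") 1 / 100 else 1
  num <- num * scale
  reported_data(
    sample_id = raw$sample_id,
    value = ifelse(nd, NA_real_, num),
    nondetect = nd,
    limit = ifelse(nd, num, NA_real_)
  )
}

read_validated_csv <- function(path, required, ...) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, ...)
  if (nrow(raw) == 0L) stop("empty dataset: ", path, call. = FALSE)
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  raw
}

#' Bundled datasets
#'
#' `load_fixture("calgary_giardia_2012")` returns the eight raw water
#' Giardia cyst samples (City of Calgary, AB, Canada, October 2012) exactly
#' as printed in the source monitoring records: counts 1, 0, 0, 0, 0, 0, 0,
#' 2 in volumes 64.4 to 53.2 L (419.5 L total, 3 cysts). This is the worked
#' dataset for comparing non-detect handling approaches.
#'
#' @param name Dataset name; see Details for the available names.
#' @return A [count_data] table.
#'
#' @examples
#' giardia <- load_fixture()
#' naive_pooled_mean(giardia)  # 3 cysts / 419.5 L
#' @export
load_fixture <- function(name = "calgary_giardia_2012") {
  available <- c("calgary_giardia_2012")
  if (!name %in% available) {
    stop("unknown fixture '", name, "'; available: ",
         paste(available, collapse = ", "), call. = FALSE)
  }
  path <- system.file("extdata", paste0(name, ".csv"), package = "ndcount",
                      mustWork = TRUE)
  read_counts(path)
}

#' Display-mode reported concentrations
#'
#' Formats a [reported_data] table the way monitoring reports print it:
#' per 100 L at 2 significant figures, non-detects as `"<x"`. For display
#' only — analysis functions always use full-precision values.
#'
#' @param data A [reported_data] table.
#' @return Character vector, one entry per sample.
#' @export
format_reported_per_100L <- function(data) {
  stopifnot(inherits(data, "reported_data"))
  ifelse(data$nondetect,
         paste0("<", signif(data$limit * 100, 2)),
         as.character(signif(data$value * 100, 2)))
}
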