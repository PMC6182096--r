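#' Raw count observations
#'
#' Construct a validated table of raw microbial enumeration records: one row
#' per analysed sample, with the observed organism count and the analytical
#' volume in liters. A count may instead be recorded as "too numerous to
#' count" (TNTC) — known only to be at least `tntc_threshold` — in which
#' case `count` is `NA` and the threshold carries the information.
#'
#' Raw (count, volume) records are the fundamental datum of enumeration
#' methods: a reported concentration of 0.0155/L loses the information that
#' it arose from 1 organism in 64.4 L.
#'
#' @param sample_id Sample labels (coerced to character). Defaults to
#'   `1..n`.
#' @param count Non-negative integer counts; `NA` for TNTC rows.
#' @param volume Analytical volumes in liters, all positive.
#' @param tntc_threshold Positive integer thresholds for TNTC rows (`NA`
#'   elsewhere); a TNTC row means count >= threshold.
#'
#' @return A `data.frame` of class `count_data` with columns `sample_id`,
#'   `count`, `volume`, `tntc_threshold`.
#'
#' @examples
#' count_data(count = c(1, 0, 2), volume = c(64.4, 50.2, 50.7))
#' @export
count_data <- function(sample_id = NULL, count, volume, tntc_threshold = NA) {
  n <- length(count)
  if (n == 0L) stop("at least one observation is required", call. = FALSE)
  if (is.null(sample_id)) sample_id <- as.character(seq_len(n))
  tntc_threshold <- rep_len(tntc_threshold, n)
  if (length(volume) == 1L) volume <- rep(volume, n)
  if (length(sample_id) != n || length(volume) != n) {
    stop("`sample_id`, `count` and `volume` must have equal length",
         call. = FALSE)
  }
  if (!is.numeric(volume) || any(!is.finite(volume)) || any(volume <= 0)) {
    stop("all volumes must be positive and finite", call. = FALSE)
  }
  is_tntc <- !is.na(tntc_threshold)
  if (any(is_tntc & !is.na(count))) {
    stop("a row cannot carry both an exact count and a TNTC threshold",
         call. = FALSE)
  }
  cnt <- count[!is_tntc]
  if (any(is.na(cnt)) || any(cnt < 0) || any(cnt != round(cnt))) {
    stop("counts must be non-negative integers (NA only on TNTC rows)",
         call. = FALSE)
  }
  thr <- tntc_threshold[is_tntc]
  if (length(thr) && (any(thr < 1) || any(thr != round(thr)))) {
    stop("TNTC thresholds must be positive integers", call. = FALSE)
  }
  structure(
    data.frame(sample_id = as.character(sample_id),
               count = as.numeric(count),
               volume = as.numeric(volume),
               tntc_threshold = as.numeric(tntc_threshold),
               stringsAsFactors = FALSE),
    class = c("count_data", "data.frame")
  )
}

#' Legacy reported-concentration records
#'
#' Construct a validated table of per-sample reported concentrations, the
#' input to the legacy non-detect handling approaches (omission and
#' substitution, and censored-data fitting). A detect row carries a positive
#' concentration `value` (organisms per liter); a non-detect row carries a
#' per-sample reporting `limit` (the purported MDL, one organism per
#' analysed volume, i.e. `1/volume`).
#'
#' @param sample_id Sample labels; default `1..n`.
#' @param value Concentration for detects, organisms/L; `NA` for
#'   non-detects.
#' @param nondetect Logical: is the row a non-detect?
#' @param limit Reporting limit for non-detect rows, organisms/L; `NA`
#'   allowed on detect rows.
#'
#' @return A `data.frame` of class `reported_data` with columns `sample_id`,
#'   `value`, `nondetect`, `limit`.
#'
#' @examples
#' reported_data(value = c(0.0155, NA), nondetect = c(FALSE, TRUE),
#'               limit = c(NA, 0.0199))
#' @export
reported_data <- function(sample_id = NULL, value, nondetect, limit = NA) {
  n <- length(nondetect)
  if (n == 0L) stop("at least one record is required", call. = FALSE)
  if (is.null(sample_id)) sample_id <- as.character(seq_len(n))
  value <- rep_len(value, n)
  limit <- rep_len(limit, n)
  nondetect <- as.logical(nondetect)
  if (anyNA(nondetect)) stop("`nondetect` must be TRUE/FALSE", call. = FALSE)
  if (any(nondetect & (is.na(limit) | limit <= 0))) {
    stop("every non-detect row needs a positive reporting `limit`",
         call. = FALSE)
  }
  if (any(!nondetect & (is.na(value) | value <= 0))) {
    stop("every detect row needs a positive `value`", call. = FALSE)
  }
  if (any(nondetect & !is.na(value))) {
    stop("non-detect rows must not carry a `value`", call. = FALSE)
  }
  structure(
    data.frame(sample_id = as.character(sample_id),
               value = as.numeric(value),
               nondetect = nondetect,
               limit = as.numeric(limit),
               stringsAsFactors = FALSE),
    class = c("reported_data", "data.frame")
  )
}

has_tntc <- function(obs) any(!is.na(obs$tntc_threshold))
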