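#' Construct a digitized Kaplan-Meier curve
#'
#' A digitized survival curve is the list of (time, survival) coordinates
#' read off a published Kaplan-Meier figure for one endpoint (PFS or OS) of
#' one treatment arm. Times are months; survival is a fraction.
#'
#' @param time event-free times in months, strictly increasing, `>= 0`.
#' @param survival survival fractions in \[0, 1\], non-increasing.
#' @param endpoint `"PFS"` or `"OS"`.
#' @param arm optional arm label.
#' @return a tibble of class `km_curve` with columns `time`, `survival`
#'   and attributes `endpoint`, `arm`.
#' @export
#' @examples
#' km_curve(c(0, 6, 12), c(1, 0.7, 0.4), endpoint = "PFS")
km_curve <- function(time, survival, endpoint = c("PFS", "OS"), arm = NULL) {
  endpoint <- match.arg(endpoint)
  out <- tibble::tibble(time = as.numeric(time), survival = as.numeric(survival))
  out <- structure(out, endpoint = endpoint, arm = arm,
                   class = c("km_curve", class(out)))
  validate_km_curve(out)
}

#' Validate a digitized Kaplan-Meier curve
#'
#' Checks the curve invariants: at least 3 points, times strictly
#' increasing, survival within \[0, 1\] and non-increasing, and an anchor
#' point (0, 1). The anchor is prepended when absent; any other violation
#' is an error naming the offending row indices.
#'
#' @param curve a `km_curve` or a data frame with columns `time`, `survival`.
#' @return the validated curve (anchor completed), as a `km_curve` tibble.
#' @export
validate_km_curve <- function(curve) {
  if (!all(c("time", "survival") %in% names(curve))) {
    abort("a KM curve needs `time` and `survival` columns.")
  }
  endpoint <- attr(curve, "endpoint") %||% "PFS"
  arm <- attr(curve, "arm")
  tm <- curve$time
  sv <- curve$survival
  if (length(tm) < 2) abort("a KM curve needs at least 3 points (incl. the (0, 1) anchor).")
  if (any(!is.finite(tm)) || any(!is.finite(sv))) abort("KM curve contains non-finite values.")
  if (any(tm < 0)) abort("KM times must be non-negative.")
  if (any(sv < 0 | sv > 1)) {
    bad <- which(sv < 0 | sv > 1)
    abort(paste0("KM survival outside [0, 1] at index ", paste(bad, collapse = ", "), "."))
  }
  if (!(tm[1] == 0 && sv[1] == 1)) {
    if (tm[1] <= 0) abort("first KM point must be the (0, 1) anchor.")
    tm <- c(0, tm)
    sv <- c(1, sv)
  }
  if (any(diff(tm) <= 0)) {
    bad <- which(diff(tm) <= 0) + 1
    abort(paste0("KM times must be strictly increasing; violation at index ",
                 paste(bad, collapse = ", "), "."))
  }
  if (any(diff(sv) > 0)) {
    bad <- which(diff(sv) > 0) + 1
    abort(paste0("KM survival must be non-increasing; violation at index ",
                 paste(bad, collapse = ", "), "."))
  }
  if (length(tm) < 3) abort("a KM curve needs at least 3 points.")
  out <- tibble::tibble(time = tm, survival = sv)
  structure(out, endpoint = endpoint, arm = arm,
            class = c("km_curve", class(out)))
}

#' Read a digitized KM curve from a two-column delimited file
#'
#' The file dialect is two whitespace- or comma-separated columns
#' (time in months, survival fraction); lines starting with `#` are
#' comments.
#'
#' @param path file path.
#' @inheritParams km_curve
#' @return a validated `km_curve`.
#' @export
read_km_curve <- function(path, endpoint = c("PFS", "OS"), arm = NULL) {
  endpoint <- match.arg(endpoint)
  if (!file.exists(path)) abort(paste0("KM file not found: ", path))
  raw <- tryCatch(
    read.table(path, comment.char = "#", header = FALSE,
               sep = "", col.names = c("time", "survival"),
               colClasses = "numeric"),
    error = function(e) {
      read.table(path, comment.char = "#", header = FALSE, sep = ",",
                 col.names = c("time", "survival"), colClasses = "numeric")
    }
  )
  km_curve(raw$time, raw$survival, endpoint = endpoint, arm = arm)
}

#' Write a KM curve to the two-column dialect
#'
#' @param curve a `km_curve`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_km_curve <- function(curve, path) {
  curve <- validate_km_curve(curve)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# endpoint: %s", attr(curve, "endpoint")), con)
  if (!is.null(attr(curve, "arm"))) {
    writeLines(sprintf("# arm: %s", attr(curve, "arm")), con)
  }
  writeLines("# time_months survival", con)
  writeLines(sprintf("%.10g %.10g", curve$time, curve$survival), con)
  invisible(path)
}
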