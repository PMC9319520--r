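#' Sampled measurement series
#'
#' A light container for sampled experimental measurements: a data frame
#' with columns `time_h`, `value` and `replicate`, carrying a declared
#' measurement kind. The kinds used across the package are
#' `"cumulative_per_area"` (ug/cm^2), `"receptor_concentration"` (ug/mL),
#' `"plasma_concentration"` (ng/mL), `"flux"` (ug/cm^2/h) and
#' `"amount"` (ug). Times must be strictly increasing within a replicate.
#'
#' @param times sampling times (h).
#' @param values measured magnitudes, same length as `times`.
#' @param kind one of the measurement kinds above.
#' @param replicate replicate labels (recycled), default `"r1"`.
#'
#' @return An object of classes `time_series` and `data.frame`.
#' @examples
#' ts <- time_series(c(3, 5, 7), c(90, 220, 390), kind = "cumulative_per_area")
#' @export
time_series <- function(times, values, kind, replicate = "r1") {
  kind <- match.arg(kind, c("cumulative_per_area", "receptor_concentration",
                            "plasma_concentration", "flux", "amount"))
  if (length(times) != length(values))
    stop("'times' and 'values' must have the same length")
  if (any(!is.finite(values))) stop("'values' must be finite")
  df <- data.frame(time_h = as.numeric(times), value = as.numeric(values),
                   replicate = rep_len(as.character(replicate), length(times)))
  for (r in unique(df$replicate)) {
    tt <- df$time_h[df$replicate == r]
    if (any(diff(tt) <= 0))
      stop("'times' must be strictly increasing within each replicate")
  }
  structure(df, kind = kind, class = c("time_series", "data.frame"))
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("Time series (%s), %d points, %d replicate(s)\n",
              attr(x, "kind"), nrow(x), length(unique(x$replicate))))
  print.data.frame(x, ...)
  invisible(x)
}

#' Read a measurement series from delimited text
#'
#' Reads a comma-separated file with header `time_h,value,replicate`
#' (the `replicate` column is optional) into a [time_series()].
#'
#' @param path file path.
#' @param kind measurement kind to declare (see [time_series()]).
#' @return A `time_series` object.
#' @export
read_time_series <- function(path, kind) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_h", "value") %in% names(df)))
    stop("file must have columns 'time_h' and 'value'")
  rep <- if ("replicate" %in% names(df)) df$replicate else "r1"
  time_series(df$time_h, df$value, kind = kind, replicate = rep)
}

#' Write a measurement series to delimited text
#'
#' @param x a [time_series()] object.
#' @param path output file path.
#' @return `x`, invisibly.
#' @export
write_time_series <- function(x, path) {
  stopifnot(inherits(x, "time_series"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(x)
}

# mean curve across replicates (common time grid assumed)
#' Average a multi-replicate series into a single mean curve
#'
#' Replicates must share a common sampling schedule; the mean value at each
#' time is returned as a single-replicate series of the same kind.
#'
#' @param x a [time_series()] object.
#' @return A `time_series` with one replicate labelled `"mean"`.
#' @export
mean_time_series <- function(x) {
  stopifnot(inherits(x, "time_series"))
  agg <- stats::aggregate(value ~ time_h, data = as.data.frame(x), FUN = mean)
  agg <- agg[order(agg$time_h), ]
  time_series(agg$time_h, agg$value, kind = attr(x, "kind"), replicate = "mean")
}
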