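# Per-frame scalar metric time series and tabular output.

#' Construct a metric time series
#'
#' @param name metric name (e.g. \code{"thickness"}).
#' @param unit unit string (e.g. \code{"A"}).
#' @param times frame times, ns.
#' @param values metric values, finite, same length as \code{times}.
#' @param replicate_id replicate label.
#' @param condition \code{"cis"}, \code{"trans"} or \code{"other"}.
#' @return Object of class \code{"metric_series"}.
#' @export
metric_series <- function(name, unit, times, values, replicate_id = "r1",
                          condition = "other") {
  if (length(times) != length(values))
    stop("times and values must have equal length")
  if (length(values) && !all(is.finite(values)))
    stop("metric values must be finite")
  structure(list(name = name, unit = unit, times = as.numeric(times),
                 values = as.numeric(values), replicate_id = replicate_id,
                 condition = match.arg(condition,
                                       c("cis", "trans", "other"))),
            class = "metric_series")
}

#' @export
print.metric_series <- function(x, ...) {
  cat(sprintf("<metric_series> %s [%s], %d frames, %s/%s", x$name, x$unit,
              length(x$values), x$replicate_id, x$condition))
  if (length(x$values))
    cat(sprintf("; mean %.4g, sd %.4g", mean(x$values),
                stats::sd(x$values)))
  cat("\n")
  invisible(x)
}

#' @export
mean.metric_series <- function(x, ...) mean(x$values, ...)

#' @export
as.data.frame.metric_series <- function(x, ...) {
  n <- length(x$values)
  data.frame(time_ns = x$times, value = x$values,
             name = rep_len(x$name, n), unit = rep_len(x$unit, n),
             replicate_id = rep_len(x$replicate_id, n),
             condition = rep_len(x$condition, n), stringsAsFactors = FALSE)
}

#' Write metric series or tables to CSV or JSON
#'
#' CSV output is one row per frame/record with a header carrying name and
#' unit; JSON output is schema-versioned.  Writing is deterministic: two
#' writes of the same data give byte-identical files.
#'
#' @param x a \code{\link{metric_series}}, a list of them, or a data.frame.
#' @param path output file path.
#' @param format \code{"csv"} or \code{"json"} (default from file extension).
#' @return \code{path}, invisibly.
#' @export
write_metrics <- function(x, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else
      "csv"
  df <- if (inherits(x, "metric_series")) as.data.frame(x) else
    if (is.data.frame(x)) x else
      do.call(rbind, lapply(x, as.data.frame))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  if (format == "csv") {
    con <- file(path, open = "wb")  # binary: fixed newlines across platforms
    on.exit(close(con))
    utils::write.csv(df, con, row.names = FALSE, eol = "\n")
  } else {
    jsonlite::write_json(list(schema = "memiso/metrics-v1", records = df),
                         path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Read back a metrics table written by \code{\link{write_metrics}}
#' @param path file path.
#' @return data.frame of records.
#' @export
read_metrics <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    out <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!identical(out$schema, "memiso/metrics-v1"))
      stop("unrecognized metrics schema in ", path)
    as.data.frame(out$records)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
}
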