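# Simulation traces: a fixed time grid plus named observable columns.

#' Construct a simulation trace
#'
#' A trace is a data frame whose first column is `Time` (strictly increasing)
#' followed by one numeric column per observable.
#'
#' @param times Numeric vector of strictly increasing time points.
#' @param columns Named list of numeric vectors, all of `length(times)`.
#' @return An object of classes `hpn_trace` and `data.frame`.
#' @export
hpn_trace <- function(times, columns) {
  stopifnot(is.numeric(times), !is.unsorted(times, strictly = TRUE) || length(times) <= 1L)
  if (length(columns)) {
    lens <- vapply(columns, length, 0L)
    if (any(lens != length(times)))
      stop("every trace column must have the same length as the time grid",
           call. = FALSE)
  }
  df <- as.data.frame(c(list(Time = as.numeric(times)), lapply(columns, as.numeric)),
                      optional = TRUE)
  class(df) <- c("hpn_trace", "data.frame")
  df
}

as_hpn_trace <- function(df) {
  stopifnot(is.data.frame(df), names(df)[1L] == "Time")
  class(df) <- c("hpn_trace", "data.frame")
  df
}

trace_columns <- function(trace) setdiff(names(trace), "Time")

#' @export
print.hpn_trace <- function(x, ...) {
  cat(sprintf("Simulation trace: %d time points on [%g, %g], %d observable(s)\n",
              nrow(x), if (nrow(x)) min(x$Time) else NA,
              if (nrow(x)) max(x$Time) else NA, ncol(x) - 1L))
  cat("  columns:", paste(trace_columns(x), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.hpn_trace <- function(x, columns = trace_columns(x), ...) {
  cols <- match.arg(columns, trace_columns(x), several.ok = TRUE)
  matplot(x$Time, as.matrix(x[cols]), type = "l", lty = 1,
          xlab = "Time", ylab = "Marking", ...)
  legend("topright", legend = cols, col = seq_along(cols), lty = 1, bty = "n")
  invisible(x)
}

#' Pointwise mean of an ensemble of traces
#'
#' Averages an ensemble of single-run traces column by column, e.g. to obtain
#' the population-level (cell-population) trajectory from many single-cell
#' runs.  All traces must share the same time grid and columns.
#'
#' @param traces List of `hpn_trace` objects.
#' @return A single `hpn_trace` with the pointwise arithmetic means.
#' @export
population_mean <- function(traces) {
  stopifnot(is.list(traces), length(traces) >= 1L)
  ref <- traces[[1L]]
  for (tr in traces[-1L]) {
    if (!identical(dim(tr), dim(ref)) || !identical(names(tr), names(ref)) ||
        !isTRUE(all.equal(tr$Time, ref$Time, tolerance = 0)))
      stop("all traces must share the same time grid and columns", call. = FALSE)
  }
  acc <- as.matrix(ref[trace_columns(ref)])
  for (tr in traces[-1L]) acc <- acc + as.matrix(tr[trace_columns(tr)])
  acc <- acc / length(traces)
  hpn_trace(ref$Time, as.list(as.data.frame(acc, optional = TRUE)))
}
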