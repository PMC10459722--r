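#' Hourly IEQ panel
#'
#' An hourly panel holds the (derived) IEQ variables: one row per time step
#' (clock hour of the working day) and one column per criterion. The
#' `orientation` flag records whether values are raw measurements (`"raw"`)
#' or have been transformed so that lower is always better (`"cost"`); the
#' scoring engines only accept cost panels.
#'
#' @param values Numeric matrix, rows = time steps, columns = criteria.
#'   Row names are hour labels ("9", "10", ...), column names criterion ids.
#' @param orientation Either `"raw"` or `"cost"`.
#' @return An object of class `ieq_panel`: the matrix with an `orientation`
#'   attribute.
#' @examples
#' m <- cbind(pm25 = c(9.3, 8.4), sound = c(46.4, 46.6))
#' rownames(m) <- c("9", "10")
#' ieq_panel(m, "cost")
#' @export
ieq_panel <- function(values, orientation = c("raw", "cost")) {
  orientation <- match.arg(orientation)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyNA(values)) stop("panel has missing cells")
  if (nrow(values) < 2L) stop("panel needs at least two time steps")
  if (ncol(values) < 1L) stop("panel needs at least one criterion")
  if (is.null(rownames(values))) stop("panel rows must be labelled by hour")
  if (is.null(colnames(values))) stop("panel columns must be labelled by criterion")
  structure(values, orientation = orientation, class = c("ieq_panel", "matrix", "array"))
}

#' @export
print.ieq_panel <- function(x, ...) {
  cat(sprintf("ieq_panel: %d time steps x %d criteria (orientation: %s)\n",
              nrow(x), ncol(x), panel_orientation(x)))
  print(unclass_panel(x), ...)
  invisible(x)
}

#' Panel orientation flag
#' @param panel An [ieq_panel].
#' @return `"raw"` or `"cost"`.
#' @export
panel_orientation <- function(panel) attr(panel, "orientation")

unclass_panel <- function(panel) {
  attr(panel, "orientation") <- NULL
  class(panel) <- NULL
  panel
}

is_cost_panel <- function(panel) {
  inherits(panel, "ieq_panel") && identical(panel_orientation(panel), "cost")
}

#' Assemble an hourly panel from per-variable hourly columns
#'
#' @param columns Named list; each element a data.frame with columns `hour`
#'   and `value` (as returned by [hourly_means()]), all sharing the same hour
#'   labels in the same order.
#' @return A raw-oriented [ieq_panel].
#' @examples
#' a <- data.frame(hour = 9:10, value = c(1, 2))
#' b <- data.frame(hour = 9:10, value = c(3, 4))
#' build_panel(list(pm25 = a, sound = b))
#' @export
build_panel <- function(columns) {
  if (!is.list(columns) || is.null(names(columns)) || any(names(columns) == ""))
    stop("columns must be a named list of hourly sequences")
  hours <- lapply(columns, function(d) as.character(d$hour))
  ref <- hours[[1L]]
  for (i in seq_along(hours)) {
    if (!identical(hours[[i]], ref)) {
      extra <- setdiff(hours[[i]], ref)
      missing <- setdiff(ref, hours[[i]])
      stop(sprintf(
        "hour labels of column '%s' differ from column '%s' (extra: %s; missing: %s)",
        names(columns)[i], names(columns)[1L],
        paste(extra, collapse = ","), paste(missing, collapse = ",")))
    }
  }
  m <- do.call(cbind, lapply(columns, function(d) as.numeric(d$value)))
  colnames(m) <- names(columns)
  rownames(m) <- ref
  ieq_panel(m, "raw")
}

#' Read / write an hourly panel as CSV
#'
#' The CSV has a first column `hour` and one column per criterion.
#'
#' @param path File path.
#' @param orientation Orientation to stamp on the panel read from disk.
#' @return `read_panel_csv()` returns an [ieq_panel]; `write_panel_csv()`
#'   returns `path` invisibly.
#' @export
read_panel_csv <- function(path, orientation = c("raw", "cost")) {
  orientation <- match.arg(orientation)
  d <- utils::read.csv(path, check.names = FALSE)
  if (!"hour" %in% names(d)) stop("panel CSV must have an 'hour' column")
  m <- as.matrix(d[setdiff(names(d), "hour")])
  rownames(m) <- as.character(d$hour)
  ieq_panel(m, orientation)
}

#' @rdname read_panel_csv
#' @param panel An [ieq_panel] to write.
#' @export
write_panel_csv <- function(panel, path) {
  d <- data.frame(hour = rownames(panel), unclass_panel(panel),
                  check.names = FALSE, row.names = NULL)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Working-day schedule
#'
#' @param start First included clock hour (e.g. 9 for a 9:00 start).
#' @param end End hour, exclusive (18 means the last included hour is 17:00).
#' @param exclude Integer vector of excluded hours within `[start, end)`,
#'   e.g. a lunch break.
#' @return An object of class `ieq_schedule`.
#' @examples
#' schedule(9, 18, exclude = 13)  # 8 working hours with a lunch break
#' @export
schedule <- function(start = 9, end = 18, exclude = integer()) {
  start <- as.integer(start); end <- as.integer(end)
  exclude <- as.integer(exclude)
  if (start < 0 || end > 24 || start >= end) stop("need 0 <= start < end <= 24")
  if (length(exclude) && (any(exclude < start) || any(exclude >= end)))
    stop("excluded hours must lie within [start, end)")
  hours <- setdiff(seq.int(start, end - 1L), exclude)
  if (!length(hours)) stop("schedule has no included hours")
  structure(list(start = start, end = end, exclude = exclude, hours = hours),
            class = "ieq_schedule")
}

#' @export
print.ieq_schedule <- function(x, ...) {
  cat(sprintf("ieq_schedule: %02d:00-%02d:00, excluded: %s (%d hours)\n",
              x$start, x$end,
              if (length(x$exclude)) paste(x$exclude, collapse = ",") else "none",
              length(x$hours)))
  invisible(x)
}
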