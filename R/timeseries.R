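# Sensor stream ingestion, piecewise-linear segmentation, hourly aggregation.

.sensor_defaults <- list(
  temperature = list(unit = "°C",        range = c(-40, 85)),
  humidity    = list(unit = "%RH",            range = c(0, 100)),
  illuminance = list(unit = "lux",            range = c(0, 120000)),
  pm25        = list(unit = "μg/m³", range = c(0, 1000)),
  sound       = list(unit = "dB",             range = c(22, 136))
)

#' IEQ sensor variables
#'
#' Canonical variable identifiers, default units and default measurement
#' ranges for the five monitored IEQ streams (low-cost sensor set: air
#' temperature, relative humidity, desk illuminance, pm2.5, A-weighted sound
#' level).
#'
#' @return A data.frame with columns `variable`, `unit`, `min`, `max`.
#' @export
sensor_variables <- function() {
  data.frame(
    variable = names(.sensor_defaults),
    unit = vapply(.sensor_defaults, `[[`, "", "unit"),
    min = vapply(.sensor_defaults, function(x) x$range[1L], 0),
    max = vapply(.sensor_defaults, function(x) x$range[2L], 0),
    row.names = NULL
  )
}

#' Construct a sensor series
#'
#' A sensor series is an ordered sequence of (time, value) samples for one
#' IEQ variable. Times are seconds since midnight of the monitored day.
#' Values falling outside the declared measurement range are flagged (kept,
#' with a warning), not dropped.
#'
#' @param time Numeric, strictly increasing, seconds since midnight.
#' @param value Numeric sample values.
#' @param variable One of `sensor_variables()$variable`, or any custom id.
#' @param unit Measurement unit; defaults to the canonical unit if known.
#' @param range Length-2 numeric measurement range; defaults to the sensor
#'   spec range for known variables, otherwise unbounded.
#' @return An object of class `sensor_series`.
#' @export
sensor_series <- function(time, value, variable, unit = NULL, range = NULL) {
  time <- as.numeric(time); value <- as.numeric(value)
  if (length(time) != length(value)) stop("time and value lengths differ")
  if (anyNA(time) || anyNA(value)) stop("sensor series has missing samples")
  bad <- which(diff(time) <= 0)
  if (length(bad))
    stop(sprintf("timestamps not strictly increasing at sample %d", bad[1L] + 1L))
  def <- .sensor_defaults[[variable]]
  unit <- unit %||% (if (!is.null(def)) def$unit else "")
  range <- range %||% (if (!is.null(def)) def$range else c(-Inf, Inf))
  out_of_range <- which(value < range[1L] | value > range[2L])
  if (length(out_of_range))
    warning(sprintf("%d of %d %s samples outside measurement range [%g, %g]",
                    length(out_of_range), length(value), variable,
                    range[1L], range[2L]))
  structure(
    list(variable = variable, unit = unit, range = range,
         time = time, value = value, out_of_range = out_of_range),
    class = "sensor_series")
}

#' @export
print.sensor_series <- function(x, ...) {
  cat(sprintf("sensor_series '%s' [%s]: %d samples over %.2f h\n",
              x$variable, x$unit, length(x$time),
              (x$time[length(x$time)] - x$time[1L]) / 3600))
  invisible(x)
}

#' Read a sensor stream from CSV
#'
#' Expects a header `timestamp,value`. Timestamps are either numeric epoch /
#' second-of-day values or ISO-8601 datetimes; ISO timestamps are converted
#' to seconds since midnight of the first sample's (UTC) date.
#'
#' @param path CSV file path.
#' @param variable,unit,range Passed to [sensor_series()].
#' @return A validated [sensor_series()].
#' @export
read_sensor_csv <- function(path, variable, unit = NULL, range = NULL) {
  d <- utils::read.csv(path, colClasses = "character")
  if (!all(c("timestamp", "value") %in% names(d)))
    stop("sensor CSV must have header 'timestamp,value'")
  raw_ts <- trimws(d$timestamp)
  ts <- suppressWarnings(as.numeric(raw_ts))
  if (anyNA(ts)) {
    parsed <- as.POSIXct(raw_ts, tz = "UTC",
                         tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
    bad <- which(is.na(parsed))
    if (length(bad))
      stop(sprintf("unparseable timestamp at line %d: '%s'",
                   bad[1L] + 1L, raw_ts[bad[1L]]))
    midnight <- as.POSIXct(format(parsed[1L], "%Y-%m-%d"), tz = "UTC")
    ts <- as.numeric(difftime(parsed, midnight, units = "secs"))
  }
  val <- suppressWarnings(as.numeric(trimws(d$value)))
  if (anyNA(val))
    stop(sprintf("unparseable value at line %d: '%s'",
                 which(is.na(val))[1L] + 1L, d$value[which(is.na(val))[1L]]))
  bad <- which(diff(ts) <= 0)
  if (length(bad))
    stop(sprintf("timestamps not strictly increasing at line %d", bad[1L] + 2L))
  sensor_series(ts, val, variable, unit = unit, range = range)
}

# Fill sub-5-minute gaps by linear interpolation at the median sampling step;
# longer gaps are an error (the pipeline assumes continuous collection).
fill_short_gaps <- function(series, max_gap = 300) {
  dt <- diff(series$time)
  step <- stats::median(dt)
  gaps <- which(dt > 1.5 * step)
  if (!length(gaps)) return(series)
  if (any(dt[gaps] > max_gap))
    stop(sprintf("gap of %.0f s at t=%.0f exceeds the %g s interpolation limit",
                 max(dt[gaps]), series$time[gaps[which.max(dt[gaps])]], max_gap))
  full_t <- sort(unique(c(series$time,
                          unlist(lapply(gaps, function(i)
                            seq(series$time[i], series$time[i + 1L], by = step))))))
  full_v <- stats::approx(series$time, series$value, xout = full_t)$y
  sensor_series(full_t, full_v, series$variable, series$unit, series$range)
}

# OLS line through samples given sufficient statistics; returns c(intercept,
# slope, sse). Falls back to a flat line when x has no spread.
.seg_fit <- function(n, sx, sy, sxx, sxy, syy) {
  vx <- sxx - sx * sx / n
  if (vx <= 0) {
    b <- 0; a <- sy / n
    sse <- syy - sy * sy / n
  } else {
    b <- (sxy - sx * sy / n) / vx
    a <- (sy - b * sx) / n
    sse <- (syy - sy * sy / n) - b * b * vx
  }
  c(a, b, max(sse, 0))
}

#' Bottom-up piecewise-linear segmentation
#'
#' Approximates a high-frequency sensor stream by a small number of linear
#' segments: starts from minimal two-sample segments and greedily merges the
#' adjacent pair whose merged least-squares fit has the lowest RMSE, until
#' either merging any pair would exceed `max_rmse` or `n_segments` segments
#' remain. Exactly one stopping rule may be given; with neither, `max_rmse`
#' defaults to 2% of the series value range (enough to remove sampling noise
#' without flattening diurnal trends).
#'
#' @param series A [sensor_series()] with at least 4 samples. Gaps shorter
#'   than 5 minutes are linearly interpolated first; longer gaps are an error.
#' @param max_rmse Stop when every possible merge would exceed this RMSE
#'   (series units).
#' @param n_segments Alternatively, merge down to exactly this many segments.
#' @return An object of class `segmented_series`: segment table (start/end
#'   time, intercept, slope, n, sse), breakpoints, and the fitted value at
#'   every original sample time.
#' @export
segment_series <- function(series, max_rmse = NULL, n_segments = NULL) {
  if (!inherits(series, "sensor_series")) stop("series must be a sensor_series")
  if (!is.null(max_rmse) && !is.null(n_segments))
    stop("give either max_rmse or n_segments, not both")
  if (is.null(max_rmse) && is.null(n_segments)) {
    rng <- diff(range(series$value))
    max_rmse <- 0.02 * max(rng, .Machine$double.eps)
  }
  series <- fill_short_gaps(series)
  x <- series$time; y <- series$value
  n <- length(x)
  if (n < 4L) stop("segmentation needs at least 4 samples")

  # initial segments: consecutive pairs (last segment absorbs an odd sample)
  starts <- seq(1L, n - 1L, by = 2L)
  if (starts[length(starts)] == n) starts <- starts[-length(starts)]
  ends <- c(starts[-1L] - 1L, n)
  ns <- length(starts)
  if (!is.null(n_segments) && (n_segments < 1L || n_segments > ns))
    stop(sprintf("n_segments must be in [1, %d] for this series", ns))

  # per-segment sufficient statistics
  seg_stat <- function(i, j) {
    xs <- x[i:j]; ys <- y[i:j]
    c(n = j - i + 1, sx = sum(xs), sy = sum(ys),
      sxx = sum(xs * xs), sxy = sum(xs * ys), syy = sum(ys * ys))
  }
  S <- t(vapply(seq_len(ns), function(k) seg_stat(starts[k], ends[k]), numeric(6)))
  alive <- rep(TRUE, ns)
  nxt <- c(seq_len(ns)[-1L], NA_integer_)
  prv <- c(NA_integer_, seq_len(ns)[-ns])

  merge_rmse <- function(k) {
    j <- nxt[k]
    st <- S[k, ] + S[j, ]
    fit <- .seg_fit(st[1L], st[2L], st[3L], st[4L], st[5L], st[6L])
    sqrt(fit[3L] / st[1L])
  }
  cost <- rep(Inf, ns)
  for (k in seq_len(ns - 1L)) cost[k] <- merge_rmse(k)

  alive_n <- ns
  repeat {
    if (!is.null(n_segments) && alive_n <= n_segments) break
    k <- which.min(cost)
    if (is.null(n_segments) && cost[k] > max_rmse) break
    if (!is.finite(cost[k])) break
    j <- nxt[k]
    S[k, ] <- S[k, ] + S[j, ]
    ends_k <- ends[j]; ends[k] <- ends_k
    alive[j] <- FALSE
    nxt[k] <- nxt[j]
    if (!is.na(nxt[j])) prv[nxt[j]] <- k
    cost[j] <- Inf
    cost[k] <- if (!is.na(nxt[k])) merge_rmse(k) else Inf
    if (!is.na(prv[k])) cost[prv[k]] <- merge_rmse(prv[k])
    alive_n <- alive_n - 1L
  }

  keep <- which(alive)
  st <- starts[keep]; en <- ends[keep]

  # boundary refinement: slide each breakpoint to the split that minimises
  # the SSE of its two adjacent segments (exact via prefix sums), sweeping
  # until stable; the segment count never changes
  px <- c(0, cumsum(x)); py <- c(0, cumsum(y))
  pxx <- c(0, cumsum(x * x)); pxy <- c(0, cumsum(x * y))
  pyy <- c(0, cumsum(y * y))
  rng_sse <- function(i, j) {
    m <- j - i + 1
    sx <- px[j + 1] - px[i]; sy <- py[j + 1] - py[i]
    sxx <- pxx[j + 1] - pxx[i]; sxy <- pxy[j + 1] - pxy[i]
    syy <- pyy[j + 1] - pyy[i]
    vx <- pmax(sxx - sx * sx / m, 0)
    b <- ifelse(vx > 0, (sxy - sx * sy / m) / vx, 0)
    pmax(syy - sy * sy / m - b * b * vx, 0)
  }
  if (length(st) > 1L) {
    for (sweep in 1:20) {
      changed <- FALSE
      for (r in seq_len(length(st) - 1L)) {
        i <- st[r]; j <- en[r + 1L]
        bs <- (i + 1L):(j - 2L)
        tot <- rng_sse(rep(i, length(bs)), bs) + rng_sse(bs + 1L, rep(j, length(bs)))
        bi <- which.min(tot)
        cur <- rng_sse(i, en[r]) + rng_sse(en[r] + 1L, j)
        if (bs[bi] != en[r] && tot[bi] < cur - 1e-12) {
          en[r] <- bs[bi]; st[r + 1L] <- bs[bi] + 1L
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }

  fits <- t(vapply(seq_along(st), function(r) {
    i <- st[r]; j <- en[r]
    .seg_fit(j - i + 1, px[j + 1] - px[i], py[j + 1] - py[i],
             pxx[j + 1] - pxx[i], pxy[j + 1] - pxy[i], pyy[j + 1] - pyy[i])
  }, numeric(3)))
  segs <- data.frame(
    start_time = x[st], end_time = x[en],
    intercept = fits[, 1L], slope = fits[, 2L],
    n = en - st + 1, sse = fits[, 3L])
  fitted <- numeric(n)
  for (r in seq_along(st)) {
    idx <- st[r]:en[r]
    fitted[idx] <- segs$intercept[r] + segs$slope[r] * x[idx]
  }
  structure(
    list(series = series, segments = segs,
         breakpoints = c(segs$start_time, segs$end_time[nrow(segs)]),
         fitted = fitted,
         settings = list(max_rmse = max_rmse, n_segments = n_segments)),
    class = "segmented_series")
}

#' @export
print.segmented_series <- function(x, ...) {
  cat(sprintf("segmented_series '%s': %d samples -> %d segments (total SSE %.4g)\n",
              x$series$variable, length(x$series$time), nrow(x$segments),
              sum(x$segments$sse)))
  invisible(x)
}

#' Fitted piecewise-linear values
#' @param object A `segmented_series`.
#' @param ... Unused.
#' @return Numeric vector of fitted values at the original sample times.
#' @export
fitted.segmented_series <- function(object, ...) object$fitted

#' Hourly means of a segmented series
#'
#' For each included schedule hour `[h:00, h+1:00)`, the mean of the fitted
#' piecewise-linear approximation evaluated at the original sample times in
#' that hour. Set `use_fitted = FALSE` to average the raw samples instead
#' (sensitivity checks).
#'
#' @param segmented A `segmented_series` (or, with `use_fitted = FALSE`
#'   semantics, any object with `$series`).
#' @param schedule An [schedule()].
#' @param use_fitted Average the fitted approximation (default) or the raw
#'   samples.
#' @return A data.frame with columns `hour` and `value`, one row per
#'   included hour.
#' @export
hourly_means <- function(segmented, schedule, use_fitted = TRUE) {
  if (!inherits(segmented, "segmented_series")) stop("expected a segmented_series")
  if (!inherits(schedule, "ieq_schedule")) stop("expected an ieq_schedule")
  t <- segmented$series$time
  v <- if (use_fitted) segmented$fitted else segmented$series$value
  vals <- vapply(schedule$hours, function(h) {
    in_h <- t >= h * 3600 & t < (h + 1) * 3600
    if (!any(in_h))
      stop(sprintf("no samples in hour %02d:00-%02d:00", h, h + 1))
    mean(v[in_h])
  }, numeric(1))
  data.frame(hour = schedule$hours, value = vals)
}
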