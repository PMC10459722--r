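test_that("sensor CSVs parse, validate and flag bad input", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,value", "0,20.1", "1,20.2", "2,20.0"), tmp)
  s <- read_sensor_csv(tmp, "temperature")
  expect_s3_class(s, "sensor_series")
  expect_length(s$time, 3L)
  expect_equal(s$value, c(20.1, 20.2, 20.0))

  writeLines(c("timestamp,value", "0,20.1", "2,20.2", "1,20.0"), tmp)
  expect_error(read_sensor_csv(tmp, "temperature"), "line 4")

  writeLines(c("timestamp,value", "0,20.1", "1,not_a_number"), tmp)
  expect_error(read_sensor_csv(tmp, "temperature"), "line 3")

  # ISO-8601 timestamps become seconds since midnight
  writeLines(c("timestamp,value",
               "2023-03-14T09:00:00,45.0",
               "2023-03-14T09:00:01,45.1"), tmp)
  s <- read_sensor_csv(tmp, "humidity")
  expect_equal(s$time, c(9 * 3600, 9 * 3600 + 1))

  # out-of-range values are flagged, not dropped
  expect_warning(sensor_series(1:3, c(50, 101, 60), "humidity"),
                 "outside measurement range")
})

test_that("a generated 1 Hz stream round-trips through CSV at full length", {
  cfg <- day_config(schedule = schedule(9, 17), seed = 11)
  hum <- gen_sensor_day(cfg)$humidity
  expect_length(hum$time, 8 * 3600)   # 28,800 rows over the 8 h span
  tmp <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(timestamp = hum$time, value = hum$value),
                   tmp, row.names = FALSE)
  back <- read_sensor_csv(tmp, "humidity")
  expect_length(back$time, 28800L)
  expect_equal(diff(range(back$time)), 8 * 3600 - 1)
  expect_equal(back$value, hum$value)
})

test_that("segmentation recovers exact piecewise-linear structure", {
  # exactly linear: one segment, zero residual, fitted equals input
  t <- 0:99
  s <- sensor_series(t, 2 + 0.5 * t, "temperature", range = c(-Inf, Inf))
  seg <- segment_series(s, max_rmse = 0.1)
  expect_identical(nrow(seg$segments), 1L)
  expect_equal(fitted(seg), s$value, tolerance = 1e-10)

  # two linear pieces with a slope change at t = 50
  y2 <- ifelse(t <= 50, t, 50 + 3 * (t - 50))
  s2 <- sensor_series(t, y2, "temperature", range = c(-Inf, Inf))
  one_seg_rmse <- {
    f <- lm.fit(cbind(1, t), y2)
    sqrt(mean(f$residuals^2))
  }
  seg2 <- segment_series(s2, max_rmse = 0.9 * one_seg_rmse)
  expect_identical(nrow(seg2$segments), 2L)
  expect_lte(abs(seg2$segments$end_time[1L] - 50), 1)
  expect_lt(sum(seg2$segments$sse), 1e-9)
})

test_that("greedy 6-segment fit beats the exhaustive optimal 5-segment fit", {
  set.seed(42)
  t <- seq(0, 2 * pi, length.out = 60)
  y <- sin(t) + rnorm(60, sd = 0.05)
  s <- sensor_series(t, y, "signal", range = c(-Inf, Inf))
  seg <- segment_series(s, n_segments = 6)
  expect_identical(nrow(seg$segments), 6L)
  expect_lte(sum(seg$segments$sse), oracle_best_sse(t, y, 5) + 1e-9)
})

test_that("segmentation is idempotent and monotone in the threshold", {
  set.seed(7)
  t <- 0:299
  y <- ifelse(t < 100, 20 + 0.01 * t, ifelse(t < 200, 21 - 0.02 * (t - 100),
                                             19 + 0.03 * (t - 200))) +
    rnorm(300, sd = 0.01)
  s <- sensor_series(t, y, "temperature", range = c(-Inf, Inf))
  seg <- segment_series(s, max_rmse = 0.05)
  reseg <- segment_series(
    sensor_series(t, fitted(seg), "temperature", range = c(-Inf, Inf)),
    max_rmse = 0.05)
  expect_equal(reseg$breakpoints, seg$breakpoints)

  n_at <- vapply(c(0.005, 0.02, 0.05, 0.2, 1),
                 function(r) nrow(segment_series(s, max_rmse = r)$segments),
                 numeric(1))
  expect_true(all(diff(n_at) <= 0))
})

test_that("stopping rules are mutually exclusive with a sane default", {
  s <- sensor_series(0:19, rnorm(20), "x", range = c(-Inf, Inf))
  expect_error(segment_series(s, max_rmse = 1, n_segments = 3), "not both")
  expect_s3_class(segment_series(s), "segmented_series")  # 2%-range default
})

test_that("hourly means follow the schedule and stay within sample range", {
  t <- seq(9 * 3600, 18 * 3600 - 1, by = 30)
  s <- sensor_series(t, rep(5, length(t)), "pm25")
  seg <- segment_series(s, max_rmse = 0.01)
  hm <- hourly_means(seg, schedule(9, 18, exclude = 13))
  expect_equal(hm$hour, c(9:12, 14:17))   # 8 labels, lunch excluded
  expect_equal(hm$value, rep(5, 8))

  # linear ramp 0 -> 1 over a single hour averages to ~0.5
  t1 <- seq(9 * 3600, 10 * 3600 - 1, by = 1)
  ramp <- (t1 - t1[1L]) / (3600 - 1)
  s1 <- sensor_series(t1, ramp, "x", range = c(-Inf, Inf))
  hm1 <- hourly_means(segment_series(s1, max_rmse = 0.01), schedule(9, 10))
  expect_equal(hm1$value, 0.5, tolerance = 1e-6)

  # noisy series: each hourly mean within that hour's raw sample range
  set.seed(3)
  y <- 20 + cumsum(rnorm(length(t), sd = 0.02))
  sn <- sensor_series(t, y, "temperature", range = c(-Inf, Inf))
  hmn <- hourly_means(segment_series(sn), schedule(9, 18, 13))
  for (i in seq_len(nrow(hmn))) {
    h <- hmn$hour[i]
    raw <- y[t >= h * 3600 & t < (h + 1) * 3600]
    expect_gte(hmn$value[i], min(raw))
    expect_lte(hmn$value[i], max(raw))
  }
})

test_that("panels assemble from aligned columns and reject misaligned ones", {
  hrs <- c(9:12, 14:17)
  col <- function(v) data.frame(hour = hrs, value = v)
  d <- utils::read.csv(system.file("extdata", "hourly_derived_panel.csv",
                                   package = "ieqelicit"))
  p <- build_panel(list(illuminance = col(d$illuminance), pm25 = col(d$pm25),
                        sound = col(d$sound), pmv = col(d$pmv_operator1)))
  expect_identical(dim(p), c(8L, 4L))
  expect_identical(panel_orientation(p), "raw")

  p1 <- build_panel(list(pm25 = col(d$pm25)))
  expect_identical(ncol(p1), 1L)

  bad <- data.frame(hour = c(9:12, 13:16), value = 1:8)
  expect_error(build_panel(list(a = col(d$pm25), b = bad)), "differ")
})
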