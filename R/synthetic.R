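# Synthetic office-day generator: diurnal sensor streams, simulated
# occupants with latent simplex weights, noisy ordinal ratings, and a
# parameter-recovery experiment harness. All outputs are deterministic
# given the configured seed and pass the ingestion validators.

.default_streams <- list(
  # baseline + amplitude*sin(pi*frac) + drift*frac + AR(1) noise; shapes
  # emulate a monitored office day: temperature peaking mid-afternoon,
  # illuminance and pm2.5 drifting down, sound roughly stationary.
  temperature = list(baseline = 22,  amplitude = 2,   drift = 0,    noise_sd = 0.05, ar = 0.995),
  humidity    = list(baseline = 45,  amplitude = -4,  drift = 0,    noise_sd = 0.10, ar = 0.995),
  illuminance = list(baseline = 592, amplitude = 0,   drift = -113, noise_sd = 1.50, ar = 0.99),
  pm25        = list(baseline = 9.4, amplitude = 0,   drift = -4.8, noise_sd = 0.10, ar = 0.99),
  sound       = list(baseline = 46,  amplitude = 1.5, drift = -4,   noise_sd = 0.40, ar = 0.98)
)

#' Synthetic office-day configuration
#'
#' @param schedule Working-day [schedule()] (default 9:00-18:00, 13:00
#'   lunch, the monitored 8-hour day).
#' @param rate_hz Sampling rate in Hz (default 1, the collection frequency
#'   of the monitored streams).
#' @param streams Named list of per-variable generators; each a list with
#'   `baseline`, `amplitude` (half-sine diurnal swing), `drift` (linear
#'   across the day), `noise_sd` (stationary AR(1) sd) and `ar`
#'   (autocorrelation).
#' @param seed Integer seed; generation is deterministic given it.
#' @return A `day_config` list.
#' @export
day_config <- function(schedule = ieqelicit::schedule(9, 18, 13),
                       rate_hz = 1, streams = .default_streams, seed = 1L) {
  if (rate_hz <= 0) stop("rate_hz must be positive")
  structure(list(schedule = schedule, rate_hz = rate_hz,
                 streams = streams, seed = as.integer(seed)),
            class = "day_config")
}

#' Generate one day of synthetic sensor streams
#'
#' One [sensor_series()] per configured variable, sampled at `rate_hz` over
#' the schedule span (lunch included: sensors keep running; the hour is
#' excluded only at aggregation). Values are clipped to the sensor
#' measurement ranges so every stream passes validation.
#'
#' @param config A [day_config()].
#' @return Named list of [sensor_series()].
#' @export
gen_sensor_day <- function(config) {
  stopifnot(inherits(config, "day_config"))
  sch <- config$schedule
  t0 <- sch$start * 3600; t1 <- sch$end * 3600
  tt <- seq(t0, t1 - 1 / config$rate_hz, by = 1 / config$rate_hz)
  frac <- (tt - t0) / (t1 - t0)
  with_local_seed(config$seed, {
    out <- lapply(names(config$streams), function(v) {
      g <- config$streams[[v]]
      trend <- g$baseline + g$amplitude * sin(pi * frac) + g$drift * frac
      innov <- stats::rnorm(length(tt), sd = g$noise_sd * sqrt(1 - g$ar^2))
      noise <- as.numeric(stats::filter(innov, g$ar, method = "recursive"))
      def <- .sensor_defaults[[v]]
      rng <- if (is.null(def)) c(-Inf, Inf) else def$range
      sensor_series(tt, pmin(pmax(trend + noise, rng[1L]), rng[2L]), v)
    })
    stats::setNames(out, names(config$streams))
  })
}

#' Synthetic occupant
#'
#' A simulated operator whose comfort ratings derive from latent simplex
#' weights through one of the scoring engines.
#'
#' @param operator_id Identifier.
#' @param weights Latent [weight_vector()] over the panel criteria.
#' @param clo,met Profile parameters (see [operator_profile()]).
#' @param noise_prob Probability that an hourly rating is shifted by one
#'   level (clipped to 1..5).
#' @param engine Generating engine, `"topsis"` or `"promethee"`.
#' @return A `synthetic_occupant` list.
#' @export
synthetic_occupant <- function(operator_id, weights, clo = 1.2, met = 1.2,
                               noise_prob = 0,
                               engine = c("promethee", "topsis")) {
  engine <- match.arg(engine)
  if (noise_prob < 0 || noise_prob > 1) stop("noise_prob must be in [0, 1]")
  structure(list(operator_id = as.character(operator_id),
                 weights = weight_vector(weights),
                 profile = operator_profile(operator_id, clo, met),
                 noise_prob = noise_prob, engine = engine),
            class = "synthetic_occupant")
}

#' Generate ordinal ratings from a latent-weight occupant
#'
#' Scores the cost panel with the occupant's engine and latent weights, maps
#' the scores to ratings 1-5 by equal-frequency binning (higher score ->
#' higher rating; with T >= 5 all five levels appear), then perturbs each
#' hour's rating by one level with probability `noise_prob`.
#'
#' @param panel Cost-oriented [ieq_panel()].
#' @param occupant A [synthetic_occupant()].
#' @param seed Integer seed for the rating noise.
#' @return Named integer vector of ratings (names = hour labels).
#' @export
gen_ratings <- function(panel, occupant, seed = 1L) {
  stopifnot(inherits(occupant, "synthetic_occupant"))
  engine <- .score_engine(occupant$engine)
  w <- occupant$weights
  if (!is.null(names(w))) w <- w[colnames(panel)]
  sc <- engine(panel, w)
  T_ <- length(sc)
  if (T_ < 5L)
    warning("fewer than 5 time steps: not all rating levels can appear")
  ranks <- rank(as.numeric(sc), ties.method = "first")
  ratings <- as.integer(ceiling(5 * ranks / T_))
  if (occupant$noise_prob > 0) {
    ratings <- with_local_seed(seed, {
      flip <- stats::runif(T_) < occupant$noise_prob
      shift <- sample(c(-1L, 1L), T_, replace = TRUE)
      pmin(pmax(ratings + ifelse(flip, shift, 0L), 1L), 5L)
    })
  }
  stats::setNames(ratings, names(sc))
}

# quick standalone cost panel (positive criteria on different scales);
# used by the recovery experiment where full stream synthesis is overkill
gen_cost_panel <- function(T_ = 8L, K = 4L, seed = 1L) {
  with_local_seed(seed, {
    scales <- stats::runif(K, 0.5, 50)
    m <- vapply(scales, function(s) s * stats::rlnorm(T_, sdlog = 0.4),
                numeric(T_))
    colnames(m) <- paste0("c", seq_len(K))
    rownames(m) <- as.character(seq_len(T_) + 8L)
    ieq_panel(m, "cost")
  })
}

#' Weight-recovery experiment
#'
#' Monte-Carlo harness for the identifiability of indirect eliciting: for
#' each replicate, noise level and scoring engine, a random cost panel and a
#' latent flat-Dirichlet weight vector are drawn, ratings are generated from
#' that engine's scores at the latent weights (parameter recovery within the
#' model class), and weights are elicited back with the same engine. Error
#' rates on the occupant's nonredundant relations are recorded for the
#' optimised weights, for equal weights, and for a deliberately mismatched
#' vector: all weight on the occupant's least-important category, emulating
#' a confidently wrong direct statement of preferences (the situation in
#' which stated AHP judgments contradict observed behaviour).
#'
#' @param n_occupants Replicates per noise level.
#' @param T_,K Panel size (time steps, criteria).
#' @param noise_probs Vector of rating-noise probabilities.
#' @param seed Master seed; per-replicate seeds are derived from it.
#' @param restarts Elicitation restarts (see [elicit_weights()]).
#' @param engines Scoring engines to run.
#' @return Tidy data.frame: `replicate`, `noise_prob`, `engine`,
#'   `weight_set` (`optimized`/`equal`/`mismatched`), `error_rate`,
#'   `n_relations`, `seed`.
#' @export
recovery_experiment <- function(n_occupants = 10L, T_ = 8L, K = 4L,
                                noise_probs = c(0, 0.1), seed = 1L,
                                restarts = 20L,
                                engines = c("topsis", "promethee")) {
  rows <- list()
  for (eps in noise_probs) {
    for (r in seq_len(n_occupants)) {
      rep_seed <- (as.integer(seed) + 7919L * r +
                     1000L * as.integer(round(100 * eps))) %% 2147480000L
      panel <- gen_cost_panel(T_, K, seed = rep_seed)
      w_true <- with_local_seed(rep_seed + 1L, rdirichlet1(K))
      w_equal <- rep(1 / K, K)
      w_mismatch <- as.numeric(seq_len(K) == which.min(w_true))
      for (engine in engines) {
        scorer <- .score_engine(engine)
        occ <- synthetic_occupant(paste0("sim", r), w_true,
                                  noise_prob = eps, engine = engine)
        ratings <- suppressWarnings(gen_ratings(panel, occ, seed = rep_seed + 2L))
        rel <- transitive_reduction(relations_from_ratings(ratings))
        fit <- suppressWarnings(
          elicit_weights(panel, rel, engine, restarts = restarts,
                         seed = rep_seed + 3L))
        ers <- c(
          optimized = suppressWarnings(error_rate(scorer(panel, fit$weights), rel)),
          equal = suppressWarnings(error_rate(scorer(panel, w_equal), rel)),
          mismatched = suppressWarnings(error_rate(scorer(panel, w_mismatch), rel)))
        rows[[length(rows) + 1L]] <- data.frame(
          replicate = r, noise_prob = eps, engine = engine,
          weight_set = names(ers), error_rate = unname(ers),
          n_relations = nrow(rel), seed = rep_seed, row.names = NULL)
      }
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}
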