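#' Generate a seeded event log for one session
#'
#' Draws target and message appearances as independent Poisson processes
#' per phase, with exponential on-screen lifetimes (mean
#' `mean_processing_time`). Each event is assigned a screen zone from a
#' mixture of a point mass on one zone and the uniform distribution over
#' all zones, weighted by the phase's `spatial_concentration`, so later
#' phases can spread targets more widely and raise spatial entropy.
#'
#' @param config An [scenario_config()] object.
#' @param seed Integer seed; the log is a pure function of
#'   `(config, seed)`. `NULL` uses the current RNG stream.
#' @return A data frame with columns `t_appear_s`, `t_removed_s`, `kind`,
#'   `zone_row`, `zone_col`, sorted by appearance time, with attributes
#'   `span` and `grid`.
#' @export
generate_event_log <- function(config, seed = NULL) {
  stopifnot(inherits(config, "ofs_scenario"))
  if (!is.null(seed)) set.seed(seed)
  edges <- c(0, cumsum(config$phase_durations))
  n_zones <- prod(config$screen_grid)
  rows <- list()
  for (ph in 1:4) {
    dur <- config$phase_durations[ph]
    for (kind in c("target", "message")) {
      rate <- if (kind == "target") config$target_rate[ph] else
        config$message_rate[ph]
      n <- stats::rpois(1, rate * dur / 60)
      if (n == 0) next
      t0 <- sort(stats::runif(n, edges[ph], edges[ph + 1]))
      life <- stats::rexp(n, rate = 1 / config$mean_processing_time)
      conc <- config$spatial_concentration[ph]
      zone <- ifelse(stats::runif(n) < conc, 1L,
                     sample.int(n_zones, n, replace = TRUE))
      rows[[length(rows) + 1L]] <- data.frame(
        t_appear_s = t0, t_removed_s = t0 + life, kind = kind,
        zone_row = (zone - 1L) %/% config$screen_grid[2] + 1L,
        zone_col = (zone - 1L) %% config$screen_grid[2] + 1L)
    }
  }
  log <- if (length(rows)) do.call(rbind, rows) else
    data.frame(t_appear_s = numeric(0), t_removed_s = numeric(0),
               kind = character(0), zone_row = integer(0),
               zone_col = integer(0))
  log <- log[order(log$t_appear_s), , drop = FALSE]
  rownames(log) <- NULL
  attr(log, "span") <- scenario_span(config)
  attr(log, "grid") <- config$screen_grid
  log
}

# TD level at arbitrary times, from a 1 Hz series (value at tick t applies
# to (t-1, t]); times before the first tick take the first value.
td_at <- function(td_series, t) {
  idx <- pmin(pmax(ceiling(t), 1L), nrow(td_series))
  td_series$td[idx]
}

#' Generate RR-interval and pupil-diameter streams for one session
#'
#' Inverts the analysis model: RR intervals are drawn with a per-beat
#' Gaussian jitter whose SD equals `rr_baseline_sd` minus
#' `sdnn_load_slope` per TD step above 1 (floored at 1 ms), so windowed
#' SDNN decreases with load; pupil samples at `pupil_rate_hz` have mean
#' `pupil_baseline + pupil_load_gain * (TD - 1)` plus a slow AR(1) drift
#' and white measurement noise, and each sample is replaced with
#' probability `artifact_prob` by an out-of-range artifact drawn
#' uniformly from \[0.5, 2) or (8, 10\] mm.
#'
#' @param td_series An `ofs_td_series` covering the session span (or any
#'   data frame with a `td` column at 1 Hz).
#' @param params A [participant_params()] object.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return A list with data frames `rr` (`t_s`, `rr_ms`) and `pupil`
#'   (`t_s`, `pd_mm`).
#' @export
generate_physio <- function(td_series, params, seed = NULL) {
  stopifnot(inherits(params, "ofs_participant"), is.data.frame(td_series),
            nrow(td_series) > 0)
  if (!is.null(seed)) set.seed(seed)
  span <- nrow(td_series)

  # RR stream: sequential because the jitter SD depends on the beat time
  n_max <- ceiling(span * 1000 / params$rr_baseline_mean * 1.5) + 100L
  bt <- numeric(n_max); rr <- numeric(n_max)
  t <- 0; i <- 0L
  while (t < span) {
    i <- i + 1L
    sd_t <- max(params$rr_baseline_sd -
                  params$sdnn_load_slope * (td_at(td_series, t) - 1), 1)
    r <- max(params$rr_baseline_mean + stats::rnorm(1, 0, sd_t), 250)
    t <- t + r / 1000
    bt[i] <- t; rr[i] <- r
  }
  rr_df <- data.frame(t_s = bt[seq_len(i)], rr_ms = rr[seq_len(i)])

  # pupil stream
  tp <- seq(1 / params$pupil_rate_hz, span, by = 1 / params$pupil_rate_hz)
  td_p <- td_at(td_series, tp)
  n <- length(tp)
  drift <- if (params$pupil_drift_sd > 0) {
    phi <- exp(-1 / (params$pupil_rate_hz * 20))  # ~20 s time constant
    e <- stats::rnorm(n, 0, params$pupil_drift_sd * sqrt(1 - phi^2))
    as.numeric(stats::filter(e, phi, method = "recursive"))
  } else numeric(n)
  pd <- params$pupil_baseline + params$pupil_load_gain * (td_p - 1) +
    drift + stats::rnorm(n, 0, params$pupil_noise_sd)
  art <- stats::runif(n) < params$artifact_prob
  n_art <- sum(art)
  if (n_art > 0) {
    low <- stats::runif(n_art) < 1.5 / 3.5  # widths of [0.5,2) and (8,10]
    pd[art] <- ifelse(low, stats::runif(n_art, 0.5, 2 - 1e-9),
                      stats::runif(n_art, 8 + 1e-9, 10))
  }
  list(rr = rr_df, pupil = data.frame(t_s = tp, pd_mm = pd))
}

#' Generate subjective workload probes for one session
#'
#' One Instantaneous Self-Assessment (ISA, 1--5) and one Likert
#' difficulty response every `interval` seconds. Each response equals the
#' true difficulty level at the probe instant with probability
#' `probe_fidelity`, otherwise it is perturbed by one step (clipped to
#' the scale). The ISA value is then mapped into five levels by a fixed
#' monotone smear: TD1 to ISA 1 or 2, TD2 to ISA 2 or 3, TD3 to ISA 4
#' or 5 (equal probability).
#'
#' @param td_series An `ofs_td_series` (or data frame with `td` at 1 Hz).
#' @param params A [participant_params()] object.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param interval Probe spacing in seconds (default 90).
#' @return A data frame with columns `t_s`, `true_td`, `isa`, `likert`.
#' @export
generate_probes <- function(td_series, params, seed = NULL, interval = 90) {
  stopifnot(inherits(params, "ofs_participant"), is.data.frame(td_series))
  if (nrow(td_series) == 0) stop("td_series is empty", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ticks <- seq(interval, nrow(td_series), by = interval)
  if (!length(ticks)) stop("session shorter than one probe interval", call. = FALSE)
  true_td <- td_at(td_series, ticks)

  noisy <- function(x, lo, hi) {
    miss <- stats::runif(length(x)) >= params$probe_fidelity
    step <- ifelse(stats::runif(length(x)) < 0.5, -1L, 1L)
    pmin(pmax(x + miss * step, lo), hi)
  }
  # Likert reported on its own ordinal scale via a monotone stretch of TD
  L <- params$likert_levels
  lik_true <- round(1 + (true_td - 1) * (L - 1) / 2)
  likert <- noisy(lik_true, 1L, L)
  td_noisy <- noisy(true_td, 1L, 3L)
  smear <- stats::runif(length(ticks)) < 0.5
  isa <- ifelse(td_noisy == 1L, ifelse(smear, 1L, 2L),
                ifelse(td_noisy == 2L, ifelse(smear, 2L, 3L),
                       ifelse(smear, 4L, 5L)))
  data.frame(t_s = ticks, true_td = true_td, isa = as.integer(isa),
             likert = as.integer(likert))
}

#' Generate a resting baseline recording
#'
#' Five minutes (by default) in front of a blank screen: difficulty fixed
#' at the lowest level, no events. Used to estimate the per-participant
#' normalization moments.
#'
#' @param params A [participant_params()] object.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param duration Recording length in seconds (default 300).
#' @return A list with data frames `rr` and `pupil` as in
#'   [generate_physio()].
#' @export
generate_baseline <- function(params, seed = NULL, duration = 300) {
  rest <- data.frame(t_s = seq_len(duration), td = 1L)
  generate_physio(rest, params, seed)
}

# draw per-participant parameters around population values
draw_participant <- function(population, heterogeneity) {
  cv <- 0.15 * heterogeneity
  jig <- function(x, lo = -Inf, hi = Inf)
    min(max(x * (1 + stats::rnorm(1, 0, cv)), lo), hi)
  participant_params(
    rr_baseline_mean = jig(population$rr_baseline_mean, lo = 400),
    rr_baseline_sd = jig(population$rr_baseline_sd, lo = 5),
    sdnn_load_slope = jig(population$sdnn_load_slope, lo = 0),
    pupil_baseline = jig(population$pupil_baseline, lo = 2.5, hi = 7.5),
    pupil_load_gain = jig(population$pupil_load_gain, lo = 0),
    pupil_noise_sd = jig(population$pupil_noise_sd, lo = 0.01),
    pupil_drift_sd = jig(population$pupil_drift_sd, lo = 0),
    artifact_prob = min(max(population$artifact_prob, 0), 1),
    probe_fidelity = population$probe_fidelity,
    pupil_rate_hz = population$pupil_rate_hz,
    likert_levels = population$likert_levels)
}

#' Generate a cohort of simulated operator sessions
#'
#' Each participant receives an independent event log drawn from the same
#' scenario, the derived task-difficulty series, RR and pupil streams,
#' subjective probes, and a 5-min resting baseline. Participant
#' parameters are drawn around `population` with a coefficient of
#' variation proportional to `heterogeneity` (0 = identical
#' participants).
#'
#' @param config An [scenario_config()] object.
#' @param n_participants Number of participants (>= 2).
#' @param heterogeneity Non-negative scale factor for between-participant
#'   parameter spread; 1 corresponds to a 15% coefficient of variation.
#' @param seed Integer seed for the whole cohort.
#' @param population A [participant_params()] object of population means.
#' @param rules Difficulty fusion rule table.
#' @return An object of class `ofs_cohort`: a list of session bundles,
#'   each with elements `id`, `params`, `events`, `td`, `rr`, `pupil`,
#'   `probes`, `baseline` (list of `rr`, `pupil`).
#' @export
generate_cohort <- function(config = scenario_config(), n_participants = 17,
                            heterogeneity = 1, seed = 1,
                            population = participant_params(),
                            rules = default_difficulty_rules()) {
  stopifnot(inherits(config, "ofs_scenario"))
  if (n_participants < 2)
    stop("a cohort needs at least 2 participants", call. = FALSE)
  if (heterogeneity < 0) stop("heterogeneity must be >= 0", call. = FALSE)
  set.seed(seed)
  cohort <- vector("list", n_participants)
  for (p in seq_len(n_participants)) {
    params <- draw_participant(population, heterogeneity)
    events <- generate_event_log(config)
    td <- compute_td_series(events, rules = rules)
    physio <- generate_physio(td, params)
    probes <- generate_probes(td, params)
    baseline <- generate_baseline(params)
    cohort[[p]] <- list(id = sprintf("P%02d", p), params = params,
                        events = events, td = td, rr = physio$rr,
                        pupil = physio$pupil, probes = probes,
                        baseline = baseline)
  }
  structure(cohort, class = "ofs_cohort", config = config,
            heterogeneity = heterogeneity, seed = seed)
}

#' @export
print.ofs_cohort <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("Simulated cohort: %d participants, %d s scenario, heterogeneity %g, seed %d\n",
              length(x), scenario_span(cfg), attr(x, "heterogeneity"),
              attr(x, "seed")))
  invisible(x)
}
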