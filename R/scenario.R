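#' Scenario configuration for a simulated supervisory-control session
#'
#' Describes a four-phase monitoring scenario: a waiting phase with no
#' stimuli followed by three attack phases of increasing difficulty.
#' Difficulty is manipulated through the arrival rates of targets and
#' messages and through how concentrated targets are across screen zones.
#'
#' @param phase_durations Numeric vector of 4 phase durations in seconds.
#'   Default `c(120, 420, 420, 540)`: a 2-min wait then 7, 7 and 9 min
#'   attack phases (25 min total).
#' @param target_rate Target appearance rate per phase, appearances/min.
#'   Must be 0 in phase 1 and non-decreasing over phases 2--4.
#' @param message_rate Message appearance rate per phase, appearances/min.
#'   Same constraints as `target_rate`.
#' @param mean_processing_time Mean time (s) a target or message stays on
#'   screen before it is processed and removed.
#' @param screen_grid Integer vector `c(rows, cols)` of equal screen zones
#'   used for the spatial-entropy computation. Default 2 x 4 = 8 zones.
#' @param spatial_concentration Per-phase value in \[0, 1\] controlling how
#'   concentrated targets are in space: 1 places every target in a single
#'   zone (zero entropy), 0 spreads them uniformly over all zones.
#'
#' @return An object of class `ofs_scenario`.
#' @export
#' @examples
#' cfg <- scenario_config()
#' scenario_span(cfg)
scenario_config <- function(phase_durations = c(120, 420, 420, 540),
                            target_rate = c(0, 2, 6, 14),
                            message_rate = c(0, 0.5, 1.5, 4),
                            mean_processing_time = 60,
                            screen_grid = c(2L, 4L),
                            spatial_concentration = c(1, 0.85, 0.5, 0.1)) {
  stopifnot(length(phase_durations) == 4L, length(target_rate) == 4L,
            length(message_rate) == 4L, length(spatial_concentration) == 4L,
            length(screen_grid) == 2L)
  if (any(phase_durations <= 0))
    stop("phase durations must be positive", call. = FALSE)
  if (target_rate[1] != 0 || message_rate[1] != 0)
    stop("phase 1 is a waiting period: rates must be 0", call. = FALSE)
  if (any(target_rate < 0) || any(message_rate < 0))
    stop("arrival rates must be non-negative", call. = FALSE)
  if (is.unsorted(target_rate[2:4]) || is.unsorted(message_rate[2:4]))
    stop("rates must be non-decreasing across phases 2-4", call. = FALSE)
  if (mean_processing_time <= 0)
    stop("mean_processing_time must be positive", call. = FALSE)
  if (any(spatial_concentration < 0 | spatial_concentration > 1))
    stop("spatial_concentration must lie in [0, 1]", call. = FALSE)
  screen_grid <- as.integer(screen_grid)
  if (any(screen_grid < 1))
    stop("screen_grid dimensions must be positive integers", call. = FALSE)
  structure(list(phase_durations = as.numeric(phase_durations),
                 target_rate = as.numeric(target_rate),
                 message_rate = as.numeric(message_rate),
                 mean_processing_time = as.numeric(mean_processing_time),
                 screen_grid = screen_grid,
                 spatial_concentration = as.numeric(spatial_concentration)),
            class = "ofs_scenario")
}

#' Total scenario length in seconds
#' @param config An `ofs_scenario` object.
#' @return Scenario span (s).
#' @export
scenario_span <- function(config) {
  stopifnot(inherits(config, "ofs_scenario"))
  sum(config$phase_durations)
}

# phase index (1..4) for a vector of times in [0, span)
phase_at <- function(config, t) {
  edges <- c(0, cumsum(config$phase_durations))
  findInterval(t, edges, rightmost.closed = TRUE)
}

#' @export
print.ofs_scenario <- function(x, ...) {
  cat("Supervisory-control scenario (", scenario_span(x), " s, 4 phases)\n",
      sep = "")
  cat(sprintf("  phase durations (s): %s\n",
              paste(x$phase_durations, collapse = ", ")))
  cat(sprintf("  target rate (/min):  %s\n",
              paste(x$target_rate, collapse = ", ")))
  cat(sprintf("  message rate (/min): %s\n",
              paste(x$message_rate, collapse = ", ")))
  cat(sprintf("  mean processing time: %g s; grid %d x %d zones\n",
              x$mean_processing_time, x$screen_grid[1], x$screen_grid[2]))
  invisible(x)
}

#' Physiological and behavioural parameters of a simulated participant
#'
#' Parameters that govern how a participant's cardiac, pupillary and
#' self-report streams respond to task difficulty (TD, three ordinal
#' levels). RR intervals are drawn with a per-beat jitter whose standard
#' deviation shrinks with load, so windowed SDNN decreases as difficulty
#' rises; pupil diameter dilates with load on top of a slow baseline
#' drift; probe responses agree with the true difficulty with probability
#' `probe_fidelity`.
#'
#' @param rr_baseline_mean Mean RR interval at rest, ms.
#' @param rr_baseline_sd Per-beat RR jitter SD at rest, ms. The long-run
#'   SDNN at the lowest difficulty approaches this value.
#' @param sdnn_load_slope Drop in RR jitter SD (ms) per TD step above 1.
#' @param pupil_baseline Resting pupil diameter, mm; must lie strictly
#'   inside the 2--8 mm physiological band.
#' @param pupil_load_gain Pupil dilation (mm) per TD step above 1.
#' @param pupil_noise_sd Per-sample pupil measurement noise SD, mm.
#' @param pupil_drift_sd Stationary SD (mm) of a slow autoregressive
#'   drift added to pupil diameter, emulating spontaneous fluctuation.
#' @param artifact_prob Probability that a pupil sample is replaced by an
#'   out-of-range artifact (uniform over \[0.5, 2) and (8, 10\] mm).
#' @param probe_fidelity Probability an ISA or Likert response equals the
#'   true difficulty level; otherwise it is perturbed by one step.
#' @param pupil_rate_hz Pupil sampling rate, Hz.
#' @param likert_levels Number of levels of the Likert difficulty scale.
#'
#' @return An object of class `ofs_participant`.
#' @export
participant_params <- function(rr_baseline_mean = 800,
                               rr_baseline_sd = 50,
                               sdnn_load_slope = 15,
                               pupil_baseline = 4,
                               pupil_load_gain = 0.2,
                               pupil_noise_sd = 0.2,
                               pupil_drift_sd = 0.25,
                               artifact_prob = 0.02,
                               probe_fidelity = 0.8,
                               pupil_rate_hz = 60,
                               likert_levels = 3L) {
  if (rr_baseline_mean <= 0 || rr_baseline_sd <= 0 || pupil_noise_sd <= 0)
    stop("means and noise SDs must be positive", call. = FALSE)
  if (pupil_drift_sd < 0)
    stop("pupil_drift_sd must be non-negative", call. = FALSE)
  if (sdnn_load_slope < 0 || pupil_load_gain < 0)
    stop("load slopes/gains must be non-negative", call. = FALSE)
  if (pupil_baseline <= 2 || pupil_baseline >= 8)
    stop("pupil_baseline must lie strictly inside (2, 8) mm", call. = FALSE)
  if (artifact_prob < 0 || artifact_prob > 1 ||
      probe_fidelity < 0 || probe_fidelity > 1)
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (pupil_rate_hz <= 0) stop("pupil_rate_hz must be positive", call. = FALSE)
  likert_levels <- as.integer(likert_levels)
  if (likert_levels < 2) stop("likert_levels must be >= 2", call. = FALSE)
  structure(list(rr_baseline_mean = rr_baseline_mean,
                 rr_baseline_sd = rr_baseline_sd,
                 sdnn_load_slope = sdnn_load_slope,
                 pupil_baseline = pupil_baseline,
                 pupil_load_gain = pupil_load_gain,
                 pupil_noise_sd = pupil_noise_sd,
                 pupil_drift_sd = pupil_drift_sd,
                 artifact_prob = artifact_prob,
                 probe_fidelity = probe_fidelity,
                 pupil_rate_hz = pupil_rate_hz,
                 likert_levels = likert_levels),
            class = "ofs_participant")
}

#' @export
print.ofs_participant <- function(x, ...) {
  cat("Simulated participant parameters\n")
  cat(sprintf("  RR: mean %g ms, jitter SD %g ms, load slope -%g ms/TD step\n",
              x$rr_baseline_mean, x$rr_baseline_sd, x$sdnn_load_slope))
  cat(sprintf("  Pupil: baseline %g mm, gain %g mm/TD step, noise %g mm, drift %g mm, artifacts %.1f%%\n",
              x$pupil_baseline, x$pupil_load_gain, x$pupil_noise_sd,
              x$pupil_drift_sd, 100 * x$artifact_prob))
  cat(sprintf("  Probes: fidelity %g; pupil sampling %g Hz\n",
              x$probe_fidelity, x$pupil_rate_hz))
  invisible(x)
}
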