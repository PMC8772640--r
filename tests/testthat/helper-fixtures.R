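# Small fixtures shared across tests; everything is generated in code.

# hand-built event log: attributes follow generate_event_log()
toy_log <- function(span = 60, grid = c(2L, 4L)) {
  log <- data.frame(
    t_appear_s = c(5, 10, 12, 20, 30),
    t_removed_s = c(15, 20, 40, 50, 45),
    kind = c("target", "target", "target", "target", "message"),
    zone_row = c(1L, 1L, 1L, 2L, 1L),
    zone_col = c(1L, 2L, 3L, 4L, 1L))
  attr(log, "span") <- span
  attr(log, "grid") <- grid
  log
}

# short scenario so cohort-level tests stay fast; rates scaled so the
# shorter 30 s processing time still drives N1/N2 across their thresholds
short_scenario <- function() {
  scenario_config(phase_durations = c(30, 90, 90, 150),
                  target_rate = c(0, 4, 12, 28),
                  message_rate = c(0, 1, 3, 8),
                  mean_processing_time = 30,
                  spatial_concentration = c(1, 0.85, 0.5, 0.1))
}

# Gaussian blobs in feature space with 3-class labels
make_blobs <- function(n_per_class = 60, sep = 5, sd = 1, seed = 1,
                       levels = c("low", "medium", "high")) {
  set.seed(seed)
  k <- length(levels)
  df <- do.call(rbind, lapply(seq_len(k), function(i) {
    data.frame(hrv_z = stats::rnorm(n_per_class, sep * i, sd),
               pd_z = stats::rnorm(n_per_class, -sep * i, sd),
               label = levels[i])
  }))
  df$label <- factor(df$label, levels = levels)
  df$td <- as.integer(df$label)
  df
}

# a constant-difficulty series for direct probe/physio generation
flat_td <- function(span = 300, td = 1L) data.frame(t_s = seq_len(span), td = td)

# a stepped series covering all three levels
stepped_td <- function(per_level = 300) {
  data.frame(t_s = seq_len(3 * per_level), td = rep(1:3, each = per_level))
}
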