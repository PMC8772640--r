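#' Count targets and messages active at given times
#'
#' An event is active on the half-open interval
#' `[t_appear_s, t_removed_s)`, so an event is not counted at the instant
#' of its removal.
#'
#' @param log An event log data frame with columns `t_appear_s`,
#'   `t_removed_s` and `kind` (`"target"` or `"message"`).
#' @param t Numeric vector of query times (s), within the scenario span.
#' @param span Optional scenario span (s) used to validate `t`; taken from
#'   the log's `span` attribute when present.
#' @return A data frame with columns `t`, `n1` (active targets) and `n2`
#'   (active messages), one row per query time.
#' @export
active_counts <- function(log, t, span = attr(log, "span")) {
  stopifnot(is.data.frame(log), is.numeric(t))
  if (!is.null(span) && any(t < 0 | t > span))
    stop("query time outside the scenario span", call. = FALSE)
  is_target <- log$kind == "target"
  n1 <- vapply(t, function(ti)
    sum(is_target & log$t_appear_s <= ti & ti < log$t_removed_s), integer(1))
  n2 <- vapply(t, function(ti)
    sum(!is_target & log$t_appear_s <= ti & ti < log$t_removed_s), integer(1))
  data.frame(t = t, n1 = n1, n2 = n2)
}

#' Shannon spatial entropy of a zone distribution
#'
#' Entropy (natural log, nats) of the proportions of displayed targets
#' across screen zones: H = -sum p_i log p_i with 0 log 0 := 0. An empty
#' screen (all-zero counts) has entropy 0, the lowest-difficulty state.
#'
#' @param p Zone counts or proportions (non-negative); normalized
#'   internally.
#' @return Entropy in nats, in `[0, log(length(p))]`.
#' @export
#' @examples
#' spatial_entropy(rep(1, 8))  # uniform over 8 zones: log(8)
#' spatial_entropy(c(5, 0, 0)) # degenerate: 0
spatial_entropy <- function(p) {
  if (any(is.na(p)) || any(p < 0))
    stop("zone proportions must be non-negative", call. = FALSE)
  s <- sum(p)
  if (s == 0) return(0)
  p <- p[p > 0] / s
  -sum(p * log(p))
}

#' Discretize the raw difficulty components
#'
#' Maps the raw target count N1, message count N2 and spatial entropy to
#' their ordinal states using fixed thresholds: N1 low <= 5 < medium
#' <= 11 < high; N2 low <= 2 < high; entropy low <= 0.45 < medium <= 1
#' < high. Boundaries are inclusive on the lower state.
#'
#' @param n1,n2 Non-negative integer counts (vectorized).
#' @param entropy Spatial entropy in nats (vectorized).
#' @return A data frame with integer state columns `n1d` (1--3),
#'   `n2d` (1--2) and `entropyd` (1--3); 1 = low.
#' @export
discretize_difficulty <- function(n1, n2, entropy) {
  stopifnot(length(n1) == length(n2), length(n1) == length(entropy))
  if (any(n1 < 0) || any(n2 < 0)) stop("counts must be non-negative", call. = FALSE)
  data.frame(n1d = 1L + (n1 > 5) + (n1 > 11),
             n2d = 1L + (n2 > 2),
             entropyd = 1L + (entropy > 0.45) + (entropy > 1))
}

#' Default fusion rule table for the task-difficulty indicator
#'
#' All 18 combinations of the discretized components with the fused TD
#' level. TD = 3 (high) exactly when N1d is high, N2d is high and the
#' entropy state is at least medium; TD = 1 (low) when at most one
#' component is above its minimum state; TD = 2 otherwise. The table is
#' monotone: raising any component never lowers TD.
#'
#' @return A data frame with columns `n1d`, `n2d`, `entropyd`, `td`.
#' @export
default_difficulty_rules <- function() {
  g <- expand.grid(n1d = 1:3, n2d = 1:2, entropyd = 1:3,
                   KEEP.OUT.ATTRS = FALSE)
  high <- g$n1d == 3L & g$n2d == 2L & g$entropyd >= 2L
  above <- (g$n1d > 1L) + (g$n2d > 1L) + (g$entropyd > 1L)
  g$td <- ifelse(high, 3L, ifelse(above <= 1L, 1L, 2L))
  g
}

#' Fuse discretized components into a three-level difficulty label
#'
#' @param n1d,n2d,entropyd Integer states as returned by
#'   [discretize_difficulty()] (vectorized).
#' @param rules Rule table covering all 18 states; see
#'   [default_difficulty_rules()].
#' @return Integer TD levels in `{1, 2, 3}`.
#' @export
fuse_difficulty <- function(n1d, n2d, entropyd,
                            rules = default_difficulty_rules()) {
  stopifnot(all(n1d %in% 1:3), all(n2d %in% 1:2), all(entropyd %in% 1:3))
  key <- paste(rules$n1d, rules$n2d, rules$entropyd)
  idx <- match(paste(n1d, n2d, entropyd), key)
  if (anyNA(idx)) stop("rule table does not cover all states", call. = FALSE)
  as.integer(rules$td[idx])
}

#' Compute the per-second task-difficulty series from an event log
#'
#' Evaluates, at 1 Hz over the scenario span, the active target and
#' message counts, the spatial entropy of displayed targets over the
#' screen zones, their discretized states and the fused three-level
#' difficulty indicator TD. All components start from the empty-screen
#' state at scenario onset.
#'
#' @param log Event log data frame (columns `t_appear_s`, `t_removed_s`,
#'   `kind`, `zone_row`, `zone_col`).
#' @param span Scenario span in seconds; defaults to the log's `span`
#'   attribute.
#' @param grid Integer `c(rows, cols)` of screen zones; defaults to the
#'   log's `grid` attribute, else 2 x 4.
#' @param rules Fusion rule table, see [default_difficulty_rules()].
#' @return A data frame of class `ofs_td_series` with one row per second
#'   (`t_s` = 1..span) and columns `n1`, `n2`, `entropy`, `n1d`, `n2d`,
#'   `entropyd`, `td`.
#' @export
compute_td_series <- function(log, span = attr(log, "span"),
                              grid = attr(log, "grid"),
                              rules = default_difficulty_rules()) {
  stopifnot(is.data.frame(log))
  if (is.null(span)) stop("scenario span must be supplied", call. = FALSE)
  if (is.null(grid)) grid <- c(2L, 4L)
  n_zones <- prod(grid)
  ticks <- seq_len(floor(span))
  is_target <- log$kind == "target"
  zone_id <- (log$zone_row - 1L) * grid[2] + log$zone_col
  if (any(is_target & (log$zone_row < 1 | log$zone_row > grid[1] |
                       log$zone_col < 1 | log$zone_col > grid[2])))
    stop("target zone outside the screen grid", call. = FALSE)

  n1 <- integer(length(ticks)); n2 <- integer(length(ticks))
  H <- numeric(length(ticks))
  for (i in seq_along(ticks)) {
    t <- ticks[i]
    act <- log$t_appear_s <= t & t < log$t_removed_s
    n1[i] <- sum(act & is_target)
    n2[i] <- sum(act & !is_target)
    if (n1[i] > 0) {
      H[i] <- spatial_entropy(tabulate(zone_id[act & is_target], n_zones))
    }
  }
  d <- discretize_difficulty(n1, n2, H)
  out <- data.frame(t_s = ticks, n1 = n1, n2 = n2, entropy = H,
                    n1d = d$n1d, n2d = d$n2d, entropyd = d$entropyd,
                    td = fuse_difficulty(d$n1d, d$n2d, d$entropyd, rules))
  class(out) <- c("ofs_td_series", "data.frame")
  attr(out, "grid") <- grid
  out
}

#' @export
print.ofs_td_series <- function(x, ...) {
  cat(sprintf("Task-difficulty series: %d s at 1 Hz\n", nrow(x)))
  tab <- table(factor(x$td, levels = 1:3,
                      labels = c("TD1 (low)", "TD2 (medium)", "TD3 (high)")))
  print(tab)
  invisible(x)
}

#' Plot a task-difficulty series
#'
#' Step plot of the fused TD level over time, with the raw target count
#' overlaid on a secondary scale.
#'
#' @param x An `ofs_td_series` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ofs_td_series <- function(x, ...) {
  graphics::plot(x$t_s, x$td, type = "s", ylim = c(0.5, 3.5), yaxt = "n",
                 xlab = "time (s)", ylab = "task difficulty",
                 main = "Dynamic task-difficulty indicator", ...)
  graphics::axis(2, at = 1:3, labels = c("TD1", "TD2", "TD3"))
  invisible(x)
}
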