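#' Write a session bundle to plain-text files
#'
#' Writes `events.csv` (t_appear_s, t_removed_s, kind, zone_row,
#' zone_col), `rr.csv` (t_s, rr_ms), `pupil.csv` (t_s, pd_mm),
#' `probes.csv` (t_s, isa, likert), baseline files
#' `baseline_rr.csv`/`baseline_pupil.csv`, and `session.json` with the
#' participant parameters.
#'
#' @param session One element of an `ofs_cohort`.
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, file) utils::write.csv(df, file.path(dir, file),
                                           row.names = FALSE)
  w(session$events, "events.csv")
  w(session$rr, "rr.csv")
  w(session$pupil, "pupil.csv")
  w(session$probes[, c("t_s", "isa", "likert")], "probes.csv")
  w(session$baseline$rr, "baseline_rr.csv")
  w(session$baseline$pupil, "baseline_pupil.csv")
  jsonlite::write_json(list(id = session$id,
                            params = unclass(session$params)),
                       file.path(dir, "session.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a session bundle written by [write_session()]
#'
#' @param dir Directory containing the session files.
#' @param span Scenario span in seconds, recorded on the event log.
#' @param grid Screen grid `c(rows, cols)` recorded on the event log.
#' @return A session list with `id`, `params`, `events`, `rr`, `pupil`,
#'   `probes` and `baseline`.
#' @export
read_session <- function(dir, span = NULL, grid = c(2L, 4L)) {
  r <- function(file) utils::read.csv(file.path(dir, file))
  meta <- jsonlite::read_json(file.path(dir, "session.json"),
                              simplifyVector = TRUE)
  events <- r("events.csv")
  attr(events, "span") <- span
  attr(events, "grid") <- as.integer(grid)
  list(id = meta$id,
       params = do.call(participant_params, meta$params),
       events = events, rr = r("rr.csv"), pupil = r("pupil.csv"),
       probes = r("probes.csv"),
       baseline = list(rr = r("baseline_rr.csv"),
                       pupil = r("baseline_pupil.csv")))
}

#' Write a whole cohort to a directory tree
#'
#' One sub-directory per participant plus `cohort.json` holding the
#' scenario configuration, heterogeneity and seed.
#'
#' @param cohort An `ofs_cohort`.
#' @param dir Output directory.
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ofs_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- attr(cohort, "config")
  jsonlite::write_json(list(config = unclass(cfg),
                            heterogeneity = attr(cohort, "heterogeneity"),
                            seed = attr(cohort, "seed"),
                            participants = vapply(cohort, `[[`,
                                                  character(1), "id")),
                       file.path(dir, "cohort.json"),
                       auto_unbox = TRUE, digits = NA)
  for (s in cohort) write_session(s, file.path(dir, s$id))
  invisible(dir)
}
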