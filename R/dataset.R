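ofs_levels3 <- c("low", "medium", "high")
ofs_levels2 <- c("low", "high")

#' Join features to difficulty labels
#'
#' Inner join of the per-second feature table and the task-difficulty
#' series on the second; rows with a missing feature are dropped.
#'
#' @param features An `ofs_features` data frame (`t_s`, `hrv_z`, `pd_z`).
#' @param td An `ofs_td_series` data frame (`t_s`, ..., `td`).
#' @param participant Optional participant id recorded with each row.
#' @return A data frame of class `ofs_dataset` with columns
#'   `participant`, `t_s`, `hrv_z`, `pd_z`, `td` (integer 1--3) and
#'   `label` (factor low/medium/high).
#' @export
align_labels <- function(features, td, participant = NA_character_) {
  stopifnot(is.data.frame(features), is.data.frame(td))
  m <- merge(features, td[, c("t_s", "td")], by = "t_s")
  m <- m[stats::complete.cases(m[, c("hrv_z", "pd_z")]), , drop = FALSE]
  if (nrow(m) == 0) stop("empty join: no labelled seconds", call. = FALSE)
  out <- data.frame(participant = participant, t_s = m$t_s,
                    hrv_z = m$hrv_z, pd_z = m$pd_z, td = as.integer(m$td),
                    label = factor(ofs_levels3[m$td], levels = ofs_levels3))
  out <- out[order(out$t_s), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ofs_dataset", "data.frame")
  out
}

#' Collapse the three difficulty classes to two
#'
#' `"merge_low"` (default) merges TD1 and TD2 into `low` and keeps TD3 as
#' `high`, targeting detection of the high-risk state; `"drop_medium"`
#' discards TD2 rows and relabels TD1/TD3 as low/high.
#'
#' @param ds An `ofs_dataset`.
#' @param scheme `"merge_low"` or `"drop_medium"`.
#' @return The dataset with a two-level `label` factor.
#' @export
binarize_labels <- function(ds, scheme = c("merge_low", "drop_medium")) {
  scheme <- match.arg(scheme)
  stopifnot(is.data.frame(ds), "td" %in% names(ds))
  if (scheme == "drop_medium") {
    ds <- ds[ds$td != 2L, , drop = FALSE]
    rownames(ds) <- NULL
  }
  ds$label <- factor(ifelse(ds$td == 3L, "high", "low"),
                     levels = ofs_levels2)
  ds
}

#' Partition a cohort's participants into train and test sets
#'
#' Between-subject split for the pooled layer: with 17 participants, 13
#' train and 4 test; for other cohort sizes the test share stays at 4/17
#' of the cohort (at least 1).
#'
#' @param participants Character vector of participant ids.
#' @param n_test Number of held-out participants; default `round(n*4/17)`.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return A list of class `ofs_split` with elements `layer = "pooled"`,
#'   `train` and `test` (disjoint id vectors).
#' @export
pooled_split <- function(participants, n_test = NULL, seed = NULL) {
  participants <- unique(as.character(participants))
  n <- length(participants)
  if (n < 5) stop("the pooled layer needs at least 5 participants", call. = FALSE)
  if (is.null(n_test)) n_test <- max(1L, round(n * 4 / 17))
  if (!is.null(seed)) set.seed(seed)
  test <- sort(sample(participants, n_test))
  structure(list(layer = "pooled", train = setdiff(participants, test),
                 test = test), class = "ofs_split")
}

# stratified fold assignment; returns integer folds of length n.
# classes with fewer members than folds cannot appear in every fold and
# are only spread as widely as possible.
stratified_folds <- function(label, folds, max_tries = 20) {
  n <- length(label)
  counts <- table(label)
  full <- names(counts)[counts >= folds]
  for (try in seq_len(max_tries)) {
    f <- integer(n)
    for (lv in levels(label)) {
      idx <- which(label == lv)
      f[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    ok <- all(vapply(seq_len(folds), function(k)
      all(table(label[f == k])[full] > 0), logical(1)))
    if (ok) return(f)
    warning("a class was absent from a fold; re-drawing", call. = FALSE)
  }
  stop("could not build folds with every class present", call. = FALSE)
}

#' Within-participant 75/25 split with cross-validation folds
#'
#' Stratified random row split: 25% of each class held out for testing;
#' the training part receives stratified fold labels for fourfold
#' cross-validated tuning. Rows at 1 Hz are autocorrelated, so a random
#' split is optimistic about temporal generalization; a contiguous block
#' split is available via `blocked = TRUE`.
#'
#' @param label Factor of class labels, one per row.
#' @param test_frac Held-out fraction (default 0.25).
#' @param folds Number of CV folds on the training rows (default 4).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param blocked If `TRUE`, the test set is the final `test_frac` block
#'   of rows instead of a stratified random sample.
#' @return A list of class `ofs_split` with `layer = "individual"`,
#'   integer row indices `train`, `test`, and `fold` (per training row).
#' @export
individual_split <- function(label, test_frac = 0.25, folds = 4,
                             seed = NULL, blocked = FALSE) {
  stopifnot(is.factor(label), length(label) > folds)
  if (!is.null(seed)) set.seed(seed)
  n <- length(label)
  if (blocked) {
    test <- seq.int(floor(n * (1 - test_frac)) + 1L, n)
  } else {
    # largest-remainder allocation: exactly round(n * test_frac) rows in
    # total while keeping per-class proportions as close as possible
    counts <- table(label)
    raw <- as.numeric(counts) * test_frac
    take <- floor(raw)
    short <- round(n * test_frac) - sum(take)
    if (short > 0) {
      ord <- order(raw - take, decreasing = TRUE)
      take[ord[seq_len(short)]] <- take[ord[seq_len(short)]] + 1L
    }
    test <- sort(unlist(lapply(seq_along(levels(label)), function(k) {
      idx <- which(label == levels(label)[k])
      sample(idx, min(take[k], length(idx)))
    }), use.names = FALSE))
  }
  train <- setdiff(seq_len(n), test)
  fold <- stratified_folds(droplevels(label[train]), folds)
  structure(list(layer = "individual", train = train, test = test,
                 fold = fold), class = "ofs_split")
}

#' @export
print.ofs_split <- function(x, ...) {
  if (x$layer == "pooled") {
    cat(sprintf("Pooled split: %d train / %d test participants\n",
                length(x$train), length(x$test)))
  } else {
    cat(sprintf("Individual split: %d train / %d test rows, %d CV folds\n",
                length(x$train), length(x$test), max(x$fold)))
  }
  invisible(x)
}

#' Serialize a split plan to JSON
#'
#' @param split An `ofs_split` object.
#' @param path Output file path.
#' @export
write_split <- function(split, path) {
  jsonlite::write_json(unclass(split), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# assemble the labelled per-participant datasets of a cohort
cohort_datasets <- function(cohort, window_beats = 300, warmup_beats = 30) {
  stopifnot(inherits(cohort, "ofs_cohort"))
  lapply(cohort, function(b) {
    bl <- estimate_baseline(b$baseline, window_beats = window_beats,
                            warmup_beats = warmup_beats)
    feats <- build_feature_table(b$rr, b$pupil, bl, span = nrow(b$td),
                                 window_beats = window_beats,
                                 warmup_beats = warmup_beats)
    align_labels(feats, b$td, participant = b$id)
  })
}
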