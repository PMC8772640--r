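#' Spearman correlation between difficulty labels and subjective ratings
#'
#' Tie-corrected Spearman rank correlation with a two-sided asymptotic
#' p-value, used to check that the dynamic task-difficulty indicator
#' tracks the participants' subjective experience.
#'
#' @param td Ordinal vector (e.g. TD level at each probe).
#' @param rating Ordinal vector of the same length (Likert or ISA).
#' @return A list with `rho` and `p`.
#' @export
spearman_validation <- function(td, rating) {
  if (length(td) != length(rating))
    stop("series must have equal length", call. = FALSE)
  if (length(td) < 3) stop("need at least 3 pairs", call. = FALSE)
  ct <- suppressWarnings(
    stats::cor.test(as.numeric(td), as.numeric(rating),
                    method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Cross-tabulate predicted operator state against ISA level
#'
#' Builds the 5 x 3 contingency table of ISA self-assessment level (rows)
#' by predicted OFS class (columns), with column totals and column
#' percentages.
#'
#' @param ofs Integer vector of OFS classes in `{1, 2, 3}`.
#' @param isa Integer vector of ISA levels in `{1, ..., 5}`.
#' @return An object of class `ofs_contingency` with elements `counts`
#'   (5 x 3 matrix), `col_totals` and `col_pct` (unrounded column
#'   percentages).
#' @export
build_contingency <- function(ofs, isa) {
  if (length(ofs) != length(isa))
    stop("series must have equal length", call. = FALSE)
  if (!all(ofs %in% 1:3)) stop("OFS classes must be in 1..3", call. = FALSE)
  if (!all(isa %in% 1:5)) stop("ISA levels must be in 1..5", call. = FALSE)
  counts <- table(factor(isa, 1:5), factor(ofs, 1:3))
  counts <- matrix(as.integer(counts), 5, 3,
                   dimnames = list(ISA = paste0("ISA", 1:5),
                                   OFS = paste0("OFS", 1:3)))
  new_contingency(counts)
}

new_contingency <- function(counts, col_pct = NULL) {
  totals <- colSums(counts)
  if (is.null(col_pct)) {
    col_pct <- sweep(counts, 2, pmax(totals, 1), "/") * 100
    col_pct[, totals == 0] <- NA_real_
  }
  structure(list(counts = counts, col_totals = totals, col_pct = col_pct),
            class = "ofs_contingency")
}

#' Reconstruct a contingency table from column percentages and totals
#'
#' Counts are obtained per column by largest-remainder rounding of
#' `pct/100 * total`, constrained so each column sums to its printed
#' total. The supplied percentages are retained (not recomputed), so
#' block-percentage arithmetic reproduces the source table even when
#' its rounded percentages do not sum to exactly 100.
#'
#' @param col_pct 5 x 3 matrix of column percentages (ISA rows, OFS
#'   columns).
#' @param col_totals Length-3 vector of column totals.
#' @return An `ofs_contingency` object.
#' @export
contingency_from_percentages <- function(col_pct, col_totals) {
  stopifnot(nrow(col_pct) == 5, ncol(col_pct) == 3,
            length(col_totals) == 3)
  counts <- matrix(0L, 5, 3, dimnames = list(ISA = paste0("ISA", 1:5),
                                             OFS = paste0("OFS", 1:3)))
  for (j in 1:3) {
    raw <- col_pct[, j] / 100 * col_totals[j]
    base <- floor(raw)
    rem <- raw - base
    short <- col_totals[j] - sum(base)
    if (short > 0)
      base[order(rem, decreasing = TRUE)[seq_len(short)]] <-
        base[order(rem, decreasing = TRUE)[seq_len(short)]] + 1
    counts[, j] <- as.integer(base)
  }
  new_contingency(counts, col_pct = col_pct)
}

#' Reference OFS x ISA contingency table
#'
#' The published cross-tabulation of predicted operator state against
#' ISA level from a drone-swarm supervision study (column percentages
#' with column totals 27, 195 and 104), reconstructed into counts by
#' [contingency_from_percentages()]. Used as a desk-checkable input for
#' the rank-association statistics.
#'
#' @return An `ofs_contingency` object.
#' @export
reference_contingency <- function() {
  pct <- matrix(c(52, 33, 11, 4, 0,
                  16, 30, 23, 22, 10,
                  1, 8, 23, 44, 24), nrow = 5,
                dimnames = list(ISA = paste0("ISA", 1:5),
                                OFS = paste0("OFS", 1:3)))
  contingency_from_percentages(pct, c(27, 195, 104))
}

#' @export
print.ofs_contingency <- function(x, digits = 0, ...) {
  cat("OFS x ISA contingency table (column % with counts)\n")
  disp <- matrix(sprintf("%s%% (%d)", formatC(x$col_pct, format = "f",
                                              digits = digits),
                         x$counts), 5, 3, dimnames = dimnames(x$counts))
  print(disp, quote = FALSE)
  cat("Totals:", paste(x$col_totals, collapse = ", "), "\n")
  invisible(x)
}

#' Sum of column-percentage cells for a block of ISA levels
#'
#' E.g. the share of high-risk predictions that coincide with ISA levels
#' 4 and 5.
#'
#' @param table An `ofs_contingency`.
#' @param ofs_class OFS column index (1--3).
#' @param isa_levels Set of ISA row indices (subset of 1--5).
#' @return Percentage (0--100).
#' @export
block_percentage <- function(table, ofs_class, isa_levels) {
  stopifnot(inherits(table, "ofs_contingency"))
  if (!ofs_class %in% 1:3 || !all(isa_levels %in% 1:5))
    stop("invalid OFS class or ISA level", call. = FALSE)
  sum(table$col_pct[isa_levels, ofs_class])
}

#' Kendall tau-b from a contingency table
#'
#' Tie-corrected Kendall rank association computed from concordant and
#' discordant pair counts of the cross-tabulation:
#' tau_b = (C - D) / sqrt((N0 - Nr)(N0 - Nc)) where N0 = n(n-1)/2 and
#' Nr, Nc are the tied-pair counts of the row and column marginals.
#'
#' @param table An `ofs_contingency` or a counts matrix with ordered
#'   rows and columns.
#' @return Kendall tau-b in `[-1, 1]`.
#' @export
kendall_tau_b <- function(table) {
  m <- if (inherits(table, "ofs_contingency")) table$counts else as.matrix(table)
  if (sum(rowSums(m) > 0) < 2 || sum(colSums(m) > 0) < 2)
    stop("degenerate table: tau-b undefined", call. = FALSE)
  R <- nrow(m); C <- ncol(m)
  conc <- disc <- 0
  for (i in seq_len(R)) for (j in seq_len(C)) {
    if (m[i, j] == 0) next
    if (i < R && j < C)
      conc <- conc + m[i, j] * sum(m[(i + 1):R, (j + 1):C])
    if (i < R && j > 1)
      disc <- disc + m[i, j] * sum(m[(i + 1):R, 1:(j - 1)])
  }
  n <- sum(m)
  n0 <- n * (n - 1) / 2
  nr <- sum(rowSums(m) * (rowSums(m) - 1) / 2)
  nc <- sum(colSums(m) * (colSums(m) - 1) / 2)
  (conc - disc) / sqrt((n0 - nr) * (n0 - nc))
}

#' Assemble a full analysis report
#'
#' Collects the classification experiment, the label-validation Spearman
#' statistics and the OFS x ISA contingency analysis into one report
#' object; missing stages are tolerated with a warning so partial runs
#' can still be inspected.
#'
#' @param experiment An `ofs_experiment`, or `NULL`.
#' @param td_validation Result of [spearman_validation()] on TD vs
#'   Likert probes, or `NULL`.
#' @param contingency An `ofs_contingency` of predicted OFS vs ISA, or
#'   `NULL`.
#' @param config The [scenario_config()] used.
#' @param seed The driving seed.
#' @return An object of class `ofs_report`.
#' @export
build_report <- function(experiment = NULL, td_validation = NULL,
                         contingency = NULL, config = NULL, seed = NULL) {
  missing <- c(if (is.null(experiment)) "experiment",
               if (is.null(td_validation)) "td_validation",
               if (is.null(contingency)) "contingency")
  if (length(missing))
    warning("partial report; missing: ", paste(missing, collapse = ", "),
            call. = FALSE)
  tau <- if (!is.null(contingency)) kendall_tau_b(contingency) else NULL
  structure(list(experiment = experiment, td_validation = td_validation,
                 contingency = contingency, kendall_tau_b = tau,
                 config = config, seed = seed),
            class = "ofs_report")
}

#' @export
print.ofs_report <- function(x, ...) {
  cat("=== Operator functional state analysis report ===\n")
  if (!is.null(x$seed)) cat("seed:", x$seed, "\n")
  if (!is.null(x$td_validation))
    cat(sprintf("TD vs Likert (Spearman): rho = %.3f, p = %.3g\n",
                x$td_validation$rho, x$td_validation$p))
  if (!is.null(x$experiment)) print(x$experiment)
  if (!is.null(x$contingency)) {
    print(x$contingency)
    cat(sprintf("Kendall tau-b (OFS vs ISA): %.3f\n", x$kendall_tau_b))
  }
  invisible(x)
}
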