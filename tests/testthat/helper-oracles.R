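# independent brute-force oracles used by multiple test files

rank_pearson <- function(x, y) stats::cor(rank(x), rank(y))

# O(n^2) pairwise concordance count with tie correction
tau_b_pairs <- function(x, y) {
  n <- length(x); conc <- disc <- tx <- ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[i] - x[j]); dy <- sign(y[i] - y[j])
    if (dx == 0 && dy == 0) next
    else if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (dx == dy) conc <- conc + 1
    else disc <- disc + 1
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

# expand a counts matrix into the paired ordinal observations it tabulates
expand_table <- function(m) {
  list(x = rep(rep(seq_len(nrow(m)), ncol(m)), as.vector(m)),
       y = rep(rep(seq_len(ncol(m)), each = nrow(m)), as.vector(m)))
}
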