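test_that("active counts use the half-open [appear, removed) convention", {
  empty <- data.frame(t_appear_s = numeric(0), t_removed_s = numeric(0),
                      kind = character(0), zone_row = integer(0),
                      zone_col = integer(0))
  expect_equal(active_counts(empty, 5)[, c("n1", "n2")],
               data.frame(n1 = 0L, n2 = 0L))

  one <- data.frame(t_appear_s = 10, t_removed_s = 20, kind = "target",
                    zone_row = 1L, zone_col = 1L)
  expect_equal(active_counts(one, c(10, 19.9, 20))$n1, c(1L, 1L, 0L))

  # five overlapping targets queried at 12 s: alive are those with
  # appear <= 12 < removed, frozen from the interval layout
  log <- toy_log()
  expect_equal(active_counts(log, 12)$n1, 3L)  # targets at 5, 10, 12
  expect_equal(active_counts(log, 35)$n2, 1L)
  expect_error(active_counts(log, 120), "span")
})

test_that("spatial entropy is the positive Shannon form in nats", {
  expect_equal(spatial_entropy(c(5, 0, 0, 0)), 0)
  expect_equal(spatial_entropy(rep(1, 8)), log(8))
  expect_equal(spatial_entropy(c(0.5, 0.5, 0, 0, 0, 0, 0, 0)), log(2))
  expect_equal(spatial_entropy(rep(0, 8)), 0)  # empty screen
  expect_error(spatial_entropy(c(-1, 2)), "non-negative")

  # bounds attained only at the degenerate/uniform distributions
  set.seed(42)
  for (i in 1:100) {
    p <- stats::rgamma(8, 1)
    H <- spatial_entropy(p)
    expect_gte(H, 0)
    expect_lte(H, log(8) + 1e-12)
  }
})

test_that("discretization respects the printed thresholds at boundaries", {
  d <- discretize_difficulty(c(0, 5, 6, 11, 12), c(0, 2, 3, 2, 3),
                             c(0, 0.45, 0.46, 1, 1.01))
  expect_equal(d$n1d, c(1L, 1L, 2L, 2L, 3L))
  expect_equal(d$n2d, c(1L, 1L, 2L, 1L, 2L))
  expect_equal(d$entropyd, c(1L, 1L, 2L, 2L, 3L))
})

test_that("fusion honours the high rule and is monotone over all 18 states", {
  # the one fully specified rule: N1d high, N2d high, entropy >= medium
  expect_equal(fuse_difficulty(3L, 2L, 2L), 3L)
  expect_equal(fuse_difficulty(3L, 2L, 3L), 3L)
  # minimal state is low
  expect_equal(fuse_difficulty(1L, 1L, 1L), 1L)

  # full table equals a brute-force evaluation of the documented rules
  g <- expand.grid(n1d = 1:3, n2d = 1:2, entropyd = 1:3)
  oracle <- apply(g, 1, function(s) {
    if (s["n1d"] == 3 && s["n2d"] == 2 && s["entropyd"] >= 2) return(3L)
    if (sum(s > 1) <= 1) return(1L)
    2L
  })
  expect_equal(fuse_difficulty(g$n1d, g$n2d, g$entropyd), oracle)

  # monotone: raising any single component never lowers TD
  for (r in seq_len(nrow(g))) {
    s <- as.integer(g[r, ])
    td0 <- fuse_difficulty(s[1], s[2], s[3])
    for (j in 1:3) {
      s2 <- s; s2[j] <- s2[j] + 1L
      if (s2[1] > 3 || s2[2] > 2 || s2[3] > 3) next
      expect_gte(fuse_difficulty(s2[1], s2[2], s2[3]), td0)
    }
  }
})

test_that("TD series covers the span, starts at TD1 and ignores record order", {
  log <- toy_log(span = 60)
  td <- compute_td_series(log)
  expect_equal(nrow(td), 60)
  expect_equal(td$t_s, 1:60)
  # before any stimulus the screen is empty: lowest difficulty
  expect_true(all(td$td[1:4] == 1L))

  shuffled <- log[sample(nrow(log)), ]
  attr(shuffled, "span") <- attr(log, "span")
  attr(shuffled, "grid") <- attr(log, "grid")
  td2 <- compute_td_series(shuffled)
  expect_equal(td2$td, td$td)
  expect_equal(td2$entropy, td$entropy)
})

test_that("TD series matches a hand computation on a dense toy log", {
  # 12 targets alive on [0, 10): zone counts (2,2,2,2,1,1,1,1), 3 messages
  log <- data.frame(
    t_appear_s = rep(0, 15), t_removed_s = rep(10, 15),
    kind = c(rep("target", 12), rep("message", 3)),
    zone_row = c(rep(1L, 8), rep(2L, 4), 1L, 1L, 1L),
    zone_col = c(1:4, 1:4, 1:4, 1L, 1L, 1L))
  attr(log, "span") <- 12; attr(log, "grid") <- c(2L, 4L)
  td <- compute_td_series(log)
  H <- -(4 * (2 / 12) * log(2 / 12) + 4 * (1 / 12) * log(1 / 12))
  expect_equal(td$n1[5], 12L)
  expect_equal(td$n2[5], 3L)
  expect_equal(td$entropy[5], H)
  # N1 high, N2 high, entropy high (H > 1) -> TD3 while events are alive
  expect_true(all(td$td[1:9] == 3L))
  # after removal at t = 10 the screen is empty again
  expect_true(all(td$td[10:12] == 1L))
})

test_that("a custom rule table overrides the fusion", {
  rules <- default_difficulty_rules()
  rules$td[] <- 2L
  expect_equal(fuse_difficulty(1L, 1L, 1L, rules), 2L)
  expect_error(fuse_difficulty(1L, 1L, 1L, rules[-1, ]), "cover")
})
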