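test_that("scenario and participant invariants are enforced", {
  expect_error(scenario_config(phase_durations = c(0, 1, 1, 1)), "positive")
  expect_error(scenario_config(target_rate = c(1, 2, 4, 8)), "waiting")
  expect_error(scenario_config(target_rate = c(0, 4, 2, 8)), "non-decreasing")
  expect_error(participant_params(rr_baseline_sd = 0), "positive")
  expect_error(participant_params(artifact_prob = 1.5), "0, 1")
  expect_error(participant_params(pupil_baseline = 9), "2, 8")
})

test_that("event logs are empty in the waiting phase and seed-deterministic", {
  cfg <- short_scenario()
  log <- generate_event_log(cfg, seed = 4)
  expect_true(all(log$t_appear_s >= cfg$phase_durations[1]))
  expect_true(all(log$t_removed_s >= log$t_appear_s))
  expect_true(all(log$zone_row %in% 1:2 & log$zone_col %in% 1:4))

  expect_identical(log, generate_event_log(cfg, seed = 4))
  log2 <- generate_event_log(cfg, seed = 5)
  expect_false(identical(log, log2))
})

test_that("steady-state target count follows rate x mean lifetime", {
  # M/G/infinity: E[N1] = lambda * E[lifetime] = (8/60) * 60 = 8 in the
  # final phase, sampled well after the last rate change
  cfg <- scenario_config(target_rate = c(0, 2, 4, 8),
                         message_rate = c(0, 0, 0, 0))
  probe_t <- c(1260, 1320, 1380, 1440)
  set.seed(99)
  means <- replicate(150, {
    log <- generate_event_log(cfg)
    mean(active_counts(log, probe_t)$n1)
  })
  expect_equal(mean(means), 8, tolerance = 0.05 * 8)
})

test_that("pupil artifacts are injected at the configured rate", {
  params <- participant_params(artifact_prob = 0.1)
  td <- flat_td(167)  # ~10k samples at 60 Hz
  set.seed(8)
  physio <- generate_physio(td, params)
  n <- nrow(physio$pupil)
  outside <- sum(physio$pupil$pd_mm < 2 | physio$pupil$pd_mm > 8)
  expect_equal(outside, 0.1 * n, tolerance = 4 * sqrt(0.1 * 0.9 * n) / (0.1 * n))

  clean <- clean_pupil(physio$pupil)
  expect_equal(attr(clean, "n_removed"), outside)

  none <- generate_physio(td, participant_params(artifact_prob = 0), seed = 8)
  expect_equal(attr(clean_pupil(none$pupil), "n_removed"), 0L)
})

test_that("physiology carries the difficulty signal monotonically", {
  # modest drift so level means estimate the load gain cleanly
  params <- participant_params(pupil_drift_sd = 0.05)
  td <- stepped_td(300)
  set.seed(10)
  physio <- generate_physio(td, params)
  pupil <- clean_pupil(physio$pupil)
  lev <- td$td[ceiling(pupil$t_s)]
  means <- tapply(pupil$pd_mm, lev, mean)
  expect_true(all(diff(means) > 0))
  expect_equal(as.vector(diff(means)), rep(params$pupil_load_gain, 2),
               tolerance = 0.25)

  # per-beat RR jitter shrinks with load
  rr_lev <- td$td[pmin(ceiling(physio$rr$t_s), nrow(td))]
  sds <- tapply(physio$rr$rr_ms, rr_lev, stats::sd)
  expect_true(all(diff(sds) < 0))
})

test_that("probes tick every 90 s and track difficulty at full fidelity", {
  td <- stepped_td(500)  # 1500 s
  params <- participant_params(probe_fidelity = 1)
  probes <- generate_probes(td, params, seed = 6)
  expect_equal(probes$t_s, seq(90, 1440, by = 90))
  expect_equal(nrow(probes), 16)
  expect_equal(probes$likert, probes$true_td)
  expect_equal(spearman_validation(probes$true_td, probes$likert)$rho, 1)
  # ISA smear is monotone: TD1 -> {1,2}, TD2 -> {2,3}, TD3 -> {4,5}
  expect_true(all(probes$isa[probes$true_td == 1] %in% 1:2))
  expect_true(all(probes$isa[probes$true_td == 2] %in% 2:3))
  expect_true(all(probes$isa[probes$true_td == 3] %in% 4:5))

  expect_error(generate_probes(td[0, ], params), "empty")
})

test_that("imperfect probes still correlate positively with difficulty", {
  td <- stepped_td(500)
  params <- participant_params(probe_fidelity = 0.8)
  set.seed(12)
  hits <- replicate(30, {
    probes <- do.call(rbind, lapply(1:17, function(i)
      generate_probes(td, params)))
    s <- spearman_validation(probes$true_td, probes$likert)
    s$rho > 0 && s$p < 0.05
  })
  expect_gte(mean(hits), 0.95)
})

test_that("cohorts bundle complete sessions and obey the seed", {
  cfg <- short_scenario()
  coh <- generate_cohort(cfg, n_participants = 3, heterogeneity = 1,
                         seed = 31)
  expect_s3_class(coh, "ofs_cohort")
  expect_length(coh, 3)
  for (b in coh) {
    expect_named(b, c("id", "params", "events", "td", "rr", "pupil",
                      "probes", "baseline"))
    expect_equal(nrow(b$td), scenario_span(cfg))
    expect_equal(nrow(b$baseline$rr) > 300, TRUE)
  }
  coh2 <- generate_cohort(cfg, n_participants = 3, heterogeneity = 1,
                          seed = 31)
  expect_identical(coh, coh2)

  expect_error(generate_cohort(cfg, n_participants = 1), "at least 2")

  # zero heterogeneity: all participants share the population parameters
  flat <- generate_cohort(cfg, n_participants = 3, heterogeneity = 0,
                          seed = 32)
  expect_identical(flat[[1]]$params, flat[[2]]$params)
})

test_that("sessions round-trip through the plain-text formats", {
  cfg <- short_scenario()
  coh <- generate_cohort(cfg, n_participants = 2, seed = 33)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "cohort.json")))
  s <- read_session(file.path(dir, "P01"), span = scenario_span(cfg))
  expect_equal(s$rr$rr_ms, coh[[1]]$rr$rr_ms)
  expect_equal(s$pupil$pd_mm, coh[[1]]$pupil$pd_mm)
  expect_equal(s$probes$isa, coh[[1]]$probes$isa)
  expect_equal(s$params, coh[[1]]$params)
  td <- compute_td_series(s$events)
  expect_equal(td$td, coh[[1]]$td$td)
})
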