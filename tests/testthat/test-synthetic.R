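# Synthetic fixtures: declared ground truth must match the pipeline's own
# answers (the central self-test of the fixture generators).

test_that("generator ground truths match the simulated fixtures", {
  decay <- make_decay_cpn(5, 0.3)
  tr <- simulate_hpn(decay, hpn_sim_config(t_end = 10, n_intervals = 100,
                                           rtol = 1e-10, atol = 1e-12))
  expect_lt(max(abs(tr$A - attr(decay, "closed_form")(tr$Time))), 1e-6)
  expect_equal(attr(decay, "closed_form")(1), 5 * exp(-0.3), tolerance = 1e-12)

  bd <- make_birth_death_spn(10, 1)
  expect_equal(attr(bd, "stationary"), list(mean = 10, var = 10))

  # transport conserves matter: once the nuclear pool is exhausted the
  # cytoplasmic concentration equals w * N0 exactly, in every run
  tp <- make_transport_hybrid(N0 = 30, k = 2, w = 0.00847)
  for (s in 1:5) {
    tr <- simulate_hpn(tp, hpn_sim_config(t_end = 15, n_intervals = 50,
                                          seed = s))
    expect_equal(tr$A_n[nrow(tr)], 0)
    expect_equal(tr$A_c[nrow(tr)], 0.00847 * 30, tolerance = 1e-12)
  }
})

test_that("pulse-trace geometry guarantees its declared classification", {
  expect_equal(classify_trace(make_pulse_trace(0, baseline = 500)), "no_pulse")
  expect_equal(classify_trace(make_pulse_trace(1)), "one_pulse")
  expect_equal(classify_trace(make_pulse_trace(2)), "multi_pulse")
  expect_equal(classify_trace(make_pulse_trace(3)), "multi_pulse")
  expect_error(make_pulse_trace(10, width = 4),
               "infeasible|re-arm")
  expect_error(make_pulse_trace(1, baseline = 1300), "below the middle")
  expect_error(make_pulse_trace(1, baseline = 500, amplitude = 100),
               "exceed the upper")
})

test_that("classification survives measurement noise at 5% of amplitude", {
  set.seed(99)
  n_ok <- 0L; n <- 1000L
  for (i in seq_len(n)) {
    np <- sample(0:3, 1L)
    tr <- make_pulse_trace(np, baseline = 500, amplitude = 2000, width = 1,
                           noise_sd = 100, t_end = 48, n_points = 400)
    want <- c("no_pulse", "one_pulse", "multi_pulse", "multi_pulse")[np + 1L]
    if (classify_trace(tr) == want) n_ok <- n_ok + 1L
  }
  expect_gte(n_ok / n, 0.99)
})

test_that("generators are deterministic under a fixed seed", {
  a <- make_pulse_trace(2, noise_sd = 50, seed = 123)
  b <- make_pulse_trace(2, noise_sd = 50, seed = 123)
  expect_identical(a, b)
})

test_that("the fixture directory carries a manifest the suite can replay", {
  dir <- withr::local_tempdir()
  man <- gen_fixtures(dir, seed = 3L)
  for (fx in man$fixtures)
    expect_true(file.exists(file.path(dir, fx$file)))

  # replay: ground truths in the manifest match recomputation
  gt <- man$fixtures$pulse_2$ground_truth
  tr <- read_trace_csv(file.path(dir, "pulse_2.csv"))
  expect_equal(count_pulses(tr), gt$n_pulses)
  m <- read_hpn_model(file.path(dir, "decay_cpn.hpn"))
  gtd <- man$fixtures$decay_cpn$ground_truth
  tr2 <- simulate_hpn(m, hpn_sim_config(t_end = 5, n_intervals = 50))
  expect_equal(tr2$A, gtd$A0 * exp(-gtd$d * tr2$Time), tolerance = 1e-5)
  p <- read_parameter_set(file.path(dir, "params_surrogate.txt"))
  expect_equal(p$provenance, "surrogate")
})

test_that("surrogate ensembles show the calibrated dose-response regimes", {
  se <- surrogate_ensembles()
  rep <- verify_ensemble(se$ens, se$spec)
  # no-stress control
  expect_gt(rep$P1[rep$dose == 0], 0.95)
  # pulse-count variability grows with dose
  p3 <- rep$P3[rep$dose > 0][order(rep$dose[rep$dose > 0])]
  expect_gt(p3[3], p3[1])

  # damped population-mean oscillation at 2.5 Gy: smooth the mean of 200 runs
  # (a 1 h moving average), then require at least two maxima above twice the
  # no-stress baseline with non-increasing amplitude
  pm <- population_mean(se$ens[["2.5"]]$traces)
  k <- 41L
  sm <- pm
  sm$p53 <- as.numeric(stats::filter(pm$p53, rep(1 / k, k), sides = 2))
  sm$p53[is.na(sm$p53)] <- pm$p53[is.na(sm$p53)]
  pk <- detect_peaks(sm, threshold_set(500, 700, 1000))
  expect_gte(nrow(pk), 2L)
  expect_true(all(diff(pk$amplitude) <= 0))
  # the first population pulse dominates
  expect_gt(pk$amplitude[1], 1500)
})
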