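# Verification pipeline: pulse counting, classification, peak detection,
# ensemble reports.

test_that("the pulse-counting state machine counts threshold excursions", {
  th <- threshold_set()
  flat <- hpn_trace(0:10, list(p53 = rep(500, 11)))
  expect_equal(count_pulses(flat, th), 0L)

  one <- make_pulse_trace(1, baseline = 1000, amplitude = 1200, width = 1.2,
                          n_points = 300)
  expect_equal(count_pulses(one, th), 1L)

  three <- make_pulse_trace(3, baseline = 500, amplitude = 1500, width = 1,
                            n_points = 600)
  expect_equal(count_pulses(three, th), 3L)

  # starts above T_M: not armed until the signal first drops below T_M
  high_start <- hpn_trace(0:4, list(p53 = c(1900, 1900, 500, 1900, 500)))
  expect_equal(count_pulses(high_start, th), 1L)

  # re-arming requires dropping below T_M, not merely below T_U
  no_rearm <- hpn_trace(0:4, list(p53 = c(500, 1900, 1500, 1900, 500)))
  expect_equal(count_pulses(no_rearm, th), 1L)

  expect_error(count_pulses(hpn_trace(0:1, list(x = c(0, 0))), th),
               "no column")
})

test_that("temporal-logic classification matches the counting oracle on clean traces", {
  corpus <- pulse_corpus()
  want <- ifelse(corpus$n_pulses == 0L, "no_pulse",
                 ifelse(corpus$n_pulses == 1L, "one_pulse", "multi_pulse"))
  got <- vapply(corpus$traces, classify_trace, "")
  expect_equal(got, want)
  counts <- vapply(corpus$traces, count_pulses, 0L)
  expect_equal(counts, corpus$n_pulses)
})

test_that("peak detection returns strict local maxima above the middle threshold", {
  mono <- hpn_trace(0:10, list(p53 = seq(0, 3000, length.out = 11)))
  expect_equal(nrow(detect_peaks(mono)), 0L)

  tt <- seq(0, 30, length.out = 601)
  damp <- hpn_trace(tt, list(p53 = 3000 * exp(-tt / 12) * sin(pi * tt / 6)^2))
  pk <- detect_peaks(damp)
  expect_gte(nrow(pk), 2L)
  expect_true(all(diff(pk$amplitude) < 0))
  # analytic peak positions: centres of the sin^2 arches, shifted by damping
  expect_true(all(abs(pk$time %% 6 - 3) < 1))
})

test_that("report estimates are satisfying fractions with an exact partition", {
  corpus <- pulse_corpus()
  est <- verify_traces(corpus$traces)
  expect_equal(sum(est), 1)
  expect_equal(est[["P2"]], mean(corpus$n_pulses == 1L))

  rep <- verify_ensemble(list(`1` = list(dose = 1, traces = corpus$traces[1:50]),
                              `2` = list(dose = 2, traces = corpus$traces[51:100])))
  expect_s3_class(rep, "verification_report")
  expect_equal(rep$dose, c(1, 2))
  expect_equal(rep$P1 + rep$P2 + rep$P3, c(1, 1))
  expect_true(all(rep$P2_lo <= rep$P2 & rep$P2 <= rep$P2_hi))
})

test_that("ensembles write one CSV per run and re-running reproduces bytes", {
  spec <- ensemble_spec(ir_doses = 2.5, n_runs = 3, base_seed = 7,
                        config = hpn_sim_config(t_end = 6, n_intervals = 60))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  e1 <- run_ensemble(spec, out_dir = d1)
  e2 <- run_ensemble(spec, out_dir = d2)
  f1 <- list.files(file.path(d1, "dose2.5"), full.names = TRUE)
  expect_length(f1, 3L)
  f2 <- list.files(file.path(d2, "dose2.5"), full.names = TRUE)
  for (i in seq_along(f1))
    expect_identical(readLines(f1[i]), readLines(f2[i]))
  headers <- vapply(f1, function(f) readLines(f, n = 1L), "")
  expect_length(unique(headers), 1L)

  # re-verification from saved CSVs equals in-memory verification exactly
  mem <- verify_ensemble(e1, spec)
  disk <- verify_ensemble(read_trace_dir(d1), thresholds = spec$thresholds[[1]])
  expect_identical(mem$P1, disk$P1)
  expect_identical(mem$P2, disk$P2)
  expect_identical(mem$P3, disk$P3)
})

test_that("a dose-zero ensemble draws no double-strand breaks", {
  spec <- ensemble_spec(ir_doses = 0, n_runs = 3, base_seed = 1,
                        config = hpn_sim_config(t_end = 2, n_intervals = 20))
  ens <- run_ensemble(spec)
  expect_true(all(ens[["0"]]$dsb$total_dsb == 0))
})
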