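# Hybrid engine: continuous limit, stochastic law, hybrid coupling,
# determinism.

test_that("pure-continuous decay matches the closed form", {
  net <- make_decay_cpn(A0 = 5, d = 0.3)
  cfg <- hpn_sim_config(t_end = 10, n_intervals = 200, rtol = 1e-10,
                        atol = 1e-12)
  tr <- simulate_hpn(net, cfg)
  expect_lt(max(abs(tr$A - attr(net, "closed_form")(tr$Time))), 1e-6)

  flat <- make_decay_cpn(A0 = 5, d = 0)
  tr2 <- simulate_hpn(flat, hpn_sim_config(t_end = 10, n_intervals = 50))
  expect_equal(tr2$A, rep(5, 51))

  zero <- make_decay_cpn(A0 = 0, d = 0.3)
  tr3 <- simulate_hpn(zero, hpn_sim_config(t_end = 10, n_intervals = 50))
  expect_equal(tr3$A, rep(0, 51))
})

test_that("pure-stochastic birth-death reaches the M/M/inf stationary law", {
  net <- make_birth_death_spn(lam = 10, mu = 1)
  cfg <- hpn_sim_config(t_end = 100, n_intervals = 200)
  runs <- lapply(1:200, function(i) {
    cfg$seed <- 1000 + i
    simulate_hpn(net, cfg)
  })
  # discrete markings stay non-negative integers at every grid point
  for (tr in runs[1:10])
    expect_true(all(tr$A >= 0 & tr$A == round(tr$A)))
  # per-run time averages over [50, 100] are i.i.d. across runs
  sel <- runs[[1]]$Time >= 50
  means <- vapply(runs, function(tr) mean(tr$A[sel]), 0)
  se <- stats::sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 10), 3 * se)

  # end states are independent draws from the stationary law Poisson(10)
  finals <- vapply(runs, function(tr) tr$A[nrow(tr)], 0)
  breaks <- c(-Inf, 5:15, Inf)
  obs <- table(cut(finals, breaks))
  pr <- diff(stats::ppois(c(-Inf, 5:15, Inf), 10))
  chi <- suppressWarnings(stats::chisq.test(as.numeric(obs), p = pr))
  expect_gt(chi$p.value, 0.01)
})

test_that("birth-death firing delays have the exponential mean", {
  # single constant-rate transition: inter-event times are Exp(a)
  net <- hpn_model(
    places = list(hpn_place("N", "discrete", 0)),
    transitions = list(hpn_transition("arrive", "stochastic", rate = "a")),
    arcs = list(hpn_arc("arrive", "N")), constants = list(a = 4))
  cfg <- hpn_sim_config(t_end = 2500, n_intervals = 100, seed = 5)
  tr <- simulate_hpn(net, cfg)
  n_events <- tr$N[nrow(tr)]
  # mean waiting time = total time / events ~ 1/a within 3 SE
  expect_gt(n_events, 1000)
  se <- (1 / 4) / sqrt(n_events)
  expect_lt(abs(2500 / n_events - 1 / 4), 3 * se)
})

test_that("hybrid transport motif matches the pure-death expectation", {
  net <- make_transport_hybrid(N0 = 50, k = 1, w = 0.00847)
  cfg <- hpn_sim_config(t_end = 1, n_intervals = 20)
  finals <- vapply(1:300, function(i) {
    cfg$seed <- 2000 + i
    tr <- simulate_hpn(net, cfg)
    tr$A_c[nrow(tr)]
  }, 0)
  want <- attr(net, "mean_law")(1)          # w * N0 * (1 - e^-1)
  se <- stats::sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - want), 3 * se)
})

test_that("time-varying hazards follow the integrated-hazard law", {
  # jump propensity k * A_c with A_c(t) = e^(-t): survival
  # S(t) = exp(-k (1 - e^(-t))); checked by Kolmogorov-Smirnov on the
  # probability-integral transform of the first firing times
  net <- hpn_model(
    places = list(hpn_place("A_c", "continuous", 1),
                  hpn_place("N", "discrete", 0)),
    transitions = list(
      hpn_transition("decay", "continuous", rate = "A_c"),
      hpn_transition("jump", "stochastic", rate = "2 * A_c")),
    arcs = list(hpn_arc("A_c", "decay"),
                hpn_arc("A_c", "jump", kind = "modifier"),
                hpn_arc("jump", "N")))
  expect_false(hpnfate:::compile_hpn(net)$decoupled)
  cfg <- hpn_sim_config(t_end = 8, n_intervals = 800)
  first_fire <- vapply(1:300, function(i) {
    cfg$seed <- 3000 + i
    tr <- simulate_hpn(net, cfg)
    w <- which(tr$N >= 1)
    if (length(w)) tr$Time[w[1]] else NA_real_
  }, 0)
  cdf <- function(t) 1 - exp(-2 * (1 - exp(-t)))
  obs <- first_fire[!is.na(first_fire)]
  expect_gt(length(obs), 200)
  u <- cdf(obs) / cdf(8)
  ks <- suppressWarnings(stats::ks.test(u, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("zero total propensity yields a still trace", {
  net <- make_birth_death_spn(lam = 0, mu = 1, A0 = 0)
  tr <- simulate_hpn(net, hpn_sim_config(t_end = 10, n_intervals = 20, seed = 1))
  expect_equal(tr$A, rep(0, 21))
})

test_that("identical seed and config reproduce the identical trace", {
  net <- make_transport_hybrid(N0 = 20, k = 0.7, w = 0.5)
  cfg <- hpn_sim_config(t_end = 5, n_intervals = 100, seed = 99)
  expect_identical(simulate_hpn(net, cfg), simulate_hpn(net, cfg))

  m <- build_cellfate_model()
  cfg2 <- hpn_sim_config(t_end = 6, n_intervals = 100, seed = 4)
  expect_identical(simulate_hpn(m, cfg2), simulate_hpn(m, cfg2))
})

test_that("compiled and reference event loops produce the same trace", {
  m <- build_cellfate_model()
  cm <- hpnfate:::compile_hpn(m)
  cfg <- hpn_sim_config(t_end = 12, n_intervals = 200)
  for (s in 1:3) {
    set.seed(s); d <- sample_dsb(2.5)
    a <- hpnfate:::.simulate_compiled(cm, cfg,
                                      init = c(DSB = d$total_dsb, IR = 1),
                                      use_compiled = TRUE)
    set.seed(s); d <- sample_dsb(2.5)
    b <- hpnfate:::.simulate_compiled(cm, cfg,
                                      init = c(DSB = d$total_dsb, IR = 1),
                                      use_compiled = FALSE)
    expect_identical(a, b)
  }
})

test_that("grid refinement changes recorded values only within tolerance", {
  net <- make_decay_cpn(A0 = 5, d = 0.3)
  c1 <- hpn_sim_config(t_end = 10, n_intervals = 200)
  c2 <- hpn_sim_config(t_end = 10, n_intervals = 400)
  t1 <- simulate_hpn(net, c1)
  t2 <- simulate_hpn(net, c2)
  shared <- t2$Time %in% t1$Time
  expect_lt(max(abs(t2$A[shared] - t1$A)), 1e-5)
})

test_that("immediate-transition livelock is detected", {
  net <- hpn_model(
    places = list(hpn_place("A", "discrete", 1), hpn_place("B", "discrete", 0)),
    transitions = list(hpn_transition("im1", "immediate", priority = 2L),
                       hpn_transition("im2", "immediate", priority = 1L)),
    arcs = list(hpn_arc("A", "im1"), hpn_arc("im1", "B"),
                hpn_arc("B", "im2"), hpn_arc("im2", "A")))
  expect_error(simulate_hpn(net, hpn_sim_config(t_end = 1, n_intervals = 10)),
               "livelock")
})

test_that("population_mean averages pointwise and validates grids", {
  tr <- make_pulse_trace(1, n_points = 50)
  expect_trace_equal(population_mean(list(tr, tr)), tr)
  z <- hpn_trace(tr$Time, list(p53 = rep(0, nrow(tr))))
  two <- hpn_trace(tr$Time, list(p53 = rep(2, nrow(tr))))
  expect_equal(population_mean(list(z, two))$p53, rep(1, nrow(tr)))
  short <- hpn_trace(tr$Time[1:10], list(p53 = rep(0, 10)))
  expect_error(population_mean(list(tr, short)), "same time grid")
})

test_that("assemble_odes matches the net flow rules", {
  decay <- make_decay_cpn(A0 = 2, d = 1)
  expect_equal(assemble_odes(decay), c(A = -2))

  # association / dissociation: dA/dt = -f A B + r A_B (and symmetric for B)
  net <- hpn_model(
    places = list(hpn_place("A", "continuous", 2), hpn_place("B", "continuous", 3),
                  hpn_place("A_B", "continuous", 4)),
    transitions = list(hpn_transition("bind", "continuous", rate = "f * A * B"),
                       hpn_transition("unbind", "continuous", rate = "r * A_B")),
    arcs = list(hpn_arc("A", "bind"), hpn_arc("B", "bind"), hpn_arc("bind", "A_B"),
                hpn_arc("A_B", "unbind"), hpn_arc("unbind", "A"),
                hpn_arc("unbind", "B")),
    constants = list(f = 0.5, r = 0.25))
  dy <- assemble_odes(net)
  expect_equal(dy[["A"]], -0.5 * 2 * 3 + 0.25 * 4)
  expect_equal(dy[["B"]], -0.5 * 2 * 3 + 0.25 * 4)
  expect_equal(dy[["A_B"]], 0.5 * 2 * 3 - 0.25 * 4)

  # stochastic transitions contribute nothing to the flows
  tp <- make_transport_hybrid(10, 1, 0.5)
  expect_equal(assemble_odes(tp), c(A_c = 0))
})

test_that("next_stochastic_event draws exponential firing times", {
  net <- make_birth_death_spn(lam = 4, mu = 1, A0 = 0)   # only birth enabled
  set.seed(21)
  times <- replicate(2000, {
    ev <- next_stochastic_event(net, initial_state(net), t_end = 100)
    ev$time
  })
  se <- stats::sd(times) / sqrt(length(times))
  expect_lt(abs(mean(times) - 1 / 4), 3 * se)

  # zero total propensity: no event before the horizon
  dead <- make_birth_death_spn(lam = 0, mu = 1, A0 = 0)
  expect_null(next_stochastic_event(dead, initial_state(dead), t_end = 10))
})
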