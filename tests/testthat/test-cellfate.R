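# Cell-fate model: DSB input law, structure, transport bridge, controls.

test_that("DSB input follows the Poisson law with the 70/30 split", {
  set.seed(1)
  for (i in 1:20) expect_equal(sample_dsb(0)$total_dsb, 0L)

  d <- list(total_dsb = 10L, sdsb = round(0.7 * 10))
  expect_equal(d$sdsb, 7)
  set.seed(2)
  draws <- replicate(2000, sample_dsb(2.5)$total_dsb)
  se <- stats::sd(draws) / sqrt(length(draws)) / 2.5
  expect_lt(abs(mean(draws) / 2.5 - 35), 3 * se)

  set.seed(3)
  for (i in 1:50) {
    s <- sample_dsb(stats::runif(1, 0, 6))
    expect_equal(s$sdsb + s$cdsb, s$total_dsb)
    expect_equal(s$sdsb, round(0.7 * s$total_dsb))
    expect_gte(s$cdsb, 0)
  }
  expect_error(sample_dsb(-1), "non-negative")
})

test_that("the built model has the exact node census", {
  m <- build_cellfate_model()
  census <- hpn_census(m)
  expect_equal(census[["discrete_places"]], 29L)
  expect_equal(census[["stochastic_transitions"]], 52L)
  expect_equal(census[["continuous_places"]], 45L)
  expect_equal(census[["continuous_transitions"]], 69L)
  expect_equal(census[["immediate_transitions"]], 1L)
  expect_length(validate_hpn(m), 0L)
})

test_that("missing kinetic parameters are reported by name", {
  p <- surrogate_params()
  p$constants$k_rep_s <- NULL
  expect_error(build_cellfate_model(p), "missing parameter.*k_rep_s")
})

test_that("mRNA transport transitions carry the trans ratio onto continuous places", {
  m <- build_cellfate_model()
  kinds <- vapply(m$places, `[[`, "", "kind")
  for (tid in c("transport_p21", "transport_Bax", "transport_PIDD",
                "transport_Bcl2")) {
    post <- Filter(function(a) a$kind == "standard" && a$source == tid, m$arcs)
    expect_length(post, 1L)
    expect_equal(kinds[[post[[1]]$target]], "continuous")
    expect_equal(post[[1]]$weight, "trans_ratio")
  }
  expect_equal(m$constants$trans_ratio, 0.00847)
})

test_that("count conversion follows C = N / (N_A V_c)", {
  expect_equal(concentration_from_count(0), 0)
  got <- concentration_from_count(1)
  expect_equal(got, 1 / (6.02214076e23 * 1.96e-12) * 1e9, tolerance = 1e-12)
  expect_equal(got, 8.47e-4, tolerance = 1e-3)
  # the shipped trans ratio is the configurable constant, not the formula value
  expect_equal(conversion_constants()$trans_ratio, 0.00847)
})

test_that("Div_IR splits the DSB pool once at t = 0 and only under irradiation", {
  m <- build_cellfate_model()
  cm <- hpnfate:::compile_hpn(m)
  cfg <- hpn_sim_config(t_end = 0.02, n_intervals = 2, seed = 1)
  tr <- hpnfate:::.simulate_compiled(cm, cfg, init = c(DSB = 10, IR = 1))
  expect_equal(tr$DSB_open[1], 10)   # split happened before the first sample
  # the split is exactly round(0.7 * DSB) / remainder
  s0 <- fire_transition(m, "Div_IR",
                        local({
                          st <- initial_state(m)
                          st$discrete[["DSB"]] <- 11
                          st$discrete[["IR"]] <- 1
                          st
                        }))
  expect_equal(s0$discrete[["SDSB"]], 8)   # round(7.7)
  expect_equal(s0$discrete[["CDSB"]], 3)
  expect_equal(s0$discrete[["DSB"]], 0)
  expect_equal(s0$discrete[["IR"]], 0)
  expect_false(is_enabled(m, "Div_IR", s0))  # fires exactly once

  no_ir <- initial_state(m)
  expect_false(is_enabled(m, "Div_IR", no_ir))
})

test_that("the network contains the p53-Mdm2 and ATM-p53-Wip1 feedback cycles", {
  m <- build_cellfate_model()
  # reachability over the directed bipartite graph (modifier arcs included:
  # they carry regulatory influence into rate laws)
  edges <- do.call(rbind, lapply(m$arcs, function(a) c(a$source, a$target)))
  reach <- function(from, to) {
    seen <- character(); frontier <- from
    while (length(frontier)) {
      nxt <- unique(edges[edges[, 1] %in% frontier, 2])
      nxt <- setdiff(nxt, seen)
      if (to %in% nxt) return(TRUE)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    FALSE
  }
  expect_true(reach("p53", "Mdm2"))
  expect_true(reach("Mdm2", "p53"))
  expect_true(reach("ATM", "Wip1"))
  expect_true(reach("Wip1", "ATM"))
  expect_true(reach("ATMP", "p53_P"))
})

test_that("without irradiation total p53 stays below the low threshold", {
  se <- surrogate_ensembles()
  traces0 <- se$ens[["0"]]$traces
  frac_quiet <- mean(vapply(traces0, function(tr) max(tr$p53) < 920, NA))
  expect_gt(frac_quiet, 0.95)
  expect_true(all(se$ens[["0"]]$dsb$total_dsb == 0))
})

test_that("at 2.5 Gy a substantial fraction of runs crosses the upper threshold", {
  se <- surrogate_ensembles()
  traces <- se$ens[["2.5"]]$traces[1:100]
  frac_cross <- mean(vapply(traces, function(tr) any(tr$p53 > 1800), NA))
  expect_gte(frac_cross, 0.2)
})
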