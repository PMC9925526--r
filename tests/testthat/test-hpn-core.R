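# Static semantics: validation, enabling, propensities, firing.

table2_motif <- function() {
  # discrete pre-place, stochastic transport transition, continuous
  # post-place carrying the molecules-to-nM weight
  hpn_model(
    places = list(hpn_place("A_n", "discrete", 4),
                  hpn_place("A_c", "continuous", 0)),
    transitions = list(hpn_transition("transport", "stochastic",
                                      rate = "k * A_n")),
    arcs = list(hpn_arc("A_n", "transport"),
                hpn_arc("transport", "A_c", weight = 0.00847)),
    constants = list(k = 0.5), validate = FALSE)
}

test_that("validation accepts the transport motif and flags broken nets", {
  expect_length(validate_hpn(table2_motif()), 0L)

  bad <- hpn_model(
    places = list(hpn_place("A", "discrete", 1), hpn_place("B", "discrete", 0)),
    transitions = list(hpn_transition("t1", "stochastic", rate = "A")),
    arcs = list(hpn_arc("A", "B")),   # place -> place
    validate = FALSE)
  expect_match(validate_hpn(bad), "alternate place/transition", all = FALSE)

  frac <- hpn_model(
    places = list(hpn_place("A", "discrete", 2.5)),
    transitions = list(hpn_transition("t1", "stochastic", rate = "A")),
    arcs = list(hpn_arc("A", "t1")), validate = FALSE)
  expect_match(validate_hpn(frac), "non-negative integer", all = FALSE)

  dangling <- hpn_model(
    places = list(hpn_place("A", "discrete", 1)),
    transitions = list(hpn_transition("t1", "stochastic", rate = "A")),
    arcs = list(hpn_arc("A", "t1"), hpn_arc("ghost", "t1")), validate = FALSE)
  expect_match(validate_hpn(dangling), "dangling", all = FALSE)

  stray <- hpn_model(
    places = list(hpn_place("A", "discrete", 1), hpn_place("B", "discrete", 1)),
    transitions = list(hpn_transition("t1", "stochastic", rate = "A * B")),
    arcs = list(hpn_arc("A", "t1")), validate = FALSE)
  expect_match(validate_hpn(stray), "not connected", all = FALSE)

  modw <- hpn_model(
    places = list(hpn_place("A", "discrete", 1)),
    transitions = list(hpn_transition("t1", "stochastic", rate = "A")),
    arcs = list(hpn_arc("A", "t1"),
                structure(list(source = "A", target = "t1", kind = "modifier",
                               weight = 2), class = "hpn_arc")),
    validate = FALSE)
  expect_match(validate_hpn(modw), "carry no weight", all = FALSE)
})

test_that("enabling requires sufficient pre-place marking", {
  m <- hpn_model(
    places = list(hpn_place("A", "discrete", 0)),
    transitions = list(hpn_transition("deg", "stochastic", rate = "d * A")),
    arcs = list(hpn_arc("A", "deg")), constants = list(d = 1))
  s0 <- initial_state(m)
  expect_false(is_enabled(m, "deg", s0))
  s3 <- hpn_state(0, discrete = c(A = 3))
  expect_true(is_enabled(m, "deg", s3))
  expect_error(is_enabled(m, "nope", s0), "unknown transition")
})

test_that("propensities follow the mass-action forms and vanish when disabled", {
  syn <- hpn_model(
    places = list(hpn_place("A", "discrete", 3), hpn_place("B", "discrete", 0)),
    transitions = list(hpn_transition("synB", "stochastic", rate = "s * A")),
    arcs = list(hpn_arc("A", "synB", kind = "modifier"), hpn_arc("synB", "B")),
    constants = list(s = 2))
  expect_equal(propensity(syn, "synB", initial_state(syn)), 6)

  assoc <- hpn_model(
    places = list(hpn_place("A", "discrete", 0), hpn_place("B", "discrete", 5),
                  hpn_place("A_B", "discrete", 0)),
    transitions = list(hpn_transition("bind", "stochastic", rate = "f * A * B")),
    arcs = list(hpn_arc("A", "bind"), hpn_arc("B", "bind"),
                hpn_arc("bind", "A_B")),
    constants = list(f = 1))
  expect_equal(propensity(assoc, "bind", initial_state(assoc)), 0)

  tp <- table2_motif()
  expect_equal(propensity(tp, "transport", initial_state(tp)), 0.5 * 4)
})

test_that("firing moves tokens by evaluated weights without mutating input", {
  diss <- hpn_model(
    places = list(hpn_place("A_P", "discrete", 1), hpn_place("A", "discrete", 0)),
    transitions = list(hpn_transition("diss", "stochastic", rate = "k * A_P")),
    arcs = list(hpn_arc("A_P", "diss"), hpn_arc("diss", "A", weight = 2)),
    constants = list(k = 1))
  s0 <- initial_state(diss)
  s1 <- fire_transition(diss, "diss", s0)
  expect_equal(s1$discrete[["A_P"]], 0)
  expect_equal(s1$discrete[["A"]], 2)
  expect_equal(s0$discrete[["A_P"]], 1)   # input untouched
  expect_identical(s1$time, s0$time)

  tp <- table2_motif()
  s1 <- fire_transition(tp, "transport", initial_state(tp))
  expect_equal(s1$discrete[["A_n"]], 3)
  expect_equal(s1$continuous[["A_c"]], 0.00847)

  loop <- hpn_model(
    places = list(hpn_place("A", "discrete", 2)),
    transitions = list(hpn_transition("self", "stochastic", rate = "A")),
    arcs = list(hpn_arc("A", "self"), hpn_arc("self", "A")))
  s1 <- fire_transition(loop, "self", initial_state(loop))
  expect_equal(s1$discrete[["A"]], 2)

  empty <- hpn_state(0, discrete = c(A_P = 0, A = 0))
  expect_error(fire_transition(diss, "diss", empty), "not enabled")
})

test_that("firing conserves tokens when in-weight equals out-weight", {
  set.seed(11)
  for (rep in 1:20) {
    m <- random_conserving_net()
    s <- initial_state(m)
    for (tid in names(m$transitions)) {
      if (!is_enabled(m, tid, s)) next
      s2 <- fire_transition(m, tid, s)
      expect_equal(sum(s2$discrete), sum(s$discrete))
      s <- s2
    }
  }
})

test_that("fire then un-fire restores the original state exactly", {
  set.seed(12)
  for (rep in 1:10) {
    m <- random_conserving_net()
    s <- initial_state(m)
    for (tid in names(m$transitions)) {
      if (!is_enabled(m, tid, s)) next
      s2 <- fire_transition(m, tid, s)
      delta <- s2$discrete - s$discrete
      restored <- s2$discrete - delta
      expect_identical(restored, s$discrete)
    }
  }
})
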