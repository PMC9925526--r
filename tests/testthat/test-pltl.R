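# PLTL parsing and finite-trace semantics.

test_that("parser handles the probability operator and precedence", {
  f <- parse_pltl("P=? [ G (p53 < 920) ]")
  expect_equal(f$mode, "query")
  expect_equal(f$body$kind, "G")
  expect_equal(f$body$children[[1]]$kind, "cmp")

  b <- parse_pltl("P>=0.5 [ F (x > 1) ]")
  expect_equal(b$mode, "bound")
  expect_equal(b$cmp, ">=")
  expect_equal(b$x, 0.5)

  # unary > & > | > -> > U
  g <- parse_pltl("P=? [ !x > 1 & y < 2 | a = 1 U b != 0 ]")
  expect_equal(g$body$kind, "U")
  lhs <- g$body$children[[1]]
  expect_equal(lhs$kind, "or")
  expect_equal(lhs$children[[1]]$kind, "and")
  expect_equal(lhs$children[[1]]$children[[1]]$kind, "not")

  # implication desugars to !a | b
  h <- parse_pltl("P=? [ (x > 1) -> (y > 2) ]")
  expect_equal(h$body$kind, "or")
  expect_equal(h$body$children[[1]]$kind, "not")
})

test_that("parser reports errors with positions and rejects bad bounds", {
  expect_error(parse_pltl("P=? [ G ]"), "missing operand|expected")
  expect_error(parse_pltl("P=? [ x > ]"), "syntax error")
  expect_error(parse_pltl("G (x > 1)"), "must start with")
  expect_error(parse_pltl("P>=1.5 [ F (x > 1) ]"), "\\[0, 1\\]")
  expect_error(parse_pltl("P=? [ x > 1 ] trailing"), "trailing")
})

test_that("parse and format round-trip on random formulas", {
  set.seed(42)
  for (i in 1:200) {
    txt <- sprintf("P=? [ %s ]", random_ltl_text(3L, c("x", "y")))
    f <- parse_pltl(txt)
    expect_identical(parse_pltl(format(f)), f)
  }
  b <- parse_pltl("P<0.25 [ X (x > 1) ]")
  expect_identical(parse_pltl(format(b)), b)
})

test_that("vectorised evaluator agrees with the naive recursive oracle", {
  set.seed(101)
  n_checked <- 0L
  for (i in 1:1000) {
    tr <- random_trace(sample(4:9, 1L), c("x", "y"))
    f <- parse_pltl(sprintf("P=? [ %s ]", random_ltl_text(3L, c("x", "y"))))
    pos <- sample(nrow(tr), 1L)
    got <- eval_ltl(f$body, tr, pos)
    want <- naive_eval_ltl(f$body, tr, pos)
    if (!identical(got, want)) {
      fail(sprintf("disagreement on %s at position %d", format(f), pos))
    }
    n_checked <- n_checked + 1L
  }
  expect_equal(n_checked, 1000L)
})

test_that("temporal dualities hold on random traces", {
  set.seed(202)
  for (i in 1:100) {
    tr <- random_trace(8L, c("x"))
    body <- sprintf("(%s)", random_ltl_text(2L, "x"))
    g <- parse_pltl(sprintf("P=? [ G %s ]", body))$body
    notfnot <- parse_pltl(sprintf("P=? [ !(F (!%s)) ]", body))$body
    f_ <- parse_pltl(sprintf("P=? [ F %s ]", body))$body
    tu <- parse_pltl(sprintf("P=? [ true U %s ]", body))$body
    for (pos in seq_len(nrow(tr))) {
      expect_identical(eval_ltl(g, tr, pos), eval_ltl(notfnot, tr, pos))
      expect_identical(eval_ltl(f_, tr, pos), eval_ltl(tu, tr, pos))
    }
  }
})

test_that("next is strong at the final position", {
  tr <- hpn_trace(0:2, list(x = c(1, 1, 1)))
  xf <- parse_pltl("P=? [ X (x = 1) ]")$body
  expect_true(eval_ltl(xf, tr, 1))
  expect_false(eval_ltl(xf, tr, 3))   # no successor row
})

test_that("check_trace evaluates the body at the first position", {
  props <- builtin_properties()
  flat <- hpn_trace(0:9, list(p53 = rep(900, 10)))
  expect_true(check_trace(props$P1, flat))
  crossing <- hpn_trace(0:9, list(p53 = c(rep(900, 5), rep(1000, 5))))
  expect_false(check_trace(props$P1, crossing))
  capped <- make_pulse_trace(1, baseline = 500, amplitude = 1210,
                             thresholds = threshold_set(920, 1200, 1700),
                             n_points = 200)
  expect_false(check_trace(props$P2, capped))  # max 1710 < 1800 upper threshold
  expect_error(check_trace(props$P1, hpn_trace(0:1, list(x = c(0, 0)))),
               "unknown column")
})

test_that("single- and double-pulse traces satisfy P2 and P3 respectively", {
  props <- builtin_properties()
  one <- make_pulse_trace(1, baseline = 1000, amplitude = 1200, width = 1.2,
                          n_points = 400)
  expect_false(check_trace(props$P1, one))
  expect_true(check_trace(props$P2, one))
  expect_false(check_trace(props$P3, one))
  two <- make_pulse_trace(2, baseline = 1000, amplitude = 1200, width = 1.2,
                          n_points = 400)
  expect_false(check_trace(props$P2, two))
  expect_true(check_trace(props$P3, two))
})

test_that("P1, P2, P3 partition every trace in the corpus", {
  props <- builtin_properties()
  corpus <- pulse_corpus()
  for (tr in corpus$traces) {
    sat <- c(check_trace(props$P1, tr), check_trace(props$P2, tr),
             check_trace(props$P3, tr))
    expect_equal(sum(sat), 1L)
  }
  # an oscillation strictly between T_L and T_U is multi-pulse by formula
  # (documented formula/oracle divergence: the counting oracle sees 0 pulses)
  osc <- hpn_trace(seq(0, 10, length.out = 101),
                   list(p53 = 1200 + 500 * sin(seq(0, 10, length.out = 101))))
  expect_equal(classify_trace(osc), "multi_pulse")
  expect_equal(count_pulses(osc), 0L)
})

test_that("probability estimation is the satisfying fraction", {
  corpus <- pulse_corpus()
  props <- builtin_properties()
  one_idx <- which(corpus$n_pulses == 1L)
  mixed <- c(corpus$traces[one_idx[1:13]], corpus$traces[which(corpus$n_pulses == 0L)[1:7]])
  expect_equal(estimate_probability(props$P2, mixed), 13 / 20)
  expect_equal(estimate_probability(props$P2, corpus$traces[one_idx[1:5]]), 1)
  bound <- parse_pltl(sprintf("P>=0.5 [ %s ]",
                              sub("^P=\\? \\[ (.*) \\]$", "\\1",
                                  format(props$P2))))
  got <- estimate_probability(bound, mixed)
  expect_true(got)                       # 0.65 >= 0.5
  expect_equal(attr(got, "estimate"), 0.65)
  expect_error(estimate_probability(props$P1, list()), "empty")
})

test_that("builtin properties substitute thresholds verbatim", {
  props <- builtin_properties(threshold_set(920, 1200, 1800))
  expect_match(format(props$P1), "p53 < 920", fixed = TRUE)
  expect_match(format(props$P2), "p53 > 1800", fixed = TRUE)
  expect_error(threshold_set(1200, 920, 1800))
})
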