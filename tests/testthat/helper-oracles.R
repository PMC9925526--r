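# Independent oracles and random-case generators shared across test files.

# Naive recursive LTL evaluator: direct transcription of the finite-trace
# semantics, no vectorisation or memoisation.  Deliberately independent of
# the package's evaluator.
naive_eval_ltl <- function(node, trace, i) {
  n <- nrow(trace)
  switch(node$kind,
    bool = node$value,
    cmp = {
      row <- as.list(trace[i, , drop = FALSE])
      lhs <- eval(node$lhs, row, baseenv())
      rhs <- eval(node$rhs, row, baseenv())
      switch(node$op,
             "<" = lhs < rhs, ">" = lhs > rhs,
             "<=" = lhs <= rhs, ">=" = lhs >= rhs,
             "=" = lhs == rhs, "!=" = lhs != rhs)
    },
    not = !naive_eval_ltl(node$children[[1L]], trace, i),
    and = naive_eval_ltl(node$children[[1L]], trace, i) &&
          naive_eval_ltl(node$children[[2L]], trace, i),
    or = naive_eval_ltl(node$children[[1L]], trace, i) ||
         naive_eval_ltl(node$children[[2L]], trace, i),
    X = i + 1L <= n && naive_eval_ltl(node$children[[1L]], trace, i + 1L),
    G = all(vapply(i:n, function(j)
      naive_eval_ltl(node$children[[1L]], trace, j), NA)),
    F = any(vapply(i:n, function(j)
      naive_eval_ltl(node$children[[1L]], trace, j), NA)),
    U = {
      a <- node$children[[1L]]; b <- node$children[[2L]]
      ok <- FALSE
      for (j in i:n) {
        if (naive_eval_ltl(b, trace, j)) { ok <- TRUE; break }
        if (!naive_eval_ltl(a, trace, j)) break
      }
      ok
    },
    stop("unknown node kind"))
}

# Random LTL formula over columns `cols`, as a parse string.
random_ltl_text <- function(depth, cols) {
  if (depth <= 0L || stats::runif(1) < 0.3) {
    col <- sample(cols, 1L)
    op <- sample(c("<", ">", "<=", ">=", "=", "!="), 1L)
    thr <- sample(0:5, 1L)
    return(sprintf("%s %s %d", col, op, thr))
  }
  pick <- sample(c("not", "and", "or", "X", "G", "F", "U", "arrow"), 1L)
  a <- random_ltl_text(depth - 1L, cols)
  b <- random_ltl_text(depth - 1L, cols)
  switch(pick,
         not = sprintf("!(%s)", a),
         and = sprintf("(%s) & (%s)", a, b),
         or = sprintf("(%s) | (%s)", a, b),
         X = sprintf("X (%s)", a),
         G = sprintf("G (%s)", a),
         F = sprintf("F (%s)", a),
         U = sprintf("(%s) U (%s)", a, b),
         arrow = sprintf("(%s) -> (%s)", a, b))
}

# Random short trace with small integer values (ties with atom thresholds on
# purpose, to exercise comparison edge cases).
random_trace <- function(len, cols) {
  vals <- lapply(cols, function(...) as.numeric(sample(0:5, len, replace = TRUE)))
  hpn_trace(seq_len(len) - 1, stats::setNames(vals, cols))
}

# Random mass-action net whose transitions all have equal total in/out weight
# (so firing conserves tokens) -- for the conservation property.
random_conserving_net <- function(n_places = 4L, n_trans = 5L) {
  pids <- paste0("P", seq_len(n_places))
  places <- lapply(pids, function(p)
    hpn_place(p, "discrete", sample(0:5, 1L)))
  transitions <- list(); arcs <- list()
  for (k in seq_len(n_trans)) {
    tid <- paste0("T", k)
    w <- sample(1:2, 1L)
    from <- sample(pids, 1L); to <- sample(pids, 1L)
    transitions[[k]] <- hpn_transition(tid, "stochastic",
                                       rate = sprintf("%g * %s", stats::runif(1, 0.1, 2), from))
    arcs <- c(arcs, list(hpn_arc(from, tid, weight = w),
                         hpn_arc(tid, to, weight = w)))
  }
  hpn_model(places, transitions, arcs, name = sprintf("conserve%d", n_trans))
}

expect_trace_equal <- function(a, b, tolerance = 0) {
  expect_identical(names(a), names(b))
  strip <- function(x) as.data.frame(lapply(unclass(x), as.numeric),
                                     optional = TRUE)
  if (tolerance == 0) expect_identical(strip(a), strip(b))
  else expect_equal(strip(a), strip(b), tolerance = tolerance)
}
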