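# Shared surrogate ensembles, computed once per test session and reused by
# the cell-fate, synthetic-data and acceptance tests.  Study conditions: the
# default 48 h horizon with 2000 output intervals, 200 runs per dose at
# 0, 0.3, 2.5 and 6 Gy, base seed 42.

.ens_cache <- new.env(parent = emptyenv())

surrogate_ensembles <- function() {
  if (is.null(.ens_cache$ens)) {
    spec <- ensemble_spec(ir_doses = c(0, 0.3, 2.5, 6), n_runs = 200,
                          base_seed = 42,
                          config = hpn_sim_config(t_end = 48,
                                                  n_intervals = 2000))
    .ens_cache$spec <- spec
    .ens_cache$ens <- run_ensemble(spec)
  }
  list(spec = .ens_cache$spec, ens = .ens_cache$ens)
}

# 500 noise-free pulse traces with declared counts, shared between the
# classification and partition tests.
pulse_corpus <- function() {
  if (is.null(.ens_cache$corpus)) {
    set.seed(7)
    corpus <- vector("list", 500L)
    truth <- integer(500L)
    for (i in seq_len(500L)) {
      np <- sample(0:3, 1L)
      tr <- make_pulse_trace(
        n_pulses = np,
        baseline = sample(c(300, 500, 800), 1L),
        amplitude = sample(c(1600, 2000, 2500), 1L),
        width = stats::runif(1, 0.6, 1.6),
        noise_sd = 0, t_end = 48, n_points = 400)
      corpus[[i]] <- tr
      truth[i] <- np
    }
    .ens_cache$corpus <- corpus
    .ens_cache$corpus_truth <- truth
  }
  list(traces = .ens_cache$corpus, n_pulses = .ens_cache$corpus_truth)
}
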