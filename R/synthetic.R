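# Synthetic fixtures with declared ground truth: analytically solvable nets
# (pure-continuous decay, birth-death, the hybrid transport motif) and p53-like
# pulse traces with a known pulse count.  These stand in for downloadable data
# so every stage of the pipeline is testable offline, and they double as the
# calibration instruments for the engine.

#' Pure-continuous decay net with closed-form solution
#'
#' One continuous place `A` (initial `A0`) degraded by one continuous
#' transition with rate `d * A`.  The exact trajectory is
#' `A(t) = A0 * exp(-d * t)`, attached as attribute `closed_form`
#' (a function of `t`).
#'
#' @param A0 Initial concentration (>= 0).
#' @param d Degradation rate constant (>= 0, 1/time).
#' @return An `hpn` model with attribute `closed_form`.
#' @export
make_decay_cpn <- function(A0, d) {
  stopifnot(A0 >= 0, d >= 0)
  m <- hpn_model(
    places = list(hpn_place("A", "continuous", A0)),
    transitions = list(hpn_transition("deg_A", "continuous", rate = "d * A")),
    arcs = list(hpn_arc("A", "deg_A")),
    constants = list(d = d),
    name = "decay_cpn")
  attr(m, "closed_form") <- function(t) A0 * exp(-d * t)
  m
}

#' Pure-stochastic birth-death net with known stationary law
#'
#' One discrete place `A`; a birth transition with constant propensity `lam`
#' and a death transition with propensity `mu * A`.  The stationary
#' distribution is Poisson(`lam/mu`) (immigration-death / M/M/inf queue), with
#' stationary mean and variance `lam/mu`, attached as attribute
#' `stationary`.
#'
#' @param lam Birth rate (>= 0, 1/time).
#' @param mu Per-capita death rate (> 0, 1/time).
#' @param A0 Initial token count.
#' @return An `hpn` model with attribute `stationary` (`list(mean, var)`).
#' @export
make_birth_death_spn <- function(lam, mu, A0 = 0) {
  stopifnot(lam >= 0, mu > 0, A0 >= 0)
  m <- hpn_model(
    places = list(hpn_place("A", "discrete", A0)),
    transitions = list(
      hpn_transition("birth", "stochastic", rate = "lam"),
      hpn_transition("death", "stochastic", rate = "mu * A")),
    arcs = list(hpn_arc("birth", "A"), hpn_arc("A", "death")),
    constants = list(lam = lam, mu = mu),
    name = "birth_death_spn")
  attr(m, "stationary") <- list(mean = lam / mu, var = lam / mu)
  m
}

#' Hybrid nucleus-to-cytoplasm transport motif
#'
#' The canonical bridge between the stochastic and continuous regimes: a
#' discrete pre-place `A_n` (initially `N0` molecules), a stochastic transport
#' transition with propensity `k * A_n`, and a continuous post-place `A_c`
#' that gains `w` concentration units per firing (the molecules-to-nM
#' conversion weight).  The ensemble mean of `A_c` is
#' `w * N0 * (1 - exp(-k t))` (each molecule is transported after an
#' independent Exp(k) delay), attached as attribute `mean_law`.
#'
#' @param N0 Initial molecule count (non-negative integer).
#' @param k Per-molecule transport rate (1/time).
#' @param w Post-arc weight: concentration added per transported molecule (nM).
#' @return An `hpn` model with attribute `mean_law` (a function of `t`).
#' @export
make_transport_hybrid <- function(N0, k, w) {
  stopifnot(N0 >= 0, N0 == round(N0), k >= 0, w >= 0)
  m <- hpn_model(
    places = list(hpn_place("A_n", "discrete", N0),
                  hpn_place("A_c", "continuous", 0)),
    transitions = list(hpn_transition("transport", "stochastic",
                                      rate = "k * A_n")),
    arcs = list(hpn_arc("A_n", "transport"),
                hpn_arc("transport", "A_c", weight = w)),
    constants = list(k = k, w = w),
    name = "transport_hybrid")
  attr(m, "mean_law") <- function(t) w * N0 * (1 - exp(-k * t))
  m
}

#' Generate a p53-like pulse trace with declared ground truth
#'
#' Builds a trace directly (bypassing simulation) as a baseline plus a sum of
#' Gaussian bumps, with optional additive Gaussian noise.  With
#' `noise_sd = 0` the construction guarantees the pulse-pattern ground truth:
#' the signal starts below the middle threshold, each bump exceeds the upper
#' threshold, the signal re-arms (drops below the middle threshold) between
#' bumps and settles below it at the end.
#'
#' @param n_pulses Number of pulses (>= 0).
#' @param baseline Resting level; must be below `thresholds$T_M`.
#' @param amplitude Bump height; `baseline + amplitude` must exceed
#'   `thresholds$T_U` when `n_pulses > 0`.
#' @param width Gaussian bump standard deviation (time units).
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param thresholds A [threshold_set()].
#' @param t_end,n_points Time horizon and grid size.
#' @param seed RNG seed used for the noise.
#' @param column Name of the signal column.
#' @return An `hpn_trace` with attribute `pulse_count` (the declared ground
#'   truth).
#' @export
make_pulse_trace <- function(n_pulses, baseline = 500, amplitude = 1500,
                             width = 1, noise_sd = 0,
                             thresholds = threshold_set(),
                             t_end = 48, n_points = 2000, seed = NULL,
                             column = "p53") {
  stopifnot(n_pulses >= 0, n_pulses == round(n_pulses), width > 0,
            noise_sd >= 0)
  if (baseline >= thresholds$T_M)
    stop("baseline must be below the middle threshold", call. = FALSE)
  if (n_pulses > 0 && baseline + amplitude <= thresholds$T_U)
    stop("baseline + amplitude must exceed the upper threshold", call. = FALSE)
  times <- seq(0, t_end, length.out = n_points + 1L)
  y <- rep(baseline, length(times))
  if (n_pulses > 0) {
    centers <- t_end * (seq_len(n_pulses) - 0.5) / n_pulses
    sep <- if (n_pulses > 1) diff(centers)[1L] else Inf
    # between-pulse trough and trace ends must sit below T_M for the declared
    # count to be unambiguous
    trough <- baseline + 2 * amplitude * exp(-(sep / 2)^2 / (2 * width^2))
    edge <- baseline + amplitude * exp(-(min(centers, t_end - max(centers)))^2 /
                                         (2 * width^2))
    if (trough >= thresholds$T_M || edge >= thresholds$T_M)
      stop("infeasible pulse geometry: signal does not re-arm below the middle threshold",
           call. = FALSE)
    for (ct in centers) y <- y + amplitude * exp(-(times - ct)^2 / (2 * width^2))
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + stats::rnorm(length(y), 0, noise_sd)
  }
  tr <- hpn_trace(times, stats::setNames(list(y), column))
  attr(tr, "pulse_count") <- as.integer(n_pulses)
  tr
}

#' Write the full fixture collection to a directory
#'
#' Generates every offline test fixture with its declared ground truth: the
#' three analytically solvable nets (as model files), the surrogate parameter
#' file, noise-free and noisy pulse traces (as trace CSVs), and a
#' machine-readable JSON manifest recording each fixture's ground truth
#' (closed form parameters, stationary moments, or pulse count) and the seed.
#'
#' @param dir Output directory (created if needed).
#' @param seed Seed used for the noisy pulse traces.
#' @return Invisibly, the manifest as a list.
#' @export
gen_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = seed, fixtures = list())
  add <- function(name, file, ground_truth) {
    manifest$fixtures[[name]] <<- list(file = file, ground_truth = ground_truth)
  }

  decay <- make_decay_cpn(A0 = 5, d = 0.3)
  write_hpn_model(decay, file.path(dir, "decay_cpn.hpn"))
  add("decay_cpn", "decay_cpn.hpn",
      list(kind = "closed_form", A0 = 5, d = 0.3,
           trajectory = "A0 * exp(-d * t)"))

  bd <- make_birth_death_spn(lam = 10, mu = 1)
  write_hpn_model(bd, file.path(dir, "birth_death_spn.hpn"))
  add("birth_death_spn", "birth_death_spn.hpn",
      list(kind = "stationary", law = "Poisson(lam/mu)", mean = 10, var = 10))

  tp <- make_transport_hybrid(N0 = 50, k = 1, w = 0.00847)
  write_hpn_model(tp, file.path(dir, "transport_hybrid.hpn"))
  add("transport_hybrid", "transport_hybrid.hpn",
      list(kind = "mean_law", law = "w * N0 * (1 - exp(-k*t))",
           N0 = 50, k = 1, w = 0.00847))

  write_parameter_set(surrogate_params(),
                      file.path(dir, "params_surrogate.txt"))
  add("params_surrogate", "params_surrogate.txt",
      list(kind = "parameter_set", provenance = "surrogate"))

  for (np in 0:3) {
    tr <- make_pulse_trace(np, baseline = 500, amplitude = 1500, width = 1,
                           noise_sd = 0)
    f <- sprintf("pulse_%d.csv", np)
    write_trace_csv(tr, file.path(dir, f))
    add(sprintf("pulse_%d", np), f,
        list(kind = "pulse_count", n_pulses = np, noise_sd = 0))
  }
  trn <- make_pulse_trace(2, baseline = 500, amplitude = 1500, width = 1,
                          noise_sd = 75, seed = seed)
  write_trace_csv(trn, file.path(dir, "pulse_2_noisy.csv"))
  add("pulse_2_noisy", "pulse_2_noisy.csv",
      list(kind = "pulse_count", n_pulses = 2, noise_sd = 75, seed = seed))

  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
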