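# Verification pipeline: per-dose ensembles of seeded model variants,
# property checking over the resulting traces, and the per-dose report of
# estimated pulse-count probabilities.

#' Ensemble specification
#'
#' @param ir_doses Radiation doses in Gray.
#' @param n_runs Runs (model variants) per dose.
#' @param base_seed Base RNG seed; run `i` of dose `d` uses
#'   `base_seed + (d_index - 1) * n_runs + (i - 1)`.
#' @param config An [hpn_sim_config()] shared by all runs.
#' @param thresholds A [threshold_set()], or a list of one per dose (named by
#'   dose or positional).
#' @return An `ensemble_spec` record.
#' @export
ensemble_spec <- function(ir_doses = c(0.3, 2.5, 6), n_runs = 1000,
                          base_seed = 1,
                          config = hpn_sim_config(t_end = 48,
                                                  n_intervals = 2000),
                          thresholds = threshold_set()) {
  stopifnot(n_runs >= 1, all(ir_doses >= 0))
  if (inherits(thresholds, "threshold_set"))
    thresholds <- rep(list(thresholds), length(ir_doses))
  stopifnot(length(thresholds) == length(ir_doses))
  structure(list(ir_doses = ir_doses, n_runs = as.integer(n_runs),
                 base_seed = as.integer(base_seed), config = config,
                 thresholds = thresholds),
            class = "ensemble_spec")
}

#' Simulate per-dose ensembles of cell-fate model variants
#'
#' For each dose, `spec$n_runs` model variants are generated: each variant
#' draws its own Poisson DSB input ([sample_dsb()]) and is simulated with its
#' own seed, so re-running with the same spec reproduces every trace exactly.
#' Optionally each trace is written to `<out_dir>/dose<d>/run<i>.csv`.
#'
#' @param spec An [ensemble_spec()].
#' @param params,constants Passed to [build_cellfate_model()].
#' @param model Optionally a prebuilt model (overrides `params`/`constants`);
#'   it must contain the `IR` and `DSB` input places.
#' @param out_dir Directory for CSV output, or `NULL` for in-memory only.
#' @param verbose Print one line per dose.
#' @return A named list (one entry per dose) of lists with elements `traces`
#'   (list of `hpn_trace`), `dsb` (data frame of the sampled DSB inputs) and
#'   `seeds`.
#' @export
run_ensemble <- function(spec, params = surrogate_params(),
                         constants = conversion_constants(), model = NULL,
                         out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(spec, "ensemble_spec"))
  if (is.null(model)) model <- build_cellfate_model(params, constants)
  stopifnot(all(c("IR", "DSB") %in% place_ids(model)))
  cm <- compile_hpn(model)
  out <- list()
  for (di in seq_along(spec$ir_doses)) {
    dose <- spec$ir_doses[[di]]
    traces <- vector("list", spec$n_runs)
    dsb <- data.frame(run = seq_len(spec$n_runs), seed = NA_integer_,
                      total_dsb = NA_integer_, sdsb = NA_integer_,
                      cdsb = NA_integer_)
    dir <- NULL
    if (!is.null(out_dir)) {
      dir <- file.path(out_dir, sprintf("dose%s", format(dose)))
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    }
    for (i in seq_len(spec$n_runs)) {
      seed <- spec$base_seed + (di - 1L) * spec$n_runs + (i - 1L)
      set.seed(seed)
      d <- sample_dsb(dose)
      cfg <- spec$config
      cfg$seed <- NULL       # the RNG stream set above covers the whole run
      tr <- .simulate_compiled(cm, cfg,
                               init = c(DSB = d$total_dsb,
                                        IR = as.numeric(d$total_dsb > 0)))
      traces[[i]] <- tr
      dsb$seed[i] <- seed
      dsb$total_dsb[i] <- d$total_dsb
      dsb$sdsb[i] <- d$sdsb
      dsb$cdsb[i] <- d$cdsb
      if (!is.null(dir))
        write_trace_csv(tr, file.path(dir, sprintf("run%04d.csv", i)))
    }
    if (verbose)
      message(sprintf("dose %g Gy: %d runs simulated", dose, spec$n_runs))
    out[[format(dose)]] <- list(dose = dose, traces = traces, dsb = dsb,
                                seeds = dsb$seed, dir = dir)
  }
  out
}

#' Count p53 pulses with a two-state threshold machine
#'
#' Counts maximal excursions of the signal: starting ARMED (signal below the
#' middle threshold `T_M`), a pulse is counted when the signal exceeds the
#' upper threshold `T_U`; the machine re-arms only once the signal has
#' dropped below `T_M` again.  The machine starts armed only if the trace
#' starts below `T_M`.  This is the independent oracle against which the
#' temporal-logic classification is cross-validated.
#'
#' @param trace An `hpn_trace`.
#' @param thresholds A [threshold_set()].
#' @param column Signal column (default `"p53"`).
#' @return Non-negative integer pulse count.
#' @export
count_pulses <- function(trace, thresholds = threshold_set(), column = "p53") {
  if (!column %in% names(trace))
    stop("trace has no column ", sQuote(column), call. = FALSE)
  y <- trace[[column]]
  if (!length(y)) return(0L)
  armed <- y[1L] < thresholds$T_M
  count <- 0L
  for (v in y) {
    if (armed) {
      if (v > thresholds$T_U) { count <- count + 1L; armed <- FALSE }
    } else if (v < thresholds$T_M) armed <- TRUE
  }
  count
}

#' Classify a trace by its p53 pulse pattern
#'
#' Evaluates the three built-in PLTL bodies ([builtin_properties()]) on the
#' trace and returns the unique class that holds: the three properties
#' partition every trace (P3 is defined as neither-P1-nor-P2).
#'
#' @inheritParams count_pulses
#' @return One of `"no_pulse"`, `"one_pulse"`, `"multi_pulse"`.
#' @export
classify_trace <- function(trace, thresholds = threshold_set(),
                           column = "p53") {
  props <- builtin_properties(thresholds, column)
  sat <- c(no_pulse = check_trace(props$P1, trace),
           one_pulse = check_trace(props$P2, trace),
           multi_pulse = check_trace(props$P3, trace))
  if (sum(sat) != 1L)
    stop("internal error: P1/P2/P3 did not partition the trace", call. = FALSE)
  names(sat)[sat]
}

#' Detect p53 peaks in a trace
#'
#' Strict local maxima of the signal above the middle threshold, in time
#' order — used for the damped-oscillation check on population means (peak
#' amplitudes of the averaged signal decrease as runs desynchronise).
#'
#' @inheritParams count_pulses
#' @return Data frame with columns `time` and `amplitude` (possibly empty).
#' @export
detect_peaks <- function(trace, thresholds = threshold_set(), column = "p53") {
  if (!column %in% names(trace))
    stop("trace has no column ", sQuote(column), call. = FALSE)
  y <- trace[[column]]
  n <- length(y)
  if (n < 3L) return(data.frame(time = numeric(), amplitude = numeric()))
  i <- 2L:(n - 1L)
  is_peak <- y[i] > y[i - 1L] & y[i] > y[i + 1L] & y[i] > thresholds$T_M
  idx <- i[is_peak]
  data.frame(time = trace$Time[idx], amplitude = y[idx])
}

#' Estimate the pulse-count probabilities of a trace ensemble
#'
#' @param traces List of `hpn_trace` objects (one dose's ensemble).
#' @param thresholds A [threshold_set()].
#' @param column Signal column.
#' @return Named numeric vector `c(P1 =, P2 =, P3 =)`; the three estimates
#'   sum to one exactly.
#' @export
verify_traces <- function(traces, thresholds = threshold_set(),
                          column = "p53") {
  stopifnot(length(traces) >= 1L)
  props <- builtin_properties(thresholds, column)
  cls <- vapply(traces, classify_trace, "", thresholds = thresholds,
                column = column)
  n <- length(traces)
  c(P1 = sum(cls == "no_pulse") / n,
    P2 = sum(cls == "one_pulse") / n,
    P3 = sum(cls == "multi_pulse") / n)
}

#' Verify the pulse-count properties over per-dose ensembles
#'
#' Estimates, for each dose, the probabilities that total p53 shows zero,
#' one, or two-or-more pulses, as satisfying fractions of the ensemble, with
#' exact binomial 95% confidence intervals.
#'
#' @param ensembles Either the result of [run_ensemble()] or a named list
#'   `dose -> list of traces`.
#' @param spec The [ensemble_spec()] used (supplies per-dose thresholds); or
#'   pass `thresholds` directly.
#' @param thresholds A [threshold_set()] applied to every dose when `spec` is
#'   missing.
#' @param column Signal column.
#' @return A `verification_report`: a data frame with one row per dose and
#'   columns `dose`, `P1`, `P2`, `P3`, `n`, and per-property confidence
#'   bounds.
#' @export
verify_ensemble <- function(ensembles, spec = NULL,
                            thresholds = threshold_set(), column = "p53") {
  rows <- list()
  for (di in seq_along(ensembles)) {
    ent <- ensembles[[di]]
    traces <- if (is.list(ent) && !is.null(ent$traces)) ent$traces else ent
    dose <- if (is.list(ent) && !is.null(ent$dose)) ent$dose
            else suppressWarnings(as.numeric(names(ensembles)[di]))
    th <- if (!is.null(spec)) spec$thresholds[[di]] else thresholds
    est <- verify_traces(traces, th, column)
    n <- length(traces)
    ci <- lapply(est, function(p) stats::binom.test(round(p * n), n)$conf.int)
    rows[[di]] <- data.frame(
      dose = dose, P1 = est[["P1"]], P2 = est[["P2"]], P3 = est[["P3"]], n = n,
      P1_lo = ci$P1[1], P1_hi = ci$P1[2],
      P2_lo = ci$P2[1], P2_hi = ci$P2[2],
      P3_lo = ci$P3[1], P3_hi = ci$P3[2])
  }
  rep <- do.call(rbind, rows)
  rep <- rep[order(rep$dose), , drop = FALSE]
  rownames(rep) <- NULL
  attr(rep, "thresholds") <- if (!is.null(spec)) spec$thresholds else thresholds
  attr(rep, "seeds") <- lapply(ensembles, function(ent)
    if (is.list(ent)) ent$seeds else NULL)
  class(rep) <- c("verification_report", "data.frame")
  rep
}

#' @export
print.verification_report <- function(x, ...) {
  cat("Pulse-count verification report (satisfying fractions, n runs/dose)\n")
  df <- data.frame(dose = x$dose,
                   `P1 (no pulse)` = sprintf("%.3f", x$P1),
                   `P2 (one pulse)` = sprintf("%.3f", x$P2),
                   `P3 (2+ pulses)` = sprintf("%.3f", x$P3),
                   n = x$n, check.names = FALSE)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Load a directory of trace CSVs as an ensemble
#'
#' Reads every `*.csv` under `dir` (recursively, one subdirectory per dose as
#' written by [run_ensemble()]; a flat directory is treated as a single
#' unnamed dose).
#'
#' @param dir Directory containing trace CSV files.
#' @return A named list `dose -> list(traces = ...)` suitable for
#'   [verify_ensemble()].
#' @export
read_trace_dir <- function(dir) {
  if (!dir.exists(dir)) stop("no such directory: ", dir, call. = FALSE)
  subs <- list.dirs(dir, recursive = FALSE)
  subs <- subs[grepl("^dose", basename(subs))]
  load_one <- function(d) {
    files <- sort(list.files(d, pattern = "\\.csv$", full.names = TRUE))
    if (!length(files)) stop("no traces found in ", d, call. = FALSE)
    list(traces = lapply(files, read_trace_csv))
  }
  if (!length(subs)) return(list(`NA` = load_one(dir)))
  out <- lapply(subs, load_one)
  names(out) <- sub("^dose", "", basename(subs))
  for (i in seq_along(out)) out[[i]]$dose <- as.numeric(names(out)[i])
  out
}

#' Write a verification report as CSV
#'
#' @param report A `verification_report`.
#' @param path Output file.
#' @export
write_report_csv <- function(report, path) {
  df <- as.data.frame(report)
  cells <- matrix(vapply(df, .fmt_num, character(nrow(df))),
                  nrow = nrow(df), ncol = ncol(df))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(names(df), collapse = ","),
               apply(cells, 1L, paste, collapse = ",")), con, sep = "\n")
  invisible(path)
}
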