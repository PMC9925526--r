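# Hybrid simulation engine: exact-in-distribution stochastic firing
# interleaved with ODE integration of the continuous subnet.
#
# Two execution paths, identical in distribution where both apply:
#
# * decoupled: when no stochastic/immediate element reads or consumes a
#   continuous place and no continuous element reads a discrete place, the
#   jump process is simulated first (total propensity is piecewise constant,
#   so firing delays are plain exponentials) and the ODE system is then
#   integrated once over the whole horizon with the recorded discrete->
#   continuous jumps (e.g. mRNA transport) applied as solver events.
#
# * coupled (general): the integrated-hazard method.  Between firings the
#   ODEs are integrated jointly with the cumulative total propensity
#   Lambda(t); with u ~ Exp(1) the next firing time is the root of
#   Lambda(t) = u, located by the solver's root detection (lsodar), and the
#   firing transition is drawn proportionally to the propensities at that
#   time.

#' Simulation configuration
#'
#' @param t_end Simulation horizon (> 0), in model time units.
#' @param n_intervals Output grid size: the trace is recorded on
#'   `n_intervals + 1` equally spaced points from 0 to `t_end`.
#' @param seed RNG seed for the run (`NULL` leaves the RNG state alone).
#' @param rtol,atol Relative/absolute ODE solver tolerances.
#' @param max_step Maximum ODE step size (`NULL` for the solver default).
#' @return An object of class `hpn_sim_config`.
#' @export
hpn_sim_config <- function(t_end, n_intervals = 2000, seed = NULL,
                           rtol = 1e-6, atol = 1e-8, max_step = NULL) {
  stopifnot(t_end > 0, n_intervals >= 2)
  structure(list(t_end = as.numeric(t_end), n_intervals = as.integer(n_intervals),
                 seed = seed, rtol = rtol, atol = atol, max_step = max_step),
            class = "hpn_sim_config")
}

.env_set <- function(ev, ids, vals) {
  for (j in seq_along(ids)) assign(ids[j], vals[[j]], envir = ev)
  invisible(ev)
}

# grow-able numeric vector helpers (amortised O(1) appends)
.grow <- function() new.env(parent = emptyenv())
.grow_init <- function(g) { g$v <- numeric(64); g$n <- 0L; g }
.grow_push <- function(g, x) {
  if (g$n + length(x) > length(g$v)) g$v <- c(g$v, numeric(max(length(g$v), length(x))))
  g$v[g$n + seq_along(x)] <- x
  g$n <- g$n + length(x)
}
.grow_get <- function(g) g$v[seq_len(g$n)]

#' Simulate a hybrid Petri net
#'
#' Runs one realisation of the hybrid semantics: immediate transitions fire to
#' quiescence in zero time (priority order, then id order) at t = 0 and after
#' every stochastic firing; stochastic transitions fire after exponentially
#' distributed delays whose rates are their propensities; continuous
#' transitions define the ODE system of the continuous places, integrated with
#' a stiff-capable solver ([deSolve::lsoda()] / [deSolve::lsodar()]).
#' Observables are recorded on a fixed output grid.  The same model, config
#' and seed always reproduce the identical trace.
#'
#' @param model A validated `hpn` model.
#' @param config An [hpn_sim_config()].
#' @return An [hpn_trace()] with `config$n_intervals + 1` rows.
#' @examples
#' net <- make_decay_cpn(A0 = 5, d = 0.3)
#' tr <- simulate_hpn(net, hpn_sim_config(t_end = 10, n_intervals = 50))
#' max(abs(tr$A - 5 * exp(-0.3 * tr$Time)))
#' @export
simulate_hpn <- function(model, config) {
  diags <- validate_hpn(model)
  if (length(diags))
    stop("model fails validation:\n", paste("-", diags, collapse = "\n"),
         call. = FALSE)
  cm <- compile_hpn(model)
  .simulate_compiled(cm, config)
}

#' @rdname simulate_hpn
#' @param object An `hpn` model (for the [stats::simulate()] generic).
#' @param nsim Number of runs.
#' @param seed Base seed; run `i` uses `seed + i - 1`.
#' @param ... Unused.
#' @return For `simulate.hpn`: a list of `nsim` traces (a single trace if
#'   `nsim = 1`).
#' @export
simulate.hpn <- function(object, nsim = 1, seed = NULL, config, ...) {
  cm <- compile_hpn(object)
  out <- vector("list", nsim)
  for (i in seq_len(nsim)) {
    cfg <- config
    if (!is.null(seed)) cfg$seed <- seed + i - 1L
    out[[i]] <- .simulate_compiled(cm, cfg)
  }
  if (nsim == 1L) out[[1L]] else out
}

# init: optional named numeric vector overriding initial markings by place id.
# use_compiled = FALSE forces the reference R event loop (it consumes the RNG
# identically to the C++ kernel, so both paths yield the same trace).
.simulate_compiled <- function(cm, config, init = NULL, use_compiled = TRUE) {
  if (!is.null(config$seed)) set.seed(config$seed)
  n_pts <- config$n_intervals + 1L
  grid <- seq(0, config$t_end, length.out = n_pts)

  init_all <- vapply(cm$model$places, `[[`, 0, "initial")
  names(init_all) <- place_ids(cm$model)
  if (!is.null(init)) {
    bad <- setdiff(names(init), names(init_all))
    if (length(bad)) stop("unknown place(s) in init: ", paste(bad, collapse = ", "))
    init_all[names(init)] <- init
  }
  md <- init_all[cm$disc_ids]
  mc <- init_all[cm$cont_ids]

  ev <- new.env(parent = cm$const_env)
  .env_set(ev, cm$disc_ids, md)
  .env_set(ev, cm$cont_ids, mc)

  # ---- immediate-transition machinery --------------------------------------
  imm_enabled <- function(k) {
    for (a in cm$im_pre[[k]]) {
      w <- if (is.numeric(a$w)) a$w else eval(a$w, ev)
      if (md[[a$place]] < w - 1e-9) return(FALSE)
    }
    TRUE
  }
  # fires all enabled immediates; mutates md/ev in the caller's frame via <<-,
  # returns accumulated continuous jump deltas
  fire_immediates <- function() {
    cj <- numeric(cm$n_cont)
    if (!length(cm$im_ids)) return(cj)
    if (!any(vapply(seq_along(cm$im_ids), imm_enabled, NA))) return(cj)
    seen <- paste(md, collapse = " ")
    count <- 0L
    repeat {
      fired <- FALSE
      for (k in seq_along(cm$im_ids)) {
        if (!imm_enabled(k)) next
        rec <- cm$im_fire[[k]]
        dynw <- lapply(rec$dyn, function(d) eval(d$expr, ev))
        if (length(rec$di)) md[rec$di] <<- md[rec$di] + rec$dv
        if (length(rec$ci)) cj[rec$ci] <- cj[rec$ci] + rec$cv
        for (j in seq_along(rec$dyn)) {
          d <- rec$dyn[[j]]; w <- d$sign * dynw[[j]]
          if (d$disc) {
            if (abs(w - round(w)) > 1e-9)
              stop("immediate transition ", cm$im_ids[k],
                   ": non-integer weight on a discrete place", call. = FALSE)
            md[d$idx] <<- md[d$idx] + round(w)
          } else cj[d$idx] <- cj[d$idx] + w
        }
        if (any(md < -1e-9))
          stop("immediate transition ", cm$im_ids[k],
               " drove a discrete marking negative", call. = FALSE)
        md <<- round(md)
        .env_set(ev, cm$disc_ids, md)
        key <- paste(md, collapse = " ")
        if (key %in% seen)
          stop("immediate-transition livelock: marking revisited in zero time",
               call. = FALSE)
        seen <- c(seen, key)
        count <- count + 1L
        if (count > 10000L)
          stop("immediate-transition livelock: cascade exceeded 10000 firings",
               call. = FALSE)
        fired <- TRUE
        break
      }
      if (!fired) break
    }
    cj
  }

  # ---- propensity helpers --------------------------------------------------
  base_mask <- function() {
    en <- rep(TRUE, cm$n_st)
    if (length(cm$en_tidx)) {
      viol <- md[cm$en_pidx] < cm$en_w - 1e-9
      if (any(viol)) en[cm$en_tidx[viol]] <- FALSE
    }
    en
  }
  full_mask <- function(en, mc_loc) {
    for (e in cm$en_cont)
      if (e$w > 0 && mc_loc[e$idx] <= 0) en[e$tidx] <- FALSE
    for (e in cm$en_dyn) {
      w <- eval(e$expr, ev)
      m <- if (e$disc) md[e$idx] else mc_loc[e$idx]
      if (e$disc) { if (m < w - 1e-9) en[e$tidx] <- FALSE }
      else if (w > 0 && m <= 0) en[e$tidx] <- FALSE
    }
    en
  }
  eval_props <- function(mc_loc) {
    p <- eval(cm$prop_call, ev)
    if (anyNA(p) || any(p < 0))
      stop("negative or undefined propensity encountered", call. = FALSE)
    en <- full_mask(base_mask(), mc_loc)
    p[!en] <- 0
    p
  }

  fire_stochastic <- function(k) {
    # returns continuous jump deltas; evaluates dynamic weights pre-firing
    rec <- cm$st_fire[[k]]
    cj <- numeric(cm$n_cont)
    dynw <- lapply(rec$dyn, function(d) eval(d$expr, ev))
    if (length(rec$di)) md[rec$di] <<- md[rec$di] + rec$dv
    if (length(rec$ci)) cj[rec$ci] <- cj[rec$ci] + rec$cv
    for (j in seq_along(rec$dyn)) {
      d <- rec$dyn[[j]]; w <- d$sign * dynw[[j]]
      if (d$disc) {
        if (abs(w - round(w)) > 1e-9)
          stop("transition ", cm$st_ids[k],
               ": non-integer weight on a discrete place", call. = FALSE)
        md[d$idx] <<- md[d$idx] + round(w)
      } else cj[d$idx] <- cj[d$idx] + w
    }
    if (any(md < -1e-9))
      stop("firing ", cm$st_ids[k], " drove a discrete marking negative",
           call. = FALSE)
    md <<- round(md)
    .env_set(ev, cm$disc_ids, md)
    cj
  }

  # ---- ODE right-hand side -------------------------------------------------
  rhs_flow <- function(mc_loc) {
    .env_set(ev, cm$cont_ids, mc_loc)
    r <- eval(cm$rate_call, ev)
    dy <- as.numeric(cm$S %*% r)
    for (d in cm$ct_dyn)
      dy[d$pidx] <- dy[d$pidx] + d$sign * eval(d$expr, ev) * r[d$tidx]
    dy
  }

  Mdisc <- matrix(0, nrow = n_pts, ncol = cm$n_disc,
                  dimnames = list(NULL, cm$disc_ids))
  Mcont <- matrix(0, nrow = n_pts, ncol = cm$n_cont,
                  dimnames = list(NULL, cm$cont_ids))

  if (cm$decoupled) {
    # ---- phase 1: jump process --------------------------------------------
    cj0 <- fire_immediates()
    mc <- pmax(mc + cj0, 0)
    .env_set(ev, cm$cont_ids, mc)
    jt <- .grow_init(.grow()); jp <- .grow_init(.grow()); jv <- .grow_init(.grow())
    use_cpp <- use_compiled && cm$n_st > 0L && !is.null(cm$st_rpn) &&
      cm$st_fire_simple && .immediates_quiescent(cm, md, ev)
    if (use_cpp) {
      res <- .ssa_decoupled(cm$st_rpn$ops, cm$st_rpn$args, cm$st_rpn$off,
                            md, cm$en_tidx0, cm$en_pidx0, cm$en_w,
                            cm$fire_di0, cm$fire_dv, cm$fire_ci0, cm$fire_cv,
                            grid, config$t_end, cm$n_cont)
      Mdisc[] <- res$Mdisc
      md <- stats::setNames(res$md, cm$disc_ids)
      .env_set(ev, cm$disc_ids, md)
      if (length(res$jt)) {
        .grow_push(jt, res$jt); .grow_push(jp, res$jp + 1L)
        .grow_push(jv, res$jv)
      }
    } else {
      t <- 0; gi <- 1L
      if (cm$n_st > 0L) {
        repeat {
          props <- eval_props(mc)
          L <- sum(props)
          if (L <= 0) break
          te <- t + stats::rexp(1L) / L
          if (te > config$t_end) break
          while (gi <= n_pts && grid[gi] < te) {
            Mdisc[gi, ] <- md; gi <- gi + 1L
          }
          u <- stats::runif(1L) * L
          k <- 1L; acc <- props[1L]
          while (k < cm$n_st && u > acc) { k <- k + 1L; acc <- acc + props[k] }
          cj <- fire_stochastic(k)
          cj <- cj + fire_immediates()
          nz <- which(cj != 0)
          if (length(nz)) {
            .grow_push(jt, rep(te, length(nz))); .grow_push(jp, nz)
            .grow_push(jv, cj[nz])
          }
          t <- te
        }
      }
      while (gi <= n_pts) { Mdisc[gi, ] <- md; gi <- gi + 1L }
    }

    # ---- phase 2: continuous subnet ---------------------------------------
    if (cm$n_cont > 0L) {
      jtv <- .grow_get(jt); jpv <- .grow_get(jp); jvv <- .grow_get(jv)
      if (cm$n_ct == 0L) {
        # no flows: piecewise-constant accumulation of jumps
        for (j in seq_len(cm$n_cont)) {
          sel <- jpv == j
          if (!any(sel)) { Mcont[, j] <- mc[j]; next }
          tj <- jtv[sel]; vj <- jvv[sel]
          o <- order(tj)
          cum <- c(0, cumsum(vj[o]))
          Mcont[, j] <- pmax(mc[j] + cum[findInterval(grid, tj[o]) + 1L], 0)
        }
      } else {
        odef <- if (!is.null(cm$ct_rpn)) {
          function(t, y, parms)
            list(.rpn_ode_rhs(cm$ct_rpn$ops, cm$ct_rpn$args, cm$ct_rpn$off,
                              y, cm$S_si, cm$S_sj, cm$S_sx))
        } else {
          function(t, y, parms) list(rhs_flow(pmax(y, 0)))
        }
        evdf <- NULL
        if (length(jtv)) {
          evdf <- data.frame(var = cm$cont_ids[jpv], time = jtv, value = jvv,
                             method = "add", stringsAsFactors = FALSE)
          evdf <- stats::aggregate(value ~ var + time, data = evdf, FUN = sum)
          evdf$method <- "add"
          evdf <- evdf[order(evdf$time), c("var", "time", "value", "method")]
        }
        args <- list(y = mc, times = grid, func = odef, parms = NULL,
                     rtol = config$rtol, atol = config$atol)
        if (!is.null(config$max_step)) args$hmax <- config$max_step
        if (!is.null(evdf)) args$events <- list(data = evdf)
        # event times not on the grid are added to the solver's output times
        # (a benign notice); any other solver warning is a failure
        out <- withCallingHandlers(
          do.call(deSolve::lsoda, args),
          warning = function(w) {
            if (grepl("automatically included", conditionMessage(w)))
              invokeRestart("muffleWarning")
            stop("ODE solver failure: ", conditionMessage(w), call. = FALSE)
          })
        rows <- match(grid, out[, 1L])
        if (anyNA(rows))
          stop("ODE solver failure: output grid points missing", call. = FALSE)
        Mcont[] <- pmax(out[rows, cm$cont_ids, drop = FALSE], 0)
      }
    }
  } else {
    # ---- general coupled path: integrated-hazard event loop ---------------
    cj0 <- fire_immediates()
    mc <- pmax(mc + cj0, 0)
    .env_set(ev, cm$cont_ids, mc)
    Mdisc[1L, ] <- md; Mcont[1L, ] <- mc
    gi <- 2L; t <- 0
    aug <- function(tt, y, parms) {
      mc_loc <- pmax(y[seq_len(cm$n_cont)], 0)
      dy <- rhs_flow(mc_loc)
      p <- eval(cm$prop_call, ev)
      if (anyNA(p) || any(p < 0))
        stop("negative or undefined propensity encountered", call. = FALSE)
      en <- full_mask(parms$en_base, mc_loc)
      list(c(dy, sum(p[en])))
    }
    repeat {
      if (t >= config$t_end) break
      u <- stats::rexp(1L)
      times <- c(t, grid[grid > t + 1e-12])
      if (length(times) < 2L || times[length(times)] < config$t_end)
        times <- c(times, config$t_end)
      parms <- list(en_base = base_mask())
      rootf <- function(tt, y, p) y[cm$n_cont + 1L] - u
      args <- list(y = c(mc, .LAMBDA = 0), times = times, func = aug,
                   parms = parms, rootfunc = rootf,
                   rtol = config$rtol, atol = config$atol)
      if (!is.null(config$max_step)) args$hmax <- config$max_step
      out <- tryCatch(do.call(deSolve::lsodar, args),
                      warning = function(w) stop(
                        "ODE solver failure: ", conditionMessage(w), call. = FALSE))
      troot <- attr(out, "troot")
      ot <- out[, 1L]
      # record any grid points reached in this segment (excluding a root row)
      for (r in seq_along(ot)[-1L]) {
        if (gi <= n_pts && abs(ot[r] - grid[gi]) <= 1e-9 * max(1, grid[gi])) {
          Mcont[gi, ] <- pmax(out[r, 1L + seq_len(cm$n_cont)], 0)
          Mdisc[gi, ] <- md
          gi <- gi + 1L
        }
      }
      last <- nrow(out)
      mc <- pmax(as.numeric(out[last, 1L + seq_len(cm$n_cont)]), 0)
      names(mc) <- cm$cont_ids
      .env_set(ev, cm$cont_ids, mc)
      if (length(troot) && troot < config$t_end - 1e-12) {
        t <- troot
        props <- eval_props(mc)
        if (sum(props) > 0) {
          k <- if (cm$n_st == 1L) 1L else sample.int(cm$n_st, 1L, prob = props)
          cj <- fire_stochastic(k)
          cj <- cj + fire_immediates()
          mc <- pmax(mc + cj, 0)
          .env_set(ev, cm$cont_ids, mc)
        }
      } else {
        t <- config$t_end
      }
    }
    while (gi <= n_pts) { Mcont[gi, ] <- mc; Mdisc[gi, ] <- md; gi <- gi + 1L }
  }

  # ---- observables ---------------------------------------------------------
  colenv <- new.env(parent = cm$const_env)
  for (j in seq_len(cm$n_disc)) assign(cm$disc_ids[j], Mdisc[, j], envir = colenv)
  for (j in seq_len(cm$n_cont)) assign(cm$cont_ids[j], Mcont[, j], envir = colenv)
  cols <- lapply(cm$obs_exprs, function(e) {
    v <- if (is.numeric(e)) as.numeric(e) else eval(e, colenv)
    if (length(v) == 1L) rep(v, n_pts) else v
  })
  hpn_trace(grid, cols)
}

#' Continuous-subnet derivative at a given state
#'
#' Assembles the ODE right-hand side defined by the continuous transitions:
#' for each continuous place, the sum of inflow transition rates times arc
#' weights minus the sum of outflow rates times weights, evaluated on the
#' given hybrid state (markings clamped at zero).  Stochastic transitions
#' contribute nothing.
#'
#' @param model A validated `hpn` model.
#' @param state An [hpn_state()]; defaults to the initial marking.
#' @return Named numeric vector: d(marking)/dt per continuous place.
#' @examples
#' net <- make_decay_cpn(A0 = 2, d = 1)
#' assemble_odes(net)   # dA/dt = -d * A = -2
#' @export
assemble_odes <- function(model, state = initial_state(model)) {
  cm <- compile_hpn(model)
  if (cm$n_cont == 0L) return(stats::setNames(numeric(), character()))
  if (cm$n_ct == 0L)
    return(stats::setNames(numeric(cm$n_cont), cm$cont_ids))
  ev <- new.env(parent = cm$const_env)
  .env_set(ev, cm$disc_ids, state$discrete[cm$disc_ids])
  mc <- pmax(state$continuous[cm$cont_ids], 0)
  .env_set(ev, cm$cont_ids, mc)
  r <- eval(cm$rate_call, ev)
  dy <- as.numeric(cm$S %*% r)
  for (d in cm$ct_dyn)
    dy[d$pidx] <- dy[d$pidx] + d$sign * eval(d$expr, ev) * r[d$tidx]
  stats::setNames(dy, cm$cont_ids)
}

#' Draw the next stochastic firing by the integrated-hazard method
#'
#' Draws `u ~ Exp(1)`, integrates the ODE system jointly with the cumulative
#' total propensity from `state$time` to `t_end`, locates the firing time as
#' the root of the cumulative hazard equalling `u` (solver root detection),
#' and picks the firing transition with probability proportional to the
#' propensities at that time.  Returns `NULL` when the accumulated hazard
#' never reaches `u` before `t_end`.
#'
#' @param model A validated `hpn` model.
#' @param state Current [hpn_state()].
#' @param t_end Horizon for the search.
#' @param config Solver tolerances ([hpn_sim_config()]; `t_end` therein is
#'   ignored in favour of the argument).
#' @return `NULL`, or a list with elements `time`, `transition` and `state`
#'   (the continuous marking advanced to the firing time; the firing itself
#'   is not applied).
#' @export
next_stochastic_event <- function(model, state, t_end,
                                  config = hpn_sim_config(t_end = t_end)) {
  cm <- compile_hpn(model)
  if (cm$n_st == 0L) return(NULL)
  ev <- new.env(parent = cm$const_env)
  md <- state$discrete[cm$disc_ids]
  mc <- if (cm$n_cont) pmax(state$continuous[cm$cont_ids], 0) else numeric()
  .env_set(ev, cm$disc_ids, md)
  .env_set(ev, cm$cont_ids, mc)

  en_base <- rep(TRUE, cm$n_st)
  if (length(cm$en_tidx)) {
    viol <- md[cm$en_pidx] < cm$en_w - 1e-9
    if (any(viol)) en_base[cm$en_tidx[viol]] <- FALSE
  }
  props_at <- function(mc_loc) {
    .env_set(ev, cm$cont_ids, mc_loc)
    p <- eval(cm$prop_call, ev)
    if (anyNA(p) || any(p < 0))
      stop("negative or undefined propensity encountered", call. = FALSE)
    en <- en_base
    for (e in cm$en_cont) if (e$w > 0 && mc_loc[e$idx] <= 0) en[e$tidx] <- FALSE
    for (e in cm$en_dyn) {
      w <- eval(e$expr, ev)
      m <- if (e$disc) md[e$idx] else mc_loc[e$idx]
      if (e$disc) { if (m < w - 1e-9) en[e$tidx] <- FALSE }
      else if (w > 0 && m <= 0) en[e$tidx] <- FALSE
    }
    p[!en] <- 0
    p
  }
  flow <- function(mc_loc) {
    if (cm$n_ct == 0L) return(numeric(cm$n_cont))
    .env_set(ev, cm$cont_ids, mc_loc)
    r <- eval(cm$rate_call, ev)
    dy <- as.numeric(cm$S %*% r)
    for (d in cm$ct_dyn)
      dy[d$pidx] <- dy[d$pidx] + d$sign * eval(d$expr, ev) * r[d$tidx]
    dy
  }

  u <- stats::rexp(1L)
  aug <- function(tt, y, parms) {
    mc_loc <- pmax(y[seq_len(cm$n_cont)], 0)
    list(c(flow(mc_loc), sum(props_at(mc_loc))))
  }
  out <- deSolve::lsodar(
    y = c(mc, .LAMBDA = 0), times = c(state$time, t_end), func = aug,
    parms = NULL, rootfunc = function(tt, y, p) y[cm$n_cont + 1L] - u,
    rtol = config$rtol, atol = config$atol)
  troot <- attr(out, "troot")
  if (!length(troot) || troot >= t_end - 1e-12) return(NULL)
  last <- nrow(out)
  mc_fire <- if (cm$n_cont) {
    stats::setNames(pmax(as.numeric(out[last, 1L + seq_len(cm$n_cont)]), 0),
                    cm$cont_ids)
  } else numeric()
  props <- props_at(mc_fire)
  if (sum(props) <= 0) return(NULL)
  uu <- stats::runif(1L) * sum(props)
  k <- 1L; acc <- props[1L]
  while (k < cm$n_st && uu > acc) { k <- k + 1L; acc <- acc + props[k] }
  list(time = troot, transition = cm$st_ids[k],
       state = hpn_state(troot, md, mc_fire))
}
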