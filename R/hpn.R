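# Hybrid Petri net data model: places, transitions, arcs, markings, static
# validation, enabling, propensities and discrete firing.
#
# A hybrid Petri net is the tuple (P, T, h, Pre, Post, M0): places and
# transitions partitioned by a hybrid kind function into discrete/stochastic
# and continuous nodes, input/output incidence maps (arc weights, possibly
# marking-dependent expressions) and an initial marking.  Discrete places hold
# non-negative integer token counts (molecules); continuous places hold
# non-negative real concentrations (nM).

#' Declare a place of a hybrid Petri net
#'
#' @param id Unique identifier (a syntactic R name; it is referenced from rate
#'   laws and observables).
#' @param kind `"discrete"` (integer token count) or `"continuous"`
#'   (non-negative real concentration).
#' @param initial Initial marking: a non-negative integer for discrete places,
#'   a non-negative real for continuous ones.
#' @param name Optional human-readable label; defaults to `id`.
#' @return A `hpn_place` record (named list).
#' @seealso [hpn_model()]
#' @export
hpn_place <- function(id, kind = c("discrete", "continuous"), initial = 0,
                      name = id) {
  kind <- match.arg(kind)
  structure(list(id = as.character(id), kind = kind,
                 initial = as.numeric(initial), name = as.character(name)),
            class = "hpn_place")
}

#' Declare a transition of a hybrid Petri net
#'
#' Stochastic transitions fire after an exponentially distributed delay whose
#' rate (the propensity, 1/time) is given by `rate`.  Continuous transitions
#' define a flow (nM/time) that enters the ODE system of their continuous
#' post-places.  Immediate transitions fire in zero time as soon as they are
#' enabled, in decreasing `priority` order.
#'
#' @param id Unique identifier.
#' @param kind `"stochastic"`, `"continuous"` or `"immediate"`.
#' @param rate Rate-law expression (string) over pre-place/modifier markings
#'   and named constants; unused for immediate transitions.
#' @param priority Integer priority, immediate transitions only (higher fires
#'   first).
#' @param name Optional label.
#' @return A `hpn_transition` record.
#' @export
hpn_transition <- function(id, kind = c("stochastic", "continuous", "immediate"),
                           rate = NULL, priority = NULL, name = id) {
  kind <- match.arg(kind)
  structure(list(id = as.character(id), kind = kind,
                 rate = if (!is.null(rate)) as.character(rate),
                 priority = if (!is.null(priority)) as.integer(priority),
                 name = as.character(name)),
            class = "hpn_transition")
}

#' Declare an arc of a hybrid Petri net
#'
#' Standard arcs connect a place to a transition (consumption) or a transition
#' to a place (production) and carry a constant or marking-dependent weight.
#' Modifier arcs connect a place to a transition only, carry no weight, and
#' expose the place's marking to the transition's rate law without consuming
#' it; they never disable the transition.
#'
#' @param source,target Endpoint ids (one must be a place, the other a
#'   transition for standard arcs; modifier arcs go place to transition).
#' @param kind `"standard"` or `"modifier"`.
#' @param weight Non-negative number or expression string; ignored (and
#'   disallowed) for modifier arcs.
#' @return A `hpn_arc` record.
#' @export
hpn_arc <- function(source, target, kind = c("standard", "modifier"),
                    weight = 1) {
  kind <- match.arg(kind)
  if (kind == "modifier") weight <- NULL
  structure(list(source = as.character(source), target = as.character(target),
                 kind = kind,
                 weight = if (!is.null(weight)) {
                   if (is.numeric(weight)) weight else as.character(weight)
                 }),
            class = "hpn_arc")
}

#' Assemble a hybrid Petri net model
#'
#' @param places List of [hpn_place()] records.
#' @param transitions List of [hpn_transition()] records.
#' @param arcs List of [hpn_arc()] records.
#' @param constants Named list of real parameters available to all rate-law
#'   and weight expressions.
#' @param observables Named list of expression strings over place ids (and
#'   constants); these become the columns of simulation traces.  If empty,
#'   every place is its own observable.
#' @param name Model name.
#' @param validate Run [validate_hpn()] and stop on diagnostics.
#' @return An object of class `hpn`.
#' @examples
#' net <- hpn_model(
#'   places = list(hpn_place("A", "discrete", 3)),
#'   transitions = list(hpn_transition("deg", "stochastic", rate = "d * A")),
#'   arcs = list(hpn_arc("A", "deg")),
#'   constants = list(d = 0.1))
#' propensity(net, "deg", initial_state(net))
#' @export
hpn_model <- function(places, transitions, arcs, constants = list(),
                      observables = list(), name = "hpn", validate = TRUE) {
  stopifnot(is.list(places), is.list(transitions), is.list(arcs))
  names(places) <- vapply(places, `[[`, "", "id")
  names(transitions) <- vapply(transitions, `[[`, "", "id")
  model <- structure(
    list(places = places, transitions = transitions, arcs = arcs,
         constants = constants, observables = observables, name = name),
    class = "hpn")
  if (validate) {
    diags <- validate_hpn(model)
    if (length(diags))
      stop("invalid hybrid Petri net:\n", paste("-", diags, collapse = "\n"),
           call. = FALSE)
  }
  model
}

#' @export
print.hpn <- function(x, ...) {
  kinds_p <- vapply(x$places, `[[`, "", "kind")
  kinds_t <- vapply(x$transitions, `[[`, "", "kind")
  cat("Hybrid Petri net", sQuote(x$name), "\n")
  cat(sprintf("  places:      %d discrete, %d continuous\n",
              sum(kinds_p == "discrete"), sum(kinds_p == "continuous")))
  cat(sprintf("  transitions: %d stochastic, %d continuous, %d immediate\n",
              sum(kinds_t == "stochastic"), sum(kinds_t == "continuous"),
              sum(kinds_t == "immediate")))
  cat(sprintf("  arcs:        %d (%d modifier)\n", length(x$arcs),
              sum(vapply(x$arcs, `[[`, "", "kind") == "modifier")))
  if (length(x$observables))
    cat("  observables:", paste(names(x$observables), collapse = ", "), "\n")
  invisible(x)
}

# ---- static validation ------------------------------------------------------

place_ids <- function(model) names(model$places)
transition_ids <- function(model) names(model$transitions)

# Arcs incident to a transition, split by role.
.arcs_of <- function(model, tid) {
  pre <- list(); post <- list(); mod <- list()
  for (a in model$arcs) {
    if (a$kind == "modifier") {
      if (a$target == tid) mod[[length(mod) + 1L]] <- a
    } else if (a$target == tid) {
      pre[[length(pre) + 1L]] <- a
    } else if (a$source == tid) {
      post[[length(post) + 1L]] <- a
    }
  }
  list(pre = pre, post = post, mod = mod)
}

.is_int <- function(x, tol = 1e-9) abs(x - round(x)) < tol

#' Validate a hybrid Petri net
#'
#' Checks the static well-formedness rules of the hybrid formalism and
#' returns diagnostics (an empty character vector means the model is valid):
#' unique ids, bipartite arcs (never place-place or transition-transition),
#' modifier arcs only place to transition, integer non-negative initial
#' markings on discrete places, non-negative reals on continuous ones,
#' priorities only on immediate transitions, rate laws referencing only
#' connected places, continuous transitions touching discrete places only via
#' modifier arcs, and every expression evaluating on the initial marking.
#'
#' @param model An `hpn` object (built with `validate = FALSE` if you expect
#'   diagnostics).
#' @return Character vector of diagnostics, empty iff the model is valid.
#' @export
validate_hpn <- function(model) {
  d <- character()
  pids <- place_ids(model); tids <- transition_ids(model)
  if (anyDuplicated(pids)) d <- c(d, "duplicate place ids")
  if (anyDuplicated(tids)) d <- c(d, "duplicate transition ids")
  if (length(intersect(pids, tids)))
    d <- c(d, paste("ids shared between places and transitions:",
                    paste(intersect(pids, tids), collapse = ", ")))
  bad_names <- pids[pids != make.names(pids)]
  if (length(bad_names))
    d <- c(d, paste("place ids must be syntactic names:",
                    paste(bad_names, collapse = ", ")))

  for (p in model$places) {
    if (p$initial < 0)
      d <- c(d, sprintf("place %s: negative initial marking", p$id))
    if (p$kind == "discrete" && !.is_int(p$initial))
      d <- c(d, sprintf(
        "place %s: discrete initial marking must be a non-negative integer",
        p$id))
  }

  for (a in model$arcs) {
    s_is_p <- a$source %in% pids; t_is_p <- a$target %in% pids
    s_is_t <- a$source %in% tids; t_is_t <- a$target %in% tids
    if (!(s_is_p || s_is_t) || !(t_is_p || t_is_t)) {
      d <- c(d, sprintf("arc %s -> %s: dangling endpoint", a$source, a$target))
      next
    }
    if (a$kind == "modifier") {
      if (!(s_is_p && t_is_t))
        d <- c(d, sprintf("arc %s -> %s: modifier arcs connect a place to a transition only",
                          a$source, a$target))
      if (!is.null(a$weight))
        d <- c(d, sprintf("arc %s -> %s: modifier arcs carry no weight",
                          a$source, a$target))
    } else if ((s_is_p && t_is_p) || (s_is_t && t_is_t)) {
      d <- c(d, sprintf("arc %s -> %s: arc endpoints must alternate place/transition",
                        a$source, a$target))
    }
  }

  # expression checks need an initial-marking environment
  env0 <- c(lapply(model$places, `[[`, "initial"), model$constants)
  names(env0)[seq_along(model$places)] <- pids

  for (tr in model$transitions) {
    if (tr$kind == "immediate") {
      if (!is.null(tr$rate))
        d <- c(d, sprintf("transition %s: immediate transitions have no rate law", tr$id))
    } else {
      if (!is.null(tr$priority))
        d <- c(d, sprintf("transition %s: priority is defined only for immediate transitions", tr$id))
      if (is.null(tr$rate)) {
        d <- c(d, sprintf("transition %s: missing rate law", tr$id))
        next
      }
    }
    ar <- .arcs_of(model, tr$id)
    connected <- unique(c(vapply(ar$pre, `[[`, "", "source"),
                          vapply(ar$mod, `[[`, "", "source")))
    if (!is.null(tr$rate)) {
      e <- tryCatch(parse_expr(tr$rate), error = function(err) err)
      if (inherits(e, "error")) {
        d <- c(d, sprintf("transition %s: %s", tr$id, conditionMessage(e)))
      } else {
        vars <- expr_vars(e)
        unknown <- setdiff(vars, c(pids, names(model$constants)))
        if (length(unknown))
          d <- c(d, sprintf("transition %s: rate law references unknown name(s) %s",
                            tr$id, paste(unknown, collapse = ", ")))
        stray <- setdiff(intersect(vars, pids), connected)
        if (length(stray))
          d <- c(d, sprintf(
            "transition %s: rate law references place(s) %s not connected by an incoming standard or modifier arc",
            tr$id, paste(stray, collapse = ", ")))
        if (!length(unknown)) {
          v <- tryCatch(eval_expr(e, env0), error = function(err) err)
          if (inherits(v, "error") || !is.finite(v))
            d <- c(d, sprintf("transition %s: rate law does not evaluate on the initial marking", tr$id))
        }
      }
    }
    if (tr$kind == "continuous") {
      std <- c(ar$pre, ar$post)
      ends <- vapply(std, function(a)
        if (a$target == tr$id) a$source else a$target, "")
      disc <- ends[ends %in% pids &
                   vapply(model$places[ends], `[[`, "", "kind") == "discrete"]
      if (length(disc))
        d <- c(d, sprintf(
          "transition %s: continuous transitions may touch discrete place(s) %s only via modifier arcs",
          tr$id, paste(unique(disc), collapse = ", ")))
    }
  }

  for (a in model$arcs) {
    if (is.null(a$weight)) next
    e <- tryCatch(parse_expr(a$weight), error = function(err) err)
    if (inherits(e, "error")) {
      d <- c(d, sprintf("arc %s -> %s: %s", a$source, a$target, conditionMessage(e)))
      next
    }
    vars <- expr_vars(e)
    unknown <- setdiff(vars, c(pids, names(model$constants)))
    if (length(unknown)) {
      d <- c(d, sprintf("arc %s -> %s: weight references unknown name(s) %s",
                        a$source, a$target, paste(unknown, collapse = ", ")))
      next
    }
    v <- tryCatch(eval_expr(e, env0), error = function(err) err)
    if (inherits(v, "error") || !is.finite(v)) {
      d <- c(d, sprintf("arc %s -> %s: weight does not evaluate on the initial marking",
                        a$source, a$target))
    } else if (v < 0) {
      d <- c(d, sprintf("arc %s -> %s: weight is negative on the initial marking",
                        a$source, a$target))
    }
  }

  for (ob in names(model$observables)) {
    e <- tryCatch(parse_expr(model$observables[[ob]]), error = function(err) err)
    if (inherits(e, "error")) {
      d <- c(d, sprintf("observable %s: %s", ob, conditionMessage(e)))
      next
    }
    unknown <- setdiff(expr_vars(e), c(pids, names(model$constants)))
    if (length(unknown))
      d <- c(d, sprintf("observable %s: references unknown name(s) %s", ob,
                        paste(unknown, collapse = ", ")))
  }
  d
}

# ---- state ------------------------------------------------------------------

#' Hybrid marking (state) of a model
#'
#' @param time Non-negative simulation time.
#' @param discrete Named integer vector: token counts of discrete places.
#' @param continuous Named numeric vector: concentrations of continuous places.
#' @return An object of class `hpn_state`.
#' @export
hpn_state <- function(time = 0, discrete = numeric(), continuous = numeric()) {
  stopifnot(time >= 0, all(discrete >= 0), all(continuous >= 0))
  structure(list(time = time, discrete = discrete, continuous = continuous),
            class = "hpn_state")
}

#' @rdname hpn_state
#' @param model An `hpn` model.
#' @export
initial_state <- function(model) {
  kinds <- vapply(model$places, `[[`, "", "kind")
  init <- vapply(model$places, `[[`, 0, "initial")
  hpn_state(0, discrete = init[kinds == "discrete"],
            continuous = init[kinds == "continuous"])
}

# Evaluation environment (as a named list) for a state.
state_env <- function(model, state) {
  c(as.list(state$discrete), as.list(state$continuous), model$constants)
}

# ---- enabling / propensity / firing ----------------------------------------

.get_transition <- function(model, tid) {
  tr <- model$transitions[[tid]]
  if (is.null(tr)) stop("unknown transition id ", sQuote(tid), call. = FALSE)
  tr
}

.marking <- function(state, pid) {
  if (pid %in% names(state$discrete)) state$discrete[[pid]]
  else state$continuous[[pid]]
}

#' Is a transition enabled in a given state?
#'
#' A transition is enabled when every discrete pre-place holds at least the
#' evaluated arc weight and every continuous pre-place consumed by a standard
#' arc is strictly positive.  Modifier arcs never disable.
#'
#' @param model An `hpn` model.
#' @param tid Transition id.
#' @param state An `hpn_state`.
#' @return Logical scalar.
#' @export
is_enabled <- function(model, tid, state) {
  .get_transition(model, tid)     # errors on unknown id
  env <- state_env(model, state)
  for (a in model$arcs) {
    if (a$kind != "standard" || a$target != tid) next
    w <- eval_expr(parse_expr(a$weight), env)
    p <- model$places[[a$source]]
    m <- .marking(state, a$source)
    if (p$kind == "discrete") {
      if (m < w - 1e-9) return(FALSE)
    } else {
      if (w > 0 && m <= 0) return(FALSE)
    }
  }
  TRUE
}

#' Propensity of a stochastic transition
#'
#' Evaluates the transition's rate law on the current markings; returns 0 when
#' the transition is not enabled.
#'
#' @inheritParams is_enabled
#' @return Non-negative rate (1/time).
#' @export
propensity <- function(model, tid, state) {
  tr <- .get_transition(model, tid)
  stopifnot(tr$kind == "stochastic")
  if (!is_enabled(model, tid, state)) return(0)
  eval_expr(parse_expr(tr$rate), state_env(model, state))
}

#' Fire a stochastic or immediate transition
#'
#' Decrements pre-places and increments post-places by the evaluated arc
#' weights (weights are evaluated on the state *before* firing).  Continuous
#' pre-places are clamped at zero.  Time is unchanged and the input state is
#' not mutated.
#'
#' @inheritParams is_enabled
#' @return The successor `hpn_state`.
#' @export
fire_transition <- function(model, tid, state) {
  tr <- .get_transition(model, tid)
  stopifnot(tr$kind %in% c("stochastic", "immediate"))
  if (!is_enabled(model, tid, state))
    stop("transition ", sQuote(tid), " is not enabled", call. = FALSE)
  env <- state_env(model, state)
  disc <- state$discrete; cont <- state$continuous
  for (a in model$arcs) {
    if (a$kind != "standard") next
    if (a$target == tid) {                       # consumption
      w <- eval_expr(parse_expr(a$weight), env)
      p <- model$places[[a$source]]
      if (p$kind == "discrete") {
        if (!.is_int(w))
          stop("arc ", a$source, " -> ", tid,
               ": non-integer weight on a discrete place", call. = FALSE)
        nv <- disc[[a$source]] - round(w)
        if (nv < 0)
          stop("firing ", sQuote(tid), " would drive place ", sQuote(a$source),
               " negative", call. = FALSE)
        disc[[a$source]] <- nv
      } else {
        cont[[a$source]] <- max(cont[[a$source]] - w, 0)
      }
    } else if (a$source == tid) {                # production
      w <- eval_expr(parse_expr(a$weight), env)
      p <- model$places[[a$target]]
      if (p$kind == "discrete") {
        if (!.is_int(w))
          stop("arc ", tid, " -> ", a$target,
               ": non-integer weight on a discrete place", call. = FALSE)
        disc[[a$target]] <- disc[[a$target]] + round(w)
      } else {
        cont[[a$target]] <- cont[[a$target]] + w
      }
    }
  }
  hpn_state(state$time, disc, cont)
}
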