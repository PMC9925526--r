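# Internal compiled representation of a hybrid Petri net.  All rate laws are
# bundled into a single `c(...)` call per transition class so the simulator
# evaluates one expression per event, and arc weights are split into constant
# index/delta vectors (the common case) and marking-dependent expressions.

compile_hpn <- function(model) {
  pids <- place_ids(model)
  kinds_p <- vapply(model$places, `[[`, "", "kind")
  disc_ids <- pids[kinds_p == "discrete"]
  cont_ids <- pids[kinds_p == "continuous"]
  kinds_t <- vapply(model$transitions, `[[`, "", "kind")
  st_ids <- transition_ids(model)[kinds_t == "stochastic"]
  ct_ids <- transition_ids(model)[kinds_t == "continuous"]
  im_ids <- transition_ids(model)[kinds_t == "immediate"]

  # immediate transitions in firing order: priority (desc), then id
  if (length(im_ids)) {
    prio <- vapply(model$transitions[im_ids], function(tr)
      if (is.null(tr$priority)) 0L else tr$priority, 0L)
    im_ids <- im_ids[order(-prio, im_ids)]
  }

  const_env <- list2env(model$constants, parent = baseenv())

  parse_w <- function(w) {
    if (is.numeric(w)) return(w)
    e <- parse_expr(w)
    # fold weights that only reference named constants
    if (!length(setdiff(expr_vars(e), names(model$constants))))
      return(eval_expr(e, model$constants))
    e
  }
  is_const <- function(e) is.numeric(e)

  # --- per-transition arc digest --------------------------------------------
  digest <- function(tid) {
    pre <- list(); post <- list(); mods <- character()
    for (a in model$arcs) {
      if (a$kind == "modifier") {
        if (a$target == tid) mods <- c(mods, a$source)
      } else if (a$target == tid) {
        pre[[length(pre) + 1L]] <- list(place = a$source, w = parse_w(a$weight))
      } else if (a$source == tid) {
        post[[length(post) + 1L]] <- list(place = a$target, w = parse_w(a$weight))
      }
    }
    list(pre = pre, post = post, mods = mods)
  }

  # firing recipe: constant deltas as index/value vectors, dynamic weights kept
  # as expressions (evaluated on the pre-firing marking)
  fire_recipe <- function(dg) {
    di <- integer(); dv <- numeric(); ci <- integer(); cv <- numeric()
    dyn <- list()
    add <- function(place, w, sign) {
      idx_d <- match(place, disc_ids); idx_c <- match(place, cont_ids)
      if (is_const(w)) {
        if (!is.na(idx_d)) { di <<- c(di, idx_d); dv <<- c(dv, sign * w) }
        else { ci <<- c(ci, idx_c); cv <<- c(cv, sign * w) }
      } else {
        dyn[[length(dyn) + 1L]] <<- list(
          disc = !is.na(idx_d), idx = if (!is.na(idx_d)) idx_d else idx_c,
          sign = sign, expr = w)
      }
    }
    for (a in dg$pre) add(a$place, a$w, -1)
    for (a in dg$post) add(a$place, a$w, +1)
    list(di = di, dv = dv, ci = ci, cv = cv, dyn = dyn)
  }

  # enabling recipe: constant discrete pre-arcs vectorized across transitions
  st_digests <- lapply(st_ids, digest)
  names(st_digests) <- st_ids
  en_tidx <- integer(); en_pidx <- integer(); en_w <- numeric()
  en_dyn <- list()    # (tidx, place id, kind, expr) -> checked per event
  en_cont <- list()   # (tidx, cont idx, const w) -> continuous pre-place > 0
  for (k in seq_along(st_ids)) {
    for (a in st_digests[[k]]$pre) {
      idx_d <- match(a$place, disc_ids)
      if (!is.na(idx_d)) {
        if (is_const(a$w)) {
          en_tidx <- c(en_tidx, k); en_pidx <- c(en_pidx, idx_d)
          en_w <- c(en_w, a$w)
        } else {
          en_dyn[[length(en_dyn) + 1L]] <- list(tidx = k, place = a$place,
                                                disc = TRUE, idx = idx_d,
                                                expr = a$w)
        }
      } else {
        idx_c <- match(a$place, cont_ids)
        if (is_const(a$w)) {
          en_cont[[length(en_cont) + 1L]] <- list(tidx = k, idx = idx_c, w = a$w)
        } else {
          en_dyn[[length(en_dyn) + 1L]] <- list(tidx = k, place = a$place,
                                                disc = FALSE, idx = idx_c,
                                                expr = a$w)
        }
      }
    }
  }

  st_rates <- lapply(model$transitions[st_ids], function(tr) parse_expr(tr$rate))
  prop_call <- compile_expr_vector(st_rates)
  st_fire <- lapply(st_digests, fire_recipe)

  im_digests <- lapply(im_ids, digest); names(im_digests) <- im_ids
  im_fire <- lapply(im_digests, fire_recipe)
  im_pre <- lapply(im_digests, `[[`, "pre")

  # --- continuous transitions: stoichiometry and rate vector ----------------
  ct_rates <- lapply(model$transitions[ct_ids], function(tr) parse_expr(tr$rate))
  rate_call <- compile_expr_vector(ct_rates)
  S <- matrix(0, nrow = length(cont_ids), ncol = length(ct_ids),
              dimnames = list(cont_ids, ct_ids))
  ct_dyn <- list()  # (cont idx, ct idx, sign, expr)
  for (k in seq_along(ct_ids)) {
    dg <- digest(ct_ids[k])
    for (a in dg$pre) {
      idx <- match(a$place, cont_ids)
      if (is_const(a$w)) S[idx, k] <- S[idx, k] - a$w
      else ct_dyn[[length(ct_dyn) + 1L]] <- list(pidx = idx, tidx = k,
                                                 sign = -1, expr = a$w)
    }
    for (a in dg$post) {
      idx <- match(a$place, cont_ids)
      if (is_const(a$w)) S[idx, k] <- S[idx, k] + a$w
      else ct_dyn[[length(ct_dyn) + 1L]] <- list(pidx = idx, tidx = k,
                                                 sign = +1, expr = a$w)
    }
  }

  # --- coupling analysis ----------------------------------------------------
  # The stochastic and continuous layers decouple (allowing an exact two-phase
  # simulation: one jump-process pass, one ODE solve with jump events) when no
  # stochastic/immediate element reads or consumes a continuous place and no
  # continuous element reads a discrete place.  Otherwise the general
  # integrated-hazard event loop is used.
  reads_cont <- function(e) length(intersect(expr_vars(e), cont_ids)) > 0L
  reads_disc <- function(e) length(intersect(expr_vars(e), disc_ids)) > 0L
  decoupled <- TRUE
  for (k in seq_along(st_ids)) {
    dg <- st_digests[[k]]
    if (reads_cont(st_rates[[k]])) decoupled <- FALSE
    for (a in dg$pre) {
      if (a$place %in% cont_ids) decoupled <- FALSE
      if (!is_const(a$w) && reads_cont(a$w)) decoupled <- FALSE
    }
    for (a in dg$post) if (!is_const(a$w) && reads_cont(a$w)) decoupled <- FALSE
  }
  for (k in seq_along(im_ids)) {
    dg <- im_digests[[k]]
    for (a in dg$pre) {
      if (a$place %in% cont_ids)
        stop("immediate transition ", sQuote(im_ids[k]),
             " must not consume a continuous place", call. = FALSE)
      if (!is_const(a$w) && reads_cont(a$w)) decoupled <- FALSE
    }
    for (a in dg$post) if (!is_const(a$w) && reads_cont(a$w)) decoupled <- FALSE
  }
  for (k in seq_along(ct_ids)) {
    if (reads_disc(ct_rates[[k]])) decoupled <- FALSE
    dg <- digest(ct_ids[k])
    for (a in c(dg$pre, dg$post))
      if (!is_const(a$w) && reads_disc(a$w)) decoupled <- FALSE
  }

  obs <- model$observables
  if (!length(obs)) {
    obs <- as.list(pids); names(obs) <- pids
  }
  obs_exprs <- lapply(obs, parse_expr)

  # --- bytecode for the C++ kernels (NULL disables the fast path) -----------
  st_rpn <- if (length(st_ids)) compile_rpn_list(st_rates, disc_ids,
                                                 model$constants)
  ct_rpn <- if (!length(ct_dyn)) compile_rpn_list(ct_rates, cont_ids,
                                                  model$constants)
  st_fire_simple <- length(en_dyn) == 0L && length(en_cont) == 0L &&
    all(vapply(st_fire, function(r) length(r$dyn) == 0L, NA))
  Snz <- which(S != 0, arr.ind = TRUE)
  # places whose marking no stochastic/continuous transition can alter
  tids <- transition_ids(model)
  std_arcs <- Filter(function(a) a$kind == "standard", model$arcs)
  produced <- unique(vapply(Filter(function(a) a$source %in% tids, std_arcs),
                            `[[`, "", "target"))
  st_consumed <- unique(vapply(
    Filter(function(a) a$target %in% c(st_ids, ct_ids), std_arcs),
    `[[`, "", "source"))
  inert_places <- setdiff(pids, c(produced, st_consumed))

  list(model = model,
       disc_ids = disc_ids, cont_ids = cont_ids,
       n_disc = length(disc_ids), n_cont = length(cont_ids),
       st_ids = st_ids, n_st = length(st_ids),
       ct_ids = ct_ids, n_ct = length(ct_ids),
       im_ids = im_ids,
       const_env = const_env,
       prop_call = prop_call,
       en_tidx = en_tidx, en_pidx = en_pidx, en_w = en_w,
       en_dyn = en_dyn, en_cont = en_cont,
       st_fire = st_fire, im_fire = im_fire, im_pre = im_pre,
       rate_call = rate_call, S = S, ct_dyn = ct_dyn,
       decoupled = decoupled,
       obs_exprs = obs_exprs,
       st_rpn = st_rpn, ct_rpn = ct_rpn, st_fire_simple = st_fire_simple,
       en_tidx0 = en_tidx - 1L, en_pidx0 = en_pidx - 1L,
       fire_di0 = lapply(st_fire, function(r) r$di - 1L),
       fire_dv = lapply(st_fire, `[[`, "dv"),
       fire_ci0 = lapply(st_fire, function(r) r$ci - 1L),
       fire_cv = lapply(st_fire, `[[`, "cv"),
       S_si = as.integer(Snz[, 1L] - 1L), S_sj = as.integer(Snz[, 2L] - 1L),
       S_sx = S[Snz],
       inert_places = inert_places)
}

# TRUE when no immediate transition can ever fire again: each one is blocked
# by an under-marked pre-place that no stochastic/continuous transition
# produces or consumes (and whose weight depends only on such places).
.immediates_quiescent <- function(cm, md, ev) {
  if (!length(cm$im_ids)) return(TRUE)
  for (k in seq_along(cm$im_ids)) {
    blocked <- FALSE
    for (a in cm$im_pre[[k]]) {
      if (!a$place %in% cm$inert_places) next
      wvars <- if (is.numeric(a$w)) character() else all.vars(a$w)
      if (length(setdiff(wvars, cm$inert_places))) next
      w <- if (is.numeric(a$w)) a$w else eval(a$w, ev)
      if (md[[a$place]] < w - 1e-9) { blocked <- TRUE; break }
    }
    if (!blocked) return(FALSE)
  }
  TRUE
}
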