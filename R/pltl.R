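# PLTL: linear temporal logic with numeric atoms over finite simulation
# traces, wrapped in a probability operator estimated over trace ensembles.
#
# Finite-trace semantics with strong next: at position i (1-based) on a trace
# of length n,
#   X phi   <=>  i+1 <= n and phi holds at i+1
#   G phi   <=>  phi holds at all j in [i, n]
#   F phi   <=>  phi holds at some j in [i, n]
#   phi U psi <=> exists j in [i, n] with psi at j and phi at all k in [i, j)
# Atoms compare two arithmetic expressions over trace column names and
# numeric literals.  ASCII operator spellings: G F X U & | ! -> and the
# probability operator P=? / P<op>x.

#' Pulse-detection thresholds for total p53
#'
#' Three levels (in total-p53 trace units) used by the built-in properties
#' and the pulse-counting oracle: a pulse starts from below the middle
#' threshold `T_M`, must exceed the upper threshold `T_U`, and the no-pulse
#' property requires the signal to stay below the low threshold `T_L`.
#'
#' @param T_L,T_M,T_U Low / middle / upper thresholds, `T_L < T_M < T_U`.
#' @return An object of class `threshold_set`.
#' @export
threshold_set <- function(T_L = 920, T_M = 1200, T_U = 1800) {
  stopifnot(T_L < T_M, T_M < T_U)
  structure(list(T_L = T_L, T_M = T_M, T_U = T_U), class = "threshold_set")
}

# ---- tokenizer --------------------------------------------------------------

.pltl_tokenize <- function(text) {
  pats <- c(
    ws      = "^\\s+",
    num     = "^[0-9]+(\\.[0-9]*)?([eE][+-]?[0-9]+)?",
    pq      = "^P=\\?",
    pb      = "^P(<=|>=|!=|<|>|=)",
    arrow   = "^->",
    cmp     = "^(<=|>=|!=|<|>|=)",
    and     = "^&",
    or      = "^\\|",
    not     = "^!",
    lbrak   = "^\\[", rbrak = "^\\]",
    lpar    = "^\\(", rpar = "^\\)",
    plus    = "^\\+", minus = "^-", times = "^\\*", divide = "^/", pow = "^\\^",
    ident   = "^[A-Za-z_][A-Za-z0-9_.]*"
  )
  toks <- list(); pos <- 1L; n <- nchar(text)
  while (pos <= n) {
    rest <- substr(text, pos, n)
    matched <- FALSE
    for (ty in names(pats)) {
      m <- regmatches(rest, regexpr(pats[[ty]], rest))
      if (length(m) && nzchar(m)) {
        if (ty != "ws") {
          val <- m
          if (ty == "ident" && val %in% c("X", "G", "F", "U"))
            ty <- "temporal"
          if (ty == "ident" && val %in% c("true", "false")) ty <- "bool"
          toks[[length(toks) + 1L]] <- list(type = ty, value = val, pos = pos)
        }
        pos <- pos + nchar(m)
        matched <- TRUE
        break
      }
    }
    if (!matched)
      stop("PLTL syntax error at position ", pos, ": unexpected character ",
           sQuote(substr(text, pos, pos)), call. = FALSE)
  }
  toks
}

# ---- parser (recursive descent with backtracking for atoms) -----------------

.ltl_node <- function(kind, ...) structure(list(kind = kind, ...), class = "ltl_node")

#' Parse a PLTL formula
#'
#' Parses the probability operator (`P=? [ phi ]` or `P<op>x [ phi ]` with
#' `x` in \[0, 1\]) around an LTL path formula.  Operator precedence:
#' unary (`!`, `X`, `G`, `F`) binds tightest, then `&`, then `|`, then `->`
#' (desugared to `!a | b` at parse time), then `U`; parentheses override.
#'
#' @param text A formula string, e.g. `"P=? [ G (p53 < 920) ]"`.
#' @return An object of class `pltl_formula` with fields `mode`
#'   (`"query"`/`"bound"`), `cmp`, `x` and `body` (the LTL AST).
#' @examples
#' f <- parse_pltl("P=? [ F (p53 > 1800) ]")
#' tr <- make_pulse_trace(1)
#' check_trace(f, tr)
#' @export
parse_pltl <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  toks <- .pltl_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$i <- 1L; st$text <- text

  peek <- function() if (st$i <= length(st$toks)) st$toks[[st$i]] else NULL
  advance <- function() { tk <- peek(); st$i <- st$i + 1L; tk }
  expect <- function(type) {
    tk <- peek()
    if (is.null(tk) || tk$type != type)
      stop("PLTL syntax error at position ",
           if (is.null(tk)) nchar(st$text) + 1L else tk$pos,
           ": expected ", type, call. = FALSE)
    advance()
  }

  parse_formula <- function() parse_until()

  parse_until <- function() {
    lhs <- parse_arrow()
    tk <- peek()
    if (!is.null(tk) && tk$type == "temporal" && tk$value == "U") {
      advance()
      rhs <- parse_until()     # right-associative
      return(.ltl_node("U", children = list(lhs, rhs)))
    }
    lhs
  }

  parse_arrow <- function() {
    lhs <- parse_or()
    tk <- peek()
    if (!is.null(tk) && tk$type == "arrow") {
      advance()
      rhs <- parse_arrow()
      # a -> b  desugars to  !a | b
      return(.ltl_node("or", children = list(.ltl_node("not", children = list(lhs)), rhs)))
    }
    lhs
  }

  parse_or <- function() {
    lhs <- parse_and()
    repeat {
      tk <- peek()
      if (is.null(tk) || tk$type != "or") return(lhs)
      advance()
      lhs <- .ltl_node("or", children = list(lhs, parse_and()))
    }
  }

  parse_and <- function() {
    lhs <- parse_unary()
    repeat {
      tk <- peek()
      if (is.null(tk) || tk$type != "and") return(lhs)
      advance()
      lhs <- .ltl_node("and", children = list(lhs, parse_unary()))
    }
  }

  parse_unary <- function() {
    tk <- peek()
    if (is.null(tk))
      stop("PLTL syntax error: unexpected end of input (missing operand)",
           call. = FALSE)
    if (tk$type == "not") {
      advance(); return(.ltl_node("not", children = list(parse_unary())))
    }
    if (tk$type == "temporal" && tk$value %in% c("X", "G", "F")) {
      advance(); return(.ltl_node(tk$value, children = list(parse_unary())))
    }
    parse_primary()
  }

  parse_primary <- function() {
    tk <- peek()
    if (is.null(tk))
      stop("PLTL syntax error: unexpected end of input (missing operand)",
           call. = FALSE)
    if (tk$type == "bool") {
      advance(); return(.ltl_node("bool", value = tk$value == "true"))
    }
    # try an atom (arith cmp arith); on failure reparse as (formula)
    save <- st$i
    atom <- tryCatch(parse_atom(), error = function(e) e)
    if (!inherits(atom, "error")) return(atom)
    st$i <- save
    if (tk$type == "lpar") {
      advance()
      inner <- parse_formula()
      expect("rpar")
      return(inner)
    }
    stop(conditionMessage(atom), call. = FALSE)
  }

  parse_atom <- function() {
    lhs <- parse_aexpr()
    tk <- peek()
    if (is.null(tk) || tk$type != "cmp")
      stop("PLTL syntax error at position ",
           if (is.null(tk)) nchar(st$text) + 1L else tk$pos,
           ": expected a comparison operator", call. = FALSE)
    advance()
    rhs <- parse_aexpr()
    .ltl_node("cmp", op = tk$value, lhs = lhs, rhs = rhs)
  }

  # arithmetic expressions: + - * / ^ over numbers and column names
  parse_aexpr <- function() parse_sum()
  parse_sum <- function() {
    lhs <- parse_prod()
    repeat {
      tk <- peek()
      if (is.null(tk) || !tk$type %in% c("plus", "minus")) return(lhs)
      advance()
      lhs <- call(if (tk$type == "plus") "+" else "-", lhs, parse_prod())
    }
  }
  parse_prod <- function() {
    lhs <- parse_pow()
    repeat {
      tk <- peek()
      if (is.null(tk) || !tk$type %in% c("times", "divide")) return(lhs)
      advance()
      lhs <- call(if (tk$type == "times") "*" else "/", lhs, parse_pow())
    }
  }
  parse_pow <- function() {
    lhs <- parse_aprim()
    tk <- peek()
    if (!is.null(tk) && tk$type == "pow") {
      advance()
      return(call("^", lhs, parse_pow()))
    }
    lhs
  }
  parse_aprim <- function() {
    tk <- peek()
    if (is.null(tk))
      stop("PLTL syntax error: unexpected end of arithmetic expression",
           call. = FALSE)
    if (tk$type == "minus") { advance(); return(call("-", parse_aprim())) }
    if (tk$type == "num") { advance(); return(as.numeric(tk$value)) }
    if (tk$type == "ident") { advance(); return(as.name(tk$value)) }
    if (tk$type == "lpar") {
      advance()
      e <- parse_aexpr()
      expect("rpar")
      return(e)
    }
    stop("PLTL syntax error at position ", tk$pos,
         ": expected a number, name or parenthesis", call. = FALSE)
  }

  # probability operator
  tk <- peek()
  if (is.null(tk) || !tk$type %in% c("pq", "pb"))
    stop("PLTL syntax error: formula must start with the probability operator P",
         call. = FALSE)
  advance()
  mode <- if (tk$type == "pq") "query" else "bound"
  cmp <- NULL; x <- NULL
  if (mode == "bound") {
    cmp <- sub("^P", "", tk$value)
    ntk <- expect("num")
    x <- as.numeric(ntk$value)
    if (x < 0 || x > 1)
      stop("probability bound must lie in [0, 1], got ", x, call. = FALSE)
  }
  expect("lbrak")
  body <- parse_formula()
  expect("rbrak")
  if (!is.null(peek()))
    stop("PLTL syntax error at position ", peek()$pos, ": trailing input",
         call. = FALSE)
  structure(list(mode = mode, cmp = cmp, x = x, body = body),
            class = "pltl_formula")
}

# ---- printer (fully parenthesised; parse(format(f)) == f) -------------------

.format_aexpr <- function(e) {
  if (is.numeric(e)) return(format(e, digits = 15))
  if (is.name(e)) return(as.character(e))
  op <- as.character(e[[1L]])
  if (length(e) == 2L) return(paste0("-", .format_aexpr(e[[2L]])))
  paste0("(", .format_aexpr(e[[2L]]), " ", op, " ", .format_aexpr(e[[3L]]), ")")
}

format_ltl <- function(node) {
  switch(node$kind,
    bool = if (node$value) "true" else "false",
    cmp = paste0(.format_aexpr(node$lhs), " ", node$op, " ",
                 .format_aexpr(node$rhs)),
    not = paste0("!(", format_ltl(node$children[[1L]]), ")"),
    X = paste0("X (", format_ltl(node$children[[1L]]), ")"),
    G = paste0("G (", format_ltl(node$children[[1L]]), ")"),
    F = paste0("F (", format_ltl(node$children[[1L]]), ")"),
    and = paste0("(", format_ltl(node$children[[1L]]), ") & (",
                 format_ltl(node$children[[2L]]), ")"),
    or = paste0("(", format_ltl(node$children[[1L]]), ") | (",
                format_ltl(node$children[[2L]]), ")"),
    U = paste0("(", format_ltl(node$children[[1L]]), ") U (",
               format_ltl(node$children[[2L]]), ")"),
    stop("unknown LTL node kind ", node$kind))
}

#' @export
format.pltl_formula <- function(x, ...) {
  head <- if (x$mode == "query") "P=?" else paste0("P", x$cmp,
                                                   format(x$x, digits = 15))
  paste0(head, " [ ", format_ltl(x$body), " ]")
}

#' @export
print.pltl_formula <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# ---- evaluation -------------------------------------------------------------

# Satisfaction vector of `node` at every position of `trace` (logical, length
# nrow(trace)).  Linear in trace length per node.
eval_ltl_vec <- function(node, trace) {
  n <- nrow(trace)
  rec <- function(nd) {
    switch(nd$kind,
      bool = rep(nd$value, n),
      cmp = {
        env <- list2env(as.list(trace), parent = baseenv())
        lhs <- eval(nd$lhs, env); rhs <- eval(nd$rhs, env)
        if (length(lhs) == 1L) lhs <- rep(lhs, n)
        if (length(rhs) == 1L) rhs <- rep(rhs, n)
        ok <- switch(nd$op,
                     "<" = lhs < rhs, ">" = lhs > rhs,
                     "<=" = lhs <= rhs, ">=" = lhs >= rhs,
                     "=" = lhs == rhs, "!=" = lhs != rhs)
        ok
      },
      not = !rec(nd$children[[1L]]),
      and = rec(nd$children[[1L]]) & rec(nd$children[[2L]]),
      or = rec(nd$children[[1L]]) | rec(nd$children[[2L]]),
      X = {
        v <- rec(nd$children[[1L]])
        c(v[-1L], FALSE)                        # strong next
      },
      G = {
        v <- rec(nd$children[[1L]])
        rev(cumsum(rev(!v))) == 0L
      },
      F = {
        v <- rec(nd$children[[1L]])
        rev(cumsum(rev(v))) > 0L
      },
      U = {
        a <- rec(nd$children[[1L]]); b <- rec(nd$children[[2L]])
        u <- logical(n)
        u[n] <- b[n]
        if (n > 1L) for (i in (n - 1L):1L) u[i] <- b[i] || (a[i] && u[i + 1L])
        u
      },
      stop("unknown LTL node kind ", nd$kind))
  }
  rec(node)
}

ltl_columns <- function(node) {
  if (node$kind == "cmp")
    return(unique(c(all.vars(node$lhs), all.vars(node$rhs))))
  if (!is.null(node$children))
    return(unique(unlist(lapply(node$children, ltl_columns))))
  character()
}

#' Evaluate an LTL path formula on a finite trace
#'
#' @param node An LTL AST node (the `body` of a parsed [parse_pltl()]
#'   formula).
#' @param trace An [hpn_trace()].
#' @param position 1-based trace position at which to evaluate.
#' @return Logical scalar.
#' @export
eval_ltl <- function(node, trace, position = 1L) {
  stopifnot(inherits(node, "ltl_node"), position >= 1L, position <= nrow(trace))
  missing_cols <- setdiff(ltl_columns(node), names(trace))
  if (length(missing_cols))
    stop("unknown column(s) in formula: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  eval_ltl_vec(node, trace)[[position]]
}

#' Check a PLTL formula's path body on one trace
#'
#' Evaluates the LTL body at the first trace position (offline checking of a
#' complete finite run).
#'
#' @param formula A `pltl_formula`.
#' @param trace An `hpn_trace`.
#' @return Logical scalar: does the trace satisfy the path formula?
#' @export
check_trace <- function(formula, trace) {
  stopifnot(inherits(formula, "pltl_formula"))
  eval_ltl(formula$body, trace, 1L)
}

#' Estimate the probability operator over a trace ensemble
#'
#' The satisfying fraction of the ensemble estimates the path-formula
#' probability (each trace contributes a 0/1 indicator; their average is the
#' Monte-Carlo estimate).  In bound mode the estimate is compared against the
#' formula's probability bound.
#'
#' @param formula A `pltl_formula`.
#' @param traces Non-empty list of `hpn_trace` objects.
#' @return Query mode: the estimated probability in \[0, 1\].  Bound mode: a
#'   logical with attribute `"estimate"`.
#' @export
estimate_probability <- function(formula, traces) {
  stopifnot(inherits(formula, "pltl_formula"))
  if (!length(traces)) stop("empty trace ensemble", call. = FALSE)
  sat <- vapply(traces, function(tr) check_trace(formula, tr), NA)
  frac <- mean(sat)
  if (formula$mode == "query") return(frac)
  ok <- switch(formula$cmp,
               "<" = frac < formula$x, ">" = frac > formula$x,
               "<=" = frac <= formula$x, ">=" = frac >= formula$x,
               "=" = frac == formula$x, "!=" = frac != formula$x)
  structure(ok, estimate = frac)
}

#' Built-in pulse-count properties P1, P2, P3
#'
#' The three mutually exclusive, exhaustive path formulas classifying a total
#' p53 trace by pulse count:
#' * `P1` (no pulse): `G (p53 < T_L)` — the signal never reaches the low
#'   threshold.
#' * `P2` (exactly one pulse): the signal starts below `T_M`, eventually
#'   exceeds `T_U`, eventually settles for good below `T_M`, and after any
#'   excursion above `T_U` stays above `T_M` until it drops below `T_U` for
#'   good (so the excursion above the upper threshold happens once).
#' * `P3` (two or more pulses): neither `P1` nor `P2`.
#'
#' @param thresholds A [threshold_set()].
#' @param column Trace column the properties bind to (the derived total-p53
#'   observable).
#' @return Named list of three `pltl_formula` objects.
#' @export
builtin_properties <- function(thresholds = threshold_set(), column = "p53") {
  tl <- format(thresholds$T_L, digits = 15)
  tm <- format(thresholds$T_M, digits = 15)
  tu <- format(thresholds$T_U, digits = 15)
  p1_body <- sprintf("G (%s < %s)", column, tl)
  p2_body <- sprintf(
    "(%s < %s) & F (%s > %s) & F (G (%s < %s)) & G ((%s > %s) -> ((%s > %s) U (G (%s < %s))))",
    column, tm, column, tu, column, tm, column, tu, column, tm, column, tu)
  p3_body <- sprintf("!(%s) & !(%s)", p2_body, p1_body)
  list(P1 = parse_pltl(sprintf("P=? [ %s ]", p1_body)),
       P2 = parse_pltl(sprintf("P=? [ %s ]", p2_body)),
       P3 = parse_pltl(sprintf("P=? [ %s ]", p3_body)))
}

#' Read PLTL properties from a file
#'
#' One formula per line; blank lines and lines starting with `#` are ignored.
#'
#' @param path File path.
#' @return Named list of `pltl_formula` (names `prop1`, `prop2`, ... unless
#'   a line is of the form `name: formula`).
#' @export
read_properties <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    nm <- sprintf("prop%d", i)
    if (grepl("^[A-Za-z_][A-Za-z0-9_]*\\s*:", ln)) {
      nm <- sub("\\s*:.*$", "", ln)
      ln <- sub("^[A-Za-z_][A-Za-z0-9_]*\\s*:\\s*", "", ln)
    }
    out[[nm]] <- parse_pltl(ln)
  }
  out
}
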