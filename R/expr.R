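# Small arithmetic expression language used for rate laws, arc weights and
# observables: numbers, names (place ids and named constants), +, -, *, /, ^
# and parentheses.  Expressions are stored as strings and compiled to R
# language objects once, at model-validation time.

.expr_ops <- c("+", "-", "*", "/", "^", "(")

# Whitelisted function calls.  `round`/`floor`/`ceiling` exist so that
# marking-dependent arc weights can produce integer token counts (e.g. the
# 70/30 split of double-strand breaks); min/max/abs/exp cover saturating and
# decaying rate laws.
.expr_funs <- c("round", "floor", "ceiling", "min", "max", "abs", "exp")

#' Parse a rate-law / arc-weight expression
#'
#' Parses a string in the model's arithmetic expression language and checks
#' that it only uses the permitted operators (`+`, `-`, `*`, `/`, `^`,
#' parentheses), a small set of whitelisted functions (`round`, `floor`,
#' `ceiling`, `min`, `max`, `abs`, `exp`), numeric literals and names.
#' Anything else (assignments, indexing, arbitrary calls) is rejected.
#'
#' @param text A single character string, e.g. `"k * A_n"`.
#' @return An R language object (or numeric constant) with attribute `"text"`.
#' @examples
#' e <- parse_expr("k * A_n")
#' eval_expr(e, list(k = 0.5, A_n = 4))
#' @export
parse_expr <- function(text) {
  if (is.numeric(text) && length(text) == 1L) {
    return(structure(as.numeric(text), text = format(text)))
  }
  stopifnot(is.character(text), length(text) == 1L)
  parsed <- tryCatch(parse(text = text, keep.source = FALSE),
                     error = function(e) stop("expression syntax error in ",
                                              sQuote(text), ": ",
                                              conditionMessage(e), call. = FALSE))
  if (length(parsed) != 1L)
    stop("expected a single expression, got ", length(parsed), " in ",
         sQuote(text), call. = FALSE)
  lang <- parsed[[1L]]
  .check_expr_lang(lang, text)
  if (is.name(lang)) return(lang)   # attributes cannot be set on symbols
  structure(lang, text = text)
}

.check_expr_lang <- function(lang, text) {
  if (is.numeric(lang) || is.name(lang)) return(invisible(TRUE))
  if (is.call(lang)) {
    op <- as.character(lang[[1L]])
    if (!op %in% c(.expr_ops, .expr_funs))
      stop("operator ", sQuote(op), " not allowed in expression ",
           sQuote(text), call. = FALSE)
    for (i in seq_along(lang)[-1L]) .check_expr_lang(lang[[i]], text)
    return(invisible(TRUE))
  }
  stop("invalid token in expression ", sQuote(text), call. = FALSE)
}

#' @rdname parse_expr
#' @param expr A parsed expression from [parse_expr()].
#' @param env A named list or environment supplying place markings and
#'   constants.
#' @export
eval_expr <- function(expr, env) {
  if (is.numeric(expr)) return(as.numeric(expr))
  if (is.list(env)) env <- list2env(env, parent = baseenv())
  eval(expr, env)
}

# Names referenced by a parsed expression (place ids and constants).
expr_vars <- function(expr) {
  if (is.numeric(expr)) return(character())
  all.vars(expr)
}

expr_text <- function(expr) {
  txt <- attr(expr, "text")
  if (!is.null(txt)) txt else paste(deparse(expr), collapse = " ")
}

# Bundle a list of parsed expressions into one `c(...)` call so the whole
# vector is evaluated with a single eval() — the hot path of the simulator.
compile_expr_vector <- function(exprs) {
  stripped <- lapply(exprs, function(e) {
    attributes(e) <- NULL
    e
  })
  as.call(c(quote(c), stripped))
}
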