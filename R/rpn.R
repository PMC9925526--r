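# Compile rate-law expressions to RPN bytecode for the C++ kernels.
# Constants are folded to literals at compile time; place references become
# indices into the marking vector.  Returns NULL when an expression uses a
# construct the bytecode does not cover (the R evaluator is the fallback).

.rpn_ops <- c("+" = 3L, "-" = 4L, "*" = 5L, "/" = 6L, "^" = 7L)
.rpn_un <- c("exp" = 9L, "abs" = 10L, "floor" = 11L, "ceiling" = 12L,
             "round" = 13L)
.rpn_bin <- c("min" = 14L, "max" = 15L)

compile_rpn <- function(lang, var_names, constants) {
  ops <- integer(); args <- numeric()
  emit <- function(op, arg = 0) {
    ops[length(ops) + 1L] <<- op
    args[length(args) + 1L] <<- arg
  }
  ok <- TRUE
  rec <- function(e) {
    if (!ok) return()
    if (is.numeric(e)) { emit(1L, as.numeric(e)); return() }
    if (is.name(e)) {
      nm <- as.character(e)
      idx <- match(nm, var_names)
      if (!is.na(idx)) { emit(2L, idx - 1L) }                 # 0-based
      else if (nm %in% names(constants)) emit(1L, constants[[nm]])
      else ok <<- FALSE
      return()
    }
    if (is.call(e)) {
      op <- as.character(e[[1L]])
      if (op == "(") { rec(e[[2L]]); return() }
      if (op == "-" && length(e) == 2L) { rec(e[[2L]]); emit(8L); return() }
      if (op == "+" && length(e) == 2L) { rec(e[[2L]]); return() }
      if (op %in% names(.rpn_ops) && length(e) == 3L) {
        rec(e[[2L]]); rec(e[[3L]]); emit(.rpn_ops[[op]]); return()
      }
      if (op %in% names(.rpn_un) && length(e) == 2L) {
        rec(e[[2L]]); emit(.rpn_un[[op]]); return()
      }
      if (op %in% names(.rpn_bin) && length(e) == 3L) {
        rec(e[[2L]]); rec(e[[3L]]); emit(.rpn_bin[[op]]); return()
      }
    }
    ok <<- FALSE
  }
  e <- lang
  attributes(e) <- NULL
  rec(e)
  if (!ok) return(NULL)
  list(ops = ops, args = args)
}

# Flattened program set: list(ops, args, off) with 0-based offsets, the form
# the C++ kernels consume.  NULL if any expression fails to compile.
compile_rpn_list <- function(exprs, var_names, constants) {
  progs <- vector("list", length(exprs))
  for (i in seq_along(exprs)) {
    p <- compile_rpn(exprs[[i]], var_names, constants)
    if (is.null(p)) return(NULL)
    progs[[i]] <- p
  }
  lens <- vapply(progs, function(p) length(p$ops), 0L)
  list(ops = as.integer(unlist(lapply(progs, `[[`, "ops"))),
       args = as.numeric(unlist(lapply(progs, `[[`, "args"))),
       off = as.integer(c(0L, cumsum(lens))))
}
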