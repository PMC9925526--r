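# Readers and writers: trace CSV, model files and parameter files.  All
# formats are plain text, comma- or whitespace-separated, "." decimal point,
# LF line endings, so runs are byte-reproducible across platforms.

.fmt_num <- function(x) {
  # shortest decimal representation that round-trips a double exactly
  s <- sprintf("%.15g", x)
  back <- as.numeric(s)
  fix <- !is.na(back) & back != x
  if (any(fix)) s[fix] <- sprintf("%.17g", x[fix])
  s
}

#' Read and write trace CSV files
#'
#' The trace format has a header row, `Time` as first column, one column per
#' observable and plain decimal values.  Writing uses the shortest decimal
#' representation that round-trips each double exactly, so
#' `read_trace_csv(write_trace_csv(tr, f))` reproduces `tr` bit for bit.
#'
#' @param path File path.
#' @return For `read_trace_csv`: an [hpn_trace()].
#' @export
read_trace_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty trace file: ", path, call. = FALSE)
  header <- strsplit(lines[[1L]], ",", fixed = TRUE)[[1L]]
  if (length(header) < 1L || header[1L] != "Time")
    stop("trace file must start with a 'Time' column: ", path, call. = FALSE)
  n <- length(lines) - 1L
  if (n == 0L)
    return(hpn_trace(numeric(),
                     stats::setNames(rep(list(numeric()), length(header) - 1L),
                                     header[-1L])))
  cells <- strsplit(lines[-1L], ",", fixed = TRUE)
  lens <- lengths(cells)
  bad <- which(lens != length(header))
  if (length(bad))
    stop("ragged row in ", path, " at line ", bad[1L] + 1L, ": expected ",
         length(header), " cells, found ", lens[bad[1L]], call. = FALSE)
  m <- matrix(suppressWarnings(as.numeric(unlist(cells))), nrow = n, byrow = TRUE)
  if (anyNA(m)) {
    bad_row <- which(apply(is.na(m), 1L, any))[1L]
    stop("non-numeric cell in ", path, " at line ", bad_row + 1L, call. = FALSE)
  }
  colnames(m) <- header
  hpn_trace(m[, 1L], as.list(as.data.frame(m[, -1L, drop = FALSE],
                                           optional = TRUE)))
}

#' @rdname read_trace_csv
#' @param trace An `hpn_trace`.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "hpn_trace"))
  cols <- vapply(trace, .fmt_num, character(nrow(trace)))
  if (nrow(trace) == 1L) cols <- matrix(cols, nrow = 1L)
  body <- if (nrow(trace)) apply(cols, 1L, paste, collapse = ",") else character()
  con <- file(path, open = "wb")   # binary mode pins LF line endings
  on.exit(close(con))
  writeLines(c(paste(names(trace), collapse = ","), body), con, sep = "\n")
  invisible(path)
}

# ---- model files ------------------------------------------------------------
# Sections: [constants], [places], [transitions], [arcs], [observables].
#   place:       id kind initial
#   transition:  id kind "rate expression" | id immediate priority
#   arc:         source -> target kind [weight]
#   observable:  name = "expression"

.split_fields <- function(line) {
  # whitespace-separated fields, double quotes group
  scan(text = line, what = "character", quiet = TRUE)
}

.quote_expr <- function(w) {
  if (is.numeric(w)) .fmt_num(w) else paste0("\"", w, "\"")
}

#' Read and write hybrid Petri net model files
#'
#' A structured-text format with five sections (`[constants]`, `[places]`,
#' `[transitions]`, `[arcs]`, `[observables]`); see the package vignette for
#' the schema.  `write_hpn_model()` followed by `read_hpn_model()` preserves
#' structure, expressions and constants.  Reading validates the model and
#' stops with the collected diagnostics if it is not well formed.
#'
#' @param path File path.
#' @param validate Stop on validation diagnostics (default `TRUE`).
#' @return For `read_hpn_model`: an `hpn` model.
#' @export
read_hpn_model <- function(path, validate = TRUE) {
  lines <- readLines(path, warn = FALSE)
  section <- ""
  name <- tools::file_path_sans_ext(basename(path))
  places <- list(); transitions <- list(); arcs <- list()
  constants <- list(); observables <- list()
  perr <- function(i, ...) stop("model file ", path, ", line ", i, ": ", ...,
                                call. = FALSE)
  for (i in seq_along(lines)) {
    ln <- trimws(sub("#.*$", "", lines[[i]]))
    if (!nzchar(ln)) next
    if (grepl("^\\[", ln)) {
      section <- sub("^\\[(.*)\\]$", "\\1", ln)
      if (!section %in% c("constants", "places", "transitions", "arcs",
                          "observables"))
        perr(i, "unknown section [", section, "]")
      next
    }
    if (grepl("^hpn\\b", ln)) {
      name <- gsub("\"", "", sub("^hpn\\s+", "", ln))
      next
    }
    f <- .split_fields(ln)
    if (section == "constants") {
      if (length(f) != 3L || f[2L] != "=") perr(i, "expected 'name = value'")
      v <- suppressWarnings(as.numeric(f[3L]))
      if (is.na(v)) perr(i, "non-numeric constant value ", sQuote(f[3L]))
      constants[[f[1L]]] <- v
    } else if (section == "places") {
      if (length(f) != 3L) perr(i, "expected 'id kind initial'")
      v <- suppressWarnings(as.numeric(f[3L]))
      if (is.na(v)) perr(i, "non-numeric initial marking")
      if (!f[2L] %in% c("discrete", "continuous")) perr(i, "unknown place kind ", sQuote(f[2L]))
      places[[length(places) + 1L]] <- hpn_place(f[1L], f[2L], v)
    } else if (section == "transitions") {
      if (length(f) < 2L) perr(i, "expected 'id kind ...'")
      kind <- f[2L]
      if (!kind %in% c("stochastic", "continuous", "immediate"))
        perr(i, "unknown transition kind ", sQuote(kind))
      if (kind == "immediate") {
        prio <- if (length(f) >= 3L) suppressWarnings(as.integer(f[3L])) else 0L
        if (is.na(prio)) perr(i, "non-integer priority")
        transitions[[length(transitions) + 1L]] <-
          hpn_transition(f[1L], kind, priority = prio)
      } else {
        if (length(f) != 3L) perr(i, "expected 'id kind \"rate\"'")
        transitions[[length(transitions) + 1L]] <-
          hpn_transition(f[1L], kind, rate = f[3L])
      }
    } else if (section == "arcs") {
      if (length(f) < 4L || f[2L] != "->")
        perr(i, "expected 'source -> target kind [weight]'")
      kind <- f[4L]
      if (!kind %in% c("standard", "modifier")) perr(i, "unknown arc kind ", sQuote(kind))
      if (kind == "modifier") {
        if (length(f) != 4L) perr(i, "modifier arcs carry no weight")
        arcs[[length(arcs) + 1L]] <- hpn_arc(f[1L], f[3L], "modifier")
      } else {
        if (length(f) != 5L) perr(i, "expected a weight")
        w <- suppressWarnings(as.numeric(f[5L]))
        arcs[[length(arcs) + 1L]] <-
          hpn_arc(f[1L], f[3L], "standard", if (is.na(w)) f[5L] else w)
      }
    } else if (section == "observables") {
      if (length(f) != 3L || f[2L] != "=") perr(i, "expected 'name = \"expression\"'")
      observables[[f[1L]]] <- f[3L]
    } else {
      perr(i, "content outside any section")
    }
  }
  model <- hpn_model(places, transitions, arcs, constants, observables,
                     name = name, validate = FALSE)
  if (validate) {
    diags <- validate_hpn(model)
    if (length(diags))
      stop("model file ", path, " fails validation:\n",
           paste("-", diags, collapse = "\n"), call. = FALSE)
  }
  model
}

#' @rdname read_hpn_model
#' @param model An `hpn` model.
#' @export
write_hpn_model <- function(model, path) {
  stopifnot(inherits(model, "hpn"))
  out <- c(paste0("hpn \"", model$name, "\""), "", "[constants]")
  for (nm in names(model$constants))
    out <- c(out, paste(nm, "=", .fmt_num(model$constants[[nm]])))
  out <- c(out, "", "[places]")
  for (p in model$places)
    out <- c(out, paste(p$id, p$kind, .fmt_num(p$initial)))
  out <- c(out, "", "[transitions]")
  for (tr in model$transitions) {
    out <- c(out, if (tr$kind == "immediate") {
      paste(tr$id, "immediate", if (is.null(tr$priority)) 0L else tr$priority)
    } else {
      paste(tr$id, tr$kind, paste0("\"", tr$rate, "\""))
    })
  }
  out <- c(out, "", "[arcs]")
  for (a in model$arcs) {
    out <- c(out, if (a$kind == "modifier") {
      paste(a$source, "->", a$target, "modifier")
    } else {
      paste(a$source, "->", a$target, "standard", .quote_expr(a$weight))
    })
  }
  if (length(model$observables)) {
    out <- c(out, "", "[observables]")
    for (nm in names(model$observables))
      out <- c(out, paste(nm, "=", paste0("\"", model$observables[[nm]], "\"")))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(out, con, sep = "\n")
  invisible(path)
}

# ---- parameter files --------------------------------------------------------

#' Read and write parameter-set files
#'
#' Flat key-value text: an optional `provenance = ...` line, a `[constants]`
#' section (kinetic constants) and an `[initial]` section (initial markings
#' by place id).
#'
#' @param path File path.
#' @return For `read_parameter_set`: a [parameter_set()].
#' @export
read_parameter_set <- function(path) {
  lines <- readLines(path, warn = FALSE)
  section <- ""
  constants <- list(); initial <- numeric(); provenance <- "user"
  for (i in seq_along(lines)) {
    ln <- trimws(sub("#.*$", "", lines[[i]]))
    if (!nzchar(ln)) next
    if (grepl("^\\[", ln)) {
      section <- sub("^\\[(.*)\\]$", "\\1", ln)
      if (!section %in% c("constants", "initial"))
        stop("parameter file ", path, ", line ", i, ": unknown section [",
             section, "]", call. = FALSE)
      next
    }
    f <- .split_fields(ln)
    if (length(f) != 3L || f[2L] != "=")
      stop("parameter file ", path, ", line ", i, ": expected 'name = value'",
           call. = FALSE)
    if (f[1L] == "provenance" && section == "") {
      provenance <- f[3L]
      next
    }
    v <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(v))
      stop("parameter file ", path, ", line ", i, ": non-numeric value",
           call. = FALSE)
    if (section == "initial") initial[f[1L]] <- v
    else constants[[f[1L]]] <- v
  }
  parameter_set(constants, initial, provenance)
}

#' @rdname read_parameter_set
#' @param params A `parameter_set`.
#' @export
write_parameter_set <- function(params, path) {
  stopifnot(inherits(params, "parameter_set"))
  out <- c(paste("provenance =", params$provenance), "", "[constants]")
  for (nm in names(params$constants))
    out <- c(out, paste(nm, "=", .fmt_num(params$constants[[nm]])))
  out <- c(out, "", "[initial]")
  for (nm in names(params$initial))
    out <- c(out, paste(nm, "=", .fmt_num(params$initial[[nm]])))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(out, con, sep = "\n")
  invisible(path)
}
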