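# Internal helpers shared across modules.

# Signal a classed error so callers can distinguish validation failures.
igems_error <- function(class, msg, call. = sys.call(-1)) {
  stop(structure(
    class = c(class, "igems_error", "error", "condition"),
    list(message = msg, call = call.)
  ))
}

igems_validation_error <- function(class, msg) {
  igems_error(c(class, "igems_validation_error"), msg, call. = sys.call(-2))
}

# Lightweight logging: messages are collected by the pipeline's logger when
# one is active, otherwise emitted with message().
.igems_log_env <- new.env(parent = emptyenv())

igems_log <- function(fmt, ...) {
  txt <- sprintf(fmt, ...)
  if (!is.null(.igems_log_env$sink)) {
    .igems_log_env$sink(txt)
  } else {
    message(txt)
  }
  invisible(txt)
}

with_log_collector <- function(code) {
  lines <- character(0)
  old <- .igems_log_env$sink
  .igems_log_env$sink <- function(txt) lines <<- c(lines, txt)
  on.exit(.igems_log_env$sink <- old)
  result <- force(code)
  list(result = result, log = lines)
}

# Deterministic child seeds from a master seed, kept within 32-bit range.
spawn_seeds <- function(seed, n) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
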