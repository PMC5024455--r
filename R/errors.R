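# Typed conditions so callers (and the CLI exit-code mapping) can
# distinguish bad inputs from bad configuration from I/O failures.

stop_typed <- function(class, ...) {
  msg <- paste0(...)
  stop(structure(class = c(class, "fusioncounter_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stop_validation <- function(...) stop_typed("fusioncounter_validation_error", ...)
stop_config     <- function(...) stop_typed("fusioncounter_config_error", ...)
stop_parse      <- function(...) stop_typed("fusioncounter_parse_error", ...)
stop_io         <- function(...) stop_typed("fusioncounter_io_error", ...)

# run an expression with the RNG seeded, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
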