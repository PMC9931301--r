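# Classed error helpers so callers (and the CLI) can distinguish
# configuration, data, protocol and numeric failures.

abort_fedtte <- function(message, class) {
  stop(structure(
    class = c(class, "fedtte_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

config_error   <- function(msg) abort_fedtte(msg, "fedtte_config_error")
data_error     <- function(msg) abort_fedtte(msg, "fedtte_data_error")
protocol_error <- function(msg) abort_fedtte(msg, "fedtte_protocol_error")
numeric_error  <- function(msg) abort_fedtte(msg, "fedtte_numeric_error")
io_error       <- function(msg) abort_fedtte(msg, "fedtte_io_error")
range_error    <- function(msg) abort_fedtte(msg, "fedtte_range_error")
simulation_error <- function(msg) abort_fedtte(msg, "fedtte_simulation_error")

# Run an expression under a temporary RNG seed, restoring the caller's
# RNG state afterwards. seed = NULL leaves the RNG stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
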