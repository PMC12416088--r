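`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom withr with_seed
NULL

# Evaluate expr under a local RNG seeded with `seed`, restoring global state.
local_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Derive a child seed; kept below 2^31 so it is a valid R integer.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 9973) %% 2147483647L)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)

stop_alscreen <- function(msg, class) {
  stop(structure(class = c(class, "alscreen_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

abort_format <- function(msg) stop_alscreen(msg, "alscreen_format_error")
abort_validation <- function(msg) stop_alscreen(msg, "alscreen_validation_error")
abort_integrity <- function(msg) stop_alscreen(msg, "alscreen_integrity_error")
abort_training <- function(msg) stop_alscreen(msg, "alscreen_training_error")
abort_domain <- function(msg) stop_alscreen(msg, "alscreen_domain_error")
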