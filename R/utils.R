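# Internal helpers shared across modules.

#' Signal a classed error
#'
#' All user-facing errors in the package carry the class `cycleASF_error`
#' plus a subclass naming the failure mode, so callers can condition on
#' them with `tryCatch(..., cycleASF_invalid_input = ...)`.
#'
#' @noRd
abort_cycleASF <- function(message, subclass, call = sys.call(-1), data = NULL) {
  cond <- errorCondition(
    message,
    class = c(paste0("cycleASF_", subclass), "cycleASF_error"),
    call = call
  )
  if (!is.null(data)) cond$data <- data
  stop(cond)
}

stop_invalid <- function(message) abort_cycleASF(message, "invalid_input")

check_scalar_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid(sprintf("`%s` must be a single finite number", name))
  }
  if (positive && x <= 0) {
    stop_invalid(sprintf("`%s` must be > 0 (got %g)", name, x))
  }
  if (nonneg && x < 0) {
    stop_invalid(sprintf("`%s` must be >= 0 (got %g)", name, x))
  }
  invisible(x)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. `seed = NULL` leaves the ambient stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_invalid("`seed` must be a single integer")
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and a stream index, staying inside
# the 32-bit integer range R requires for set.seed().
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1000003 + index * 7919) %% 2147483629L)
}
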