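## Internal helpers: classed conditions, RNG scoping, small numerics.

stop_cellkin <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "cellkin_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

input_error   <- function(msg, ...) stop_cellkin("cellkin_input_error", msg, ...)
format_error  <- function(msg, ...) stop_cellkin("cellkin_format_error", msg, ...)
io_error      <- function(msg, ...) stop_cellkin("cellkin_io_error", msg, ...)
consistency_error <- function(msg, ...) stop_cellkin("cellkin_consistency_error", msg, ...)
degenerate_error  <- function(msg, ...) stop_cellkin("cellkin_degenerate_error", msg, ...)
no_object_error   <- function(msg, ...) stop_cellkin("cellkin_no_object_error", msg, ...)
parse_error   <- function(msg, ...) stop_cellkin("cellkin_parse_error", msg, ...)

#' Evaluate an expression with a locally seeded RNG
#'
#' Saves and restores `.Random.seed` so seeded simulation helpers never
#' disturb the caller's random stream.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## scalar checks
chk_num1 <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    input_error("'%s' must be a single finite number", name)
  if (positive && x <= 0) input_error("'%s' must be > 0", name)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
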