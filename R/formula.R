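## Expression-defined custom formulas (the "Function editor"): a small,
## validated arithmetic language over named series and scalars.
## Grammar: + - * / ^, parentheses, functions exp, log, sqrt, abs, min,
## max (min/max are elementwise across their arguments). Unknown
## identifiers are rejected at parse time; division by zero yields
## per-element NaN with a warning.

FORMULA_FUNS <- c("exp", "log", "sqrt", "abs", "min", "max")
FORMULA_OPS <- c("+", "-", "*", "/", "^", "(")

#' Parse a formula expression
#'
#' @param text expression string, e.g. `"inner_mean - shell_mean"`.
#' @param vars character vector of identifiers that may appear.
#' @return an object of class `"FormulaExpr"`.
#' @examples
#' parse_formula("exp(-k*t)", c("k", "t"))
#' @export
parse_formula <- function(text, vars = character()) {
  expr <- tryCatch(parse(text = text, keep.source = FALSE)[[1]],
                   error = function(e)
                     parse_error("cannot parse '%s': %s", text,
                                 conditionMessage(e)))
  validate_formula_ast(expr, vars, text)
  structure(list(text = text, expr = expr, vars = vars),
            class = "FormulaExpr")
}

validate_formula_ast <- function(e, vars, text) {
  if (is.numeric(e) || is.integer(e)) return(invisible(TRUE))
  if (is.symbol(e)) {
    nm <- as.character(e)
    if (!(nm %in% vars))
      parse_error("unknown identifier '%s' in \"%s\"", nm, text)
    return(invisible(TRUE))
  }
  if (is.call(e)) {
    fn <- as.character(e[[1]])
    if (!(fn %in% c(FORMULA_FUNS, FORMULA_OPS)))
      parse_error("function or operator '%s' is not allowed in \"%s\"", fn, text)
    for (i in seq_along(e)[-1]) validate_formula_ast(e[[i]], vars, text)
    return(invisible(TRUE))
  }
  parse_error("unsupported element in \"%s\"", text)
}

eval_ast <- function(e, env, state) {
  if (is.numeric(e)) return(e)
  if (is.symbol(e)) return(env[[as.character(e)]])
  fn <- as.character(e[[1]])
  args <- lapply(seq_along(e)[-1], function(i) eval_ast(e[[i]], env, state))
  switch(fn,
    "(" = args[[1]],
    "+" = if (length(args) == 1L) args[[1]] else args[[1]] + args[[2]],
    "-" = if (length(args) == 1L) -args[[1]] else args[[1]] - args[[2]],
    "*" = args[[1]] * args[[2]],
    "/" = {
      den <- args[[2]]
      zero <- den == 0
      if (any(zero)) {
        state$div0 <- TRUE
        den[zero] <- NA_real_
        out <- args[[1]] / den
        out[rep_len(zero, length(out))] <- NaN
        out
      } else args[[1]] / den
    },
    "^" = args[[1]]^args[[2]],
    "exp" = exp(args[[1]]),
    "log" = log(args[[1]]),
    "sqrt" = sqrt(args[[1]]),
    "abs" = abs(args[[1]]),
    "min" = do.call(pmin, args),
    "max" = do.call(pmax, args))
}

#' Evaluate a formula over named series and scalars
#'
#' @param expr a `"FormulaExpr"` from [parse_formula()], or a string
#'   (parsed against the names of `bindings`).
#' @param bindings named list of equal-length numeric series and scalars.
#' @return a numeric series (elementwise evaluation, standard precedence).
#' @examples
#' eval_formula("2+3*4", list())
#' @export
eval_formula <- function(expr, bindings = list()) {
  if (is.character(expr)) expr <- parse_formula(expr, names(bindings))
  if (!inherits(expr, "FormulaExpr")) input_error("'expr' must be a FormulaExpr")
  missing_ids <- setdiff(expr$vars, names(bindings))
  if (length(missing_ids))
    input_error("unbound identifiers: %s", paste(missing_ids, collapse = ", "))
  lens <- vapply(bindings, length, integer(1))
  if (length(lens) && length(unique(lens[lens > 1L])) > 1L)
    input_error("all series bindings must have equal length")
  state <- new.env(parent = emptyenv())
  state$div0 <- FALSE
  out <- eval_ast(expr$expr, bindings, state)
  if (isTRUE(state$div0)) warning("division by zero produced NaN elements")
  out
}
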