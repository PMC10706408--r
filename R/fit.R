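## Model specification and bounded least-squares fitting.
##
## A ModelSpec is a named parametric curve y(t; theta): either one of the
## built-ins ("crc1".."crc3", "expdecay", "frap1", "frap2", "diffusion")
## or an expression over t and declared parameters. Fitting minimizes the
## residual sum of squares with bounded Levenberg-Marquardt
## (minpack.lm) from user initials: the initials only nudge the
## optimizer, the solver does the rest.

#' Define a kinetic model from an expression or built-in id
#'
#' @param spec expression string over `t` and the declared parameters
#'   (grammar of [parse_formula()]), or a built-in id: `"crc1"`,
#'   `"crc2"`, `"crc3"`, `"expdecay"`, `"frap1"`, `"frap2"`,
#'   `"diffusion"`.
#' @param params named list or vector of initial parameter values
#'   (required for expression models; optional to override built-in
#'   defaults).
#' @param lower,upper named bounds (optional; built-ins supply
#'   positivity bounds for rates).
#' @param name model name (defaults to the built-in id or the
#'   expression).
#' @return an object of class `"ModelSpec"` with fields `name`, `fn(t,
#'   par)`, `par_names`, `init`, `lower`, `upper`.
#' @examples
#' m <- parse_model("C + A*exp(-k*t)", params = c(A = 1, k = 0.1, C = 0))
#' m$fn(c(0, 10), c(A = 1, k = 0.1, C = 0))
#' @export
parse_model <- function(spec, params = NULL, lower = NULL, upper = NULL,
                        name = NULL) {
  if (spec %in% names(BUILTIN_MODELS)) {
    m <- BUILTIN_MODELS[[spec]]()
    if (!is.null(params)) m$init[names(params)] <- unlist(params)
    if (!is.null(lower)) m$lower[names(lower)] <- unlist(lower)
    if (!is.null(upper)) m$upper[names(upper)] <- unlist(upper)
    if (!is.null(name)) m$name <- name
    return(m)
  }
  if (is.null(params) || is.null(names(params)) || any(names(params) == ""))
    input_error("expression models need named 'params'")
  par_names <- names(params)
  fexpr <- parse_formula(spec, c("t", par_names))
  fn <- function(t, par) {
    eval_formula(fexpr, c(list(t = t), as.list(par)))
  }
  new_model_spec(name %||% spec, fn, par_names,
                 init = unlist(params),
                 lower = fill_named(lower, par_names, -Inf),
                 upper = fill_named(upper, par_names, Inf),
                 expression = spec)
}

fill_named <- function(x, nms, default) {
  out <- stats::setNames(rep(default, length(nms)), nms)
  if (!is.null(x)) out[names(x)] <- unlist(x)
  out
}

new_model_spec <- function(name, fn, par_names, init, lower, upper,
                           expression = NULL) {
  structure(list(name = name, fn = fn, par_names = par_names,
                 init = init[par_names], lower = lower[par_names],
                 upper = upper[par_names], expression = expression),
            class = "ModelSpec")
}

#' @export
print.ModelSpec <- function(x, ...) {
  cat(sprintf("<ModelSpec %s: parameters %s>\n", x$name,
              paste(x$par_names, collapse = ", ")))
  invisible(x)
}

crc_builtin <- function(m) {
  knames <- paste0("k", seq_len(m))
  pn <- c(knames, "kr", "f_rem", "A", "B")
  function() new_model_spec(
    paste0("crc", m),
    function(t, par) crc_model(t, k = unname(par[knames]), kr = par[["kr"]],
                               f_rem = par[["f_rem"]], A = par[["A"]],
                               B = par[["B"]]),
    pn,
    init = stats::setNames(c(0.1 / seq_len(m), 0.01, 0.8, 1, 0), pn),
    lower = stats::setNames(c(rep(1e-8, m), 0, 0, 1e-12, -Inf), pn),
    upper = stats::setNames(c(rep(Inf, m), Inf, 1, Inf, Inf), pn))
}

BUILTIN_MODELS <- list(
  crc1 = crc_builtin(1L),
  crc2 = crc_builtin(2L),
  crc3 = crc_builtin(3L),
  expdecay = function() new_model_spec(
    "expdecay",
    function(t, par) exp_decay_model(t, par[["A"]], par[["k"]], par[["C"]]),
    c("A", "k", "C"),
    init = c(A = 1, k = 0.1, C = 0),
    lower = c(A = -Inf, k = 1e-8, C = -Inf),
    upper = c(A = Inf, k = Inf, C = Inf)),
  frap1 = function() new_model_spec(
    "frap1",
    function(t, par) par[["Finf"]] -
      (par[["Finf"]] - par[["F0"]]) * exp(-par[["k"]] * t),
    c("F0", "Finf", "k"),
    init = c(F0 = 0, Finf = 1, k = 0.05),
    lower = c(F0 = -Inf, Finf = -Inf, k = 1e-8),
    upper = c(F0 = Inf, Finf = Inf, k = Inf)),
  frap2 = function() new_model_spec(
    ## parameterized as (F0, B1, B2, k1, k2); Finf := F0 + B1 + B2, which
    ## enforces the amplitude constraint by construction
    "frap2",
    function(t, par) (par[["F0"]] + par[["B1"]] + par[["B2"]]) -
      par[["B1"]] * exp(-par[["k1"]] * t) -
      par[["B2"]] * exp(-par[["k2"]] * t),
    c("F0", "B1", "B2", "k1", "k2"),
    init = c(F0 = 0.2, B1 = 0.5, B2 = 0.2, k1 = 0.05, k2 = 0.005),
    lower = c(F0 = -Inf, B1 = 0, B2 = 0, k1 = 1e-8, k2 = 1e-8),
    upper = c(F0 = Inf, B1 = Inf, B2 = Inf, k1 = Inf, k2 = Inf)),
  diffusion = function() new_model_spec(
    "diffusion",
    function(t, par) diffusion_model(t, par[["tau_D"]], par[["M"]],
                                     par[["F0"]]),
    c("F0", "M", "tau_D"),
    init = c(F0 = 0.2, M = 1, tau_D = 10),
    lower = c(F0 = -Inf, M = -Inf, tau_D = 1e-6),
    upper = c(F0 = Inf, M = Inf, tau_D = Inf))
)

#' Load a plain-text model library
#'
#' One model per block, blocks separated by blank lines:
#' ```
#' [model_name]
#' expression over t and parameters   # or: builtin: crc2
#' param = init [lower, upper]        # one line per parameter
#' ```
#' The packaged library of recruitment-chain equations is at
#' `system.file("extdata", "crc_models.txt", package = "cellkin")`.
#'
#' @param path path to a model library file.
#' @return named list of `"ModelSpec"` objects.
#' @export
load_model_library <- function(path) {
  if (!file.exists(path)) input_error("model library '%s' not found", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[!grepl("^#", lines)]
  blocks <- split(lines, cumsum(grepl("^\\[", lines)))
  blocks <- blocks[vapply(blocks, function(b) any(grepl("^\\[", b)), logical(1))]
  models <- list()
  for (b in blocks) {
    b <- b[nzchar(b)]
    nm <- sub("^\\[(.*)\\]$", "\\1", b[1])
    body <- b[-1]
    if (grepl("^builtin:", body[1])) {
      models[[nm]] <- parse_model(trimws(sub("^builtin:", "", body[1])),
                                  name = nm)
      next
    }
    expr <- body[1]
    pl <- body[-1]
    init <- numeric(); lower <- numeric(); upper <- numeric()
    for (p in pl) {
      mt <- regmatches(p, regexec(
        "^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*([-+0-9.eE]+)(\\s*\\[([^,]+),([^\\]]+)\\])?", p))[[1]]
      if (length(mt) == 0L) parse_error("bad parameter line '%s' in %s", p, nm)
      init[mt[2]] <- as.numeric(mt[3])
      lower[mt[2]] <- if (nzchar(mt[4])) as.numeric(mt[5]) else -Inf
      upper[mt[2]] <- if (nzchar(mt[4])) as.numeric(mt[6]) else Inf
    }
    models[[nm]] <- parse_model(expr, params = init, lower = lower,
                                upper = upper, name = nm)
  }
  models
}

## ---- fitting --------------------------------------------------------------

#' Fit a kinetic model to a curve by bounded least squares
#'
#' Minimizes the residual sum of squares with Levenberg-Marquardt
#' (minpack.lm), box-constrained by the model's bounds. Deterministic
#' given the initials. Non-finite model output during the search is
#' penalized and flagged; the best parameters seen are returned.
#'
#' @param model a `"ModelSpec"` (or built-in id string).
#' @param curve a `"KineticsCurve"`, or anything with `t` and `y`.
#' @param initials named numeric overrides of the model's initial values.
#' @param lower,upper named bound overrides.
#' @return an object of class `"kin_fit"` with `coef`, `rss`,
#'   `r_squared`, `converged`, `n_iter`, the initials used, and the data.
#'   Methods: `print`, `summary`, `coef`, `predict`, `residuals`,
#'   `fitted`, `plot`.
#' @examples
#' cv <- kinetics_curve(0:100, exp_decay_model(0:100, A = 2, k = 0.05, C = 1))
#' fit <- fit_model("expdecay", cv, initials = c(A = 1, k = 0.1, C = 0))
#' coef(fit)
#' @export
fit_model <- function(model, curve, initials = NULL, lower = NULL,
                      upper = NULL) {
  if (is.character(model)) model <- parse_model(model)
  if (!inherits(model, "ModelSpec")) input_error("'model' must be a ModelSpec")
  t <- curve$t; y <- curve$y
  if (length(t) <= length(model$par_names))
    input_error("need more points (%d) than parameters (%d)", length(t),
                length(model$par_names))
  init <- model$init
  if (!is.null(initials)) init[names(initials)] <- unlist(initials)
  lo <- model$lower; up <- model$upper
  if (!is.null(lower)) lo[names(lower)] <- unlist(lower)
  if (!is.null(upper)) up[names(upper)] <- unlist(upper)
  init <- pmin(pmax(init, lo), up)

  bad_model_output <- FALSE
  resid_fn <- function(par) {
    names(par) <- model$par_names
    yy <- tryCatch(model$fn(t, par), error = function(e) rep(NA_real_, length(t)))
    r <- y - yy
    if (any(!is.finite(r))) {
      bad_model_output <<- TRUE
      r[!is.finite(r)] <- 1e6 * max(1, stats::sd(y))
    }
    r
  }
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                     ptol = 1e-12)
  res <- minpack.lm::nls.lm(par = init, lower = lo, upper = up,
                            fn = resid_fn, control = ctrl)
  par <- stats::setNames(as.numeric(res$par), model$par_names)
  fitted <- model$fn(t, par)
  rss <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - rss / ss_tot else NA_real_
  converged <- res$info %in% c(1, 2, 3, 4) && !bad_model_output
  structure(list(model = model, coef = par, rss = rss, r_squared = r2,
                 converged = converged, n_iter = res$niter,
                 initials = init, t = t, y = y, fitted = fitted,
                 info = res$info, message = res$message),
            class = "kin_fit")
}

#' @export
print.kin_fit <- function(x, ...) {
  cat(sprintf("Kinetic model fit: %s\n", x$model$name))
  cat("Coefficients:\n")
  print(signif(x$coef, 6))
  cat(sprintf("RSS %.6g, R-squared %.6f, %sconverged in %d iterations\n",
              x$rss, x$r_squared, if (x$converged) "" else "NOT ", x$n_iter))
  invisible(x)
}

#' @export
summary.kin_fit <- function(object, ...) {
  res <- object$y - object$fitted
  out <- list(model = object$model$name, coef = object$coef,
              initials = object$initials, rss = object$rss,
              r_squared = object$r_squared, converged = object$converged,
              n_iter = object$n_iter, n = length(object$y),
              sigma = sqrt(object$rss / max(1, length(object$y) -
                                              length(object$coef))),
              resid_range = range(res))
  class(out) <- "summary.kin_fit"
  out
}

#' @export
print.summary.kin_fit <- function(x, ...) {
  cat(sprintf("Model: %s (n = %d)\n", x$model, x$n))
  cat("Parameters (initial -> fitted):\n")
  for (nm in names(x$coef))
    cat(sprintf("  %-8s %.6g -> %.6g\n", nm, x$initials[[nm]], x$coef[[nm]]))
  cat(sprintf("RSS %.6g | residual sigma %.4g | R-squared %.6f\n",
              x$rss, x$sigma, x$r_squared))
  cat(if (x$converged) "Converged" else "Did not converge",
      sprintf("(%d iterations)\n", x$n_iter))
  invisible(x)
}

#' @export
coef.kin_fit <- function(object, ...) object$coef

#' @export
fitted.kin_fit <- function(object, ...) object$fitted

#' @export
residuals.kin_fit <- function(object, ...) object$y - object$fitted

#' @export
predict.kin_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$t
       else if (is.list(newdata)) newdata$t else newdata
  object$model$fn(t, object$coef)
}

#' @export
plot.kin_fit <- function(x, ...) {
  graphics::plot(x$t, x$y, pch = 16, cex = 0.5, xlab = "time (s)",
                 ylab = "intensity", main = x$model$name, ...)
  tt <- seq(min(x$t), max(x$t), length.out = 400)
  graphics::lines(tt, x$model$fn(tt, x$coef), col = "red", lwd = 2)
  invisible(x)
}

#' Derived FRAP quantities from a double-exponential fit
#'
#' @param fit a `"kin_fit"` of the `"frap2"` (or `"frap1"`) model.
#' @param F_pre pre-bleach reference intensity (1 on normalized curves).
#' @return a list with `half_time_s`, `mobile_fraction`, and the
#'   underlying [frap_params()].
#' @export
frap_derive <- function(fit, F_pre = 1) {
  cf <- coef(fit)
  p <- if (fit$model$name == "frap1")
    frap_params("single", F0 = cf[["F0"]], Finf = cf[["Finf"]],
                k = cf[["k"]], F_pre = F_pre)
  else {
    if (cf[["k2"]] > cf[["k1"]])      # canonical labeling: k1 is the fast rate
      cf[c("k1", "k2", "B1", "B2")] <- cf[c("k2", "k1", "B2", "B1")]
    frap_params("double", F0 = cf[["F0"]], B1 = cf[["B1"]], B2 = cf[["B2"]],
                k1 = cf[["k1"]], k2 = cf[["k2"]], F_pre = F_pre)
  }
  list(half_time_s = frap_half_time(p),
       mobile_fraction = mobile_fraction(p),
       params = p)
}

#' Export a fit result as TSV and/or JSON
#' @param fit a `"kin_fit"`.
#' @param path output path; extension `.json` selects JSON, else TSV.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(
      model = fit$model$name, coef = as.list(fit$coef), rss = fit$rss,
      r_squared = fit$r_squared, converged = fit$converged,
      n_iter = fit$n_iter, initials = as.list(fit$initials)),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    utils::write.table(
      data.frame(parameter = names(fit$coef), value = as.numeric(fit$coef),
                 initial = as.numeric(fit$initials)),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
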