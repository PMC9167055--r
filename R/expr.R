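# LEMS expression handling.
#
# LEMS value/condition expressions are parsed into R language objects (ASTs).
# The same ASTs are (a) deparsed into generated kernel source and (b) evaluated
# directly by the interpreted reference simulator, so both execution paths
# perform identical floating-point operations.

.fb_fun_whitelist <- c(
  "exp", "ln", "log", "log10", "sqrt", "abs", "sin", "cos", "tanh",
  "H", "random", "hh_explinear",
  "+", "-", "*", "/", "^", "(",
  ">", "<", ">=", "<=", "==", "!=", "&", "|", "!"
)

#' @keywords internal
#' Heaviside step function used in LEMS expressions (H(0) = 0.5, LEMS
#' convention).
H <- function(x) 0.5 * (sign(x) + 1)

#' @keywords internal
#' Guarded x / (1 - exp(-x)) used by the exponential-linear HH rate form;
#' returns the limit 1 at the removable singularity.
hh_explinear <- function(x) {
  ifelse(x == 0, 1, x / (1 - exp(-x)))
}

#' Parse a LEMS expression into an R AST
#'
#' Accepts the LEMS arithmetic/comparison subset: `+ - * / ^`, comparisons
#' (both symbolic `>` and dotted `.gt. .lt. .geq. .leq. .eq. .neq. .and. .or.`
#' forms), and the functions exp, ln, log (10-based per LEMS), sqrt, abs, sin,
#' cos, tanh, H and random. `ln` is mapped to natural log, `log` to log10.
#'
#' @param text expression string.
#' @return an R language object.
#' @keywords internal
fb_parse_expr <- function(text) {
  s <- text
  # dotted LEMS comparison/logic operators
  subs <- c(
    "\\.gt\\."  = ">",  "\\.lt\\."  = "<",
    "\\.geq\\." = ">=", "\\.leq\\." = "<=",
    "\\.eq\\."  = "==", "\\.neq\\." = "!=",
    "\\.and\\." = "&",  "\\.or\\."  = "|"
  )
  for (pat in names(subs)) s <- gsub(pat, subs[[pat]], s)
  ast <- tryCatch(
    parse(text = s, keep.source = FALSE)[[1]],
    error = function(e) fb_abort(
      "UnsupportedLemsFeature",
      sprintf("cannot parse expression '%s': %s", text, conditionMessage(e))
    )
  )
  ast <- fb_map_functions(ast)
  fb_check_expr(ast, text)
  ast
}

#' @keywords internal
#' Rename LEMS function names to their R equivalents (ln -> log, log -> log10).
fb_map_functions <- function(e) {
  if (is.call(e)) {
    fn <- as.character(e[[1]])
    if (identical(fn, "ln")) e[[1]] <- as.name("log")
    else if (identical(fn, "log")) e[[1]] <- as.name("log10")
    for (i in seq_along(e)[-1]) {
      if (!is.null(e[[i]])) e[[i]] <- fb_map_functions(e[[i]])
    }
  }
  e
}

#' @keywords internal
fb_check_expr <- function(e, orig) {
  if (is.call(e)) {
    fn <- as.character(e[[1]])
    if (length(fn) == 1L && !(fn %in% .fb_fun_whitelist)) {
      fb_abort("UnknownFunction",
               sprintf("unknown function '%s' in expression '%s'", fn, orig))
    }
    for (i in seq_along(e)[-1]) {
      if (!is.null(e[[i]])) fb_check_expr(e[[i]], orig)
    }
  } else if (!(is.name(e) || is.numeric(e) || is.logical(e))) {
    fb_abort("UnsupportedLemsFeature",
             sprintf("unsupported token in expression '%s'", orig))
  }
  invisible(TRUE)
}

#' @keywords internal
#' All variable names read by an expression.
fb_expr_vars <- function(e) {
  if (is.name(e)) return(as.character(e))
  if (is.call(e)) {
    out <- character(0)
    for (i in seq_along(e)[-1]) {
      if (!is.null(e[[i]])) out <- c(out, fb_expr_vars(e[[i]]))
    }
    return(unique(out))
  }
  character(0)
}

#' @keywords internal
#' Substitute symbols in an AST: `map` is a named list name -> replacement
#' (language object, symbol name string, or numeric).
fb_expr_subst <- function(e, map) {
  if (is.name(e)) {
    nm <- as.character(e)
    if (!is.null(map[[nm]])) {
      r <- map[[nm]]
      if (is.character(r)) r <- as.name(r)
      return(r)
    }
    return(e)
  }
  if (is.call(e)) {
    for (i in seq_along(e)[-1]) {
      if (!is.null(e[[i]])) e[[i]] <- fb_expr_subst(e[[i]], map)
    }
  }
  e
}

#' @keywords internal
#' TRUE if the derivative expression is linear in `var`: d(expr)/d(var) does
#' not itself mention `var`. Used by the integrator chooser.
fb_linear_in <- function(expr, var) {
  d <- tryCatch(stats::D(expr, var), error = function(e) NULL)
  if (is.null(d)) return(FALSE)
  !(var %in% fb_expr_vars(d))
}
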