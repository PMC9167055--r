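#' @keywords internal
#' Raise a classed error. `class` is the semantic error class used across the
#' package (e.g. "UnresolvedReference"); callers match it with tryCatch or
#' testthat::expect_error(class = ...).
fb_abort <- function(class, msg, ...) {
  extra <- list(...)
  cond <- structure(
    class = c(class, "flatbrain_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  for (nm in names(extra)) cond[[nm]] <- extra[[nm]]
  stop(cond)
}

fb_warn <- function(msg) {
  warning(structure(
    class = c("flatbrain_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
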