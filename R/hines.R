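# Linear-time tree solver for the compartmental cable system.

#' Solve a tree-structured symmetric linear system (Hines elimination)
#'
#' Solves `A v = r` where A has diagonal `a`, and the only off-diagonal
#' entries couple each compartment `i > 1` to its parent `parent[i]` with the
#' symmetric coefficient `b[i]`. Compartments must be in topological order
#' (every parent index is smaller than its child's). One back-to-front
#' elimination pass followed by one front-to-back substitution pass solves
#' the system in O(n), equivalently to Gaussian elimination ordered by the
#' tree.
#'
#' @param a diagonal coefficients (length n).
#' @param b off-diagonal coefficient to the parent (length n; `b[1]` ignored).
#' @param r right-hand side (length n).
#' @param parent 1-based parent index per compartment (`parent[1] = 0`).
#' @return the solution vector `v`.
#' @export
hines_solve <- function(a, b, r, parent) {
  n <- length(a)
  if (n == 0L) return(numeric(0))
  if (n > 1L) {
    for (i in n:2) {
      if (a[i] == 0) fb_abort("SingularSystem", "zero pivot in elimination")
      f <- b[i] / a[i]
      p <- parent[i]
      a[p] <- a[p] - f * b[i]
      r[p] <- r[p] - f * r[i]
    }
  }
  if (a[1] == 0) fb_abort("SingularSystem", "zero pivot at root")
  v <- numeric(n)
  v[1] <- r[1] / a[1]
  if (n > 1L) {
    for (i in 2:n) {
      v[i] <- (r[i] - b[i] * v[parent[i]]) / a[i]
    }
  }
  v
}
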