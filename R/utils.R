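#' @importFrom stats rnorm runif sd cor var
#' @importFrom utils write.csv read.csv
NULL

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so package internals never disturb the
#' caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    # materialize a seed so we can restore it
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Derive a child seed from a base seed
#'
#' Deterministic mixing that keeps results inside the 32-bit integer range
#' expected by `set.seed()`.
#' @keywords internal
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 1103L + as.double(k) * 7919L) %% 2147483587)
}

abort_if <- function(cond, msg) if (isTRUE(cond)) stop(msg, call. = FALSE)

#' Slice time step `t` out of a (T, B, D) array as a B x D matrix
#' @keywords internal
tslice <- function(A, t) {
  dm <- dim(A)
  matrix(A[t, , ], nrow = dm[2], ncol = dm[3])
}

#' Add a bias row-vector to every row of a matrix
#' @keywords internal
addb <- function(M, b) M + matrix(b, nrow = nrow(M), ncol = length(b), byrow = TRUE)

zeros_like_list <- function(ps) lapply(ps, function(p) {
  if (is.list(p)) zeros_like_list(p) else if (is.null(p)) NULL else array(0, dim = dim(p) %||% length(p))
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Glorot (Xavier) uniform initialization
#' @keywords internal
glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}
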