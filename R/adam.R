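# Adam optimizer over arbitrarily nested lists of numeric arrays, used both
# for offline training (alpha = 0.001) and for error-regression posterior
# updates (alpha = 0.2).

#' Initialize Adam state for a nested parameter list
#' @param params nested list of numeric arrays.
#' @export
adam_init <- function(params) {
  list(m = zeros_like_list(params), v = zeros_like_list(params), t = 0L)
}

map2_params <- function(a, b, f) {
  if (is.list(a)) {
    out <- mapply(map2_params, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE)
    out
  } else if (is.null(a)) NULL else f(a, b)
}

#' One Adam update
#'
#' @param state Adam state from [adam_init()].
#' @param params nested list of parameters.
#' @param grads matching nested list of gradients.
#' @param alpha,beta1,beta2,eps Adam hyperparameters.
#' @return list with updated `params` and `state`.
#' @export
adam_step <- function(state, params, grads, alpha = 0.001, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- map2_params(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- map2_params(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- map2_params(state$m, state$v, function(m, v)
    alpha * (m / bc1) / (sqrt(v / bc2) + eps))
  params <- map2_params(params, upd, function(p, u) p - u)
  list(params = params, state = state)
}

# global-norm gradient clipping over a nested list
clip_global_norm <- function(grads, max_norm = 10) {
  ss <- 0
  walk <- function(g) {
    if (is.list(g)) lapply(g, walk) else if (!is.null(g)) ss <<- ss + sum(g^2)
    invisible(NULL)
  }
  walk(grads)
  nrm <- sqrt(ss)
  if (nrm > max_norm) {
    sc <- max_norm / nrm
    scale_rec <- function(g) if (is.list(g)) lapply(g, scale_rec) else
      if (is.null(g)) NULL else g * sc
    grads <- scale_rec(grads)
  }
  grads
}
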