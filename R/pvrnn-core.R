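# Layer-level mathematics of the PV-RNN: leaky (MTRNN) integration, the
# sequential prior, the adaptive-variable posterior, reparameterized
# sampling and the closed-form diagonal-Gaussian KL divergence.

# Log-stdev clamp applied to both prior and posterior sigma heads.  exp() can
# overflow under long BPTT; the clamp is wide enough that it never binds
# under default initializations (asserted in the training smoke test).
SIGMA_LOG_MIN <- log(1e-6)
SIGMA_LOG_MAX <- log(1e3)

clamp_log_sigma <- function(x) pmin(pmax(x, SIGMA_LOG_MIN), SIGMA_LOG_MAX)

#' Layer configuration
#'
#' @param d_dim size of the deterministic state `d` (>= 1).
#' @param z_dim size of the stochastic latent `z` (>= 1).
#' @param tau leaky-integrator time constant (>= 1); large `tau` gives slow
#'   dynamics, `tau = 1` reduces to a vanilla RNN update.
#' @return a `layer_config` list.
#' @export
layer_config <- function(d_dim, z_dim, tau) {
  abort_if(d_dim < 1 || z_dim < 1, "d_dim and z_dim must be >= 1")
  abort_if(tau < 1, "tau must be >= 1")
  structure(list(d_dim = as.integer(d_dim), z_dim = as.integer(z_dim),
                 tau = as.numeric(tau)), class = "layer_config")
}

#' Leaky-integrator (MTRNN) state update
#'
#' `h = (1 - 1/tau) * h_prev + u / tau`, `d = tanh(h)`.  Accepts vectors or
#' row-matrices (batched).
#'
#' @param h_prev previous internal state.
#' @param u summed input.
#' @param tau time constant, >= 1.
#' @return list with elements `h` and `d`.
#' @export
leaky_update <- function(h_prev, u, tau) {
  abort_if(tau < 1, "tau must be >= 1")
  h <- (1 - 1 / tau) * h_prev + u / tau
  list(h = h, d = tanh(h))
}

#' Diagonal Gaussian parameters
#'
#' @param mu mean vector (or B x Z matrix).
#' @param sigma positive stdev vector (or matrix), elementwise.
#' @return a `gaussian_params` list.
#' @export
gaussian_params <- function(mu, sigma) {
  abort_if(any(sigma <= 0), "sigma must be positive elementwise")
  structure(list(mu = mu, sigma = sigma), class = "gaussian_params")
}

#' Unit Gaussian prior N(0, I)
#'
#' Used as the prior of `z` at the first time step.
#' @param z_dim latent dimension.
#' @export
unit_prior <- function(z_dim) {
  abort_if(z_dim < 1, "z_dim must be >= 1")
  gaussian_params(rep(0, z_dim), rep(1, z_dim))
}

#' Sequential prior head
#'
#' `mu = tanh(W_mu_p' d_prev + b_mu_p)`, `sigma = exp(W_sigma_p' d_prev +
#' b_sigma_p)` with the log-sigma clamp.  `d_prev` may be a vector or a
#' B x D matrix; weight matrices are stored D x Z.
#'
#' @param d_prev previous deterministic state.
#' @param params layer parameter list with `Wpm`, `bpm`, `Wps`, `bps`.
#' @export
prior_params <- function(d_prev, params) {
  dp <- if (is.matrix(d_prev)) d_prev else matrix(d_prev, nrow = 1)
  abort_if(ncol(dp) != nrow(params$Wpm), "d_prev dimension mismatch")
  mu <- tanh(addb(dp %*% params$Wpm, params$bpm))
  sg <- exp(clamp_log_sigma(addb(dp %*% params$Wps, params$bps)))
  if (!is.matrix(d_prev)) gaussian_params(drop(mu), drop(sg))
  else gaussian_params(mu, sg)
}

#' Posterior head with adaptive variables
#'
#' Identical form to the prior head but with distinct weights and the
#' per-time-step adaptive variables `a` added before the nonlinearities:
#' `mu = tanh(W_mu_q' d_prev + a_mu + b_mu_q)`,
#' `sigma = exp(W_sigma_q' d_prev + a_sigma + b_sigma_q)`.
#'
#' @param d_prev previous deterministic state (vector or B x D matrix).
#' @param a list with `a_mu`, `a_sigma` (vector or B x Z matrix).
#' @param params layer parameter list with `Wqm`, `bqm`, `Wqs`, `bqs`.
#' @export
posterior_params <- function(d_prev, a, params) {
  dp <- if (is.matrix(d_prev)) d_prev else matrix(d_prev, nrow = 1)
  am <- if (is.matrix(a$a_mu)) a$a_mu else matrix(a$a_mu, nrow = nrow(dp),
                                                  ncol = length(a$a_mu), byrow = TRUE)
  as_ <- if (is.matrix(a$a_sigma)) a$a_sigma else matrix(a$a_sigma, nrow = nrow(dp),
                                                         ncol = length(a$a_sigma), byrow = TRUE)
  abort_if(ncol(dp) != nrow(params$Wqm), "d_prev dimension mismatch")
  abort_if(ncol(am) != ncol(params$Wqm), "adaptive variable dimension mismatch")
  mu <- tanh(addb(dp %*% params$Wqm, params$bqm) + am)
  sg <- exp(clamp_log_sigma(addb(dp %*% params$Wqs, params$bqs) + as_))
  if (!is.matrix(d_prev)) gaussian_params(drop(mu), drop(sg))
  else gaussian_params(mu, sg)
}

#' Reparameterized sample
#'
#' `z = mu + sigma * eps` with `eps ~ N(0, I)` supplied by the caller.
#' @param g `gaussian_params`.
#' @param eps standard-normal draw of matching shape.
#' @export
reparameterize <- function(g, eps) {
  abort_if(length(eps) != length(g$mu), "eps dimension mismatch")
  g$mu + g$sigma * eps
}

#' Closed-form KL divergence between diagonal Gaussians
#'
#' `KL(q || p) = sum_i ln(sigma_p/sigma_q) + ((mu_p - mu_q)^2 + sigma_q^2) /
#' (2 sigma_p^2) - 1/2`.  For matrix-valued (batched) inputs, returns a
#' vector of per-row divergences.
#'
#' @param q,p `gaussian_params` of equal dimension.
#' @export
gaussian_kl <- function(q, p) {
  abort_if(length(q$mu) != length(p$mu), "dimension mismatch")
  abort_if(any(q$sigma <= 0) || any(p$sigma <= 0), "sigma must be positive")
  el <- log(p$sigma / q$sigma) + ((p$mu - q$mu)^2 + q$sigma^2) / (2 * p$sigma^2) - 0.5
  if (is.matrix(el)) rowSums(el) else sum(el)
}

# Elementwise partial derivatives of the closed-form KL, used by BPTT.
kl_grads <- function(mu_q, sg_q, mu_p, sg_p) {
  list(mu_q = (mu_q - mu_p) / sg_p^2,
       sg_q = -1 / sg_q + sg_q / sg_p^2,
       mu_p = (mu_p - mu_q) / sg_p^2,
       sg_p = 1 / sg_p - ((mu_p - mu_q)^2 + sg_q^2) / sg_p^3)
}

# Fresh parameter set for one layer.  Glorot-uniform weights, zero biases.
init_layer_params <- function(d_dim, z_dim, parent_dim = NULL) {
  p <- list(
    Wdd = glorot(d_dim, d_dim),
    Wdz = glorot(z_dim, d_dim),
    Wtd = if (!is.null(parent_dim)) glorot(parent_dim, d_dim) else NULL,
    b   = rep(0, d_dim),
    Wpm = glorot(d_dim, z_dim), bpm = rep(0, z_dim),
    Wps = glorot(d_dim, z_dim), bps = rep(0, z_dim),
    Wqm = glorot(d_dim, z_dim), bqm = rep(0, z_dim),
    Wqs = glorot(d_dim, z_dim), bqs = rep(0, z_dim))
  p
}
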