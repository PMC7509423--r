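# Full multimodal network: one associative layer on top of slow/fast
# proprioception and vision branches, connected by same-time-step top-down
# links.  Forward generation, the meta-prior-weighted cost, and exact
# backpropagation through time are implemented here.

LAYER_NAMES <- c("assoc", "prop_slow", "prop_fast", "vis_slow", "vis_fast")
LAYER_PARENT <- c(assoc = NA, prop_slow = "assoc", prop_fast = "prop_slow",
                  vis_slow = "assoc", vis_fast = "vis_slow")
# reverse topological order (children before parents) for the backward pass
LAYER_REV <- c("prop_fast", "vis_fast", "prop_slow", "vis_slow", "assoc")

#' Network configuration
#'
#' Defaults follow the reference configuration: deterministic sizes
#' 10/20/30/20/30, latent sizes 1/2/3/2/3 and time constants 15/8/2/8/2 for
#' (associative, proprioception slow/fast, vision slow/fast), 16
#' proprioception dimensions and a 20-dimensional vision latent.
#'
#' @param d named sizes of the deterministic states.
#' @param z named sizes of the stochastic latents.
#' @param tau named time constants (>= 1).
#' @param p_dim proprioception output size.
#' @param l_dim vision latent size.
#' @export
network_config <- function(d = c(assoc = 10, prop_slow = 20, prop_fast = 30,
                                 vis_slow = 20, vis_fast = 30),
                           z = c(assoc = 1, prop_slow = 2, prop_fast = 3,
                                 vis_slow = 2, vis_fast = 3),
                           tau = c(assoc = 15, prop_slow = 8, prop_fast = 2,
                                   vis_slow = 8, vis_fast = 2),
                           p_dim = 16L, l_dim = 20L) {
  abort_if(!all(LAYER_NAMES %in% names(d)) || !all(LAYER_NAMES %in% names(z)) ||
             !all(LAYER_NAMES %in% names(tau)), "all five layers must be configured")
  layers <- lapply(LAYER_NAMES, function(nm) {
    lc <- layer_config(d[[nm]], z[[nm]], tau[[nm]])
    lc$name <- nm
    lc$parent <- if (is.na(LAYER_PARENT[[nm]])) NULL else LAYER_PARENT[[nm]]
    lc
  })
  names(layers) <- LAYER_NAMES
  structure(list(layers = layers, p_dim = as.integer(p_dim),
                 l_dim = as.integer(l_dim)), class = "network_config")
}

#' Half-width variant of the default configuration (desk-scale tests)
#' @param l_dim vision latent size for the scaled model.
#' @export
network_config_scaled <- function(l_dim = 8L) {
  network_config(d = c(assoc = 5, prop_slow = 10, prop_fast = 15,
                       vis_slow = 10, vis_fast = 15),
                 l_dim = l_dim)
}

#' Per-layer meta-priors
#'
#' `w` weights the KL (complexity) term from the second time step on; `w1`
#' weights the first-step KL against the unit prior.  Large values pin the
#' posterior to the prior (prior-dominated, "egocentric" dynamics); small
#' values let observations revise it.
#'
#' @param w,w1 named nonnegative numeric vectors over the five layers.
#' @export
meta_priors <- function(w, w1 = w) {
  abort_if(!all(LAYER_NAMES %in% names(w)) || !all(LAYER_NAMES %in% names(w1)),
           "w and w1 must name all five layers")
  abort_if(any(w < 0) || any(w1 < 0), "meta-priors must be nonnegative")
  structure(list(w = w[LAYER_NAMES], w1 = w1[LAYER_NAMES]), class = "meta_priors")
}

#' Reference meta-prior setting with tighter vision regulation
#'
#' Proprioception gets the larger `w` values and vision the smaller ones
#' (the setting that absorbs vision noise inside the vision module).
#' @export
meta_priors_w1 <- function() meta_priors(
  w  = c(assoc = 0.0025, prop_slow = 0.005, prop_fast = 0.01,
         vis_slow = 0.0025, vis_fast = 0.005),
  w1 = c(assoc = 0.01, prop_slow = 0.01, prop_fast = 0.01,
         vis_slow = 0.05, vis_fast = 0.05))

#' Swapped meta-prior setting (tighter proprioception regulation)
#' @export
meta_priors_w2 <- function() meta_priors(
  w  = c(assoc = 0.0025, prop_slow = 0.0025, prop_fast = 0.005,
         vis_slow = 0.005, vis_fast = 0.01),
  w1 = c(assoc = 0.01, prop_slow = 0.05, prop_fast = 0.05,
         vis_slow = 0.01, vis_fast = 0.01))

#' Build a network with freshly initialized parameters
#'
#' Glorot-uniform weights, zero biases, zero initial states.
#'
#' @param config a [network_config()].
#' @param seed integer seed for the initialization.
#' @param meta default [meta_priors()] attached to the model.
#' @export
build_network <- function(config = network_config(), seed = 1L,
                          meta = meta_priors_w1()) {
  params <- with_seed(seed, {
    ps <- lapply(config$layers, function(lc) {
      pdim <- if (is.null(lc$parent)) NULL else config$layers[[lc$parent]]$d_dim
      init_layer_params(lc$d_dim, lc$z_dim, pdim)
    })
    ps$heads <- list(
      p = list(W = glorot(config$layers$prop_fast$d_dim, config$p_dim),
               b = rep(0, config$p_dim)),
      l = list(W = glorot(config$layers$vis_fast$d_dim, config$l_dim),
               b = rep(0, config$l_dim)))
    ps
  })
  structure(list(config = config, params = params, meta = meta, seed = seed),
            class = "pvrnn_network")
}

#' Fresh all-zero network state
#' @param net a `pvrnn_network`.
#' @param B batch size.
#' @export
network_state <- function(net, B = 1L) {
  st <- lapply(net$config$layers, function(lc)
    list(h = matrix(0, B, lc$d_dim), d = matrix(0, B, lc$d_dim)))
  structure(list(layers = st, t = 0L, B = as.integer(B)), class = "network_state")
}

#' Zero-initialized adaptive variables for T steps, batch B
#'
#' One `(T, B, z_dim)` array pair (`a_mu`, `a_sigma`) per layer; the free
#' posterior parameters optimized during training and error regression.
#' @param net a `pvrnn_network`.
#' @param T number of time steps.
#' @param B batch size (number of sequences).
#' @export
zero_adaptive <- function(net, T, B) {
  lapply(net$config$layers, function(lc)
    list(a_mu = array(0, dim = c(T, B, lc$z_dim)),
         a_sigma = array(0, dim = c(T, B, lc$z_dim))))
}

#' Standard-normal (or zero) noise arrays for the reparameterized sampler
#'
#' @param net a `pvrnn_network`.
#' @param T,B steps and batch size.
#' @param seed optional seed.
#' @param zeros return zero arrays (mean propagation).
#' @export
draw_eps <- function(net, T, B, seed = NULL, zeros = FALSE) {
  mk <- function(lc) {
    if (zeros) array(0, dim = c(T, B, lc$z_dim))
    else array(rnorm(T * B * lc$z_dim), dim = c(T, B, lc$z_dim))
  }
  if (!is.null(seed)) with_seed(seed, lapply(net$config$layers, mk))
  else lapply(net$config$layers, mk)
}

# One generative step across all layers.  dprev/hprev: named lists of B x D
# matrices.  a_t / eps_t: named lists of B x Z matrices (a_t only in
# posterior mode).  unit_prior: TRUE when this step is the first of an
# episode (prior is N(0, I)).
pvrnn_step <- function(net, dprev, hprev, mode, a_t, eps_t, unit_prior) {
  out <- list(d = list(), h = list(), z = list(), mu_p = list(), sg_p = list(),
              mu_q = list(), sg_q = list(), msk_p = list(), msk_q = list())
  dnow <- list()
  for (nm in LAYER_NAMES) {
    lc <- net$config$layers[[nm]]; pp <- net$params[[nm]]
    dp <- dprev[[nm]]; B <- nrow(dp)
    if (unit_prior) {
      mu_p <- matrix(0, B, lc$z_dim); sg_p <- matrix(1, B, lc$z_dim)
      msk_p <- matrix(1, B, lc$z_dim)
    } else {
      pre_m <- addb(dp %*% pp$Wpm, pp$bpm)
      pre_s <- addb(dp %*% pp$Wps, pp$bps)
      msk_p <- (pre_s >= SIGMA_LOG_MIN & pre_s <= SIGMA_LOG_MAX) * 1
      mu_p <- tanh(pre_m); sg_p <- exp(clamp_log_sigma(pre_s))
    }
    if (mode == "posterior") {
      pre_m <- addb(dp %*% pp$Wqm, pp$bqm) + a_t[[nm]]$a_mu
      pre_s <- addb(dp %*% pp$Wqs, pp$bqs) + a_t[[nm]]$a_sigma
      msk_q <- (pre_s >= SIGMA_LOG_MIN & pre_s <= SIGMA_LOG_MAX) * 1
      mu_q <- tanh(pre_m); sg_q <- exp(clamp_log_sigma(pre_s))
      z <- mu_q + sg_q * eps_t[[nm]]
    } else {
      mu_q <- NULL; sg_q <- NULL; msk_q <- NULL
      z <- mu_p + sg_p * eps_t[[nm]]
    }
    u <- dp %*% pp$Wdd + z %*% pp$Wdz
    if (!is.null(lc$parent)) u <- u + dnow[[lc$parent]] %*% pp$Wtd
    u <- addb(u, pp$b)
    h <- (1 - 1 / lc$tau) * hprev[[nm]] + u / lc$tau
    d <- tanh(h)
    dnow[[nm]] <- d
    out$d[[nm]] <- d; out$h[[nm]] <- h; out$z[[nm]] <- z
    out$mu_p[[nm]] <- mu_p; out$sg_p[[nm]] <- sg_p; out$msk_p[[nm]] <- msk_p
    out$mu_q[[nm]] <- mu_q; out$sg_q[[nm]] <- sg_q; out$msk_q[[nm]] <- msk_q
  }
  out
}

head_outputs <- function(net, dnow) {
  list(p = tanh(addb(dnow$prop_fast %*% net$params$heads$p$W, net$params$heads$p$b)),
       l = tanh(addb(dnow$vis_fast %*% net$params$heads$l$W, net$params$heads$l$b)))
}

#' Run the network forward over a whole episode (batched)
#'
#' Core generative pass used by training, error regression and rollouts.
#' In `"posterior"` mode the latents are sampled from the adaptive-variable
#' posterior and per-layer KL divergences against the sequential prior are
#' recorded; in `"prior"` mode the latents come from the prior itself.
#'
#' @param net a `pvrnn_network`.
#' @param T number of steps.
#' @param mode `"posterior"` or `"prior"`.
#' @param a adaptive variables (required in posterior mode), as produced by
#'   `zero_adaptive()`.
#' @param eps noise arrays (NULL = zeros, i.e. mean propagation).
#' @param state0 entry state (`network_state()` layers; NULL = zeros).
#' @param B batch size.
#' @param unit_prior_start TRUE when step 1 is the first step of an episode
#'   (prior at step 1 is then N(0, I)); FALSE when continuing from a cached
#'   state, e.g. inside a shifted error-regression window.
#' @return a forward cache with per-layer arrays (`d`, `h` of dim
#'   (T+1, B, D) including the initial state; `z`, `mu_p`, ... of dim
#'   (T, B, Z)), per-layer KL matrix (T x B) in posterior mode, and output
#'   arrays `p`, `l` of dim (T, B, dim).
#' @export
pvrnn_forward <- function(net, T, mode = c("posterior", "prior"), a = NULL,
                          eps = NULL, state0 = NULL, B = 1L,
                          unit_prior_start = TRUE) {
  mode <- match.arg(mode)
  abort_if(T < 1, "T must be >= 1")
  abort_if(mode == "posterior" && is.null(a),
           "adaptive variables are required in posterior mode")
  cfg <- net$config
  if (!is.null(a)) B <- dim(a[[1]]$a_mu)[2]
  if (is.null(eps)) eps <- draw_eps(net, T, B, zeros = TRUE)
  # (T, B, Z) -> (B, Z, T) cubes for the compiled core
  to_cube <- function(x) aperm(x, c(2, 3, 1))
  from_cube <- function(x) aperm(x, c(3, 1, 2))
  lay <- lapply(seq_along(LAYER_NAMES), function(i) {
    lc <- cfg$layers[[LAYER_NAMES[i]]]
    list(d_dim = lc$d_dim, z_dim = lc$z_dim, tau = lc$tau,
         parent = if (is.null(lc$parent)) -1L else
           match(lc$parent, LAYER_NAMES) - 1L)
  })
  pars <- lapply(LAYER_NAMES, function(nm) net$params[[nm]])
  a_mu <- a_sg <- eps_c <- vector("list", length(LAYER_NAMES))
  d0 <- h0 <- vector("list", length(LAYER_NAMES))
  for (i in seq_along(LAYER_NAMES)) {
    nm <- LAYER_NAMES[i]
    zd <- cfg$layers[[nm]]$z_dim
    eps_c[[i]] <- to_cube(eps[[nm]])
    if (!is.null(a)) {
      a_mu[[i]] <- to_cube(a[[nm]]$a_mu)
      a_sg[[i]] <- to_cube(a[[nm]]$a_sigma)
    } else {
      a_mu[[i]] <- a_sg[[i]] <- array(0, c(B, zd, 1))
    }
    if (!is.null(state0)) {
      d0[[i]] <- state0$layers[[nm]]$d
      h0[[i]] <- state0$layers[[nm]]$h
    } else {
      d0[[i]] <- h0[[i]] <- matrix(0, B, cfg$layers[[nm]]$d_dim)
    }
  }
  raw <- cpp_pvrnn_forward(lay, pars, net$params$heads, T, B,
                           mode == "posterior", a_mu, a_sg, eps_c, d0, h0,
                           unit_prior_start,
                           match("prop_fast", LAYER_NAMES) - 1L,
                           match("vis_fast", LAYER_NAMES) - 1L)
  cache <- list(T = T, B = B, mode = mode,
                unit_prior_start = unit_prior_start, a = a, eps = eps)
  for (i in seq_along(LAYER_NAMES)) {
    nm <- LAYER_NAMES[i]
    ci <- raw$layers[[i]]
    ci$eps <- eps_c[[i]]  # kept in cube layout for the backward pass
    cache[[nm]] <- list(d = from_cube(ci$d), h = from_cube(ci$h),
                        z = from_cube(ci$z),
                        mu_p = from_cube(ci$mu_p), sg_p = from_cube(ci$sg_p),
                        mu_q = from_cube(ci$mu_q), sg_q = from_cube(ci$sg_q),
                        msk_p = from_cube(ci$msk_p),
                        msk_q = from_cube(ci$msk_q),
                        kl = ci$kl)
    raw$layers[[i]] <- ci
  }
  cache$cpp <- list(layers = lay, raw = raw)
  cache$p <- from_cube(raw$p)
  cache$l <- from_cube(raw$l)
  cache
}

# per-step meta-prior weight for a layer: w1 at the unit-prior step, w after
kl_weight <- function(meta, nm, t, unit_prior_start, z_dim) {
  w <- if (t == 1 && unit_prior_start) meta$w1[[nm]] else meta$w[[nm]]
  w / z_dim
}

#' Meta-prior-weighted cost of a forward cache against targets
#'
#' `total = sum_t [ ||p_t - pbar_t||^2 / (2 R_p) + ||l_t - lbar_t||^2 /
#' (2 R_l) ] + sum_layers sum_t (w_l / R_z^l) KL_t`, summed over the batch.
#' The vision accuracy term is computed in the codec latent space.
#'
#' @param cache posterior-mode forward cache from [pvrnn_forward()].
#' @param net the network.
#' @param pbar,lbar target arrays of dim (T, B, R_p) and (T, B, R_l).
#' @param meta [meta_priors()].
#' @return list with `total` and per-component breakdown (per-modality
#'   error, weighted and raw per-layer KL sums).
#' @export
pvrnn_cost <- function(cache, net, pbar, lbar, meta = net$meta) {
  abort_if(cache$mode != "posterior", "cost is defined for posterior mode")
  abort_if(!all(dim(pbar) == dim(cache$p)) || !all(dim(lbar) == dim(cache$l)),
           "target dimension mismatch")
  Rp <- net$config$p_dim; Rl <- net$config$l_dim
  prop_err <- sum((cache$p - pbar)^2) / (2 * Rp)
  vis_err <- sum((cache$l - lbar)^2) / (2 * Rl)
  kl_w <- kl_raw <- stats::setNames(numeric(length(LAYER_NAMES)), LAYER_NAMES)
  for (nm in LAYER_NAMES) {
    zd <- net$config$layers[[nm]]$z_dim
    kl_t <- rowSums(matrix(cache[[nm]]$kl, nrow = cache$T))
    wts <- vapply(seq_len(cache$T), kl_weight, numeric(1), meta = meta,
                  nm = nm, unit_prior_start = cache$unit_prior_start, z_dim = zd)
    kl_w[nm] <- sum(wts * kl_t)
    kl_raw[nm] <- sum(kl_t)
  }
  list(total = prop_err + vis_err + sum(kl_w),
       prop_err = prop_err, vis_err = vis_err, kl_w = kl_w, kl_raw = kl_raw)
}

#' Exact BPTT gradients of the weighted cost
#'
#' Backpropagates the [pvrnn_cost()] objective through the cached episode.
#' Returns gradients for the network parameters and/or the adaptive
#' variables (the latter are the only quantities updated during error
#' regression).
#'
#' @param net the network.
#' @param cache posterior-mode forward cache.
#' @param pbar,lbar targets as in [pvrnn_cost()].
#' @param meta [meta_priors()].
#' @param wrt any of `"params"`, `"a"`.
#' @export
pvrnn_backward <- function(net, cache, pbar, lbar, meta = net$meta,
                           wrt = c("params", "a")) {
  abort_if(cache$mode != "posterior", "backward is defined for posterior mode")
  cfg <- net$config
  T <- cache$T; B <- cache$B
  want_params <- "params" %in% wrt
  want_a <- "a" %in% wrt
  kw <- vapply(LAYER_NAMES, function(nm) vapply(seq_len(T), kl_weight,
    numeric(1), meta = meta, nm = nm,
    unit_prior_start = cache$unit_prior_start,
    z_dim = cfg$layers[[nm]]$z_dim), numeric(T))
  kw <- matrix(kw, nrow = T)
  to_cube <- function(x) aperm(x, c(2, 3, 1))
  pars <- lapply(LAYER_NAMES, function(nm) net$params[[nm]])
  raw <- cpp_pvrnn_backward(cache$cpp$layers, pars, net$params$heads,
                            cache$cpp$raw, to_cube(pbar), to_cube(lbar), kw,
                            cache$unit_prior_start, want_params, want_a,
                            match("prop_fast", LAYER_NAMES) - 1L,
                            match("vis_fast", LAYER_NAMES) - 1L,
                            cfg$p_dim, cfg$l_dim)
  out <- list()
  if (want_params) {
    gp <- stats::setNames(lapply(seq_along(LAYER_NAMES), function(i) {
      g <- raw$params[[i]]
      for (f in c("b", "bpm", "bps", "bqm", "bqs")) g[[f]] <- as.vector(g[[f]])
      g
    }), LAYER_NAMES)
    gp$heads <- list(p = list(W = raw$heads$p$W, b = as.vector(raw$heads$p$b)),
                     l = list(W = raw$heads$l$W, b = as.vector(raw$heads$l$b)))
    out$params <- gp
  }
  if (want_a) {
    out$a <- stats::setNames(lapply(seq_along(LAYER_NAMES), function(i)
      list(a_mu = aperm(raw$a[[i]]$a_mu, c(3, 1, 2)),
           a_sigma = aperm(raw$a[[i]]$a_sigma, c(3, 1, 2)))), LAYER_NAMES)
  }
  out
}

#' Single forward step (public stepping interface)
#'
#' Advances a [network_state()] by one time step and returns the new state
#' together with the step output: predicted proprioception `p`, predicted
#' vision latent `l`, per-layer prior/posterior parameters, sampled `z`, and
#' per-layer KL (posterior mode).
#'
#' @param net the network.
#' @param state current `network_state`.
#' @param mode `"prior"` or `"posterior"`.
#' @param a named list per layer of `list(a_mu, a_sigma)` row matrices
#'   (required in posterior mode).
#' @param eps named list per layer of noise rows, or NULL for zeros.
#' @param unit_prior use the N(0, I) prior (first step of an episode);
#'   defaults to TRUE when `state$t == 0`.
#' @export
forward_step <- function(net, state, mode = c("prior", "posterior"), a = NULL,
                         eps = NULL, unit_prior = (state$t == 0L)) {
  mode <- match.arg(mode)
  abort_if(mode == "posterior" && is.null(a),
           "adaptive variables are required in posterior mode")
  B <- state$B
  if (is.null(eps)) eps <- lapply(net$config$layers, function(lc)
    matrix(0, B, lc$z_dim))
  eps <- lapply(eps, function(e) if (is.matrix(e)) e else matrix(e, nrow = B))
  if (!is.null(a)) a <- lapply(a, function(al) list(
    a_mu = if (is.matrix(al$a_mu)) al$a_mu else matrix(al$a_mu, nrow = B),
    a_sigma = if (is.matrix(al$a_sigma)) al$a_sigma else matrix(al$a_sigma, nrow = B)))
  dprev <- lapply(state$layers, `[[`, "d")
  hprev <- lapply(state$layers, `[[`, "h")
  st <- pvrnn_step(net, dprev, hprev, mode, a, eps, unit_prior)
  ho <- head_outputs(net, st$d)
  kl <- if (mode == "posterior") vapply(LAYER_NAMES, function(nm) {
    sum(log(st$sg_p[[nm]] / st$sg_q[[nm]]) +
          ((st$mu_p[[nm]] - st$mu_q[[nm]])^2 + st$sg_q[[nm]]^2) /
          (2 * st$sg_p[[nm]]^2) - 0.5)
  }, numeric(1)) else NULL
  new_state <- structure(list(
    layers = stats::setNames(lapply(LAYER_NAMES, function(nm)
      list(h = st$h[[nm]], d = st$d[[nm]])), LAYER_NAMES),
    t = state$t + 1L, B = B), class = "network_state")
  list(state = new_state,
       output = list(p = ho$p, l = ho$l, z = st$z,
                     prior = lapply(LAYER_NAMES, function(nm)
                       gaussian_params(st$mu_p[[nm]], st$sg_p[[nm]])),
                     posterior = if (mode == "posterior")
                       lapply(LAYER_NAMES, function(nm)
                         gaussian_params(st$mu_q[[nm]], st$sg_q[[nm]])),
                     kl = kl))
}

#' Free generation: chained forward steps
#'
#' @param net the network.
#' @param T number of steps (>= 1).
#' @param mode `"prior"` (default) or `"posterior"`.
#' @param state0 starting state (NULL = zeros, with a unit prior at step 1).
#' @param a adaptive variables for posterior mode (as in [pvrnn_forward()]).
#' @param eps noise arrays (NULL = zeros), as in [pvrnn_forward()].
#' @param seed if given, eps is drawn N(0,1) under this seed.
#' @return forward cache (see [pvrnn_forward()]).
#' @export
rollout <- function(net, T, mode = c("prior", "posterior"), state0 = NULL,
                    a = NULL, eps = NULL, seed = NULL, B = 1L) {
  mode <- match.arg(mode)
  abort_if(T < 1, "T must be >= 1")
  if (!is.null(seed)) eps <- draw_eps(net, T, B, seed = seed)
  pvrnn_forward(net, T, mode = mode, a = a, eps = eps, state0 = state0, B = B,
                unit_prior_start = is.null(state0))
}

#' Cost of a target sequence under given adaptive variables
#'
#' Convenience wrapper: runs a posterior-mode forward pass and evaluates the
#' weighted cost.
#'
#' @param net the network.
#' @param pbar,lbar targets, (T x R_p) and (T x R_l) matrices or (T, B, R)
#'   arrays.
#' @param a adaptive variables covering all steps.
#' @param meta [meta_priors()].
#' @param eps noise arrays (NULL = zeros).
#' @export
compute_cost <- function(net, pbar, lbar, a, meta = net$meta, eps = NULL) {
  if (length(dim(pbar)) == 2) pbar <- array(pbar, c(nrow(pbar), 1, ncol(pbar)))
  if (length(dim(lbar)) == 2) lbar <- array(lbar, c(nrow(lbar), 1, ncol(lbar)))
  T <- dim(pbar)[1]
  cache <- pvrnn_forward(net, T, mode = "posterior", a = a, eps = eps,
                         B = dim(pbar)[2])
  pvrnn_cost(cache, net, pbar, lbar, meta)
}
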