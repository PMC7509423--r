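# Shifting-window error regression (ER): online posterior inference with
# frozen weights.  At every sensory step the window of the immediate past is
# re-inferred by iterated forward/BPTT cycles updating only the adaptive
# variables, then a prior-driven look-ahead prediction is emitted.

#' Error-regression configuration
#'
#' @param window_len window length T' (default 30).
#' @param iters Adam iterations per sensory step (default 30).
#' @param alpha,beta1,beta2 Adam hyperparameters (defaults 0.2/0.9/0.999).
#' @param meta [meta_priors()] used during ER (NULL = the model's own,
#'   possibly rescaled with [rescale_meta_priors()]).
#' @param lookahead number of prior-rollout steps emitted after the window.
#' @param eps `"draw"` (default): slot noise is drawn once when the slot
#'   enters the window and held fixed across iterations; `"zero"`: mean
#'   propagation (fully deterministic inference).
#' @export
er_config <- function(window_len = 30L, iters = 30L, alpha = 0.2,
                      beta1 = 0.9, beta2 = 0.999, meta = NULL,
                      lookahead = 1L, eps = c("draw", "zero")) {
  abort_if(window_len < 1, "window_len must be >= 1")
  abort_if(iters < 0, "iters must be >= 0")
  abort_if(lookahead < 1, "lookahead must be >= 1")
  structure(list(window_len = as.integer(window_len),
                 iters = as.integer(iters), alpha = alpha, beta1 = beta1,
                 beta2 = beta2, meta = meta, lookahead = as.integer(lookahead),
                 eps = match.arg(eps)),
            class = "er_config")
}

#' Rescale per-layer meta-priors
#'
#' Multiplies every layer's `w` (and `w1`) by a common factor, or loads one
#' of the named sweep settings `"W1"`..`"W5"`: the reference tight-vision
#' setting's `w` column scaled by 10^(k-3), spanning four orders of
#' magnitude around the training values.
#'
#' @param base a [meta_priors()] object (ignored for named settings).
#' @param factor positive scale factor, or one of `"W1"`..`"W5"`.
#' @export
rescale_meta_priors <- function(base, factor) {
  if (is.character(factor)) {
    abort_if(!(factor %in% paste0("W", 1:5)), "unknown setting name")
    k <- as.integer(substring(factor, 2))
    ref <- meta_priors_w1()
    fac <- 10^(k - 3)
    return(meta_priors(w = ref$w * fac, w1 = ref$w1 * fac))
  }
  abort_if(!is.numeric(factor) || factor <= 0, "factor must be positive")
  meta_priors(w = base$w * factor, w1 = base$w1 * factor)
}

#' Create an empty error-regression window
#'
#' @param net the (frozen) network.
#' @return an `er_window`: zero entry state at absolute time 0, no slots.
#' @export
er_window <- function(net) {
  entry <- lapply(net$config$layers, function(lc)
    list(h = matrix(0, 1, lc$d_dim), d = matrix(0, 1, lc$d_dim)))
  structure(list(entry = entry, t0 = 1L, len = 0L,
                 pbar = NULL, lbar = NULL, a = NULL, eps = NULL,
                 errors = NULL, kl = NULL), class = "er_window")
}

# posterior-mode forward over the current window content
er_forward <- function(net, window) {
  st0 <- list(layers = window$entry)
  pvrnn_forward(net, window$len, mode = "posterior", a = window$a,
                eps = window$eps, state0 = st0, B = 1L,
                unit_prior_start = (window$t0 == 1L))
}

# per-slot diagnostics from a window forward cache
er_diagnostics <- function(net, cache, window) {
  Rp <- net$config$p_dim; Rl <- net$config$l_dim
  ep <- rowSums(matrix((cache$p - window$pbar_arr)^2, nrow = window$len)) / Rp
  el <- rowSums(matrix((cache$l - window$lbar_arr)^2, nrow = window$len)) / Rl
  kl <- vapply(LAYER_NAMES, function(nm)
    cache[[nm]]$kl[, 1] / net$config$layers[[nm]]$z_dim,
    numeric(window$len))
  list(e_p = ep, e_l = el, kl = matrix(kl, nrow = window$len,
                                       dimnames = list(NULL, LAYER_NAMES)))
}

#' One error-regression iteration
#'
#' One posterior-mode forward pass over the window from the cached entry
#' state, windowed weighted cost, BPTT to the adaptive variables only, and
#' one Adam step on them.  Weights and biases stay frozen.
#'
#' @param net the network (frozen).
#' @param window an `er_window` with at least one slot.
#' @param meta [meta_priors()] in effect.
#' @param opt Adam state for the adaptive variables (NULL = fresh).
#' @param alpha,beta1,beta2 Adam hyperparameters.
#' @return list with the updated `window`, Adam state `opt`, the windowed
#'   `cost` before the update, and per-slot diagnostics.
#' @export
er_iteration <- function(net, window, meta = net$meta, opt = NULL,
                         alpha = 0.2, beta1 = 0.9, beta2 = 0.999) {
  abort_if(window$len < 1, "window is empty")
  cache <- er_forward(net, window)
  cost <- pvrnn_cost(cache, net, window$pbar_arr, window$lbar_arr, meta)
  gr <- pvrnn_backward(net, cache, window$pbar_arr, window$lbar_arr, meta,
                       wrt = "a")
  if (is.null(opt)) opt <- adam_init(window$a)
  st <- adam_step(opt, window$a, gr$a, alpha = alpha, beta1 = beta1,
                  beta2 = beta2)
  window$a <- st$params
  diag <- er_diagnostics(net, cache, window)
  window$errors <- list(e_p = diag$e_p, e_l = diag$e_l)
  window$kl <- diag$kl
  list(window = window, opt = st$state, cost = cost, diagnostics = diag)
}

# append one observation slot (targets + zero adaptive vars + fixed noise)
er_append_slot <- function(net, window, p_obs, l_obs, eps_seed = NULL,
                           eps_zero = FALSE) {
  grow <- function(arr, zdim, val) {
    new <- array(0, c(window$len + 1L, 1L, zdim))
    if (window$len > 0L) new[seq_len(window$len), , ] <- arr
    new[window$len + 1L, 1L, ] <- val
    new
  }
  eps_draws <- if (eps_zero)
    lapply(net$config$layers, function(lc) rep(0, lc$z_dim))
  else if (!is.null(eps_seed))
    with_seed(eps_seed, lapply(net$config$layers, function(lc) rnorm(lc$z_dim)))
  else lapply(net$config$layers, function(lc) rnorm(lc$z_dim))
  if (is.null(window$a)) {
    window$a <- zero_adaptive(net, 0L, 1L)
    window$eps <- draw_eps(net, 0L, 1L, zeros = TRUE)
  }
  for (nm in LAYER_NAMES) {
    zd <- net$config$layers[[nm]]$z_dim
    window$a[[nm]]$a_mu <- grow(window$a[[nm]]$a_mu, zd, 0)
    window$a[[nm]]$a_sigma <- grow(window$a[[nm]]$a_sigma, zd, 0)
    window$eps[[nm]] <- grow(window$eps[[nm]], zd, eps_draws[[nm]])
  }
  window$pbar <- rbind(window$pbar, p_obs)
  window$lbar <- rbind(window$lbar, l_obs)
  window$len <- window$len + 1L
  window$pbar_arr <- array(window$pbar, c(window$len, 1L, ncol(window$pbar)))
  window$lbar_arr <- array(window$lbar, c(window$len, 1L, ncol(window$lbar)))
  window
}

# retire the oldest slot: commit its posterior mean to advance the cached
# entry state by one step, then drop the slot
er_retire_slot <- function(net, window) {
  a1 <- lapply(window$a, function(al) list(a_mu = tslice(al$a_mu, 1),
                                           a_sigma = tslice(al$a_sigma, 1)))
  eps0 <- lapply(net$config$layers, function(lc) matrix(0, 1, lc$z_dim))
  dprev <- lapply(window$entry, `[[`, "d")
  hprev <- lapply(window$entry, `[[`, "h")
  st <- pvrnn_step(net, dprev, hprev, "posterior", a1, eps0,
                   unit_prior = (window$t0 == 1L))
  window$entry <- stats::setNames(lapply(LAYER_NAMES, function(nm)
    list(h = st$h[[nm]], d = st$d[[nm]])), LAYER_NAMES)
  drop1 <- function(arr) {
    array(arr[-1, , , drop = FALSE], c(dim(arr)[1] - 1L, 1L, dim(arr)[3]))
  }
  for (nm in LAYER_NAMES) {
    window$a[[nm]]$a_mu <- drop1(window$a[[nm]]$a_mu)
    window$a[[nm]]$a_sigma <- drop1(window$a[[nm]]$a_sigma)
    window$eps[[nm]] <- drop1(window$eps[[nm]])
  }
  window$pbar <- window$pbar[-1, , drop = FALSE]
  window$lbar <- window$lbar[-1, , drop = FALSE]
  window$len <- window$len - 1L
  window$t0 <- window$t0 + 1L
  window$pbar_arr <- array(window$pbar, c(window$len, 1L, ncol(window$pbar)))
  window$lbar_arr <- array(window$lbar, c(window$len, 1L, ncol(window$lbar)))
  window
}

# window-end state from a forward cache (state after the last slot)
er_end_state <- function(net, cache) {
  structure(list(layers = stats::setNames(lapply(LAYER_NAMES, function(nm)
    list(h = tslice(cache[[nm]]$h, cache$T + 1L),
         d = tslice(cache[[nm]]$d, cache$T + 1L))), LAYER_NAMES),
    t = 0L, B = 1L), class = "network_state")
}

#' Shift the window by one observation and re-infer the posterior
#'
#' Encodes the new frame (if a codec and frame are given), appends the
#' observation, retires the oldest slot into the cached entry state once the
#' window is full, runs `cfg$iters` error-regression iterations, and emits a
#' deterministic (mean) prior rollout of `cfg$lookahead` steps from the
#' window end; its first step is the one-step look-ahead prediction.
#'
#' @param net frozen network.
#' @param window an `er_window`.
#' @param p_obs observed proprioception vector.
#' @param frame observed frame (requires `codec`), or NULL.
#' @param l_obs observed vision latent (if the frame is already encoded).
#' @param codec trained codec (required when `frame` is given).
#' @param cfg an [er_config()].
#' @return list: updated `window`, `prediction` (p and l for the next step),
#'   `lookahead` rollout cache, per-slot `diagnostics`, windowed `cost`.
#' @export
shift_and_predict <- function(net, window, p_obs, frame = NULL, l_obs = NULL,
                              codec = NULL, cfg = er_config()) {
  meta <- cfg$meta %||% net$meta
  if (!is.null(frame)) {
    abort_if(is.null(codec) || !isTRUE(codec$trained),
             "a trained codec is required to encode frames")
    l_obs <- encode(codec, frame)
  }
  abort_if(is.null(l_obs), "either frame or l_obs must be supplied")
  window <- er_append_slot(net, window, p_obs, l_obs,
                           eps_zero = identical(cfg$eps, "zero"))
  if (window$len > cfg$window_len) window <- er_retire_slot(net, window)
  opt <- NULL
  cost <- NULL
  for (i in seq_len(cfg$iters)) {
    it <- er_iteration(net, window, meta, opt, alpha = cfg$alpha,
                       beta1 = cfg$beta1, beta2 = cfg$beta2)
    window <- it$window
    opt <- it$opt
    cost <- it$cost
  }
  # final forward with the updated posterior for diagnostics and lookahead
  cache <- er_forward(net, window)
  diag <- er_diagnostics(net, cache, window)
  window$errors <- list(e_p = diag$e_p, e_l = diag$e_l)
  window$kl <- diag$kl
  end_state <- er_end_state(net, cache)
  la <- pvrnn_forward(net, cfg$lookahead, mode = "prior",
                      state0 = end_state, B = 1L, unit_prior_start = FALSE)
  list(window = window,
       prediction = list(p = drop(la$p[1, 1, ]), l = drop(la$l[1, 1, ])),
       lookahead = la, diagnostics = diag,
       cost = pvrnn_cost(cache, net, window$pbar_arr, window$lbar_arr, meta))
}

#' Run a full pseudo-imitative interaction
#'
#' Feeds a target sequence step by step through the shifting-window error
#' regression and aggregates the standard metrics: windowed reconstruction
#' errors per modality (normalized by dimension, averaged over window slots
#' and interaction steps), per-layer normalized KL divergence, and one-step
#' look-ahead prediction errors.
#'
#' @param net frozen trained network.
#' @param target a `primitive_sequence` with `latents` filled (or frames
#'   plus a `codec`).
#' @param cfg an [er_config()].
#' @param seed seed for the per-slot noise draws.
#' @param codec optional trained codec for frame encoding.
#' @param keep_slots store the per-step slot-level diagnostics in the trace
#'   (used to validate the metric aggregation against a reference loop).
#' @return an `interaction_trace`: list with per-step data frame `steps`,
#'   per-step per-layer KL matrix `kl`, and `summary` (prop_err, vis_err,
#'   kld per layer, onestep errors).
#' @export
run_interaction <- function(net, target, cfg = er_config(), seed = 1L,
                            codec = NULL, keep_slots = FALSE) {
  pbar <- target$joints
  lbar <- target$latents
  if (is.null(lbar)) {
    abort_if(is.null(codec), "target has no latents and no codec was given")
    lbar <- encode_frames(codec, target$frames)
  }
  T <- nrow(pbar)
  abort_if(T <= cfg$window_len, "target must be longer than the window")
  Rp <- net$config$p_dim; Rl <- net$config$l_dim
  window <- er_window(net)
  win_ep <- win_el <- one_ep <- one_el <- rep(NA_real_, T)
  klm <- matrix(NA_real_, T, length(LAYER_NAMES),
                dimnames = list(NULL, LAYER_NAMES))
  slots <- if (keep_slots) vector("list", T)
  pred_prev <- NULL
  with_seed(seed, {
    for (t in seq_len(T)) {
      if (!is.null(pred_prev)) {
        one_ep[t] <- sum((pred_prev$p - pbar[t, ])^2) / Rp
        one_el[t] <- sum((pred_prev$l - lbar[t, ])^2) / Rl
      }
      sp <- shift_and_predict(net, window, pbar[t, ], l_obs = lbar[t, ],
                              cfg = cfg)
      window <- sp$window
      win_ep[t] <- mean(sp$diagnostics$e_p)
      win_el[t] <- mean(sp$diagnostics$e_l)
      klm[t, ] <- colMeans(matrix(sp$diagnostics$kl, nrow = window$len,
                                  dimnames = list(NULL, LAYER_NAMES)))
      if (keep_slots) slots[[t]] <- sp$diagnostics
      pred_prev <- sp$prediction
    }
  })
  steps <- data.frame(t = seq_len(T), win_prop_err = win_ep,
                      win_vis_err = win_el, onestep_prop_err = one_ep,
                      onestep_vis_err = one_el)
  summary <- c(prop_err = mean(win_ep), vis_err = mean(win_el),
               stats::setNames(colMeans(klm), paste0("kld_", LAYER_NAMES)),
               onestep_prop_err = mean(one_ep, na.rm = TRUE),
               onestep_vis_err = mean(one_el, na.rm = TRUE))
  structure(list(steps = steps, kl = klm, summary = summary, cfg = cfg,
                 seed = seed, slots = if (keep_slots) slots),
            class = "interaction_trace")
}

#' Write an interaction trace to disk (CSV steps + JSON summary)
#' @param trace an `interaction_trace`.
#' @param dir output directory.
#' @export
write_trace <- function(trace, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(cbind(trace$steps, trace$kl), file.path(dir, "steps.csv"),
            row.names = FALSE)
  jsonlite::write_json(as.list(trace$summary), file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
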