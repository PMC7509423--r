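# Offline training: full-batch BPTT over a sequence corpus, jointly
# optimizing network weights, biases and the per-sequence per-time-step
# adaptive variables with Adam.

#' Training configuration
#'
#' @param epochs number of epochs (one full-batch update per epoch).
#' @param alpha,beta1,beta2 Adam hyperparameters (defaults 0.001/0.9/0.999).
#' @param meta [meta_priors()] used in the cost (NULL = the model's own).
#' @param seed seed for noise draws during training.
#' @param log_every log history every this many epochs.
#' @param clip global-norm gradient clip (BPTT over hundreds of steps can
#'   spike); NULL disables.
#' @export
train_config <- function(epochs = 10000L, alpha = 0.001, beta1 = 0.9,
                         beta2 = 0.999, meta = NULL, seed = 1L,
                         log_every = 10L, clip = 10) {
  abort_if(epochs < 1, "epochs must be positive")
  abort_if(alpha <= 0, "alpha must be positive")
  structure(list(epochs = as.integer(epochs), alpha = alpha, beta1 = beta1,
                 beta2 = beta2, meta = meta, seed = seed,
                 log_every = as.integer(log_every), clip = clip),
            class = "train_config")
}

# stack a dataset's joints/latents into (T, B, R) target arrays
dataset_tensors <- function(dataset, p_dim, l_dim) {
  Ts <- vapply(dataset, function(s) nrow(s$joints), numeric(1))
  abort_if(length(unique(Ts)) != 1,
           "all sequences must have equal length (padding is unsupported)")
  T <- Ts[1]; B <- length(dataset)
  pbar <- array(0, c(T, B, p_dim))
  lbar <- array(0, c(T, B, l_dim))
  for (b in seq_len(B)) {
    abort_if(ncol(dataset[[b]]$joints) != p_dim, "joint dimension mismatch")
    abort_if(is.null(dataset[[b]]$latents),
             "latent targets missing; run encode_dataset() first")
    abort_if(ncol(dataset[[b]]$latents) != l_dim, "latent dimension mismatch")
    pbar[, b, ] <- dataset[[b]]$joints
    lbar[, b, ] <- dataset[[b]]$latents
  }
  list(pbar = pbar, lbar = lbar, T = T, B = B)
}

#' Train the network on a sequence corpus
#'
#' Minimizes the meta-prior-weighted cost by full-batch BPTT with Adam,
#' optimizing weights, biases and per-sequence adaptive variables jointly.
#' One fresh noise draw per layer, time step and sequence is used per epoch
#' (single-sample bound estimate).
#'
#' @param net a `pvrnn_network`.
#' @param dataset list of `primitive_sequence` objects with `latents` filled
#'   (see [encode_dataset()]); all sequences must share one length.
#' @param cfg a [train_config()].
#' @return list with the trained `net`, the optimized adaptive variables
#'   `a`, and a `history` data frame (epoch, total, prop_err, vis_err and
#'   per-layer raw KL, logged every `cfg$log_every` epochs).
#' @export
train <- function(net, dataset, cfg = train_config()) {
  meta <- cfg$meta %||% net$meta
  tg <- dataset_tensors(dataset, net$config$p_dim, net$config$l_dim)
  a <- zero_adaptive(net, tg$T, tg$B)
  pars <- list(params = net$params, a = a)
  opt <- adam_init(pars)
  hist <- vector("list", ceiling(cfg$epochs / cfg$log_every) + 1L)
  hi <- 0L
  clamp_bound <- FALSE
  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      eps <- draw_eps(net, tg$T, tg$B)
      cache <- pvrnn_forward(net, tg$T, mode = "posterior", a = pars$a,
                             eps = eps)
      cost <- pvrnn_cost(cache, net, tg$pbar, tg$lbar, meta)
      for (nm in LAYER_NAMES)
        if (any(cache[[nm]]$msk_q == 0) || any(cache[[nm]]$msk_p == 0))
          clamp_bound <- TRUE
      gr <- pvrnn_backward(net, cache, tg$pbar, tg$lbar, meta)
      grads <- list(params = gr$params, a = gr$a)
      if (!is.null(cfg$clip)) grads <- clip_global_norm(grads, cfg$clip)
      st <- adam_step(opt, pars, grads, alpha = cfg$alpha,
                      beta1 = cfg$beta1, beta2 = cfg$beta2)
      pars <- st$params
      opt <- st$state
      net$params <- pars$params
      if (ep == 1L || ep %% cfg$log_every == 0L || ep == cfg$epochs) {
        hi <- hi + 1L
        hist[[hi]] <- data.frame(epoch = ep, total = cost$total,
                                 prop_err = cost$prop_err,
                                 vis_err = cost$vis_err,
                                 t(cost$kl_raw))
      }
    }
  })
  history <- do.call(rbind, hist[seq_len(hi)])
  attr(history, "sigma_clamp_bound") <- clamp_bound
  list(net = net, a = pars$a, history = history)
}

#' Write a learning history to CSV
#' @param history history data frame from [train()].
#' @param path output file.
#' @export
write_history <- function(history, path) {
  write.csv(history, path, row.names = FALSE)
  invisible(path)
}

#' Paired training runs under two modality-specific meta-prior settings
#'
#' Trains the two settings `n_inits` times each with different parameter
#' initializations, then evaluates every trained model with error-regression
#' on held-out sequences.  Reports per-run learning histories, test metrics,
#' and the direction-of-effect comparison between the settings (associative
#' KL and vision reconstruction error).
#'
#' @param dataset training corpus (latents filled).
#' @param test_set held-out sequences (latents filled).
#' @param setting_a,setting_b the two [meta_priors()] settings.
#' @param n_inits number of random initializations per setting.
#' @param config [network_config()] for the models.
#' @param train_cfg [train_config()].
#' @param er_cfg [er_config()] used in the test interactions.
#' @param seed base seed.
#' @return list with `runs` (per-run metrics data frame), `summary`
#'   (mean/sd per setting), and `direction` (per-seed sign comparisons).
#' @export
replicate_exp1 <- function(dataset, test_set, setting_a = meta_priors_w1(),
                           setting_b = meta_priors_w2(), n_inits = 10L,
                           config = network_config(),
                           train_cfg = train_config(epochs = 4000L),
                           er_cfg = er_config(), seed = 1L) {
  rows <- list()
  models <- list(a = list(), b = list())
  for (i in seq_len(n_inits)) {
    for (s in c("a", "b")) {
      meta <- if (s == "a") setting_a else setting_b
      net <- build_network(config, seed = child_seed(seed, i * 2L + (s == "b")),
                           meta = meta)
      cfg_i <- train_cfg
      cfg_i$seed <- child_seed(seed, 100L + i)
      cfg_i$meta <- meta
      fit <- train(net, dataset, cfg_i)
      models[[s]][[i]] <- fit
      mets <- lapply(seq_along(test_set), function(k)
        run_interaction(fit$net, test_set[[k]], er_cfg,
                        seed = child_seed(seed, 200L + i * 10L + k))$summary)
      avg <- Reduce(`+`, lapply(mets, unlist)) / length(mets)
      rows[[length(rows) + 1L]] <- data.frame(setting = s, init = i, t(avg))
    }
  }
  runs <- do.call(rbind, rows)
  nums <- setdiff(names(runs), c("setting", "init"))
  summary <- do.call(rbind, lapply(split(runs[nums], runs$setting), function(d)
    data.frame(metric = nums, mean = colMeans(d), sd = apply(d, 2, sd))))
  summary$setting <- rep(c("a", "b"), each = length(nums))
  ra <- runs[runs$setting == "a", ]; rb <- runs[runs$setting == "b", ]
  direction <- data.frame(
    init = ra$init,
    assoc_kld_a_lt_b = ra$kld_assoc < rb$kld_assoc,
    vis_err_a_lt_b = ra$vis_err < rb$vis_err)
  list(runs = runs, summary = summary, direction = direction, models = models)
}
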