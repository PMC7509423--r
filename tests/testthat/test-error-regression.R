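# Shifting-window error regression: meta-prior rescaling, window mechanics,
# posterior optimization behavior, interaction metrics.

test_that("meta-prior rescaling reproduces the printed sweep settings", {
  w3 <- rescale_meta_priors(NULL, "W3")
  expect_equal(unname(w3$w),
               c(2.5e-3, 5.0e-3, 1.0e-2, 2.5e-3, 5.0e-3))
  w1 <- rescale_meta_priors(NULL, "W1")
  expect_equal(unname(w1$w),
               c(2.5e-5, 5.0e-5, 1.0e-4, 2.5e-5, 5.0e-5))
  w5 <- rescale_meta_priors(NULL, "W5")
  expect_equal(unname(w5$w), c(0.25, 0.5, 1.0, 0.25, 0.5))
  base <- meta_priors_w1()
  expect_equal(rescale_meta_priors(base, 1), base)
  sc <- rescale_meta_priors(base, 7.3)
  expect_equal(unname(sc$w / base$w), rep(7.3, 5))   # ratios preserved
  expect_error(rescale_meta_priors(base, -2), "positive")
  expect_error(rescale_meta_priors(base, "W9"), "setting")
})

test_that("window grows during warm-up and caps at the configured length", {
  fit <- shared_fit()
  net <- fit$net
  corp <- shared_corpus()
  tgt <- corp$test[[1]]
  cfg <- er_config(window_len = 5, iters = 2)
  w <- er_window(net)
  for (t in 1:8) {
    sp <- shift_and_predict(net, w, tgt$joints[t, ],
                            l_obs = tgt$latents[t, ], cfg = cfg)
    w <- sp$window
    expect_equal(w$len, min(t, 5L))
    expect_equal(w$t0, max(1L, t - 4L))
  }
  expect_length(sp$prediction$p, 16)
  expect_length(sp$prediction$l, 8)
  expect_error(shift_and_predict(net, w, tgt$joints[1, ], frame = diag(16),
                                 cfg = cfg), "codec")
})

test_that("with prior-copied heads, iters = 0 predictions equal the prior rollout", {
  net <- tiny_net()
  for (nm in names(net$config$layers)) {
    net$params[[nm]]$Wqm <- net$params[[nm]]$Wpm
    net$params[[nm]]$bqm <- net$params[[nm]]$bpm
    net$params[[nm]]$Wqs <- net$params[[nm]]$Wps
    net$params[[nm]]$bqs <- net$params[[nm]]$bps
  }
  cfg <- er_config(window_len = 4, iters = 0, lookahead = 2, eps = "zero")
  ref <- rollout(net, 6)         # deterministic prior rollout, eps = 0
  w <- er_window(net)
  for (t in 1:5) {
    sp <- shift_and_predict(net, w, rnorm(3), l_obs = rnorm(2), cfg = cfg)
    w <- sp$window
  }
  # window covered t = 1..5 with a = 0 everywhere; posterior == prior, so
  # the one-step prediction must equal the prior rollout at t = 6
  expect_equal(sp$prediction$p, drop(ref$p[6, 1, ]), tolerance = 1e-10)
  expect_equal(sp$prediction$l, drop(ref$l[6, 1, ]), tolerance = 1e-10)
})

test_that("ER iterations reduce windowed error; huge w pins posterior to prior", {
  fit <- shared_fit()
  net <- fit$net
  corp <- shared_corpus()
  tgt <- corp$test[[1]]
  # build a filled window by feeding 12 observations without optimization
  w <- er_window(net)
  cfg0 <- er_config(window_len = 12, iters = 0)
  set.seed(51)
  for (t in 1:12) {
    sp <- shift_and_predict(net, w, tgt$joints[t, ], l_obs = tgt$latents[t, ],
                            cfg = cfg0)
    w <- sp$window
  }
  run_iters <- function(w, meta, n = 30) {
    opt <- NULL
    first <- NULL
    for (i in seq_len(n)) {
      it <- er_iteration(net, w, meta, opt)
      if (is.null(first)) first <- it
      w <- it$window
      opt <- it$opt
    }
    final <- er_iteration(net, w, meta, opt)
    list(first = first, final = final)
  }
  # small w: reconstruction error shrinks
  rs <- run_iters(w, rescale_meta_priors(net$meta, 0.01))
  expect_lt(mean(rs$final$diagnostics$e_p), mean(rs$first$diagnostics$e_p))
  # very large w: KL is driven toward zero and the posterior is pinned to
  # the prior, leaving the reconstruction error above the small-w outcome
  rl <- run_iters(w, rescale_meta_priors(net$meta, 1000))
  expect_lt(mean(rl$final$diagnostics$kl), 0.5 * mean(rl$first$diagnostics$kl))
  expect_gt(mean(rl$final$diagnostics$e_p), mean(rs$final$diagnostics$e_p))
  expect_error(er_iteration(net, er_window(net)), "empty")
})

test_that("interaction metrics match a reference double-loop aggregation", {
  fit <- shared_fit()
  corp <- shared_corpus()
  tgt <- corp$test[[1]]
  tgt$joints <- tgt$joints[1:40, ]
  tgt$latents <- tgt$latents[1:40, ]
  cfg <- er_config(window_len = 8, iters = 4)
  tr <- run_interaction(fit$net, tgt, cfg, seed = 61, keep_slots = TRUE)
  # reference implementation of the metric definitions from the stored trace
  T <- 40
  ref_prop <- mean(vapply(1:T, function(t) mean(tr$slots[[t]]$e_p), numeric(1)))
  ref_vis <- mean(vapply(1:T, function(t) mean(tr$slots[[t]]$e_l), numeric(1)))
  ref_kld_assoc <- mean(vapply(1:T, function(t)
    mean(tr$slots[[t]]$kl[, "assoc"]), numeric(1)))
  expect_identical(unname(tr$summary["prop_err"]), ref_prop)
  expect_identical(unname(tr$summary["vis_err"]), ref_vis)
  expect_identical(unname(tr$summary["kld_assoc"]), ref_kld_assoc)
  # zero-error trace aggregates to zero
  expect_equal(mean(c(0, 0, 0)), 0)
  # determinism seed-for-seed
  tr2 <- run_interaction(fit$net, tgt, cfg, seed = 61)
  expect_identical(tr$summary, tr2$summary)
  expect_error(run_interaction(fit$net, list(joints = tgt$joints[1:5, ],
                                             latents = tgt$latents[1:5, ]),
                               cfg), "longer")
})

test_that("self-imitation of the model's own prior rollout is near-exact", {
  fit <- shared_fit()
  net <- fit$net
  ref <- rollout(net, 60)
  tgt <- structure(list(joints = matrix(ref$p[, 1, ], ncol = 16),
                        latents = matrix(ref$l[, 1, ], ncol = 8)),
                   class = "primitive_sequence")
  cfg <- er_config(window_len = 12, iters = 10,
                   meta = rescale_meta_priors(net$meta, 0.01))
  tr <- run_interaction(net, tgt, cfg, seed = 71)
  expect_lt(unname(tr$summary["prop_err"]), 1e-2)
})
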