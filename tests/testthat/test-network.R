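# Network assembly: stepping vs batched forward, reductions, timescale
# hierarchy, cost bookkeeping, KL-weight gradient structure.

test_that("default configuration matches the reference architecture", {
  cfg <- network_config()
  expect_equal(vapply(cfg$layers, `[[`, numeric(1), "d_dim"),
               c(assoc = 10, prop_slow = 20, prop_fast = 30,
                 vis_slow = 20, vis_fast = 30))
  expect_equal(vapply(cfg$layers, `[[`, numeric(1), "z_dim"),
               c(assoc = 1, prop_slow = 2, prop_fast = 3,
                 vis_slow = 2, vis_fast = 3))
  expect_equal(vapply(cfg$layers, `[[`, numeric(1), "tau"),
               c(assoc = 15, prop_slow = 8, prop_fast = 2,
                 vis_slow = 8, vis_fast = 2))
  expect_equal(cfg$p_dim, 16L)
  expect_equal(cfg$l_dim, 20L)
})

test_that("forward_step chain reproduces the batched forward exactly", {
  net <- tiny_net()
  T <- 7
  a <- zero_adaptive(net, T, 1L)
  for (nm in names(a)) {
    a[[nm]]$a_mu[] <- rnorm(length(a[[nm]]$a_mu), 0, 0.2)
    a[[nm]]$a_sigma[] <- rnorm(length(a[[nm]]$a_sigma), 0, 0.2)
  }
  eps <- draw_eps(net, T, 1L, seed = 8)
  cache <- pvrnn_forward(net, T, "posterior", a = a, eps = eps)
  st <- network_state(net)
  for (t in seq_len(T)) {
    a_t <- lapply(a, function(al) list(a_mu = matrix(al$a_mu[t, , ], nrow = 1),
                                       a_sigma = matrix(al$a_sigma[t, , ], nrow = 1)))
    eps_t <- lapply(eps, function(el) matrix(el[t, , ], nrow = 1))
    fs <- forward_step(net, st, "posterior", a = a_t, eps = eps_t)
    st <- fs$state
    expect_equal(drop(fs$output$p), drop(cache$p[t, 1, ]), tolerance = 1e-12)
    expect_equal(drop(fs$output$l), drop(cache$l[t, 1, ]), tolerance = 1e-12)
    expect_equal(drop(st$layers$assoc$d), drop(cache$assoc$d[t + 1, 1, ]),
                 tolerance = 1e-12)
    kl_batched <- vapply(c("assoc", "prop_fast"), function(nm)
      cache[[nm]]$kl[t, 1], numeric(1))
    expect_equal(fs$output$kl[c("assoc", "prop_fast")], kl_batched,
                 tolerance = 1e-12)
  }
  expect_error(forward_step(net, network_state(net), "posterior"),
               "adaptive")
})

test_that("prior at the first step is the unit Gaussian", {
  net <- tiny_net()
  cache <- rollout(net, 1)
  for (nm in c("assoc", "vis_fast")) {
    expect_equal(as.vector(cache[[nm]]$mu_p[1, 1, ]),
                 rep(0, net$config$layers[[nm]]$z_dim))
    expect_equal(as.vector(cache[[nm]]$sg_p[1, 1, ]),
                 rep(1, net$config$layers[[nm]]$z_dim))
  }
  # continuing from a cached state uses the conditional prior instead
  st <- list(layers = lapply(net$config$layers, function(lc)
    list(h = matrix(0.5, 1, lc$d_dim), d = matrix(tanh(0.5), 1, lc$d_dim))))
  c2 <- pvrnn_forward(net, 1, "prior", state0 = st, unit_prior_start = FALSE)
  expect_false(all(c2$assoc$mu_p[1, 1, ] == 0))
})

test_that("zero-noise prior rollouts are deterministic", {
  net <- tiny_net()
  r1 <- rollout(net, 20)
  r2 <- rollout(net, 20)
  expect_identical(r1$p, r2$p)
  expect_identical(r1$assoc$d, r2$assoc$d)
  expect_error(rollout(net, 0), "T")
})

test_that("tau = 1 with silenced z reduces to a plain tanh RNN", {
  cfg <- network_config(
    d = c(assoc = 3, prop_slow = 4, prop_fast = 5, vis_slow = 4, vis_fast = 5),
    z = c(assoc = 1, prop_slow = 2, prop_fast = 2, vis_slow = 2, vis_fast = 2),
    tau = c(assoc = 1, prop_slow = 1, prop_fast = 1, vis_slow = 1, vis_fast = 1),
    p_dim = 3, l_dim = 2)
  net <- build_network(cfg, seed = 3)
  for (nm in names(cfg$layers)) net$params[[nm]]$Wdz[] <- 0
  T <- 10
  cache <- rollout(net, T, seed = 4)   # noise irrelevant once W_dz = 0
  # hand-rolled plain RNN oracle over the same topology
  d <- lapply(cfg$layers, function(lc) rep(0, lc$d_dim))
  for (t in seq_len(T)) {
    dn <- list()
    for (nm in names(cfg$layers)) {
      pp <- net$params[[nm]]
      u <- drop(d[[nm]] %*% pp$Wdd) + pp$b
      par <- cfg$layers[[nm]]$parent
      if (!is.null(par)) u <- u + drop(dn[[par]] %*% pp$Wtd)
      dn[[nm]] <- tanh(u)
    }
    d <- dn
    expect_equal(as.vector(cache$prop_fast$d[t + 1, 1, ]), d$prop_fast,
                 tolerance = 1e-12)
  }
})

test_that("slow layers decorrelate more slowly than fast layers", {
  net <- build_network(network_config_scaled(l_dim = 8), seed = 5)
  cache <- rollout(net, 200, seed = 6)
  ac_time <- function(x) {
    # mean over units of lag-1 autocorrelation of d
    mean(apply(x, 2, function(v) suppressWarnings(cor(v[-1], v[-length(v)]))),
         na.rm = TRUE)
  }
  d_assoc <- matrix(cache$assoc$d[-1, 1, ], ncol = dim(cache$assoc$d)[3])
  d_fast <- matrix(cache$prop_fast$d[-1, 1, ], ncol = dim(cache$prop_fast$d)[3])
  expect_gt(ac_time(d_assoc), ac_time(d_fast))
})

test_that("cost: zero case, quadratic increments, component identity", {
  net <- tiny_net()
  # copy posterior heads from prior heads so a = 0 makes posterior == prior
  for (nm in names(net$config$layers)) {
    net$params[[nm]]$Wqm <- net$params[[nm]]$Wpm
    net$params[[nm]]$bqm <- net$params[[nm]]$bpm
    net$params[[nm]]$Wqs <- net$params[[nm]]$Wps
    net$params[[nm]]$bqs <- net$params[[nm]]$bps
  }
  T <- 6
  a <- zero_adaptive(net, T, 1L)
  cache <- pvrnn_forward(net, T, "posterior", a = a)
  # note: at t = 1 the posterior is head-driven but the prior is N(0, I),
  # so KL at t = 1 need not vanish; silence it via w1 = 0
  meta0 <- meta_priors(w = net$meta$w, w1 = c(assoc = 0, prop_slow = 0,
                                              prop_fast = 0, vis_slow = 0,
                                              vis_fast = 0))
  cost0 <- pvrnn_cost(cache, net, cache$p, cache$l, meta0)
  expect_equal(cost0$total, 0, tolerance = 1e-12)
  # perturbing one target entry adds delta^2 / (2 R_p)
  pbar <- cache$p
  pbar[3, 1, 2] <- pbar[3, 1, 2] + 0.2
  cost1 <- pvrnn_cost(cache, net, pbar, cache$l, meta0)
  expect_equal(cost1$total, 0.2^2 / (2 * net$config$p_dim), tolerance = 1e-12)
  # components always sum to the total
  net2 <- tiny_net(seed = 9)
  a2 <- zero_adaptive(net2, T, 2L)
  eps2 <- draw_eps(net2, T, 2L, seed = 10)
  cache2 <- pvrnn_forward(net2, T, "posterior", a = a2, eps = eps2)
  pb <- array(rnorm(T * 2 * 3), c(T, 2, 3))
  lb <- array(rnorm(T * 2 * 2), c(T, 2, 2))
  cc <- pvrnn_cost(cache2, net2, pb, lb)
  expect_equal(cc$total, cc$prop_err + cc$vis_err + sum(cc$kl_w),
               tolerance = 1e-10)
  expect_error(pvrnn_cost(cache2, net2, pb[, , 1:2], lb), "mismatch")
})

test_that("with all meta-priors zero the KL exerts no gradient", {
  net <- tiny_net()
  T <- 5
  a <- zero_adaptive(net, T, 1L)
  eps <- draw_eps(net, T, 1L, seed = 11)
  cache <- pvrnn_forward(net, T, "posterior", a = a, eps = eps)
  zero <- c(assoc = 0, prop_slow = 0, prop_fast = 0, vis_slow = 0,
            vis_fast = 0)
  meta0 <- meta_priors(w = zero, w1 = zero)
  pb <- array(rnorm(T * 3), c(T, 1, 3))
  lb <- array(rnorm(T * 2), c(T, 1, 2))
  gr <- pvrnn_backward(net, cache, pb, lb, meta0)
  # prior heads only enter the cost through the KL: their gradients vanish
  for (nm in names(net$config$layers)) {
    expect_equal(max(abs(gr$params[[nm]]$Wpm)), 0)
    expect_equal(max(abs(gr$params[[nm]]$Wps)), 0)
  }
  # reconstruction gradients persist
  expect_gt(max(abs(gr$params$heads$p$W)), 0)
})

test_that("meta-prior tables are loaded as printed", {
  w1 <- meta_priors_w1()
  expect_equal(unname(w1$w), c(0.0025, 0.005, 0.01, 0.0025, 0.005))
  expect_equal(unname(w1$w1), c(0.01, 0.01, 0.01, 0.05, 0.05))
  w2 <- meta_priors_w2()
  expect_equal(unname(w2$w), c(0.0025, 0.0025, 0.005, 0.005, 0.01))
  expect_equal(unname(w2$w1), c(0.01, 0.05, 0.05, 0.01, 0.01))
  expect_error(meta_priors(w = c(assoc = -1)), "layers|nonnegative")
})
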