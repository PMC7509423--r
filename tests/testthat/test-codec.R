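# Convolutional codec: shape chain, CoordConv, determinism, exact gradients
# (central-difference oracle), and training behavior.

test_that("shape chain collapses to 1x1 at every supported size", {
  for (n in c(16L, 32L, 64L)) {
    codec <- build_codec(codec_config(n, 6), seed = 1)
    expect_equal(codec$ctx$enc3$Ho, 1L)
    # mirrored decoder reproduces the frame size
    fr <- matrix(runif(n * n, -1, 1), n)
    expect_equal(dim(decode(codec, encode(codec, fr))), c(n, n))
  }
  expect_error(codec_config(24), "image_size")
})

test_that("coordconv appends exactly two coordinate channels", {
  fr <- matrix(rnorm(16 * 16), 16)
  aug <- coordconv_augment(fr)
  expect_equal(dim(aug), c(16, 16, 3))
  expect_equal(aug[, , 1], fr)                    # content unchanged
  expect_equal(aug[1, 1, 2:3], c(-1, -1))         # corner coordinates
  expect_equal(aug[16, 16, 2:3], c(1, 1))
  expect_equal(aug[16, 1, 2:3], c(1, -1))
})

test_that("encode/decode are deterministic with the documented ranges", {
  codec <- build_codec(codec_config(16, 8), seed = 2)
  fr <- matrix(runif(256, -1, 1), 16)
  z1 <- encode(codec, fr)
  expect_identical(z1, encode(codec, fr))
  expect_length(z1, 8)
  expect_true(all(abs(z1) < 1))
  img <- decode(codec, z1)
  expect_true(all(abs(img) < 1))
  expect_identical(img, decode(codec, z1))
  expect_error(encode(codec, matrix(0, 8, 8)), "size")
  expect_error(decode(codec, rep(0, 5)), "dimension")
  # default latent dimension is 20
  expect_equal(codec_config()$latent_dim, 20L)
})

test_that("codec backprop matches central finite differences", {
  codec <- build_codec(codec_config(16, 4), seed = 3)
  set.seed(4)
  fr <- matrix(runif(256, -1, 1), 16)
  loss <- function(cd) {
    fw <- pvrnnagency:::codec_fwd(cd, fr)
    mean((fw$rec - fr)^2)
  }
  fw <- pvrnnagency:::codec_fwd(codec, fr, keep = TRUE)
  gr <- pvrnnagency:::codec_bwd(codec, fr, fw)
  h <- 1e-6
  for (side in c("enc", "dec")) {
    for (f in c("W1", "W2", "W3")) {
      v <- codec$params[[side]][[f]]
      for (i in sample(length(v), 3)) {
        cp <- codec; cp$params[[side]][[f]][i] <- v[i] + h
        cm <- codec; cm$params[[side]][[f]][i] <- v[i] - h
        fd <- (loss(cp) - loss(cm)) / (2 * h)
        expect_lt(rel_err(gr[[side]][[f]][i], fd), 1e-4)
      }
    }
  }
  # bridge projections and a bias
  for (pick in list(c("enc", "Wp"), c("dec", "Wp"), c("dec", "b3"))) {
    v <- codec$params[[pick[1]]][[pick[2]]]
    i <- sample(length(v), 1)
    cp <- codec; cp$params[[pick[1]]][[pick[2]]][i] <- v[i] + h
    cm <- codec; cm$params[[pick[1]]][[pick[2]]][i] <- v[i] - h
    fd <- (loss(cp) - loss(cm)) / (2 * h)
    expect_lt(rel_err(gr[[pick[1]]][[pick[2]]][i], fd), 1e-4)
  }
})

test_that("training reduces held-out loss and is seed-reproducible", {
  ds <- build_dataset(n_sequences = 2, n_segments = 2, segment_len = 25,
                      seed = 6, image_size = 16)
  frames <- do.call(pvrnnagency:::abind_first, lapply(ds, `[[`, "frames"))
  codec <- train_codec(frames, codec_config(16, 8), epochs = 5, seed = 7,
                       alpha = 3e-3)
  hist <- codec$history
  expect_lt(hist$holdout_mse[nrow(hist)], hist$holdout_mse[1])
  codec2 <- train_codec(frames, codec_config(16, 8), epochs = 5, seed = 7,
                        alpha = 3e-3)
  expect_identical(codec$history$holdout_mse, codec2$history$holdout_mse)
  expect_error(train_codec(array(0, c(0, 16, 16))), "frames|corpus")
})

test_that("trained codec separates primitives better than an untrained one", {
  corp <- shared_corpus()
  codec <- corp$codec
  J <- render_proprioception(c("A", "B", "C", "A"), 25, joint_noise_sd = 0,
                             style_seed = 1)
  cl <- render_vision(J, 16, pixel_noise_sd = 0)
  labs <- rep(c("A", "B", "C", "A"), each = 25)
  ratio <- function(cd) {
    lat <- encode_frames(cd, cl)
    cents <- sapply(c("A", "B", "C"), function(g)
      colMeans(lat[labs == g, , drop = FALSE]))
    within <- mean(unlist(lapply(c("A", "B", "C"), function(g) {
      L <- lat[labs == g, , drop = FALSE]
      mean(sqrt(rowSums((L - matrix(colMeans(L), nrow(L), ncol(L),
                                    byrow = TRUE))^2)))
    })))
    mean(dist(t(cents))) / within
  }
  r_trained <- ratio(codec)
  r_raw <- ratio(build_codec(codec_config(16, 8), seed = 99))
  expect_gt(r_trained, 1)          # between-primitive > within-primitive
  expect_gt(r_trained, r_raw)      # training improves discriminability
  # reconstruction of clean frames beats the injected noise floor
  rmse <- sqrt(mean(vapply(seq_len(nrow(J)), function(t)
    mean((reconstruct(codec, cl[t, , ]) - cl[t, , ])^2), numeric(1))))
  expect_lt(rmse, 0.15)
  # time-independence: encoding is per-frame (permutation equivariance)
  lat <- encode_frames(codec, cl[c(3, 1, 2), , ])
  expect_equal(lat[2, ], encode(codec, cl[1, , ]))
})
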