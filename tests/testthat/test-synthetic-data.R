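# Synthetic visuo-proprioceptive generator: state-machine laws, waveform
# contracts, noise asymmetry, determinism, plain-text I/O.

test_that("state machine obeys its transition laws", {
  labs <- lapply(1:1000, function(i) sample_labels(8, seed = i))
  all_pairs <- do.call(rbind, lapply(labs, function(l)
    cbind(l[-length(l)], l[-1])))
  from_bc <- all_pairs[all_pairs[, 1] %in% c("B", "C"), , drop = FALSE]
  expect_true(all(from_bc[, 2] == "A"))                 # B/C -> A always
  from_a <- all_pairs[all_pairs[, 1] == "A", , drop = FALSE]
  expect_true(all(from_a[, 2] %in% c("B", "C")))        # no A -> A
  p_hat <- mean(from_a[, 2] == "B")
  se <- sqrt(0.5 * 0.5 / nrow(from_a))
  expect_lt(abs(p_hat - 0.5), 3 * se)
  expect_true(all(vapply(labs, `[`, character(1), 1) == "A"))  # start state
  # no two consecutive identical labels
  expect_true(all(all_pairs[, 1] != all_pairs[, 2]))
  expect_identical(sample_labels(8, seed = 42), sample_labels(8, seed = 42))
  expect_error(sample_labels(0, seed = 1), "n_segments")
  expect_error(sample_labels(3, seed = 1, p_AB = 1.5), "probability")
})

test_that("proprioception: range, continuity, periodicity, determinism", {
  labs <- c("A", "B", "A", "C")
  J <- render_proprioception(labs, 48, joint_noise_sd = 0, style_seed = 3)
  expect_equal(dim(J), c(192, 16))
  expect_lte(max(abs(J)), 1)
  # noiseless: the oscillation cycles repeat exactly on the arm joints away
  # from the 4-step entry/exit ramps (cycle length 16 at segment_len 48)
  arm <- c(1, 2, 7, 8)
  seg <- J[1:48, arm]                       # an A segment
  expect_equal(seg[5:16, ], seg[21:32, ], tolerance = 1e-12)
  expect_equal(seg[17:28, ], seg[33:44, ], tolerance = 1e-12)
  # continuity at segment boundaries within 0.1
  jumps <- abs(J[-1, ] - J[-nrow(J), ])
  at_boundary <- jumps[seq(48, 144, by = 48), ]
  expect_lt(max(at_boundary), 0.1)
  # torso offsets have opposite signs for B (segment 2) vs C (segment 4)
  torso_B <- mean(J[49:96, 13:14])
  torso_C <- mean(J[145:192, 13:14])
  expect_gt(torso_B, 0.1)
  expect_lt(torso_C, -0.1)
  # determinism and noise
  expect_identical(render_proprioception(labs, 48, 0.02, style_seed = 9),
                   render_proprioception(labs, 48, 0.02, style_seed = 9))
  Jn <- render_proprioception(labs, 48, joint_noise_sd = 0.02, style_seed = 3)
  expect_lte(max(abs(Jn)), 1)
  expect_equal(sd(Jn - J), 0.02, tolerance = 0.1)
  expect_error(render_proprioception(labs, 8), "segment_len")
  expect_error(render_proprioception(c("A", "Q"), 48), "labels")
})

test_that("vision: deterministic projection, noise asymmetry, discriminability", {
  labs <- c("A", "B")
  J <- render_proprioception(labs, 25, joint_noise_sd = 0, style_seed = 1)
  # identical joint rows give identical frames when noiseless
  J2 <- rbind(J[1, ], J[1, ], J[2, ])
  F0 <- render_vision(J2, 16, pixel_noise_sd = 0)
  expect_identical(F0[1, , ], F0[2, , ])
  expect_false(identical(F0[1, , ], F0[3, , ]))
  expect_true(all(F0 >= -1 & F0 <= 1))
  # seeded noise reproducible
  Fa <- render_vision(J, 16, 0.15, seed = 5)
  expect_identical(Fa, render_vision(J, 16, 0.15, seed = 5))
  expect_false(identical(Fa, render_vision(J, 16, 0.15, seed = 6)))
  expect_error(render_vision(J, 24), "image_size")
  # default config: per-step frame-to-frame variance exceeds joint noise
  ds <- build_dataset(n_sequences = 1, n_segments = 2, segment_len = 25,
                      seed = 2, image_size = 16)
  fr <- ds[[1]]$frames
  clean <- render_vision(ds[[1]]$joints, 16, pixel_noise_sd = 0)
  vis_resid_var <- var(as.vector(fr - clean))
  expect_gt(vis_resid_var, 0.01^2)    # far above the proprioceptive noise
  # distinct primitives are separated well beyond the noise floor
  JA <- render_proprioception("A", 25, 0, style_seed = 1)
  JB <- render_proprioception("B", 25, 0, style_seed = 1)
  fA <- render_vision(JA[13, , drop = FALSE], 16, 0)
  fB <- render_vision(JB[13, , drop = FALSE], 16, 0)
  expect_gt(sqrt(sum((fA - fB)^2)), 3 * 0.15)
})

test_that("build_dataset: geometry, manifest, determinism, classification", {
  ds <- build_dataset(n_sequences = 3, n_segments = 8, segment_len = 50,
                      seed = 4, image_size = 16, n_styles = 3)
  expect_length(ds, 3)
  expect_equal(nrow(ds[[1]]$joints), 400)     # 8 x 50 steps
  expect_equal(dim(ds[[1]]$frames), c(400, 16, 16))
  man <- attr(ds, "manifest")
  expect_length(man$sequences, 3)
  expect_equal(man$sequences[[2]]$labels, ds[[2]]$labels)
  expect_equal(vapply(man$sequences, `[[`, numeric(1), "style"), 1:3)
  ds2 <- build_dataset(n_sequences = 3, n_segments = 8, segment_len = 50,
                       seed = 4, image_size = 16, n_styles = 3)
  expect_identical(ds[[2]]$joints, ds2[[2]]$joints)
  expect_identical(ds[[3]]$frames, ds2[[3]]$frames)
  # single-sequence corpus is valid
  d1 <- build_dataset(n_sequences = 1, n_segments = 2, segment_len = 25,
                      seed = 1, with_frames = FALSE, image_size = 16)
  expect_length(d1, 1)
  expect_null(d1[[1]]$frames)
  # noiseless segments classify back to their generating primitive
  J <- render_proprioception(c("A", "B", "A", "C"), 25, 0, style_seed = 1)
  got <- vapply(1:4, function(k)
    classify_primitive(J[((k - 1) * 25 + 1):(k * 25), ]), character(1))
  expect_equal(got, c("A", "B", "A", "C"))
})

test_that("plain-text dataset I/O round-trips", {
  dir <- withr::local_tempdir()
  ds <- build_dataset(n_sequences = 2, n_segments = 2, segment_len = 25,
                      seed = 9, image_size = 16)
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  J <- read.csv(file.path(dir, "seq001", "joints.csv"))
  expect_equal(names(J)[1], "j00")
  expect_equal(as.matrix(J), ds[[1]]$joints, ignore_attr = TRUE,
               tolerance = 1e-6)
  fr <- read_pgm(file.path(dir, "seq002", "frame0007.pgm"))
  expect_equal(fr, ds[[2]]$frames[7, , ], tolerance = 1 / 127)
})
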