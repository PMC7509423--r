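# Synthetic visuo-proprioceptive sequence generator.
#
# Emulates the statistical structure of the movement dataset the model is
# designed for: a 3-primitive probabilistic finite state machine
# (A -> {B, C} with probability p_AB / 1 - p_AB; B -> A and C -> A with
# probability 1), smooth 16-joint trajectories in [-1, 1], and grayscale
# stick-figure observations whose fluctuation substantially exceeds the
# proprioceptive noise.

PRIMITIVES <- c("A", "B", "C")

# joint roles in the 16-dof configuration (6 per arm, 4 torso/head)
ARM_WAVE_J  <- c(1L, 2L, 7L, 8L)    # designated arm oscillation joints
ARM_SEC_J   <- c(3L, 4L, 9L, 10L)   # secondary arm joints
TORSO_J     <- c(13L, 14L)          # torso rotation joints
HELD_J      <- c(5L, 6L, 11L, 12L, 15L, 16L)

#' Sample a primitive label sequence from the movement state machine
#'
#' The machine starts in primitive A ("waving"); after every A the next
#' segment is B with probability `p_AB`, otherwise C; after every B or C the
#' next segment is A with probability 1.
#'
#' @param n_segments number of primitive segments (>= 1).
#' @param seed integer seed; same seed gives an identical sequence.
#' @param p_AB probability of A -> B (default 0.5).
#' @return character vector of labels in `c("A","B","C")`.
#' @export
sample_labels <- function(n_segments, seed, p_AB = 0.5) {
  abort_if(n_segments < 1, "n_segments must be >= 1")
  abort_if(p_AB < 0 || p_AB > 1, "p_AB must be a probability")
  with_seed(seed, {
    labels <- character(n_segments)
    cur <- "A"
    for (i in seq_len(n_segments)) {
      labels[i] <- cur
      cur <- if (cur == "A") {
        if (runif(1) < p_AB) "B" else "C"
      } else "A"
    }
    labels
  })
}

# deterministic style variant (amplitude / phase / posture), emulating
# different human demonstrators
style_params <- function(style_seed) {
  with_seed(style_seed, {
    list(amp   = runif(1, 0.8, 1.0),
         phase = runif(1, 0, 0.6),
         posture = rnorm(16, 0, 0.02))
  })
}

# noiseless trajectory of one segment; s in [0, 1), three oscillation
# cycles per segment.  The oscillation is a style-phase-shaped sinusoid that
# vanishes at both segment ends, and a 4-step cosine ramp at segment entry
# and exit suppresses the sampled value next to the seam, so consecutive
# segments join continuously at the neutral posture.
segment_wave <- function(label, segment_len, style) {
  L <- segment_len
  s <- (seq_len(L) - 1) / L
  env <- sin(pi * s)
  # three exact cycles, zero at s = 0 and s = 1 for any style phase
  cyc <- function(delta)
    cos(delta) * sin(6 * pi * s) + 0.5 * sin(delta) * (1 - cos(6 * pi * s))
  ramp_in <- 0.5 * (1 - cos(pi * pmin(seq_len(L) - 1, 4) / 4))
  ramp <- ramp_in * rev(ramp_in)
  M <- matrix(rep(style$posture, each = L), L, 16)
  osc  <- ramp * cyc(style$phase)
  osc2 <- ramp * cyc(style$phase + 0.9)
  if (label == "A") {
    M[, ARM_WAVE_J] <- M[, ARM_WAVE_J] + 0.70 * style$amp * osc
    M[, ARM_SEC_J]  <- M[, ARM_SEC_J]  + 0.35 * style$amp * osc2
  } else {
    sgn <- if (label == "B") 1 else -1
    M[, ARM_WAVE_J] <- M[, ARM_WAVE_J] + 0.25 * style$amp * osc
    M[, ARM_SEC_J]  <- M[, ARM_SEC_J]  + 0.10 * style$amp * osc2
    M[, TORSO_J]    <- M[, TORSO_J] + sgn * 0.45 * env + 0.30 * style$amp * osc
  }
  for (j in HELD_J) M[, j] <- M[, j] + 0.03 * sin(2 * pi * s + j)
  M
}

#' Render a proprioceptive trajectory for a label sequence
#'
#' Each A segment carries exactly three oscillation cycles on the designated
#' arm joints; B / C segments carry three cycles on the torso joints riding
#' on opposite-sign lean offsets.  All oscillatory components vanish at
#' segment boundaries, so the trajectory is continuous there by
#' construction.  Additive Gaussian noise with sd `joint_noise_sd` is
#' applied and values are clipped to [-1, 1].
#'
#' @param labels character vector of primitive labels.
#' @param segment_len steps per segment (>= 12, so three cycles resolve).
#' @param joint_noise_sd nonnegative noise sd.
#' @param style_seed integer seed controlling the style variant and noise.
#' @return T x 16 matrix, T = length(labels) * segment_len.
#' @export
render_proprioception <- function(labels, segment_len, joint_noise_sd = 0.01,
                                  style_seed = 1L) {
  abort_if(segment_len < 12, "segment_len must be >= 12")
  abort_if(joint_noise_sd < 0, "joint_noise_sd must be nonnegative")
  abort_if(!all(labels %in% PRIMITIVES), "labels must be in {A, B, C}")
  style <- style_params(style_seed)
  M <- do.call(rbind, lapply(labels, segment_wave,
                             segment_len = segment_len, style = style))
  if (joint_noise_sd > 0) {
    M <- M + with_seed(child_seed(style_seed, 17L),
                       matrix(rnorm(length(M), 0, joint_noise_sd), nrow(M), 16))
  }
  pmin(pmax(M, -1), 1)
}

# supported image sizes
VISION_SIZES <- c(16L, 32L, 64L)

# squared distance from every pixel to a line segment p1 -> p2
seg_dist2 <- function(px, py, p1, p2) {
  vx <- p2[1] - p1[1]; vy <- p2[2] - p1[2]
  L2 <- vx^2 + vy^2
  t <- ((px - p1[1]) * vx + (py - p1[2]) * vy) / max(L2, 1e-12)
  t <- pmin(pmax(t, 0), 1)
  (px - (p1[1] + t * vx))^2 + (py - (p1[2] + t * vy))^2
}

# deterministic stick-figure projection of one joint configuration onto an
# n x n grayscale grid with values in [-0.8, 0.8]
render_frame <- function(joints, grid) {
  theta <- 0.9 * mean(joints[TORSO_J])
  hip  <- c(0, -0.55)
  neck <- hip + 0.8 * c(sin(theta), cos(theta))
  head <- neck + 0.22 * c(sin(theta), cos(theta))
  perp <- c(cos(theta), -sin(theta))
  shL <- neck - 0.16 * perp
  shR <- neck + 0.16 * perp
  aL <- -2.35 + 1.1 * joints[1] + 0.25 * joints[3]
  aR <-  2.35 - 1.1 * joints[7] - 0.25 * joints[9]
  handL <- shL + 0.5 * c(sin(aL + theta), cos(aL + theta))
  handR <- shR + 0.5 * c(sin(aR + theta), cos(aR + theta))
  w2 <- 0.0045  # squared stroke width
  I <- exp(-seg_dist2(grid$x, grid$y, hip, neck) / w2) +
    exp(-seg_dist2(grid$x, grid$y, shL, handL) / w2) +
    exp(-seg_dist2(grid$x, grid$y, shR, handR) / w2) +
    exp(-pmax(sqrt((grid$x - head[1])^2 + (grid$y - head[2])^2) - 0.12, 0)^2 / w2)
  -0.8 + 1.6 * pmin(I, 1)
}

#' Render grayscale vision frames from a joint trajectory
#'
#' A deterministic nonlinear stick-figure projection of each joint
#' configuration, plus per-pixel Gaussian noise (sd `pixel_noise_sd`) and a
#' slowly drifting global brightness term emulating varying optical
#' conditions.  The drift amplitude scales with `pixel_noise_sd`, so the
#' noiseless projection is fully deterministic.
#'
#' @param joints T x 16 joint matrix.
#' @param image_size one of 16, 32, 64.
#' @param pixel_noise_sd nonnegative noise sd (defaults far above the
#'   proprioceptive noise, matching the asymmetry of real recordings).
#' @param seed integer seed for the noise field.
#' @return array of dim c(T, image_size, image_size) with values in [-1, 1].
#' @export
render_vision <- function(joints, image_size = 64L, pixel_noise_sd = 0.15,
                          seed = 1L) {
  abort_if(!(image_size %in% VISION_SIZES), "image_size must be 16, 32 or 64")
  abort_if(pixel_noise_sd < 0, "pixel_noise_sd must be nonnegative")
  n <- as.integer(image_size)
  ax <- seq(-1, 1, length.out = n)
  grid <- list(x = rep(ax, times = n), y = rep(rev(ax), each = n))
  T <- nrow(joints)
  frames <- array(0, dim = c(T, n, n))
  for (t in seq_len(T)) frames[t, , ] <- render_frame(joints[t, ], grid)
  if (pixel_noise_sd > 0) {
    with_seed(seed, {
      drift_phase <- runif(1, 0, 2 * pi)
      drift <- pixel_noise_sd * sin(2 * pi * seq_len(T) / 200 + drift_phase)
      noise <- array(rnorm(T * n * n, 0, pixel_noise_sd), dim = c(T, n, n))
      frames <- frames + noise + array(rep(drift, n * n), dim = c(T, n, n))
    })
  }
  pmin(pmax(frames, -1), 1)
}

#' Build a synthetic visuo-proprioceptive dataset
#'
#' Defaults reproduce the reference corpus geometry: 30 sequences of
#' 8 primitive segments x 50 steps = 400 time steps, three style variants
#' cycling over sequences (emulating three demonstrators).
#'
#' @param n_sequences number of sequences (default 30).
#' @param n_segments segments per sequence (default 8).
#' @param segment_len steps per segment (default 50).
#' @param seed corpus seed; per-sequence seeds are derived from it.
#' @param n_styles number of style variants (default 3).
#' @param image_size frame size (default 64).
#' @param joint_noise_sd proprioceptive noise sd (default 0.01).
#' @param pixel_noise_sd vision noise sd (default 0.15).
#' @param with_frames render vision frames (set FALSE for label/joint-only
#'   corpora; frames dominate memory).
#' @param p_AB state-machine branch probability (default 0.5).
#' @return list of `primitive_sequence` objects with a `manifest` attribute.
#' @export
build_dataset <- function(n_sequences = 30L, n_segments = 8L, segment_len = 50L,
                          seed = 1L, n_styles = 3L, image_size = 64L,
                          joint_noise_sd = 0.01, pixel_noise_sd = 0.15,
                          with_frames = TRUE, p_AB = 0.5) {
  abort_if(n_sequences < 1, "n_sequences must be >= 1")
  abort_if(n_styles < 1, "n_styles must be >= 1")
  seqs <- vector("list", n_sequences)
  manifest <- list(generator_version = "1.0", corpus_seed = seed,
                   n_segments = n_segments, segment_len = segment_len,
                   image_size = image_size, p_AB = p_AB,
                   joint_noise_sd = joint_noise_sd,
                   pixel_noise_sd = pixel_noise_sd, start_state = "A",
                   sequences = vector("list", n_sequences))
  for (i in seq_len(n_sequences)) {
    sseed <- child_seed(seed, i)
    style <- ((i - 1L) %% n_styles) + 1L
    style_seed <- child_seed(seed, 1000L + style) + sseed %% 97L
    labels <- sample_labels(n_segments, seed = sseed, p_AB = p_AB)
    joints <- render_proprioception(labels, segment_len,
                                    joint_noise_sd = joint_noise_sd,
                                    style_seed = style_seed)
    frames <- if (with_frames)
      render_vision(joints, image_size, pixel_noise_sd,
                    seed = child_seed(sseed, 7L)) else NULL
    seqs[[i]] <- structure(
      list(labels = labels, joints = joints, frames = frames, latents = NULL,
           segment_len = as.integer(segment_len), seed = sseed, style = style),
      class = "primitive_sequence")
    manifest$sequences[[i]] <- list(index = i, seed = sseed, style = style,
                                    labels = labels)
  }
  attr(seqs, "manifest") <- manifest
  seqs
}

#' Classify a joint-trajectory segment by nearest primitive template
#'
#' Compares against the noiseless style-1 waveforms of the three primitives
#' (RMSE over the designated oscillation joints).
#'
#' @param segment segment_len x 16 matrix.
#' @param style_seed style of the templates.
#' @return one of "A", "B", "C".
#' @export
classify_primitive <- function(segment, style_seed = 1L) {
  style <- style_params(style_seed)
  L <- nrow(segment)
  idx <- c(ARM_WAVE_J, TORSO_J)
  err <- vapply(PRIMITIVES, function(lb) {
    tmpl <- segment_wave(lb, L, style)
    sqrt(mean((segment[, idx] - tmpl[, idx])^2))
  }, numeric(1))
  PRIMITIVES[which.min(err)]
}

#' Write a dataset to disk in plain-text formats
#'
#' Joints as CSV (`seq{i}/joints.csv`, header j00..j15), frames as ASCII PGM
#' (`seq{i}/frame{t}.pgm`), manifest as JSON.
#'
#' @param dataset result of [build_dataset()].
#' @param dir output directory.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(dataset)) {
    sq <- dataset[[i]]
    sdir <- file.path(dir, sprintf("seq%03d", i))
    dir.create(sdir, showWarnings = FALSE)
    J <- as.data.frame(sq$joints)
    names(J) <- sprintf("j%02d", 0:15)
    write.csv(J, file.path(sdir, "joints.csv"), row.names = FALSE)
    if (!is.null(sq$frames)) {
      for (t in seq_len(dim(sq$frames)[1]))
        write_pgm(sq$frames[t, , ], file.path(sdir, sprintf("frame%04d.pgm", t)))
    }
  }
  jsonlite::write_json(attr(dataset, "manifest"),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Write one grayscale frame as plain-text PGM (P2)
#' @param frame n x n matrix in [-1, 1].
#' @param path output file.
#' @export
write_pgm <- function(frame, path) {
  v <- round((frame + 1) / 2 * 255)
  v <- pmin(pmax(v, 0), 255)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(frame), nrow(frame)), "255"), con)
  writeLines(apply(v, 1, paste, collapse = " "), con)
  invisible(path)
}

#' Read a plain-text PGM (P2) frame back into [-1, 1]
#' @param path PGM file written by [write_pgm()].
#' @export
read_pgm <- function(path) {
  txt <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  abort_if(txt[1] != "P2", "only ASCII PGM (P2) is supported")
  w <- as.integer(txt[2]); h <- as.integer(txt[3]); mx <- as.numeric(txt[4])
  v <- as.numeric(txt[-(1:4)])
  matrix(v, nrow = h, ncol = w, byrow = TRUE) / mx * 2 - 1
}
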