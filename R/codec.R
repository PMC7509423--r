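# Static convolutional encoder/decoder mapping grayscale frames to/from the
# low-dimensional vision latent.  Stride-1 valid convolutions with large
# kernels collapse the frame to 1x1 spatial extent in three stages; a final
# linear+tanh bridge maps the 30 encoder channels to the latent dimension
# (and its transpose back).  Convolutions are evaluated as im2col matrix
# products; transposed convolutions reuse the same index structure through a
# sparse scatter matrix, which also yields exact gradients.

# kernel sizes per supported image size: spatial chain n -> n/2 -> n/4 -> 1
CODEC_KERNELS <- list(`64` = c(33L, 17L, 16L),
                      `32` = c(17L, 9L, 8L),
                      `16` = c(9L, 5L, 4L))
CODEC_CHANNELS <- c(5L, 15L, 30L)

#' Codec configuration
#'
#' @param image_size one of 16, 32, 64 (kernels scale with the frame size).
#' @param latent_dim vision latent size (default 20).
#' @param coordconv append normalized x/y coordinate channels to the encoder
#'   input (default TRUE).
#' @export
codec_config <- function(image_size = 64L, latent_dim = 20L, coordconv = TRUE) {
  abort_if(!(image_size %in% VISION_SIZES), "image_size must be 16, 32 or 64")
  abort_if(latent_dim < 1, "latent_dim must be >= 1")
  structure(list(image_size = as.integer(image_size),
                 latent_dim = as.integer(latent_dim),
                 kernels = CODEC_KERNELS[[as.character(image_size)]],
                 channels = CODEC_CHANNELS,
                 coordconv = isTRUE(coordconv)), class = "codec_config")
}

# im2col context for a valid stride-1 convolution: H x H x Cin -> Ho x Ho
# patches of k x k x Cin.  idx indexes the flattened input so that
# matrix(xvec[idx], Ho^2, k^2 * Cin) is the patch matrix; S scatters patch
# gradients back onto the input (and implements the transposed convolution).
make_conv_ctx <- function(H, k, Cin) {
  Ho <- H - k + 1L
  abort_if(Ho < 1, "kernel larger than input")
  oi <- rep(seq_len(Ho), times = Ho)
  oj <- rep(seq_len(Ho), each = Ho)
  pi_v <- rep(seq_len(k), times = k * Cin)
  pj_v <- rep(rep(seq_len(k), each = k), times = Cin)
  c_v <- rep(seq_len(Cin), each = k * k)
  base_op <- oi + (oj - 1L) * H
  base_q <- (pi_v - 1L) + (pj_v - 1L) * H + (c_v - 1L) * H * H
  idx <- as.vector(outer(base_op, base_q, "+"))
  S <- Matrix::sparseMatrix(i = idx, j = seq_along(idx), x = 1,
                            dims = c(H * H * Cin, length(idx)))
  list(H = H, k = k, Cin = Cin, Ho = Ho, idx = idx, S = S)
}

conv_fwd <- function(xvec, ctx, W, b) {
  M <- matrix(xvec[ctx$idx], nrow = ctx$Ho^2)
  list(Y = addb(M %*% W, b), M = M)
}

# gY: Ho^2 x Cout gradient; returns gradients for x, W, b
conv_bwd <- function(gY, M, W, ctx) {
  list(gx = as.vector(ctx$S %*% as.vector(gY %*% t(W))),
       gW = crossprod(M, gY), gb = colSums(gY))
}

# transposed convolution: X (n^2 x Cin) -> Y (H^2 x Cout) where ctx was
# built for the mirrored conv (H, k, Cout); W has shape (k^2*Cout, Cin)
tconv_fwd <- function(X, ctx, W, b) {
  M <- X %*% t(W)
  Y <- matrix(as.vector(ctx$S %*% as.vector(M)), ncol = ctx$Cin)
  list(Y = addb(Y, b), M = M)
}

tconv_bwd <- function(gY, X, W, ctx) {
  gM <- matrix(as.vector(Matrix::crossprod(ctx$S, as.vector(gY))),
               nrow = nrow(X))
  list(gX = gM %*% W, gW = crossprod(gM, X), gb = colSums(gY))
}

#' Append CoordConv coordinate channels to a frame
#'
#' Adds two channels holding the normalized x and y pixel coordinates in
#' [-1, 1]; the content channel is unchanged.  The corner (1,1) carries
#' coordinates (-1, -1) and the opposite corner (1, 1).
#'
#' @param frame n x n matrix (or n x n x C array).
#' @return n x n x (C + 2) array.
#' @export
coordconv_augment <- function(frame) {
  if (is.matrix(frame)) frame <- array(frame, c(nrow(frame), ncol(frame), 1))
  n <- dim(frame)[1]
  ax <- seq(-1, 1, length.out = n)
  xc <- matrix(ax, n, n)         # varies along the first index
  yc <- matrix(ax, n, n, byrow = TRUE)
  out <- array(0, c(n, n, dim(frame)[3] + 2))
  out[, , seq_len(dim(frame)[3])] <- frame
  out[, , dim(frame)[3] + 1] <- xc
  out[, , dim(frame)[3] + 2] <- yc
  out
}

#' Build a codec with freshly initialized parameters
#'
#' @param config a [codec_config()].
#' @param seed initialization seed.
#' @export
build_codec <- function(config = codec_config(), seed = 1L) {
  n <- config$image_size; ks <- config$kernels; ch <- config$channels
  cin1 <- if (config$coordconv) 3L else 1L
  s1 <- n - ks[1] + 1L
  s2 <- s1 - ks[2] + 1L
  ctx <- list(enc1 = make_conv_ctx(n, ks[1], cin1),
              enc2 = make_conv_ctx(s1, ks[2], ch[1]),
              enc3 = make_conv_ctx(s2, ks[3], ch[2]),
              dec3 = make_conv_ctx(n, ks[1], 1L))
  stopifnot(ctx$enc3$Ho == 1L)  # shape chain must collapse to 1x1
  params <- with_seed(seed, list(
    enc = list(W1 = glorot(ks[1]^2 * cin1, ch[1]), b1 = rep(0, ch[1]),
               W2 = glorot(ks[2]^2 * ch[1], ch[2]), b2 = rep(0, ch[2]),
               W3 = glorot(ks[3]^2 * ch[2], ch[3]), b3 = rep(0, ch[3]),
               Wp = glorot(ch[3], config$latent_dim),
               bp = rep(0, config$latent_dim)),
    dec = list(Wp = glorot(config$latent_dim, ch[3]), bp = rep(0, ch[3]),
               W3 = glorot(ks[3]^2 * ch[2], ch[3]), b3 = rep(0, ch[2]),
               W2 = glorot(ks[2]^2 * ch[1], ch[2]), b2 = rep(0, ch[1]),
               W1 = glorot(ks[1]^2 * 1L, ch[1]), b1 = 0)))
  structure(list(config = config, ctx = ctx, params = params, seed = seed,
                 trained = FALSE),
            class = "pvrnn_codec")
}

# full forward pass of one frame with intermediates kept for backprop
codec_fwd <- function(codec, frame, keep = FALSE) {
  cfg <- codec$config; pr <- codec$params; ctx <- codec$ctx
  abort_if(!all(dim(frame)[1:2] == cfg$image_size), "frame size mismatch")
  x <- if (cfg$coordconv) coordconv_augment(frame) else
    array(frame, c(cfg$image_size, cfg$image_size, 1))
  e1 <- conv_fwd(as.vector(x), ctx$enc1, pr$enc$W1, pr$enc$b1)
  a1 <- pmax(e1$Y, 0)
  e2 <- conv_fwd(as.vector(a1), ctx$enc2, pr$enc$W2, pr$enc$b2)
  a2 <- pmax(e2$Y, 0)
  e3 <- conv_fwd(as.vector(a2), ctx$enc3, pr$enc$W3, pr$enc$b3)
  a3 <- tanh(e3$Y)                       # 1 x 30
  lat <- tanh(addb(a3 %*% pr$enc$Wp, pr$enc$bp))   # 1 x latent
  # decoder
  d0 <- addb(lat %*% pr$dec$Wp, pr$dec$bp)         # 1 x 30
  t3 <- tconv_fwd(d0, ctx$enc3, pr$dec$W3, pr$dec$b3)
  a5 <- pmax(t3$Y, 0)
  t2 <- tconv_fwd(a5, ctx$enc2, pr$dec$W2, pr$dec$b2)
  a6 <- pmax(t2$Y, 0)
  t1 <- tconv_fwd(a6, ctx$dec3, pr$dec$W1, pr$dec$b1)
  rec <- tanh(t1$Y)                      # n^2 x 1
  out <- list(latent = drop(lat), rec = matrix(rec, cfg$image_size))
  if (keep) out$cache <- list(x = x, e1 = e1, a1 = a1, e2 = e2, a2 = a2,
                              e3 = e3, a3 = a3, lat = lat, d0 = d0, t3 = t3,
                              a5 = a5, t2 = t2, a6 = a6, t1 = t1, rec = rec)
  out
}

# gradients of the pixel MSE of one frame w.r.t. all codec parameters
codec_bwd <- function(codec, frame, fw) {
  cfg <- codec$config; pr <- codec$params; ctx <- codec$ctx
  cc <- fw$cache
  npix <- cfg$image_size^2
  gRec <- 2 * (cc$rec - as.vector(frame)) / npix      # dMSE/drec, n^2 x 1
  gT1 <- matrix(gRec * (1 - cc$rec^2), ncol = 1)
  b1g <- tconv_bwd(gT1, cc$a6, pr$dec$W1, ctx$dec3)
  gA6 <- b1g$gX * (cc$a6 > 0)
  b2g <- tconv_bwd(gA6, cc$a5, pr$dec$W2, ctx$enc2)
  gA5 <- b2g$gX * (cc$a5 > 0)
  b3g <- tconv_bwd(gA5, cc$d0, pr$dec$W3, ctx$enc3)
  gD0 <- b3g$gX                                       # 1 x 30
  gdec <- list(Wp = crossprod(cc$lat, gD0), bp = colSums(gD0),
               W3 = b3g$gW, b3 = b3g$gb, W2 = b2g$gW, b2 = b2g$gb,
               W1 = b1g$gW, b1 = b1g$gb)
  gLat <- (gD0 %*% t(pr$dec$Wp)) * (1 - cc$lat^2)
  gA3 <- (gLat %*% t(pr$enc$Wp)) * (1 - cc$a3^2)
  e3g <- conv_bwd(gA3, cc$e3$M, pr$enc$W3, ctx$enc3)
  gA2 <- matrix(e3g$gx, nrow = nrow(cc$a2)) * (cc$a2 > 0)
  e2g <- conv_bwd(gA2, cc$e2$M, pr$enc$W2, ctx$enc2)
  gA1 <- matrix(e2g$gx, nrow = nrow(cc$a1)) * (cc$a1 > 0)
  e1g <- conv_bwd(gA1, cc$e1$M, pr$enc$W1, ctx$enc1)
  genc <- list(W1 = e1g$gW, b1 = e1g$gb, W2 = e2g$gW, b2 = e2g$gb,
               W3 = e3g$gW, b3 = e3g$gb,
               Wp = crossprod(cc$a3, gLat), bp = colSums(gLat))
  list(enc = genc, dec = gdec,
       mse = mean((cc$rec - as.vector(frame))^2))
}

#' Encode a frame to its vision latent
#'
#' @param codec a `pvrnn_codec`.
#' @param frame n x n matrix with pixels in [-1, 1].
#' @return latent vector in (-1, 1)^latent_dim.
#' @export
encode <- function(codec, frame) codec_fwd(codec, frame)$latent

#' Decode a vision latent to a frame
#'
#' @param codec a `pvrnn_codec`.
#' @param latent latent vector.
#' @return n x n frame with pixels in (-1, 1).
#' @export
decode <- function(codec, latent) {
  cfg <- codec$config; pr <- codec$params; ctx <- codec$ctx
  abort_if(length(latent) != cfg$latent_dim, "latent dimension mismatch")
  d0 <- addb(matrix(latent, 1) %*% pr$dec$Wp, pr$dec$bp)
  t3 <- tconv_fwd(d0, ctx$enc3, pr$dec$W3, pr$dec$b3)
  a5 <- pmax(t3$Y, 0)
  t2 <- tconv_fwd(a5, ctx$enc2, pr$dec$W2, pr$dec$b2)
  a6 <- pmax(t2$Y, 0)
  t1 <- tconv_fwd(a6, ctx$dec3, pr$dec$W1, pr$dec$b1)
  matrix(tanh(t1$Y), cfg$image_size)
}

#' Encode every frame of a (T, n, n) array
#' @param codec a `pvrnn_codec`.
#' @param frames array of frames.
#' @return T x latent_dim matrix.
#' @export
encode_frames <- function(codec, frames) {
  T <- dim(frames)[1]
  out <- matrix(0, T, codec$config$latent_dim)
  for (t in seq_len(T)) out[t, ] <- encode(codec, frames[t, , ])
  out
}

#' Fill the latent targets of a dataset using a trained codec
#' @param dataset list of `primitive_sequence` objects with frames.
#' @param codec a trained `pvrnn_codec`.
#' @export
encode_dataset <- function(dataset, codec) {
  for (i in seq_along(dataset)) {
    abort_if(is.null(dataset[[i]]$frames), "sequence has no frames")
    dataset[[i]]$latents <- encode_frames(codec, dataset[[i]]$frames)
  }
  dataset
}

#' Train the codec on a frame corpus
#'
#' Minimizes per-pixel MSE with Adam on minibatches; 10% of the frames are
#' held out and the held-out loss is logged per epoch.
#'
#' @param frames (N, n, n) array, or a dataset whose sequences carry frames.
#' @param config a [codec_config()] matching the frame size.
#' @param epochs training epochs.
#' @param seed seed for initialization, split and shuffling.
#' @param batch_size minibatch size.
#' @param alpha Adam step size.
#' @return trained `pvrnn_codec` with a `history` data frame.
#' @export
train_codec <- function(frames, config = NULL, epochs = 20L, seed = 1L,
                        batch_size = 32L, alpha = 1e-3) {
  if (is.list(frames) && inherits(frames[[1]], "primitive_sequence")) {
    frames <- do.call(abind_first, lapply(frames, `[[`, "frames"))
  }
  abort_if(is.null(frames) || length(frames) == 0, "empty frame corpus")
  N <- dim(frames)[1]
  abort_if(N < 2, "need at least 2 frames")
  if (is.null(config)) config <- codec_config(image_size = dim(frames)[2])
  codec <- build_codec(config, seed = seed)
  opt <- adam_init(codec$params)
  hist <- data.frame(epoch = integer(), train_mse = numeric(),
                     holdout_mse = numeric())
  with_seed(child_seed(seed, 3L), {
    perm <- sample.int(N)
    n_hold <- max(1L, floor(0.1 * N))
    hold <- perm[seq_len(n_hold)]
    tr <- perm[-seq_len(n_hold)]
    eval_mse <- function(idx) {
      mean(vapply(idx, function(i) {
        fw <- codec_fwd(codec, frames[i, , ])
        mean((fw$rec - frames[i, , ])^2)
      }, numeric(1)))
    }
    hist <- rbind(hist, data.frame(epoch = 0L, train_mse = NA_real_,
                                   holdout_mse = eval_mse(hold)))
    for (ep in seq_len(epochs)) {
      ord <- sample(tr)
      tot <- 0
      for (start in seq(1, length(ord), by = batch_size)) {
        bidx <- ord[start:min(start + batch_size - 1, length(ord))]
        gsum <- NULL
        for (i in bidx) {
          fw <- codec_fwd(codec, frames[i, , ], keep = TRUE)
          g <- codec_bwd(codec, frames[i, , ], fw)
          tot <- tot + g$mse
          gi <- list(enc = g$enc, dec = g$dec)
          gsum <- if (is.null(gsum)) gi else
            map2_params(gsum, gi, `+`)
        }
        gavg <- map2_params(gsum, gsum, function(a, b) a / length(bidx))
        st <- adam_step(opt, codec$params, gavg, alpha = alpha)
        codec$params <- st$params
        opt <- st$state
      }
      hist <- rbind(hist, data.frame(epoch = ep, train_mse = tot / length(tr),
                                     holdout_mse = eval_mse(hold)))
    }
  })
  codec$history <- hist
  codec$trained <- TRUE
  codec
}

# bind arrays along the first dimension
abind_first <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  n <- sum(vapply(arrs, function(a) dim(a)[1], numeric(1)))
  out <- array(0, c(n, d[2], d[3]))
  at <- 1L
  for (a in arrs) {
    k <- dim(a)[1]
    out[at:(at + k - 1), , ] <- a
    at <- at + k
  }
  out
}

#' Reconstruct a frame through the codec (encode then decode)
#' @param codec a `pvrnn_codec`.
#' @param frame input frame.
#' @export
reconstruct <- function(codec, frame) codec_fwd(codec, frame)$rec
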