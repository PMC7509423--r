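# End-to-end experiment runners: modality-specific meta-prior training
# (experiment 1) and the global meta-prior sweep modulating the strength of
# agency (experiment 2), at desk scale by default.

#' Experiment specification
#'
#' Defaults are scaled so each experiment finishes in minutes on one CPU;
#' pass `full_scale = TRUE` for the reference configuration (30 sequences of
#' 400 steps, full-width model, 4,000 epochs - a long run).
#'
#' @param name experiment name.
#' @param n_train,n_test numbers of training / held-out sequences.
#' @param n_segments,segment_len sequence geometry.
#' @param image_size frame size.
#' @param latent_dim vision latent size.
#' @param codec_epochs codec training epochs.
#' @param epochs network training epochs.
#' @param n_seeds number of random initializations / ER seeds.
#' @param window_len,er_iters error-regression window and iteration counts.
#' @param seed base seed.
#' @param outdir optional output directory for reports.
#' @param full_scale use the reference configuration.
#' @export
experiment_spec <- function(name = "scaled", n_train = 4L, n_test = 2L,
                            n_segments = 4L, segment_len = 25L,
                            image_size = 16L, latent_dim = 8L,
                            codec_epochs = 8L, epochs = 300L, n_seeds = 2L,
                            window_len = 12L, er_iters = 10L, seed = 1L,
                            outdir = NULL, full_scale = FALSE) {
  if (full_scale) {
    n_train <- 27L; n_test <- 3L; n_segments <- 8L; segment_len <- 50L
    image_size <- 64L; latent_dim <- 20L; codec_epochs <- 20L
    epochs <- 4000L; n_seeds <- 10L; window_len <- 30L; er_iters <- 30L
  }
  structure(list(name = name, n_train = n_train, n_test = n_test,
                 n_segments = n_segments, segment_len = segment_len,
                 image_size = image_size, latent_dim = latent_dim,
                 codec_epochs = codec_epochs, epochs = epochs,
                 n_seeds = n_seeds, window_len = window_len,
                 er_iters = er_iters, seed = seed, outdir = outdir,
                 full_scale = isTRUE(full_scale)), class = "experiment_spec")
}

#' Generate a corpus, train the codec, and encode latent targets
#'
#' @param spec an [experiment_spec()].
#' @param max_codec_frames cap on codec training frames (subsampled).
#' @return list with `train_set`, `test_set` (latents filled), `codec`, and
#'   the generation `manifest`.
#' @export
prepare_corpus <- function(spec, max_codec_frames = 400L) {
  ds <- build_dataset(n_sequences = spec$n_train + spec$n_test,
                      n_segments = spec$n_segments,
                      segment_len = spec$segment_len,
                      seed = spec$seed, image_size = spec$image_size)
  tr_idx <- seq_len(spec$n_train)
  frames <- do.call(abind_first, lapply(ds[tr_idx], `[[`, "frames"))
  if (dim(frames)[1] > max_codec_frames) {
    keep <- with_seed(child_seed(spec$seed, 5L),
                      sort(sample.int(dim(frames)[1], max_codec_frames)))
    frames <- frames[keep, , , drop = FALSE]
  }
  codec <- train_codec(frames,
                       codec_config(spec$image_size, spec$latent_dim),
                       epochs = spec$codec_epochs,
                       seed = child_seed(spec$seed, 11L))
  ds <- encode_dataset(ds, codec)
  list(train_set = ds[tr_idx], test_set = ds[-tr_idx], codec = codec,
       manifest = attr(ds, "manifest"))
}

scaled_config_for <- function(spec) {
  if (spec$full_scale) network_config(l_dim = spec$latent_dim)
  else network_config_scaled(l_dim = spec$latent_dim)
}

#' Experiment 1: training with modality-specific meta-priors
#'
#' Trains the tight-vision setting and the swapped setting `n_seeds` times
#' each, evaluates every model with error regression on the held-out
#' sequences, and reports the standard metric table (mean and sd per
#' setting), the learning curves, and the per-seed direction-of-effect
#' comparison (associative KL and vision reconstruction error expected lower
#' under the tight-vision setting).
#'
#' @param spec an [experiment_spec()].
#' @return report list; written as CSV/JSON under `spec$outdir` if set.
#' @export
run_experiment1 <- function(spec = experiment_spec()) {
  corp <- prepare_corpus(spec)
  er <- er_config(window_len = spec$window_len, iters = spec$er_iters)
  rep1 <- replicate_exp1(corp$train_set, corp$test_set,
                         setting_a = meta_priors_w1(),
                         setting_b = meta_priors_w2(),
                         n_inits = spec$n_seeds,
                         config = scaled_config_for(spec),
                         train_cfg = train_config(epochs = spec$epochs),
                         er_cfg = er, seed = spec$seed)
  report <- list(spec = spec[setdiff(names(spec), "outdir")],
                 runs = rep1$runs, summary = rep1$summary,
                 direction = rep1$direction,
                 train_manifest = corp$manifest,
                 held_out = seq.int(spec$n_train + 1L,
                                    spec$n_train + spec$n_test))
  result <- list(report = report, models = rep1$models, corpus = corp)
  if (!is.null(spec$outdir)) {
    dir.create(spec$outdir, recursive = TRUE, showWarnings = FALSE)
    write.csv(rep1$runs, file.path(spec$outdir, "exp1_runs.csv"),
              row.names = FALSE)
    write.csv(rep1$summary, file.path(spec$outdir, "exp1_summary.csv"),
              row.names = FALSE)
    jsonlite::write_json(report[c("direction", "held_out")],
                         file.path(spec$outdir, "exp1_direction.json"),
                         auto_unbox = TRUE, digits = NA)
    for (i in seq_along(rep1$models$a))
      write_history(rep1$models$a[[i]]$history,
                    file.path(spec$outdir, sprintf("exp1_history_a_%02d.csv", i)))
  }
  result
}

#' Experiment 2: meta-prior sweep over a trained model
#'
#' Runs the shifting-window interaction over the held-out sequences under
#' five meta-prior rescalings spanning four orders of magnitude (consistent
#' ratio across layers), `n_seeds` ER noise seeds each, and reports the
#' per-setting metric panels plus Spearman monotonicity statistics of
#' reconstruction error (expected non-decreasing in w) and total KL
#' divergence (expected non-increasing).
#'
#' @param spec an [experiment_spec()].
#' @param fit a trained model as returned by [train()] (with `net`), e.g.
#'   one of experiment 1's models; required.
#' @param test_set held-out sequences with latents (from [prepare_corpus()]).
#' @return report list; written under `spec$outdir` if set.
#' @export
run_experiment2 <- function(spec, fit, test_set) {
  abort_if(is.null(fit) || is.null(fit$net),
           "a trained model checkpoint is required")
  net <- fit$net
  settings <- paste0("W", 1:5)
  factors <- 10^((1:5) - 3)
  rows <- list()
  for (k in seq_along(settings)) {
    meta_k <- rescale_meta_priors(net$meta, factors[k])
    er <- er_config(window_len = spec$window_len, iters = spec$er_iters,
                    meta = meta_k)
    for (s in seq_len(spec$n_seeds)) {
      mets <- lapply(seq_along(test_set), function(j)
        run_interaction(net, test_set[[j]], er,
                        seed = child_seed(spec$seed, 500L + k * 37L + s))$summary)
      avg <- Reduce(`+`, lapply(mets, unlist)) / length(mets)
      rows[[length(rows) + 1L]] <- data.frame(setting = settings[k],
                                              k = k, seed = s, t(avg))
    }
  }
  sweep <- do.call(rbind, rows)
  sweep$recon_total <- sweep$prop_err + sweep$vis_err
  kcols <- paste0("kld_", LAYER_NAMES)
  sweep$kld_total <- rowSums(sweep[kcols])
  per_seed <- split(sweep, sweep$seed)
  mono <- do.call(rbind, lapply(per_seed, function(d) {
    d <- d[order(d$k), ]
    data.frame(seed = d$seed[1],
               rho_recon = cor(d$k, d$recon_total, method = "spearman"),
               rho_kld = cor(d$k, d$kld_total, method = "spearman"),
               onestep_min_at_W1 = which.min(d$onestep_prop_err) == 1L)
  }))
  nums <- setdiff(names(sweep), c("setting", "k", "seed"))
  summary <- do.call(rbind, lapply(split(sweep, sweep$k), function(d)
    data.frame(setting = d$setting[1], metric = nums, mean = colMeans(d[nums]),
               sd = apply(d[nums], 2, sd))))
  report <- list(sweep = sweep, summary = summary, monotonicity = mono,
                 settings = stats::setNames(as.list(factors), settings))
  if (!is.null(spec$outdir)) {
    dir.create(spec$outdir, recursive = TRUE, showWarnings = FALSE)
    write.csv(sweep, file.path(spec$outdir, "exp2_sweep.csv"), row.names = FALSE)
    write.csv(summary, file.path(spec$outdir, "exp2_summary.csv"),
              row.names = FALSE)
    write.csv(mono, file.path(spec$outdir, "exp2_monotonicity.csv"),
              row.names = FALSE)
  }
  report
}

#' Save / load a model checkpoint
#'
#' Runtime serialization of a trained model (and optionally codec) with a
#' deterministic load round-trip.
#' @param object list to serialize (e.g. a [train()] fit).
#' @param path file path.
#' @export
save_checkpoint <- function(object, path) {
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
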