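## End-to-end experiment drivers: noise robustness, reaction-time
## distributions, difficulty-dependent pathway dominance, and hierarchical
## reconstruction. Every driver is a pure function of (model, config); CSV
## outputs and a reproducibility manifest are written when an output
## directory is given.

#' Experiment configuration
#'
#' Defaults follow the full testing protocol: noise levels 0 to 0.2 in
#' steps of 0.01 (21 values), 100 repeats of the same balanced 1000-pair
#' test set. Scaled-down runs simply pass smaller `n_repeats` /
#' `n_test_pairs`.
#'
#' @param sigma_grid Noise standard deviations.
#' @param n_repeats Evaluation repeats per noise level.
#' @param n_test_pairs Balanced test-set size.
#' @param test_seed Seed for drawing the test set (fixed across repeats).
#' @param trial_seed Base seed for trial noise streams.
#' @param rt_sigma Pixel noise used in the reaction-time experiment.
#' @param difficulty_sigma Pixel noise used in the difficulty experiment.
#' @param protocol From [trial_protocol()].
#' @param output_dir Optional directory for CSV outputs.
#' @return List of settings.
#' @export
experiment_config <- function(sigma_grid = seq(0, 0.2, 0.01),
                              n_repeats = 100, n_test_pairs = 1000,
                              test_seed = 1234, trial_seed = 1,
                              rt_sigma = 0, difficulty_sigma = 0.05,
                              protocol = trial_protocol(),
                              output_dir = NULL) {
  stopifnot(n_repeats >= 1, n_test_pairs >= 2, all(sigma_grid >= 0))
  list(sigma_grid = sigma_grid, n_repeats = n_repeats,
       n_test_pairs = n_test_pairs, test_seed = test_seed,
       trial_seed = trial_seed, rt_sigma = rt_sigma,
       difficulty_sigma = difficulty_sigma, protocol = protocol,
       output_dir = output_dir)
}

.write_out <- function(df, config, name) {
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(df, file.path(config$output_dir, name),
                     row.names = FALSE)
  }
  invisible(df)
}

.write_manifest <- function(config, model, name) {
  if (is.null(config$output_dir)) return(invisible(NULL))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  lines <- c(
    sprintf("experiment: %s", name),
    sprintf("variant: %s", model$variant),
    sprintf("model_seed: %d", model$seed),
    sprintf("test_seed: %d", config$test_seed),
    sprintf("trial_seed: %d", config$trial_seed),
    sprintf("n_repeats: %d", config$n_repeats),
    sprintf("n_test_pairs: %d", config$n_test_pairs),
    sprintf("sigma_grid: %s", paste(config$sigma_grid, collapse = ",")),
    sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  writeLines(lines, file.path(config$output_dir,
                              paste0(name, "_manifest.txt")))
  invisible(NULL)
}

#' Noise-robustness experiment
#'
#' For every noise level and repeat, runs the fixed balanced test set
#' (cues assigned half pro / half anti, reshuffled per repeat) through the
#' full trial dynamics and scores the fraction of correct choices
#' (unresolved trials count as incorrect).
#'
#' @param model From [build_ff_model()] or [build_pc_model()].
#' @param config From [experiment_config()].
#' @return Data frame `(sigma, repeat, accuracy)`, with a per-sigma summary
#'   in `attr(, "summary")`.
#' @export
run_noise_robustness <- function(model, config = experiment_config()) {
  pairs <- make_test_set(config$n_test_pairs, config$test_seed)
  rows <- list()
  for (si in seq_along(config$sigma_grid)) {
    sg <- config$sigma_grid[si]
    for (rep in seq_len(config$n_repeats)) {
      seed <- config$trial_seed + 1000L * si + rep
      old <- .save_rng(); set.seed(seed)
      cues <- sample(rep(c("pro", "anti"), length.out = nrow(pairs)))
      .restore_rng(old)
      trl <- as_trials(pairs, cues)
      res <- run_trials(model, trl, sigma = sg,
                        protocol = config$protocol, seed = seed)
      acc <- mean(res$choice != "none" & !is.na(res$correct) & res$correct)
      rows[[length(rows) + 1L]] <-
        data.frame(sigma = sg, repeat_id = rep, accuracy = acc)
    }
  }
  out <- do.call(rbind, rows)
  smry <- do.call(rbind, lapply(split(out, out$sigma), function(d)
    data.frame(sigma = d$sigma[1], mean_accuracy = mean(d$accuracy),
               sd_accuracy = stats::sd(d$accuracy), n = nrow(d))))
  rownames(smry) <- NULL
  attr(out, "summary") <- smry
  .write_out(out, config, "noise_robustness.csv")
  .write_out(smry, config, "noise_robustness_summary.csv")
  .write_manifest(config, model, "noise_robustness")
  out
}

#' Reaction-time experiment
#'
#' Runs the balanced test set once per cue condition and summarizes the
#' reaction-time distributions.
#'
#' @inheritParams run_noise_robustness
#' @return Data frame of per-trial results; `attr(, "summary")` holds the
#'   per-cue mean/sd/n.
#' @export
run_rt_experiment <- function(model, config = experiment_config()) {
  pairs <- make_test_set(config$n_test_pairs, config$test_seed)
  res <- rbind(
    run_trials(model, as_trials(pairs, "pro"), sigma = config$rt_sigma,
               protocol = config$protocol, seed = config$trial_seed),
    run_trials(model, as_trials(pairs, "anti"), sigma = config$rt_sigma,
               protocol = config$protocol, seed = config$trial_seed + 1L))
  smry <- rt_summary(res)
  attr(res, "summary") <- smry
  .write_out(res, config, "rt_trials.csv")
  .write_out(smry, config, "rt_summary.csv")
  .write_manifest(config, model, "rt")
  res
}

#' Difficulty-dominance experiment
#'
#' Draws prosaccade trials uniformly over the fine brightness grid
#' (ties excluded), runs them through the model, and tabulates which
#' pathway drove each decision as a function of stimulus difficulty
#' `|x_left - x_right|`.
#'
#' @inheritParams run_noise_robustness
#' @param breaks Difficulty bin edges.
#' @return The per-bin table from [difficulty_analysis()];
#'   `attr(, "trials")` holds the raw per-trial results.
#' @export
run_difficulty_experiment <- function(model, config = experiment_config(),
                                      breaks = seq(0, 1, 0.1)) {
  old <- .save_rng(); set.seed(config$test_seed)
  g <- 0:100
  xl <- sample(g, config$n_test_pairs, replace = TRUE)
  xr <- sample(g, config$n_test_pairs, replace = TRUE)
  keep <- xl != xr
  .restore_rng(old)
  pairs <- data.frame(x_left = xl[keep] / 100, x_right = xr[keep] / 100)
  pairs$difficulty <- abs(pairs$x_left - pairs$x_right)
  trl <- as_trials(pairs, "pro")
  res <- run_trials(model, trl, sigma = config$difficulty_sigma,
                    protocol = config$protocol, seed = config$trial_seed)
  tab <- difficulty_analysis(res, breaks)
  attr(tab, "trials") <- res
  .write_out(res, config, "difficulty_trials.csv")
  .write_out(tab, config, "difficulty_bins.csv")
  .write_manifest(config, model, "difficulty")
  tab
}

#' Hierarchical-reconstruction demonstration
#'
#' For a sample of cue and stimulus screens, reconstructs the input from
#' layer-1 and layer-2 latents of the predictive-coding hierarchy and
#' reports per-image reconstruction errors. Reconstruction is defined only
#' for the predictive-coding variant.
#'
#' @inheritParams run_noise_robustness
#' @param n_stimuli Number of stimulus screens sampled from the test grid.
#' @return Data frame `(frame, layer, mse, pearson_r)`;
#'   `attr(, "images")` holds the input and reconstructed frames. When
#'   `config$output_dir` is set, frames are also written as pixel CSVs and,
#'   if the `png` package is available, as grayscale PNG images.
#' @export
run_reconstruction_demo <- function(model, config = experiment_config(),
                                    n_stimuli = 4) {
  if (model$variant != "pc")
    stop("reconstruction is defined only for the predictive-coding variant")
  pairs <- make_test_set(max(2L * n_stimuli, 10L), config$test_seed)
  frames <- c(list(pro_cue = render_cue("pro"),
                   anti_cue = render_cue("anti")),
              stats::setNames(
                Map(render_stimulus, pairs$x_left[seq_len(n_stimuli)],
                    pairs$x_right[seq_len(n_stimuli)]),
                paste0("stim", seq_len(n_stimuli))))
  rows <- list(); images <- list()
  for (nm in names(frames)) {
    f <- frames[[nm]]
    st <- pc_infer(model$pc, f, model$pc$hyper)
    images[[paste0(nm, "_input")]] <- f
    for (layer in 1:2) {
      rec <- reconstruct_from_layer(model$pc, st, layer)
      images[[paste0(nm, "_layer", layer)]] <- rec
      rows[[length(rows) + 1L]] <- data.frame(
        frame = nm, layer = layer,
        mse = mean((as.numeric(f) - as.numeric(rec))^2),
        pearson_r = stats::cor(as.numeric(f), as.numeric(rec)))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "images") <- images
  .write_out(out, config, "reconstruction_errors.csv")
  if (!is.null(config$output_dir)) {
    for (nm in names(images))
      write_frame_csv(images[[nm]],
                      file.path(config$output_dir, paste0(nm, ".csv")))
    if (requireNamespace("png", quietly = TRUE)) {
      for (nm in names(images)) {
        v <- as.matrix(images[[nm]])
        v <- (v - min(v)) / max(max(v) - min(v), 1e-12)
        png::writePNG(v, file.path(config$output_dir, paste0(nm, ".png")))
      }
    }
  }
  .write_manifest(config, model, "reconstruction")
  out
}
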