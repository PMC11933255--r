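# Shared light-weight fixtures: small-montage simulations and a reduced
# pipeline configuration used across tests (full-montage defaults are
# exercised where the test is about the default geometry).

light_config <- function(seed = 1, alpha_grid = c(0, 0.5, 0.75),
                         beta_grid = 0, ...) {
  pipeline_config(streams = "voltage", m = 2, filter_k = 8, select_k = 3,
                  use_sfs = FALSE, outer_folds = 5, inner_folds = 3,
                  alpha_grid = alpha_grid, beta_grid = beta_grid,
                  window_span = c(0, 400), source_window_span = c(0, 400),
                  seed = seed, ...)
}

light_study <- function(seed = 1, gamma = 1, class_gap = 0.5,
                        n_channels = 16, n_target = 60,
                        n_source_trials = 300, ...) {
  simulate_study(target_spec = latent_spec(n_channels = n_channels,
                                           gamma = gamma,
                                           class_gap = class_gap),
                 n_target = n_target, n_source_trials = n_source_trials,
                 seed = seed, ...)
}

as_streams <- function(epochs) signal_streams(epochs, streams = "voltage")

raw_sources <- function(study) {
  lapply(study$sources, function(ep)
    list(streams = as_streams(ep), labels = ep$trials$class_label))
}

# Random symmetric PSD matrix with unit trace.
random_psd <- function(d, seed) {
  rng_old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  a <- matrix(rnorm(d * d), d)
  if (!is.null(rng_old)) assign(".Random.seed", rng_old, globalenv())
  s <- crossprod(a) + 0.1 * diag(d)
  s / sum(diag(s))
}

# Single-trial epoch_set wrapper around a channels x samples matrix.
matrix_epochs <- function(x, srate = 250, t0 = 0) {
  dat <- array(0, c(1, nrow(x), ncol(x)))
  dat[1, , ] <- x
  structure(list(data = dat, srate = srate, t0 = t0,
                 channels = paste0("ch", seq_len(nrow(x))),
                 task_id = "test",
                 trials = data.frame(trial_index = 1)),
            class = "epoch_set")
}
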