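#' Write an epoch set to a directory container
#'
#' Stores the trials x channels x samples array as little-endian float64
#' (`data.bin`), the metadata (`srate`, `t0`, `channels`, `task`,
#' dimensions) as `meta.json`, and the trial table as a UTF-8 `events.tsv`
#' with a fixed header.  The round trip through [read_epochs()] is
#' lossless.
#'
#' @param epochs an `epoch_set`.
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(path, "data.bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(epochs$data), con, size = 8, endian = "little")
  meta <- list(srate = epochs$srate, t0 = epochs$t0,
               channels = epochs$channels, task = epochs$task_id,
               dim = dim(epochs$data))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(as.data.frame(epochs$trials),
                     file.path(path, "events.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an epoch set from a directory container
#'
#' @param path directory written by [write_epochs()].
#' @return an `epoch_set`.
#' @export
read_epochs <- function(path) {
  meta_file <- file.path(path, "meta.json")
  if (!file.exists(meta_file)) stop("missing meta.json in ", path)
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  for (field in c("srate", "t0", "channels", "task", "dim"))
    if (is.null(meta[[field]])) stop("missing `", field, "` attribute")
  dn <- as.integer(meta$dim)
  con <- file(file.path(path, "data.bin"), "rb")
  on.exit(close(con))
  raw <- readBin(con, "double", n = prod(dn), size = 8, endian = "little")
  if (length(raw) != prod(dn))
    stop("`data` size does not match `dim` metadata")
  trials <- utils::read.delim(file.path(path, "events.tsv"),
                              stringsAsFactors = FALSE)
  if (nrow(trials) != dn[1])
    stop("`events.tsv` row count (", nrow(trials),
         ") does not match trial dimension (", dn[1], ")")
  if (length(meta$channels) != dn[2])
    stop("`channels` length does not match channel dimension")
  class(trials) <- c("trial_table", "data.frame")
  attr(trials, "task_id") <- meta$task
  structure(list(data = array(raw, dim = dn), srate = as.numeric(meta$srate),
                 t0 = as.numeric(meta$t0), channels = meta$channels,
                 task_id = meta$task, trials = trials),
            class = "epoch_set")
}

#' Run the full decoding pipeline on synthetic data
#'
#' Simulates the four-task study, extracts signal streams, trains the
#' three source models, runs the nested multi-source transfer, integrates
#' the evidence scores, and performs the stepwise, control, and dynamics
#' analyses.  When `outdir` is given, writes TSV/JSON outputs and a log
#' of the seed and configuration.
#'
#' @param config a [pipeline_config()].
#' @param sim_args list of arguments passed to [simulate_study()].
#' @param outdir optional output directory.
#' @param run_controls logical; include the shuffled-source and
#'   no-adjustment controls.
#' @return list with `cv`, `stepwise`, `controls`, `dynamics`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), sim_args = list(),
                         outdir = NULL, run_controls = TRUE) {
  sim_args$seed <- sim_args$seed %||% config$seed
  study <- do.call(simulate_study, sim_args)
  target_streams <- signal_streams(study$target, streams = config$streams)
  labels <- study$target$trials$class_label
  sources_raw <- lapply(study$sources, function(ep)
    list(streams = signal_streams(ep, streams = config$streams),
         labels = ep$trials$class_label))
  models <- lapply(sources_raw, function(s)
    train_source_model(s$streams, s$labels, config))
  cv <- nested_cv(target_streams, labels, models, config)
  sw <- stepwise_sources(cv)
  controls <- NULL
  if (run_controls) {
    shuf <- control_shuffled_sources(target_streams, labels, sources_raw,
                                     config, seed = config$seed + 41L)
    noadj <- control_no_adjustment(target_streams, labels, models, config)
    controls <- list(shuffled = shuf$balanced_accuracy,
                     no_adjustment = noadj$balanced_accuracy)
  }
  nb <- c(16, 12, 10, 8, 6, 5, 4)
  nb <- nb[length(labels) %% nb == 0][1]
  tot <- time_on_task_summary(cv$score_matrix, labels == "hit",
                              n_blocks = nb)
  result <- list(cv = cv, stepwise = sw, controls = controls,
                 dynamics = tot, config = config)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(cbind(trial = seq_len(nrow(cv$score_matrix)),
                             as.data.frame(cv$score_matrix)),
                       file.path(outdir, "score_matrix.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(sw$table, file.path(outdir, "stepwise.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(tot$block_means, file.path(outdir, "miniblocks.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(tot$slopes, file.path(outdir, "slopes.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    summary <- list(balanced_accuracy = cv$balanced_accuracy,
                    stepwise_by_step = as.list(sw$by_step),
                    controls = controls, seed = config$seed,
                    package_version = as.character(utils::packageVersion("memtransfer")))
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}
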