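#' Task specification for a synthetic behavioral session
#'
#' Builds the design of one of the four session tasks: the visual perception
#' task (4 blocks of 72 color-majority grids), the sustained attention task
#' (4 blocks of 200 conjunctive continuous-performance trials, 30% targets),
#' the selective attention task (4 blocks of 100 spatially cued trials, 75%
#' valid), and the episodic memory encoding task (4 blocks of 60 trials
#' arranged as 16 mini-blocks of 15).
#'
#' @param task_id one of `"perception"`, `"sustained"`, `"selective"`,
#'   `"memory"`.
#' @param n_blocks number of blocks.
#' @param trials_per_block trials per block.
#' @param proportions named numeric vector of condition fractions; must sum
#'   to 1 and yield integer trial counts.
#' @param timing list with `span` (epoch span in ms relative to stimulus
#'   onset, length 2) and `onset` (stimulus onset, ms).
#' @param p_correct fraction of response-eligible trials simulated as
#'   correct (exact count).  Eligibility: all trials (perception), target
#'   trials (sustained), valid trials (selective); ignored for memory.
#' @return an object of class `"task_spec"`.
#' @export
task_spec <- function(task_id = c("perception", "sustained", "selective", "memory"),
                      n_blocks = NULL, trials_per_block = NULL,
                      proportions = NULL, timing = NULL, p_correct = NULL) {
  task_id <- match.arg(task_id)
  def <- .task_defaults(task_id)
  if (is.null(n_blocks)) n_blocks <- def$n_blocks
  if (is.null(trials_per_block)) trials_per_block <- def$trials_per_block
  if (is.null(proportions)) proportions <- def$proportions
  if (is.null(timing)) timing <- def$timing
  if (is.null(p_correct)) p_correct <- def$p_correct
  stopifnot(n_blocks >= 1, trials_per_block >= 1)
  if (abs(sum(proportions) - 1) > 1e-8)
    stop("condition proportions must sum to 1")
  n <- n_blocks * trials_per_block
  counts <- proportions * n
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("proportions do not yield integer trial counts for n = ", n)
  structure(list(task_id = task_id, n_blocks = n_blocks,
                 trials_per_block = trials_per_block,
                 proportions = proportions, timing = timing,
                 p_correct = p_correct),
            class = "task_spec")
}

.task_defaults <- function(task_id) {
  switch(task_id,
    perception = list(n_blocks = 4, trials_per_block = 72,
                      proportions = c(blue = 0.5, red = 0.5),
                      timing = list(span = c(-500, 800), onset = 0),
                      p_correct = 0.8),
    sustained = list(n_blocks = 4, trials_per_block = 200,
                     proportions = c(target = 0.30, red_nonsquare = 0.175,
                                     nonred_square = 0.175, neutral = 0.35),
                     timing = list(span = c(-500, 800), onset = 0),
                     p_correct = 0.95),
    selective = list(n_blocks = 4, trials_per_block = 100,
                     proportions = c(valid = 0.75, invalid = 0.25),
                     timing = list(span = c(-500, 800), onset = 0),
                     p_correct = 0.95),
    memory = list(n_blocks = 4, trials_per_block = 60,
                  proportions = c(hit = 0.6, miss = 0.4),
                  timing = list(span = c(-1000, 1500), onset = 0),
                  p_correct = NA_real_))
}

#' Generate a behavioral trial table for a task
#'
#' Condition counts are deterministic (exact fractions of the total trial
#' count); only the ordering of conditions, response accuracy placement, and
#' reaction times are randomized by `seed`.  For the memory task the
#' condition labels are the eventual retrieval outcomes (`hit`/`miss`) and
#' a `mini_block` column (16 mini-blocks of 15 trials) is added.
#'
#' @param spec a [task_spec()].
#' @param seed integer seed.
#' @return a `data.frame` of class `"trial_table"` with columns
#'   `trial_index`, `block`, (`mini_block`,) `condition`, `rt` (ms, `NA`
#'   where no speeded response exists), `accuracy`, `class_label`.
#' @export
make_task_trials <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "task_spec"))
  n <- spec$n_blocks * spec$trials_per_block
  rng <- .local_rng(seed)
  counts <- round(spec$proportions * n)
  condition <- rng(sample(rep(names(spec$proportions), counts)))
  tab <- data.frame(trial_index = seq_len(n),
                    block = rep(seq_len(spec$n_blocks),
                                each = spec$trials_per_block),
                    condition = condition,
                    rt = NA_real_, accuracy = NA,
                    class_label = "excluded",
                    stringsAsFactors = FALSE)
  if (spec$task_id == "memory") {
    if (spec$trials_per_block %% 15 == 0) {
      tab$mini_block <- rep(seq_len(n %/% 15), each = 15)
      tab <- tab[, c("trial_index", "block", "mini_block", "condition",
                     "rt", "accuracy", "class_label")]
    }
    tab$class_label <- tab$condition
    tab$accuracy <- tab$condition == "hit"
  } else {
    eligible <- switch(spec$task_id,
                       perception = rep(TRUE, n),
                       sustained = tab$condition == "target",
                       selective = tab$condition == "valid")
    n_el <- sum(eligible)
    n_corr <- round(spec$p_correct * n_el)
    acc <- rep(FALSE, n_el)
    acc[rng(sample(n_el, n_corr))] <- TRUE
    tab$accuracy[eligible] <- acc
    # response-eligible trials get a lognormal RT (ms)
    tab$rt[eligible] <- rng(stats::rlnorm(n_el, meanlog = log(400), sdlog = 0.2))
    if (spec$task_id == "perception") {
      tab$class_label <- ifelse(tab$accuracy, "high", "low")
    }
  }
  class(tab) <- c("trial_table", "data.frame")
  attr(tab, "task_id") <- spec$task_id
  tab
}

# Run `expr` under a private RNG stream seeded by `seed`; returns a closure
# so consecutive draws continue the same stream without touching the
# caller's RNG state.
.local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  function(expr) {
    expr <- substitute(expr)
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    })
    eval(expr, envir = parent.frame())
  }
}

#' Generate color-majority grid stimuli for the perception task
#'
#' Each stimulus is a 7 x 7 grid of blue and red circles with 27 circles of
#' the dominant color and 22 of the other.  Across `n_trials` the dominant
#' color is balanced (half majority-blue, half majority-red), mirroring the
#' task design.
#'
#' @param n_trials number of grids to generate.
#' @param seed integer seed.
#' @return a list of 7 x 7 character matrices (`"blue"`/`"red"`), each with
#'   attribute `dominant`.
#' @export
make_perception_grid <- function(n_trials = 1, seed = 1) {
  stopifnot(n_trials >= 1)
  rng <- .local_rng(seed)
  n_blue <- n_trials %/% 2 + (n_trials %% 2)
  dominant <- rng(sample(rep(c("blue", "red"), c(n_blue, n_trials - n_blue))))
  lapply(dominant, function(dom) {
    other <- if (dom == "blue") "red" else "blue"
    cells <- rng(sample(rep(c(dom, other), c(27, 22))))
    g <- matrix(cells, 7, 7)
    attr(g, "dominant") <- dom
    g
  })
}

#' Median-split-style labeling of correct reaction times
#'
#' Assigns `"high"` to the fastest `fraction` and `"low"` to the slowest
#' `fraction` of correct, response-eligible trials; the middle trials and
#' all incorrect or response-ineligible trials are `"excluded"`.  Ties at a
#' cutoff are broken by ascending `trial_index` so the split is
#' deterministic.
#'
#' @param table a `trial_table`.
#' @param fraction fraction labeled per class (default 0.40).
#' @return the table with `class_label` filled in.
#' @export
label_rt_split <- function(table, fraction = 0.40) {
  stopifnot(inherits(table, "data.frame"), fraction > 0, fraction <= 0.5)
  ok <- !is.na(table$rt) & !is.na(table$accuracy) & table$accuracy
  n_corr <- sum(ok)
  if (n_corr < 5)
    stop("fewer than 5 correct trials; high/low classes would be degenerate")
  k <- floor(fraction * n_corr)
  idx <- which(ok)
  ord <- idx[order(table$rt[idx], table$trial_index[idx])]
  table$class_label <- "excluded"
  table$class_label[ord[seq_len(k)]] <- "high"
  table$class_label[ord[seq.int(n_corr - k + 1, n_corr)]] <- "low"
  table
}

#' Latent-state specification for the synthetic EEG generator
#'
#' Controls the planted class structure of the simulated epochs.  Trials are
#' zero-mean multivariate draws whose spatial covariance is a common
#' isotropic background plus a rank-`k` discriminative factor component
#' whose amplitude follows a per-trial latent level: class mean (1 for
#' high/hit, 0 for low/miss) plus a linear drift in trial index plus
#' stationary AR(1) noise.
#'
#' @param n_channels channel count (default 31, the montage size).
#' @param gamma fraction of the rank-`k` discriminative subspace shared
#'   between a source task and the target task, in `[0, 1]`.
#' @param class_gap scale of the factor-variance difference between classes.
#' @param drift_slope per-trial change of the latent level (negative values
#'   emulate a time-on-task decline).
#' @param ar_phi AR(1) coefficient of the latent-state noise, `|ar_phi| < 1`.
#' @param noise_sd standard deviation of the background sensor noise.
#' @param state_sd stationary standard deviation of the AR(1) latent noise.
#' @param k rank of the discriminative factor model.
#' @return an object of class `"latent_spec"`.
#' @export
latent_spec <- function(n_channels = 31, gamma = 0.8, class_gap = 1,
                        drift_slope = 0, ar_phi = 0, noise_sd = 1,
                        state_sd = 0.2, k = 3) {
  stopifnot(n_channels >= 2, gamma >= 0, gamma <= 1, abs(ar_phi) < 1,
            class_gap >= 0, noise_sd > 0, state_sd >= 0, k >= 1,
            k <= n_channels)
  structure(list(n_channels = n_channels, gamma = gamma,
                 class_gap = class_gap, drift_slope = drift_slope,
                 ar_phi = ar_phi, noise_sd = noise_sd, state_sd = state_sd,
                 k = k),
            class = "latent_spec")
}

#' Orthonormal factor loadings for a discriminative subspace
#'
#' @param spec a [latent_spec()].
#' @param seed integer seed.
#' @return `n_channels` x `k` matrix with orthonormal columns.
#' @export
make_loadings <- function(spec, seed = 1) {
  rng <- .local_rng(seed)
  m <- rng(matrix(stats::rnorm(spec$n_channels * spec$k), spec$n_channels))
  qr.Q(qr(m))
}

#' Source-task loadings sharing a fraction of the target subspace
#'
#' Keeps `round(gamma * k)` columns of the target loadings and replaces the
#' rest with random directions orthogonal to the retained ones, so `gamma`
#' is the fraction of discriminative directions shared across tasks.
#'
#' @param target_loadings loadings of the target task ([make_loadings()]).
#' @param gamma shared fraction in `[0, 1]`.
#' @param seed integer seed.
#' @return loadings matrix of the same shape.
#' @export
share_loadings <- function(target_loadings, gamma, seed = 1) {
  k <- ncol(target_loadings)
  n_shared <- round(gamma * k)
  if (n_shared == k) return(target_loadings)
  rng <- .local_rng(seed)
  kept <- target_loadings[, seq_len(n_shared), drop = FALSE]
  m <- rng(matrix(stats::rnorm(nrow(target_loadings) * k), nrow(target_loadings)))
  # replacement directions orthogonal to the whole target subspace, so the
  # shared fraction is exactly n_shared / k
  basis <- qr.Q(qr(cbind(target_loadings, m)))
  cbind(kept, basis[, seq.int(k + 1, 2 * k - n_shared), drop = FALSE])
}

#' Theoretical class covariance of the generator
#'
#' With zero drift and zero latent noise, class-1 (high/hit) trials have
#' covariance `noise_sd^2 I + class_gap B B'` and class-2 trials
#' `noise_sd^2 I`; empirical trial covariances converge to these as the
#' trial count grows.
#'
#' @param spec a [latent_spec()].
#' @param loadings factor loadings.
#' @param class `1` (high/hit) or `2` (low/miss).
#' @return covariance matrix.
#' @export
class_covariance <- function(spec, loadings, class = 1) {
  amp <- if (class == 1) spec$class_gap else 0
  spec$noise_sd^2 * diag(spec$n_channels) + amp * tcrossprod(loadings)
}

#' Simulate multichannel EEG epochs for a trial table
#'
#' Each trial is drawn as `X = noise_sd * Z + sqrt(a_i) * B F` with iid
#' normal `Z` (channels x samples) and `F` (k x samples), so the spatial
#' covariance `noise_sd^2 I + a_i B B'` is positive semi-definite by
#' construction.  The factor amplitude is
#' `a_i = class_gap * max(level_i, 0)` with latent level
#' `level_i = class_mean_i + drift_slope * (i - (n+1)/2) + e_i`, where `e`
#' is stationary AR(1) noise (`ar_phi`, `state_sd`).  Class means are 1 for
#' `high`/`hit` trials, 0 for `low`/`miss`, and 0.5 for `excluded`.
#'
#' @param table a `trial_table`.
#' @param spec a [latent_spec()].
#' @param epoch_span epoch span in ms relative to stimulus onset.
#' @param srate sampling rate in Hz.
#' @param loadings optional loadings matrix (default [make_loadings()] with
#'   `seed`); pass shared loadings to plant cross-task transferability.
#' @param amp_scale global amplitude multiplier applied to the whole epoch
#'   (emulates feature-range shifts between recording contexts).
#' @param seed integer seed.
#' @return an object of class `"epoch_set"`: list with `data` (trials x
#'   channels x samples), `srate`, `t0`, `channels`, `task_id`, `trials`
#'   (the table), and the realized `latent_level` per trial.
#' @export
simulate_epochs <- function(table, spec, epoch_span = c(-1000, 1500),
                            srate = 250, loadings = NULL, amp_scale = 1,
                            seed = 1) {
  stopifnot(inherits(spec, "latent_spec"), srate > 0,
            epoch_span[1] < epoch_span[2])
  n <- nrow(table)
  rng <- .local_rng(seed)
  if (is.null(loadings)) loadings <- make_loadings(spec, seed = seed + 1L)
  stopifnot(nrow(loadings) == spec$n_channels, ncol(loadings) == spec$k)
  n_samp <- round((epoch_span[2] - epoch_span[1]) * srate / 1000)
  cls_mean <- c(high = 1, hit = 1, low = 0, miss = 0, excluded = 0.5)
  base <- unname(cls_mean[table$class_label])
  base[is.na(base)] <- 0.5
  e <- numeric(n)
  if (spec$state_sd > 0) {
    innov <- rng(stats::rnorm(n))
    e[1] <- spec$state_sd * innov[1]
    if (n > 1) {
      sd_in <- spec$state_sd * sqrt(1 - spec$ar_phi^2)
      for (i in 2:n) e[i] <- spec$ar_phi * e[i - 1] + sd_in * innov[i]
    }
  }
  level <- base + spec$drift_slope * (seq_len(n) - (n + 1) / 2) + e
  amp <- spec$class_gap * pmax(level, 0)
  data <- array(0, dim = c(n, spec$n_channels, n_samp))
  for (i in seq_len(n)) {
    z <- rng(matrix(stats::rnorm(spec$n_channels * n_samp), spec$n_channels))
    f <- rng(matrix(stats::rnorm(spec$k * n_samp), spec$k))
    data[i, , ] <- amp_scale * (spec$noise_sd * z +
                                sqrt(amp[i]) * (loadings %*% f))
  }
  structure(list(data = data, srate = srate, t0 = epoch_span[1],
                 channels = paste0("ch", seq_len(spec$n_channels)),
                 task_id = attr(table, "task_id") %||% "unknown",
                 trials = table, latent_level = level),
            class = "epoch_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a full multi-task study
#'
#' Builds trial tables and epochs for the memory target plus the three
#' source tasks, with source discriminative subspaces sharing a fraction
#' `gamma` of the target subspace.  Intended for end-to-end pipeline runs
#' on synthetic data.
#'
#' @param target_spec,source_spec latent specs for the target and source
#'   generators (source spec's `gamma` controls subspace sharing).
#' @param source_specs optional named list of per-task latent specs
#'   overriding `source_spec` (e.g. to make one source informative and the
#'   others pure noise).
#' @param n_target optional override of memory trial count (must be a
#'   multiple of 60 to keep the block structure; `NULL` keeps 240).
#' @param n_source_trials trials per source task actually simulated as
#'   epochs (labeled high/low rows only are used downstream).
#' @param source_tasks character vector of source task ids.
#' @param source_amp_scale amplitude multiplier applied to source epochs.
#' @param seed integer seed.
#' @return list with `target` (epoch_set) and `sources` (named list of
#'   epoch_sets restricted to labeled trials).
#' @export
simulate_study <- function(target_spec = latent_spec(),
                           source_spec = target_spec,
                           n_target = NULL, n_source_trials = 200,
                           source_tasks = c("perception", "sustained", "selective"),
                           source_amp_scale = 1, source_specs = NULL,
                           seed = 1) {
  mem_spec <- task_spec("memory")
  if (!is.null(n_target)) {
    stopifnot(n_target %% mem_spec$n_blocks == 0)
    mem_spec <- task_spec("memory", trials_per_block = n_target %/% mem_spec$n_blocks)
  }
  mem_tab <- make_task_trials(mem_spec, seed = seed)
  B_t <- make_loadings(target_spec, seed = seed + 17L)
  target <- simulate_epochs(mem_tab, target_spec,
                            epoch_span = mem_spec$timing$span,
                            loadings = B_t, seed = seed + 29L)
  sources <- list()
  for (j in seq_along(source_tasks)) {
    tk <- source_tasks[j]
    sp <- task_spec(tk)
    tab <- make_task_trials(sp, seed = seed + 100L * j)
    if (tk %in% c("sustained", "selective")) tab <- label_rt_split(tab)
    lab <- tab[tab$class_label %in% c("high", "low"), , drop = FALSE]
    if (nrow(lab) > n_source_trials) {
      keep <- sort(c(which(lab$class_label == "high")[seq_len(n_source_trials %/% 2)],
                     which(lab$class_label == "low")[seq_len(n_source_trials - n_source_trials %/% 2)]))
      lab <- lab[keep, , drop = FALSE]
    }
    attr(lab, "task_id") <- tk
    sspec <- source_specs[[tk]] %||% source_spec
    B_s <- share_loadings(B_t, sspec$gamma, seed = seed + 100L * j + 1L)
    sources[[tk]] <- simulate_epochs(lab, sspec,
                                     epoch_span = sp$timing$span,
                                     loadings = B_s,
                                     amp_scale = source_amp_scale,
                                     seed = seed + 100L * j + 2L)
  }
  list(target = target, sources = sources)
}

#' Simulate per-trial evidence scores for the dynamics analyses
#'
#' Generates, for `n_subjects` simulated participants, a hit/miss sequence
#' and an evidence-score matrix (trials x source-window columns) with an
#' optional additive shift on trials that follow a hit.  This works at the
#' evidence level (the interface the history analyses consume) so that
#' power and null calibration of the ANOVA can be assessed directly.
#'
#' @param n_subjects number of simulated participants.
#' @param n_trials encoding trials per participant.
#' @param n_sources,n_windows score-matrix geometry.
#' @param p_hit hit probability per trial.
#' @param after_hit_shift additive evidence shift on trials following a hit.
#' @param subject_sd between-subject standard deviation of mean evidence.
#' @param noise_sd trial-level evidence noise standard deviation.
#' @param seed integer seed.
#' @return list of per-subject lists with `scores` (matrix with
#'   `score_<src>[a-b]` column names) and `hits` (logical vector).
#' @export
simulate_evidence_scores <- function(n_subjects = 43, n_trials = 240,
                                     n_sources = 3, n_windows = 14,
                                     p_hit = 0.6, after_hit_shift = 0,
                                     subject_sd = 0.05, noise_sd = 0.1,
                                     seed = 1) {
  rng <- .local_rng(seed)
  srcs <- c("per", "sus", "sel")[seq_len(n_sources)]
  grid <- window_grid()[seq_len(n_windows), , drop = FALSE]
  cols <- unlist(lapply(srcs, function(s)
    sprintf("score_%s[%d-%d]", s, grid[, 1], grid[, 2])))
  lapply(seq_len(n_subjects), function(sj) {
    mu <- 0.5 + rng(stats::rnorm(1, 0, subject_sd))
    hits <- rng(stats::runif(n_trials)) < p_hit
    shift <- c(0, ifelse(hits[-n_trials], after_hit_shift, 0))
    m <- mu + shift +
      matrix(rng(stats::rnorm(n_trials * n_sources * n_windows, 0, noise_sd)),
             n_trials)
    colnames(m) <- cols
    list(scores = m, hits = hits)
  })
}
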