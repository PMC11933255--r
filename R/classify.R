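#' Fisher-score feature filter
#'
#' Ranks features by `(mu1 - mu2)^2 / (s1^2 + s2^2)` and returns the top
#' `k` column indices (descending score, ties broken by lower index).  A
#' feature with zero within-class variance in both classes but distinct
#' means gets score `+Inf` and ranks first.
#'
#' @param features trials x features matrix.
#' @param labels two-class label vector.
#' @param k number of features to keep (default 40).
#' @return integer vector of column indices, length `k`.
#' @export
fisher_filter <- function(features, labels, k = 40) {
  cls <- unique(labels)
  if (length(cls) != 2) stop("exactly two classes required")
  if (k > ncol(features)) stop("k exceeds the number of features")
  x1 <- features[labels == cls[1], , drop = FALSE]
  x2 <- features[labels == cls[2], , drop = FALSE]
  num <- (colMeans(x1) - colMeans(x2))^2
  den <- apply(x1, 2, stats::var) + apply(x2, 2, stats::var)
  score <- ifelse(den > 0, num / den, ifelse(num > 0, Inf, 0))
  order(-score, seq_along(score))[seq_len(k)]
}

#' Gaussian naive Bayes
#'
#' Minimal Gaussian naive Bayes used throughout the pipeline: per-class
#' feature means and variances (floored at `var_floor`) with empirical
#' class priors.  Handles two or more classes.
#'
#' @param x trials x features matrix.
#' @param y label vector.
#' @param var_floor lower bound on per-feature variances.
#' @return object of class `"gnb"`.
#' @export
gnb_fit <- function(x, y, var_floor = 1e-9) {
  x <- as.matrix(x)
  cls <- sort(unique(as.character(y)))
  if (length(cls) < 2) stop("need at least two classes")
  stats_by <- lapply(cls, function(cl) {
    xi <- x[y == cl, , drop = FALSE]
    list(mean = colMeans(xi),
         var = pmax(apply(xi, 2, stats::var), var_floor),
         prior = nrow(xi) / nrow(x))
  })
  names(stats_by) <- cls
  structure(list(classes = cls, stats = stats_by, var_floor = var_floor),
            class = "gnb")
}

#' @describeIn gnb_fit posterior class probabilities (`type = "prob"`,
#'   trials x classes matrix) or hard labels (`type = "class"`).
#' @param object a fitted `"gnb"`.
#' @param type `"prob"` or `"class"`.
#' @param ... unused.
#' @export
predict.gnb <- function(object, x, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  x <- as.matrix(x)
  ll <- vapply(object$classes, function(cl) {
    s <- object$stats[[cl]]
    rowSums(sweep(sweep(x, 2, s$mean)^2, 2, -2 * s$var, "/") -
              rep(0.5 * log(2 * pi * s$var), each = nrow(x))) + log(s$prior)
  }, numeric(nrow(x)))
  ll <- matrix(ll, nrow = nrow(x),
               dimnames = list(NULL, object$classes))
  mx <- apply(ll, 1, max)
  p <- exp(ll - mx)
  p <- p / rowSums(p)
  if (type == "prob") p else object$classes[max.col(p, ties.method = "first")]
}

#' Balanced accuracy
#'
#' Mean of per-class recall; for two classes this is the average of
#' sensitivity and specificity.
#'
#' @param predicted,truth label vectors of equal length.
#' @return fraction in `[0, 1]`.
#' @export
balanced_accuracy <- function(predicted, truth) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  cls <- unique(truth)
  if (length(cls) < 2) stop("truth contains a single class")
  mean(vapply(cls, function(cl)
    mean(predicted[truth == cl] == cl), numeric(1)))
}

#' Stratified fold assignment
#'
#' @param labels label vector.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer fold id per trial (1..k), stratified by class.
#' @export
make_folds <- function(labels, k = 5, seed = 1) {
  rng <- .local_rng(seed)
  folds <- integer(length(labels))
  for (cl in sort(unique(as.character(labels)))) {
    idx <- which(labels == cl)
    idx <- rng(sample(idx))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

# Pooled cross-validated balanced accuracy of a Gaussian NB on the given
# feature columns.
.cv_gnb_ba <- function(x, y, folds) {
  pred <- character(length(y))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2) return(NA_real_)
    fit <- gnb_fit(x[tr, , drop = FALSE], y[tr])
    pred[!tr] <- predict(fit, x[!tr, , drop = FALSE], type = "class")
  }
  balanced_accuracy(pred, y)
}

#' Sequential forward selection (wrapper method)
#'
#' Greedy forward selection over the filtered feature set maximizing
#' inner-cross-validated balanced accuracy of the Gaussian naive Bayes
#' classifier.  Folds are fixed once per call so the path is
#' deterministic; ties are broken by lower feature index.
#'
#' @param features trials x features matrix (typically the Fisher-filtered
#'   top 40).
#' @param labels two-class label vector.
#' @param k number of features to select (default 5).
#' @param inner_folds folds for the wrapped evaluation.
#' @param seed integer seed for the fold assignment.
#' @return integer vector of `k` column indices, in selection order.
#' @export
sfs_select <- function(features, labels, k = 5, inner_folds = 5, seed = 1) {
  if (k > ncol(features)) stop("k exceeds the number of available features")
  if (min(table(labels)) < inner_folds)
    stop("fewer trials per class than inner folds")
  folds <- make_folds(labels, inner_folds, seed)
  selected <- integer(0)
  remaining <- seq_len(ncol(features))
  for (step in seq_len(k)) {
    ba <- vapply(remaining, function(j)
      .cv_gnb_ba(features[, c(selected, j), drop = FALSE], labels, folds),
      numeric(1))
    best <- remaining[which.max(ba)]
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
  }
  selected
}

#' SMOTE class balancing
#'
#' Equalizes binary class counts by adding synthetic minority samples:
#' each synthetic point is a random convex combination of a minority
#' sample and one of its `k_neighbors` nearest minority neighbors
#' (Euclidean distance).
#'
#' @param features trials x features matrix.
#' @param labels two-class label vector.
#' @param k_neighbors neighborhood size (default 5; reduced when the
#'   minority class is smaller).
#' @param seed integer seed.
#' @return list with augmented `features`, `labels` and logical
#'   `synthetic` flags.
#' @export
smote_balance <- function(features, labels, k_neighbors = 5, seed = 1) {
  labels <- as.character(labels)
  tab <- table(labels)
  if (length(tab) != 2) stop("exactly two classes required")
  if (min(tab) < 2) stop("minority class has fewer than 2 trials")
  n_new <- max(tab) - min(tab)
  if (n_new == 0)
    return(list(features = features, labels = labels,
                synthetic = rep(FALSE, length(labels))))
  min_cl <- names(tab)[which.min(tab)]
  mi <- which(labels == min_cl)
  xm <- features[mi, , drop = FALSE]
  kk <- min(k_neighbors, length(mi) - 1)
  d <- as.matrix(stats::dist(xm))
  diag(d) <- Inf
  nb <- apply(d, 1, function(r) order(r)[seq_len(kk)])
  nb <- matrix(nb, nrow = kk)
  rng <- .local_rng(seed)
  base <- rep_len(seq_along(mi), n_new)
  synth <- t(vapply(seq_len(n_new), function(i) {
    b <- base[i]
    nbj <- nb[rng(sample.int(kk, 1)), b]
    u <- rng(stats::runif(1))
    xm[b, ] + u * (xm[nbj, ] - xm[b, ])
  }, numeric(ncol(features))))
  list(features = rbind(features, synth),
       labels = c(labels, rep(min_cl, n_new)),
       synthetic = c(rep(FALSE, length(labels)), rep(TRUE, n_new)))
}

# Full training path on an extracted feature matrix: SMOTE balancing,
# Fisher filter, optional SFS wrapper, Gaussian NB fit.  Returns the
# selected global column indices and the fitted classifier.
.train_classifier <- function(features, labels, config, seed) {
  sm <- smote_balance(features, labels, k_neighbors = config$smote_k,
                      seed = seed)
  fk <- min(config$filter_k, ncol(features))
  filt <- fisher_filter(sm$features, sm$labels, k = fk)
  sk <- min(config$select_k, fk)
  sel <- if (isTRUE(config$use_sfs) && sk < fk) {
    filt[sfs_select(sm$features[, filt, drop = FALSE], sm$labels,
                    k = sk, inner_folds = config$inner_folds,
                    seed = seed + 1L)]
  } else filt[seq_len(sk)]
  fit <- gnb_fit(sm$features[, sel, drop = FALSE], sm$labels)
  list(selected = sel, fit = fit)
}

# Posterior probability of the class-1-aligned label for all trials.
.classifier_scores <- function(clf, features, class1) {
  p <- predict(clf$fit, features[, clf$selected, drop = FALSE], type = "prob")
  p[, class1]
}

#' Train a source-task high/low model
#'
#' Finds the 200-ms source window with the best own-task cross-validated
#' balanced accuracy (fold-wise CSP fitting; Fisher-top features during
#' the search), then stores the per-stream class covariances at that
#' window together with an own-task filter bank and classifier (used by
#' the no-adjustment control and the task-identity classifier).  When a
#' list of stream sets is supplied (multiple participants), a single
#' common window maximizing the mean accuracy is chosen.
#'
#' @param streams a `stream_set` or list of them.
#' @param labels high/low label vector or list matching `streams`.
#' @param config a [pipeline_config()].
#' @param candidate_windows optional window matrix; default: all 200-ms
#'   windows at 100-ms steps within the configured source span.
#' @return object of class `"source_model"`.
#' @export
train_source_model <- function(streams, labels, config = pipeline_config(),
                               candidate_windows = NULL) {
  multi <- !inherits(streams, "stream_set")
  slist <- if (multi) streams else list(streams)
  llist <- if (multi) labels else list(labels)
  if (is.null(candidate_windows))
    candidate_windows <- window_grid(config$source_window_span,
                                     config$window_length, config$window_step)
  if (nrow(candidate_windows) == 0) stop("no candidate source window")
  eval_one <- function(st, lb, window) {
    keep <- which(lb %in% c("high", "low"))
    folds <- make_folds(lb[keep], config$inner_folds, config$seed)
    stack <- stream_window(st, window)
    pred <- character(length(keep))
    for (f in sort(unique(folds))) {
      tr_lab <- lb[keep]
      tr_lab[folds == f] <- NA
      pairs <- stack_covariance_pairs_subset(stack, keep, tr_lab)
      banks <- stream_filter_banks(pairs, m = config$m)
      feats <- csp_features_subset(stack, banks, keep)
      fk <- min(config$filter_k, ncol(feats))
      sk <- min(config$select_k, fk)
      tr <- folds != f
      filt <- fisher_filter(feats[tr, , drop = FALSE], lb[keep][tr], k = fk)
      sel <- filt[seq_len(sk)]
      fit <- gnb_fit(feats[tr, sel, drop = FALSE], lb[keep][tr])
      pred[!tr] <- predict(fit, feats[!tr, sel, drop = FALSE], type = "class")
    }
    balanced_accuracy(pred, lb[keep])
  }
  ba <- vapply(seq_len(nrow(candidate_windows)), function(i) {
    mean(vapply(seq_along(slist), function(j)
      eval_one(slist[[j]], llist[[j]], candidate_windows[i, ]), numeric(1)))
  }, numeric(1))
  best <- which.max(ba)
  window <- candidate_windows[best, ]
  # pool subjects for the stored covariances and own-task classifier
  st1 <- slist[[1]]
  lb <- llist[[1]]
  keep <- which(lb %in% c("high", "low"))
  stack <- stream_window(st1, window)
  pairs <- stack_covariance_pairs_subset(stack, keep, lb[keep])
  own_bank <- stream_filter_banks(pairs, m = config$m)
  own_feats <- csp_features_subset(stack, own_bank, keep)
  own_clf <- .train_classifier(own_feats, lb[keep], config,
                               seed = config$seed + 3L)
  structure(list(task_id = st1$task_id, window = window,
                 window_accuracy = stats::setNames(ba, NULL),
                 pairs = pairs, m = config$m,
                 own_bank = own_bank, own_classifier = own_clf),
            class = "source_model")
}

# Covariance pairs / features restricted to a trial subset of a stack.
stack_covariance_pairs_subset <- function(stack, idx, labels,
                                          class1 = "high", class2 = "low") {
  lapply(stack$streams, function(a)
    class_covariance_pair(a[idx, , , drop = FALSE], labels,
                          class1 = class1, class2 = class2))
}

csp_features_subset <- function(stack, banks, idx) {
  sub <- stack
  sub$streams <- lapply(stack$streams, function(a) {
    out <- a[idx, , , drop = FALSE]
    attr(out, "srate") <- attr(a, "srate")
    out
  })
  csp_features(sub, banks)
}

#' Transfer a source model to one target window
#'
#' Builds RCSP filters from the blended class covariances (source high
#' aligned with target hit, source low with target miss), extracts CSP
#' features for all target trials, trains the selection + SMOTE + naive
#' Bayes path on the training trials only, and returns the posterior
#' probability of the hit-aligned class for every trial.
#'
#' @param model a [train_source_model()] result.
#' @param target_streams the target `stream_set`.
#' @param window target window `[a, b)` ms (same length as the source
#'   window).
#' @param alpha,beta RCSP regularization weights.
#' @param train_idx indices of target trials available for training.
#' @param labels target labels (`"hit"`/`"miss"`); only `train_idx`
#'   entries are consumed for fitting.
#' @param config a [pipeline_config()].
#' @param seed integer seed for SMOTE/selection.
#' @return list with `scores` (posterior per trial, in `[0, 1]`),
#'   `classifier`, `banks`, `alpha`, `beta`.
#' @export
transfer_window_scores <- function(model, target_streams, window,
                                   alpha = 0, beta = 0, train_idx, labels,
                                   config = pipeline_config(), seed = 1) {
  stopifnot(inherits(model, "source_model"),
            inherits(target_streams, "stream_set"))
  if (nrow(model$pairs[[1]]$C1) != length(target_streams$channels))
    stop("source and target montages differ")
  stack <- stream_window(target_streams, window)
  lab_tr <- labels
  lab_tr[setdiff(seq_along(labels), train_idx)] <- NA
  target_pairs <- stack_covariance_pairs(stack, lab_tr,
                                         class1 = "hit", class2 = "miss")
  banks <- stream_filter_banks(target_pairs, source_pairs = model$pairs,
                               alpha = alpha, beta = beta, m = model$m)
  feats <- csp_features(stack, banks)
  clf <- .train_classifier(feats[train_idx, , drop = FALSE],
                           labels[train_idx], config, seed = seed)
  scores <- .classifier_scores(clf, feats, class1 = "hit")
  list(scores = scores, classifier = clf, banks = banks,
       alpha = alpha, beta = beta)
}

# Short source-task tags used in score-matrix column names.
.src_tag <- function(task_id) {
  map <- c(perception = "per", sustained = "sus", selective = "sel")
  if (task_id %in% names(map)) unname(map[task_id])
  else substr(task_id, 1, 3)
}

.score_colnames <- function(sources, grid) {
  unlist(lapply(sources, function(m)
    sprintf("score_%s[%d-%d]", .src_tag(m$task_id), grid[, 1], grid[, 2])))
}

# Fit everything for one outer fold from its training trials alone.
# Deterministic given (streams, labels, sources, config, folds, fold).
.fit_fold <- function(target_streams, labels, sources, config, folds, fold) {
  train_idx <- which(folds != fold)
  test_idx <- which(folds == fold)
  grid <- config$window_grid
  cols <- .score_colnames(sources, grid)
  n <- length(labels)
  scores <- matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols))
  choices <- list()
  col <- 0L
  for (si in seq_along(sources)) {
    model <- sources[[si]]
    for (wi in seq_len(nrow(grid))) {
      col <- col + 1L
      seed_cw <- config$seed + 7919L * fold + 97L * col
      ab <- .select_alpha_beta(model, target_streams, grid[wi, ],
                               train_idx, labels, config, seed_cw)
      tw <- transfer_window_scores(model, target_streams, grid[wi, ],
                                   alpha = ab[1], beta = ab[2],
                                   train_idx = train_idx, labels = labels,
                                   config = config, seed = seed_cw)
      scores[, col] <- tw$scores
      choices[[col]] <- list(source = model$task_id,
                             window = grid[wi, ], alpha = ab[1],
                             beta = ab[2],
                             selected = tw$classifier$selected)
    }
  }
  y01 <- as.integer(labels == "hit")
  int_model <- fit_integration(scores[train_idx, , drop = FALSE],
                               y01[train_idx])
  pred <- predict_memory(scores[test_idx, , drop = FALSE], int_model)
  list(fold = fold, train_idx = train_idx, test_idx = test_idx,
       scores = scores, choices = choices, integration = int_model,
       predictions = pred)
}

# Inner-CV choice of (alpha, beta) for one (source, window) pair: each
# grid point is scored by cross-validated balanced accuracy on the
# training trials using Fisher-top features (the cheap proxy for the full
# selection path); ties take the earlier grid point.
.select_alpha_beta <- function(model, target_streams, window, train_idx,
                               labels, config, seed) {
  combos <- expand.grid(alpha = config$alpha_grid, beta = config$beta_grid,
                        KEEP.OUT.ATTRS = FALSE)
  if (nrow(combos) == 0) stop("empty alpha/beta grid")
  if (nrow(combos) == 1) return(as.numeric(combos[1, ]))
  stack <- stream_window(target_streams, window)
  y <- labels[train_idx]
  folds <- make_folds(y, config$inner_folds, seed)
  ba <- vapply(seq_len(nrow(combos)), function(ci) {
    a <- combos$alpha[ci]; b <- combos$beta[ci]
    pred <- character(length(y))
    for (f in sort(unique(folds))) {
      tr_lab <- y
      tr_lab[folds == f] <- NA
      pairs <- stack_covariance_pairs_subset(stack, train_idx, tr_lab,
                                             class1 = "hit", class2 = "miss")
      banks <- stream_filter_banks(pairs, source_pairs = model$pairs,
                                   alpha = a, beta = b, m = model$m)
      feats <- csp_features_subset(stack, banks, train_idx)
      tr <- folds != f
      fk <- min(config$filter_k, ncol(feats))
      sk <- min(config$select_k, fk)
      sel <- fisher_filter(feats[tr, , drop = FALSE], y[tr], k = fk)[seq_len(sk)]
      fit <- gnb_fit(feats[tr, sel, drop = FALSE], y[tr])
      pred[!tr] <- predict(fit, feats[!tr, sel, drop = FALSE], type = "class")
    }
    balanced_accuracy(pred, y)
  }, numeric(1))
  as.numeric(combos[which.max(ba), ])
}

#' Nested cross-validated multi-source transfer
#'
#' Outer stratified folds hold out one fifth of the target trials; within
#' each outer fold, inner cross-validation on the training trials selects
#' the RCSP weights per (source, window) and the feature subset, evidence
#' scores are produced for every trial, and the score integration is
#' fitted on training trials only.  The returned score matrix holds each
#' trial's scores from the fold in which it was held out, so downstream
#' accuracy is fully held-out.
#'
#' @param target_streams target `stream_set`.
#' @param labels `"hit"`/`"miss"` per target trial.
#' @param sources list of [train_source_model()] results.
#' @param config a [pipeline_config()].
#' @return object of class `"nested_cv_result"`: `score_matrix` (trials x
#'   source-window columns, held-out scores), `folds`, `fold_results`,
#'   `predictions`, `balanced_accuracy`.
#' @export
nested_cv <- function(target_streams, labels, sources,
                      config = pipeline_config()) {
  stopifnot(length(sources) >= 1)
  if (min(table(labels)) < config$outer_folds)
    stop("fewer than one trial per class per outer fold")
  folds <- make_folds(labels, config$outer_folds, config$seed)
  n <- length(labels)
  grid <- config$window_grid
  cols <- .score_colnames(sources, grid)
  score_matrix <- matrix(NA_real_, n, length(cols),
                         dimnames = list(NULL, cols))
  predictions <- character(n)
  fold_results <- vector("list", config$outer_folds)
  for (f in sort(unique(folds))) {
    fr <- .fit_fold(target_streams, labels, sources, config, folds, f)
    score_matrix[fr$test_idx, ] <- fr$scores[fr$test_idx, , drop = FALSE]
    predictions[fr$test_idx] <- as.character(fr$predictions)
    fold_results[[f]] <- fr
  }
  structure(list(score_matrix = score_matrix, folds = folds,
                 fold_results = fold_results, predictions = predictions,
                 labels = labels,
                 balanced_accuracy = balanced_accuracy(predictions, labels)),
            class = "nested_cv_result")
}

#' Refit one outer fold from training data alone
#'
#' Re-derives every fitted quantity of an outer fold (feature ranks, SFS
#' path, SMOTE samples, classifier parameters, alpha/beta choice,
#' integration coefficients) from the training trials; used to audit that
#' no held-out trial influences any training statistic.
#'
#' @inheritParams nested_cv
#' @param folds the fold assignment used by the original run.
#' @param fold the outer fold to refit.
#' @return the same structure as the corresponding `fold_results` entry.
#' @export
refit_fold <- function(target_streams, labels, sources, config, folds, fold) {
  .fit_fold(target_streams, labels, sources, config, folds, fold)
}

#' Three-class task-identity classifier
#'
#' Verifies that the source tasks engage discriminable neural patterns: a
#' multiclass Gaussian naive Bayes on pairwise-CSP features with
#' stratified 5-fold cross-validation (filters fitted per fold on training
#' trials).  Empirical chance is the mean accuracy over label
#' permutations; with `n_permutations = 0` the nominal 1/3 is reported.
#'
#' @param stream_list named list of `stream_set`s, one per task (>= 3).
#' @param n_permutations permutations for the empirical chance level.
#' @param config a [pipeline_config()].
#' @param window analysis window (ms) within the source epochs.
#' @return list with `accuracy`, `chance`, `predictions`, `labels`.
#' @export
task_identity_classifier <- function(stream_list, n_permutations = 0,
                                     config = pipeline_config(),
                                     window = c(0, 200)) {
  if (length(stream_list) < 3) stop("need at least 3 tasks")
  stacks <- lapply(stream_list, stream_window, window = window)
  n_per <- vapply(stacks, function(s) dim(s$streams[[1]])[1], 1L)
  task_lab <- rep(names(stream_list), n_per)
  streams <- names(stacks[[1]]$streams)
  arrs <- lapply(streams, function(s) {
    parts <- lapply(stacks, function(st) st$streams[[s]])
    out <- array(0, dim = c(sum(n_per), dim(parts[[1]])[2], dim(parts[[1]])[3]))
    at <- 0
    for (p in parts) {
      out[at + seq_len(dim(p)[1]), , ] <- p
      at <- at + dim(p)[1]
    }
    out
  })
  names(arrs) <- streams
  run_cv <- function(lab) {
    folds <- make_folds(lab, config$inner_folds, config$seed)
    pred <- character(length(lab))
    tasks <- sort(unique(lab))
    prs <- utils::combn(tasks, 2, simplify = FALSE)
    for (f in sort(unique(folds))) {
      tr <- folds != f
      feats <- do.call(cbind, lapply(streams, function(s) {
        do.call(cbind, lapply(prs, function(pr) {
          lab_tr <- ifelse(tr, lab, NA)
          pair <- class_covariance_pair(arrs[[s]], lab_tr,
                                        class1 = pr[1], class2 = pr[2])
          bank <- csp_filters(pair, m = config$m)
          W <- bank$w[bank$selected_rows, , drop = FALSE]
          t(vapply(seq_along(lab), function(i)
            apply(W %*% matrix(arrs[[s]][i, , ], dim(arrs[[s]])[2]), 1,
                  stats::var),
            numeric(nrow(W))))
        }))
      }))
      fit <- gnb_fit(feats[tr, , drop = FALSE], lab[tr])
      pred[!tr] <- predict(fit, feats[!tr, , drop = FALSE], type = "class")
    }
    mean(pred == lab)
  }
  acc <- run_cv(task_lab)
  chance <- if (n_permutations > 0) {
    rng <- .local_rng(config$seed + 11L)
    mean(vapply(seq_len(n_permutations), function(p)
      run_cv(rng(sample(task_lab))), numeric(1)))
  } else 1 / length(stream_list)
  list(accuracy = acc, chance = chance, n_trials = length(task_lab))
}
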