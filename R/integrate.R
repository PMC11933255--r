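#' Fit the evidence-score integration model
#'
#' Ordinary least squares of the 0/1 memory outcome (hit = 1, miss = 0)
#' on the per-source per-window evidence scores, plus an intercept.  The
#' fitted memory score is compared to the fixed 0.5 threshold by
#' [predict_memory()]; larger absolute coefficients mark the
#' (source, window) combinations most informative for memory success.
#' Rank-deficient designs fall back to the minimum-norm solution with a
#' warning.
#'
#' @param scores trials x columns score matrix (training trials).
#' @param labels numeric 0/1 vector or `"hit"`/`"miss"` labels.
#' @param intercept logical; the default `TRUE` keeps the threshold
#'   calibrated under unequal class priors, `FALSE` fits the pure
#'   weighted-sum form.
#' @return object of class `"integration_model"` with `coef` (intercept
#'   first when present), `columns`, `threshold = 0.5`.
#' @export
fit_integration <- function(scores, labels, intercept = TRUE) {
  scores <- as.matrix(scores)
  y <- if (is.numeric(labels)) labels else as.integer(labels == "hit")
  if (length(unique(y)) < 2) stop("both classes must be present")
  X <- if (intercept) cbind(`(Intercept)` = 1, scores) else scores
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    warning("rank-deficient score design; using the minimum-norm solution")
    sv <- svd(X)
    pos <- sv$d > max(sv$d) * 1e-10
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos])
    beta <- drop(beta)
  } else {
    beta <- drop(qr.coef(qx, y))
  }
  names(beta) <- colnames(X)
  structure(list(coef = beta, columns = colnames(scores),
                 intercept = intercept, threshold = 0.5),
            class = "integration_model")
}

#' Predict hit/miss from integrated evidence scores
#'
#' A trial is labeled `"hit"` when its fitted memory score strictly
#' exceeds 0.5 and `"miss"` otherwise (a score of exactly 0.5 is a miss).
#'
#' @param scores trials x columns score matrix (columns must match the
#'   model).
#' @param model a [fit_integration()] result.
#' @return factor with levels `miss`, `hit`.
#' @export
predict_memory <- function(scores, model) {
  scores <- as.matrix(scores)
  if (!identical(colnames(scores), model$columns))
    stop("score columns do not match the integration model")
  X <- if (model$intercept) cbind(1, scores) else scores
  yhat <- drop(X %*% model$coef)
  factor(ifelse(yhat > model$threshold, "hit", "miss"),
         levels = c("miss", "hit"))
}

#' @describeIn fit_integration fitted memory scores for a score matrix.
#' @export
memory_scores <- function(scores, model) {
  scores <- as.matrix(scores)
  X <- if (model$intercept) cbind(1, scores) else scores
  drop(X %*% model$coef)
}

#' Stepwise source addition
#'
#' Re-runs the score integration restricted to the columns of the sources
#' included so far, for every order in which the sources can be added,
#' reusing the per-fold training scores of a [nested_cv()] run so each
#' step's accuracy stays fully held-out.  Step 3 uses the full column set
#' and is therefore identical across orders.
#'
#' @param cv a `"nested_cv_result"`.
#' @param orders optional list of source-id character vectors; default all
#'   permutations of the sources present in the score matrix.
#' @return list with `table` (data.frame: order, step, source added,
#'   balanced accuracy) and `by_step` (mean accuracy per step across
#'   orders).
#' @export
stepwise_sources <- function(cv, orders = NULL) {
  stopifnot(inherits(cv, "nested_cv_result"))
  cols <- colnames(cv$score_matrix)
  tags <- sub("^score_([a-z]+)\\[.*$", "\\1", cols)
  srcs <- unique(tags)
  if (is.null(orders)) {
    orders <- .permutations(srcs)
  }
  rows <- list()
  for (oi in seq_along(orders)) {
    ord <- orders[[oi]]
    for (step in seq_along(ord)) {
      use <- which(tags %in% ord[seq_len(step)])
      pred <- character(length(cv$labels))
      for (fr in cv$fold_results) {
        m <- fit_integration(fr$scores[fr$train_idx, use, drop = FALSE],
                             as.integer(cv$labels[fr$train_idx] == "hit"))
        pred[fr$test_idx] <- as.character(
          predict_memory(fr$scores[fr$test_idx, use, drop = FALSE], m))
      }
      rows[[length(rows) + 1]] <-
        data.frame(order = paste(ord, collapse = ">"), step = step,
                   added = ord[step],
                   balanced_accuracy = balanced_accuracy(pred, cv$labels))
    }
  }
  table <- do.call(rbind, rows)
  by_step <- tapply(table$balanced_accuracy, table$step, mean)
  list(table = table, by_step = by_step)
}

.permutations <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (p in .permutations(x[-i]))
      out[[length(out) + 1]] <- c(x[i], p)
  out
}

#' Control analysis: shuffled source labels
#'
#' Randomly permutes each source task's high/low labels (class counts
#' preserved), retrains the source models and repeats the full transfer
#' pipeline.  If the source brain states carry information relevant to
#' encoding success, the shuffled run should underperform the intact one.
#'
#' @param target_streams,labels,config as in [nested_cv()].
#' @param sources_raw named list of `list(streams = <stream_set>,
#'   labels = <high/low labels>)` per source task.
#' @param perms optional list of permutations (one per source); by default
#'   drawn from `seed`.  Supplying identity permutations reproduces the
#'   unshuffled pipeline exactly.
#' @param seed integer seed for the label permutations.
#' @param candidate_windows optional fixed source windows (passed to
#'   [train_source_model()]).
#' @return list with `balanced_accuracy`, `cv`, `perms`.
#' @export
control_shuffled_sources <- function(target_streams, labels, sources_raw,
                                     config = pipeline_config(),
                                     perms = NULL, seed = 1,
                                     candidate_windows = NULL) {
  rng <- .local_rng(seed)
  if (is.null(perms))
    perms <- lapply(sources_raw, function(s)
      rng(sample(seq_along(s$labels))))
  models <- lapply(seq_along(sources_raw), function(i) {
    s <- sources_raw[[i]]
    train_source_model(s$streams, s$labels[perms[[i]]], config,
                       candidate_windows = candidate_windows)
  })
  cv <- nested_cv(target_streams, labels, models, config)
  list(balanced_accuracy = cv$balanced_accuracy, cv = cv, perms = perms)
}

#' Control analysis: transfer without target adjustment
#'
#' Applies each trained source model to the target data verbatim: spatial
#' filters come from the source covariances alone (equivalent to
#' `alpha = 1` with no channel penalty), the classifier and its decision
#' boundary are those fitted on the source task's own trials, and no
#' target training data is consumed anywhere.  Per-trial memory scores
#' are the mean posterior across all (source, window) combinations,
#' thresholded at 0.5; target labels are used only to evaluate the
#' resulting balanced accuracy.
#'
#' @param target_streams target `stream_set`.
#' @param labels target labels (evaluation only).
#' @param sources list of [train_source_model()] results.
#' @param config a [pipeline_config()].
#' @return list with `balanced_accuracy`, `alpha = 1`, `scores` (trials x
#'   source-window matrix), `predictions`.
#' @export
control_no_adjustment <- function(target_streams, labels, sources,
                                  config = pipeline_config()) {
  grid <- config$window_grid
  cols <- .score_colnames(sources, grid)
  n <- dim(target_streams$streams[[1]])[1]
  scores <- matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols))
  col <- 0L
  for (model in sources) {
    for (wi in seq_len(nrow(grid))) {
      col <- col + 1L
      stack <- stream_window(target_streams, grid[wi, ])
      feats <- csp_features(stack, model$own_bank)
      scores[, col] <- .classifier_scores(model$own_classifier, feats,
                                          class1 = "high")
    }
  }
  mem <- rowMeans(scores)
  pred <- factor(ifelse(mem > 0.5, "hit", "miss"), levels = c("miss", "hit"))
  list(balanced_accuracy = balanced_accuracy(as.character(pred), labels),
       alpha = 1, scores = scores, predictions = pred)
}
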