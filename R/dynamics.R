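#' Per-trial evidence series averaged over windows
#'
#' Collapses a score matrix to one evidence value per trial and source by
#' averaging across the 14 encoding windows.
#'
#' @param score_matrix trials x `score_<src>[a-b]` matrix.
#' @return trials x sources matrix (columns named by source tag).
#' @export
evidence_series <- function(score_matrix) {
  tags <- sub("^score_([a-z]+)\\[.*$", "\\1", colnames(score_matrix))
  srcs <- unique(tags)
  out <- vapply(srcs, function(s)
    rowMeans(score_matrix[, tags == s, drop = FALSE]), numeric(nrow(score_matrix)))
  colnames(out) <- srcs
  out
}

#' Fill a condition's evidence track over all trial positions
#'
#' The time-on-task analysis needs an evidence value at every trial
#' position for each memory condition, but each position belongs to only
#' one condition (and some are excluded).  Positions without a real value
#' are filled from the nearest preceding real value of that condition
#' (`variant = "previous"`, the default); leading gaps copy the first real
#' value.  The `"next"` variant fills from the nearest following value,
#' and `"mean"` averages the two.
#'
#' @param values numeric vector over trial positions.
#' @param mask logical; `TRUE` where `values` holds a real observation of
#'   this condition.
#' @param variant fill rule.
#' @return list with `values` (filled vector) and `filled` (logical; which
#'   positions were filled).
#' @export
forward_fill_condition <- function(values, mask,
                                   variant = c("previous", "next", "mean")) {
  variant <- match.arg(variant)
  stopifnot(length(values) == length(mask))
  if (!any(mask)) stop("condition has no observed trials")
  n <- length(values)
  real <- which(mask)
  prev_i <- findInterval(seq_len(n), real)          # 0 before first real
  prev <- values[real[pmax(prev_i, 1)]]             # leading gap: first value
  next_i <- findInterval(seq_len(n) - 1L, real) + 1L
  nxt <- values[real[pmin(next_i, length(real))]]   # trailing gap: last value
  filled <- switch(variant,
                   previous = prev,
                   "next" = nxt,
                   mean = (prev + nxt) / 2)
  filled[mask] <- values[mask]
  list(values = filled, filled = !mask)
}

#' Mini-block means of a trial series
#'
#' @param series numeric vector (length divisible by `n_blocks`).
#' @param n_blocks number of mini-blocks (default 16, i.e. blocks of 15
#'   trials for the 240-trial encoding session).
#' @return numeric vector of `n_blocks` means.
#' @export
miniblock_means <- function(series, n_blocks = 16) {
  n <- length(series)
  if (n %% n_blocks != 0)
    stop("series length ", n, " not divisible into ", n_blocks, " mini-blocks")
  colMeans(matrix(series, n %/% n_blocks, n_blocks))
}

#' Time-on-task slope of mini-block evidence
#'
#' Pearson correlation between the mini-block index and the (typically
#' subject-averaged) mean evidence; a negative correlation indicates
#' declining engagement with time on task.
#'
#' @param block_means numeric vector of mini-block means.
#' @return list with `rho` and `p` (`NA` for zero-variance input).
#' @export
time_on_task_slope <- function(block_means) {
  stopifnot(length(block_means) >= 3)
  if (stats::sd(block_means) == 0) return(list(rho = NA_real_, p = NA_real_))
  ct <- stats::cor.test(seq_along(block_means), block_means,
                        method = "pearson")
  list(rho = unname(ct$estimate), p = ct$p.value)
}

# Window-to-chunk assignment for the default 14-window grid: windows
# starting 0-300 ms cover early encoding [0-500], 400-800 ms the middle
# [500-1000], 900-1300 ms the late chunk [1000-1500]; 4 + 5 + 5 = 14.
.chunk_map <- function() {
  list(early = 1:4, middle = 5:9, late = 10:14)
}

#' Early/middle/late chunk means of a score matrix
#'
#' Collapses the 14 windows per source into three encoding chunks (early
#' [0-500 ms], middle [500-1000 ms], late [1000-1500 ms]); a window is
#' assigned to the chunk containing its midpoint.
#'
#' @param score_matrix trials x `score_<src>[a-b]` matrix with 14 windows
#'   per source.
#' @param chunk_map optional named list of window indices per chunk (for
#'   nonstandard grids).
#' @return trials x (source x chunk) matrix with columns `<src>_<chunk>`.
#' @export
history_chunks <- function(score_matrix, chunk_map = NULL) {
  tags <- sub("^score_([a-z]+)\\[.*$", "\\1", colnames(score_matrix))
  srcs <- unique(tags)
  n_w <- sum(tags == srcs[1])
  if (is.null(chunk_map)) {
    if (n_w != 14)
      stop("nonstandard grid (", n_w, " windows); supply chunk_map")
    chunk_map <- .chunk_map()
  }
  out <- do.call(cbind, lapply(srcs, function(s) {
    cols <- which(tags == s)
    vapply(chunk_map, function(w)
      rowMeans(score_matrix[, cols[w], drop = FALSE]),
      numeric(nrow(score_matrix)))
  }))
  colnames(out) <- as.vector(outer(names(chunk_map), srcs,
                                   function(ch, s) paste0(s, "_", ch)))
  out
}

#' Build the encoding-history evidence table
#'
#' For each simulated or decoded participant, groups encoding events by
#' the hit/miss status of the previous (or next) event, collapsing the
#' current events' own outcomes, and averages the chunked evidence per
#' (memory condition, source, time chunk) cell.
#'
#' @param subjects list of per-subject `list(scores, hits)` (e.g. from
#'   [simulate_evidence_scores()], or assembled from [nested_cv()] score
#'   matrices).
#' @param direction `"previous"` groups by the preceding event's outcome,
#'   `"next"` by the following event's.
#' @param chunk_map see [history_chunks()].
#' @return long `data.frame` with columns `subject`, `memory`, `source`,
#'   `time`, `evidence` (one row per cell).
#' @export
history_evidence_table <- function(subjects, direction = c("previous", "next"),
                                   chunk_map = NULL) {
  direction <- match.arg(direction)
  rows <- list()
  for (sj in seq_along(subjects)) {
    sc <- subjects[[sj]]
    ch <- history_chunks(sc$scores, chunk_map)
    n <- length(sc$hits)
    if (direction == "previous") {
      idx <- 2:n
      cond <- ifelse(sc$hits[idx - 1], "after_hit", "after_miss")
    } else {
      idx <- 1:(n - 1)
      cond <- ifelse(sc$hits[idx + 1], "before_hit", "before_miss")
    }
    for (cc in unique(cond)) {
      sub <- ch[idx[cond == cc], , drop = FALSE]
      mu <- colMeans(sub)
      parts <- strsplit(names(mu), "_")
      rows[[length(rows) + 1]] <-
        data.frame(subject = sj, memory = cc,
                   source = vapply(parts, `[`, "", 1),
                   time = vapply(parts, `[`, "", 2),
                   evidence = unname(mu))
    }
  }
  out <- do.call(rbind, rows)
  if (length(unique(out$memory)) < 2) stop("empty memory-condition cell")
  out$memory <- factor(out$memory)
  out$source <- factor(out$source)
  out$time <- factor(out$time, levels = c("early", "middle", "late"))
  out
}

#' Memory x Source x Time repeated-measures ANOVA
#'
#' Within-subject ANOVA of the chunked evidence with subjects as the
#' error stratum: each effect is tested against its own
#' subject-by-effect interaction stratum
#' (`Error(subject/(memory*source*time))`).  Partial eta squared is
#' `SS_effect / (SS_effect + SS_error)` within the effect's stratum.
#'
#' @param data a [history_evidence_table()] data.frame.
#' @return data.frame with `effect`, `df1`, `df2`, `F`, `p`, `pes`.
#' @export
history_anova <- function(data) {
  stopifnot(all(c("subject", "memory", "source", "time", "evidence")
                %in% names(data)))
  if (any(table(data$memory, data$source, data$time) == 0))
    stop("empty design cell")
  data$subject <- factor(data$subject)
  fit <- stats::aov(evidence ~ memory * source * time +
                      Error(subject / (memory * source * time)),
                    data = data)
  sm <- summary(fit)
  rows <- list()
  for (stratum in sm) {
    tab <- stratum[[1]]
    terms <- trimws(rownames(tab))
    resid <- which(terms == "Residuals")
    if (length(resid) == 0) next
    for (i in setdiff(seq_along(terms), resid)) {
      rows[[length(rows) + 1]] <- data.frame(
        effect = terms[i],
        df1 = tab$Df[i], df2 = tab$Df[resid],
        F = tab$`F value`[i], p = tab$`Pr(>F)`[i],
        pes = tab$`Sum Sq`[i] / (tab$`Sum Sq`[i] + tab$`Sum Sq`[resid]))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Holm-Bonferroni multiple-comparison correction
#'
#' Standard step-down adjustment (via [stats::p.adjust()]) with rejection
#' decisions at level `alpha`.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param alpha family-wise error level.
#' @return list with `adjusted` p-values and logical `reject`.
#' @export
holm_bonferroni <- function(p, alpha = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p, method = "holm")
  list(adjusted = adj, reject = adj <= alpha)
}

#' Time-on-task summary for a decoded session
#'
#' Builds, per source and memory condition, the condition-filled evidence
#' series, its 16 mini-block means, and the Pearson slope statistics,
#' plus the hit-minus-miss difference slope.
#'
#' @param score_matrix held-out score matrix of a [nested_cv()] run.
#' @param hits logical vector (`TRUE` = hit) per trial.
#' @param n_blocks mini-block count.
#' @param variant fill rule, see [forward_fill_condition()].
#' @return list with `block_means` (data.frame: source, condition, block,
#'   mean) and `slopes` (data.frame: source, condition, rho, p; condition
#'   `"difference"` is the hit-minus-miss series).
#' @export
time_on_task_summary <- function(score_matrix, hits, n_blocks = 16,
                                 variant = "previous") {
  ev <- evidence_series(score_matrix)
  bm_rows <- list(); sl_rows <- list()
  for (s in colnames(ev)) {
    tracks <- list(hit = forward_fill_condition(ev[, s], hits, variant)$values,
                   miss = forward_fill_condition(ev[, s], !hits, variant)$values)
    means <- lapply(tracks, miniblock_means, n_blocks = n_blocks)
    means$difference <- means$hit - means$miss
    for (cond in names(means)) {
      sl <- time_on_task_slope(means[[cond]])
      sl_rows[[length(sl_rows) + 1]] <-
        data.frame(source = s, condition = cond, rho = sl$rho, p = sl$p)
      if (cond != "difference")
        bm_rows[[length(bm_rows) + 1]] <-
          data.frame(source = s, condition = cond,
                     block = seq_len(n_blocks), mean = means[[cond]])
    }
  }
  list(block_means = do.call(rbind, bm_rows),
       slopes = do.call(rbind, sl_rows))
}
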