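#' Trace-normalized trial covariance
#'
#' `C = X X' / trace(X X')` for one trial's channels-by-samples matrix, so
#' every trial contributes a unit-trace, symmetric, PSD covariance
#' regardless of its overall amplitude.
#'
#' @param X channels x samples matrix.
#' @return symmetric matrix with trace exactly 1.
#' @export
trial_covariance <- function(X) {
  stopifnot(is.matrix(X), ncol(X) >= 2)
  cc <- tcrossprod(X)
  tr <- sum(diag(cc))
  if (tr <= 0) stop("all-zero trial: covariance trace is 0")
  cc <- cc / tr
  (cc + t(cc)) / 2
}

#' Class-averaged covariance pair for one stream
#'
#' Averages trace-normalized trial covariances within each class.
#'
#' @param x trials x channels x samples array (one stream).
#' @param labels per-trial labels; `class1`/`class2` name the two classes
#'   (class 1 is the high/hit-aligned class whose variance the top filters
#'   maximize).
#' @param class1,class2 label values of the two classes.
#' @return object of class `"cov_pair"`: list `C1`, `C2`, `n1`, `n2`.
#' @export
class_covariance_pair <- function(x, labels, class1 = "high", class2 = "low") {
  i1 <- which(labels == class1)
  i2 <- which(labels == class2)
  if (length(i1) == 0 || length(i2) == 0)
    stop("both classes must be present")
  avg <- function(idx) {
    s <- 0
    for (i in idx) s <- s + trial_covariance(matrix(x[i, , ], dim(x)[2]))
    s / length(idx)
  }
  structure(list(C1 = avg(i1), C2 = avg(i2),
                 n1 = length(i1), n2 = length(i2)),
            class = "cov_pair")
}

# Generalized symmetric eigenproblem A w = lambda B w via whitening of B.
# Returns filters as rows (descending eigenvalue) plus the eigenvalues.
# B gets a small ridge when ill-conditioned.
.geneig <- function(A, B, ridge = 1e-8) {
  stopifnot(nrow(A) == nrow(B))
  if (max(abs(A - t(A))) > 1e-8 * max(1, max(abs(A))) ||
      max(abs(B - t(B))) > 1e-8 * max(1, max(abs(B))))
    stop("covariance inputs must be symmetric")
  A <- (A + t(A)) / 2
  B <- (B + t(B)) / 2
  eb <- eigen(B, symmetric = TRUE)
  if (min(eb$values) <= max(eb$values) / 1e10) {
    B <- B + ridge * diag(nrow(B))
    eb <- eigen(B, symmetric = TRUE)
  }
  P <- diag(1 / sqrt(eb$values), nrow(B)) %*% t(eb$vectors)
  S <- P %*% A %*% t(P)
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  W <- t(es$vectors) %*% P
  # sign convention: largest-magnitude entry of each filter is positive
  for (i in seq_len(nrow(W))) {
    j <- which.max(abs(W[i, ]))
    if (W[i, j] < 0) W[i, ] <- -W[i, ]
  }
  list(w = W, values = es$values)
}

.filter_bank <- function(w, values, m, alpha, beta, D1 = NULL, D31 = NULL,
                         selected_rows = NULL) {
  ch <- ncol(w)
  if (is.null(selected_rows)) {
    stopifnot(2 * m <= ch)
    selected_rows <- c(seq_len(m), seq.int(ch - m + 1, ch))
  }
  structure(list(w = w, eigenvalues = values, m = m,
                 selected_rows = selected_rows,
                 alpha = alpha, beta = beta, D1 = D1, D31 = D31),
            class = "filter_bank")
}

#' Common Spatial Patterns filters
#'
#' Solves the CSP objective `max_w (w' C1 w) / (w' C2 w)` as a generalized
#' eigenproblem.  Filter rows are ordered by descending generalized
#' eigenvalue: the first row maximizes class-1 relative variance, the last
#' maximizes class-2 relative variance.
#'
#' @param pair a [class_covariance_pair()].
#' @param m filter pairs to select per stream (first `m` and last `m` rows;
#'   default 15 on a 31-channel montage).
#' @return object of class `"filter_bank"`.
#' @export
csp_filters <- function(pair, m = 15) {
  stopifnot(inherits(pair, "cov_pair"))
  g <- .geneig(pair$C1, pair$C2)
  .filter_bank(g$w, g$values, m = min(m, floor(ncol(g$w) / 2)),
               alpha = 0, beta = 0)
}

#' Blend source and target class covariances
#'
#' Convex combination `alpha * Cs + (1 - alpha) * Ct`; with unit-trace
#' inputs the result keeps trace 1.
#'
#' @param Cs,Ct source and target covariance matrices.
#' @param alpha blend weight in `[0, 1]` (`0` = target only, `1` = source
#'   only).
#' @return blended covariance.
#' @export
blend_covariances <- function(Cs, Ct, alpha) {
  stopifnot(alpha >= 0, alpha <= 1)
  if (!all(dim(Cs) == dim(Ct))) stop("covariance shape mismatch")
  alpha * Cs + (1 - alpha) * Ct
}

#' Regularized CSP filters for source-to-target transfer
#'
#' Blends the source- and target-task class covariances with weight `alpha`
#' and penalizes channels with weight `beta` through diagonal matrices
#' built from the most discriminative unpenalized filters.  Because the
#' penalty matrices are defined in terms of the solution's own extreme
#' filters, a two-pass scheme is used: pass 1 solves plain CSP on the
#' blended covariances to obtain an initial filter matrix; its first and
#' last rows define `D1` and `D31` (diagonal entries: inverse squared
#' filter weights, entries clipped to machine epsilon in magnitude before
#' inversion).  Pass 2 then solves
#' `max_w (w' C1reg w) / (w' C2reg w + beta w' D1 w)` keeping the top `m`
#' eigenvectors, and the analogous `D31` problem keeping the bottom `m`.
#' With `alpha = 0` and `beta = 0` this reduces exactly to target-only CSP.
#'
#' @param source,target [class_covariance_pair()]s on the same channel set.
#' @param alpha covariance blend weight in `[0, 1]`.
#' @param beta channel-penalty weight, `>= 0`.
#' @param m filter pairs to keep.
#' @return a `"filter_bank"` whose `w` holds the `2m` selected filters
#'   (rows 1..m from the `D1` problem, rows m+1..2m from the `D31`
#'   problem's bottom eigenvectors).
#' @export
rcsp_filters <- function(source, target, alpha = 0, beta = 0, m = 15) {
  stopifnot(inherits(source, "cov_pair"), inherits(target, "cov_pair"),
            beta >= 0)
  if (!all(dim(source$C1) == dim(target$C1)))
    stop("source and target channel sets differ")
  ch <- nrow(target$C1)
  m <- min(m, floor(ch / 2))
  R1 <- blend_covariances(source$C1, target$C1, alpha)
  R2 <- blend_covariances(source$C2, target$C2, alpha)
  pass1 <- .geneig(R1, R2)
  clip <- function(v) {
    s <- ifelse(v == 0, .Machine$double.eps, v)
    sign(s) * pmax(abs(s), .Machine$double.eps)
  }
  d1 <- 1 / clip(pass1$w[1, ])^2
  d31 <- 1 / clip(pass1$w[ch, ])^2
  D1 <- diag(d1, ch)
  D31 <- diag(d31, ch)
  top <- .geneig(R1, R2 + beta * D1)
  bot <- .geneig(R1, R2 + beta * D31)
  w <- rbind(top$w[seq_len(m), , drop = FALSE],
             bot$w[seq.int(ch - m + 1, ch), , drop = FALSE])
  values <- c(top$values[seq_len(m)], bot$values[seq.int(ch - m + 1, ch)])
  .filter_bank(w, values, m = m, alpha = alpha, beta = beta,
               D1 = D1, D31 = D31, selected_rows = seq_len(2 * m))
}

#' Per-stream RCSP (or CSP) filter banks for a signal stack
#'
#' @param source_pairs,target_pairs named lists of [class_covariance_pair()]
#'   per stream; pass `source_pairs = NULL` for plain target-only CSP.
#' @param alpha,beta,m see [rcsp_filters()].
#' @return named list of `filter_bank` objects.
#' @export
stream_filter_banks <- function(target_pairs, source_pairs = NULL,
                                alpha = 0, beta = 0, m = 15) {
  lapply(stats::setNames(names(target_pairs), names(target_pairs)),
         function(s) {
    if (is.null(source_pairs)) csp_filters(target_pairs[[s]], m = m)
    else rcsp_filters(source_pairs[[s]], target_pairs[[s]],
                      alpha = alpha, beta = beta, m = m)
  })
}

#' Class covariance pairs for every stream of a windowed stack
#'
#' @param stack a `signal_stack`.
#' @param labels per-trial labels (length = trial count of the stack).
#' @param class1,class2 see [class_covariance_pair()].
#' @return named list of `cov_pair` per stream.
#' @export
stack_covariance_pairs <- function(stack, labels, class1 = "high",
                                   class2 = "low") {
  stopifnot(inherits(stack, "signal_stack"))
  lapply(stack$streams, class_covariance_pair, labels = labels,
         class1 = class1, class2 = class2)
}

#' CSP feature extraction
#'
#' Projects each trial of each stream through the selected spatial filters
#' and takes the variance of every projected time series; features are
#' concatenated across streams in stack order (voltage, theta, alpha,
#' beta, gamma by default).  The default configuration (5 streams, 15
#' filter pairs on 31 channels) yields 150 features per trial.
#'
#' @param stack a `signal_stack`.
#' @param banks named list of `filter_bank` per stream (same names as the
#'   stack's streams).
#' @return trials x features numeric matrix.
#' @export
csp_features <- function(stack, banks) {
  stopifnot(inherits(stack, "signal_stack"),
            identical(names(stack$streams), names(banks)))
  feats <- lapply(names(stack$streams), function(s) {
    a <- stack$streams[[s]]
    bank <- banks[[s]]
    if (length(bank$selected_rows) == 0) stop("empty filter selection")
    W <- bank$w[bank$selected_rows, , drop = FALSE]
    n_tr <- dim(a)[1]
    out <- matrix(0, n_tr, nrow(W))
    for (i in seq_len(n_tr)) {
      y <- W %*% matrix(a[i, , ], dim(a)[2])
      out[i, ] <- apply(y, 1, stats::var)
    }
    colnames(out) <- paste0(s, "_f", seq_len(nrow(W)))
    out
  })
  do.call(cbind, feats)
}
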