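test_that("trial covariance is trace-normalized and matches hand computation", {
  expect_equal(trial_covariance(diag(2)), diag(0.5, 2))
  X <- rbind(c(1, 1), c(2, 2))
  expect_equal(trial_covariance(X),
               rbind(c(0.2, 0.4), c(0.4, 0.8)))
  set.seed(1)
  Y <- matrix(rnorm(40), 4)
  expect_equal(sum(diag(trial_covariance(Y))), 1)
  expect_error(trial_covariance(matrix(0, 3, 10)), "all-zero")
})

test_that("CSP on diagonal covariances recovers the analytic filters", {
  pair <- structure(list(C1 = diag(c(4, 1)) / 5, C2 = diag(c(1, 4)) / 5,
                         n1 = 10, n2 = 10), class = "cov_pair")
  bank <- csp_filters(pair, m = 1)
  w1 <- bank$w[1, ] / max(abs(bank$w[1, ]))
  w2 <- bank$w[2, ] / max(abs(bank$w[2, ]))
  expect_equal(abs(w1), c(1, 0), tolerance = 1e-10)
  expect_equal(abs(w2), c(0, 1), tolerance = 1e-10)
  expect_equal(bank$eigenvalues, c(4, 1 / 4), tolerance = 1e-10)

  # degenerate: identical class covariances give unit eigenvalues
  same <- structure(list(C1 = random_psd(3, 5), C2 = random_psd(3, 5),
                         n1 = 5, n2 = 5), class = "cov_pair")
  expect_equal(csp_filters(same)$eigenvalues, rep(1, 3), tolerance = 1e-8)
})

test_that("CSP top filter attains the brute-force Rayleigh-quotient optimum", {
  quotient <- function(w, C1, C2) drop((w %*% C1 %*% w) / (w %*% C2 %*% w))
  for (s in 1:5) {
    C1 <- random_psd(4, 100 + s)
    C2 <- random_psd(4, 200 + s)
    pair <- structure(list(C1 = C1, C2 = C2, n1 = 8, n2 = 8),
                      class = "cov_pair")
    bank <- csp_filters(pair, m = 2)
    top <- quotient(bank$w[1, ], C1, C2)
    # brute force: many random unit starts, polished with BFGS
    set.seed(s)
    best <- -Inf
    for (r in 1:200) {
      w0 <- rnorm(4)
      best <- max(best, quotient(w0 / sqrt(sum(w0^2)), C1, C2))
    }
    opt <- stats::optim(rnorm(4), function(w) -quotient(w, C1, C2),
                        method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    best <- max(best, -opt$value)
    expect_lt(abs(top - best) / best, 1e-9)
    # no random vector beats the eigensolver
    expect_gte(top + 1e-9, best)
  }
})

test_that("covariance blending is a convex combination preserving trace", {
  Cs <- diag(c(1, 0))
  Ct <- diag(c(0, 1))
  expect_equal(blend_covariances(Cs, Ct, 0), Ct)
  expect_equal(blend_covariances(Cs, Ct, 1), Cs)
  expect_equal(blend_covariances(Cs, Ct, 0.5), diag(0.5, 2))
  A <- random_psd(3, 1); B <- random_psd(3, 2)
  expect_equal(sum(diag(blend_covariances(A, B, 0.3))), 1)
  expect_error(blend_covariances(A, diag(2) / 2, 0.5), "shape")
})

test_that("RCSP with alpha = beta = 0 reduces to target-only CSP", {
  src <- structure(list(C1 = random_psd(5, 11), C2 = random_psd(5, 12),
                        n1 = 10, n2 = 10), class = "cov_pair")
  tgt <- structure(list(C1 = random_psd(5, 13), C2 = random_psd(5, 14),
                        n1 = 10, n2 = 10), class = "cov_pair")
  r <- rcsp_filters(src, tgt, alpha = 0, beta = 0, m = 2)
  c0 <- csp_filters(tgt, m = 2)
  sel <- c0$w[c0$selected_rows, ]
  # same filters up to sign/scale: normalized absolute cosine similarity 1
  for (i in 1:4) {
    a <- r$w[i, ] / sqrt(sum(r$w[i, ]^2))
    b <- sel[i, ] / sqrt(sum(sel[i, ]^2))
    expect_equal(abs(sum(a * b)), 1, tolerance = 1e-8)
  }
})

test_that("the channel penalty drives penalized channels toward zero weight", {
  # solver-level property: a diagonal penalty loading heavily on channel 3
  # forces the top filter's channel-3 entry toward 0 as beta grows
  C1 <- random_psd(3, 21); C2 <- random_psd(3, 22)
  D <- diag(c(1e-6, 1e-6, 1))
  g <- memtransfer:::.geneig(C1, C2 + 1e6 * D)
  w <- g$w[1, ] / sqrt(sum(g$w[1, ]^2))
  expect_lt(abs(w[3]), 1e-2)

  # two-pass construction: D1/D31 diagonals are the inverse squared
  # entries of the pass-1 extreme filters on the blended covariances
  src <- structure(list(C1 = random_psd(3, 23), C2 = random_psd(3, 24),
                        n1 = 10, n2 = 10), class = "cov_pair")
  tgt <- structure(list(C1 = random_psd(3, 25), C2 = random_psd(3, 26),
                        n1 = 10, n2 = 10), class = "cov_pair")
  alpha <- 0.5
  pass1 <- memtransfer:::.geneig(blend_covariances(src$C1, tgt$C1, alpha),
                                 blend_covariances(src$C2, tgt$C2, alpha))
  r <- rcsp_filters(src, tgt, alpha = alpha, beta = 0.1, m = 1)
  expect_equal(diag(r$D1), 1 / pass1$w[1, ]^2)
  expect_equal(diag(r$D31), 1 / pass1$w[3, ]^2)
})

test_that("filter ordering, class swap, and channel permutation invariants hold", {
  C1 <- random_psd(6, 31); C2 <- random_psd(6, 32)
  pair <- structure(list(C1 = C1, C2 = C2, n1 = 9, n2 = 9),
                    class = "cov_pair")
  bank <- csp_filters(pair, m = 3)
  expect_true(all(diff(bank$eigenvalues) <= 1e-10))
  # class swap inverts the eigenvalues (reversed order)
  swap <- structure(list(C1 = C2, C2 = C1, n1 = 9, n2 = 9),
                    class = "cov_pair")
  expect_equal(csp_filters(swap, m = 3)$eigenvalues,
               rev(1 / bank$eigenvalues), tolerance = 1e-8)
  # channel permutation permutes filter entries
  p <- c(3, 1, 6, 2, 5, 4)
  pp <- structure(list(C1 = C1[p, p], C2 = C2[p, p], n1 = 9, n2 = 9),
                  class = "cov_pair")
  bp <- csp_filters(pp, m = 3)
  expect_equal(abs(bp$w[1, ]), abs(bank$w[1, p]), tolerance = 1e-8)

  expect_error(memtransfer:::.geneig(matrix(1:9, 3), diag(3)), "symmetric")
})

test_that("CSP features are projected-series variances; defaults give 150", {
  spec <- latent_spec(n_channels = 4, class_gap = 1, k = 1)
  tab <- data.frame(trial_index = 1:20, block = 1, condition = rep(c("hit", "miss"), 10),
                    rt = NA, accuracy = TRUE,
                    class_label = rep(c("hit", "miss"), 10))
  ep <- simulate_epochs(tab, spec, epoch_span = c(0, 400), seed = 2)
  st <- signal_streams(ep, streams = "voltage")
  stk <- stream_window(st, c(0, 200))
  pairs <- stack_covariance_pairs(stk, tab$class_label, "hit", "miss")
  banks <- stream_filter_banks(pairs, m = 2)
  f <- csp_features(stk, banks)
  expect_equal(dim(f), c(20, 4))
  # brute-force recomputation for one trial/row
  W <- banks$voltage$w[banks$voltage$selected_rows, ]
  x <- matrix(stk$streams$voltage[7, , ], 4)
  expect_equal(unname(f[7, ]), apply(W %*% x, 1, var))
  # identity bank on white noise: variances approximate channel variances
  ib <- banks
  ib$voltage$w <- diag(4)
  ib$voltage$selected_rows <- 1:4
  fi <- csp_features(stk, ib)
  expect_equal(unname(fi[7, ]), apply(x, 1, var))
  ib$voltage$selected_rows <- integer(0)
  expect_error(csp_features(stk, ib), "empty filter selection")
})
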