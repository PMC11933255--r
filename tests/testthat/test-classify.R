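test_that("Fisher scores match the formula; ranking and ties behave", {
  # feature with mu1 = 1, mu2 = 0, var1 = var2 = 0.5 has score 1.0
  x1 <- c(0, 1, 2); x2 <- c(-1, 0, 1)       # means 1, 0; vars 1, 1 -> 0.5
  x1 <- c(1 - sqrt(0.5), 1, 1 + sqrt(0.5))  # var = 0.5
  x2 <- c(-sqrt(0.5), 0, sqrt(0.5))
  feats <- cbind(f1 = c(x1, x2),
                 f2 = rep(c(5, 5), each = 3),      # identical means: score 0
                 f3 = c(x1, x2) * 2)
  labels <- rep(c("a", "b"), each = 3)
  sc_num <- (mean(x1) - mean(x2))^2 / (var(x1) + var(x2))
  expect_equal(sc_num, 1.0)
  idx <- fisher_filter(feats, labels, k = 3)
  expect_equal(idx[3], 2)                    # zero-score feature ranks last
  expect_equal(sort(idx[1:2]), c(1, 3))
  # zero variance in both classes with distinct means ranks first
  feats2 <- cbind(feats, f4 = rep(c(0, 1), each = 3))
  expect_equal(fisher_filter(feats2, labels, k = 1), 4)
  # k = 40 out of 150 returns exactly 40 indices
  set.seed(1)
  big <- matrix(rnorm(40 * 150), 40)
  expect_length(fisher_filter(big, rep(c("a", "b"), 20), k = 40), 40)
})

test_that("Gaussian naive Bayes matches the independent reference", {
  skip_if_not_installed("e1071")
  set.seed(3)
  x <- matrix(rnorm(60 * 4), 60)
  y <- rep(c("a", "b"), 30)
  x[y == "a", 1] <- x[y == "a", 1] + 1
  fit <- gnb_fit(x, y)
  ref <- e1071::naiveBayes(data.frame(x), factor(y))
  p_ours <- predict(fit, x, type = "prob")
  p_ref <- predict(ref, data.frame(x), type = "raw")
  expect_equal(unname(p_ours), unname(p_ref), tolerance = 1e-6)
})

test_that("balanced accuracy is the mean of sensitivity and specificity", {
  truth <- rep(c("hit", "miss"), c(10, 10))
  pred <- c(rep("hit", 8), rep("miss", 2), rep("hit", 4), rep("miss", 6))
  expect_equal(balanced_accuracy(pred, truth), (0.8 + 0.6) / 2)
  expect_equal(balanced_accuracy(truth, truth), 1)
  expect_equal(balanced_accuracy(rep("hit", 20), truth), 0.5)
  expect_error(balanced_accuracy(pred, rep("hit", 20)), "single class")
})

test_that("stratified folds partition trials and balance classes", {
  y <- rep(c("hit", "miss"), c(60, 40))
  f <- make_folds(y, 5, seed = 2)
  expect_equal(sort(unique(f)), 1:5)
  expect_equal(as.integer(table(f)), rep(20L, 5))
  expect_true(all(table(f, y)[, "hit"] == 12))
  expect_identical(make_folds(y, 5, seed = 2), f)
})

test_that("SFS selects a perfectly separating feature first", {
  set.seed(5)
  n <- 20
  y <- rep(c("a", "b"), each = n / 2)
  x <- matrix(rnorm(n * 6), n)
  x[, 4] <- ifelse(y == "a", 1, -1) + rnorm(n, 0, 0.01)
  sel <- sfs_select(x, y, k = 3, inner_folds = 5, seed = 1)
  expect_equal(sel[1], 4)
  expect_length(sel, 3)
  # k = n_available returns the full set
  expect_setequal(sfs_select(x, y, k = 6, inner_folds = 5, seed = 1), 1:6)
  expect_error(sfs_select(x, y, k = 7), "exceeds")
})

test_that("SMOTE balances classes with interpolated minority samples", {
  set.seed(8)
  x <- matrix(rnorm(100 * 3), 100)
  y <- rep(c("hit", "miss"), c(60, 40))
  out <- smote_balance(x, y, seed = 4)
  expect_equal(as.integer(table(out$labels)), c(60L, 60L))
  expect_equal(sum(out$synthetic), 20)
  # each synthetic point lies on a segment between two minority samples
  xm <- x[y == "miss", ]
  seg_dist <- function(s, a, b) {
    t <- sum((s - a) * (b - a)) / sum((b - a)^2)
    t <- min(max(t, 0), 1)
    sqrt(sum((s - (a + t * (b - a)))^2))
  }
  prs <- utils::combn(nrow(xm), 2)
  for (i in which(out$synthetic)) {
    s <- out$features[i, ]
    dmin <- min(apply(prs, 2, function(pr)
      seg_dist(s, xm[pr[1], ], xm[pr[2], ])))
    expect_lt(dmin, 1e-8)
  }
  # already balanced input returned unchanged
  out2 <- smote_balance(x[1:80, ], rep(c("hit", "miss"), 40), seed = 1)
  expect_identical(out2$features, x[1:80, ])
  expect_error(smote_balance(x[1:3, ], c("a", "a", "b")), "fewer than 2")
})

test_that("SMOTE-balanced training makes balanced accuracy equal accuracy on balanced tests", {
  set.seed(11)
  x <- matrix(rnorm(80 * 3), 80)
  y <- rep(c("hit", "miss"), 40)
  x[y == "hit", 1] <- x[y == "hit", 1] + 1.5
  fit <- gnb_fit(x, y)
  pred <- predict(fit, x, type = "class")
  expect_equal(balanced_accuracy(pred, y), mean(pred == y))
})

test_that("source-model training picks the window holding the signal", {
  # plant the discriminative signal only inside [200, 400) ms by zeroing
  # the factor component elsewhere
  cfg <- light_config(seed = 6)
  hits <- 0
  for (seed in 1:5) {
    spec <- latent_spec(n_channels = 8, class_gap = 2, k = 2)
    tab <- data.frame(trial_index = 1:120, block = 1,
                      condition = rep(c("high", "low"), 60), rt = NA,
                      accuracy = TRUE,
                      class_label = rep(c("high", "low"), 60))
    ep <- simulate_epochs(tab, spec, epoch_span = c(-500, 800), seed = seed)
    flat <- simulate_epochs(transform(tab, class_label = "low"), spec,
                            epoch_span = c(-500, 800), seed = seed + 500)
    idx <- memtransfer:::.window_idx(-500, 250, dim(ep$data)[3], c(200, 400))
    mix <- flat
    mix$data[, , idx] <- ep$data[, , idx]
    mix$trials <- tab
    st <- signal_streams(mix, streams = "voltage")
    model <- train_source_model(st, tab$class_label, cfg)
    if (model$window[1] == 200) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("nested CV is deterministic, partitions trials, and nulls out under shuffling", {
  cfg <- light_config(seed = 9, alpha_grid = 0.5)
  study <- light_study(seed = 9, n_channels = 8, n_target = 80,
                       n_source_trials = 100, source_tasks = "perception")
  tst <- as_streams(study$target)
  labels <- study$target$trials$class_label
  src <- raw_sources(study)[[1]]
  model <- train_source_model(src$streams, src$labels, cfg)
  cv1 <- nested_cv(tst, labels, list(model), cfg)
  cv2 <- nested_cv(tst, labels, list(model), cfg)
  expect_identical(cv1, cv2)
  # outer test sets partition all trials exactly once
  test_sets <- lapply(cv1$fold_results, `[[`, "test_idx")
  expect_equal(sort(unlist(test_sets)), seq_along(labels))
  expect_false(any(duplicated(unlist(test_sets))))
  expect_true(all(cv1$score_matrix >= 0 & cv1$score_matrix <= 1))

  # label permutation destroys decodability
  bas <- vapply(1:8, function(s) {
    rng <- memtransfer:::.local_rng(s + 300L)
    yp <- rng(sample(labels))
    nested_cv(tst, yp, list(model), cfg)$balanced_accuracy
  }, numeric(1))
  expect_gt(mean(bas), 0.42)
  expect_lt(mean(bas), 0.58)
})

test_that("task-identity classifier separates distinct tasks and honors chance", {
  cfg <- light_config(seed = 12)
  specs <- lapply(1:3, function(i)
    latent_spec(n_channels = 8, gamma = 0, class_gap = 3, k = 2))
  tabs <- lapply(1:3, function(i)
    data.frame(trial_index = 1:40, block = 1, condition = "high", rt = NA,
               accuracy = TRUE, class_label = "high"))
  eps <- lapply(1:3, function(i) {
    B <- make_loadings(specs[[i]], seed = 40 + i)   # distinct subspaces
    ep <- simulate_epochs(tabs[[i]], specs[[i]], epoch_span = c(0, 400),
                          loadings = B, seed = 50 + i)
    ep$task_id <- c("perception", "sustained", "selective")[i]
    ep
  })
  sts <- setNames(lapply(eps, as_streams),
                  c("perception", "sustained", "selective"))
  res <- task_identity_classifier(sts, n_permutations = 0, config = cfg)
  expect_gt(res$accuracy, 0.8)
  expect_equal(res$chance, 1 / 3)
  resp <- task_identity_classifier(sts, n_permutations = 2, config = cfg)
  expect_lt(abs(resp$chance - 1 / 3), 0.15)
  expect_error(task_identity_classifier(sts[1:2]), "at least 3")
})
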