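test_that("condition filling carries the nearest preceding value", {
  # misses at trials 3 and 7: trials 4, 5, 6 carry trial 3's value
  v <- c(10, 20, 3, 40, 50, 60, 7, 80)
  mask <- seq_along(v) %in% c(3, 7)
  out <- forward_fill_condition(v, mask)
  expect_equal(out$values[4:6], rep(3, 3))
  expect_equal(out$values[c(3, 7)], c(3, 7))
  expect_equal(out$values[1:2], c(3, 3))       # leading gap: first real value
  expect_equal(out$values[8], 7)
  expect_equal(out$filled, !mask)
  # no gaps: unchanged
  full <- forward_fill_condition(v, rep(TRUE, 8))
  expect_equal(full$values, v)
  # variants agree when surrounding real values are equal
  v2 <- c(5, 0, 5); m2 <- c(TRUE, FALSE, TRUE)
  expect_equal(forward_fill_condition(v2, m2, "previous")$values,
               forward_fill_condition(v2, m2, "next")$values)
  expect_equal(forward_fill_condition(v2, m2, "mean")$values, c(5, 5, 5))
  expect_error(forward_fill_condition(v, rep(FALSE, 8)), "no observed")
})

test_that("mini-block means follow the 16 x 15 layout", {
  x <- seq_len(240)
  bm <- miniblock_means(x)
  expect_length(bm, 16)
  expect_equal(diff(bm), rep(15, 15))         # linear series: slope 15
  expect_equal(miniblock_means(rep(2, 240)), rep(2, 16))
  expect_error(miniblock_means(seq_len(241)), "not divisible")
})

test_that("time-on-task slope is the Pearson correlation with block index", {
  expect_equal(time_on_task_slope(16:1)$rho, -1)
  expect_true(is.na(time_on_task_slope(rep(1, 16))$rho))
  ct <- cor.test(1:16, c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3, 5, 8, 9, 7, 9, 3))
  sl <- time_on_task_slope(c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3, 5, 8, 9, 7, 9, 3))
  expect_equal(sl$rho, unname(ct$estimate))
  expect_equal(sl$p, ct$p.value)
})

test_that("window-to-chunk map partitions the 14 windows 4+5+5", {
  cm <- memtransfer:::.chunk_map()
  expect_equal(lengths(cm), c(early = 4L, middle = 5L, late = 5L))
  expect_equal(sort(unlist(cm)), 1:14, ignore_attr = TRUE)

  grid <- window_grid()
  cols <- sprintf("score_per[%d-%d]", grid[, 1], grid[, 2])
  sc <- matrix(0.5, 6, 14, dimnames = list(NULL, cols))
  ch <- history_chunks(sc)
  expect_equal(unname(ch[1, ]), rep(0.5, 3))  # constant scores: equal chunks
  # signal only in the last window moves only the late chunk
  sc2 <- sc
  sc2[, 14] <- 1
  ch2 <- history_chunks(sc2)
  expect_equal(ch2[1, "per_early"], ch2[1, "per_middle"], ignore_attr = TRUE)
  expect_gt(ch2[1, "per_late"], ch2[1, "per_early"])
  expect_error(history_chunks(sc[, 1:5]), "nonstandard grid")
})

test_that("history ANOVA matches brute-force sums of squares on a toy design", {
  # 4 subjects x 2 memory x 3 source x 3 time, one value per cell
  set.seed(9)
  d <- expand.grid(subject = 1:4, memory = c("after_hit", "after_miss"),
                   source = c("per", "sus", "sel"),
                   time = c("early", "middle", "late"))
  d$evidence <- rnorm(nrow(d)) +
    0.5 * (d$memory == "after_hit") + 0.2 * (d$time == "late")
  an <- history_anova(d)

  g <- mean(d$evidence)
  mean_of <- function(...) tapply(d$evidence, lapply(list(...), function(f) d[[f]]), mean)
  # memory main effect against its subject-by-memory stratum
  m_a <- mean_of("memory"); m_s <- mean_of("subject")
  m_as <- tapply(d$evidence, list(d$memory, d$subject), mean)
  ss_a <- 4 * 9 * sum((m_a - g)^2)
  ss_as <- 9 * sum((sweep(sweep(m_as, 1, m_a), 2, m_s - g))^2)
  f_a <- (ss_a / 1) / (ss_as / 3)
  row <- an[an$effect == "memory", ]
  expect_equal(row$F, f_a, tolerance = 1e-8)
  expect_equal(row$df1, 1)
  expect_equal(row$df2, 3)
  expect_equal(row$pes, ss_a / (ss_a + ss_as), tolerance = 1e-8)
  # source main effect
  m_b <- mean_of("source")
  m_bs <- tapply(d$evidence, list(d$source, d$subject), mean)
  ss_b <- 4 * 6 * sum((m_b - g)^2)
  ss_bs <- 6 * sum((sweep(sweep(m_bs, 1, m_b), 2, m_s - g))^2)
  f_b <- (ss_b / 2) / (ss_bs / 6)
  expect_equal(an$F[an$effect == "source"], f_b, tolerance = 1e-8)
  expect_error(history_anova(d[d$memory == "after_hit", ]),
               "empty design cell")
})

test_that("history table groups trials by the neighboring event's outcome", {
  grid <- window_grid()
  cols <- sprintf("score_per[%d-%d]", grid[, 1], grid[, 2])
  hits <- c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE)
  sc <- matrix(seq_len(6 * 14) / 100, 6, 14, dimnames = list(NULL, cols))
  tab <- history_evidence_table(list(list(scores = sc, hits = hits)),
                                direction = "previous")
  expect_setequal(levels(tab$memory), c("after_hit", "after_miss"))
  # trials 2, 4, 5 follow a hit; 3, 6 follow a miss
  ev <- evidence_series(sc)[, 1]
  expect_equal(tab$evidence[tab$memory == "after_hit" & tab$time == "early"],
               unname(mean(history_chunks(sc)[c(2, 4, 5), "per_early"])))
  tabn <- history_evidence_table(list(list(scores = sc, hits = hits)),
                                 direction = "next")
  expect_setequal(levels(tabn$memory), c("before_hit", "before_miss"))
})

test_that("Holm-Bonferroni matches the hand-computed step-down adjustment", {
  out <- holm_bonferroni(c(0.01, 0.04, 0.03), alpha = 0.05)
  expect_equal(out$adjusted, c(0.03, 0.06, 0.06))
  expect_equal(out$reject, c(TRUE, FALSE, FALSE))
  expect_equal(holm_bonferroni(0.04)$adjusted, 0.04)
  expect_false(any(holm_bonferroni(rep(1, 5))$reject))
  expect_error(holm_bonferroni(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("evidence-level ANOVA has calibrated null p-values", {
  ps <- vapply(1:60, function(seed) {
    subs <- simulate_evidence_scores(n_subjects = 12, n_trials = 60,
                                     after_hit_shift = 0, seed = seed + 2000)
    an <- history_anova(history_evidence_table(subs, "previous"))
    an$p[an$effect == "memory"]
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
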