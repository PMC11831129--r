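test_that("single-trial conditions flag degenerate standard errors", {
  cond <- run_condition(D = 25, bar_size = 0.6, n_trials = 1, seed = 3)
  expect_true(cond$fraction_correct %in% c(0, 1))
  expect_true(cond$se_degenerate)
  expect_equal(nrow(cond$trials), 1L)
  expect_true(cond$trials$path_length_arcmin >= 0)
  expect_equal(cond$trials$correct,
               cond$trials$decoded == cond$trials$true_orientation)
})

test_that("conditions reproduce exactly under one master seed", {
  a <- run_condition(D = 50, bar_size = 0.5, n_trials = 4, seed = 7)
  b <- run_condition(D = 50, bar_size = 0.5, n_trials = 4, seed = 7)
  expect_identical(a$trials, b$trials)
  expect_identical(a$decisions, b$decisions)
})

test_that("zero-gain pipeline performs at chance", {
  cond <- run_condition(D = 25, bar_size = 0.3, n_trials = 200, seed = 11,
                        contrast_scale = 0)
  expect_gt(cond$fraction_correct, 0.25 - 0.09)
  expect_lt(cond$fraction_correct, 0.25 + 0.09)
})

test_that("path-length heatmap partitions trials and handles edge cases", {
  set.seed(2)
  trials <- data.frame(overall_size = rep(c(1.5, 2.5, 4), each = 40),
                       path_length_arcmin = rexp(120, 1 / 8),
                       correct = runif(120) < 0.7)
  hm <- path_length_heatmap(trials, length_bins = 4)
  expect_equal(sum(hm$table$n), nrow(trials))
  all_correct <- trials
  all_correct$correct <- TRUE
  hm2 <- path_length_heatmap(all_correct, length_bins = 3)
  occupied <- hm2$table$n > 0
  expect_true(all(hm2$table$fraction_correct[occupied] == 1))
  expect_true(all(is.na(hm2$table$fraction_correct[!occupied])))
})

test_that("weighted accuracy over D is a convex combination", {
  ## fabricate a sweep shell: weights act on the cells table only
  sweep <- structure(list(
    cells = expand.grid(D = c(0, 50), bar_size = c(0.3, 0.5)),
    D_list = c(0, 50), bar_sizes = c(0.3, 0.5),
    accuracy_by_time = array(0.5, dim = c(2, 2, 10))),
    class = "fem_sweep")
  sweep$cells$fraction_correct <- c(0.4, 0.9, 0.6, 1.0)
  sweep$cells$n_trials <- 20
  one_hot <- c(`0` = 1, `50` = 0)
  w <- weighted_accuracy_over_D(sweep, one_hot)
  expect_equal(w$fraction_correct,
               sweep$cells$fraction_correct[sweep$cells$D == 0])
  half <- c(`0` = 0.5, `50` = 0.5)
  wh <- weighted_accuracy_over_D(sweep, half)
  for (i in seq_len(nrow(wh))) {
    fr <- sweep$cells$fraction_correct[sweep$cells$bar_size ==
                                         wh$bar_size[i]]
    expect_gte(wh$fraction_correct[i], min(fr))
    expect_lte(wh$fraction_correct[i], max(fr))
  }
  expect_error(weighted_accuracy_over_D(sweep, c(`0` = 0.7, `50` = 0.7)),
               "sum to 1")
  expect_error(weighted_accuracy_over_D(sweep, c(`0` = 2, `50` = -1)),
               "negative")
})

test_that("synthetic subject profiles carry the assumed population structure", {
  pr <- make_subject_profiles(seed = 13)
  t <- pr$table
  expect_equal(length(unique(t$subject_eye)), 34L)
  expect_equal(nrow(t), 34L * 5L)
  expect_true(all(t$D > 0))
  ## ~3x spread of per-eye base D
  baseD <- tapply(t$D, t$subject_eye, mean)
  expect_gt(max(baseD) / min(baseD), 2)
  expect_lt(max(baseD) / min(baseD), 4.5)
  ## requested fraction of eyes modulated
  mod <- tapply(t$modulated, t$subject_eye, any)
  expect_equal(mean(mod), 12 / 34, tolerance = 0.02)
  ## modulated eyes vary D with size, unmodulated only by noise
  spread <- tapply(t$D, t$subject_eye, function(x) diff(range(x)) / mean(x))
  expect_gt(mean(spread[mod]), mean(spread[!mod]))
})

test_that("degenerate profiles make all D conditions indistinguishable", {
  pr <- make_subject_profiles(n_subjects = 2, eyes_per_subject = 1,
                              bar_sizes = c(0.4, 0.6), D_range = c(50, 50),
                              frac_modulated = 0, noise_sd = 0,
                              n_trials_per_size = 4, seed = 3)
  expect_equal(pr$table$D, rep(50, nrow(pr$table)), tolerance = 1e-12)
  res <- stimulus_dependent_D_experiment(pr, seed = 5, fixed_D_list = 50,
                                         D_resolution = 10)
  t <- res$table
  expect_equal(res$n_trials_total, 2 * 2 * 4 * 4)  # eyes x sizes x conds x trials
  ## every condition used the same D, mosaic and seeds derive per cell:
  ## accuracies must agree within binomial error of identical conditions
  for (sz in unique(t$bar_size)) {
    fr <- t$fraction_correct[t$bar_size == sz]
    expect_lt(diff(range(fr)), 0.5 + 1e-9)
    expect_true(all(fr >= 0 & fr <= 1))
  }
})
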