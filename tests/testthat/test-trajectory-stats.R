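test_that("estimate_D recovers the generating coefficient and isotropy", {
  p <- diffusion_params(200)
  trs <- lapply(1:300, function(i) generate_trajectory(p, 0.5, seed = i))
  est <- estimate_D(trs)
  expect_equal(est$D, 200, tolerance = 0.06)
  expect_equal(est$D_x + est$D_y, est$D)
  expect_gt(est$D_x / est$D_y, 0.9)
  expect_lt(est$D_x / est$D_y, 1.1)
  ## static trajectories -> D = 0
  p0 <- diffusion_params(0)
  trs0 <- lapply(1:5, function(i) generate_trajectory(p0, 0.5, seed = i))
  expect_equal(estimate_D(trs0)$D, 0)
  ## too-short trajectory errors with its index
  short <- fem_trajectory(c(0, 0.01), c(0, 1), c(0, 1))
  expect_error(estimate_D(list(short), lag = 0.05), "trajectory 1")
})

test_that("msd slope and estimate_D agree (two routes to one D)", {
  p <- diffusion_params(60)
  trs <- lapply(1:300, function(i) generate_trajectory(p, 0.5, seed = 500 + i))
  est <- estimate_D(trs)
  m <- msd_curve(trs)
  expect_equal(m$slope, est$D, tolerance = 0.1)
})

test_that("power spectrum finds a sinusoid peak and flat white noise", {
  n <- 480
  tt <- (0:(n - 1)) / 960
  f0 <- 30
  sin_tr <- fem_trajectory(tt, sin(2 * pi * f0 * tt), rep(0, n))
  ps <- power_spectrum(list(sin_tr), axis = "x")
  expect_equal(ps$frequencies[which.max(ps$power)], f0, tolerance = 0.05)
  set.seed(8)
  wn <- lapply(1:100, function(i)
    fem_trajectory(tt, rnorm(n), rnorm(n)))
  psw <- power_spectrum(wn)
  expect_lt(abs(psw$loglog_slope), 0.25)
  expect_error(power_spectrum(fem_trajectory(0:6 * 0.05, rnorm(7), rnorm(7))),
               "at least 8 samples")
})

test_that("diffusion position spectra fall as 1/f^2", {
  p <- diffusion_params(50)
  trs <- lapply(1:200, function(i)
    upsample_trajectory(generate_trajectory(p, 0.5, seed = 900 + i), 960))
  ps <- power_spectrum(trs)
  expect_gt(ps$loglog_slope, -2.3)
  expect_lt(ps$loglog_slope, -1.7)
})

test_that("path length is 0 for static, L for a straight segment, grows with D", {
  static <- fem_trajectory(c(0, 0.05, 0.1), c(1, 1, 1), c(2, 2, 2))
  expect_equal(path_length(static), 0)
  seg <- fem_trajectory(c(0, 0.05, 0.1), c(0, 1.5, 3), c(0, 2, 4))
  expect_equal(path_length(seg), 5)  # straight line of length 5
  mean_pl <- function(D, seeds) {
    p <- diffusion_params(D)
    mean(vapply(seeds, function(s)
      path_length(generate_trajectory(p, 0.5, seed = s)), 1))
  }
  expect_lt(mean_pl(20, 1:80), mean_pl(80, 1:80))
  expect_lt(mean_pl(80, 1:80), mean_pl(200, 1:80))
})

test_that("displacement autocorrelation separates diffusion from AR(1)", {
  ar <- lapply(1:60, function(i) oracle_ar1_trajectory(40, 0.6, seed = i))
  ac <- displacement_autocorrelation(ar, max_lag = 4)
  expect_equal(ac$acf[1], 1)
  expect_gt(ac$acf[2], 0.4)   # AR(1) with phi = 0.6
})

test_that("path-length comparison across sizes behaves under null and effect", {
  ## null: one D for all sizes
  make_table <- function(D_by_size, n_per, seed0) {
    rows <- list()
    sizes <- as.numeric(names(D_by_size))
    k <- 0
    for (s in seq_along(sizes)) for (i in seq_len(n_per)) {
      k <- k + 1
      tr <- generate_trajectory(diffusion_params(D_by_size[[s]]), 0.5,
                                seed = seed0 + k)
      rows[[k]] <- data.frame(subject_eye = "s1_L", trial = k,
                              stim_size_arcmin = sizes[s],
                              path_length_arcmin = path_length(tr))
    }
    do.call(rbind, rows)
  }
  null_tab <- make_table(list(`1.5` = 50, `2.5` = 50, `4` = 50), 30, 0)
  null_res <- compare_path_lengths_across_sizes(null_tab)
  expect_gt(null_res$p.value, 0.01)
  eff_tab <- make_table(list(`1.5` = 25, `2.5` = 60, `4` = 120), 30, 1000)
  eff_res <- compare_path_lengths_across_sizes(eff_tab)
  expect_lt(eff_res$p.value, 1e-4)
  expect_gt(eff_res$H, null_res$H)
  ## permuting the size labels destroys the effect (permutation oracle)
  set.seed(99)
  perm <- eff_tab
  perm$stim_size_arcmin <- sample(perm$stim_size_arcmin)
  expect_gt(compare_path_lengths_across_sizes(perm)$p.value, 0.001)
  ## a 1-trial bin is dropped with a warning
  tiny <- rbind(null_tab, data.frame(subject_eye = "s1_L", trial = 999,
                                     stim_size_arcmin = 9,
                                     path_length_arcmin = 1))
  expect_warning(compare_path_lengths_across_sizes(tiny), "dropping")
})

test_that("consecutive-trial comparison detects direction of amplitude changes", {
  mk <- function(sizes, e2e) data.frame(subject_eye = "s1_L",
                                        trial = seq_along(sizes),
                                        stim_size_arcmin = sizes,
                                        end_to_end_arcmin = e2e)
  ## no size increases -> empty result
  none <- compare_consecutive_trials(mk(c(4, 3, 2, 1), c(5, 4, 3, 2)))
  expect_equal(none$n_pairs, 0L)
  expect_equal(none$direction, "none")
  ## size-dependent amplitude: larger size -> larger e2e on increase pairs
  set.seed(5)
  sizes <- rep(c(1, 2, 1, 3, 2, 4), 10)
  e2e_dep <- sizes * 2 + runif(length(sizes), 0, 0.3)
  dep <- compare_consecutive_trials(mk(sizes, e2e_dep))
  expect_equal(dep$direction, "increase")
  expect_lt(dep$p.value, 0.01)
  ## time-decreasing amplitude regardless of size -> detected decrease
  e2e_time <- seq(10, 1, length.out = length(sizes))
  conf <- compare_consecutive_trials(mk(sizes, e2e_time))
  expect_equal(conf$direction, "decrease")
})
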