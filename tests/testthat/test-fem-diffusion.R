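test_that("transition kernel is a normalized point mass at D = 0", {
  k <- make_transition_kernel(diffusion_params(0))
  expect_equal(sum(k$probs), 1)
  center <- which(k$dx == 0)
  expect_equal(k$probs[center, center], 1)
})

test_that("transition kernel is normalized, sign-symmetric and isotropic", {
  for (D in c(5, 30, 100)) {
    k <- make_transition_kernel(
      diffusion_params(D, kernel_radius = kernel_radius_for(D)))
    expect_equal(sum(k$probs), 1, tolerance = 1e-12)
    ## sign flip per axis and axis swap leave the kernel unchanged
    expect_equal(k$probs, k$probs[rev(seq_along(k$dx)), ])
    expect_equal(k$probs, k$probs[, rev(seq_along(k$dy))])
    expect_equal(k$probs, t(k$probs))
  }
})

test_that("kernel per-axis variance matches the Monte-Carlo step oracle", {
  ## D = 200, dt = 0.05, spacing = 0.5 -> per-axis variance D*dt/2 = 5
  D <- 200
  p <- diffusion_params(D, kernel_radius = kernel_radius_for(D))
  k <- make_transition_kernel(p)
  mu <- driftcode:::step_variance_grid(p)
  expect_equal(mu, 20)
  mc <- oracle_step_sample(1e6, mu, seed = 123) * p$grid_spacing
  expect_equal(var(mc), 5, tolerance = 0.01)        # raw step process
  kv <- driftcode:::kernel_axis_variance(k)
  ## truncation at the 1%-mass radius clips at most a few percent
  expect_equal(kv, var(mc), tolerance = 0.05)
  expect_equal(kv, D * p$dt / 2, tolerance = 0.05)
})

test_that("kernel construction rejects radii that truncate > 1% of mass", {
  expect_error(make_transition_kernel(diffusion_params(200, kernel_radius = 4)),
               "kernel_radius is too small")
  expect_silent(make_transition_kernel(
    diffusion_params(200, kernel_radius = kernel_radius_for(200))))
})

test_that("trajectories at D = 0 stay at the start; seeds reproduce", {
  p0 <- diffusion_params(0)
  tr <- generate_trajectory(p0, 0.5, seed = 1)
  expect_true(all(tr$xs == tr$xs[1]) && all(tr$ys == tr$ys[1]))
  p <- diffusion_params(80)
  a <- generate_trajectory(p, 0.5, seed = 42)
  b <- generate_trajectory(p, 0.5, seed = 42)
  expect_identical(a, b)
  c <- generate_trajectory(p, 0.5, seed = 43)
  expect_false(identical(a$xs, c$xs))
})

test_that("ensemble MSD of generated trajectories grows as D * lag", {
  D <- 100
  p <- diffusion_params(D)
  trs <- lapply(1:400, function(i) generate_trajectory(p, 0.5, seed = i))
  m <- msd_curve(trs)
  expect_equal(m$slope, D, tolerance = 0.1)
  expect_lt(abs(m$intercept), 0.6)
  expect_true(all(m$table$msd_2d >= 0))
})

test_that("per-bin displacements at lags >= 1 are uncorrelated", {
  p <- diffusion_params(60)
  trs <- lapply(1:150, function(i) generate_trajectory(p, 0.5, seed = 100 + i))
  ac <- displacement_autocorrelation(trs, max_lag = 5)
  expect_equal(ac$acf[1], 1)
  expect_true(all(abs(ac$acf[-1]) < 0.08))
})

test_that("upsampling preserves endpoints, midpoints and identity", {
  p <- diffusion_params(50)
  tr <- generate_trajectory(p, 0.5, seed = 3)
  same <- upsample_trajectory(tr, rate = 1 / p$dt)
  expect_equal(same$times, tr$times)
  expect_equal(same$xs, tr$xs)
  up <- upsample_trajectory(tr, 960)
  expect_equal(up$xs[1], tr$xs[1])
  expect_equal(up$xs[length(up$xs)], tr$xs[length(tr$xs)])
  expect_equal(end_to_end_length(up), end_to_end_length(tr))
  two <- fem_trajectory(c(0, 0.05), c(0, 1), c(2, 0))
  mid <- upsample_trajectory(two, 40)
  expect_equal(mid$xs[2], 0.5)
  expect_equal(mid$ys[2], 1)
  expect_error(upsample_trajectory(tr, 1), "rate")
})

test_that("trajectory CSV round-trips, flags bad rows, handles empty files", {
  p <- diffusion_params(40)
  trs <- lapply(1:3, function(i)
    generate_trajectory(p, 0.25, seed = i,
                        meta = list(subject_eye = "s1_L", trial = i,
                                    stim_size_arcmin = 2.5,
                                    stim_orientation = "up",
                                    correct = i %% 2 == 0)))
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write_trajectories(trs, f)
  back <- read_trajectories(f)
  expect_length(back, 3)
  for (i in 1:3) {
    expect_equal(back[[i]]$xs, trs[[i]]$xs, tolerance = 1e-9)
    expect_equal(back[[i]]$times, trs[[i]]$times, tolerance = 1e-9)
    expect_equal(back[[i]]$meta$stim_orientation, "up")
  }
  ## corrupt one coordinate of trial 2 -> that trial dropped, others kept
  df <- read.csv(f)
  df$x_arcmin[df$trial == 2][1] <- NA
  write.csv(df, f, row.names = FALSE)
  expect_warning(back2 <- read_trajectories(f), "non-finite")
  expect_length(back2, 2)
  ## empty file
  writeLines("subject_eye,trial,t_s,x_arcmin,y_arcmin", f)
  expect_warning(empty <- read_trajectories(f), "no trajectory rows")
  expect_identical(empty, list())
  ## missing required column
  writeLines(c("subject_eye,trial,t_s,x_arcmin", "a,1,0,0"), f)
  expect_error(read_trajectories(f), "missing required")
})
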