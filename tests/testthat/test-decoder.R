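test_that("flat initial posterior is uniform with zero log normalizer", {
  st <- init_posterior(3)
  expect_equal(dim(st$probs), c(4L, 3L, 3L))
  expect_true(all(st$probs == 1 / 36))
  expect_equal(sum(st$probs), 1)
  expect_equal(st$log_norm, 0)
  ## entropy of the uniform joint
  expect_equal(-sum(st$probs * log(st$probs)), log(36))
})

test_that("pair log-likelihood matches a direct product of Poisson pmfs", {
  s <- tiny_setup()
  params <- s$mosaic$params
  set.seed(21)
  counts <- rpois(nrow(s$mosaic$centers), 1.2)
  for (l in 1:4) for (pos in list(c(1, 1), c(2, 3))) {
    for (prev in list(NULL, c(3, 2))) {
      got <- pair_log_likelihood(counts, s$config$otables, params, l, pos,
                                 prev)
      want <- log(oracle_bin_likelihood(counts, s$config$otables, params,
                                        l, pos, prev))
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
  ## all-zero counts at baseline rates: -N * r0 * dt
  nc <- nrow(s$mosaic$centers)
  blank_tables <- array(0, dim = dim(s$config$otables))
  expect_equal(pair_log_likelihood(rep(0L, nc), blank_tables, params, 1,
                                   c(1, 1), c(1, 1)),
               -nc * params$r0 * params$dt)
  ## permutation invariance over cells
  perm <- sample(nc)
  perm_tables <- s$config$otables[, , perm, , drop = FALSE]
  expect_equal(pair_log_likelihood(counts[perm], perm_tables, params, 2,
                                   c(2, 2), c(1, 2)),
               pair_log_likelihood(counts, s$config$otables, params, 2,
                                   c(2, 2), c(1, 2)))
})

test_that("recursive posterior equals exhaustive path enumeration", {
  ## 3x3 grid, 4 cells, 3 bins: forward recursion vs all 9^3 paths
  s <- tiny_setup(D = 40)
  tr <- generate_trajectory(s$dp, 0.15, seed = 31)
  sp <- simulate_trial(s$mosaic, s$rasters$left, tr, 0.15, seed = 32,
                       grid_extent = s$ext)
  want <- oracle_enumeration_posterior(sp$counts, s$config$otables,
                                       s$kernel, s$mosaic$params, s$ext)
  for (engine in c("cpp", "r")) {
    res <- run_decoder(sp, s$config, seed = 1, engine = engine)
    expect_equal(unname(res$final$probs), want, tolerance = 1e-8)
  }
})

test_that("compiled and reference recursions agree on larger problems", {
  mos <- build_mosaic(n_per_side = 3, seed = 2)
  ras <- render_E_set(0.4, 0.5)
  dp <- diffusion_params(60, grid_extent = 9,
                         kernel_radius = kernel_radius_for(60))
  cfg <- decoder_config(mos, ras, make_transition_kernel(dp),
                        grid_extent = 9)
  tr <- generate_trajectory(dp, 0.25, seed = 5)
  sp <- simulate_trial(mos, ras$down, tr, 0.25, seed = 6, grid_extent = 9)
  a <- run_decoder(sp, cfg, seed = 3, engine = "cpp")
  b <- run_decoder(sp, cfg, seed = 3, engine = "r")
  expect_equal(a$lambda_marginals, b$lambda_marginals, tolerance = 1e-10)
  expect_equal(a$log_evidence, b$log_evidence, tolerance = 1e-8)
  expect_identical(a$decisions, b$decisions)
})

test_that("posterior stays normalized after every update", {
  s <- tiny_setup(D = 25)
  tr <- generate_trajectory(s$dp, 0.5, seed = 41)
  sp <- simulate_trial(s$mosaic, s$rasters$up, tr, 0.5, seed = 42,
                       grid_extent = s$ext)
  st <- init_posterior(s$ext)
  for (t in seq_len(sp$n_bins)) {
    st <- update_posterior(st, sp$counts[, t], s$config,
                           first_bin = (t == 1))
    expect_equal(sum(st$probs), 1, tolerance = 1e-12)
    expect_true(all(st$probs >= 0))
  }
})

test_that("zero gain leaves the orientation marginal flat under diffusion", {
  mos <- build_mosaic(n_per_side = 2, seed = 8,
                      params = rgc_params(contrast_scale = 0))
  ras <- render_E_set(0.3, 0.5)
  dp <- diffusion_params(40, grid_extent = 5,
                         kernel_radius = kernel_radius_for(40))
  cfg <- decoder_config(mos, ras, make_transition_kernel(dp), grid_extent = 5)
  tr <- generate_trajectory(dp, 0.5, seed = 9)
  sp <- simulate_trial(mos, ras$up, tr, 0.5, seed = 10, grid_extent = 5)
  res <- run_decoder(sp, cfg, seed = 11)
  expect_equal(res$lambda_marginals,
               matrix(0.25, 4, 10, dimnames = list(cfg$orientations, NULL)),
               tolerance = 1e-12)
  ## position marginal remains uniform: diffusion of a flat prior is flat
  pos_marg <- apply(res$final$probs, c(2, 3), sum)
  dimnames(pos_marg) <- NULL
  expect_equal(pos_marg, matrix(1 / 25, 5, 5), tolerance = 1e-12)
})

test_that("D = 0 collapses the update to a pointwise Bayes rule", {
  s <- tiny_setup(D = 0)
  set.seed(51)
  counts2 <- rpois(4, 1)
  counts3 <- rpois(4, 1)
  st <- init_posterior(s$ext)
  st <- update_posterior(st, counts2, s$config, first_bin = TRUE)
  st2 <- update_posterior(st, counts3, s$config)
  ## manual pointwise product with prev = pos (identity transition)
  want <- st$probs
  for (l in 1:4) for (ix in 1:3) for (iy in 1:3) {
    want[l, ix, iy] <- want[l, ix, iy] *
      oracle_bin_likelihood(counts3, s$config$otables, s$mosaic$params, l,
                            c(ix, iy), c(ix, iy))
  }
  want <- want / sum(want)
  expect_equal(st2$probs, want, tolerance = 1e-10)
})

test_that("classification takes the marginal argmax and seeded ties", {
  st <- init_posterior(3)
  ## concentrated posterior
  st$probs[] <- 0
  st$probs[2, 1, 1] <- 1
  expect_equal(classify(st), "down")
  ## invariance to common rescaling before normalization
  st$probs[2, 1, 1] <- 5
  expect_equal(classify(st), "down")
  ## flat posterior: seeded uniform tie-break covers all orientations
  flat <- init_posterior(3)
  picks <- vapply(1:200, function(i) {
    set.seed(i)
    classify(flat)
  }, "")
  expect_setequal(unique(picks), c("up", "down", "left", "right"))
  tab <- table(picks)
  expect_gt(min(tab), 20)  # roughly uniform across 200 draws
})

test_that("decoder reports decisions on the requested time grid", {
  s <- tiny_setup(D = 30)
  tr <- generate_trajectory(s$dp, 0.5, seed = 61)
  sp <- simulate_trial(s$mosaic, s$rasters$right, tr, 0.5, seed = 62,
                       grid_extent = s$ext)
  res <- run_decoder(sp, s$config, seed = 63)
  expect_equal(res$decision_times, seq(0.05, 0.5, by = 0.05))
  expect_length(res$decisions, 10)
  ## determinism given spike train and seed
  res2 <- run_decoder(sp, s$config, seed = 63)
  expect_identical(res$decisions, res2$decisions)
  expect_equal(res$lambda_marginals, res2$lambda_marginals)
  ## dt mismatch is refused
  bad <- sp
  bad$dt <- 0.1
  expect_error(run_decoder(bad, s$config), "dt")
})
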