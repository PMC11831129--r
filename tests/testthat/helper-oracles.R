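## Independent oracles used across the suite. These re-derive expected
## quantities by brute force (direct simulation or exhaustive enumeration)
## without touching the package's recursion or kernel code paths.

## Monte-Carlo of the raw per-axis step process: difference of two Poisson
## counts with means mu/2, in grid units.
oracle_step_sample <- function(n, mu, seed) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed(rpois(n, mu / 2) - rpois(n, mu / 2))
}

## Cyclic transition matrix M[p_new, p_old] built directly from a kernel's
## offsets and probabilities by explicit looping (no FFTs, no package
## indexing helpers).
oracle_transition_matrix <- function(kernel, ext) {
  npos <- ext * ext
  M <- matrix(0, npos, npos)
  wrap0 <- function(i) ((i - 1) %% ext) + 1
  for (jx in seq_len(ext)) for (jy in seq_len(ext)) {
    pold <- (jx - 1) + ext * (jy - 1) + 1
    for (a in seq_along(kernel$dx)) for (b in seq_along(kernel$dy)) {
      pr <- kernel$probs[a, b]
      if (pr <= 0) next
      ix <- wrap0(jx + kernel$dx[a])
      iy <- wrap0(jy + kernel$dy[b])
      pnew <- (ix - 1) + ext * (iy - 1) + 1
      M[pnew, pold] <- M[pnew, pold] + pr
    }
  }
  M
}

## Per-cell Poisson likelihood of one bin's counts for a hypothesis
## (lambda, pos, prev_pos), computed directly from the overlap tables.
oracle_bin_likelihood <- function(counts, otables, params, l, pos, prev,
                                  rate_floor = 1e-6) {
  nc <- dim(otables)[3]
  onow <- otables[pos[1], pos[2], , l]
  oprev <- if (is.null(prev)) rep(0, nc) else otables[prev[1], prev[2], , l]
  rate <- pmax(rate_floor,
               pmax(0, params$r0 + params$contrast_scale * params$dr *
                         (onow - params$w * oprev)))
  prod(stats::dpois(counts, rate * params$dt))
}

## Exhaustive-path posterior: enumerate every latent position path
## (p_1, ..., p_T) for every orientation and sum likelihood x transition
## weights. The first bin conditions on the blank pre-stimulus frame and
## applies the transition from a flat initial position prior. Returns the
## joint posterior array (n_orient x ext x ext) at the final bin.
oracle_enumeration_posterior <- function(spikes, otables, kernel, params,
                                         ext, rate_floor = 1e-6) {
  no <- dim(otables)[4]
  npos <- ext * ext
  nb <- ncol(spikes)
  M <- oracle_transition_matrix(kernel, ext)
  pos_list <- as.matrix(expand.grid(ix = seq_len(ext), iy = seq_len(ext)))
  paths <- as.matrix(expand.grid(rep(list(seq_len(npos)), nb)))
  post <- array(0, dim = c(no, ext, ext))
  for (l in seq_len(no)) {
    for (r in seq_len(nrow(paths))) {
      path <- paths[r, ]
      ## transition from the flat initial prior into p_1
      w <- sum(M[path[1], ] / (no * npos)) *
        oracle_bin_likelihood(spikes[, 1], otables, params, l,
                              pos_list[path[1], ], NULL, rate_floor)
      if (nb > 1) for (t in 2:nb) {
        w <- w * M[path[t], path[t - 1]] *
          oracle_bin_likelihood(spikes[, t], otables, params, l,
                                pos_list[path[t], ], pos_list[path[t - 1], ],
                                rate_floor)
      }
      pe <- pos_list[path[nb], ]
      post[l, pe[1], pe[2]] <- post[l, pe[1], pe[2]] + w
    }
  }
  post / sum(post)
}

## AR(1) series with known lag-1 autocorrelation, for the displacement
## autocorrelation contrast case.
oracle_ar1_trajectory <- function(n, phi, seed) {
  set.seed(seed)
  steps_x <- as.numeric(stats::arima.sim(list(ar = phi), n))
  steps_y <- as.numeric(stats::arima.sim(list(ar = phi), n))
  fem_trajectory(times = (0:n) * 0.05, xs = cumsum(c(0, steps_x)),
                 ys = cumsum(c(0, steps_y)))
}

## Small standard configuration shared by decoder tests: 3x3 grid,
## 2x2-cell mosaic, four orientations.
tiny_setup <- function(D = 40, ext = 3L, seed = 7) {
  mosaic <- build_mosaic(n_per_side = 2L, spacing = 0.5, sigma = 0.3,
                         jitter_frac = 0.1, seed = seed)
  rasters <- render_E_set(0.3, 0.5)
  dp <- diffusion_params(D, grid_extent = ext,
                         kernel_radius = kernel_radius_for(D))
  kernel <- make_transition_kernel(dp)
  config <- decoder_config(mosaic, rasters, kernel, grid_extent = ext)
  list(mosaic = mosaic, rasters = rasters, kernel = kernel, config = config,
       dp = dp, ext = ext)
}

blank_raster <- function(bar_size = 0.5, grid_spacing = 0.5) {
  r <- render_E("up", bar_size, grid_spacing)
  r$intensities[] <- 0
  r
}

full_raster <- function(ext = 31L, grid_spacing = 0.5) {
  r <- render_E("up", 0.5, grid_spacing)
  r$intensities <- matrix(1, ext, ext)
  r
}
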