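## Linear-nonlinear Poisson model of the foveal RGC mosaic.
##
## Each cell's rate in bin t is
##   r(t) = max(0, r0 + dr * (O(t) - w * O(t-1)))
## where O(t) is the inner product of the cell's unit-normalized Gaussian
## receptive field with the stimulus at its current grid position. The
## one-lag temporal kernel (weight w) makes responses transient: with a
## static stimulus and w = 1, activity decays to baseline after the first
## bin. Spike counts are Poisson with mean r(t) * dt.

#' RGC rate-model parameters
#'
#' @param r0 baseline spiking rate in Hz (default 20).
#' @param dr gain in Hz: sensitivity to receptive-field light intensity
#'   (default 120).
#' @param w temporal-kernel weight in [0, 1] (default 0.8); \code{w = 0}
#'   gives a unimodal (non-transient) temporal filter.
#' @param dt bin width in seconds (default 0.05).
#' @param contrast_scale dimensionless multiplier on \code{dr} absorbing
#'   stimulus contrast (default 1; 0 silences stimulus drive entirely).
#' @return an object of class \code{"rgc_params"}.
#' @export
rgc_params <- function(r0 = 20, dr = 120, w = 0.8, dt = 0.05,
                       contrast_scale = 1) {
  stopifnot(r0 >= 0, dr >= 0, w >= 0, w <= 1, dt > 0, contrast_scale >= 0)
  structure(list(r0 = r0, dr = dr, w = w, dt = dt,
                 contrast_scale = contrast_scale),
            class = "rgc_params")
}

#' @export
print.rgc_params <- function(x, ...) {
  cat(sprintf("RGC parameters: r0 = %g Hz, dr = %g Hz, w = %g, dt = %g s, contrast %g\n",
              x$r0, x$dr, x$w, x$dt, x$contrast_scale))
  invisible(x)
}

#' Build a jittered lattice mosaic of model RGCs
#'
#' Centres sit on a square lattice (centred on the grid origin) with i.i.d.
#' uniform jitter of +/- \code{jitter_frac * spacing} per axis; receptive
#' field widths are \code{sigma * (1 + U(-jitter_frac, jitter_frac))}. The
#' heterogeneous variant triples the jitter fraction, opening gaps in
#' receptive-field coverage.
#'
#' @param n_per_side cells per axis (default 11, i.e. 121 cells).
#' @param spacing lattice spacing in arcmin (default 0.5, one cone per RGC
#'   at the foveola).
#' @param sigma Gaussian receptive-field width in arcmin (default 0.25).
#' @param jitter_frac jitter fraction (default 0.1).
#' @param seed optional integer seed.
#' @param heterogeneous if TRUE, use \code{3 * jitter_frac}.
#' @param params an \code{\link{rgc_params}} object shared by all cells.
#' @return an object of class \code{"rgc_mosaic"}: \code{centers}
#'   (n_cells x 2, arcmin), \code{sigmas}, \code{params},
#'   \code{jitter_frac}, \code{heterogeneous}.
#' @export
build_mosaic <- function(n_per_side = 11L, spacing = 0.5, sigma = 0.25,
                         jitter_frac = 0.1, seed = NULL,
                         heterogeneous = FALSE, params = rgc_params()) {
  stopifnot(is_count(n_per_side), n_per_side >= 1, spacing > 0, sigma > 0,
            jitter_frac >= 0, inherits(params, "rgc_params"))
  jf <- if (heterogeneous) 3 * jitter_frac else jitter_frac
  n <- as.integer(n_per_side)
  lat <- (seq_len(n) - (n + 1) / 2) * spacing
  centers <- as.matrix(expand.grid(x = lat, y = lat))
  nc <- nrow(centers)
  with_seed(seed, {
    centers <- centers + matrix(stats::runif(2 * nc, -jf * spacing,
                                             jf * spacing), nc, 2)
    sigmas <- sigma * (1 + stats::runif(nc, -jf, jf))
  })
  structure(list(centers = centers, sigmas = sigmas, params = params,
                 spacing = spacing, n_per_side = n,
                 jitter_frac = jitter_frac, heterogeneous = heterogeneous),
            class = "rgc_mosaic")
}

#' @export
print.rgc_mosaic <- function(x, ...) {
  cat(sprintf("RGC mosaic: %d cells (%d x %d lattice, %g arcmin spacing)\n",
              nrow(x$centers), x$n_per_side, x$n_per_side, x$spacing))
  cat(sprintf("  sigma: %.3f +/- %.3f arcmin; jitter %g%s\n",
              mean(x$sigmas), stats::sd(x$sigmas), x$jitter_frac,
              if (x$heterogeneous) " (heterogeneous, x3)" else ""))
  print(x$params)
  invisible(x)
}

#' @export
plot.rgc_mosaic <- function(x, ...) {
  graphics::plot(x$centers, asp = 1, xlab = "x (arcmin)",
                 ylab = "y (arcmin)", ...)
  graphics::symbols(x$centers[, 1], x$centers[, 2], circles = x$sigmas,
                    inches = FALSE, add = TRUE, fg = "gray")
  invisible(x)
}

## Receptive-field weight images on the cyclic grid, one column per cell,
## each normalized to unit sum (so a uniform unit stimulus gives overlap 1).
rf_weights <- function(mosaic, grid_extent, grid_spacing) {
  ext <- as.integer(grid_extent)
  coord <- index_to_arcmin(seq_len(ext), grid_spacing, ext)
  nc <- nrow(mosaic$centers)
  W <- matrix(0, ext * ext, nc)
  for (i in seq_len(nc)) {
    gx <- stats::dnorm(coord, mosaic$centers[i, 1], mosaic$sigmas[i])
    gy <- stats::dnorm(coord, mosaic$centers[i, 2], mosaic$sigmas[i])
    w <- outer(gx, gy)
    W[, i] <- w / sum(w)
  }
  W
}

#' Receptive-field/stimulus overlap tables
#'
#' Computes, for every grid position of the stimulus centre and every
#' orientation, the inner product of each cell's unit-normalized Gaussian
#' receptive field with the raster: the O_i(lambda, x, y) drive entering
#' the rate equation. Positions wrap cyclically, so translating the raster
#' by one grid unit shifts the table by one index. Computed once per
#' configuration (via 2D FFTs) and reused by encoder and decoder.
#'
#' @param mosaic an \code{\link{rgc_mosaic}}.
#' @param rasters a single \code{\link{stimulus_raster}} or a list of them
#'   (e.g. the four orientations from \code{\link{render_E_set}}).
#' @param grid_extent grid positions per axis (default 31).
#' @return an array of dim \code{c(grid_extent, grid_extent, n_cells,
#'   n_rasters)}; dimnames on the 4th margin name the orientations.
#' @export
overlap_table <- function(mosaic, rasters, grid_extent = 31L) {
  stopifnot(inherits(mosaic, "rgc_mosaic"))
  if (inherits(rasters, "stimulus_raster")) rasters <- list(rasters)
  stopifnot(length(rasters) >= 1L)
  ext <- as.integer(grid_extent)
  sp <- rasters[[1]]$grid_spacing
  for (r in rasters) {
    stopifnot(inherits(r, "stimulus_raster"))
    if (abs(r$grid_spacing - sp) > 1e-12)
      stop("all rasters must share one grid spacing")
    if (nrow(r$intensities) > ext)
      stop("stimulus support (", nrow(r$intensities),
           " px) exceeds the grid extent (", ext, ")")
  }
  W <- rf_weights(mosaic, ext, sp)
  nc <- ncol(W)
  FW <- matrix(0i, ext * ext, nc)
  for (i in seq_len(nc))
    FW[, i] <- as.vector(stats::fft(matrix(W[, i], ext, ext)))
  out <- array(0, dim = c(ext, ext, nc, length(rasters)),
               dimnames = list(NULL, NULL, NULL,
                               vapply(rasters, function(r) r$orientation, "")))
  for (l in seq_along(rasters)) {
    S <- rasters[[l]]$intensities
    npix <- nrow(S)
    m <- (npix - 1L) %/% 2L
    Semb <- matrix(0, ext, ext)
    ii <- wrap_index(-m:m + 1L, ext)
    Semb[ii, ii] <- S
    FS <- Conj(stats::fft(Semb))
    for (i in seq_len(nc)) {
      O <- Re(stats::fft(matrix(FW[, i] * FS, ext, ext),
                         inverse = TRUE)) / (ext * ext)
      O[abs(O) < 1e-12] <- 0
      out[, , i, l] <- O
    }
  }
  out
}

#' Rectified linear-nonlinear firing rate
#'
#' \code{rate = max(0, r0 + contrast_scale * dr * (O_now - w * O_prev))}.
#' Rectification at zero keeps the Poisson mean nonnegative (the linear
#' form can go negative when the stimulus leaves a receptive field).
#'
#' @param params an \code{\link{rgc_params}} object.
#' @param O_now,O_prev receptive-field overlaps in [0, 1] for the current
#'   and previous bin (vectorized).
#' @return firing rate(s) in Hz.
#' @export
firing_rate <- function(params, O_now, O_prev) {
  stopifnot(inherits(params, "rgc_params"))
  pmax(0, params$r0 + params$contrast_scale * params$dr *
            (O_now - params$w * O_prev))
}

#' Poisson spike counts for one bin
#'
#' Counts are Poisson with mean \code{rate * dt} (rates in Hz converted to
#' expected counts per bin).
#'
#' @param rate firing rate(s) in Hz (>= 0).
#' @param params an \code{\link{rgc_params}} object (supplies \code{dt}).
#' @param seed optional integer seed.
#' @return integer spike count(s), same length as \code{rate}.
#' @export
sample_spikes <- function(rate, params, seed = NULL) {
  stopifnot(all(rate >= 0), inherits(params, "rgc_params"))
  with_seed(seed, stats::rpois(length(rate), rate * params$dt))
}

#' Simulate population spiking for one trial
#'
#' Moves the stimulus along the trajectory (positions wrapped onto the
#' cyclic grid), computes each cell's rectified rate from the overlap at
#' the current and previous positions, and draws independent Poisson
#' counts. The first bin's previous-frame overlap is 0 (blank screen
#' before stimulus onset).
#'
#' @param mosaic an \code{\link{rgc_mosaic}}.
#' @param raster a \code{\link{stimulus_raster}} (the true stimulus).
#' @param traj a \code{\link{fem_trajectory}} sampled at the model
#'   \code{dt} and spanning at least \code{duration}.
#' @param duration trial duration in seconds (default 0.5).
#' @param seed optional integer seed.
#' @param grid_extent grid positions per axis (default 31).
#' @param otable optional precomputed overlap matrix for this raster
#'   (dim \code{c(extent, extent, n_cells)} or the 4D array from
#'   \code{\link{overlap_table}} with \code{orientation} selecting a slice).
#' @param orientation orientation name selecting the slice of a 4D
#'   \code{otable}.
#' @return an object of class \code{"spike_train"}: \code{counts}
#'   (n_cells x n_bins integer matrix), \code{dt}, \code{n_bins}.
#' @export
simulate_trial <- function(mosaic, raster, traj, duration = 0.5,
                           seed = NULL, grid_extent = 31L, otable = NULL,
                           orientation = NULL) {
  stopifnot(inherits(mosaic, "rgc_mosaic"), inherits(traj, "fem_trajectory"))
  p <- mosaic$params
  dt <- p$dt
  n_bins <- as.integer(round(duration / dt))
  stopifnot(n_bins >= 1L)
  if (is.null(otable)) {
    stopifnot(inherits(raster, "stimulus_raster"))
    ot <- overlap_table(mosaic, raster, grid_extent)
    otable <- array(ot[, , , 1, drop = FALSE], dim = dim(ot)[1:3])
    sp <- raster$grid_spacing
  } else {
    if (length(dim(otable)) == 4L) {
      stopifnot(!is.null(orientation))
      otable <- array(otable[, , , orientation, drop = FALSE],
                      dim = dim(otable)[1:3])
    }
    sp <- if (!is.null(raster)) raster$grid_spacing else mosaic$spacing
  }
  ext <- dim(otable)[1]
  nc <- dim(otable)[3]
  ## stimulus position during bin t is the trajectory sample at (t-1)*dt
  tt <- (0:(n_bins - 1L)) * dt
  if (max(tt) > traj$times[length(traj$times)] + 1e-9)
    stop("trajectory does not span the trial duration")
  xs <- stats::approx(traj$times, traj$xs, xout = tt)$y
  ys <- stats::approx(traj$times, traj$ys, xout = tt)$y
  ix <- arcmin_to_index(xs, sp, ext)
  iy <- arcmin_to_index(ys, sp, ext)
  O <- matrix(0, nc, n_bins)
  for (t in seq_len(n_bins)) O[, t] <- otable[ix[t], iy[t], ]
  counts <- matrix(0L, nc, n_bins)
  with_seed(seed, {
    for (t in seq_len(n_bins)) {
      O_prev <- if (t == 1L) 0 else O[, t - 1L]
      rate <- firing_rate(p, O[, t], O_prev)
      counts[, t] <- stats::rpois(nc, rate * dt)
    }
  })
  structure(list(counts = counts, dt = dt, n_bins = n_bins),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("Spike train: %d cells x %d bins (dt %g s)\n",
              nrow(x$counts), x$n_bins, x$dt))
  cat(sprintf("  mean rate %.2f Hz, total %d spikes\n",
              mean(x$counts) / x$dt, sum(x$counts)))
  invisible(x)
}
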