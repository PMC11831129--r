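## Ocular-drift diffusion model: parameters, transition kernel, trajectory
## generation, and upsampling to the eye-tracker time base.

#' Parameters of the discrete-grid drift diffusion model
#'
#' Ocular drift is modelled as a 2D random walk on a square grid with cyclic
#' boundary conditions. In each time bin of width \code{dt} the per-axis step
#' (in grid units) is the difference of two independent Poisson counts with
#' equal means \code{mu/2}, so the step has mean zero and variance \code{mu}.
#' \code{mu} is set so that the two-dimensional mean square displacement per
#' bin equals \code{D * dt}, i.e. \code{mu = D * dt / (2 * grid_spacing^2)}.
#'
#' @param D diffusion coefficient, arcmin^2/s: the slope of the 2D mean
#'   square displacement versus time.
#' @param dt time-bin width in seconds (default 0.05, the model's native
#'   50 ms bin).
#' @param grid_spacing arcmin per grid unit (default 0.5, the order of
#'   foveal cone spacing).
#' @param grid_extent number of grid positions per axis (odd recommended;
#'   default 31).
#' @param kernel_radius maximum per-axis step magnitude retained in the
#'   truncated transition kernel, in grid units (default 4). Use
#'   \code{\link{kernel_radius_for}} to pick a radius adequate for large
#'   \code{D}.
#' @return an object of class \code{"diffusion_params"}.
#' @seealso \code{\link{make_transition_kernel}},
#'   \code{\link{generate_trajectory}}
#' @export
diffusion_params <- function(D, dt = 0.05, grid_spacing = 0.5,
                             grid_extent = 31L, kernel_radius = 4L) {
  stopifnot(is.numeric(D), length(D) == 1L, is.finite(D), D >= 0,
            is.numeric(dt), length(dt) == 1L, dt > 0,
            is.numeric(grid_spacing), length(grid_spacing) == 1L,
            grid_spacing > 0,
            is_count(grid_extent), grid_extent >= 3,
            is_count(kernel_radius), kernel_radius >= 1)
  structure(list(D = D, dt = dt, grid_spacing = grid_spacing,
                 grid_extent = as.integer(grid_extent),
                 kernel_radius = as.integer(kernel_radius)),
            class = "diffusion_params")
}

#' @export
print.diffusion_params <- function(x, ...) {
  cat("Drift diffusion parameters\n")
  cat(sprintf("  D            : %g arcmin^2/s\n", x$D))
  cat(sprintf("  dt           : %g s\n", x$dt))
  cat(sprintf("  grid spacing : %g arcmin\n", x$grid_spacing))
  cat(sprintf("  grid extent  : %d positions/axis\n", x$grid_extent))
  cat(sprintf("  kernel radius: %d grid units\n", x$kernel_radius))
  invisible(x)
}

## Per-bin per-axis step variance in grid units^2.
step_variance_grid <- function(params) {
  params$D * params$dt / (2 * params$grid_spacing^2)
}

## pmf of the difference of two independent Poisson(mu/2) counts
## (a symmetric Skellam distribution): P(k) = exp(-mu) * I_|k|(mu).
skellam_pmf <- function(k, mu) {
  if (mu == 0) return(as.numeric(k == 0))
  besselI(mu, abs(k), expon.scaled = TRUE)
}

## Smallest truncation radius retaining at least 1 - max_discard of the 2D
## kernel mass for a given D (grows like 3-4 per-axis standard deviations).
#' Truncation radius adequate for a diffusion coefficient
#'
#' Returns the smallest \code{kernel_radius} whose truncated transition
#' kernel retains at least \code{1 - max_discard} of the 2D step-probability
#' mass, so that \code{\link{make_transition_kernel}} accepts it.
#'
#' @param D diffusion coefficient, arcmin^2/s.
#' @param dt time-bin width, s.
#' @param grid_spacing arcmin per grid unit.
#' @param max_discard maximum tolerated discarded mass (default 0.01).
#' @return an integer radius (at least 1).
#' @export
kernel_radius_for <- function(D, dt = 0.05, grid_spacing = 0.5,
                              max_discard = 0.01) {
  mu <- D * dt / (2 * grid_spacing^2)
  r <- 1L
  repeat {
    axis_mass <- sum(skellam_pmf(-r:r, mu))
    if (1 - axis_mass^2 <= max_discard) return(r)
    r <- r + 1L
    if (r > 1000L) stop("no practical truncation radius for D = ", D)
  }
}

#' Truncated position transition kernel of the drift diffusion
#'
#' Builds the per-bin transition probabilities P(dx, dy) of the
#' Poisson-difference step process: the product of two independent per-axis
#' symmetric Skellam pmfs, truncated at \code{kernel_radius} grid units per
#' axis and renormalized. This is the transition matrix the Bayesian decoder
#' uses for the latent stimulus position.
#'
#' @param params a \code{\link{diffusion_params}} object.
#' @return an object of class \code{"transition_kernel"}: a list with
#'   \code{dx}, \code{dy} (per-axis integer offsets, \code{-r..r}),
#'   \code{probs} (matrix, rows indexed by dx, columns by dy, summing to 1),
#'   \code{mu} (per-axis step variance in grid units^2), \code{discarded}
#'   (mass removed by truncation before renormalization) and the parameters.
#' @details Errors if truncation would discard more than 1% of the step
#'   mass; widen \code{kernel_radius} (see \code{\link{kernel_radius_for}}).
#' @export
make_transition_kernel <- function(params) {
  stopifnot(inherits(params, "diffusion_params"))
  r <- params$kernel_radius
  mu <- step_variance_grid(params)
  off <- -r:r
  p_axis <- skellam_pmf(off, mu)
  mass2d <- sum(p_axis)^2
  discarded <- 1 - mass2d
  if (discarded > 0.01)
    stop(sprintf(paste0("truncation at kernel_radius = %d discards %.2f%% ",
                        "of step mass (> 1%%); kernel_radius is too small ",
                        "for D = %g (need >= %d)"),
                 r, 100 * discarded, params$D,
                 kernel_radius_for(params$D, params$dt, params$grid_spacing)))
  probs <- outer(p_axis, p_axis) / mass2d
  structure(list(dx = off, dy = off, probs = probs, mu = mu,
                 discarded = discarded, params = params),
            class = "transition_kernel")
}

#' @export
print.transition_kernel <- function(x, ...) {
  cat("Drift transition kernel\n")
  cat(sprintf("  D = %g arcmin^2/s, dt = %g s, spacing = %g arcmin\n",
              x$params$D, x$params$dt, x$params$grid_spacing))
  cat(sprintf("  per-axis step variance: %g grid units^2\n", x$mu))
  cat(sprintf("  support: %d x %d offsets (radius %d), %.3g%% mass discarded\n",
              length(x$dx), length(x$dy), x$params$kernel_radius,
              100 * x$discarded))
  invisible(x)
}

## Per-axis variance (arcmin^2) of the truncated, renormalized kernel.
kernel_axis_variance <- function(kernel) {
  px <- rowSums(kernel$probs)
  sum(px * kernel$dx^2) * kernel$params$grid_spacing^2
}

#' Construct a drift trajectory object
#'
#' @param times sample times in seconds, strictly increasing.
#' @param xs,ys gaze/stimulus positions in arcmin.
#' @param meta optional named list of trial metadata (\code{subject_eye},
#'   \code{trial}, \code{stim_size_arcmin}, \code{stim_orientation},
#'   \code{correct}).
#' @return an object of class \code{"fem_trajectory"}.
#' @export
fem_trajectory <- function(times, xs, ys, meta = list()) {
  stopifnot(is.numeric(times), is.numeric(xs), is.numeric(ys),
            length(times) == length(xs), length(times) == length(ys),
            length(times) >= 2L)
  if (any(diff(times) <= 0)) stop("trajectory times must be strictly increasing")
  structure(list(times = as.numeric(times), xs = as.numeric(xs),
                 ys = as.numeric(ys), meta = meta),
            class = "fem_trajectory")
}

#' @export
print.fem_trajectory <- function(x, ...) {
  cat(sprintf("Drift trajectory: %d samples over %.3f s\n",
              length(x$times), diff(range(x$times))))
  e2e <- sqrt((x$xs[length(x$xs)] - x$xs[1])^2 +
              (x$ys[length(x$ys)] - x$ys[1])^2)
  cat(sprintf("  end-to-end displacement: %.2f arcmin\n", e2e))
  if (length(x$meta)) {
    flat <- vapply(x$meta, function(v) paste(format(v), collapse = ","), "")
    cat("  meta:", paste(names(flat), flat, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
plot.fem_trajectory <- function(x, ...) {
  graphics::plot(x$xs, x$ys, type = "l", asp = 1,
                 xlab = "x (arcmin)", ylab = "y (arcmin)", ...)
  graphics::points(x$xs[1], x$ys[1], pch = 16)
  invisible(x)
}

#' Generate a drift trajectory from the diffusion model
#'
#' Draws each bin's per-axis displacement as an independent
#' Poisson-difference step (untruncated) and accumulates from the grid
#' centre. Coordinates are returned unwrapped, in arcmin; the cyclic grid
#' wrap is applied internally wherever positions index the grid (encoding,
#' decoding), so trajectory statistics see true displacements.
#'
#' @param params a \code{\link{diffusion_params}} object.
#' @param duration trial duration in seconds (at least \code{dt}).
#' @param seed optional integer seed for reproducibility.
#' @param meta optional metadata list stored on the trajectory.
#' @return a \code{\link{fem_trajectory}} with \code{floor(duration/dt) + 1}
#'   samples at times \code{0, dt, ..., duration}.
#' @export
generate_trajectory <- function(params, duration, seed = NULL, meta = list()) {
  stopifnot(inherits(params, "diffusion_params"), duration >= params$dt)
  n_steps <- as.integer(round(duration / params$dt))
  mu <- step_variance_grid(params)
  with_seed(seed, {
    sx <- stats::rpois(n_steps, mu / 2) - stats::rpois(n_steps, mu / 2)
    sy <- stats::rpois(n_steps, mu / 2) - stats::rpois(n_steps, mu / 2)
    fem_trajectory(times = (0:n_steps) * params$dt,
                   xs = cumsum(c(0, sx)) * params$grid_spacing,
                   ys = cumsum(c(0, sy)) * params$grid_spacing,
                   meta = meta)
  })
}

#' Upsample a trajectory to a finer time base
#'
#' Linear interpolation of positions onto a regular grid at \code{rate} Hz,
#' emulating the effective temporal sampling of a scanning eye tracker
#' (~960 Hz). Endpoints are preserved.
#'
#' @param traj a \code{\link{fem_trajectory}}.
#' @param rate target sampling rate in Hz; \code{rate * dt >= 1} where
#'   \code{dt} is the native sampling step of \code{traj}.
#' @return a \code{\link{fem_trajectory}} on the finer time base.
#' @export
upsample_trajectory <- function(traj, rate) {
  stopifnot(inherits(traj, "fem_trajectory"), is.numeric(rate), rate > 0)
  if (any(diff(traj$times) <= 0)) stop("trajectory times must be increasing")
  dt_native <- min(diff(traj$times))
  if (rate * dt_native < 1 - 1e-9)
    stop("rate must be at least the native sampling rate (rate * dt >= 1)")
  t0 <- traj$times[1]
  t1 <- traj$times[length(traj$times)]
  n <- floor((t1 - t0) * rate + 1e-9)
  tt <- t0 + (0:n) / rate
  if (tt[length(tt)] < t1 - 1e-12) tt <- c(tt, t1)
  tt[length(tt)] <- t1  # guard against float drift; endpoint exact
  fem_trajectory(times = tt,
                 xs = stats::approx(traj$times, traj$xs, xout = tt)$y,
                 ys = stats::approx(traj$times, traj$ys, xout = tt)$y,
                 meta = traj$meta)
}
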