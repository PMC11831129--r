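## Snellen-E stimulus rasterization and optical blur.
##
## Geometry: the canonical E occupies a 5x5 square of bar units (bar
## thickness = gap width = bar_size arcmin): a full-height spine of
## thickness 1 plus three limbs of length 4 and thickness 1, separated by
## gaps of 1. Orientation is the direction the limbs point. Ink area is
## therefore 17 * bar_size^2. Rasters are anti-aliased by supersampling
## each grid cell and store intensities in [0, 1] on an odd-sized square
## matrix whose central pixel is the stimulus centre; intensities[ix, iy]
## has x along rows and y along columns, both increasing with coordinate.

stimulus_orientations <- c("up", "down", "left", "right")

## Stroke membership test for the E centred at the origin, limbs pointing
## `orientation`; x, y in arcmin, vectorized. Rectangles are axis-aligned
## for every orientation, so 90-degree rotations are exact.
e_indicator <- function(x, y, orientation, bar) {
  ## canonical "right": spine on the left, limbs extend to the right
  rot <- switch(orientation,
    right = list(x = x, y = y),
    up    = list(x = y, y = -x),   # inverse rotation of +90 deg
    left  = list(x = -x, y = -y),
    down  = list(x = -y, y = x))
  u <- rot$x; v <- rot$y
  h <- 2.5 * bar
  spine <- u >= -h & u <= -1.5 * bar & abs(v) <= h
  limb_v <- (abs(v) <= h & abs(v) >= 1.5 * bar) | abs(v) <= 0.5 * bar
  limbs <- u > -1.5 * bar & u <= h & limb_v
  (spine | limbs) * 1
}

#' Rasterize a Snellen E optotype
#'
#' Renders the E at one of four orientations on the model grid, with
#' area-weighted anti-aliasing from \code{supersample}^2 subsamples per
#' grid cell. Bar thickness equals gap width (\code{bar_size}); overall
#' letter size is \code{5 * bar_size}.
#'
#' @param orientation one of \code{"up"}, \code{"down"}, \code{"left"},
#'   \code{"right"} (the direction the limbs point).
#' @param bar_size bar thickness in arcmin (> \code{grid_spacing / 4}).
#' @param grid_spacing arcmin per raster pixel (default 0.5).
#' @param supersample subsamples per pixel per axis (default 8).
#' @return an object of class \code{"stimulus_raster"}: \code{intensities}
#'   (odd-sized square matrix in [0, 1], central pixel = stimulus centre),
#'   \code{orientation}, \code{bar_size}, \code{overall_size},
#'   \code{grid_spacing}, \code{blur_fwhm}.
#' @export
render_E <- function(orientation, bar_size, grid_spacing = 0.5,
                     supersample = 8L) {
  orientation <- match.arg(orientation, stimulus_orientations)
  stopifnot(is.numeric(bar_size), length(bar_size) == 1L, bar_size > 0,
            grid_spacing > 0, is_count(supersample), supersample >= 1)
  if (bar_size < grid_spacing / 4)
    stop("bar_size ", bar_size, " arcmin is below grid_spacing/4 = ",
         grid_spacing / 4, "; rasterize on a finer grid (smaller ",
         "grid_spacing) to resolve the bar")
  half <- 2.5 * bar_size
  m <- max(1L, as.integer(ceiling((half - grid_spacing / 2) / grid_spacing)))
  npix <- 2L * m + 1L
  ss <- as.integer(supersample)
  ## subsample centres, symmetric about 0 so the lattice is invariant under
  ## 90-degree rotation about the central pixel
  centers <- (seq_len(npix) - (m + 1L)) * grid_spacing
  sub_off <- ((seq_len(ss) - 0.5) / ss - 0.5) * grid_spacing
  xs <- rep(centers, each = ss) + rep(sub_off, times = npix)
  ind <- outer(xs, xs, function(px, py)
    e_indicator(px, py, orientation, bar_size))
  ## block-average ss x ss subsamples down to pixels
  block <- matrix(0, npix * ss, npix)
  for (j in seq_len(npix))
    block[, j] <- rowMeans(ind[, ((j - 1L) * ss + 1L):(j * ss), drop = FALSE])
  intens <- matrix(0, npix, npix)
  for (i in seq_len(npix))
    intens[i, ] <- colMeans(block[((i - 1L) * ss + 1L):(i * ss), ,
                                  drop = FALSE])
  structure(list(intensities = intens, orientation = orientation,
                 bar_size = bar_size, overall_size = 5 * bar_size,
                 grid_spacing = grid_spacing, blur_fwhm = 0),
            class = "stimulus_raster")
}

#' @export
print.stimulus_raster <- function(x, ...) {
  cat(sprintf("Snellen E raster: orientation %s, bar %.2f arcmin (overall %.2f)\n",
              x$orientation, x$bar_size, x$overall_size))
  cat(sprintf("  %d x %d pixels at %g arcmin", nrow(x$intensities),
              ncol(x$intensities), x$grid_spacing))
  if (x$blur_fwhm > 0) cat(sprintf(", blurred (FWHM %g arcmin)", x$blur_fwhm))
  cat(sprintf("; ink = %.3f arcmin^2\n",
              sum(x$intensities) * x$grid_spacing^2))
  invisible(x)
}

#' @export
plot.stimulus_raster <- function(x, ...) {
  n <- nrow(x$intensities)
  coord <- (seq_len(n) - (n + 1) / 2) * x$grid_spacing
  graphics::image(coord, coord, x$intensities, asp = 1, col = grDevices::gray(seq(1, 0, length.out = 64)),
                  xlab = "x (arcmin)", ylab = "y (arcmin)", ...)
  invisible(x)
}

## Rotate a raster matrix by +90 degrees about its central pixel in (x, y):
## new(x, y) = old(y, -x), i.e. R[i, j] = M[j, n + 1 - i].
rotate_raster_90 <- function(intens) {
  n <- nrow(intens)
  t(intens)[n:1, , drop = FALSE]
}

#' Blur a stimulus raster with the eye's optics
#'
#' Convolves the raster with an isotropic 2D Gaussian of the given full
#' width at half maximum, approximating optical blurring by the human eye
#' in natural (non-aberration-corrected) viewing. The raster is padded so
#' total intensity is preserved exactly; \code{blur_fwhm = 0} is the
#' identity.
#'
#' @param raster a \code{\link{stimulus_raster}}.
#' @param blur_fwhm Gaussian FWHM in arcmin (>= 0; default 1).
#' @return a \code{\link{stimulus_raster}} (larger when padding was added).
#' @export
apply_optical_blur <- function(raster, blur_fwhm = 1) {
  stopifnot(inherits(raster, "stimulus_raster"), blur_fwhm >= 0)
  if (blur_fwhm == 0) return(raster)
  s <- raster$grid_spacing
  sigma <- blur_fwhm / (2 * sqrt(2 * log(2)))
  r <- max(1L, as.integer(ceiling(4 * sigma / s)))
  k <- stats::dnorm((-r:r) * s, sd = sigma)
  k <- k / sum(k)
  a <- raster$intensities
  n <- nrow(a)
  np <- n + 2L * r
  pad <- matrix(0, np, np)
  pad[(r + 1L):(r + n), (r + 1L):(r + n)] <- a
  ## separable convolution as a banded matrix product; the pad absorbs all
  ## spread so total intensity is conserved exactly
  B <- matrix(0, np, np)
  for (j in seq_len(np)) {
    lo <- max(1L, j - r)
    hi <- min(np, j + r)
    B[lo:hi, j] <- k[(lo:hi) - j + r + 1L]
  }
  out <- B %*% pad %*% t(B)
  out[out < 0] <- 0
  structure(list(intensities = out, orientation = raster$orientation,
                 bar_size = raster$bar_size,
                 overall_size = raster$overall_size,
                 grid_spacing = s, blur_fwhm = blur_fwhm),
            class = "stimulus_raster")
}

#' Render all four E orientations at one size
#'
#' @inheritParams render_E
#' @param blur_fwhm optional Gaussian optical blur FWHM in arcmin
#'   (default 0, no blur).
#' @return a named list of four \code{\link{stimulus_raster}} objects in
#'   the order up, down, left, right.
#' @export
render_E_set <- function(bar_size, grid_spacing = 0.5, supersample = 8L,
                         blur_fwhm = 0) {
  out <- lapply(stimulus_orientations, render_E, bar_size = bar_size,
                grid_spacing = grid_spacing, supersample = supersample)
  names(out) <- stimulus_orientations
  if (blur_fwhm > 0) out <- lapply(out, apply_optical_blur, blur_fwhm = blur_fwhm)
  out
}
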