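## End-to-end 4AFC experiment drivers: generate drift, encode, decode,
## aggregate fraction correct over conditions (drift amplitude D x
## stimulus size), with per-time accuracy curves and path-length summaries.

#' Simulate one (D, stimulus size) condition
#'
#' Runs \code{n_trials} independent trials: draw a uniformly random E
#' orientation, generate a drift trajectory at \code{D}, simulate mosaic
#' spiking, decode with the matched-model ideal observer (same D), and
#' record decisions at every bin. Per-trial seeds derive from \code{seed}
#' by a counter scheme, so single trials reproduce under partial re-runs.
#'
#' @param D diffusion coefficient, arcmin^2/s.
#' @param bar_size E bar thickness in arcmin (overall size = 5x).
#' @param n_trials trials to simulate (default 20).
#' @param seed master seed for the condition.
#' @param model_variant \code{"default"}, \code{"w0"} (unimodal temporal
#'   filter), \code{"heterogeneous"} (tripled mosaic jitter), or
#'   \code{"blurred"} (optical blur on the stimulus).
#' @param duration trial duration, s (default 0.5).
#' @param grid_extent,grid_spacing decoding grid (default 31 x 31 at
#'   0.5 arcmin).
#' @param n_per_side,rf_sigma,jitter_frac mosaic geometry (defaults 11,
#'   0.25 arcmin, 0.1).
#' @param r0,dr,w,contrast_scale RGC rate parameters (defaults 20 Hz,
#'   120 Hz, 0.8, 1).
#' @param blur_fwhm optical blur FWHM used by the \code{"blurred"} variant
#'   (default 1 arcmin).
#' @param rate_floor decoder rate floor, Hz.
#' @param mosaic optional prebuilt \code{\link{rgc_mosaic}} (shared across
#'   conditions of a sweep).
#' @param config optional prebuilt \code{\link{decoder_config}}.
#' @return an object of class \code{"fem_condition"}: per-trial records
#'   (\code{trials} data frame), \code{decisions} (n_trials x n_bins),
#'   \code{accuracy_by_time}, \code{fraction_correct}, binomial \code{se}
#'   (flagged degenerate when n_trials = 1 or the estimate is 0/1), and
#'   condition metadata.
#' @export
run_condition <- function(D, bar_size, n_trials = 20L, seed = 1L,
                          model_variant = c("default", "w0",
                                            "heterogeneous", "blurred"),
                          duration = 0.5, grid_extent = 31L,
                          grid_spacing = 0.5, n_per_side = 11L,
                          rf_sigma = 0.25, jitter_frac = 0.1,
                          r0 = 20, dr = 120, w = 0.8, contrast_scale = 1,
                          blur_fwhm = 1, rate_floor = 1e-6,
                          mosaic = NULL, config = NULL) {
  model_variant <- match.arg(model_variant)
  stopifnot(is_count(n_trials), n_trials >= 1)
  params <- rgc_params(r0 = r0, dr = dr,
                       w = if (model_variant == "w0") 0 else w,
                       dt = 0.05, contrast_scale = contrast_scale)
  if (is.null(mosaic))
    mosaic <- build_mosaic(n_per_side = n_per_side, spacing = grid_spacing,
                           sigma = rf_sigma, jitter_frac = jitter_frac,
                           seed = derive_seed(seed, 0),
                           heterogeneous = model_variant == "heterogeneous",
                           params = params)
  else
    mosaic$params <- params
  if (is.null(config)) {
    rasters <- render_E_set(bar_size, grid_spacing,
                            blur_fwhm = if (model_variant == "blurred")
                              blur_fwhm else 0)
    dpar <- diffusion_params(D, dt = params$dt,
                             grid_spacing = grid_spacing,
                             grid_extent = grid_extent,
                             kernel_radius = kernel_radius_for(
                               D, params$dt, grid_spacing))
    config <- decoder_config(mosaic, rasters,
                             make_transition_kernel(dpar),
                             grid_extent = grid_extent,
                             rate_floor = rate_floor)
  }
  dpar <- config$kernel$params
  orientations <- config$orientations
  n_bins <- as.integer(round(duration / params$dt))

  decisions <- matrix(NA_character_, n_trials, n_bins)
  rec <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    tseed <- derive_seed(seed, i)
    rec[[i]] <- with_seed(tseed, {
      true_ori <- orientations[sample.int(length(orientations), 1L)]
      traj <- generate_trajectory(dpar, duration)
      spikes <- simulate_trial(mosaic, config$rasters[[true_ori]], traj,
                               duration, grid_extent = config$grid_extent,
                               otable = config$otables,
                               orientation = true_ori)
      dec <- run_decoder(spikes, config)
      decisions[i, ] <- dec$decisions
      data.frame(trial = i, seed = tseed, D = D, bar_size = bar_size,
                 overall_size = 5 * bar_size,
                 true_orientation = true_ori,
                 decoded = dec$decisions[n_bins],
                 correct = dec$decisions[n_bins] == true_ori,
                 path_length_arcmin = path_length(traj, params$dt),
                 end_to_end_arcmin = end_to_end_length(traj),
                 stringsAsFactors = FALSE)
    })
  }
  trials <- do.call(rbind, rec)
  correct_by_time <- decisions == matrix(trials$true_orientation,
                                         n_trials, n_bins)
  frac <- mean(trials$correct)
  out <- structure(list(trials = trials, decisions = decisions,
                 accuracy_by_time = colMeans(correct_by_time),
                 times = seq_len(n_bins) * params$dt,
                 fraction_correct = frac,
                 se = binomial_se(frac, n_trials),
                 se_degenerate = n_trials == 1L || frac %in% c(0, 1),
                 n_trials = n_trials, D = D, bar_size = bar_size,
                 model_variant = model_variant),
            class = "fem_condition")
  attr(out, "config") <- config
  out
}

#' @export
print.fem_condition <- function(x, ...) {
  cat(sprintf("Condition D = %g arcmin^2/s, bar %g arcmin (overall %g): ",
              x$D, x$bar_size, 5 * x$bar_size))
  cat(sprintf("%.2f correct +/- %.2f (n = %d%s)\n", x$fraction_correct,
              x$se, x$n_trials,
              if (x$se_degenerate) ", SE degenerate" else ""))
  invisible(x)
}

#' Accuracy sweep over drift amplitudes and stimulus sizes
#'
#' Full grid of \code{\link{run_condition}} over \code{D_list} x
#' \code{bar_sizes}, sharing one mosaic; deterministic given \code{seed}.
#'
#' @param D_list diffusion coefficients, arcmin^2/s (default
#'   \code{c(0, 25, 50, 100, 200)}).
#' @param bar_sizes E bar thicknesses, arcmin (default
#'   \code{c(0.3, 0.4, 0.5, 0.6, 0.8)}, i.e. overall sizes 1.5-4).
#' @param n_trials trials per cell (default 20).
#' @param seed master seed.
#' @param ... forwarded to \code{\link{run_condition}}.
#' @return an object of class \code{"fem_sweep"}: \code{cells} (data frame
#'   with fraction correct and binomial SE per (D, size)),
#'   \code{accuracy_by_time} (array D x size x time), \code{trials}
#'   (all trial records), \code{times}, \code{D_list}, \code{bar_sizes}.
#' @export
sweep_accuracy <- function(D_list = c(0, 25, 50, 100, 200),
                           bar_sizes = c(0.3, 0.4, 0.5, 0.6, 0.8),
                           n_trials = 20L, seed = 1L, ...) {
  stopifnot(length(D_list) >= 1L, length(bar_sizes) >= 1L)
  dots <- list(...)
  conds <- vector("list", length(D_list) * length(bar_sizes))
  idx <- 0L
  for (di in seq_along(D_list)) for (si in seq_along(bar_sizes)) {
    idx <- idx + 1L
    args <- c(list(D = D_list[di], bar_size = bar_sizes[si],
                   n_trials = n_trials,
                   seed = derive_seed(seed, 1000L + idx)), dots)
    if (is.null(dots$mosaic)) {
      ## share one mosaic across cells, built from the sweep master seed
      args$mosaic <- do.call(sweep_mosaic, c(list(seed = seed), dots))
    }
    conds[[idx]] <- do.call(run_condition, args)
  }
  n_bins <- length(conds[[1]]$times)
  acc <- array(NA_real_, dim = c(length(D_list), length(bar_sizes), n_bins),
               dimnames = list(D = D_list, bar = bar_sizes, NULL))
  cells <- do.call(rbind, lapply(conds, function(cc)
    data.frame(D = cc$D, bar_size = cc$bar_size,
               overall_size = 5 * cc$bar_size,
               fraction_correct = cc$fraction_correct, se = cc$se,
               n_trials = cc$n_trials)))
  idx <- 0L
  for (di in seq_along(D_list)) for (si in seq_along(bar_sizes)) {
    idx <- idx + 1L
    acc[di, si, ] <- conds[[idx]]$accuracy_by_time
  }
  structure(list(cells = cells, accuracy_by_time = acc,
                 trials = do.call(rbind, lapply(conds, `[[`, "trials")),
                 times = conds[[1]]$times, D_list = D_list,
                 bar_sizes = bar_sizes, seed = seed),
            class = "fem_sweep")
}

## mosaic shared by every cell of a sweep
sweep_mosaic <- function(seed, grid_spacing = 0.5, n_per_side = 11L,
                         rf_sigma = 0.25, jitter_frac = 0.1,
                         model_variant = "default", ...) {
  build_mosaic(n_per_side = n_per_side, spacing = grid_spacing,
               sigma = rf_sigma, jitter_frac = jitter_frac,
               seed = derive_seed(seed, 0),
               heterogeneous = identical(model_variant, "heterogeneous"))
}

#' @export
print.fem_sweep <- function(x, ...) {
  cat(sprintf("Accuracy sweep: %d D values x %d sizes, %d trials/cell\n",
              length(x$D_list), length(x$bar_sizes),
              x$cells$n_trials[1]))
  tab <- stats::xtabs(fraction_correct ~ D + overall_size, data = x$cells)
  print(round(tab, 2))
  invisible(x)
}

#' @export
summary.fem_sweep <- function(object, ...) {
  cat("Fraction correct at 500 ms (rows D in arcmin^2/s, cols overall size in arcmin)\n")
  print.fem_sweep(object)
  cat(sprintf("\nRange: %.2f - %.2f; chance = 0.25\n",
              min(object$cells$fraction_correct),
              max(object$cells$fraction_correct)))
  invisible(object)
}

#' @export
plot.fem_sweep <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, length(x$bar_sizes)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (si in seq_along(x$bar_sizes)) {
    graphics::matplot(x$times, t(x$accuracy_by_time[, si, ]), type = "l",
                      lty = 1, ylim = c(0, 1), xlab = "time (s)",
                      ylab = "fraction correct",
                      main = sprintf("%.1f arcmin", 5 * x$bar_sizes[si]))
    graphics::abline(h = 0.25, lty = 3)
  }
  invisible(x)
}

#' Fraction correct binned by drift path length and stimulus size
#'
#' Bins trial records by realized path length x stimulus size and reports
#' the fraction correct and trial count per bin (empty bins NA).
#'
#' @param trials a trial-record data frame (from a sweep or condition)
#'   with columns \code{overall_size}, \code{path_length_arcmin},
#'   \code{correct}.
#' @param size_bins optional numeric bin edges for stimulus size; default
#'   one bin per distinct size.
#' @param length_bins number of path-length quantile bins (default 4) or a
#'   numeric vector of edges.
#' @return an object of class \code{"path_length_heatmap"}: a data frame
#'   \code{table} with one row per (size bin, length bin) and the bin
#'   definitions.
#' @export
path_length_heatmap <- function(trials, size_bins = NULL, length_bins = 4L) {
  stopifnot(is.data.frame(trials),
            all(c("overall_size", "path_length_arcmin", "correct") %in%
                names(trials)))
  size_f <- if (is.null(size_bins)) factor(trials$overall_size)
            else cut(trials$overall_size, size_bins, include.lowest = TRUE)
  if (length(length_bins) == 1L) {
    edges <- unique(stats::quantile(trials$path_length_arcmin,
                                    probs = seq(0, 1,
                                                length.out = length_bins + 1)))
  } else edges <- length_bins
  len_f <- cut(trials$path_length_arcmin, edges, include.lowest = TRUE)
  grid <- expand.grid(size_bin = levels(size_f), length_bin = levels(len_f),
                      stringsAsFactors = FALSE)
  key <- interaction(size_f, len_f, drop = FALSE)
  frac <- tapply(trials$correct, key, mean)
  n <- tapply(trials$correct, key, length)
  gk <- paste(grid$size_bin, grid$length_bin, sep = ".")
  grid$fraction_correct <- as.numeric(frac[gk])
  grid$n <- as.integer(n[gk])
  grid$n[is.na(grid$n)] <- 0L
  structure(list(table = grid, length_edges = edges),
            class = "path_length_heatmap")
}

#' @export
print.path_length_heatmap <- function(x, ...) {
  cat("Fraction correct by (stimulus size x path length) bin\n")
  print(x$table)
  invisible(x)
}

#' Accuracy averaged over D with subject-derived weights
#'
#' Convex combination of per-D accuracies, weighting each D by how heavily
#' it is represented across subjects.
#'
#' @param sweep a \code{\link{sweep_accuracy}} result.
#' @param D_weights named nonnegative weights over \code{sweep$D_list},
#'   summing to 1.
#' @return a data frame with one row per stimulus size: weighted fraction
#'   correct (and per-time weighted accuracy as an attribute
#'   \code{"by_time"}).
#' @export
weighted_accuracy_over_D <- function(sweep, D_weights) {
  stopifnot(inherits(sweep, "fem_sweep"))
  wD <- D_weights[match(as.character(sweep$D_list), names(D_weights))]
  if (anyNA(wD)) stop("D_weights must name every D in the sweep")
  wD <- as.numeric(wD)
  if (any(wD < 0)) stop("negative weights")
  if (abs(sum(wD) - 1) > 1e-8) stop("weights must sum to 1")
  fmat <- matrix(NA_real_, length(sweep$D_list), length(sweep$bar_sizes))
  for (r in seq_len(nrow(sweep$cells))) {
    di <- match(sweep$cells$D[r], sweep$D_list)
    si <- match(sweep$cells$bar_size[r], sweep$bar_sizes)
    fmat[di, si] <- sweep$cells$fraction_correct[r]
  }
  out <- data.frame(bar_size = sweep$bar_sizes,
                    overall_size = 5 * sweep$bar_sizes,
                    fraction_correct = as.numeric(crossprod(wD, fmat)))
  by_time <- apply(sweep$accuracy_by_time, c(2, 3), function(v) sum(wD * v))
  attr(out, "by_time") <- by_time
  out
}
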