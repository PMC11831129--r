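## Trajectory statistics: diffusion-coefficient estimation, power spectra,
## mean-square displacement, path lengths, displacement autocorrelation,
## and rank-based comparisons of drift amplitude across stimulus sizes.

traj_sampling_step <- function(traj) {
  d <- diff(traj$times)
  if (diff(range(d)) > 1e-9 * max(d))
    stop("trajectory is not uniformly sampled")
  mean(d)
}

#' Estimate the diffusion coefficient from trajectories
#'
#' \code{D} is the slope of the two-dimensional mean square displacement
#' over one lag: the average over trajectories and over all (overlapping)
#' sample pairs separated by \code{lag} of \code{(dx^2 + dy^2) / lag}.
#' Per-axis components satisfy \code{D_x + D_y = D}; under isotropic
#' diffusion each contributes \code{D/2}.
#'
#' @param trajs a \code{\link{fem_trajectory}} or list thereof, uniformly
#'   sampled; each must span at least \code{lag}.
#' @param lag displacement lag in seconds (default 0.05, one model bin).
#' @return an object of class \code{"D_estimate"} with fields \code{D},
#'   \code{D_x}, \code{D_y} (arcmin^2/s), \code{n_trajectories},
#'   \code{n_pairs} and \code{lag}.
#' @export
estimate_D <- function(trajs, lag = 0.05) {
  if (inherits(trajs, "fem_trajectory")) trajs <- list(trajs)
  stopifnot(length(trajs) >= 1L, lag > 0)
  sx2 <- sy2 <- 0
  n_pairs <- 0L
  for (j in seq_along(trajs)) {
    tr <- trajs[[j]]
    dt <- traj_sampling_step(tr)
    k <- as.integer(round(lag / dt))
    n <- length(tr$times)
    if (k < 1L || k >= n || abs(k * dt - lag) > 1e-6)
      stop("trajectory ", j, " has no sample pairs at lag ", lag, " s")
    dx <- tr$xs[(1L + k):n] - tr$xs[1L:(n - k)]
    dy <- tr$ys[(1L + k):n] - tr$ys[1L:(n - k)]
    sx2 <- sx2 + sum(dx^2)
    sy2 <- sy2 + sum(dy^2)
    n_pairs <- n_pairs + (n - k)
  }
  D_x <- sx2 / n_pairs / lag
  D_y <- sy2 / n_pairs / lag
  structure(list(D = D_x + D_y, D_x = D_x, D_y = D_y,
                 n_trajectories = length(trajs), n_pairs = n_pairs,
                 lag = lag),
            class = "D_estimate")
}

#' @export
print.D_estimate <- function(x, ...) {
  cat(sprintf("Diffusion coefficient estimate (lag %g s, %d trajectories, %d pairs)\n",
              x$lag, x$n_trajectories, x$n_pairs))
  cat(sprintf("  D   = %.3f arcmin^2/s\n", x$D))
  cat(sprintf("  D_x = %.3f, D_y = %.3f arcmin^2/s\n", x$D_x, x$D_y))
  invisible(x)
}

#' Trial-averaged position power spectrum and log-log slope
#'
#' Computes per-trajectory periodograms of the (mean-removed) position
#' signal along one axis, averages them across trajectories, and fits the
#' log-log slope by least squares over \code{band} after excluding the
#' lowest and highest octave of the band. Drift consistent with a random
#' diffusion process shows power falling as \code{1/f^2} (slope -2).
#'
#' @param trajs a \code{\link{fem_trajectory}} or list thereof; all must
#'   share one uniform time base with at least 8 samples.
#' @param axis \code{"x"}, \code{"y"}, or \code{"both"} (averages the two).
#' @param band numeric length-2 frequency band (Hz) for the slope fit
#'   before octave trimming; default \code{c(2, 100)}.
#' @param window \code{"none"} (default) or \code{"hann"}.
#' @return an object of class \code{"fem_spectrum"}: \code{frequencies}
#'   (Hz), \code{power} (trial-averaged periodogram), \code{loglog_slope},
#'   and the fitted band.
#' @export
power_spectrum <- function(trajs, axis = c("both", "x", "y"),
                           band = c(2, 100), window = c("none", "hann")) {
  axis <- match.arg(axis)
  window <- match.arg(window)
  if (inherits(trajs, "fem_trajectory")) trajs <- list(trajs)
  stopifnot(length(trajs) >= 1L, length(band) == 2L, band[1] > 0,
            band[2] > band[1])
  n <- length(trajs[[1]]$times)
  if (n < 8L) stop("need at least 8 samples per trajectory")
  dt <- traj_sampling_step(trajs[[1]])
  fs <- 1 / dt
  nf <- floor(n / 2)
  freqs <- (1:nf) * fs / n
  sig_list <- list(x = function(tr) tr$xs, y = function(tr) tr$ys)
  use_axes <- if (axis == "both") c("x", "y") else axis
  win <- if (window == "hann") {
    0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
  } else rep(1, n)
  acc <- numeric(nf)
  m <- 0L
  for (tr in trajs) {
    if (length(tr$times) != n || abs(traj_sampling_step(tr) - dt) > 1e-9)
      stop("all trajectories must share one uniform time base")
    for (ax in use_axes) {
      s <- sig_list[[ax]](tr)
      s <- (s - mean(s)) * win
      p <- Mod(stats::fft(s))^2 * dt / n
      acc <- acc + p[2:(nf + 1)]
      m <- m + 1L
    }
  }
  power <- acc / m
  fit_lo <- band[1] * 2
  fit_hi <- band[2] / 2
  sel <- freqs >= fit_lo & freqs <= fit_hi & power > 0
  if (sum(sel) < 3L)
    stop("fewer than 3 frequencies in the slope-fit band [",
         fit_lo, ", ", fit_hi, "] Hz")
  fit <- stats::lm(log(power[sel]) ~ log(freqs[sel]))
  structure(list(frequencies = freqs, power = power,
                 loglog_slope = unname(stats::coef(fit)[2]),
                 band = band, fit_band = c(fit_lo, fit_hi),
                 axis = axis, n_averaged = m),
            class = "fem_spectrum")
}

#' @export
print.fem_spectrum <- function(x, ...) {
  cat(sprintf("Drift position power spectrum (%d periodograms averaged, axis %s)\n",
              x$n_averaged, x$axis))
  cat(sprintf("  log-log slope over [%g, %g] Hz: %.3f\n",
              x$fit_band[1], x$fit_band[2], x$loglog_slope))
  invisible(x)
}

#' @export
plot.fem_spectrum <- function(x, ...) {
  graphics::plot(x$frequencies, x$power, log = "xy", type = "l",
                 xlab = "frequency (Hz)", ylab = "power (arcmin^2 s)", ...)
  graphics::abline(v = x$fit_band, lty = 3)
  invisible(x)
}

#' Mean square end-to-end displacement versus lag
#'
#' Averages squared displacements over trajectories and start times for
#' every integer multiple of the sampling step, per axis and in 2D, and
#' fits a line to the 2D curve. For diffusive drift the slope estimates
#' \code{D} and the intercept is ~0.
#'
#' @param trajs a \code{\link{fem_trajectory}} or list thereof (uniform,
#'   shared time base).
#' @param max_lag optional maximum lag in seconds.
#' @return an object of class \code{"fem_msd"}: a data frame \code{table}
#'   with columns \code{lag}, \code{msd_x}, \code{msd_y}, \code{msd_2d},
#'   plus \code{slope} and \code{intercept} of the 2D linear fit.
#' @export
msd_curve <- function(trajs, max_lag = NULL) {
  if (inherits(trajs, "fem_trajectory")) trajs <- list(trajs)
  dt <- traj_sampling_step(trajs[[1]])
  n <- min(vapply(trajs, function(tr) length(tr$times), 1L))
  kmax <- n - 1L
  if (!is.null(max_lag)) kmax <- min(kmax, as.integer(round(max_lag / dt)))
  stopifnot(kmax >= 1L)
  msd_x <- msd_y <- numeric(kmax)
  for (k in seq_len(kmax)) {
    sx <- sy <- 0
    np <- 0L
    for (tr in trajs) {
      m <- length(tr$times)
      dx <- tr$xs[(1L + k):m] - tr$xs[1L:(m - k)]
      dy <- tr$ys[(1L + k):m] - tr$ys[1L:(m - k)]
      sx <- sx + sum(dx^2); sy <- sy + sum(dy^2)
      np <- np + (m - k)
    }
    msd_x[k] <- sx / np
    msd_y[k] <- sy / np
  }
  tab <- data.frame(lag = seq_len(kmax) * dt, msd_x = msd_x, msd_y = msd_y,
                    msd_2d = msd_x + msd_y)
  fit <- stats::lm(msd_2d ~ lag, data = tab)
  structure(list(table = tab,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 n_trajectories = length(trajs)),
            class = "fem_msd")
}

#' @export
print.fem_msd <- function(x, ...) {
  cat(sprintf("Mean square displacement over %d trajectories\n",
              x$n_trajectories))
  cat(sprintf("  2D linear fit: slope = %.3f arcmin^2/s, intercept = %.4f arcmin^2\n",
              x$slope, x$intercept))
  invisible(x)
}

#' @export
plot.fem_msd <- function(x, ...) {
  graphics::plot(x$table$lag, x$table$msd_2d, type = "b",
                 xlab = "lag (s)", ylab = "MSD (arcmin^2)", ...)
  graphics::abline(x$intercept, x$slope, lty = 2)
  invisible(x)
}

#' Path length of a trajectory at the model time base
#'
#' Total amplitude of the stimulus trajectory with respect to the eye in a
#' trial: the sum of Euclidean distances between consecutive positions
#' resampled at \code{bin_dt} (the 50 ms bin the model consumes; finer
#' sampling would inflate path length with tracker noise).
#'
#' @param traj a \code{\link{fem_trajectory}}.
#' @param bin_dt resampling step in seconds (default 0.05).
#' @return path length in arcmin.
#' @export
path_length <- function(traj, bin_dt = 0.05) {
  stopifnot(inherits(traj, "fem_trajectory"))
  t0 <- traj$times[1]
  t1 <- traj$times[length(traj$times)]
  nb <- floor((t1 - t0) / bin_dt + 1e-9)
  tt <- t0 + (0:nb) * bin_dt
  xs <- stats::approx(traj$times, traj$xs, xout = tt)$y
  ys <- stats::approx(traj$times, traj$ys, xout = tt)$y
  sum(sqrt(diff(xs)^2 + diff(ys)^2))
}

#' End-to-end displacement length of a trajectory
#'
#' @param traj a \code{\link{fem_trajectory}}.
#' @return Euclidean distance between first and last positions, arcmin.
#' @export
end_to_end_length <- function(traj) {
  stopifnot(inherits(traj, "fem_trajectory"))
  n <- length(traj$xs)
  sqrt((traj$xs[n] - traj$xs[1])^2 + (traj$ys[n] - traj$ys[1])^2)
}

#' Autocorrelation of per-bin displacements
#'
#' Average autocorrelation of the per-bin displacement series at integer-bin
#' lags, over trajectories and both axes. Diffusive drift has independent
#' increments: autocorrelation ~0 at every lag >= 1.
#'
#' @param trajs a \code{\link{fem_trajectory}} or list thereof.
#' @param max_lag maximum lag in bins (default 8).
#' @return a data frame with columns \code{lag} (bins) and \code{acf}.
#' @export
displacement_autocorrelation <- function(trajs, max_lag = 8L) {
  if (inherits(trajs, "fem_trajectory")) trajs <- list(trajs)
  ## pooled (ensemble) estimator: demeaning and normalization use all
  ## displacements jointly, avoiding the O(1/n) bias of per-trajectory
  ## ACFs on short series
  series <- list()
  for (tr in trajs) {
    for (s in list(diff(tr$xs), diff(tr$ys))) {
      if (length(s) <= max_lag) stop("trajectory too short for max_lag")
      series[[length(series) + 1L]] <- s
    }
  }
  m <- mean(unlist(series))
  denom <- sum(vapply(series, function(s) sum((s - m)^2), 1))
  if (denom == 0) return(data.frame(lag = 0:max_lag,
                                    acf = c(1, rep(0, max_lag))))
  acf_k <- vapply(0:max_lag, function(k) {
    sum(vapply(series, function(s) {
      n <- length(s)
      sum((s[seq_len(n - k)] - m) * (s[seq_len(n - k) + k] - m))
    }, 1)) / denom
  }, 1)
  data.frame(lag = 0:max_lag, acf = acf_k)
}

#' Rank-based comparison of drift path lengths across stimulus sizes
#'
#' Kruskal-Wallis test of path length across stimulus-size bins (midrank
#' tie handling, as implemented by \code{\link[stats]{kruskal.test}}), with
#' per-bin medians; optionally one test per subject eye.
#'
#' @param trial_table a data frame with one row per trial containing at
#'   least \code{value_col} and \code{size_col} (and \code{subject_eye} for
#'   the per-eye variant).
#' @param value_col column holding the compared amplitude statistic
#'   (default \code{"path_length_arcmin"}).
#' @param size_col stimulus-size column (default \code{"stim_size_arcmin"});
#'   each distinct value is one bin.
#' @param by_subject if TRUE, return one test per \code{subject_eye}.
#' @return for the pooled test, a list of class \code{"path_length_test"}
#'   with \code{H}, \code{df}, \code{p.value}, \code{medians} and
#'   \code{n_per_bin}; for \code{by_subject = TRUE}, a named list of such
#'   objects.
#' @details Size bins with fewer than 2 trials are dropped with a warning;
#'   at least 2 bins must remain.
#' @export
compare_path_lengths_across_sizes <- function(trial_table,
                                              value_col = "path_length_arcmin",
                                              size_col = "stim_size_arcmin",
                                              by_subject = FALSE) {
  stopifnot(is.data.frame(trial_table),
            all(c(value_col, size_col) %in% names(trial_table)))
  if (by_subject) {
    stopifnot("subject_eye" %in% names(trial_table))
    return(lapply(split(trial_table, trial_table$subject_eye),
                  compare_path_lengths_across_sizes,
                  value_col = value_col, size_col = size_col))
  }
  value <- trial_table[[value_col]]
  size <- factor(trial_table[[size_col]])
  counts <- table(size)
  small <- names(counts)[counts < 2]
  if (length(small)) {
    warning("dropping size bins with < 2 trials: ",
            paste(small, collapse = ", "))
    keep <- !(as.character(size) %in% small)
    value <- value[keep]
    size <- droplevels(size[keep])
  }
  if (nlevels(size) < 2L) stop("need at least 2 size bins with >= 2 trials")
  kt <- stats::kruskal.test(value, size)
  structure(list(H = unname(kt$statistic), df = unname(kt$parameter),
                 p.value = kt$p.value,
                 medians = tapply(value, size, stats::median),
                 n_per_bin = as.vector(table(size))),
            class = "path_length_test")
}

#' @export
print.path_length_test <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis on path lengths across %d size bins\n",
              length(x$medians)))
  cat(sprintf("  H = %.2f, df = %d, p = %.3g\n", x$H, x$df, x$p.value))
  invisible(x)
}

#' Paired comparison of drift amplitude in consecutive trials with a size increase
#'
#' Within each subject eye, identifies consecutive trial pairs (by trial
#' order) in which the stimulus size increased, and compares the end-to-end
#' drift lengths after versus before with a paired Wilcoxon signed-rank
#' test. Distinguishes a stimulus-driven increase in drift amplitude from a
#' monotone time trend (e.g. fatigue), which would show a decrease on these
#' pairs when sizes shrink over a session.
#'
#' @param trial_table data frame with columns \code{subject_eye},
#'   \code{trial} (ordering), \code{stim_size_arcmin}, and \code{value_col}.
#' @param value_col amplitude column (default \code{"end_to_end_arcmin"}).
#' @return a list of class \code{"consecutive_trial_test"} with
#'   \code{n_pairs}, \code{mean_diff} (after - before), \code{direction}
#'   (\code{"increase"}, \code{"decrease"} or \code{"none"}) and
#'   \code{p.value} (NA when fewer than 2 pairs qualify).
#' @export
compare_consecutive_trials <- function(trial_table,
                                       value_col = "end_to_end_arcmin") {
  need <- c("subject_eye", "trial", "stim_size_arcmin", value_col)
  stopifnot(is.data.frame(trial_table), all(need %in% names(trial_table)))
  before <- after <- numeric(0)
  for (g in split(trial_table, trial_table$subject_eye)) {
    g <- g[order(g$trial), ]
    if (nrow(g) < 2L) next
    inc <- which(diff(g$stim_size_arcmin) > 0)
    before <- c(before, g[[value_col]][inc])
    after <- c(after, g[[value_col]][inc + 1L])
  }
  n_pairs <- length(before)
  if (n_pairs == 0L)
    return(structure(list(n_pairs = 0L, mean_diff = NA_real_,
                          direction = "none", p.value = NA_real_),
                     class = "consecutive_trial_test"))
  d <- after - before
  p <- if (n_pairs >= 2L && any(d != 0))
    stats::wilcox.test(after, before, paired = TRUE,
                       exact = FALSE)$p.value else NA_real_
  structure(list(n_pairs = n_pairs, mean_diff = mean(d),
                 direction = if (mean(d) > 0) "increase"
                             else if (mean(d) < 0) "decrease" else "none",
                 p.value = p),
            class = "consecutive_trial_test")
}

#' @export
print.consecutive_trial_test <- function(x, ...) {
  cat("Consecutive-trial comparison on size increases\n")
  if (x$n_pairs == 0L) {
    cat("  no qualifying pairs\n")
  } else {
    cat(sprintf("  %d pairs, mean after-before = %.3f arcmin (%s), p = %.3g\n",
                x$n_pairs, x$mean_diff, x$direction, x$p.value))
  }
  invisible(x)
}
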