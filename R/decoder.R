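## Recursive Bayesian ideal observer. The joint posterior over stimulus
## orientation lambda and latent grid position (x, y) is updated each bin:
##
##   P(lambda, x, y | spikes_{<=t}) = (1/Z_t) * sum_{x', y'}
##       P(sigma_t | lambda, x, y, x', y') T(x, y | x', y')
##       P(lambda, x', y' | spikes_{<=t-1})
##
## The likelihood is a product of per-cell Poisson pmfs whose means depend
## on the current AND previous position through the temporal kernel; the
## transition matrix T is the truncated drift kernel. The observer knows
## the drift statistics (D) but not the trajectory. All recursions run in
## the log domain with max-shift; a rate floor keeps log-likelihoods
## finite when a rectified rate hits zero.

#' Decoder configuration
#'
#' Bundles everything the ideal observer needs: the overlap tables for the
#' four orientations, the drift transition kernel (built from the same D
#' convention as the generator when matched-model decoding is intended),
#' and the RGC rate parameters.
#'
#' @param mosaic an \code{\link{rgc_mosaic}}.
#' @param rasters list of four \code{\link{stimulus_raster}} objects (one
#'   per orientation), e.g. from \code{\link{render_E_set}}.
#' @param kernel a \code{\link{transition_kernel}}.
#' @param grid_extent grid positions per axis (default 31).
#' @param rate_floor minimum rate in Hz used inside likelihoods
#'   (default 1e-6) so a zero rectified rate cannot produce -Inf.
#' @return an object of class \code{"decoder_config"}.
#' @export
decoder_config <- function(mosaic, rasters, kernel, grid_extent = 31L,
                           rate_floor = 1e-6) {
  stopifnot(inherits(mosaic, "rgc_mosaic"),
            inherits(kernel, "transition_kernel"),
            is.list(rasters), length(rasters) == 4L, rate_floor > 0)
  ext <- as.integer(grid_extent)
  otables <- overlap_table(mosaic, rasters, ext)
  cfg <- structure(list(mosaic = mosaic, rasters = rasters, kernel = kernel,
                        otables = otables, grid_extent = ext,
                        rate_floor = rate_floor,
                        orientations = dimnames(otables)[[4]],
                        cache = new.env(parent = emptyenv())),
                   class = "decoder_config")
  cfg
}

#' @export
print.decoder_config <- function(x, ...) {
  cat(sprintf("Ideal-observer decoder config: %d orientations x %d x %d positions, %d cells\n",
              dim(x$otables)[4], x$grid_extent, x$grid_extent,
              dim(x$otables)[3]))
  cat(sprintf("  D = %g arcmin^2/s (kernel radius %d), rate floor %g Hz\n",
              x$kernel$params$D, x$kernel$params$kernel_radius, x$rate_floor))
  invisible(x)
}

#' Flat initial posterior
#'
#' Uniform joint distribution over orientations and grid positions (no
#' prior knowledge about the stimulus); accumulated log normalizer 0.
#'
#' @param grid_extent grid positions per axis.
#' @param orientations character vector of orientation labels (default the
#'   four E orientations).
#' @return an object of class \code{"posterior_state"}: \code{probs}
#'   (array n_orient x extent x extent summing to 1) and \code{log_norm}.
#' @export
init_posterior <- function(grid_extent,
                           orientations = stimulus_orientations) {
  ext <- as.integer(grid_extent)
  no <- length(orientations)
  probs <- array(1 / (no * ext * ext), dim = c(no, ext, ext),
                 dimnames = list(orientations, NULL, NULL))
  structure(list(probs = probs, log_norm = 0), class = "posterior_state")
}

#' @export
print.posterior_state <- function(x, ...) {
  marg <- apply(x$probs, 1L, sum)
  cat("Posterior state (orientation marginal):\n")
  print(round(marg, 4))
  cat(sprintf("  accumulated log normalizer: %.4f\n", x$log_norm))
  invisible(x)
}

#' Joint log-likelihood of one bin's spikes for a hypothesis pair
#'
#' Sum over cells of the Poisson log-pmf with mean
#' \code{rate_i(lambda, pos, prev_pos) * dt}, where the rate uses the
#' overlap at \code{pos} as current drive and at \code{prev_pos} as the
#' temporal-kernel subtrahend. \code{prev_pos = NULL} means the blank
#' pre-stimulus frame (overlap 0), used for the first bin.
#'
#' @param spikes_t integer vector of per-cell counts in the bin.
#' @param otables 4D overlap array from \code{\link{overlap_table}}.
#' @param params an \code{\link{rgc_params}} object.
#' @param lambda orientation index (into the 4th margin of
#'   \code{otables}).
#' @param pos,prev_pos integer length-2 grid indices \code{c(ix, iy)}.
#' @param rate_floor minimum rate in Hz (default 1e-6).
#' @return the scalar log-likelihood.
#' @export
pair_log_likelihood <- function(spikes_t, otables, params, lambda, pos,
                                prev_pos = NULL, rate_floor = 1e-6) {
  O_now <- otables[pos[1], pos[2], , lambda]
  O_prev <- if (is.null(prev_pos)) 0 else otables[prev_pos[1], prev_pos[2], , lambda]
  rate <- pmax(rate_floor, firing_rate(params, O_now, O_prev))
  sum(stats::dpois(spikes_t, rate * params$dt, log = TRUE))
}

## Pure-R reference update (readable; O(n_orient * n_pos * K * n_cells)).
## The Rcpp path in run_decoder() is the production route; tests assert
## their equality.

#' One recursive Bayesian update of the posterior
#'
#' Reference implementation of the per-bin update: for each orientation and
#' position, sums likelihood x transition x prior over the truncated
#' transition support (cyclic index wrapping), then renormalizes. Runs in
#' the log domain with max-shift. Intended for small grids and validation;
#' \code{\link{run_decoder}} uses an equivalent compiled path.
#'
#' @param state a \code{\link{init_posterior}} state.
#' @param spikes_t integer vector of per-cell counts for the bin.
#' @param config a \code{\link{decoder_config}}.
#' @param first_bin if TRUE, the likelihood conditions on the blank
#'   pre-stimulus frame instead of the previous position.
#' @return the updated \code{"posterior_state"} (renormalized;
#'   \code{log_norm} accumulates log Z_t).
#' @export
update_posterior <- function(state, spikes_t, config, first_bin = FALSE) {
  stopifnot(inherits(state, "posterior_state"),
            inherits(config, "decoder_config"))
  ext <- config$grid_extent
  no <- dim(config$otables)[4]
  ker <- config$kernel
  params <- config$mosaic$params
  dt <- params$dt
  floor_rate <- config$rate_floor
  lp <- log(state$probs)
  K <- length(ker$dx)
  logw <- array(-Inf, dim = c(no, ext, ext))
  for (l in seq_len(no)) {
    Onow <- matrix(config$otables[, , , l], ext * ext,
                   dim(config$otables)[3])
    terms <- array(-Inf, dim = c(ext, ext, K * K))
    k <- 0L
    for (a in seq_len(K)) {
      sx <- wrap_index(seq_len(ext) - ker$dx[a], ext)
      for (b in seq_len(K)) {
        k <- k + 1L
        if (ker$probs[a, b] <= 0) next
        sy <- wrap_index(seq_len(ext) - ker$dy[b], ext)
        ll <- matrix(0, ext, ext)
        for (ix in seq_len(ext)) for (iy in seq_len(ext)) {
          prev <- if (first_bin) NULL else c(sx[ix], sy[iy])
          ll[ix, iy] <- pair_log_likelihood(spikes_t, config$otables,
                                            params, l, c(ix, iy), prev,
                                            floor_rate)
        }
        prior_shift <- matrix(lp[l, , ][sx, sy], ext, ext)
        terms[, , k] <- ll + log(ker$probs[a, b]) + prior_shift
      }
    }
    mx <- apply(terms, c(1, 2), max)
    s <- apply(exp(sweep(terms, c(1, 2), mx, "-")), c(1, 2), sum)
    logw[l, , ] <- mx + log(s)
  }
  m <- max(logw)
  un <- exp(logw - m)
  z <- sum(un)
  if (!is.finite(m) || z <= 0)
    stop("posterior mass vanished; check the rate floor configuration")
  structure(list(probs = un / z, log_norm = state$log_norm + m + log(z)),
            class = "posterior_state")
}

#' Orientation decision from a posterior
#'
#' Argmax over orientations of the position-marginal posterior; ties are
#' broken uniformly at random with the current RNG stream.
#'
#' @param state a \code{"posterior_state"}.
#' @return the winning orientation label (character).
#' @export
classify <- function(state) {
  stopifnot(inherits(state, "posterior_state"))
  marg <- apply(state$probs, 1L, sum)
  classify_marginal(marg)
}

classify_marginal <- function(marg) {
  mx <- max(marg)
  ties <- which(marg >= mx * (1 - 1e-12))
  pick <- if (length(ties) > 1L) ties[sample.int(length(ties), 1L)] else ties
  names(marg)[pick]
}

#' Run the ideal observer over a spike train
#'
#' Sequential Bayesian updates over all bins, recording the orientation
#' marginal and the decision at each requested decision time (default:
#' every bin). Uses the compiled recursion; \code{engine = "r"} forces the
#' reference implementation in \code{\link{update_posterior}}.
#'
#' @param spike_train a \code{\link{simulate_trial}} result (binned at the
#'   configured \code{dt}).
#' @param config a \code{\link{decoder_config}}.
#' @param decision_times times (s) at which to record decisions; default
#'   every bin.
#' @param seed optional integer seed (only consumed by tie-breaking).
#' @param engine \code{"cpp"} (default) or \code{"r"}.
#' @return an object of class \code{"decoder_result"}:
#'   \code{lambda_marginals} (n_orient x n_bins), \code{decisions}
#'   (character, one per decision time), \code{decision_times},
#'   \code{log_evidence} (accumulated log normalizer per bin), and
#'   \code{final} (the final \code{"posterior_state"}).
#' @export
run_decoder <- function(spike_train, config, decision_times = NULL,
                        seed = NULL, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(spike_train, "spike_train"),
            inherits(config, "decoder_config"))
  params <- config$mosaic$params
  if (abs(spike_train$dt - params$dt) > 1e-12)
    stop("spike train dt (", spike_train$dt,
         ") does not match the decoder dt (", params$dt, ")")
  nb <- spike_train$n_bins
  dt <- params$dt
  if (is.null(decision_times)) decision_times <- seq_len(nb) * dt
  dec_bins <- as.integer(round(decision_times / dt))
  stopifnot(all(dec_bins >= 1L), all(dec_bins <= nb))
  ext <- config$grid_extent
  no <- length(config$orientations)

  if (engine == "cpp") {
    ptr <- decoder_tables_ptr(config)
    res <- decode_spikes_cpp(ptr, spike_train$counts)
    marg <- res$marginals
    ## compiled layout is (position-within-orientation) fastest
    final_probs <- aperm(array(res$final, dim = c(ext, ext, no)), c(3, 1, 2))
    dimnames(final_probs) <- list(config$orientations, NULL, NULL)
    log_ev <- res$log_norm
  } else {
    state <- init_posterior(ext, config$orientations)
    marg <- matrix(0, no, nb)
    log_ev <- numeric(nb)
    for (t in seq_len(nb)) {
      state <- update_posterior(state, spike_train$counts[, t], config,
                                first_bin = (t == 1L))
      marg[, t] <- apply(state$probs, 1L, sum)
      log_ev[t] <- state$log_norm
    }
    final_probs <- state$probs
  }
  rownames(marg) <- config$orientations
  decisions <- with_seed(seed, vapply(dec_bins, function(b)
    classify_marginal(marg[, b]), ""))
  structure(list(lambda_marginals = marg, decisions = decisions,
                 decision_times = dec_bins * dt, log_evidence = log_ev,
                 final = structure(list(probs = final_probs,
                                        log_norm = log_ev[nb]),
                                   class = "posterior_state")),
            class = "decoder_result")
}

#' @export
print.decoder_result <- function(x, ...) {
  nb <- ncol(x$lambda_marginals)
  cat(sprintf("Ideal-observer decoding over %d bins\n", nb))
  cat(sprintf("  final decision: %s (marginal %.3f)\n",
              x$decisions[length(x$decisions)],
              max(x$lambda_marginals[, nb])))
  invisible(x)
}

#' @export
plot.decoder_result <- function(x, ...) {
  graphics::matplot(x$decision_times, t(x$lambda_marginals), type = "l",
                    lty = 1, xlab = "time (s)",
                    ylab = "orientation marginal", ...)
  graphics::legend("topleft", rownames(x$lambda_marginals), lty = 1,
                   col = seq_len(nrow(x$lambda_marginals)), bty = "n")
  invisible(x)
}

## Build (or fetch) the compiled decoder tables for a config.
decoder_tables_ptr <- function(config) {
  ptr <- config$cache$ptr
  if (!is.null(ptr) && !cpp_ptr_is_null(ptr)) return(ptr)
  ker <- config$kernel
  off <- as.matrix(expand.grid(dx = ker$dx, dy = ker$dy))
  pr <- as.vector(ker$probs)
  keep <- pr > 0
  params <- config$mosaic$params
  ptr <- build_decoder_tables_cpp(
    as.numeric(config$otables), config$grid_extent, config$grid_extent,
    dim(config$otables)[3], dim(config$otables)[4],
    off[keep, 1], off[keep, 2], log(pr[keep]),
    params$r0, params$dr, params$w, params$contrast_scale, params$dt,
    config$rate_floor)
  config$cache$ptr <- ptr
  ptr
}
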