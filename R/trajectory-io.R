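## Trajectory CSV dialect: one long table, one row per sample, grouped into
## trials by (subject_eye, trial). Required columns: subject_eye, trial, t_s,
## x_arcmin, y_arcmin. Optional metadata columns: stim_size_arcmin,
## stim_orientation, correct.

trajectory_required_cols <- c("subject_eye", "trial", "t_s",
                              "x_arcmin", "y_arcmin")
trajectory_meta_cols <- c("stim_size_arcmin", "stim_orientation", "correct")

#' Write drift trajectories to a CSV file
#'
#' @param trajs a list of \code{\link{fem_trajectory}} objects. Metadata
#'   fields \code{subject_eye}, \code{trial}, \code{stim_size_arcmin},
#'   \code{stim_orientation} and \code{correct} are written when present;
#'   missing \code{subject_eye}/\code{trial} default to \code{"s1"} and the
#'   list index.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_trajectories <- function(trajs, path) {
  stopifnot(is.list(trajs))
  rows <- lapply(seq_along(trajs), function(i) {
    tr <- trajs[[i]]
    stopifnot(inherits(tr, "fem_trajectory"))
    m <- tr$meta
    data.frame(
      subject_eye = if (!is.null(m$subject_eye)) m$subject_eye else "s1",
      trial = if (!is.null(m$trial)) m$trial else i,
      t_s = tr$times, x_arcmin = tr$xs, y_arcmin = tr$ys,
      stim_size_arcmin = if (!is.null(m$stim_size_arcmin))
        m$stim_size_arcmin else NA_real_,
      stim_orientation = if (!is.null(m$stim_orientation))
        m$stim_orientation else NA_character_,
      correct = if (!is.null(m$correct)) m$correct else NA,
      stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read drift trajectories from a CSV file
#'
#' Parses the trajectory CSV dialect written by
#' \code{\link{write_trajectories}}. Trials containing non-finite
#' coordinates are excluded with a warning naming the offending line
#' numbers; an empty file yields an empty list with a warning.
#'
#' @param path input file path.
#' @return a list of \code{\link{fem_trajectory}} objects, one per
#'   (subject_eye, trial) group, in file order.
#' @export
read_trajectories <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    warning("no trajectory rows in ", path)
    return(list())
  }
  missing_cols <- setdiff(trajectory_required_cols, names(df))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  for (cc in c("t_s", "x_arcmin", "y_arcmin")) {
    if (!is.numeric(df[[cc]]))
      stop("column ", cc, " is not numeric")
  }
  key <- paste(df$subject_eye, df$trial, sep = "\r")
  groups <- split(seq_len(nrow(df)), factor(key, levels = unique(key)))
  out <- list()
  for (idx in groups) {
    g <- df[idx, ]
    bad <- !is.finite(g$t_s) | !is.finite(g$x_arcmin) | !is.finite(g$y_arcmin)
    if (any(bad)) {
      ## +1 for the header line
      warning(sprintf(
        "trial %s/%s dropped: non-finite coordinates at line(s) %s",
        g$subject_eye[1], g$trial[1],
        paste(idx[bad] + 1L, collapse = ", ")))
      next
    }
    meta <- list(subject_eye = g$subject_eye[1], trial = g$trial[1])
    for (mc in trajectory_meta_cols) {
      if (mc %in% names(g) && !all(is.na(g[[mc]]))) meta[[mc]] <- g[[mc]][1]
    }
    out[[length(out) + 1L]] <- fem_trajectory(g$t_s, g$x_arcmin, g$y_arcmin,
                                              meta = meta)
  }
  out
}
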