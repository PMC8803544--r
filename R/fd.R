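#' Compute framewise displacement (FD)
#'
#' FD at frame t is the sum of absolute frame-to-frame differences of the
#' six realignment parameters, with the three rotations converted to arc
#' length at a head radius before summing:
#' \deqn{FD_t = \sum_{i\in trans} |\Delta p_i(t)| + r \sum_{i\in rot} |\Delta\theta_i(t)|}
#' The first frame has no predecessor and is assigned FD = 0, so it is
#' always eligible for retention on FD grounds alone.
#'
#' The default radius of 35 mm is an infant/toddler head size; use 50 mm
#' for comparability with adult pipelines.
#'
#' @param trace a [motion_trace()].
#' @param radius_mm head radius in mm used for the rotation conversion.
#' @param filtered flag recorded on the result (set by [apply_notch()]
#'   pipelines).
#' @return an [fd_trace()].
#' @export
compute_fd <- function(trace, radius_mm = 35, filtered = FALSE) {
  stopifnot(inherits(trace, "motion_trace"))
  if (!is.numeric(radius_mm) || radius_mm <= 0)
    stop("radius_mm must be positive")
  if (!all(is.finite(trace$params)))
    stop("non-finite values in motion parameters")
  d <- abs(diff(trace$params))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
               radius_mm * rowSums(d[, 4:6, drop = FALSE]))
  fd_trace(fd, tr_s = trace$tr_s, filtered = filtered, radius_mm = radius_mm)
}

#' Compute DVARS from a parcel timeseries
#'
#' DVARS at frame t is the spatial root mean square of the temporal
#' derivative: `sqrt(mean((x[t, ] - x[t - 1, ])^2))`, with DVARS = 0 at the
#' first frame. Computed on parcel signals in their native units (no
#' normalization).
#'
#' @param ts a [parcel_timeseries()].
#' @return numeric length-T vector.
#' @export
compute_dvars <- function(ts) {
  stopifnot(inherits(ts, "parcel_timeseries"))
  if (ncol(ts$data) == 0L) stop("timeseries has no parcels")
  c(0, sqrt(rowMeans(diff(ts$data)^2)))
}

#' Build a grayplot-style QC panel
#'
#' Bundles the standard per-run quality-control views: the FD trace, DVARS,
#' the global (mean across parcels) signal, and a parcels x time matrix of
#' per-parcel z-scored intensities (the "grayplot"). Spontaneous motion
#' shows up as a vertical stripe in the grayplot co-located with FD and
#' DVARS spikes; respiratory FD oscillation does not.
#'
#' @param ts a [parcel_timeseries()].
#' @param trace the matching [motion_trace()] (same number of frames).
#' @param radius_mm head radius for FD.
#' @return a list of class `qc_panel` with elements `fd` ([fd_trace()]),
#'   `dvars`, `global_signal`, and `gray_matrix` (P x T).
#' @export
build_qc_panel <- function(ts, trace, radius_mm = 35) {
  stopifnot(inherits(ts, "parcel_timeseries"), inherits(trace, "motion_trace"))
  if (nrow(ts$data) != nrow(trace$params))
    stop("timeseries and motion trace differ in frame count")
  z <- scale(ts$data)
  flat <- attr(z, "scaled:scale") == 0 | !is.finite(attr(z, "scaled:scale"))
  if (any(flat)) {
    z[, flat] <- 0
    message(sum(flat), " zero-variance parcel(s); z-scores set to 0")
  }
  structure(list(fd = compute_fd(trace, radius_mm = radius_mm),
                 dvars = compute_dvars(ts),
                 global_signal = rowMeans(ts$data),
                 gray_matrix = t(z)),
            class = "qc_panel")
}
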