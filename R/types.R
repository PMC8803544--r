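# Canonical units throughout: mm (translations), radians (rotations),
# seconds (time); conversion happens once, at ingest.
MOTION_COLS <- c("trans_x", "trans_y", "trans_z",
                 "rot_pitch", "rot_yaw", "rot_roll")

#' Construct a rigid-body motion trace
#'
#' A `motion_trace` holds the six realignment parameters per volume:
#' translations along x, y, z (mm) followed by rotations pitch, yaw, roll
#' (radians), plus the sampling interval and which axis is the phase-encode
#' direction (where respiratory artifact concentrates).
#'
#' @param params numeric T x 6 matrix, columns
#'   `trans_x, trans_y, trans_z, rot_pitch, rot_yaw, rot_roll`
#'   (mm / radians).
#' @param tr_s repetition time (sampling interval) in seconds.
#' @param phase_axis phase-encode axis, one of `"x"`, `"y"`, `"z"`.
#' @param subject_id,run_id opaque labels.
#' @return object of class `motion_trace`.
#' @export
motion_trace <- function(params, tr_s, phase_axis = "y",
                         subject_id = NA_character_, run_id = NA_character_) {
  params <- as.matrix(params)
  if (ncol(params) != 6L) stop("params must have exactly 6 columns")
  if (nrow(params) < 2L) stop("a motion trace needs at least 2 frames")
  if (!all(is.finite(params))) stop("non-finite values in motion parameters")
  if (!is.numeric(tr_s) || length(tr_s) != 1L || tr_s <= 0)
    stop("tr_s must be a positive scalar (seconds)")
  phase_axis <- match.arg(phase_axis, c("x", "y", "z"))
  colnames(params) <- MOTION_COLS
  structure(list(params = params, tr_s = tr_s, phase_axis = phase_axis,
                 subject_id = subject_id, run_id = run_id),
            class = "motion_trace")
}

#' @export
print.motion_trace <- function(x, ...) {
  cat(sprintf("<motion_trace> %d frames, TR %.3g s, phase axis %s\n",
              nrow(x$params), x$tr_s, x$phase_axis))
  invisible(x)
}

n_frames <- function(x) UseMethod("n_frames")
#' @export
n_frames.motion_trace <- function(x) nrow(x$params)
#' @export
n_frames.parcel_timeseries <- function(x) nrow(x$data)
#' @export
n_frames.fd_trace <- function(x) length(x$fd_mm)

#' Construct a framewise-displacement trace
#'
#' @param fd_mm numeric vector of per-frame displacements (mm); the first
#'   entry is 0 by convention (no predecessor frame).
#' @param tr_s repetition time in seconds.
#' @param filtered logical: was the motion trace band-stop filtered before
#'   FD computation?
#' @param radius_mm head radius used to convert rotations to arc length.
#' @return object of class `fd_trace`.
#' @export
fd_trace <- function(fd_mm, tr_s, filtered = FALSE, radius_mm = 35) {
  fd_mm <- as.numeric(fd_mm)
  if (!all(is.finite(fd_mm)) || any(fd_mm < 0))
    stop("fd_mm must be finite and non-negative")
  if (fd_mm[1L] != 0) stop("fd_mm[1] must be 0 (no predecessor frame)")
  structure(list(fd_mm = fd_mm, tr_s = tr_s, filtered = isTRUE(filtered),
                 radius_mm = radius_mm),
            class = "fd_trace")
}

#' @export
print.fd_trace <- function(x, ...) {
  cat(sprintf("<fd_trace> %d frames, mean FD %.4f mm (%s)\n",
              length(x$fd_mm), mean(x$fd_mm),
              if (x$filtered) "filtered" else "unfiltered"))
  invisible(x)
}

#' Construct a parcellated BOLD timeseries
#'
#' @param data numeric T x P matrix of parcel-mean BOLD signals.
#' @param parcel_ids length-P character labels (defaults to column names).
#' @param network_of named character vector mapping every parcel id to a
#'   resting-state network label (an explicit `"unassigned"` label is fine).
#' @param tr_s repetition time in seconds.
#' @return object of class `parcel_timeseries`.
#' @export
parcel_timeseries <- function(data, parcel_ids = colnames(data), network_of,
                              tr_s) {
  data <- as.matrix(data)
  if (ncol(data) < 1L) stop("timeseries must contain at least one parcel")
  if (is.null(parcel_ids)) parcel_ids <- paste0("p", seq_len(ncol(data)))
  parcel_ids <- as.character(parcel_ids)
  if (length(parcel_ids) != ncol(data))
    stop("parcel_ids length must equal number of columns")
  missing <- setdiff(parcel_ids, names(network_of))
  if (length(missing))
    stop("parcels missing from network map: ", paste(missing, collapse = ", "))
  if (!is.numeric(tr_s) || tr_s <= 0) stop("tr_s must be positive")
  colnames(data) <- parcel_ids
  structure(list(data = data, parcel_ids = parcel_ids,
                 network_of = network_of[parcel_ids], tr_s = tr_s),
            class = "parcel_timeseries")
}

#' @export
print.parcel_timeseries <- function(x, ...) {
  cat(sprintf("<parcel_timeseries> %d frames x %d parcels, %d networks\n",
              nrow(x$data), ncol(x$data), length(unique(x$network_of))))
  invisible(x)
}

#' Construct a frame retention mask
#'
#' @param keep logical vector: TRUE for frames retained.
#' @param threshold_mm FD censoring threshold that produced the mask.
#' @param source `"unfiltered"` or `"filtered"`: which FD trace was
#'   thresholded.
#' @return object of class `frame_mask`.
#' @export
frame_mask <- function(keep, threshold_mm, source = c("unfiltered", "filtered")) {
  keep <- as.logical(keep)
  if (anyNA(keep)) stop("keep must not contain NA")
  if (threshold_mm <= 0) stop("threshold_mm must be positive")
  structure(list(keep = keep, threshold_mm = threshold_mm,
                 source = match.arg(source)),
            class = "frame_mask")
}

#' @export
print.frame_mask <- function(x, ...) {
  cat(sprintf("<frame_mask> %d/%d frames kept (FD <= %.3g mm, %s)\n",
              sum(x$keep), length(x$keep), x$threshold_mm, x$source))
  invisible(x)
}
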