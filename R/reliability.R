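#' Split usable frames into two equal temporal halves
#'
#' Usable frames (FD at or below threshold) are enumerated in acquisition
#' order across the concatenated runs; the first `floor(U/2)` form half 1
#' and the next `floor(U/2)` half 2 (an odd last frame is dropped), so
#' both halves hold equal amounts of data at every threshold.
#'
#' @param runs ordered list of runs, each a list with elements `ts`
#'   ([parcel_timeseries()]) and `fd` ([fd_trace()]) of matching length.
#' @param threshold_mm FD threshold defining usable frames.
#' @param split `"temporal"` (default) or `"odd_even"` (alternate usable
#'   frames between halves, for sensitivity checks).
#' @return list of class `split_half`: `half1`, `half2` (data.frames with
#'   columns `run`, `frame`), `n_usable`, `threshold_mm`.
#' @export
split_half <- function(runs, threshold_mm, split = c("temporal", "odd_even")) {
  split <- match.arg(split)
  stopifnot(length(runs) >= 1L)
  usable <- do.call(rbind, lapply(seq_along(runs), function(i) {
    r <- runs[[i]]
    if (length(r$fd$fd_mm) != nrow(r$ts$data))
      stop("run ", i, ": FD trace and timeseries differ in length")
    f <- which(r$fd$fd_mm <= threshold_mm)
    if (length(f)) data.frame(run = i, frame = f) else NULL
  }))
  u <- if (is.null(usable)) 0L else nrow(usable)
  h <- u %/% 2L
  if (h < 1L)
    stop(sprintf("insufficient usable frames (%d) at threshold %.3g mm",
                 u, threshold_mm))
  pick <- if (split == "temporal") {
    list(h1 = seq_len(h), h2 = h + seq_len(h))
  } else {
    list(h1 = seq(1L, 2L * h, by = 2L), h2 = seq(2L, 2L * h, by = 2L))
  }
  structure(list(half1 = usable[pick$h1, , drop = FALSE],
                 half2 = usable[pick$h2, , drop = FALSE],
                 n_usable = u, threshold_mm = threshold_mm),
            class = "split_half")
}

upper_tri_vec <- function(m) m[upper.tri(m)]

half_fc_vector <- function(runs, half, min_frames) {
  # concatenate retained frames across runs, correlate
  mats <- lapply(unique(half$run), function(i)
    runs[[i]]$ts$data[half$frame[half$run == i], , drop = FALSE])
  x <- do.call(rbind, mats)
  if (nrow(x) < min_frames) return(NULL)
  r <- suppressWarnings(cor(x))
  r[!is.finite(r)] <- 0
  upper_tri_vec(r)
}

#' Split-half reliability of connectivity across FD thresholds
#'
#' For each threshold and each subject: usable frames are split into two
#' equal halves ([split_half()]), a connectivity matrix is computed per
#' half, and the two upper-triangle vectors are Pearson-correlated (the
#' "spatial correlation"). The curve reports the across-subject mean, SD,
#' and SE of that correlation per threshold, for the chosen FD arm.
#' Subjects whose halves fall below `min_frames` retained frames are
#' excluded at that threshold; thresholds with fewer than 2 surviving
#' subjects are marked missing.
#'
#' @param subjects list of subjects; each subject is a list of runs as in
#'   [split_half()], with per-run elements `ts`, `fd_unfiltered`,
#'   `fd_filtered`.
#' @param thresholds_mm ascending FD threshold grid (default 0.05--0.5 mm
#'   in 0.05 steps).
#' @param arm `"filtered"` or `"unfiltered"`: which FD trace defines
#'   usable frames.
#' @param min_frames minimum frames per half (default 10).
#' @param split passed to [split_half()].
#' @return object of class `reliability_curve`: data.frame-like list with
#'   `thresholds_mm`, `mean_r`, `sd_r`, `se_r`, `n_subjects`, `arm`.
#' @export
reliability_curve <- function(subjects, thresholds_mm = seq(0.05, 0.5, 0.05),
                              arm = c("filtered", "unfiltered"),
                              min_frames = 10L,
                              split = "temporal") {
  arm <- match.arg(arm)
  if (is.unsorted(thresholds_mm, strictly = TRUE))
    stop("thresholds_mm must be strictly ascending")
  fd_field <- paste0("fd_", arm)
  mean_r <- sd_r <- se_r <- rep(NA_real_, length(thresholds_mm))
  n_sub <- integer(length(thresholds_mm))
  for (k in seq_along(thresholds_mm)) {
    thr <- thresholds_mm[k]
    rs <- c()
    for (sub in subjects) {
      runs <- lapply(sub, function(r) list(ts = r$ts, fd = r[[fd_field]]))
      sh <- tryCatch(split_half(runs, thr, split = split),
                     error = function(e) NULL)
      if (is.null(sh)) next
      v1 <- half_fc_vector(runs, sh$half1, min_frames)
      v2 <- half_fc_vector(runs, sh$half2, min_frames)
      if (is.null(v1) || is.null(v2)) next
      if (sd(v1) == 0 || sd(v2) == 0) next
      rs <- c(rs, cor(v1, v2))
    }
    n_sub[k] <- length(rs)
    if (length(rs) >= 2L) {
      mean_r[k] <- mean(rs)
      sd_r[k] <- sd(rs)
      se_r[k] <- sd_r[k] / sqrt(length(rs))
    }
  }
  structure(list(thresholds_mm = thresholds_mm, mean_r = mean_r,
                 sd_r = sd_r, se_r = se_r, n_subjects = n_sub, arm = arm),
            class = "reliability_curve")
}

#' @export
print.reliability_curve <- function(x, ...) {
  cat(sprintf("<reliability_curve> arm %s\n", x$arm))
  print(data.frame(threshold_mm = x$thresholds_mm, mean_r = round(x$mean_r, 3),
                   sd_r = round(x$sd_r, 3), n = x$n_subjects))
  invisible(x)
}
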