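#' Censor frames by FD threshold
#'
#' Frames whose FD exceeds the threshold are censored; frames at or below
#' it are retained (the measure-zero boundary case is assigned to
#' retention). The conventional threshold is 0.2 mm.
#'
#' @param fd an [fd_trace()].
#' @param threshold_mm censoring threshold (mm), default 0.2.
#' @return a [frame_mask()].
#' @export
censor <- function(fd, threshold_mm = 0.2) {
  stopifnot(inherits(fd, "fd_trace"))
  if (threshold_mm <= 0) stop("threshold_mm must be positive")
  frame_mask(fd$fd_mm <= threshold_mm, threshold_mm = threshold_mm,
             source = if (fd$filtered) "filtered" else "unfiltered")
}

#' Usable-data retention before vs after motion filtering
#'
#' Censors the unfiltered and filtered FD traces at the same threshold and
#' reports retained minutes for each (`kept_frames * tr_s / 60`, unrounded).
#' On respiration-dominated runs filtering moves the respiratory FD
#' oscillation below threshold, so `minutes_filtered` exceeds
#' `minutes_unfiltered`; spontaneous-motion spikes remain censored.
#'
#' @param fd_unf unfiltered [fd_trace()].
#' @param fd_fil filtered [fd_trace()] from the same run(s), same length
#'   and TR.
#' @param threshold_mm censoring threshold (mm).
#' @param subject_id optional label.
#' @return object of class `retention_report`: `subject_id`,
#'   `minutes_unfiltered`, `minutes_filtered`, `frames_total`,
#'   `frames_kept_unfiltered`, `frames_kept_filtered`, `threshold_mm`,
#'   `tr_s`.
#' @export
retention <- function(fd_unf, fd_fil, threshold_mm = 0.2,
                      subject_id = fd_unf$subject_id) {
  stopifnot(inherits(fd_unf, "fd_trace"), inherits(fd_fil, "fd_trace"))
  if (length(fd_unf$fd_mm) != length(fd_fil$fd_mm))
    stop("FD traces differ in length")
  if (abs(fd_unf$tr_s - fd_fil$tr_s) > 1e-12)
    stop("FD traces differ in TR")
  ku <- sum(censor(fd_unf, threshold_mm)$keep)
  kf <- sum(censor(fd_fil, threshold_mm)$keep)
  structure(list(subject_id = if (is.null(subject_id)) NA_character_ else subject_id,
                 minutes_unfiltered = ku * fd_unf$tr_s / 60,
                 minutes_filtered = kf * fd_fil$tr_s / 60,
                 frames_total = length(fd_unf$fd_mm),
                 frames_kept_unfiltered = ku,
                 frames_kept_filtered = kf,
                 threshold_mm = threshold_mm,
                 tr_s = fd_unf$tr_s),
            class = "retention_report")
}

#' @export
print.retention_report <- function(x, ...) {
  cat(sprintf(paste0("<retention_report> %s: %.2f -> %.2f usable min ",
                     "(of %.2f) at FD <= %.3g mm\n"),
              x$subject_id, x$minutes_unfiltered, x$minutes_filtered,
              x$frames_total * x$tr_s / 60, x$threshold_mm))
  invisible(x)
}

#' Aggregate retention reports across a cohort
#'
#' @param reports list of [retention()] results.
#' @return data.frame with per-arm mean and SD of usable minutes plus the
#'   per-subject table as attribute `"per_subject"`.
#' @export
retention_summary <- function(reports) {
  mu <- vapply(reports, `[[`, numeric(1), "minutes_unfiltered")
  mf <- vapply(reports, `[[`, numeric(1), "minutes_filtered")
  per <- data.frame(
    subject_id = vapply(reports, function(r) as.character(r$subject_id),
                        character(1)),
    minutes_unfiltered = mu, minutes_filtered = mf)
  out <- data.frame(arm = c("unfiltered", "filtered"),
                    mean_minutes = c(mean(mu), mean(mf)),
                    sd_minutes = c(sd(mu), sd(mf)),
                    n_subjects = length(reports))
  attr(out, "per_subject") <- per
  out
}
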