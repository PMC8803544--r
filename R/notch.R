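#' Specify a band-stop (notch) filter
#'
#' @param lo_hz,hi_hz stopband edges (Hz), `0 < lo < hi`.
#' @param center_hz notch center; defaults to the midpoint of `(lo, hi)`.
#' @param family `"butterworth_bandstop"` (default) or `"iir_notch"` (a
#'   second-order notch biquad parameterized by center and bandwidth). The
#'   two families are interchangeable in practice; both are provided
#'   because both are in common institutional use.
#' @param order filter order (Butterworth prototype order; the biquad is
#'   always second order).
#' @param zero_phase apply forward-backward so the filtered trace stays
#'   frame-aligned with censoring (default TRUE).
#' @param label optional display label.
#' @return object of class `notch_spec`.
#' @export
notch_spec <- function(lo_hz, hi_hz, center_hz = (lo_hz + hi_hz) / 2,
                       family = c("butterworth_bandstop", "iir_notch"),
                       order = 2L, zero_phase = TRUE, label = NULL) {
  family <- match.arg(family)
  if (!(0 < lo_hz && lo_hz < center_hz && center_hz < hi_hz))
    stop("need 0 < lo_hz < center_hz < hi_hz")
  if (order < 1L) stop("order must be >= 1")
  if (is.null(label)) label <- sprintf("%.3g-%.3g Hz", lo_hz, hi_hz)
  structure(list(center_hz = center_hz, lo_hz = lo_hz, hi_hz = hi_hz,
                 family = family, order = as.integer(order),
                 zero_phase = isTRUE(zero_phase), label = label),
            class = "notch_spec")
}

#' @export
print.notch_spec <- function(x, ...) {
  cat(sprintf("<notch_spec> %s stop %.4g-%.4g Hz (center %.4g), order %d%s\n",
              x$family, x$lo_hz, x$hi_hz, x$center_hz, x$order,
              if (x$zero_phase) ", zero-phase" else ""))
  invisible(x)
}

#' Recommended band-stop presets for ages 8--24 months
#'
#' `preset = "toddler"` is the recommended slightly widened band of
#' 0.25--0.50 Hz for subjects aged 8--24 months; `"quartile_derived"` is the
#' narrower 0.28--0.48 Hz band derived from cohort peak quartiles.
#'
#' @param preset which preset band.
#' @param ... passed to [notch_spec()].
#' @return a [notch_spec()].
#' @export
notch_preset <- function(preset = c("toddler", "quartile_derived"), ...) {
  switch(match.arg(preset),
         toddler = notch_spec(0.25, 0.50, label = "toddler 0.25-0.50 Hz", ...),
         quartile_derived = notch_spec(0.28, 0.48,
                                    label = "quartile 0.28-0.48 Hz", ...))
}

filter_coeffs <- function(spec, tr_s) {
  fs <- 1 / tr_s
  nyq <- fs / 2
  if (spec$hi_hz >= nyq)
    stop(sprintf(paste0("stopband edge %.3g Hz is at/above Nyquist %.3g Hz; ",
                        "the artifact is aliased at this TR -- see ",
                        "alias_frequency()"), spec$hi_hz, nyq))
  if (spec$family == "butterworth_bandstop") {
    bt <- signal::butter(spec$order, c(spec$lo_hz, spec$hi_hz) / nyq,
                         type = "stop")
    list(b = bt$b, a = bt$a)
  } else {
    # constrained second-order notch biquad: unit gain at DC/Nyquist,
    # zero at center_hz, -3 dB bandwidth (hi - lo)
    w0 <- 2 * pi * spec$center_hz / fs
    dw <- 2 * pi * (spec$hi_hz - spec$lo_hz) / fs
    k <- (1 - tan(dw / 2)) / (1 + tan(dw / 2))
    g <- (1 + k) / 2
    list(b = g * c(1, -2 * cos(w0), 1),
         a = c(1, -(1 + k) * cos(w0), k))
  }
}

check_stable <- function(co, spec) {
  r <- Mod(polyroot(rev(co$a)))
  if (any(r >= 1 - 1e-10))
    stop("unstable filter design for ", spec$label,
         sprintf(" (family %s, order %d, band %.4g-%.4g Hz)",
                 spec$family, spec$order, spec$lo_hz, spec$hi_hz))
  invisible(co)
}

#' Derive cohort notch cutoffs from subject respiratory peaks
#'
#' The cohort's central cutoff is the median of the per-subject peak
#' frequencies; the stopband edges are the 25th and 75th percentiles
#' (linear-interpolation percentiles), i.e. the span of the second and
#' third quartile groups. Low-prominence peaks are excluded (count
#' reported via message). If the interquartile span is narrower than
#' `min_width_hz` it is widened symmetrically about the center, so a
#' homogeneous cohort still yields a usable band.
#'
#' @param peaks list of [find_resp_peak()] results (or a numeric vector of
#'   peak frequencies).
#' @param min_width_hz minimum stopband width (default 0.06 Hz).
#' @param ... passed to [notch_spec()] (family, order, zero_phase).
#' @return a [notch_spec()].
#' @export
design_notch <- function(peaks, min_width_hz = 0.06, ...) {
  if (is.numeric(peaks)) {
    hz <- peaks
    n_flagged <- 0L
  } else {
    flagged <- vapply(peaks, function(p) isTRUE(p$low_prominence), logical(1))
    n_flagged <- sum(flagged)
    hz <- vapply(peaks[!flagged], `[[`, numeric(1), "peak_hz")
  }
  if (!length(hz))
    stop("all subject peaks are flagged low-prominence; no data-driven ",
         "cutoffs available -- fall back to a fixed band, e.g. ",
         'notch_preset("toddler")')
  if (n_flagged > 0L)
    message(n_flagged, " low-prominence peak(s) excluded from cutoff derivation")
  q <- unname(quantile(hz, c(0.25, 0.5, 0.75), type = 7))
  lo <- q[1]; ctr <- q[2]; hi <- q[3]
  if (hi - lo < min_width_hz) {
    lo <- ctr - min_width_hz / 2
    hi <- ctr + min_width_hz / 2
  }
  notch_spec(lo, hi, center_hz = ctr, ...)
}

#' Band-stop filter a motion trace
#'
#' Applies the specified notch identically to all six parameter columns --
#' respiratory artifact leaks from the phase-encode axis into the other
#' planes, so filtering must be applied in all directions. With
#' `zero_phase = TRUE` (default) the filter runs forward and backward so
#' the filtered trace has no lag and stays frame-aligned with censoring;
#' edges are handled by odd-symmetric padding (see the methods vignette).
#'
#' @param trace a [motion_trace()].
#' @param spec a [notch_spec()].
#' @return a new [motion_trace()] with filtered parameters.
#' @export
apply_notch <- function(trace, spec) {
  stopifnot(inherits(trace, "motion_trace"), inherits(spec, "notch_spec"))
  co <- check_stable(filter_coeffs(spec, trace$tr_s), spec)
  n <- nrow(trace$params)
  if (n < 3L * max(length(co$a), length(co$b)))
    stop("trace too short for this filter order")
  out <- trace$params
  for (j in 1:6) {
    x <- trace$params[, j]
    out[, j] <- if (spec$zero_phase) {
      filtfilt_pad(co$b, co$a, x)
    } else {
      apply_iir(co$b, co$a, x, zi = lfilter_zi(co$b, co$a) * x[1L])
    }
  }
  motion_trace(out, tr_s = trace$tr_s, phase_axis = trace$phase_axis,
               subject_id = trace$subject_id, run_id = trace$run_id)
}

#' Compare candidate notch widths on one subject
#'
#' Filters the trace with each candidate spec and tabulates the resulting
#' FD summaries: on respiration-dominated traces wider stopbands shift the
#' whole FD trace lower (and retain more frames), while spontaneous-motion
#' spikes keep exceeding the threshold under every band.
#'
#' @param trace a [motion_trace()].
#' @param specs list of [notch_spec()] objects.
#' @param radius_mm head radius for FD.
#' @param threshold_mm censoring threshold used for the retained-frame
#'   counts (default 0.2 mm).
#' @return data.frame with one row per spec (plus an `unfiltered` row):
#'   label, lo_hz, hi_hz, mean_fd_mm, n_kept, minutes_kept; the filtered
#'   [fd_trace()]s are attached as attribute `"fd_traces"`.
#' @export
compare_filters <- function(trace, specs, radius_mm = 35, threshold_mm = 0.2) {
  stopifnot(length(specs) >= 1L)
  fd0 <- compute_fd(trace, radius_mm)
  rows <- list(data.frame(label = "unfiltered", lo_hz = NA_real_,
                          hi_hz = NA_real_, mean_fd_mm = mean(fd0$fd_mm),
                          n_kept = sum(fd0$fd_mm <= threshold_mm)))
  fds <- list(unfiltered = fd0)
  for (sp in specs) {
    fd <- compute_fd(apply_notch(trace, sp), radius_mm, filtered = TRUE)
    fds[[sp$label]] <- fd
    rows[[length(rows) + 1L]] <-
      data.frame(label = sp$label, lo_hz = sp$lo_hz, hi_hz = sp$hi_hz,
                 mean_fd_mm = mean(fd$fd_mm),
                 n_kept = sum(fd$fd_mm <= threshold_mm))
  }
  out <- do.call(rbind, rows)
  out$minutes_kept <- out$n_kept * trace$tr_s / 60
  attr(out, "fd_traces") <- fds
  out
}
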