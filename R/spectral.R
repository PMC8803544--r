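hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))

# One-sided Welch power spectral density (Hann window, 50% overlap,
# per-segment mean removal). Scaled so sum(psd) * df ~ var(x) for a
# zero-mean stationary input (Parseval within window bias).
welch_psd <- function(x, fs, seg_len = 256L, overlap = 0.5) {
  n <- length(x)
  seg_len <- min(seg_len, n)
  step <- max(1L, floor(seg_len * (1 - overlap)))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  w <- hann_window(seg_len)
  u <- sum(w^2)
  nf <- floor(seg_len / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(fft(seg)[1:nf])^2
    acc <- acc + sp
  }
  psd <- acc / (length(starts) * fs * u)
  # one-sided: double interior bins (not DC; not Nyquist when seg_len even)
  dbl <- 2:(nf - if (seg_len %% 2 == 0) 1L else 0L)
  psd[dbl] <- 2 * psd[dbl]
  list(freqs_hz = (0:(nf - 1L)) * fs / seg_len, psd = psd)
}

#' Power spectrum of the six motion parameters
#'
#' Welch-averaged periodogram (Hann window, 50% overlap, segment length
#' `min(T, seg_len)`) of each realignment-parameter column on a common
#' frequency grid from 0 to Nyquist. In multiband infant data this view
#' reveals respiration as a high-power band at the breathing rate,
#' strongest on the phase-encode translation. The trace's mean FD is
#' attached for cohort ordering.
#'
#' @param trace a [motion_trace()].
#' @param detrend remove a linear trend from each column first (default
#'   TRUE; segment means are always removed).
#' @param seg_len Welch segment length in frames (default 256).
#' @param radius_mm head radius for the attached mean FD.
#' @return object of class `motion_spectrum`: `freqs_hz` (length F),
#'   `power` (F x 6), `subject_id`, `phase_axis`, `tr_s`, `mean_fd_mm`.
#' @export
motion_spectrum <- function(trace, detrend = TRUE, seg_len = 256L,
                            radius_mm = 35) {
  stopifnot(inherits(trace, "motion_trace"))
  n <- nrow(trace$params)
  if (n < 32L)
    stop("trace too short for spectral estimation (need >= 32 frames)")
  fs <- 1 / trace$tr_s
  tt <- seq_len(n)
  pw <- NULL
  freqs <- NULL
  for (j in 1:6) {
    x <- trace$params[, j]
    if (detrend) x <- stats::lm.fit(cbind(1, tt), x)$residuals
    est <- welch_psd(x, fs, seg_len = seg_len)
    if (is.null(pw)) {
      freqs <- est$freqs_hz
      pw <- matrix(0, length(freqs), 6L, dimnames = list(NULL, MOTION_COLS))
    }
    pw[, j] <- est$psd
  }
  structure(list(freqs_hz = freqs, power = pw,
                 subject_id = trace$subject_id, phase_axis = trace$phase_axis,
                 tr_s = trace$tr_s,
                 mean_fd_mm = mean(compute_fd(trace, radius_mm)$fd_mm)),
            class = "motion_spectrum")
}

#' Locate a subject's respiratory spectral peak
#'
#' For each selected motion axis, finds the frequency of maximum power
#' within the search band; the subject's peak is the median of those
#' per-axis peak frequencies (the "median high-intensity component"). A
#' peak is flagged low-prominence when no selected axis exceeds 3x its
#' median in-band power; flagged subjects should be excluded from cohort
#' cutoff derivation.
#'
#' @param spec a [motion_spectrum()].
#' @param band_hz search band `c(lo, hi)` in Hz; default 0.2--0.6 Hz, the
#'   observed infant/toddler respiratory range.
#' @param axes which parameter columns to use: `"phase"` (default, the
#'   phase-encode translation only), `"translations"`, `"all"`, or a
#'   character vector of column names.
#' @return object of class `resp_peak`: `peak_hz`, `search_band_hz`,
#'   `parameter_used`, `low_prominence`, `subject_id`.
#' @export
find_resp_peak <- function(spec, band_hz = c(0.2, 0.6), axes = "phase") {
  stopifnot(inherits(spec, "motion_spectrum"))
  nyq <- max(spec$freqs_hz)
  if (band_hz[1] <= 0 || band_hz[1] >= band_hz[2])
    stop("band_hz must satisfy 0 < lo < hi")
  if (band_hz[2] > nyq + 1e-12)
    stop(sprintf(paste0("search band [%.3g, %.3g] Hz exceeds Nyquist %.3g Hz; ",
                        "the true rate is aliased -- see alias_frequency()"),
                 band_hz[1], band_hz[2], nyq))
  cols <- if (identical(axes, "phase")) {
    paste0("trans_", spec$phase_axis)
  } else if (identical(axes, "translations")) {
    MOTION_COLS[1:3]
  } else if (identical(axes, "all")) {
    MOTION_COLS
  } else {
    match.arg(axes, MOTION_COLS, several.ok = TRUE)
  }
  sel <- spec$freqs_hz >= band_hz[1] & spec$freqs_hz <= band_hz[2]
  if (!any(sel)) stop("no frequency bins inside band_hz")
  fband <- spec$freqs_hz[sel]
  peaks <- prom <- numeric(length(cols))
  for (k in seq_along(cols)) {
    p <- spec$power[sel, cols[k]]
    peaks[k] <- fband[which.max(p)]
    med <- median(p)
    prom[k] <- if (med > 0) max(p) / med else Inf
  }
  structure(list(peak_hz = median(peaks), search_band_hz = band_hz,
                 parameter_used = cols, per_axis_peak_hz = peaks,
                 low_prominence = all(prom < 3),
                 subject_id = spec$subject_id),
            class = "resp_peak")
}

#' Fold a frequency into the sampled band (aliasing)
#'
#' Returns the apparent frequency of a `true_hz` oscillation when sampled
#' at interval `tr_s`: `|f - fs * round(f / fs)|` with `fs = 1/tr_s`,
#' always in `[0, fs/2]`. At conventional fMRI sampling (TR 2--2.5 s) an
#' infant breathing at 0.4 Hz folds to near DC, which is why the artifact
#' went unnoticed before sub-second multiband TRs.
#'
#' @param true_hz non-negative frequency (Hz); vectorized.
#' @param tr_s sampling interval (s).
#' @return folded frequency in `[0, 1/(2 tr_s)]`.
#' @export
alias_frequency <- function(true_hz, tr_s) {
  if (any(true_hz < 0)) stop("true_hz must be non-negative")
  if (tr_s <= 0) stop("tr_s must be positive")
  fs <- 1 / tr_s
  abs(true_hz - fs * round(true_hz / fs))
}

#' Stack cohort spectra ordered by mean FD
#'
#' Rows are subjects sorted ascending by mean FD (lowest-motion subjects
#' first), power row-normalized to max 1 for display, for one motion axis.
#' All spectra must share a frequency grid (equal TR and segment length).
#'
#' @param specs list of [motion_spectrum()] objects.
#' @param axis motion column to stack (default the phase-encode translation
#'   of the first spectrum).
#' @return list of class `cohort_spectra`: `freqs_hz`, `power` (subjects x
#'   F, row max 1), `mean_fd_mm` (sorted), `subject_id`, `axis`.
#' @export
cohort_spectra <- function(specs, axis = NULL) {
  stopifnot(length(specs) >= 1L)
  if (is.null(axis)) axis <- paste0("trans_", specs[[1L]]$phase_axis)
  axis <- match.arg(axis, MOTION_COLS)
  f0 <- specs[[1L]]$freqs_hz
  same <- vapply(specs, function(s)
    length(s$freqs_hz) == length(f0) && max(abs(s$freqs_hz - f0)) < 1e-9,
    logical(1))
  if (!all(same))
    stop("spectra are on different frequency grids (mixed TR or segment ",
         "length); recompute on a common grid")
  ord <- order(vapply(specs, `[[`, numeric(1), "mean_fd_mm"))
  pw <- t(vapply(specs[ord], function(s) {
    p <- s$power[, axis]
    m <- max(p)
    if (m > 0) p / m else p
  }, numeric(length(f0))))
  structure(list(freqs_hz = f0, power = pw,
                 mean_fd_mm = vapply(specs[ord], `[[`, numeric(1), "mean_fd_mm"),
                 subject_id = vapply(specs[ord], function(s)
                   as.character(s$subject_id), character(1)),
                 axis = axis),
            class = "cohort_spectra")
}
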