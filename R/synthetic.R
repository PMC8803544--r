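#' Motion simulation parameters
#'
#' Defaults emulate a sleeping 8--24-month-old scanned with a multiband
#' sequence: a ~0.4 Hz (24 breaths/min) narrow-band oscillation of ~0.15 mm
#' amplitude on the phase-encode translation with partial leak into the
#' other axes and a small rotational component, sparse large spontaneous
#' displacement spikes, slow drift, and white measurement noise on the
#' realignment estimates.
#'
#' @param t_frames frames per run (default 420, i.e. 5.6 min at TR 0.8 s).
#' @param tr_s repetition time, seconds (presets 0.8 and 0.72 are the two
#'   acquisition TRs the method targets).
#' @param resp_hz_mean mean respiratory frequency (Hz).
#' @param resp_hz_sd between-subject SD of respiratory frequency (Hz).
#' @param resp_hz_jitter SD of the slow within-run wander of instantaneous
#'   respiratory frequency (Hz).
#' @param resp_amp_mm respiration amplitude on the phase-encode axis (mm).
#' @param leak_frac fraction of respiration amplitude leaking into each
#'   non-phase translation axis.
#' @param spike_rate_per_min expected spontaneous movement spikes per
#'   minute.
#' @param spike_amp_meanlog,spike_amp_sdlog log-normal parameters of spike
#'   displacement amplitude (mm).
#' @param spike_amp_min_mm lower clip on spike amplitude (mm); gross
#'   spontaneous movements are large relative to the ~0.15 mm respiratory
#'   displacement.
#' @param spike_dur_frames range of repositioning durations (frames): the
#'   head holds the displaced position for a few seconds before
#'   resettling, so the realignment trace shows two transition edges, not
#'   a one-frame impulse.
#' @param drift_mm_per_min SD of the per-axis linear drift rate (mm/min).
#' @param noise_sd_mm white-noise SD on each translation (mm); rotation
#'   noise is `noise_sd_mm / 50` rad.
#' @param phase_axis phase-encode axis.
#' @return list of class `motion_sim_params`.
#' @export
motion_sim_params <- function(t_frames = 420L, tr_s = 0.8,
                              resp_hz_mean = 0.4, resp_hz_sd = 0.05,
                              resp_hz_jitter = 0.01,
                              resp_amp_mm = 0.15, leak_frac = 0.3,
                              spike_rate_per_min = 2,
                              spike_amp_meanlog = log(1.0),
                              spike_amp_sdlog = 0.5,
                              spike_amp_min_mm = 0.5,
                              spike_dur_frames = c(4L, 15L),
                              drift_mm_per_min = 0.1,
                              noise_sd_mm = 0.01,
                              phase_axis = "y") {
  p <- list(t_frames = as.integer(t_frames), tr_s = tr_s,
            resp_hz_mean = resp_hz_mean, resp_hz_sd = resp_hz_sd,
            resp_hz_jitter = resp_hz_jitter, resp_amp_mm = resp_amp_mm,
            leak_frac = leak_frac, spike_rate_per_min = spike_rate_per_min,
            spike_amp_meanlog = spike_amp_meanlog,
            spike_amp_sdlog = spike_amp_sdlog,
            spike_amp_min_mm = spike_amp_min_mm,
            spike_dur_frames = as.integer(spike_dur_frames),
            drift_mm_per_min = drift_mm_per_min, noise_sd_mm = noise_sd_mm,
            phase_axis = match.arg(phase_axis, c("x", "y", "z")))
  nyq <- 1 / (2 * p$tr_s)
  if (p$resp_hz_mean + 3 * p$resp_hz_sd >= nyq)
    stop(sprintf(paste0("respiratory band reaches Nyquist (%.3g Hz) at TR ",
                        "%.3g s; at this sampling rate the artifact is ",
                        "aliased -- model it explicitly via ",
                        "alias_frequency()"), nyq, p$tr_s))
  amps <- c(p$resp_amp_mm, p$leak_frac, p$spike_rate_per_min,
            p$drift_mm_per_min, p$noise_sd_mm)
  if (any(amps < 0)) stop("amplitudes and rates must be non-negative")
  structure(p, class = "motion_sim_params")
}

# slow wander: heavily smoothed white noise rescaled to target SD
slow_wander <- function(n, sd_target, smooth_frames = 50L) {
  if (sd_target <= 0) return(rep(0, n))
  raw <- rnorm(n + 2L * smooth_frames)
  w <- stats::filter(raw, rep(1 / smooth_frames, smooth_frames), sides = 2L)
  w <- w[(smooth_frames + 1L):(smooth_frames + n)]
  s <- sd(w)
  if (!is.finite(s) || s == 0) rep(0, n) else w * (sd_target / s)
}

#' Simulate one motion-trace run with ground truth
#'
#' The trace is drift + respiration + spikes + noise. Respiration is a
#' frequency-wandering sinusoid: instantaneous frequency
#' `resp_hz + slow wander (SD resp_hz_jitter)`, phase its cumulative
#' integral; full amplitude on the phase-encode axis, `leak_frac` of it
#' (with random phase offsets) on the other two translations, and a small
#' rotational component. Spikes are discrete repositioning events -- a
#' log-normal displacement on a non-phase translation axis held for a few
#' seconds and then released, with a refractory gap between events --
#' emulating gross arousal movements. Their transition frames corrupt
#' BOLD (see [gen_bold()]) while respiration does not: the central
#' identifiability premise that makes the respiratory FD component safely
#' filterable.
#'
#' @param params a [motion_sim_params()].
#' @param resp_hz subject-level respiratory frequency override (Hz);
#'   default draws from `N(resp_hz_mean, resp_hz_sd)`.
#' @param subject_id,run_id labels.
#' @return list with `trace` ([motion_trace()]) and `truth` (class
#'   `ground_truth`: `resp_hz` drawn frequency, `resp_hz_inst` length-T
#'   instantaneous frequency, `spike_frames` (onset transition frames,
#'   1-based), `spike_offsets` (release transition frames),
#'   `spike_amps_mm`, `spike_durations`).
#' @export
gen_motion <- function(params = motion_sim_params(), resp_hz = NULL,
                       subject_id = NA_character_, run_id = NA_character_) {
  stopifnot(inherits(params, "motion_sim_params"))
  n <- params$t_frames
  tr <- params$tr_s
  if (is.null(resp_hz))
    resp_hz <- rnorm(1, params$resp_hz_mean, params$resp_hz_sd)
  f_inst <- resp_hz + slow_wander(n, params$resp_hz_jitter)
  phase <- 2 * pi * cumsum(f_inst) * tr
  axes <- c(x = 1L, y = 2L, z = 3L)
  pa <- axes[[params$phase_axis]]
  others <- setdiff(1:3, pa)

  m <- matrix(0, n, 6L)
  # respiration: full amplitude on phase axis, leak elsewhere
  m[, pa] <- params$resp_amp_mm * sin(phase)
  for (ax in others)
    m[, ax] <- params$leak_frac * params$resp_amp_mm *
      sin(phase + runif(1, 0, 2 * pi))
  # small rotational respiration (rad); ~leak-sized arc at a 50 mm radius
  for (ax in 4:6)
    m[, ax] <- params$leak_frac * params$resp_amp_mm / 50 *
      sin(phase + runif(1, 0, 2 * pi)) * runif(1, 0.2, 1)
  # slow drift: random per-axis linear slope
  t_min <- (seq_len(n) - 1L) * tr / 60
  for (ax in 1:3) m[, ax] <- m[, ax] + rnorm(1, 0, params$drift_mm_per_min) * t_min
  for (ax in 4:6) m[, ax] <- m[, ax] + rnorm(1, 0, params$drift_mm_per_min / 50) * t_min
  # spontaneous repositioning events on a non-phase translation axis:
  # displacement held for dur frames then released (two transition
  # edges), refractory gap so events never overlap under filtering
  dur_min <- n * tr / 60
  n_spikes <- rpois(1, params$spike_rate_per_min * dur_min)
  dur_rng <- params$spike_dur_frames
  refractory <- 8L
  spike_frames <- spike_offsets <- spike_durs <- integer(0)
  spike_amps <- numeric(0)
  if (n_spikes > 0) {
    cand <- sort(sample.int(n - dur_rng[2L] - 2L, n_spikes) + 1L)
    last_end <- -refractory
    for (on in cand) {
      if (on <= last_end + refractory) next
      amp <- max(params$spike_amp_min_mm,
                 rlnorm(1, params$spike_amp_meanlog, params$spike_amp_sdlog))
      dur <- sample(dur_rng[1L]:dur_rng[2L], 1L)
      ax <- sample(others, 1L)
      m[on:(on + dur - 1L), ax] <- m[on:(on + dur - 1L), ax] +
        amp * sample(c(-1, 1), 1L)
      spike_frames <- c(spike_frames, on)
      spike_offsets <- c(spike_offsets, on + dur)
      spike_amps <- c(spike_amps, amp)
      spike_durs <- c(spike_durs, dur)
      last_end <- on + dur
    }
  }
  # realignment estimation noise
  m[, 1:3] <- m[, 1:3] + matrix(rnorm(3L * n, 0, params$noise_sd_mm), n, 3L)
  m[, 4:6] <- m[, 4:6] + matrix(rnorm(3L * n, 0, params$noise_sd_mm / 50), n, 3L)

  list(trace = motion_trace(m, tr_s = tr, phase_axis = params$phase_axis,
                            subject_id = subject_id, run_id = run_id),
       truth = structure(list(resp_hz = resp_hz, resp_hz_inst = f_inst,
                              spike_frames = spike_frames,
                              spike_offsets = spike_offsets,
                              spike_amps_mm = spike_amps,
                              spike_durations = spike_durs,
                              t_frames = n, tr_s = tr),
                         class = "ground_truth"))
}

#' BOLD simulation parameters
#'
#' Defaults give 50 parcels in 5 equally sized networks with block
#' (equicorrelation) structure: within-network correlation 0.35,
#' between-network 0.05, temporally smoothed with a hemodynamic-like
#' Gaussian kernel. Movement transition frames from the motion ground
#' truth inject a global signal corruption (transition indicator
#' convolved with a short kernel, scaled by `corruption_gain`, with
#' random per-parcel weights); respiration does not enter the BOLD
#' signal at all.
#'
#' @param p_parcels number of parcels.
#' @param network_sizes integer vector of parcels per network (sums to
#'   `p_parcels`).
#' @param network_labels labels, one per network.
#' @param within_r,between_r target within/between-network correlations.
#' @param corruption_gain amplitude (in signal SD units) of spike-locked
#'   global corruption.
#' @param kernel_sd_s SD of the Gaussian temporal smoothing kernel (s).
#' @param resp_coupling amplitude of an optional respiration-coupled BOLD
#'   artifact (default 0: respiratory head motion does not disrupt BOLD;
#'   nonzero only for sensitivity experiments).
#' @return list of class `bold_sim_params`.
#' @export
bold_sim_params <- function(p_parcels = 50L,
                            network_sizes = rep(p_parcels %/% 5L, 5L),
                            network_labels = c("motor", "temp", "dan",
                                               "dmn", "visual")[seq_along(network_sizes)],
                            within_r = 0.35, between_r = 0.05,
                            corruption_gain = 2,
                            kernel_sd_s = 2,
                            resp_coupling = 0) {
  if (sum(network_sizes) != p_parcels)
    stop("network_sizes must sum to p_parcels")
  if (within_r <= between_r)
    stop("need within_r > between_r for recovery tests")
  structure(list(p_parcels = as.integer(p_parcels),
                 network_sizes = as.integer(network_sizes),
                 network_labels = network_labels,
                 within_r = within_r, between_r = between_r,
                 corruption_gain = corruption_gain,
                 kernel_sd_s = kernel_sd_s, resp_coupling = resp_coupling),
            class = "bold_sim_params")
}

block_correlation <- function(params) {
  p <- params$p_parcels
  sizes <- params$network_sizes
  sig <- matrix(params$between_r, p, p)
  stops <- cumsum(sizes)
  starts <- stops - sizes + 1L
  for (k in seq_along(sizes))
    sig[starts[k]:stops[k], starts[k]:stops[k]] <- params$within_r
  diag(sig) <- 1
  sig
}

gaussian_kernel <- function(sd_frames) {
  if (sd_frames <= 0) return(1)
  half <- ceiling(3 * sd_frames)
  k <- exp(-0.5 * ((-half:half) / sd_frames)^2)
  k / sum(k)
}

conv_causal <- function(x, k) {
  out <- numeric(length(x))
  for (j in seq_along(k)) {
    shifted <- c(rep(0, j - 1L), x)[seq_along(x)]
    out <- out + k[j] * shifted
  }
  out
}

conv_same <- function(x, k) {
  # centered convolution, constant-value edge padding
  half <- (length(k) - 1L) %/% 2L
  xp <- c(rep(x[1L], half), x, rep(x[length(x)], length(k) - 1L - half))
  stats::filter(xp, rev(k), sides = 1L)[(length(k) - 1L + 1L):(length(k) - 1L + length(x))]
}

#' Simulate network-structured parcel BOLD with spike-locked corruption
#'
#' @param params a [bold_sim_params()].
#' @param truth a `ground_truth` from [gen_motion()] (supplies frame
#'   count, TR, and spike frames).
#' @return a [parcel_timeseries()] with attribute `"corruption"` (the
#'   injected global corruption timecourse).
#' @export
gen_bold <- function(params = bold_sim_params(), truth) {
  stopifnot(inherits(params, "bold_sim_params"),
            inherits(truth, "ground_truth"))
  n <- truth$t_frames
  p <- params$p_parcels
  sig <- block_correlation(params)
  ch <- tryCatch(chol(sig), error = function(e)
    stop("target network covariance is not positive definite (within_r ",
         params$within_r, ", between_r ", params$between_r, ")"))
  x <- matrix(rnorm(n * p), n, p) %*% ch
  k <- gaussian_kernel(params$kernel_sd_s / truth$tr_s)
  if (length(k) > 1L) {
    for (j in seq_len(p)) x[, j] <- conv_same(x[, j], k)
    x <- scale(x, center = FALSE, scale = apply(x, 2L, sd))
  }
  corr <- rep(0, n)
  if (length(truth$spike_frames) && params$corruption_gain > 0) {
    ind <- rep(0, n)
    trans <- c(truth$spike_frames, truth$spike_offsets)
    ind[trans[trans <= n]] <- 1
    # causal decay: disruption peaks at the movement frame, trails after it
    corr <- params$corruption_gain * conv_causal(ind, c(1, 0.6, 0.3))
    w <- 1 + 0.5 * rnorm(p)
    x <- x + outer(as.numeric(corr), w)
  }
  if (params$resp_coupling > 0)
    x <- x + params$resp_coupling *
      outer(sin(2 * pi * cumsum(truth$resp_hz_inst) * truth$tr_s), rep(1, p))
  ids <- paste0("p", seq_len(p))
  network_of <- stats::setNames(rep(params$network_labels,
                                    params$network_sizes), ids)
  ts <- parcel_timeseries(x, ids, network_of, tr_s = truth$tr_s)
  attr(ts, "corruption") <- as.numeric(corr)
  ts
}

#' Simulate a cohort with known ground truth
#'
#' Each subject draws a respiratory frequency from
#' `N(resp_hz_mean, resp_hz_sd)` and contributes `runs_per_subject` runs
#' (default: 2--4, drawn per subject) sharing that frequency. With
#' `out_dir` set, motion files, timeseries, the network map, ground-truth
#' JSON, and a manifest TSV are written in the package's text formats.
#'
#' @param n_subjects number of subjects.
#' @param motion_params a [motion_sim_params()].
#' @param bold_params a [bold_sim_params()], or NULL to skip BOLD
#'   generation (motion-only cohorts are much faster).
#' @param seed RNG seed; the cohort is fully deterministic given it.
#' @param runs_per_subject fixed runs per subject, or NULL to draw 2--4.
#' @param out_dir optional output directory.
#' @return list of class `cohort`: `subjects` (each: `subject_id`,
#'   `resp_hz`, `runs` = list of `trace`, `truth`, and `ts` when BOLD is
#'   generated), `manifest` (data.frame), `motion_params`, `bold_params`,
#'   `seed`.
#' @export
gen_cohort <- function(n_subjects, motion_params = motion_sim_params(),
                       bold_params = bold_sim_params(), seed = 1L,
                       runs_per_subject = NULL, out_dir = NULL) {
  stopifnot(n_subjects >= 1L)
  set.seed(seed)
  subjects <- vector("list", n_subjects)
  rows <- list()
  for (i in seq_len(n_subjects)) {
    sid <- sprintf("sub-%03d", i)
    f0 <- rnorm(1, motion_params$resp_hz_mean, motion_params$resp_hz_sd)
    nruns <- if (is.null(runs_per_subject)) sample(2:4, 1L)
             else as.integer(runs_per_subject)
    runs <- vector("list", nruns)
    for (r in seq_len(nruns)) {
      rid <- sprintf("run-%02d", r)
      gm <- gen_motion(motion_params, resp_hz = f0,
                       subject_id = sid, run_id = rid)
      run <- list(trace = gm$trace, truth = gm$truth)
      if (!is.null(bold_params)) run$ts <- gen_bold(bold_params, gm$truth)
      runs[[r]] <- run
      rows[[length(rows) + 1L]] <-
        data.frame(subject_id = sid, run_id = rid,
                   t_frames = motion_params$t_frames,
                   tr_s = motion_params$tr_s,
                   resp_hz = f0, n_spikes = length(gm$truth$spike_frames))
    }
    subjects[[i]] <- list(subject_id = sid, resp_hz = f0, runs = runs)
  }
  manifest <- do.call(rbind, rows)
  cohort <- structure(list(subjects = subjects, manifest = manifest,
                           motion_params = motion_params,
                           bold_params = bold_params, seed = seed),
                      class = "cohort")
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  man <- cohort$manifest
  man$motion_file <- man$ts_file <- man$truth_file <- NA_character_
  row <- 1L
  for (sub in cohort$subjects) {
    for (run in sub$runs) {
      stem <- file.path(out_dir, paste(sub$subject_id, run$trace$run_id,
                                       sep = "_"))
      man$motion_file[row] <- paste0(stem, "_motion.par")
      write_motion(run$trace, man$motion_file[row])
      man$truth_file[row] <- paste0(stem, "_truth.json")
      write_report(run$truth, man$truth_file[row])
      if (!is.null(run$ts)) {
        man$ts_file[row] <- paste0(stem, "_bold.tsv")
        write_timeseries(run$ts, man$ts_file[row])
      }
      row <- row + 1L
    }
  }
  if (!is.null(cohort$bold_params)) {
    ts1 <- cohort$subjects[[1L]]$runs[[1L]]$ts
    write.table(data.frame(ts1$parcel_ids, unname(ts1$network_of)),
                file.path(out_dir, "network_map.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  write.table(man, file.path(out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}
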