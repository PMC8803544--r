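test_that("quartile cutoffs follow linear-interpolation percentiles", {
  sp <- design_notch(c(0.30, 0.35, 0.40, 0.45, 0.50))
  expect_equal(sp$center_hz, 0.40)
  expect_equal(sp$lo_hz, 0.35)
  expect_equal(sp$hi_hz, 0.45)

  # degenerate spread: forced minimum width, symmetric about center
  sp2 <- design_notch(rep(0.40, 6), min_width_hz = 0.06)
  expect_equal(c(sp2$lo_hz, sp2$center_hz, sp2$hi_hz), c(0.37, 0.40, 0.43))
})

test_that("low-prominence peaks are excluded; all-flagged errors", {
  mk_peak <- function(hz, flag) structure(
    list(peak_hz = hz, low_prominence = flag), class = "resp_peak")
  peaks <- c(lapply(c(0.3, 0.4, 0.5), mk_peak, flag = FALSE),
             list(mk_peak(0.05, TRUE)))
  expect_message(sp <- design_notch(peaks), "1 low-prominence")
  expect_equal(sp$center_hz, 0.40)
  expect_error(design_notch(list(mk_peak(0.4, TRUE))), "fixed band")
})

test_that("presets match the recommended toddler bands", {
  td <- notch_preset("toddler")
  expect_equal(c(td$lo_hz, td$hi_hz), c(0.25, 0.50))
  bq <- notch_preset("quartile_derived")
  expect_equal(c(bq$lo_hz, bq$hi_hz), c(0.28, 0.48))
})

test_that("both filter families notch the center and pass the rest", {
  for (family in c("butterworth_bandstop", "iir_notch")) {
    sp <- notch_spec(0.25, 0.50, family = family)
    tr <- sinusoid_trace(sp$center_hz, t_frames = 2048, col = 1)
    out <- apply_notch(tr, sp)
    atten <- tone_power(tr$params[, 1], sp$center_hz, 0.8) /
      tone_power(out$params[, 1], sp$center_hz, 0.8)
    expect_gt(10 * log10(atten), 20)

    slow <- sinusoid_trace(0.05, t_frames = 2048, col = 1)
    out2 <- apply_notch(slow, sp)
    ratio <- sqrt(tone_power(out2$params[, 1], 0.05, 0.8) /
                    tone_power(slow$params[, 1], 0.05, 0.8))
    expect_lt(abs(ratio - 1), 0.05)

    dc <- motion_trace(matrix(rep(c(3, -1, 2, 0.5, 0, 1), each = 100),
                              100, 6), tr_s = 0.8)
    expect_lt(max(abs(apply_notch(dc, sp)$params - dc$params)), 1e-9)
  }
})

test_that("zero-phase filtering introduces no lag", {
  sp <- notch_spec(0.25, 0.50)
  tr <- sinusoid_trace(0.05, t_frames = 1024, col = 1)
  out <- apply_notch(tr, sp)
  cc <- ccf(out$params[, 1], tr$params[, 1], lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("the notch acts linearly on motion traces", {
  set.seed(30)
  sp <- notch_spec(0.25, 0.50)
  x <- random_trace(200)
  y <- random_trace(200)
  comb <- motion_trace(2 * x$params - 0.5 * y$params, tr_s = 0.8)
  lhs <- apply_notch(comb, sp)$params
  rhs <- 2 * apply_notch(x, sp)$params - 0.5 * apply_notch(y, sp)$params
  expect_lt(max(abs(lhs - rhs)), 1e-10)
})

test_that("bands at or above Nyquist are rejected with alias advice", {
  tr <- random_trace(100, tr_s = 2.5)  # Nyquist 0.2 Hz
  expect_error(apply_notch(tr, notch_spec(0.25, 0.50)), "alias_frequency")
})

test_that("wider stopbands lower mean FD on respiration-dominated traces", {
  set.seed(31)
  mp <- motion_sim_params(spike_rate_per_min = 0, noise_sd_mm = 0.002,
                          drift_mm_per_min = 0)
  gm <- gen_motion(mp)
  narrow <- notch_spec(0.35, 0.45)
  wide <- notch_spec(0.30, 0.50)
  tab <- compare_filters(gm$trace, list(narrow, wide))
  expect_equal(nrow(tab), 3L)
  mf <- setNames(tab$mean_fd_mm, tab$label)
  expect_lte(mf[[wide$label]], mf[[narrow$label]])
  expect_lt(mf[[wide$label]], mf[["unfiltered"]])
})

test_that("spike-only traces keep exceeding threshold under every band", {
  set.seed(32)
  mp <- motion_sim_params(resp_amp_mm = 0)
  gm <- gen_motion(mp)
  specs <- list(notch_preset("toddler"), notch_preset("quartile_derived"))
  tab <- compare_filters(gm$trace, specs)
  fds <- attr(tab, "fd_traces")
  for (nm in names(fds))
    expect_true(all(fds[[nm]]$fd_mm[gm$truth$spike_frames] > 0.2))
})

test_that("without respiration the filter leaves FD nearly unchanged", {
  # drift-only trace: all content in the passband, so any change is ripple
  set.seed(33)
  mp <- motion_sim_params(resp_amp_mm = 0, noise_sd_mm = 0,
                          spike_rate_per_min = 0)
  gm <- gen_motion(mp)
  fd0 <- compute_fd(gm$trace)
  for (sp in list(notch_preset("toddler"), notch_spec(0.2, 0.55))) {
    fd1 <- compute_fd(apply_notch(gm$trace, sp), filtered = TRUE)
    expect_lt(abs(mean(fd1$fd_mm) - mean(fd0$fd_mm)) / mean(fd0$fd_mm), 0.05)
  }
})

test_that("cohort cutoff design recovers the true respiratory band", {
  set.seed(34)
  hits <- 0
  for (s in 1:20) {
    co <- gen_cohort(30, bold_params = NULL, seed = 1000 + s,
                     runs_per_subject = 1)
    peaks <- lapply(co$subjects, function(su)
      find_resp_peak(motion_spectrum(su$runs[[1]]$trace)))
    ns <- design_notch(peaks)
    hits <- hits + (ns$lo_hz <= 0.4 && 0.4 <= ns$hi_hz)
  }
  expect_gte(hits, 19)
})
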