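test_that("cohorts are fully deterministic under a fixed seed", {
  a <- gen_cohort(3, seed = 7, runs_per_subject = 2)
  b <- gen_cohort(3, seed = 7, runs_per_subject = 2)
  expect_identical(a$manifest, b$manifest)
  for (i in 1:3) for (r in 1:2) {
    expect_lt(max(abs(a$subjects[[i]]$runs[[r]]$trace$params -
                        b$subjects[[i]]$runs[[r]]$trace$params)), 1e-12)
    expect_lt(max(abs(a$subjects[[i]]$runs[[r]]$ts$data -
                        b$subjects[[i]]$runs[[r]]$ts$data)), 1e-12)
  }
  c_ <- gen_cohort(3, seed = 8, runs_per_subject = 2)
  expect_false(isTRUE(all.equal(a$subjects[[1]]$runs[[1]]$trace$params,
                                c_$subjects[[1]]$runs[[1]]$trace$params)))
})

test_that("silent generators produce zero FD after frame 0", {
  set.seed(70)
  mp <- motion_sim_params(resp_amp_mm = 0, spike_rate_per_min = 0,
                          noise_sd_mm = 0, drift_mm_per_min = 0)
  fd <- compute_fd(gen_motion(mp)$trace)
  expect_equal(fd$fd_mm, rep(0, 420))
})

test_that("respiratory bands beyond Nyquist are refused", {
  expect_error(motion_sim_params(tr_s = 2.5), "alias")
})

test_that("generated spectra peak at the generated frequency", {
  set.seed(71)
  errs <- replicate(20, {
    gm <- gen_motion()
    sp <- motion_spectrum(gm$trace)
    band <- sp$freqs_hz >= 0.2 & sp$freqs_hz <= 0.6
    pk <- sp$freqs_hz[band][which.max(sp$power[band, "trans_y"])]
    abs(pk - mean(gm$truth$resp_hz_inst))
  })
  expect_true(all(errs <= 0.02))
})

test_that("ground-truth spike frames always exceed the FD threshold", {
  set.seed(72)
  for (i in 1:20) {
    gm <- gen_motion()
    fr <- gm$truth$spike_frames
    if (!length(fr)) next
    expect_true(all(compute_fd(gm$trace)$fd_mm[fr] > 0.2))
    expect_true(all(gm$truth$spike_amps_mm >=
                      motion_sim_params()$spike_amp_min_mm))
  }
})

test_that("BOLD block correlations converge to their targets", {
  set.seed(73)
  truth <- structure(list(resp_hz = 0.4, resp_hz_inst = rep(0.4, 4000),
                          spike_frames = integer(0),
                          spike_offsets = integer(0),
                          spike_amps_mm = numeric(0),
                          spike_durations = integer(0),
                          t_frames = 4000L, tr_s = 0.8),
                     class = "ground_truth")
  bp <- bold_sim_params(corruption_gain = 0)
  ts <- gen_bold(bp, truth)
  nb <- network_blocks(fc_matrix(ts))
  expect_lt(max(abs(diag(nb$blocks) - bp$within_r)), 0.05)
  off <- nb$blocks[upper.tri(nb$blocks)]
  expect_lt(max(abs(off - bp$between_r)), 0.05)
})

test_that("independent parcels stay uncorrelated", {
  set.seed(74)
  truth <- structure(list(resp_hz = 0.4, resp_hz_inst = rep(0.4, 2000),
                          spike_frames = integer(0),
                          spike_offsets = integer(0),
                          spike_amps_mm = numeric(0),
                          spike_durations = integer(0),
                          t_frames = 2000L, tr_s = 0.8),
                     class = "ground_truth")
  bp <- bold_sim_params(p_parcels = 30L, network_sizes = 30L,
                        network_labels = "one", within_r = 0,
                        between_r = -0.01, corruption_gain = 0)
  r <- fc_matrix(gen_bold(bp, truth))$r
  off <- r[upper.tri(r)]
  expect_lt(abs(mean(off)), 2 * sd(off) / sqrt(length(off)) + 0.01)
})

test_that("spike corruption drives DVARS above 3x its median", {
  set.seed(75)
  found <- FALSE
  for (i in 1:5) {
    gm <- gen_motion()
    tot <- c(gm$truth$spike_frames, gm$truth$spike_offsets)
    tot <- tot[tot <= 420]
    if (!length(tot)) next
    found <- TRUE
    dv <- compute_dvars(gen_bold(bold_sim_params(), gm$truth))
    expect_true(all(dv[tot] >= 3 * median(dv)))
  }
  expect_true(found)
})

test_that("a one-subject cohort still yields a usable notch", {
  co <- gen_cohort(1, bold_params = NULL, seed = 76, runs_per_subject = 1)
  pk <- find_resp_peak(motion_spectrum(co$subjects[[1]]$runs[[1]]$trace))
  ns <- design_notch(list(pk))
  expect_gte(ns$hi_hz - ns$lo_hz, 0.06 - 1e-12)
  expect_true(ns$lo_hz < ns$center_hz && ns$center_hz < ns$hi_hz)
})

test_that("cohorts written to disk round-trip through the readers", {
  dir <- withr::local_tempdir()
  co <- gen_cohort(2, seed = 77, runs_per_subject = 2, out_dir = dir)
  man <- read.table(file.path(dir, "manifest.tsv"), header = TRUE,
                    sep = "\t")
  expect_equal(nrow(man), 4L)
  tr <- read_motion(man$motion_file[1], tr_s = man$tr_s[1])
  expect_lt(max(abs(tr$params - co$subjects[[1]]$runs[[1]]$trace$params)),
            1e-9)
  ts <- read_timeseries(man$ts_file[1],
                        network_map_path = file.path(dir, "network_map.tsv"),
                        tr_s = man$tr_s[1])
  expect_lt(max(abs(ts$data - co$subjects[[1]]$runs[[1]]$ts$data)), 1e-9)
  truth <- read_report(man$truth_file[1])
  expect_equal(truth$resp_hz, co$subjects[[1]]$resp_hz)
})
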