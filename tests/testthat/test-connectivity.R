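nets4 <- function(p, k = 2) {
  setNames(rep(paste0("n", seq_len(k)), each = p / k), paste0("p", seq_len(p)))
}

test_that("band-pass keeps the infra-slow band and kills the rest", {
  tt <- (0:1023) * 0.8
  nets <- nets4(2)
  mk <- function(f) parcel_timeseries(cbind(sin(2 * pi * f * tt),
                                            cos(2 * pi * f * tt)),
                                      c("p1", "p2"), nets, 0.8)
  inband <- bandpass_interp(mk(0.03))
  ratio <- sqrt(tone_power(inband$data[, 1], 0.03, 0.8) /
                  tone_power(mk(0.03)$data[, 1], 0.03, 0.8))
  expect_lt(abs(ratio - 1), 0.10)

  fast <- bandpass_interp(mk(0.4))
  att <- tone_power(mk(0.4)$data[, 1], 0.4, 0.8) /
    tone_power(fast$data[, 1], 0.4, 0.8)
  expect_gt(10 * log10(att), 20)

  const <- parcel_timeseries(matrix(5, 500, 2), c("p1", "p2"), nets, 0.8)
  expect_lt(max(abs(bandpass_interp(const)$data)), 1e-9)
})

test_that("censored frames are interpolated, not invented", {
  set.seed(50)
  tt <- (0:499) * 0.8
  x <- sin(2 * pi * 0.03 * tt)
  ts <- parcel_timeseries(cbind(x, x), c("p1", "p2"), nets4(2), 0.8)
  keep <- rep(TRUE, 500)
  keep[sample(10:490, 100)] <- FALSE
  out <- bandpass_interp(ts, frame_mask(keep, 0.2))
  full <- bandpass_interp(ts)
  # sparse censoring of a smooth in-band signal barely perturbs it
  expect_lt(max(abs(out$data[keep, 1] - full$data[keep, 1])), 0.05)
  expect_error(bandpass_interp(ts, frame_mask(c(TRUE, rep(FALSE, 499)), 0.2)),
               "2 retained")
})

test_that("connectivity equals brute-force Pearson on kept frames", {
  set.seed(51)
  x <- matrix(rnorm(60 * 3), 60, 3)
  nets <- setNames(c("a", "a", "b"), paste0("p", 1:3))
  ts <- parcel_timeseries(x, paste0("p", 1:3), nets, 0.8)
  keep <- runif(60) > 0.3
  cm <- fc_matrix(ts, keep)
  expect_equal(cm$n_frames_used, sum(keep))
  for (i in 1:2) for (j in (i + 1):3)
    expect_lt(abs(cm$r[i, j] -
                    pearson_loop_oracle(x[keep, i], x[keep, j])), 1e-12)
  expect_equal(unname(diag(cm$r)), rep(1, 3))
  expect_equal(cm$r, t(cm$r))
})

test_that("degenerate parcels and perfect correlations behave", {
  nets <- nets4(4)
  tt <- 1:40
  x <- cbind(sin(tt), sin(tt), -sin(tt), 7)
  ts <- parcel_timeseries(x, paste0("p", 1:4), nets, 0.8)
  expect_warning(cm <- fc_matrix(ts), "zero-variance")
  expect_equal(cm$r[1, 2], 1)
  expect_equal(cm$r[1, 3], -1)
  expect_equal(cm$r[4, 1], 0)
  expect_equal(cm$r[4, 4], 1)
  expect_error(fc_matrix(ts, c(rep(TRUE, 5), rep(FALSE, 35))), "floor")
})

test_that("network blocks average the right parcel pairs", {
  # block-constant toy: within 0.6, between 0.1
  r <- matrix(0.1, 6, 6)
  r[1:3, 1:3] <- 0.6
  r[4:6, 4:6] <- 0.6
  diag(r) <- 1
  nets <- setNames(rep(c("a", "b"), each = 3), paste0("p", 1:6))
  cm <- structure(list(r = r, n_frames_used = 100L,
                       parcel_ids = paste0("p", 1:6), network_of = nets),
                  class = "connectivity_matrix")
  nb <- network_blocks(cm)
  expect_equal(unname(nb$blocks), matrix(c(0.6, 0.1, 0.1, 0.6), 2))

  set.seed(52)
  rr <- cor(matrix(rnorm(300), 30, 10))
  nets10 <- setNames(rep(c("a", "b", "c"), c(4, 5, 1)), paste0("p", 1:10))
  cm2 <- structure(list(r = rr, n_frames_used = 30L,
                        parcel_ids = paste0("p", 1:10), network_of = nets10),
                   class = "connectivity_matrix")
  nb2 <- network_blocks(cm2)
  expect_equal(nb2$blocks, block_pair_oracle(rr, unname(nets10)))
  expect_true(is.na(nb2$blocks["c", "c"]))   # singleton network
})

test_that("paired t is zero for identical lists and matches closed form", {
  set.seed(53)
  x <- matrix(rnorm(200), 50, 4)
  nets <- nets4(4)
  mats <- lapply(1:5, function(i)
    fc_matrix(parcel_timeseries(x + rnorm(200), paste0("p", 1:4), nets, 0.8)))
  pt <- paired_ttest(mats, mats)
  expect_true(all(pt$t[!is.na(pt$t)] == 0))
  expect_equal(pt$df, 4L)
  expect_error(paired_ttest(mats, mats[1:3]), "equal length")

  # constant z difference d with noise SD s across n subjects: E[t] ~ d/(s/sqrt(n))
  d <- 0.3; s <- 0.2; n <- 12
  mk_cm <- function(r12) {
    r <- diag(2); r[1, 2] <- r[2, 1] <- r12
    structure(list(r = r, n_frames_used = 50L, parcel_ids = c("p1", "p2"),
                   network_of = setNames(c("a", "a"), c("p1", "p2"))),
              class = "connectivity_matrix")
  }
  tstats <- replicate(200, {
    z0 <- rnorm(n, 0.4, 0.1)
    za <- z0 + d + rnorm(n, 0, s)
    a <- lapply(tanh(za), mk_cm)
    b <- lapply(tanh(z0), mk_cm)
    paired_ttest(a, b)$t[1, 2]
  })
  theory <- d / (s / sqrt(n))
  # noncentral-t mean is slightly above the noncentrality parameter
  expect_lt(abs(mean(tstats) - theory) / theory, 0.10)
})

test_that("adding motion-corrupted frames never improves truth recovery", {
  set.seed(54)
  bp <- bold_sim_params()
  tb <- matrix(bp$between_r, 5, 5); diag(tb) <- bp$within_r
  for (i in 1:5) {
    gm <- gen_motion()
    ts <- gen_bold(bp, gm$truth)
    bad <- unique(pmin(c(gm$truth$spike_frames, gm$truth$spike_offsets),
                       nrow(ts$data)))
    clean <- setdiff(seq_len(nrow(ts$data)), bad)
    keep_clean <- seq_len(nrow(ts$data)) %in% clean
    rmse <- function(keep) {
      b <- network_blocks(fc_matrix(ts, keep))$blocks
      sqrt(mean((b - tb)^2))
    }
    expect_gte(rmse(rep(TRUE, nrow(ts$data))), rmse(keep_clean) - 1e-3)
  }
})

test_that("fisher transform round-trips and caps at unity", {
  r <- c(-0.9, -0.2, 0, 0.5, 0.99)
  expect_equal(fisher_z_inv(fisher_z(r)), r, tolerance = 1e-12)
  expect_true(is.finite(fisher_z(1)) && is.finite(fisher_z(-1)))
})
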