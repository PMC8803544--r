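# Independent brute-force oracles: deliberately written as plain
# elementwise loops, sharing no code with the package internals.

fd_loop_oracle <- function(params, radius_mm) {
  n <- nrow(params)
  fd <- numeric(n)
  for (t in 2:n) {
    s <- 0
    for (j in 1:3) s <- s + abs(params[t, j] - params[t - 1, j])
    for (j in 4:6) s <- s + radius_mm * abs(params[t, j] - params[t - 1, j])
    fd[t] <- s
  }
  fd
}

dvars_loop_oracle <- function(x) {
  n <- nrow(x)
  out <- numeric(n)
  for (t in 2:n) {
    acc <- 0
    for (j in seq_len(ncol(x))) acc <- acc + (x[t, j] - x[t - 1, j])^2
    out[t] <- sqrt(acc / ncol(x))
  }
  out
}

pearson_loop_oracle <- function(a, b) {
  n <- length(a)
  ma <- sum(a) / n
  mb <- sum(b) / n
  num <- den_a <- den_b <- 0
  for (t in seq_len(n)) {
    num <- num + (a[t] - ma) * (b[t] - mb)
    den_a <- den_a + (a[t] - ma)^2
    den_b <- den_b + (b[t] - mb)^2
  }
  num / sqrt(den_a * den_b)
}

block_pair_oracle <- function(r, networks) {
  nets <- unique(networks)
  k <- length(nets)
  out <- matrix(NA_real_, k, k, dimnames = list(nets, nets))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    vals <- c()
    for (p in which(networks == nets[i])) for (q in which(networks == nets[j])) {
      if (i == j && p >= q) next
      vals <- c(vals, r[p, q])
    }
    out[i, j] <- if (length(vals)) mean(vals) else NA_real_
  }
  out
}

random_trace <- function(t_frames = 50, tr_s = 0.8, sd = 0.1) {
  motion_trace(matrix(rnorm(t_frames * 6, sd = sd), ncol = 6), tr_s = tr_s)
}

# single-axis sinusoid trace: amplitude on one column, zeros elsewhere
sinusoid_trace <- function(freq_hz, t_frames = 420, tr_s = 0.8, col = 2,
                           amp = 1) {
  tt <- (seq_len(t_frames) - 1) * tr_s
  m <- matrix(0, t_frames, 6)
  m[, col] <- amp * sin(2 * pi * freq_hz * tt)
  motion_trace(m, tr_s = tr_s)
}

# power of a single frequency component via direct DFT projection
tone_power <- function(x, freq_hz, tr_s) {
  tt <- (seq_along(x) - 1) * tr_s
  Mod(sum(x * exp(-2i * pi * freq_hz * tt)))^2
}

# per-subject run list for reliability_curve from a generated cohort
cohort_reliability_subjects <- function(cohort, spec = notch_preset("toddler")) {
  lapply(cohort$subjects, function(su)
    lapply(su$runs, function(r)
      list(ts = r$ts,
           fd_unfiltered = compute_fd(r$trace),
           fd_filtered = compute_fd(apply_notch(r$trace, spec),
                                    filtered = TRUE))))
}
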