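# Zero-phase IIR filtering with odd-symmetric edge padding and
# steady-state initial conditions. Runs of ~420 frames make edge
# transients non-negligible, so both matter.

pad_coeffs <- function(b, a) {
  nc <- max(length(a), length(b))
  b <- c(b, rep(0, nc - length(b)))
  a <- c(a, rep(0, nc - length(a)))
  if (a[1] == 0) stop("a[1] must be nonzero")
  list(b = b / a[1], a = a / a[1], nc = nc)
}

# Steady-state filter state for a unit-step input (direct form II
# transposed); scale by x[1] so a constant input passes with no transient.
lfilter_zi <- function(b, a) {
  co <- pad_coeffs(b, a)
  b <- co$b; a <- co$a; nc <- co$nc
  if (nc == 1L) return(numeric(0))
  comp <- matrix(0, nc - 1L, nc - 1L)
  comp[1L, ] <- -a[2:nc]
  if (nc > 2L) comp[cbind(2:(nc - 1L), 1:(nc - 2L))] <- 1
  solve(diag(nc - 1L) - t(comp), b[2:nc] - a[2:nc] * b[1L])
}

apply_iir <- function(b, a, x, zi = NULL) {
  co <- pad_coeffs(b, a)
  if (is.null(zi)) zi <- rep(0, co$nc - 1L)
  filter_df2t(co$b, co$a, x, zi)
}

# Forward-backward ("zero-phase") filtering, scipy-style: odd-symmetric
# extension of 3 * (ncoef - 1) samples at both ends, steady-state initial
# conditions scaled to the first sample of each pass.
filtfilt_pad <- function(b, a, x) {
  co <- pad_coeffs(b, a)
  npad <- 3L * (co$nc - 1L)
  n <- length(x)
  if (n <= npad)
    stop(sprintf("input too short for zero-phase filtering (need > %d samples)",
                 npad))
  zi <- lfilter_zi(co$b, co$a)
  ext <- c(2 * x[1L] - x[(npad + 1L):2L], x,
           2 * x[n] - x[(n - 1L):(n - npad)])
  y <- filter_df2t(co$b, co$a, ext, zi * ext[1L])
  y <- rev(y)
  y <- filter_df2t(co$b, co$a, y, zi * y[1L])
  rev(y)[(npad + 1L):(npad + n)]
}

# Complex frequency response H(e^{i 2 pi f / fs}) of b/a at freqs_hz.
iir_response <- function(b, a, freqs_hz, fs) {
  w <- 2 * pi * freqs_hz / fs
  zm <- exp(-1i * outer(w, seq_along(b) - 1))
  num <- zm[, seq_along(b), drop = FALSE] %*% b
  den <- exp(-1i * outer(w, seq_along(a) - 1)) %*% a
  as.complex(num / den)
}
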