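#' Fisher z-transform and its inverse
#'
#' Correlations are z-transformed before averaging or t-testing and
#' inverse-transformed for display. `fisher_z` clips |r| at 1 - 1e-7 to
#' keep degenerate r = +/-1 finite.
#'
#' @param r correlation(s) in `[-1, 1]`.
#' @param z Fisher z value(s).
#' @return transformed values, same shape.
#' @export
fisher_z <- function(r) atanh(pmin(pmax(r, -1 + 1e-7), 1 - 1e-7))

#' @rdname fisher_z
#' @export
fisher_z_inv <- function(z) tanh(z)

#' Interpolate censored frames and band-pass filter
#'
#' Censored frames are replaced by linear interpolation from the nearest
#' retained neighbors (constant extrapolation at the edges), each parcel
#' is demeaned, and a zero-phase second-order Butterworth band-pass is
#' applied. Interpolation prevents censored gaps from aliasing through the
#' band-pass; downstream estimation should re-impose the mask (as
#' [fc_matrix()] does) so interpolated frames never enter correlations.
#'
#' @param ts a [parcel_timeseries()].
#' @param mask a [frame_mask()], or NULL for all frames kept.
#' @param lo_hz,hi_hz band edges; default 0.008--0.09 Hz (the infra-slow
#'   BOLD band; use 0.005--0.1 Hz for the alternative convention).
#' @param order Butterworth prototype order (default 2).
#' @return a new [parcel_timeseries()].
#' @export
bandpass_interp <- function(ts, mask = NULL, lo_hz = 0.008, hi_hz = 0.09,
                            order = 2L) {
  stopifnot(inherits(ts, "parcel_timeseries"))
  n <- nrow(ts$data)
  keep <- if (is.null(mask)) rep(TRUE, n) else mask$keep
  if (length(keep) != n) stop("mask length does not match timeseries")
  if (sum(keep) < 2L) stop("fewer than 2 retained frames; cannot interpolate")
  fs <- 1 / ts$tr_s
  if (!(lo_hz < hi_hz && hi_hz < fs / 2))
    stop("need lo_hz < hi_hz < Nyquist")
  bt <- signal::butter(order, c(lo_hz, hi_hz) / (fs / 2), type = "pass")
  idx <- seq_len(n)
  out <- ts$data
  for (j in seq_len(ncol(out))) {
    x <- out[, j]
    if (!all(keep))
      x[!keep] <- approx(idx[keep], x[keep], xout = idx[!keep], rule = 2)$y
    out[, j] <- filtfilt_pad(bt$b, bt$a, x - mean(x))
  }
  parcel_timeseries(out, ts$parcel_ids, ts$network_of, ts$tr_s)
}

#' Censoring-aware parcel connectivity matrix
#'
#' Pearson correlation between all parcel pairs computed over retained
#' frames only. Parcels with zero variance on the retained frames get
#' zeroed rows/columns (diagonal kept at 1) with a warning.
#'
#' @param ts a [parcel_timeseries()].
#' @param mask a [frame_mask()] or logical vector, NULL for all frames.
#' @param min_frames minimum retained frames required (default 10).
#' @return object of class `connectivity_matrix`: `r` (P x P, diagonal 1),
#'   `n_frames_used`, `parcel_ids`, `network_of`.
#' @export
fc_matrix <- function(ts, mask = NULL, min_frames = 10L) {
  stopifnot(inherits(ts, "parcel_timeseries"))
  n <- nrow(ts$data)
  keep <- if (is.null(mask)) rep(TRUE, n)
          else if (inherits(mask, "frame_mask")) mask$keep
          else as.logical(mask)
  if (length(keep) != n) stop("mask length does not match timeseries")
  nk <- sum(keep)
  if (nk < min_frames)
    stop(sprintf("only %d retained frames; floor is %d", nk, min_frames))
  x <- ts$data[keep, , drop = FALSE]
  sds <- apply(x, 2L, sd)
  flat <- sds == 0 | !is.finite(sds)
  r <- suppressWarnings(cor(x))
  if (any(flat)) {
    warning(sum(flat), " zero-variance parcel(s) on retained frames; ",
            "correlations set to 0")
    r[flat, ] <- 0
    r[, flat] <- 0
  }
  r[!is.finite(r)] <- 0
  diag(r) <- 1
  structure(list(r = r, n_frames_used = nk, parcel_ids = ts$parcel_ids,
                 network_of = ts$network_of),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %d parcels, %d frames used\n",
              ncol(x$r), x$n_frames_used))
  invisible(x)
}

block_indices <- function(network_of, parcel_ids) {
  nets <- unique(unname(network_of[parcel_ids]))
  lapply(stats::setNames(nets, nets),
         function(nw) which(unname(network_of[parcel_ids]) == nw))
}

block_average <- function(m, idx) {
  nets <- names(idx)
  k <- length(nets)
  blocks <- matrix(NA_real_, k, k, dimnames = list(nets, nets))
  for (i in seq_len(k)) for (j in i:k) {
    if (i == j) {
      p <- idx[[i]]
      if (length(p) >= 2L) {
        sub <- m[p, p]
        blocks[i, i] <- mean(sub[upper.tri(sub)])
      } # singleton network: within-cell undefined, stays NA
    } else {
      blocks[i, j] <- blocks[j, i] <- mean(m[idx[[i]], idx[[j]]])
    }
  }
  blocks
}

#' Network-block summary of a connectivity matrix
#'
#' Within-network cells average the off-diagonal parcel pairs inside the
#' network (self-correlations excluded); between-network cells average all
#' cross pairs. Singleton networks have an undefined within cell, reported
#' as NA.
#'
#' @param cm a [fc_matrix()] result.
#' @return object of class `network_block_matrix`: `blocks` (K x K,
#'   symmetric), `network_labels`, `n_parcels` per network.
#' @export
network_blocks <- function(cm) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  idx <- block_indices(cm$network_of, cm$parcel_ids)
  structure(list(blocks = block_average(cm$r, idx),
                 network_labels = names(idx),
                 n_parcels = vapply(idx, length, 1L)),
            class = "network_block_matrix")
}

#' @export
print.network_block_matrix <- function(x, ...) {
  cat("<network_block_matrix>\n")
  print(round(x$blocks, 3))
  invisible(x)
}

#' Paired t-test of two connectivity conditions across subjects
#'
#' For each parcel pair (or each network-block cell), tests the
#' across-subject mean of the Fisher-z difference `z(a) - z(b)` against
#' zero. Used to compare filtered vs unfiltered censoring: positive t in
#' within-network cells indicates higher-magnitude connectivity estimates
#' under condition `a`. No multiple-comparison correction is applied; set
#' `fdr = TRUE` for Benjamini-Hochberg adjusted p-values.
#'
#' @param mats_a,mats_b equal-length lists of [fc_matrix()] results,
#'   paired by subject.
#' @param level `"parcel_pair"` or `"network_block"`.
#' @param fdr apply BH correction to the returned p-values.
#' @return list of class `paired_fc_test`: `t` (matrix of t-statistics,
#'   NA diagonal at parcel level), `df`, `p`, `mean_diff_z`, `level`.
#' @export
paired_ttest <- function(mats_a, mats_b,
                         level = c("parcel_pair", "network_block"),
                         fdr = FALSE) {
  level <- match.arg(level)
  if (length(mats_a) != length(mats_b))
    stop("paired lists must have equal length")
  n <- length(mats_a)
  if (n < 3L) stop("need at least 3 subjects for a paired t-test")
  get_vals <- if (level == "parcel_pair") {
    function(cm) fisher_z(cm$r)
  } else {
    function(cm) {
      idx <- block_indices(cm$network_of, cm$parcel_ids)
      block_average(fisher_z(cm$r), idx)
    }
  }
  diffs <- lapply(seq_len(n), function(i) get_vals(mats_a[[i]]) - get_vals(mats_b[[i]]))
  arr <- simplify2array(diffs)
  mean_d <- apply(arr, c(1, 2), mean)
  sd_d <- apply(arr, c(1, 2), sd)
  tt <- mean_d / (sd_d / sqrt(n))
  tt[sd_d == 0 & mean_d == 0] <- 0
  if (level == "parcel_pair") diag(tt) <- NA_real_
  p <- 2 * stats::pt(-abs(tt), df = n - 1)
  if (fdr) p[] <- stats::p.adjust(p, method = "BH")
  structure(list(t = tt, df = n - 1L, p = p, mean_diff_z = mean_d,
                 level = level),
            class = "paired_fc_test")
}
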