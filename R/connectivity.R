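#' @title Phase-locking-value connectivity
#'
#' @description
#' Sensor-space functional connectivity from multichannel time series. Each
#' run is segmented into 3-second epochs; per epoch and per 1-Hz frequency
#' bin the instantaneous phase of every channel is extracted (band-limited
#' analytic signal) and the phase-locking value
#' PLV = |mean_t exp(i*(phi_a(t) - phi_b(t)))| is computed for every channel
#' pair. Per-pair PLVs are averaged over epochs and then over the bins of a
#' band (theta 4-8 Hz, alpha 8-12 Hz, beta 12-30 Hz).
#' @name connectivity
NULL

#' Construct a time-series run
#'
#' @param data channels x samples numeric matrix, no NaNs, at least two
#'   channels.
#' @param fs_hz sampling rate in Hz.
#' @param channel_names optional channel labels.
#' @param run_index optional run number.
#' @return object of class `ts_run`.
#' @export
as_run <- function(data, fs_hz, channel_names = NULL, run_index = NA_integer_) {
  data <- as.matrix(data)
  if (nrow(data) < 2) stop("a run needs at least 2 channels")
  if (any(!is.finite(data))) stop("run contains non-finite samples")
  if (fs_hz <= 0) stop("sampling rate must be positive")
  if (is.null(channel_names))
    channel_names <- sprintf("ch%03d", seq_len(nrow(data)))
  stopifnot(length(channel_names) == nrow(data))
  rownames(data) <- channel_names
  structure(list(data = data, fs_hz = fs_hz, channel_names = channel_names,
                 run_index = run_index),
            class = "ts_run")
}

#' Segment a run into consecutive non-overlapping epochs
#'
#' The trailing partial epoch is discarded, so the epoch count is
#' floor(duration / epoch_len_s).
#'
#' @param run a `ts_run`.
#' @param epoch_len_s epoch length in seconds (default 3).
#' @return list of channels x samples matrices.
#' @export
segment_epochs <- function(run, epoch_len_s = 3.0) {
  stopifnot(inherits(run, "ts_run"), epoch_len_s > 0)
  len <- as.integer(floor(epoch_len_s * run$fs_hz))
  nsamp <- ncol(run$data)
  n_ep <- nsamp %/% len
  if (n_ep < 1) stop("run shorter than one epoch")
  lapply(seq_len(n_ep), function(k)
    run$data[, ((k - 1L) * len + 1L):(k * len), drop = FALSE])
}

# frequency-domain mask selecting the analytic signal of a 1-Hz bin:
# negative frequencies zeroed, positive frequencies inside
# [centre - bw/2, centre + bw/2] doubled.
analytic_bin_mask <- function(n, fs_hz, bin_center_hz, bandwidth_hz = 1) {
  freq <- (seq_len(n) - 1L) / n * fs_hz
  lo <- bin_center_hz - bandwidth_hz / 2
  hi <- bin_center_hz + bandwidth_hz / 2
  mask <- numeric(n)
  mask[freq >= lo & freq <= hi & freq > 0 & freq < fs_hz / 2] <- 2
  mask
}

#' Instantaneous phase of a 1-Hz frequency bin
#'
#' Band-limited analytic signal: the spectrum is restricted to the positive
#' frequencies of the 1-Hz bin around `bin_center_hz` (zero-phase by
#' construction) and inverse-transformed; the instantaneous phase is its
#' complex argument, in (-pi, pi].
#'
#' @param x numeric vector or channels x samples matrix (one epoch).
#' @param fs_hz sampling rate.
#' @param bin_center_hz bin centre, strictly inside (0, fs/2).
#' @param bandwidth_hz nominal bin width (default 1 Hz).
#' @return phase series, same shape as `x`.
#' @export
bin_phase <- function(x, fs_hz, bin_center_hz, bandwidth_hz = 1) {
  if (bin_center_hz + bandwidth_hz / 2 >= fs_hz / 2 || bin_center_hz <= 0)
    stop("bin centre must lie strictly inside (0, Nyquist)")
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = 1L) else t(x)  # samples x channels
  n <- nrow(xm)
  mask <- analytic_bin_mask(n, fs_hz, bin_center_hz, bandwidth_hz)
  xa <- stats::mvfft(stats::mvfft(xm) * mask, inverse = TRUE) / n
  ph <- Arg(xa)
  if (vec) ph[, 1L] else t(ph)
}

#' Phase-locking value of a channel pair
#'
#' @param phase_a,phase_b equal-length phase series (radians).
#' @return scalar in `[0, 1]`: the modulus of the time-averaged unit phasor
#'   of the phase difference.
#' @export
plv_pair <- function(phase_a, phase_b) {
  if (length(phase_a) == 0L) stop("empty phase series")
  if (length(phase_a) != length(phase_b)) stop("phase series length mismatch")
  Mod(mean(exp(1i * (phase_a - phase_b))))
}

# all-pairs PLV from a channels x samples phase matrix, via the phasor
# cross-product
plv_matrix_from_phase <- function(phase) {
  p <- exp(1i * t(phase))            # samples x channels
  m <- Mod(crossprod(Conj(p), p)) / nrow(p)
  (m + t(m)) / 2                     # enforce exact symmetry
}

#' Band-averaged PLV connectivity matrix for one run
#'
#' For each channel pair the PLV is computed per epoch and per 1-Hz bin,
#' averaged over epochs, then averaged over the bins assigned to the band.
#' A margin at both epoch edges is trimmed from the phase series before the
#' PLV to suppress transients of the band-limiting filter.
#'
#' @param run a `ts_run`.
#' @param band `"theta"`, `"alpha"` or `"beta"`.
#' @param epoch_len_s epoch length in seconds (default 3).
#' @param bins bin-centre grid (default `4:28`); bins are assigned to bands
#'   by centre.
#' @param edge_trim_s seconds trimmed from each end of every epoch's phase
#'   series (default 0.25).
#' @return object of class `band_connectivity`: `matrix` (symmetric, zero
#'   diagonal, entries in `[0, 1]`), `band`, `n_epochs_used`.
#' @export
band_plv_matrix <- function(run, band, epoch_len_s = 3.0,
                            bins = plv_bin_grid(), edge_trim_s = 0.25) {
  stopifnot(inherits(run, "ts_run"))
  band <- match.arg(band, c("theta", "alpha", "beta"))
  use_bins <- band_bins(band, bins)
  epochs <- segment_epochs(run, epoch_len_s)
  nch <- nrow(run$data)
  trim <- as.integer(round(edge_trim_s * run$fs_hz))

  acc <- matrix(0, nch, nch)
  for (ep in epochs) {
    n <- ncol(ep)
    if (2L * trim >= n) stop("edge trim leaves no samples in the epoch")
    keep <- (trim + 1L):(n - trim)
    xm <- t(ep)                       # samples x channels
    xf <- stats::mvfft(xm)
    bin_acc <- matrix(0, nch, nch)
    for (b in use_bins) {
      mask <- analytic_bin_mask(n, run$fs_hz, b)
      xa <- stats::mvfft(xf * mask, inverse = TRUE) / n
      ph <- Arg(xa)[keep, , drop = FALSE]
      bin_acc <- bin_acc + plv_matrix_from_phase(t(ph))
    }
    acc <- acc + bin_acc / length(use_bins)
  }
  m <- acc / length(epochs)
  diag(m) <- 0
  dimnames(m) <- list(run$channel_names, run$channel_names)
  structure(list(matrix = m, band = band, n_epochs_used = length(epochs)),
            class = "band_connectivity")
}

#' Band PLV matrices for all runs of a subject
#'
#' @param runs list of `ts_run`.
#' @param bands character vector of bands.
#' @param ... passed to [band_plv_matrix()].
#' @return nested list: `[[band]][[run]]` of `band_connectivity`.
#' @export
subject_connectivity <- function(runs, bands = c("theta", "alpha", "beta"),
                                 ...) {
  out <- lapply(bands, function(b) lapply(runs, band_plv_matrix, band = b, ...))
  names(out) <- bands
  out
}

#' Write / read a connectivity matrix as TSV
#'
#' @param bc a `band_connectivity`.
#' @param path output TSV path.
#' @export
write_connectivity <- function(bc, path) {
  stopifnot(inherits(bc, "band_connectivity"))
  df <- as.data.frame(bc$matrix)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_connectivity
#' @param band band label to attach on read.
#' @param n_epochs_used epoch count to attach on read.
#' @export
read_connectivity <- function(path, band, n_epochs_used = NA_integer_) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   check.names = FALSE))
  rownames(m) <- colnames(m)
  structure(list(matrix = m, band = band, n_epochs_used = n_epochs_used),
            class = "band_connectivity")
}
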