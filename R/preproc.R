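#' Epoched recordings and frequency bands
#'
#' The central container is an `epoched_recording`: a channels x samples x
#' trials array in microvolts plus sampling rate, montage, per-trial labels,
#' and the epoch window in milliseconds relative to stimulus onset. Sample
#' intervals are half-open and 0-based: an epoch window of (-300, 500) ms at
#' 1000 Hz covers samples `onset - 300` up to but excluding `onset + 500`.
#'
#' @name epoched_recording
NULL

#' Construct an epoched recording
#'
#' @param data numeric array, channels x samples x trials, microvolts
#' @param sampling_rate Hz
#' @param montage montage data frame; rows must match and label the channels
#' @param trial_labels character vector, one per trial (e.g. `"NoGo-CR"`)
#' @param window length-2 epoch window in ms relative to stimulus onset
#' @return an `epoched_recording`
#' @export
epoched_recording <- function(data, sampling_rate, montage,
                              trial_labels = NULL, window = c(-300, 500)) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  validate_montage(montage)
  if (dim(data)[1] != nrow(montage)) {
    stop("channel count (", dim(data)[1], ") does not match montage size (",
         nrow(montage), ")")
  }
  expect_samp <- round(diff(window) / 1000 * sampling_rate)
  if (dim(data)[2] != expect_samp) {
    stop("samples (", dim(data)[2], ") do not match window/sampling rate (",
         expect_samp, ")")
  }
  if (is.null(trial_labels)) trial_labels <- rep(NA_character_, dim(data)[3])
  stopifnot(length(trial_labels) == dim(data)[3])
  dimnames(data)[[1]] <- montage$label
  structure(list(data = data, sampling_rate = sampling_rate,
                 montage = montage, trial_labels = trial_labels,
                 window = window),
            class = "epoched_recording")
}

#' @export
print.epoched_recording <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoched_recording> %d channels x %d samples x %d trials @ %g Hz, window [%g, %g) ms\n",
    d[1], d[2], d[3], x$sampling_rate, x$window[1], x$window[2]))
  invisible(x)
}

#' Standard frequency bands
#'
#' Band definitions used throughout: theta 4-7 Hz, alpha 8-12 Hz,
#' beta 15-30 Hz, gamma 31-45 Hz.
#'
#' @param name one of `"theta"`, `"alpha"`, `"beta"`, `"gamma"`
#' @param low,high custom band edges in Hz (overrides the named defaults)
#' @return a `band_spec` list with `name`, `low`, `high`
#' @export
band_spec <- function(name, low = NULL, high = NULL) {
  defaults <- list(theta = c(4, 7), alpha = c(8, 12),
                   beta = c(15, 30), gamma = c(31, 45))
  if (is.null(low) || is.null(high)) {
    if (!name %in% names(defaults)) {
      stop("unknown band '", name, "'; give explicit low/high")
    }
    low <- defaults[[name]][1]; high <- defaults[[name]][2]
  }
  if (!(low > 0 && high > low)) stop("band edges must satisfy 0 < low < high")
  structure(list(name = name, low = low, high = high), class = "band_spec")
}

#' @rdname band_spec
#' @export
standard_bands <- function() {
  lapply(c("theta", "alpha", "beta", "gamma"), band_spec)
}

#' Cut a continuous recording into event-locked epochs
#'
#' Each event yields the half-open sample interval
#' `[onset + window[1], onset + window[2])` (window in ms, onset 0-based).
#' Events too close to the record edges are dropped with a warning.
#'
#' @param continuous a `continuous_recording` from [read_continuous()], or any
#'   list with `data` (channels x samples), `sampling_rate`, `labels`
#' @param events data frame with `onset_sample` (0-based); defaults to the
#'   events stored in `continuous`
#' @param window epoch window in ms relative to onset
#' @param montage montage for the channels; defaults to the 32-channel montage
#'   subset to the recording's labels
#' @return an `epoched_recording`; trial labels are taken from `events$label`
#' @export
epoch <- function(continuous, events = continuous$events,
                  window = c(-300, 500), montage = NULL) {
  fs <- continuous$sampling_rate
  x <- continuous$data
  n_samp_rec <- ncol(x)
  s0 <- round(window[1] / 1000 * fs)
  s1 <- round(window[2] / 1000 * fs)
  n_ep <- s1 - s0
  keep <- events$onset_sample + s0 >= 0 & events$onset_sample + s1 <= n_samp_rec
  if (any(!keep)) {
    warning(sum(!keep), " event(s) dropped: epoch window extends beyond the record")
  }
  ev <- events[keep, , drop = FALSE]
  if (!nrow(ev)) stop("no events remain after edge filtering")
  out <- array(0, c(nrow(x), n_ep, nrow(ev)))
  for (i in seq_len(nrow(ev))) {
    a <- ev$onset_sample[i] + s0
    out[, , i] <- x[, (a + 1):(a + n_ep), drop = FALSE]
  }
  if (is.null(montage)) montage <- montage_subset(standard_montage_32(),
                                                 continuous$labels)
  labs <- if ("label" %in% names(ev)) ev$label else NULL
  epoched_recording(out, fs, montage, trial_labels = labs, window = window)
}

# Hamming-window FIR band-pass design following the common published
# heuristic: transition bandwidth min(max(0.25 * cutoff, 2 Hz), distance to
# band edge limit); order = ceil(3.3 / (tbw / fs)) rounded up to even. A
# single linear-phase filter admits one transition width, so the smaller of
# the two edge widths is used.
fir_design <- function(low, high, sampling_rate) {
  nyq <- sampling_rate / 2
  if (!(low > 0 && high > low && high < nyq)) {
    stop("cutoffs must satisfy 0 < low < high < Nyquist (", nyq, " Hz)")
  }
  tbw_low <- min(max(0.25 * low, 2), low)
  tbw_high <- min(max(0.25 * high, 2), nyq - high)
  tbw <- min(tbw_low, tbw_high)
  ord <- ceiling(3.3 / (tbw / sampling_rate))
  ord <- ord + ord %% 2  # even order -> odd, symmetric tap count
  taps <- signal::fir1(ord, c(low, high) / nyq, type = "pass",
                       window = signal::hamming(ord + 1))
  as.numeric(taps)
}

# zero-phase FIR application along rows of a matrix (or a vector):
# reflection-tiled padding, single-pass linear-phase filter via FFT
# convolution (all rows at once), compensate the integer group delay of the
# symmetric taps
apply_fir <- function(x, taps) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  gd <- (length(taps) - 1) / 2
  pad <- length(taps)
  # symmetric reflection indices, tiled with period 2n - 2 so the padding
  # may exceed the signal length (filters longer than an epoch)
  p <- (1 - pad):(n + pad)
  m <- (p - 1) %% max(2 * n - 2, 1)
  ridx <- ifelse(m < n, m + 1, 2 * n - 1 - m)
  xp <- x[, ridx, drop = FALSE]
  nfft <- stats::nextn(ncol(xp) + length(taps) - 1, 2)
  H <- stats::fft(c(taps, rep(0, nfft - length(taps))))
  XP <- rbind(t(xp), matrix(0, nfft - ncol(xp), nrow(xp)))
  Y <- Re(stats::mvfft(stats::mvfft(XP) * H, inverse = TRUE)) / nfft
  out <- t(Y[(pad + gd + 1):(pad + gd + n), , drop = FALSE])
  if (vec) drop(out) else out
}

#' Zero-phase FIR band-pass filter
#'
#' Hamming-windowed FIR with heuristic order and transition-width selection,
#' applied in a single pass with group-delay compensation (the symmetric
#' linear-phase taps make this exactly zero-phase). Signal edges are padded
#' by tiled symmetric reflection, so the filter may be longer than the
#' signal; short epochs keep the heuristic's full spectral selectivity at
#' the cost of reflection artifacts near the edges (downstream phase
#' analysis flags edge samples as guards).
#'
#' @param x numeric vector (one signal), matrix (channels x samples), or
#'   3-d array (channels x samples x trials)
#' @param low,high band edges in Hz
#' @param sampling_rate Hz
#' @return filtered object of the same shape
#' @export
fir_bandpass <- function(x, low, high, sampling_rate) {
  taps <- fir_design(low, high, sampling_rate)
  if (is.array(x) && length(dim(x)) == 3) {
    d <- dim(x)
    # rows = channel x trial signals, filtered in one FFT batch
    flat <- matrix(aperm(x, c(1, 3, 2)), nrow = d[1] * d[3])
    y <- apply_fir(flat, taps)
    aperm(array(y, c(d[1], d[3], d[2])), c(1, 3, 2))
  } else {
    apply_fir(x, taps)
  }
}

#' Re-reference an epoched recording
#'
#' Subtracts the reference channel's signal from every channel and removes the
#' reference channel from the output (an identically-zero channel would
#' corrupt phase estimates downstream).
#'
#' @param recording an `epoched_recording`
#' @param reference_label channel to use as reference (default `"FCz"`)
#' @return the re-referenced recording, with one channel fewer
#' @export
rereference <- function(recording, reference_label = "FCz") {
  labs <- recording$montage$label
  ri <- match(reference_label, labs)
  if (is.na(ri)) stop("reference channel '", reference_label,
                      "' not present in the recording")
  ref <- recording$data[ri, , , drop = FALSE]
  out <- sweep(recording$data, 2:3, array(ref, dim(recording$data)[2:3]), "-")
  out <- out[-ri, , , drop = FALSE]
  epoched_recording(out, recording$sampling_rate,
                    montage_subset(recording$montage, labs[-ri]),
                    recording$trial_labels, recording$window)
}

# spherical-spline interpolation basis (stiffness m, L Legendre terms)
spline_g <- function(cosang, m = 4, L = 20) {
  # Legendre polynomials P_1..P_L at cosang via recurrence
  p_prev <- rep(1, length(cosang))  # P_0
  p_cur <- cosang                   # P_1
  g <- (2 * 1 + 1) / (1^m * 2^m) * p_cur
  for (n in 2:L) {
    p_new <- ((2 * n - 1) * cosang * p_cur - (n - 1) * p_prev) / n
    g <- g + (2 * n + 1) / (n^m * (n + 1)^m) * p_new
    p_prev <- p_cur; p_cur <- p_new
  }
  g / (4 * pi)
}

#' Spherical-spline interpolation of bad channels
#'
#' Replaces the listed channels with spherical-spline estimates (stiffness
#' m = 4, 20-term Legendre expansion, ridge regularization 1e-5 on the
#' spline system) computed from the remaining channels. Good channels are
#' left untouched.
#'
#' @param recording an `epoched_recording`
#' @param bad_labels channels to interpolate (strict subset; at least 4 good
#'   channels must remain)
#' @param lambda ridge regularization added to the spline system diagonal
#' @return the recording with bad channels replaced
#' @export
interpolate_channels <- function(recording, bad_labels, lambda = 1e-5) {
  labs <- recording$montage$label
  bad <- match(bad_labels, labs)
  if (anyNA(bad)) stop("unknown channel(s): ",
                       paste(bad_labels[is.na(bad)], collapse = ", "))
  good <- setdiff(seq_along(labs), bad)
  if (length(good) < 4) stop("need at least 4 good channels to interpolate")
  pos <- as.matrix(recording$montage[, c("x", "y", "z")])
  cos_gg <- tcrossprod(pos[good, , drop = FALSE])
  cos_bg <- pos[bad, , drop = FALSE] %*% t(pos[good, , drop = FALSE])
  G <- spline_g(pmin(pmax(cos_gg, -1), 1))
  Gb <- spline_g(pmin(pmax(cos_bg, -1), 1))
  ng <- length(good)
  # spline system with the constant term:  [G + lambda I, 1; 1', 0]
  A <- rbind(cbind(G + lambda * diag(ng), rep(1, ng)), c(rep(1, ng), 0))
  d <- dim(recording$data)
  V <- matrix(recording$data[good, , ], nrow = ng)  # good x (samples*trials)
  coefs <- solve(A, rbind(V, 0))
  est <- cbind(Gb, rep(1, length(bad))) %*% coefs
  out <- recording$data
  out[bad, , ] <- array(est, c(length(bad), d[2], d[3]))
  recording$data <- out
  recording
}

#' Reject high-amplitude epochs
#'
#' Drops trials in which any channel's peak-to-peak amplitude exceeds the
#' threshold — an automated stand-in for manual artifact screening.
#'
#' @param recording an `epoched_recording`
#' @param peak_to_peak_uv rejection threshold in microvolts (> 0)
#' @return the cleaned recording, with attribute `"rejection_log"` (a list
#'   with `n_total`, `n_rejected`, `rejected_trials`, `threshold`)
#' @export
reject_epochs <- function(recording, peak_to_peak_uv = 150) {
  stopifnot(peak_to_peak_uv > 0)
  d <- recording$data
  ptp <- apply(d, 3, function(tr) max(apply(tr, 1, function(ch) diff(range(ch)))))
  bad <- ptp > peak_to_peak_uv
  if (all(bad)) stop("all trials rejected at threshold ", peak_to_peak_uv, " uV")
  out <- recording
  out$data <- d[, , !bad, drop = FALSE]
  out$trial_labels <- recording$trial_labels[!bad]
  attr(out, "rejection_log") <- list(
    n_total = length(bad), n_rejected = sum(bad),
    rejected_trials = which(bad), threshold = peak_to_peak_uv
  )
  out
}

#' Write / read the epoch interchange format
#'
#' One subject's epochs are stored as a pair of files: `<stem>.bin`, the raw
#' little-endian float64 data tensor in channel-fastest order, and
#' `<stem>.json`, a sidecar with the format version, dimensions, sampling
#' rate, channel labels and positions, trial labels, and epoch window.
#'
#' @param recording an `epoched_recording`
#' @param stem output path without extension
#' @return `write_epochs`: the stem, invisibly. `read_epochs`: the recording.
#' @export
write_epochs <- function(recording, stem) {
  meta <- list(
    format = "ciplvnet-epochs", version = 1L,
    dim = dim(recording$data),
    sampling_rate = recording$sampling_rate,
    channels = recording$montage$label,
    positions = unname(as.matrix(recording$montage[, c("x", "y", "z")])),
    trial_labels = recording$trial_labels,
    window_ms = recording$window
  )
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(paste0(stem, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(recording$data), con, size = 8, endian = "little")
  invisible(stem)
}

#' @rdname write_epochs
#' @param stem path without extension, as given to [write_epochs()]
#' @export
read_epochs <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  if (!identical(meta$format, "ciplvnet-epochs")) {
    stop("not a ciplvnet epochs file: ", stem)
  }
  n <- prod(meta$dim)
  con <- file(paste0(stem, ".bin"), "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n, size = 8, endian = "little")
  mont <- data.frame(label = meta$channels, x = meta$positions[, 1],
                     y = meta$positions[, 2], z = meta$positions[, 3],
                     stringsAsFactors = FALSE)
  labs <- meta$trial_labels
  if (length(labs)) labs[labs == "NA"] <- NA_character_
  epoched_recording(array(x, meta$dim), meta$sampling_rate, mont,
                    trial_labels = labs, window = meta$window_ms)
}
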