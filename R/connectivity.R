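#' Corrected imaginary phase locking value
#'
#' Phase synchronization between two channels is measured across trials: at
#' each latency the phase differences of the N trials are averaged as unit
#' phasors, `C = mean(exp(1i * dphi))`, and the corrected imaginary PLV is
#' `|Im(C)| / sqrt(1 - Re(C)^2)`. Zero-lag (volume-conducted) coupling
#' contributes only to the real part and is suppressed; a consistent non-zero
#' phase lag drives the value toward 1. The measure is undirected (absolute
#' value) and bounded in \code{[0, 1]}.
#'
#' @name ciplv-connectivity
NULL

# analytic signal via FFT: zero negative frequencies, double positive ones
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Band-limited instantaneous phase of an epoched recording
#'
#' Band-pass filters each channel/trial (Hamming FIR, heuristic order) and
#' takes the analytic-signal phase. The outer 10% of samples at each epoch
#' edge are marked as guard samples, to be excluded from across-trial
#' statistics: filter transients and analytic-signal edge effects concentrate
#' there.
#'
#' @param recording an `epoched_recording`
#' @param band a [band_spec()]
#' @param guard_fraction fraction of samples flagged as guards at each edge
#' @return a `phase_tensor` list: `phase` (channels x samples x trials,
#'   radians in (-pi, pi]), `guard` (logical per sample), `band`,
#'   `sampling_rate`
#' @export
analytic_phase <- function(recording, band, guard_fraction = 0.1) {
  stopifnot(inherits(band, "band_spec"))
  d <- dim(recording$data)
  fs <- recording$sampling_rate
  epoch_s <- d[2] / fs
  if (epoch_s < 2 / band$low) {
    stop("epoch too short for band '", band$name, "': need >= 2 cycles of ",
         band$low, " Hz")
  }
  filt <- fir_bandpass(recording$data, band$low, band$high, fs)
  # analytic phase of every channel/trial in one FFT batch
  n <- d[2]
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  flat <- matrix(aperm(filt, c(2, 1, 3)), nrow = n)
  z <- stats::mvfft(stats::mvfft(flat) * h, inverse = TRUE) / n
  ph <- aperm(array(Arg(z), c(n, d[1], d[3])), c(2, 1, 3))
  n_guard <- ceiling(guard_fraction * d[2])
  guard <- rep(FALSE, d[2])
  guard[c(seq_len(n_guard), (d[2] - n_guard + 1):d[2])] <- TRUE
  dimnames(ph)[[1]] <- recording$montage$label
  structure(list(phase = ph, guard = guard, band = band, sampling_rate = fs),
            class = "phase_tensor")
}

#' ciPLV of a set of across-trial phase differences
#'
#' @param dphi numeric vector of phase differences (radians), one per trial
#' @return ciPLV in \code{[0, 1]}. Perfect zero-lag locking (`Re(C)^2 == 1`)
#'   returns 0 by continuity, with a message.
#' @examples
#' ciplv(rep(pi / 2, 10))  # 1
#' ciplv(rep(0, 10))       # 0
#' @export
ciplv <- function(dphi) {
  if (length(dphi) < 2) stop("need at least 2 trials")
  C <- mean(exp(1i * dphi))
  re2 <- Re(C)^2
  if (re2 >= 1 - 1e-15) {
    message("ciplv: perfect zero-lag locking; returning 0 by continuity")
    return(0)
  }
  abs(Im(C)) / sqrt(1 - re2)
}

# vectorized ciPLV over all channel pairs at every non-guard sample, averaged
# over samples; phase: channels x samples x trials
ciplv_matrix_from_phase <- function(phase, guard) {
  d <- dim(phase)
  nch <- d[1]
  samples <- which(!guard)
  acc <- matrix(0, nch, nch)
  z <- exp(1i * phase)
  for (s in samples) {
    Zs <- matrix(z[, s, ], nrow = nch)       # channels x trials
    C <- Zs %*% Conj(t(Zs)) / d[3]           # mean cross-phasor
    re2 <- pmin(Re(C)^2, 1 - 1e-15)
    acc <- acc + abs(Im(C)) / sqrt(1 - re2)
  }
  m <- acc / length(samples)
  diag(m) <- 0
  m
}

#' Across-trial ciPLV connectivity matrix
#'
#' For every channel pair, ciPLV is computed across the selected trials at
#' each non-guard latency and averaged over latencies.
#'
#' @param recording an `epoched_recording`
#' @param band a [band_spec()]
#' @param trial_selector optional: logical/integer index of trials, or a
#'   character vector of trial labels to keep (e.g. `"NoGo-CR"`)
#' @param guard_fraction see [analytic_phase()]
#' @return a `connectivity_matrix`: list with `values` (symmetric, zero
#'   diagonal, entries in \code{[0, 1]}, labelled), `band`, `n_trials`,
#'   `channels`
#' @export
connectivity_matrix <- function(recording, band, trial_selector = NULL,
                                guard_fraction = 0.1) {
  sel <- select_trials(recording, trial_selector)
  if (sum(sel) < 2) stop("fewer than 2 trials selected")
  rec <- recording
  rec$data <- recording$data[, , sel, drop = FALSE]
  rec$trial_labels <- recording$trial_labels[sel]
  pt <- analytic_phase(rec, band, guard_fraction)
  vals <- ciplv_matrix_from_phase(pt$phase, pt$guard)
  labs <- recording$montage$label
  dimnames(vals) <- list(labs, labs)
  structure(list(values = vals, band = band, n_trials = sum(sel),
                 channels = labs),
            class = "connectivity_matrix")
}

select_trials <- function(recording, trial_selector) {
  n <- dim(recording$data)[3]
  if (is.null(trial_selector)) return(rep(TRUE, n))
  if (is.character(trial_selector)) {
    return(recording$trial_labels %in% trial_selector)
  }
  if (is.logical(trial_selector)) {
    stopifnot(length(trial_selector) == n)
    return(trial_selector)
  }
  seq_len(n) %in% trial_selector
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %s band (%g-%g Hz), %d channels, %d trials, mean ciPLV %.3f\n",
              x$band$name, x$band$low, x$band$high, length(x$channels),
              x$n_trials, mean(x$values[upper.tri(x$values)])))
  invisible(x)
}

#' Write a connectivity matrix as labelled CSV
#'
#' @param cm a `connectivity_matrix`
#' @param path file path
#' @export
write_connectivity_csv <- function(cm, path) {
  utils::write.csv(as.data.frame(cm$values), path, row.names = TRUE)
  invisible(path)
}
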