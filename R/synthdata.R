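#' Synthetic coupled-oscillator EEG
#'
#' The generator emulates the signal model that phase-synchronization
#' analysis assumes: every channel is 1/f background noise plus band-limited
#' oscillations, and selected channel pairs share a band-limited component
#' injected with a fixed phase lag. The shared component has a random phase
#' in every trial, so only the *lag* is consistent across trials — exactly
#' the structure ciPLV detects. Coupling is injected additively in signal
#' space, before any analysis filtering, so the generator does not presuppose
#' the analysis path.
#'
#' @name synthdata
NULL

#' Ground-truth coupling between one channel pair
#'
#' @param pair length-2 character vector of channel labels
#' @param band a [band_spec()]
#' @param phase_lag lag in radians, in (-pi, pi]; applied to the second
#'   channel of the pair
#' @param strength fraction of shared oscillatory amplitude in \code{[0, 1]};
#'   0 means independent channels
#' @return a `coupling_spec`
#' @export
coupling_spec <- function(pair, band = band_spec("alpha"),
                          phase_lag = pi / 2, strength = 1) {
  stopifnot(length(pair) == 2, inherits(band, "band_spec"))
  if (!(phase_lag > -pi && phase_lag <= pi)) {
    stop("phase_lag must be in (-pi, pi]")
  }
  if (strength < 0 || strength > 1) stop("strength must be in [0, 1]")
  structure(list(pair = pair, band = band, phase_lag = phase_lag,
                 strength = strength), class = "coupling_spec")
}

#' Specification of a two-group synthetic EEG study
#'
#' @param n_subjects named integer vector of group sizes, default
#'   `c(subacute = 13, chronic = 14)`
#' @param channels channel labels; default the 32-channel montage
#' @param sampling_rate Hz
#' @param n_trials epochs per subject (these represent the valid No-Go trials
#'   entering connectivity)
#' @param epoch_window ms pair, default the 800 ms window (-300, +500) around
#'   stimulus onset
#' @param coupling named list (one entry per group) of lists of
#'   [coupling_spec()]s
#' @param noise_exponent power-law exponent of the background spectrum
#'   (1 = pink noise, the standard resting-EEG shape)
#' @param osc_snr total oscillatory amplitude as a multiple of the background
#'   noise amplitude
#' @param noise_amp_uv background noise SD in microvolts
#' @param osc_bands bands in which every channel carries an (independent)
#'   oscillation; defaults to theta/alpha/beta/gamma
#' @param seed integer seed; the seed fully determines the output
#' @return a `study_spec`
#' @export
study_spec <- function(n_subjects = c(subacute = 13, chronic = 14),
                       channels = NULL, sampling_rate = 250, n_trials = 75,
                       epoch_window = c(-300, 500),
                       coupling = list(), noise_exponent = 1, osc_snr = 2,
                       noise_amp_uv = 10, osc_bands = standard_bands(),
                       seed = 1) {
  if (is.null(channels)) channels <- standard_montage_32()$label
  stopifnot(all(n_subjects >= 1), length(names(n_subjects)) == length(n_subjects))
  for (g in names(coupling)) {
    if (!g %in% names(n_subjects)) stop("coupling for unknown group: ", g)
    for (cs in coupling[[g]]) {
      stopifnot(inherits(cs, "coupling_spec"))
      missing_ch <- setdiff(cs$pair, channels)
      if (length(missing_ch)) {
        stop("coupling channel(s) not in montage: ",
             paste(missing_ch, collapse = ", "))
      }
    }
  }
  structure(list(n_subjects = n_subjects, channels = channels,
                 sampling_rate = sampling_rate, n_trials = n_trials,
                 epoch_window = epoch_window, coupling = coupling,
                 noise_exponent = noise_exponent, osc_snr = osc_snr,
                 noise_amp_uv = noise_amp_uv, osc_bands = osc_bands,
                 seed = seed),
            class = "study_spec")
}

# columns of 1/f^exponent noise, each normalized to unit SD
one_over_f_mat <- function(n, m, exponent, sampling_rate) {
  W <- matrix(stats::rnorm(n * m), n, m)
  F <- stats::mvfft(W)
  freq <- c(0, seq_len(n - 1)) * sampling_rate / n
  freq <- pmin(freq, sampling_rate - freq)  # two-sided
  scale <- c(0, 1 / freq[-1]^(exponent / 2))
  X <- Re(stats::mvfft(F * scale, inverse = TRUE)) / n
  sds <- sqrt(pmax(colMeans(X^2) - colMeans(X)^2, 1e-300) * n / (n - 1))
  X / rep(sds, each = n)
}

# columns of complex narrowband signals (analytic: positive-frequency
# content only), Re part normalized to unit SD
narrowband_mat <- function(n, m, low, high, sampling_rate) {
  freq <- (0:(n - 1)) * sampling_rate / n
  bins <- which(freq >= low & freq <= high & freq <= sampling_rate / 2)
  spec <- matrix(0 + 0i, n, m)
  nb <- length(bins)
  spec[bins, ] <- matrix(complex(real = stats::rnorm(nb * m),
                                 imaginary = stats::rnorm(nb * m)), nb, m)
  Z <- stats::mvfft(spec, inverse = TRUE)
  zr <- Re(Z)
  sds <- sqrt(pmax(colMeans(zr^2) - colMeans(zr)^2, 1e-300) * n / (n - 1))
  Z / rep(sds, each = n)
}

band_key <- function(band) paste0(band$low, "-", band$high)

# generate one subject's channels x samples x trials array
generate_subject_epochs <- function(spec, group, n_samp) {
  nch <- length(spec$channels)
  ntr <- spec$n_trials
  fs <- spec$sampling_rate
  noise <- one_over_f_mat(n_samp, nch * ntr, spec$noise_exponent, fs) *
    spec$noise_amp_uv
  x <- array(noise, c(n_samp, nch, ntr))

  nb <- length(spec$osc_bands)
  a_b <- spec$noise_amp_uv * spec$osc_snr / sqrt(nb)
  coupl <- spec$coupling[[group]]
  coupl_keys <- vapply(coupl, function(cs) band_key(cs$band), "")
  for (b in spec$osc_bands) {
    Z <- narrowband_mat(n_samp, nch * ntr, b$low, b$high, fs)
    Z <- array(Z, c(n_samp, nch, ntr))
    for (ci in which(coupl_keys == band_key(b))) {
      cs <- coupl[[ci]]
      i1 <- match(cs$pair[1], spec$channels)
      i2 <- match(cs$pair[2], spec$channels)
      sh <- narrowband_mat(n_samp, ntr, b$low, b$high, fs)
      s <- cs$strength
      Z[, i1, ] <- (1 - s) * Z[, i1, ] + s * sh
      Z[, i2, ] <- (1 - s) * Z[, i2, ] + s * sh * exp(-1i * cs$phase_lag)
    }
    x <- x + a_b * Re(Z)
  }
  aperm(x, c(2, 1, 3))  # channels x samples x trials
}

#' Generate coupled multichannel EEG epochs for a whole study
#'
#' One `epoched_recording` per subject; each carries attributes `group` and
#' `subject_id`. All trials are labelled `"NoGo-CR"` (they stand for the
#' valid No-Go epochs entering connectivity analysis).
#'
#' @param spec a [study_spec()]
#' @return list of `epoched_recording`s, length `sum(spec$n_subjects)`
#' @export
generate_coupled_epochs <- function(spec) {
  stopifnot(inherits(spec, "study_spec"))
  fs <- spec$sampling_rate
  n_samp <- round(diff(spec$epoch_window) / 1000 * fs)
  mont <- montage_subset(standard_montage_32(), spec$channels)
  local_rng(spec$seed)
  n_total <- sum(spec$n_subjects)
  sub_seeds <- sample.int(2147483646, n_total)
  groups <- rep(names(spec$n_subjects), spec$n_subjects)
  out <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    set.seed(sub_seeds[i])
    arr <- generate_subject_epochs(spec, groups[i], n_samp)
    rec <- epoched_recording(arr, fs, mont,
                             trial_labels = rep("NoGo-CR", spec$n_trials),
                             window = spec$epoch_window)
    attr(rec, "group") <- groups[i]
    attr(rec, "subject_id") <- i
    out[[i]] <- rec
  }
  names(out) <- sprintf("sub%02d", seq_len(n_total))
  out
}
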