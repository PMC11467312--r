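# Independent brute-force oracles used across the network and stats tests.
# These deliberately avoid the package's own code paths.

# Floyd-Warshall all-pairs shortest paths over edge lengths 1/w
bf_shortest <- function(W) {
  n <- nrow(W)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[W > 0] <- 1 / W[W > 0]
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

bf_global_eff <- function(W) {
  n <- nrow(W)
  D <- bf_shortest(W)
  inv <- 1 / D
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

# direct Newman modularity of a partition (independent of the package)
bf_modularity <- function(W, mem, gamma = 1) {
  k <- rowSums(W)
  m2 <- sum(k)
  same <- outer(mem, mem, "==")
  sum(((W - gamma * outer(k, k) / m2) * same)) / m2
}

# enumerate all set partitions of 1..n as restricted growth strings
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxv) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(maxv + 1)) rec(c(prefix, v), max(maxv, v))
  }
  rec(integer(0), 0L)
  out
}

bf_best_q <- function(W, gamma = 1) {
  best <- -Inf
  for (mem in all_partitions(nrow(W))) {
    q <- bf_modularity(W, mem, gamma)
    if (q > best) best <- q
  }
  best
}

# random symmetric weighted graph with zero diagonal
rand_graph <- function(n, density = 0.6, wmax = 1) {
  W <- matrix(0, n, n)
  up <- upper.tri(W)
  vals <- ifelse(runif(sum(up)) < density, runif(sum(up), 0.05, wmax), 0)
  W[up] <- vals
  W + t(W)
}

# graph of two unit-weight triangles, disconnected
two_triangles <- function() {
  W <- matrix(0, 6, 6)
  for (p in list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6))) {
    W[p[1], p[2]] <- W[p[2], p[1]] <- 1
  }
  W
}

# small epoched recording filled with given per-channel signals
make_recording <- function(signals, fs = 250, labels = NULL,
                           n_trials = 1, window = NULL) {
  n_ch <- nrow(signals)
  if (is.null(labels)) {
    labels <- standard_montage_32()$label[seq_len(n_ch)]
  }
  mont <- montage_subset(standard_montage_32(), labels)
  n <- ncol(signals)
  if (is.null(window)) window <- c(0, n / fs * 1000)
  arr <- array(rep(signals, n_trials), c(n_ch, n, n_trials))
  epoched_recording(arr, fs, mont, window = window)
}

# Monte-Carlo null sample of pipeline-style ciPLV for independent channels.
# Channels are built with test-local code emulating the generator's signal
# model (1/f background plus an in-band oscillation at the default
# oscillation-to-noise ratio): phases come from a test-local analytic signal,
# ciPLV per latency is averaged over non-guard latencies. Shares only the
# fir_bandpass primitive with the package.
mc_ciplv_null <- function(n_draws, n_trials, n_samp = 200, fs = 250,
                          band = c(8, 12), guard = 0.1, osc_amp = 1) {
  analytic_local <- function(x) {
    n <- length(x)
    X <- fft(x)
    h <- numeric(n)
    h[1] <- 1
    if (n %% 2 == 0) {
      h[n / 2 + 1] <- 1
      h[2:(n / 2)] <- 2
    } else h[2:((n + 1) / 2)] <- 2
    fft(X * h, inverse = TRUE) / n
  }
  freq <- (0:(n_samp - 1)) * fs / n_samp
  freq2 <- pmin(freq, fs - freq)
  pink_scale <- c(0, 1 / sqrt(freq2[-1]))
  band_bins <- which(freq >= band[1] & freq <= band[2] & freq <= fs / 2)
  one_channel <- function() {
    # pink background, unit SD per trial
    bg <- apply(matrix(rnorm(n_samp * n_trials), n_samp), 2, function(w) {
      v <- Re(fft(fft(w) * pink_scale, inverse = TRUE)) / n_samp
      v / sd(v)
    })
    # independent in-band oscillation, unit SD, amplitude osc_amp
    osc <- apply(matrix(0, n_samp, n_trials), 2, function(col) {
      spec <- rep(0 + 0i, n_samp)
      spec[band_bins] <- complex(real = rnorm(length(band_bins)),
                                 imaginary = rnorm(length(band_bins)))
      v <- Re(fft(spec, inverse = TRUE))
      v / sd(v)
    })
    t(bg + osc_amp * osc)  # trials x samples
  }
  chan_phase <- function() {
    xf <- fir_bandpass(one_channel(), band[1], band[2], fs)
    t(apply(xf, 1, function(r) Arg(analytic_local(r))))
  }
  ng <- ceiling(guard * n_samp)
  keep <- setdiff(seq_len(n_samp), c(seq_len(ng), (n_samp - ng + 1):n_samp))
  vapply(seq_len(n_draws), function(d) {
    p1 <- chan_phase(); p2 <- chan_phase()
    vals <- vapply(keep, function(s) {
      C <- mean(exp(1i * (p1[, s] - p2[, s])))
      abs(Im(C)) / sqrt(1 - min(Re(C)^2, 1 - 1e-15))
    }, 0)
    mean(vals)
  }, 0)
}
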