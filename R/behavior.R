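#' Go/No-Go signal-detection scoring
#'
#' Trial logs record, per trial, the stimulus class (`Go` / `NoGo`), whether
#' the subject responded, and the reaction time in ms when they did.
#' Performance is summarized by hit rate, false-alarm rate (both with the
#' standard perfect-score adjustment), the sensitivity index d' (difference of
#' standard-normal quantiles of the two rates), and RT statistics over Go hits.
#'
#' @name behavior
NULL

#' Proportion with perfect-score adjustment
#'
#' Perfect scores are pulled off the boundary so that the normal quantile is
#' finite: a perfect count maps to `1 - 1/(2n)` and a zero count to `1/(2n)`;
#' anything else is the plain proportion `count/n`.
#'
#' @param count number of events (0..n)
#' @param n number of opportunities (>= 1)
#' @return adjusted proportion in (0, 1)
#' @examples
#' adjust_rate(225, 225)  # 1 - 1/450
#' adjust_rate(0, 75)     # 1/150
#' @export
adjust_rate <- function(count, n) {
  if (n < 1) stop("n must be >= 1")
  if (count < 0 || count > n) stop("count must be in [0, n]")
  if (count == n) return(1 - 1 / (2 * n))
  if (count == 0) return(1 / (2 * n))
  count / n
}

#' Sensitivity index d'
#'
#' `qnorm(adjusted hit rate) - qnorm(adjusted false-alarm rate)`.
#'
#' @param hits,n_go hit count and number of Go trials
#' @param fas,n_nogo false-alarm count and number of No-Go trials
#' @return d' (unitless, finite)
#' @examples
#' dprime(45, 60, 15, 60)  # 2 * qnorm(0.75)
#' @export
dprime <- function(hits, n_go, fas, n_nogo) {
  stats::qnorm(adjust_rate(hits, n_go)) - stats::qnorm(adjust_rate(fas, n_nogo))
}

#' Score a Go/No-Go trial log
#'
#' Hits are responded Go trials; false alarms are responded No-Go trials. RT
#' statistics are computed over Go hits only. Responses faster than 100 ms are
#' flagged as anticipatory but kept. The input log is also returned with a
#' per-trial outcome label (`Go-hit`, `Go-miss`, `NoGo-CR`, `NoGo-FA`) for
#' downstream epoch selection.
#'
#' @param log data frame with columns `stimulus` (`"Go"`/`"NoGo"`),
#'   `responded` (logical), `rt_ms` (NA when no response)
#' @return a `behavior_summary` list: counts, adjusted rates, `d_prime`,
#'   `mean_rt`, `median_rt`, `n_anticipatory`, and `trials` (the labelled log)
#' @export
score_log <- function(log) {
  stopifnot(all(c("stimulus", "responded", "rt_ms") %in% names(log)))
  go <- log$stimulus == "Go"
  n_go <- sum(go); n_nogo <- sum(!go)
  if (n_go < 1 || n_nogo < 1) stop("log must contain both Go and NoGo trials")
  hits <- sum(go & log$responded)
  fas <- sum(!go & log$responded)
  rts <- log$rt_ms[go & log$responded]
  lab <- ifelse(go,
                ifelse(log$responded, "Go-hit", "Go-miss"),
                ifelse(log$responded, "NoGo-FA", "NoGo-CR"))
  out <- list(
    n_go = n_go, n_nogo = n_nogo, hits = hits, false_alarms = fas,
    hit_rate = adjust_rate(hits, n_go), fa_rate = adjust_rate(fas, n_nogo),
    d_prime = dprime(hits, n_go, fas, n_nogo),
    mean_rt = if (length(rts)) mean(rts) else NA_real_,
    median_rt = if (length(rts)) stats::median(rts) else NA_real_,
    n_anticipatory = sum(rts < 100),
    trials = transform(log, outcome = lab)
  )
  class(out) <- "behavior_summary"
  out
}

#' @export
print.behavior_summary <- function(x, ...) {
  cat(sprintf(
    "<behavior_summary> %d Go / %d NoGo; hits %d (%.3f), FA %d (%.3f), d' = %.3f, mean RT %.0f ms\n",
    x$n_go, x$n_nogo, x$hits, x$hit_rate, x$false_alarms, x$fa_rate,
    x$d_prime, x$mean_rt))
  invisible(x)
}

#' Go/No-Go task structure
#'
#' Defaults follow the standard design: 5 blocks of 60 trials, 75% Go / 25%
#' No-Go in pseudo-random order (at most 3 consecutive No-Go trials within a
#' block), stimulus duration 300 ms, inter-stimulus intervals drawn from
#' {800, 1000, 1200} ms.
#'
#' @param n_blocks,trials_per_block task structure
#' @param p_go proportion of Go trials per block
#' @param isi_ms candidate inter-stimulus intervals (ms)
#' @param stimulus_ms stimulus duration (ms)
#' @return a `task_spec` list
#' @export
task_spec <- function(n_blocks = 5, trials_per_block = 60, p_go = 0.75,
                      isi_ms = c(800, 1000, 1200), stimulus_ms = 300) {
  n_go_block <- round(trials_per_block * p_go)
  structure(list(n_blocks = n_blocks, trials_per_block = trials_per_block,
                 n_go_block = n_go_block,
                 n_nogo_block = trials_per_block - n_go_block,
                 isi_ms = isi_ms, stimulus_ms = stimulus_ms),
            class = "task_spec")
}

# within-block shuffle with at most `max_run` consecutive No-Go trials
shuffle_block <- function(n_go, n_nogo, max_run = 3) {
  repeat {
    s <- sample(c(rep("Go", n_go), rep("NoGo", n_nogo)))
    r <- rle(s)
    if (all(r$lengths[r$values == "NoGo"] <= max_run)) return(s)
  }
}

#' Simulate a Go/No-Go trial log
#'
#' Responses are Bernoulli with the subject's hit and false-alarm
#' probabilities; RTs for responded trials are log-normal with the stated
#' median and shape.
#'
#' @param task a [task_spec()]
#' @param subject list with `hit_p`, `fa_p` (response probabilities in
#'   \code{[0, 1]}), `rt_median_ms`, `rt_sdlog`
#' @param seed integer seed; identical seed and parameters give an identical log
#' @return a trial-log data frame (`block`, `stimulus`, `isi_ms`, `responded`,
#'   `rt_ms`)
#' @export
generate_behavior <- function(task = task_spec(),
                              subject = list(hit_p = 0.95, fa_p = 0.15,
                                             rt_median_ms = 450,
                                             rt_sdlog = 0.25),
                              seed = 1) {
  if (subject$hit_p < 0 || subject$hit_p > 1 ||
      subject$fa_p < 0 || subject$fa_p > 1) {
    stop("hit_p and fa_p must be in [0, 1]")
  }
  if (subject$rt_median_ms <= 0 || subject$rt_sdlog < 0) {
    stop("invalid RT distribution parameters")
  }
  local_rng(seed)
  stim <- unlist(lapply(seq_len(task$n_blocks), function(b) {
    shuffle_block(task$n_go_block, task$n_nogo_block)
  }))
  n <- length(stim)
  p <- ifelse(stim == "Go", subject$hit_p, subject$fa_p)
  responded <- stats::runif(n) < p
  rt <- rep(NA_real_, n)
  rt[responded] <- stats::rlnorm(sum(responded),
                                 meanlog = log(subject$rt_median_ms),
                                 sdlog = subject$rt_sdlog)
  data.frame(
    block = rep(seq_len(task$n_blocks), each = task$trials_per_block),
    stimulus = stim,
    isi_ms = sample(task$isi_ms, n, replace = TRUE),
    responded = responded,
    rt_ms = round(rt, 1),
    stringsAsFactors = FALSE
  )
}

#' Read / write trial logs as CSV
#'
#' @param log a trial-log data frame
#' @param path file path
#' @export
write_trial_log <- function(log, path) {
  utils::write.csv(log, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$responded <- as.logical(df$responded)
  df
}
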