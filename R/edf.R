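#' Minimal EDF/EDF+ input and output
#'
#' Continuous multichannel recordings enter the pipeline as European Data
#' Format (EDF) files. The implementation covers the subset of EDF+ the
#' pipeline needs: 16-bit signals with per-channel physical scaling, a single
#' continuous recording, and an "EDF Annotations" channel carrying stimulus
#' events as time-stamped annotation lists (TALs). Files written by
#' [write_edf()] round-trip through [read_continuous()] to within the 16-bit
#' quantization step of each channel.
#'
#' @name edf-io
NULL

# fixed-width ASCII field, left-justified, space padded
edf_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) stop("EDF header field too long: ", s)
  sprintf(paste0("%-", width, "s"), s)
}

# numeric formatted to fit an 8-char EDF header field
fmt8 <- function(x) {
  for (d in 7:1) {
    s <- formatC(x, digits = d, format = "g", width = 1)
    if (nchar(s) <= 8) return(s)
  }
  stop("cannot format ", x, " in 8 characters")
}

#' Write a continuous recording to EDF+
#'
#' Writes one continuous data record holding the whole signal, plus an
#' EDF Annotations channel with one annotation per event.
#'
#' @param path output file path
#' @param data numeric matrix, channels x samples, in microvolts
#' @param sampling_rate sampling rate in Hz
#' @param labels channel labels (length `nrow(data)`)
#' @param events data frame with columns `onset_sample` (0-based sample index)
#'   and `label`
#' @return `path`, invisibly
#' @export
write_edf <- function(path, data, sampling_rate, labels,
                      events = data.frame(onset_sample = integer(),
                                          label = character())) {
  stopifnot(is.matrix(data), nrow(data) == length(labels))
  n_samp <- ncol(data)
  nsig <- nrow(data) + 1L  # + annotation channel

  # annotation TALs: record-start timestamp, then one TAL per event
  tal <- "+0\x14\x14"
  for (i in seq_len(nrow(events))) {
    onset_s <- events$onset_sample[i] / sampling_rate
    tal <- paste0(tal, sprintf("+%.6f\x14%s\x14", onset_s, events$label[i]))
  }
  tal_raw <- charToRaw(tal)
  tal_raw <- c(tal_raw, as.raw(rep(0, 2 - length(tal_raw) %% 2)))
  ann_nsamp <- length(tal_raw) / 2L

  # per-channel physical scaling to the full 16-bit digital range
  pmin <- apply(data, 1, min)
  pmax <- apply(data, 1, max)
  flat <- pmax - pmin < 1e-9
  pmax[flat] <- pmin[flat] + 1
  dmin <- -32768; dmax <- 32767
  dig <- round((data - pmin) / (pmax - pmin) * (dmax - dmin) + dmin)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_field("0", 8), edf_field("X X X X", 80),
    edf_field("Startdate X X X X", 80),
    edf_field("01.01.00", 8), edf_field("00.00.00", 8),
    edf_field(256 * (nsig + 1), 8), edf_field("EDF+C", 44),
    edf_field(1, 8), edf_field(fmt8(n_samp / sampling_rate), 8),
    edf_field(nsig, 4)
  )
  sig_lab <- c(labels, "EDF Annotations")
  per_sig <- function(vals, width) paste(vapply(vals, edf_field, "", width),
                                         collapse = "")
  hdr <- paste0(
    hdr,
    per_sig(sig_lab, 16),
    per_sig(rep("", nsig), 80),
    per_sig(c(rep("uV", nsig - 1), ""), 8),
    per_sig(c(vapply(pmin, fmt8, ""), "-1"), 8),
    per_sig(c(vapply(pmax, fmt8, ""), "1"), 8),
    per_sig(rep(dmin, nsig), 8),
    per_sig(rep(dmax, nsig), 8),
    per_sig(rep("", nsig), 80),
    per_sig(c(rep(n_samp, nsig - 1), ann_nsamp), 8),
    per_sig(rep("", nsig), 32)
  )
  writeChar(hdr, con, eos = NULL, useBytes = TRUE)
  for (ch in seq_len(nrow(data))) {
    writeBin(as.integer(dig[ch, ]), con, size = 2, endian = "little")
  }
  writeBin(tal_raw, con)
  invisible(path)
}

#' Read a continuous EDF+ recording with events
#'
#' @param path an EDF file with an `EDF Annotations` channel containing at
#'   least one event annotation
#' @return a list of class `continuous_recording`: `data` (channels x samples,
#'   microvolts), `sampling_rate` (Hz), `labels`, and `events` (data frame with
#'   `onset_sample`, 0-based, and `label`)
#' @export
read_continuous <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  hdr_err <- function() stop("malformed EDF file: ", path)
  ver <- rd(8)
  if (!startsWith(ver, "0")) hdr_err()
  rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes
  rd(44)
  n_rec <- suppressWarnings(as.integer(rd(8)))
  rec_dur <- suppressWarnings(as.numeric(rd(8)))
  nsig <- suppressWarnings(as.integer(rd(4)))
  if (anyNA(c(n_rec, rec_dur, nsig)) || nsig < 1) hdr_err()
  fields <- function(width) {
    vapply(seq_len(nsig), function(i) trimws(rd(width)), "")
  }
  labels <- fields(16)
  fields(80); fields(8)
  pmin <- as.numeric(fields(8)); pmax <- as.numeric(fields(8))
  dmin <- as.numeric(fields(8)); dmax <- as.numeric(fields(8))
  fields(80)
  nsamp <- as.integer(fields(8))
  fields(32)

  ann_idx <- which(labels == "EDF Annotations")
  sig_idx <- setdiff(seq_len(nsig), ann_idx)
  chunks <- vector("list", nsig)
  for (i in seq_len(nsig)) chunks[[i]] <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(nsig)) {
      if (i %in% ann_idx) {
        chunks[[i]][[r]] <- readBin(con, "raw", nsamp[i] * 2)
      } else {
        chunks[[i]][[r]] <- readBin(con, "integer", nsamp[i], size = 2,
                                    signed = TRUE, endian = "little")
      }
    }
  }
  data <- do.call(rbind, lapply(sig_idx, function(i) {
    d <- unlist(chunks[[i]])
    pmin[i] + (d - dmin[i]) / (dmax[i] - dmin[i]) * (pmax[i] - pmin[i])
  }))
  fs <- nsamp[sig_idx[1]] / rec_dur

  if (!length(ann_idx)) stop("EDF file has no annotation channel: ", path)
  raw_ann <- unlist(lapply(ann_idx, function(i) chunks[[i]]))
  events <- parse_tals(raw_ann, fs)
  if (!nrow(events)) stop("EDF annotation channel contains no events: ", path)

  structure(list(data = data, sampling_rate = fs,
                 labels = labels[sig_idx], events = events),
            class = "continuous_recording")
}

# parse TAL byte stream into an event table, skipping bare timestamps
parse_tals <- function(raw_ann, fs) {
  txt <- rawToChar(raw_ann[raw_ann != as.raw(0)], multiple = FALSE)
  onset <- numeric(); label <- character()
  for (t in strsplit(txt, "(?<=\x14)(?=\\+)", perl = TRUE)[[1]]) {
    parts <- strsplit(t, "\x14")[[1]]
    if (length(parts) < 2 || !nzchar(parts[2])) next  # record timestamp TAL
    on_s <- as.numeric(sub("\x15.*$", "", parts[1]))
    onset <- c(onset, on_s)
    label <- c(label, parts[2])
  }
  data.frame(onset_sample = as.integer(round(onset * fs)), label = label,
             stringsAsFactors = FALSE)
}
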