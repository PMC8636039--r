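# Minimal EDF+ (European Data Format) writer/reader for labelled trial sets.
# Continuous layout: trials are concatenated with zero-padded countdown/rest
# phases; task onsets/durations/labels live in the EDF+ annotation channel.

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a trial set as an EDF+ file
#'
#' One data record per second; each trial occupies
#' `countdown_s + task_s + rest_s` seconds with the task segment carrying the
#' trial data and the flanking phases zero-padded.  Task onset, duration and
#' class label are stored as EDF+ time-stamped annotations.
#'
#' @param ts A [trial_set()] whose trials are task segments.
#' @param path Output path.
#' @param countdown_s,rest_s Zero-padded phase durations (s).
#' @return Invisibly `path`.
#' @export
write_edf <- function(ts, path, countdown_s = 3, rest_s = 2) {
  stopifnot(inherits(ts, "trial_set"))
  fs <- ts$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires an integer fs")
  fs <- as.integer(round(fs))
  d <- dim(ts$data)
  task_s <- d[2] / fs
  if (abs(task_s - round(task_s)) > 1e-9)
    stop("trial length must be a whole number of seconds")
  trial_secs <- countdown_s + task_s + rest_s
  n_rec <- as.integer(d[1] * trial_secs)
  nch <- d[3]
  ns <- nch + 1L                       # + annotation channel
  ann_samples <- 60L                   # 120 bytes per record
  # physical scaling (shared symmetric range keeps the quantization simple)
  pmax_v <- max(abs(ts$data), 1e-6) * 1.0001
  dig_max <- 32767
  # continuous signal matrix
  total <- n_rec * fs
  sig <- matrix(0, total, nch)
  onset <- numeric(d[1])
  for (i in seq_len(d[1])) {
    onset[i] <- (i - 1) * trial_secs + countdown_s
    at <- round(onset[i] * fs)
    sig[(at + 1):(at + d[2]), ] <- ts$data[i, , ]
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field(paste("X X X", ts$subject), 80),
    pad_field("Startdate 01-JAN-2026 X X X", 80),
    "01.01.26", "00.00.00",
    pad_field(256 * (ns + 1), 8),
    pad_field("EDF+C", 44),
    pad_field(n_rec, 8),
    pad_field(1, 8),
    pad_field(ns, 4))
  writeChar(hdr, con, eos = NULL)
  lab <- c(ts$channels, "EDF Annotations")
  writeChar(paste0(vapply(lab, pad_field, "", 16), collapse = ""), con, eos = NULL)
  writeChar(strrep(" ", 80 * ns), con, eos = NULL)                    # transducer
  writeChar(paste0(vapply(c(rep("uV", nch), ""), pad_field, "", 8),
                   collapse = ""), con, eos = NULL)                   # phys dim
  writeChar(paste0(vapply(c(rep(sprintf("%.6g", -pmax_v), nch), "-1"),
                          pad_field, "", 8), collapse = ""), con, eos = NULL)
  writeChar(paste0(vapply(c(rep(sprintf("%.6g", pmax_v), nch), "1"),
                          pad_field, "", 8), collapse = ""), con, eos = NULL)
  writeChar(paste0(vapply(rep(-dig_max - 1, ns), pad_field, "", 8),
                   collapse = ""), con, eos = NULL)
  writeChar(paste0(vapply(rep(dig_max, ns), pad_field, "", 8),
                   collapse = ""), con, eos = NULL)
  writeChar(strrep(" ", 80 * ns), con, eos = NULL)                    # prefilter
  writeChar(paste0(vapply(c(rep(fs, nch), ann_samples), pad_field, "", 8),
                   collapse = ""), con, eos = NULL)
  writeChar(strrep(" ", 32 * ns), con, eos = NULL)
  # data records
  scale <- dig_max / pmax_v
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1) * fs + 1):(r * fs)
    writeBin(as.integer(round(sig[rows, ] * scale)), con, size = 2,
             endian = "little")
    raw_tal <- charToRaw(sprintf("+%d\x14\x14", r - 1))
    i <- which(abs(onset - (r - 1)) < 1e-9)
    if (length(i) == 1)
      raw_tal <- c(raw_tal, as.raw(0),
                   charToRaw(sprintf("+%g\x14%g\x14%s\x14", onset[i],
                                     task_s, ts$labels[i])))
    buf <- raw(2 * ann_samples)
    buf[seq_along(raw_tal)] <- raw_tal
    writeBin(buf, con)
  }
  invisible(path)
}

#' Read an EDF+ file into a trial set
#'
#' Channels are reordered to `montage_labels` when given; missing channels
#' are a hard error naming the labels.  Trials are cut from the continuous
#' record at the annotated task onsets.
#'
#' @param path EDF+ file written by [write_edf()] (or compatible: 1-s records,
#'   integer per-record sample counts, one annotation channel).
#' @param montage_labels Optional channel order to enforce.
#' @return A [trial_set()] (session ids all 1; set by the caller if needed).
#' @export
read_edf <- function(path, montage_labels = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  ver <- trimws(rd(8))
  if (ver != "0") stop("malformed EDF header (version '", ver, "')")
  subject <- strsplit(trimws(rd(80)), " ")[[1]]
  subject <- subject[length(subject)]
  rd(80); rd(8); rd(8)
  rd(8)  # header bytes
  rd(44)
  n_rec <- as.integer(trimws(rd(8)))
  rec_dur <- as.numeric(trimws(rd(8)))
  ns <- as.integer(trimws(rd(4)))
  if (any(is.na(c(n_rec, rec_dur, ns)))) stop("malformed EDF header")
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  rd(80 * ns)
  rd(8 * ns)
  pmin_ <- as.numeric(trimws(vapply(seq_len(ns), function(i) rd(8), "")))
  pmax_ <- as.numeric(trimws(vapply(seq_len(ns), function(i) rd(8), "")))
  dmin_ <- as.numeric(trimws(vapply(seq_len(ns), function(i) rd(8), "")))
  dmax_ <- as.numeric(trimws(vapply(seq_len(ns), function(i) rd(8), "")))
  rd(80 * ns)
  nspr <- as.integer(trimws(vapply(seq_len(ns), function(i) rd(8), "")))
  rd(32 * ns)
  ann_ch <- which(labels == "EDF Annotations")
  sig_ch <- setdiff(seq_len(ns), ann_ch)
  fs <- nspr[sig_ch[1]] / rec_dur
  sig <- matrix(0, n_rec * nspr[sig_ch[1]], length(sig_ch))
  ann_text <- character(0)
  for (r in seq_len(n_rec)) {
    for (j in seq_len(ns)) {
      raw_n <- nspr[j]
      if (j %in% ann_ch) {
        rw <- readBin(con, "raw", 2 * raw_n)
        ann_text <- c(ann_text, rawToChar(rw[rw != as.raw(0)]))
      } else {
        v <- readBin(con, "integer", raw_n, size = 2, endian = "little")
        jj <- match(j, sig_ch)
        g <- (pmax_[j] - pmin_[j]) / (dmax_[j] - dmin_[j])
        sig[((r - 1) * raw_n + 1):(r * raw_n), jj] <-
          (v - dmin_[j]) * g + pmin_[j]
      }
    }
  }
  # parse TALs: "+onset\x14dur\x14label\x14"
  ann_all <- paste(ann_text, collapse = "")
  tals <- regmatches(ann_all,
                     gregexpr("\\+[0-9.]+\x14[0-9.]+\x14[^\x14]+\x14",
                              ann_all))[[1]]
  if (!length(tals)) stop("no trial annotations found in ", path)
  parts <- strsplit(gsub("\x14$", "", tals), "\x14")
  onset <- as.numeric(sub("^\\+", "", vapply(parts, `[[`, "", 1)))
  dur <- as.numeric(vapply(parts, `[[`, "", 2))
  lab <- vapply(parts, `[[`, "", 3)
  ch_labels <- labels[sig_ch]
  if (!is.null(montage_labels)) {
    missing <- setdiff(montage_labels, ch_labels)
    if (length(missing))
      stop("missing montage channels: ", paste(missing, collapse = ", "))
    sig <- sig[, match(montage_labels, ch_labels), drop = FALSE]
    ch_labels <- montage_labels
  }
  nsmp <- round(dur[1] * fs)
  data <- array(0, c(length(onset), nsmp, ncol(sig)))
  for (i in seq_along(onset)) {
    at <- round(onset[i] * fs)
    data[i, , ] <- sig[(at + 1):(at + nsmp), ]
  }
  trial_set(data, lab, fs, 1L, subject, ch_labels)
}
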