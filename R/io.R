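#' Write / read a cohort table as CSV
#'
#' Fixed dialect: UTF-8, comma separator, "." decimal, header required.
#' The reader validates the schema and the BMI consistency invariant.
#'
#' @param cohort cohort data.frame.
#' @param path file path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` the cohort.
#' @export
write_cohort <- function(cohort, path) {
  check_cohort(cohort)
  write.csv(cohort, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  out <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  check_cohort(out)
  out
}

#' Write / read trial signals
#'
#' Two open formats are supported. `"csv_long"` is a plain-text long table
#' with columns `subject_id, maneuver, trial, electrode, sample_index,
#' value_mv` plus `sampling_rate_hz` and `force_kg` so trials round-trip
#' losslessly. `"edf"` is the European Data Format (16-bit): one file per
#' subject-maneuver with one data record per trial and the electrode id as
#' channel label, physical dimension mV. EDF quantizes each channel to its
#' physical range / 2^16, so EDF round trips are exact only to that
#' quantization step; µV-labelled channels are converted to mV on read.
#'
#' @param trials list of `trial_signals` for one subject-maneuver.
#' @param path file path.
#' @param format `"csv_long"` or `"edf"`.
#' @return `write_signals` returns `path` invisibly; `read_signals` a list of
#'   `trial_signals`.
#' @export
write_signals <- function(trials, path, format = c("csv_long", "edf")) {
  format <- match.arg(format)
  stopifnot(length(trials) >= 1,
            all(vapply(trials, inherits, logical(1), "trial_signals")))
  if (format == "edf") return(write_edf(trials, path))
  rows <- do.call(rbind, lapply(trials, function(ts) {
    n <- nrow(ts$traces)
    do.call(rbind, lapply(colnames(ts$traces), function(el) {
      data.frame(subject_id = ts$subject_id, maneuver = ts$maneuver,
                 trial = ts$trial_index, electrode = el,
                 sample_index = seq_len(n), value_mv = ts$traces[, el],
                 sampling_rate_hz = ts$sampling_rate, force_kg = ts$force,
                 stringsAsFactors = FALSE)
    }))
  }))
  write.csv(rows, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_signals
#' @export
read_signals <- function(path, format = c("csv_long", "edf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "edf") return(read_edf(path))
  d <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("subject_id", "maneuver", "trial", "electrode", "sample_index",
            "value_mv", "sampling_rate_hz", "force_kg")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("signals CSV lacks column(s): ",
                         paste(miss, collapse = ", "))
  lapply(split(d, d$trial), function(dt) {
    fs <- unique(dt$sampling_rate_hz)
    if (length(fs) != 1) stop("mixed sampling rates within one trial")
    electrodes <- unique(dt$electrode)
    n <- max(dt$sample_index)
    traces <- vapply(electrodes, function(el) {
      de <- dt[dt$electrode == el, ]
      if (nrow(de) != n) stop("electrode ", el, ": incomplete trace")
      de$value_mv[order(de$sample_index)]
    }, numeric(n))
    colnames(traces) <- as.character(electrodes)
    new_trial_signals(unique(dt$subject_id), unique(dt$maneuver),
                      unique(dt$trial), fs, n / fs, traces,
                      force = unique(dt$force_kg))
  })
}

# --- minimal EDF (European Data Format) support ------------------------------
# fixed 256-byte global header + 256 bytes per channel, int16 LE data records;
# one data record per trial here. No installed R package reads EDF, so the
# format is implemented directly from its public specification.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

write_edf <- function(trials, path) {
  ts1 <- trials[[1]]
  fs <- ts1$sampling_rate
  electrodes <- colnames(ts1$traces)
  ns <- length(electrodes)
  n <- nrow(ts1$traces)
  for (ts in trials)
    if (!identical(dim(ts$traces), dim(ts1$traces)) ||
        ts$sampling_rate != fs)
      stop("all trials in one EDF must share dimensions and sampling rate")
  # symmetric physical range per channel across trials
  pmax_ch <- vapply(electrodes, function(el)
    max(1e-6, max(vapply(trials, function(ts) max(abs(ts$traces[, el])),
                         numeric(1)))), numeric(1))
  meta <- paste0("maneuver=", ts1$maneuver,
                 " forces=", paste(vapply(trials, `[[`, numeric(1), "force"),
                                   collapse = ","))
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(edf_pad(x, width), con, nchars = width,
                                     eos = NULL)
  wr("0", 8)
  wr(ts1$subject_id, 80)
  wr(meta, 80)
  wr("01.01.20", 8); wr("00.00.00", 8)
  wr(256 * (1 + ns), 8)
  wr("", 44)
  wr(length(trials), 8)
  wr(format(ts1$duration, digits = 8), 8)
  wr(ns, 4)
  for (el in electrodes) wr(el, 16)
  for (el in electrodes) wr("sEMG surface electrode", 80)
  for (el in electrodes) wr("mV", 8)
  for (el in electrodes) wr(format(-pmax_ch[[el]], digits = 7), 8)
  for (el in electrodes) wr(format(pmax_ch[[el]], digits = 7), 8)
  for (el in electrodes) wr(-32768, 8)
  for (el in electrodes) wr(32767, 8)
  for (el in electrodes) wr("BP 100-500 Hz", 80)
  for (el in electrodes) wr(n, 8)
  for (el in electrodes) wr("", 32)
  for (ts in trials) {
    for (el in electrodes) {
      dig <- round(ts$traces[, el] / pmax_ch[[el]] * 32767)
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8)
  subject_id <- rd(80)
  meta <- rd(80)
  rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  dims <- vapply(seq_len(ns), function(i) rd(8), character(1))
  pmin_ch <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  pmax_ch <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(80)
  nsamp <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(nsamp)) != 1)
    stop("mixed per-channel sampling rates within a trial are not supported")
  scale_to_mv <- vapply(dims, function(d) switch(tolower(d),
    "mv" = 1, "uv" = 1e-3, "µv" = 1e-3,
    stop("unknown physical dimension in EDF: ", d)), numeric(1))
  maneuver <- sub(".*maneuver=(\\S+).*", "\\1", meta)
  forces <- if (grepl("forces=", meta))
    as.numeric(strsplit(sub(".*forces=(\\S+).*", "\\1", meta), ",")[[1]])
  else rep(NA_real_, n_rec)
  fs <- nsamp[1] / rec_dur
  lapply(seq_len(n_rec), function(r) {
    traces <- vapply(seq_len(ns), function(i) {
      dig <- readBin(con, "integer", n = nsamp[i], size = 2, endian = "little")
      (dig - dmin[i]) / (dmax[i] - dmin[i]) * (pmax_ch[i] - pmin_ch[i]) +
        pmin_ch[i]
    }, numeric(nsamp[1]))
    traces <- sweep(traces, 2, scale_to_mv, "*")
    colnames(traces) <- labels
    new_trial_signals(subject_id, maneuver, r, fs, rec_dur, traces,
                      force = forces[r])
  })
}
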