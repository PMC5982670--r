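#' @include AllClasses.R
NULL

#' Read a recording from columnar text
#'
#' Reads a CSV/TSV file with a header naming a `time` column (seconds) and
#' one column per channel: six motion channels
#' (`acc_x,acc_y,acc_z,gyr_x,gyr_y,gyr_z`) for `kind = "motion"`, a single
#' `ecg` column for `kind = "ecg"`. The nominal sampling rate is estimated
#' as the median reciprocal inter-sample interval.
#'
#' @param path file path.
#' @param kind "motion" or "ecg"; used to validate the channel count.
#' @return a [MultichannelRecording-class].
#' @seealso [writeRecording()]
#' @export
readRecording <- function(path, kind = c("motion", "ecg")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, data.table = FALSE)
  if (!"time" %in% names(dt))
    stop("missing time column (expected a column named 'time')")
  meta <- readRecordingMeta(path)
  chans <- setdiff(names(dt), "time")
  want <- if (kind == "motion") 6L else 1L
  if (length(chans) != want)
    stop(sprintf("wrong channel count for %s recording: expected %d, got %d",
                 kind, want, length(chans)))
  ts <- as.numeric(dt$time)
  if (length(ts) > 1 && any(diff(ts) <= 0))
    stop("non-monotone timestamps")
  multichannelRecording(ts, as.matrix(dt[chans]), channelNames = chans,
                        meta = meta)
}

# Sidecar metadata: condition tags travel in '#key=value' comment lines at
# the top of the CSV so one file stays self-contained.
readRecordingMeta <- function(path) {
  meta <- list()
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln) || !startsWith(ln, "#")) break
    kv <- sub("^#", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) {
      key <- substr(kv, 1, eq - 1)
      val <- substr(kv, eq + 1, nchar(kv))
      num <- suppressWarnings(as.numeric(val))
      meta[[key]] <- if (!is.na(num)) num else val
    }
  }
  meta
}

#' Write a recording to columnar text
#'
#' Writes CSV with full double precision (`%.17g`, so values round-trip
#' bit-exactly through [readRecording()]) and the metadata tags as
#' `#key=value` header comments. Channel order is preserved.
#'
#' @param rec a [MultichannelRecording-class].
#' @param path destination file path.
#' @return invisibly, `path`.
#' @export
writeRecording <- function(rec, path) {
  stopifnot(is(rec, "MultichannelRecording"))
  if (length(rec@timestamps) == 0L) stop("empty recording")
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("unwritable path: ", path)
  hdr <- character()
  for (key in names(rec@meta)) {
    val <- rec@meta[[key]]
    if (is.numeric(val) && length(val) == 1L)
      hdr <- c(hdr, sprintf("#%s=%.17g", key, val))
    else if (is.character(val) && length(val) == 1L)
      hdr <- c(hdr, sprintf("#%s=%s", key, val))
  }
  fmt <- function(x) formatC(x, format = "g", digits = 17)
  body <- cbind(time = fmt(rec@timestamps),
                apply(rec@values, 2, fmt))
  colnames(body) <- c("time", rec@channelNames)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(hdr)) writeLines(hdr, con)
  writeLines(paste(colnames(body), collapse = ","), con)
  writeLines(apply(body, 1, paste, collapse = ","), con)
  invisible(path)
}

#' Save a labeled window set
#'
#' Serializes the window tensor, labels, split tags and provenance to a
#' single Feather (Apache Arrow) file: a standard, portable, lossless
#' container for large numeric arrays. Shape and split metadata travel as
#' attributes and survive the round trip bit-exactly.
#'
#' @param ds a [LabeledWindowSet-class].
#' @param path destination file path (conventionally `.feather`).
#' @return invisibly, `path`.
#' @seealso [loadDataset()]
#' @export
saveDataset <- function(ds, path) {
  stopifnot(is(ds, "LabeledWindowSet"))
  d <- dim(ds@windows)
  flat <- matrix(aperm(ds@windows, c(1L, 3L, 2L)), nrow = d[1])
  # column order: channel-major (all samples of acc_x, then acc_y, ...)
  df <- as.data.frame(flat)
  names(df) <- paste0("v", seq_len(ncol(df)))
  df$label <- ds@labels
  df$split <- ds@split
  for (cn in names(ds@source)) df[[paste0("src_", cn)]] <- ds@source[[cn]]
  attr(df, "nChannels") <- d[2]
  attr(df, "windowLength") <- d[3]
  attr(df, "channelNames") <- ds@channelNames
  attr(df, "sampleRate") <- ds@sampleRate
  attr(df, "splitFractions") <- ds@splitFractions
  attr(df, "shuffleSeed") <- ds@shuffleSeed
  arrow::write_feather(df, path)
  invisible(path)
}

#' Load a labeled window set
#'
#' @param path a file written by [saveDataset()].
#' @return the reconstructed [LabeledWindowSet-class]; errors on a corrupt
#'   container or a shape mismatch.
#' @export
loadDataset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- as.data.frame(arrow::read_feather(path))
  nCh <- attr(df, "nChannels")
  nS <- attr(df, "windowLength")
  chn <- attr(df, "channelNames")
  if (is.null(nCh) || is.null(nS) || is.null(chn))
    stop("corrupt container: shape metadata missing")
  vcols <- grep("^v[0-9]+$", names(df), value = TRUE)
  if (length(vcols) != nCh * nS)
    stop(sprintf("shape mismatch on load: %d value columns, expected %d x %d",
                 length(vcols), nCh, nS))
  if (length(chn) != nCh)
    stop("shape mismatch on load: channel names do not match channel count")
  flat <- as.matrix(df[vcols])
  n <- nrow(flat)
  windows <- aperm(array(flat, dim = c(n, nS, nCh)), c(1L, 3L, 2L))
  srcCols <- grep("^src_", names(df), value = TRUE)
  source <- if (length(srcCols)) {
    out <- df[srcCols]
    names(out) <- sub("^src_", "", srcCols)
    out
  } else {
    data.frame(row.names = seq_len(n))
  }
  new("LabeledWindowSet",
      windows = windows, labels = df$label, split = as.character(df$split),
      source = source,
      splitFractions = attr(df, "splitFractions"),
      shuffleSeed = as.integer(attr(df, "shuffleSeed")),
      channelNames = chn, sampleRate = attr(df, "sampleRate"),
      meta = list())
}
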