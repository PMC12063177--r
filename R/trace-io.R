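#' Read a current trace from disk
#'
#' Reads a sampled current trace from a delimited text file. The canonical
#' on-disk format is CSV (or TSV) with a `current_pA` column and an optional
#' strictly increasing `time_s` column; a single unnamed column is treated
#' as current. A header comment line of the form `# sampling_rate_hz <value>`
#' (as written by [writeTrace()]) is honoured. The sampling rate is taken
#' from, in order of precedence: the `samplingRate` argument, the header
#' comment, or the median spacing of the time column.
#'
#' Axon Binary Format (ABF) and HDF5 containers are recognised extensions
#' but not supported by this build; requesting them raises an informative
#' error.
#'
#' @param path Path to the file.
#' @param format `"auto"` (by extension), `"csv"` or `"tsv"`.
#' @param samplingRate Sampling rate in Hz, overriding file metadata.
#' @param protocol Optional [VoltageProtocol-class] to attach.
#' @return A [Trace-class]; metadata records the source path.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeTrace(Trace(rnorm(100, 80, 2), samplingRate = 5e4), f)
#' tr <- readTrace(f)
#' samplingRate(tr)
#' @export
readTrace <- function(path, format = c("auto", "csv", "tsv", "abf", "hdf5"),
                      samplingRate = NULL, protocol = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, tsv = "tsv", abf = "abf", h5 = "hdf5",
                     hdf5 = "hdf5", "csv")
  }
  if (format %in% c("abf", "hdf5"))
    stop(format, " input is not supported by this build; ",
         "convert to CSV/TSV (columns time_s, current_pA)")
  sep <- if (format == "tsv") "\t" else ","
  headerRate <- NA_real_
  first <- readLines(path, n = 1L)
  if (length(first) && startsWith(first, "#")) {
    m <- regmatches(first,
                    regexec("sampling_rate_hz[[:space:]:=]+([0-9.eE+-]+)",
                            first))[[1]]
    if (length(m) == 2L) headerRate <- as.numeric(m[2])
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) == 1L) {
    current <- df[[1]]
    timeCol <- NULL
  } else {
    if (!"current_pA" %in% names(df))
      stop("no current_pA column in ", path)
    current <- df$current_pA
    timeCol <- if ("time_s" %in% names(df)) df$time_s else NULL
  }
  if (!is.null(timeCol) && length(timeCol) > 1L) {
    dt <- diff(timeCol)
    if (any(dt <= 0))
      stop("time_s column is not strictly increasing")
  }
  rate <- samplingRate
  if (is.null(rate) && !is.na(headerRate)) rate <- headerRate
  if (is.null(rate) && !is.null(timeCol) && length(timeCol) > 1L)
    rate <- 1 / stats::median(diff(timeCol))
  if (is.null(rate))
    stop("sampling rate not supplied and not inferable from file")
  Trace(samples = as.numeric(current), samplingRate = rate,
        protocol = protocol, metadata = list(source = path))
}

#' Write a current trace to disk
#'
#' Writes a [Trace-class] as CSV/TSV with a `# sampling_rate_hz` header
#' comment. Currents are written with 17 significant digits so that
#' write/read round-trips reproduce the samples to full double precision.
#'
#' @param trace A [Trace-class].
#' @param path Output path.
#' @param format `"csv"` or `"tsv"`.
#' @param includeTime Also write a `time_s` column (0-based sample times).
#' @return Invisibly, `path`.
#' @export
writeTrace <- function(trace, path, format = c("csv", "tsv"),
                       includeTime = FALSE) {
  format <- match.arg(format)
  sep <- if (format == "tsv") "\t" else ","
  x <- samples(trace)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sampling_rate_hz %.17g", samplingRate(trace)), con)
  if (includeTime) {
    writeLines(paste("time_s", "current_pA", sep = sep), con)
    t <- (seq_along(x) - 1) / samplingRate(trace)
    writeLines(paste(sprintf("%.17g", t), sprintf("%.17g", x), sep = sep),
               con)
  } else {
    writeLines("current_pA", con)
    writeLines(sprintf("%.17g", x), con)
  }
  invisible(path)
}

#' Read and write event tables
#'
#' Event tables are stored as TSV with the canonical column order
#' `start_s, dwell_s, interevent_s, I_B_pA, I_EX_pct, sweep_index, label,
#' truncated`, followed by any extra columns. Missing values are written as
#' empty cells; numbers carry 10 significant digits, so round-trips are
#' lossless well beyond the 6 significant digits guaranteed.
#'
#' @param events An [EventTable-class].
#' @param path File path.
#' @return `writeEvents()` returns `path` invisibly; `readEvents()` an
#'   [EventTable-class].
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeEvents(EventTable(), f)           # header-only file
#' nEvents(readEvents(f))
#' @export
writeEvents <- function(events, path) {
  df <- eventData(events)
  out <- df
  for (col in names(out)) {
    if (is.numeric(out[[col]]) && !is.integer(out[[col]]))
      out[[col]] <- .fmtNum(out[[col]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname writeEvents
#' @export
readEvents <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = "",
                          colClasses = NA)
  if (nrow(df)) {
    numcols <- intersect(c("start_s", "dwell_s", "interevent_s", "I_B_pA",
                           "I_EX_pct"), names(df))
    for (col in numcols) df[[col]] <- as.numeric(df[[col]])
    if ("sweep_index" %in% names(df))
      df$sweep_index <- as.integer(df$sweep_index)
    if ("truncated" %in% names(df))
      df$truncated <- as.logical(df$truncated)
    if ("label" %in% names(df))
      df$label <- as.character(df$label)
  }
  EventTable(df)
}

#' Segment a sweep-protocol trace into per-segment sample ranges
#'
#' Tiles the trace with half-open, 0-based sample ranges, one per protocol
#' segment per sweep repeat, each tagged with its voltage; segments at the
#' measuring voltage are flagged `analysis`. Samples beyond the last full
#' sweep (the remainder is less than one sweep period) are not covered.
#'
#' @param trace A [Trace-class] with a sweeps-mode protocol.
#' @param analysisVoltageMV Voltage defining the measuring segments;
#'   defaults to [analysisVoltage()] of the protocol (longest segment).
#' @return A `data.frame` with columns `sweep_index` (1-based), `segment`,
#'   `voltage_mV`, `start_sample`, `end_sample` (half-open, 0-based),
#'   `start_s`, `end_s`, `analysis`.
#' @examples
#' pr <- sweepProtocol(totalS = 600)     # 272 full 2.2 s sweeps
#' tr <- Trace(numeric(600 * 1000), samplingRate = 1000, protocol = pr)
#' segs <- segmentSweeps(tr)
#' max(segs$sweep_index)
#' @export
segmentSweeps <- function(trace, analysisVoltageMV = NULL) {
  pr <- protocol(trace)
  if (is.null(pr) || pr@mode != "sweeps")
    stop("no sweeps: trace protocol absent or gap-free")
  .protocolSegments(pr, samplingRate(trace), analysisVoltageMV)
}

## segment table from a protocol alone (also used by the simulator)
.protocolSegments <- function(pr, rate, analysisVoltageMV = NULL) {
  if (is.null(analysisVoltageMV)) analysisVoltageMV <- analysisVoltage(pr)
  nseg <- length(pr@voltageMV)
  reps <- pr@repeatCount
  ## cumulative segment end times over all repeats, then snapped to samples
  durs <- rep(pr@durationS, reps)
  volts <- rep(pr@voltageMV, reps)
  ends <- cumsum(durs)
  bounds <- round(c(0, ends) * rate)
  data.frame(
    sweep_index = rep(seq_len(reps), each = nseg),
    segment = rep(seq_len(nseg), reps),
    voltage_mV = volts,
    start_sample = bounds[-length(bounds)],
    end_sample = bounds[-1L],
    start_s = c(0, ends[-length(ends)]),
    end_s = ends,
    analysis = volts == analysisVoltageMV
  )
}
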