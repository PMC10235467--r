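#' @importFrom data.table fread fwrite
#' @importFrom utils head
NULL

# Month abbreviations fixed to English so files are locale- and
# byte-stable regardless of the session locale.
.DAM_MONTHS <- c("Jan", "Feb", "Mar", "Apr", "May", "Jun",
                 "Jul", "Aug", "Sep", "Oct", "Nov", "Dec")

.formatDamTimestamp <- function(ts) {
  lt <- as.POSIXlt(ts, tz = "UTC")
  list(date = sprintf("%d %s %02d", lt$mday, .DAM_MONTHS[lt$mon + 1],
                      lt$year %% 100),
       time = sprintf("%02d:%02d:%02d", lt$hour, lt$min, lt$sec))
}

.parseDamTimestamp <- function(date, time, lines) {
  parts <- strsplit(date, " ", fixed = TRUE)
  mon <- vapply(parts, function(p) match(p[2], .DAM_MONTHS), 0L)
  bad <- which(is.na(mon) | lengths(parts) != 3)
  if (length(bad))
    stop(sprintf("unparseable date field at line %d: '%s'",
                 lines[bad[1]], date[bad[1]]))
  day <- as.integer(vapply(parts, `[`, "", 1))
  year <- 2000L + as.integer(vapply(parts, `[`, "", 3))
  as.POSIXct(sprintf("%04d-%02d-%02d %s", year, mon, day, time),
             tz = "UTC")
}

#' Write a TriKinetics-style monitor file
#'
#' Emits the classic 42-column tab-delimited monitor layout: reading
#' index, date, time, monitor status, five extended-status columns, the
#' light-status column, then the 32 channel counts. Output is
#' byte-stable: writing the same record twice gives identical files.
#'
#' @param record a \code{\link{DamRecord}}
#' @param path output file path
#' @return \code{path}, invisibly
#' @seealso \code{\link{readDamFile}}
#' @export
writeDamFile <- function(record, path) {
  stopifnot(is(record, "DamRecord"))
  validObject(record)
  m <- nrow(record@counts)
  if (m == 0) {
    # empty record -> header-free empty file
    ok <- file.create(path)
    if (!ok) stop(sprintf("cannot write '%s'", path))
    return(invisible(path))
  }
  ts <- .formatDamTimestamp(record@timestamps)
  dt <- data.table::data.table(
    index = seq_len(m), date = ts$date, time = ts$time,
    status = rep(1L, m))
  for (k in 1:5) dt[[paste0("x", k)]] <- rep(0L, m)
  dt[["light"]] <- record@lightStatus
  cn <- record@counts
  for (k in 1:32) dt[[paste0("ch", k)]] <- cn[, k]
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE,
                     eol = "\n", quote = FALSE)
  invisible(path)
}

#' Read a TriKinetics-style monitor file
#'
#' Parses the 42-column tab-delimited monitor dialect written by
#' \code{\link{writeDamFile}} (and by TriKinetics DAMSystem software).
#' The parser never repairs data: a row with the wrong column count or a
#' non-integer count aborts with the offending line number, timestamps
#' that do not increase are an error, and gaps in the 1-min grid are
#' reported via a warning but never filled.
#'
#' @param path monitor file path
#' @param monitor monitor id to attach (default: file name without extension)
#' @param ztStart zeitgeber hour of the first row (ZT0 = lights-on)
#' @return a \code{\link{DamRecord}} with minutes in file order
#' @export
readDamFile <- function(path, monitor = NULL, ztStart = 0) {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(damRecord(matrix(integer(), 0, 32),
                     as.POSIXct(character(), tz = "UTC"),
                     monitor = monitor %||% "M01",
                     meta = list(ztStart = ztStart)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols != 42)) {
    bad <- which(ncols != 42)[1]
    stop(sprintf("malformed row at line %d: %d columns, expected 42",
                 bad, ncols[bad]))
  }
  tab <- do.call(rbind, fields)
  cnt <- suppressWarnings(
    matrix(as.numeric(tab[, 11:42, drop = FALSE]), ncol = 32))
  badv <- which(is.na(cnt) | cnt != round(cnt) | cnt < 0, arr.ind = TRUE)
  if (nrow(badv))
    stop(sprintf("non-integer or negative count at line %d (channel %d)",
                 badv[1, 1], badv[1, 2]))
  ts <- .parseDamTimestamp(tab[, 2], tab[, 3], seq_along(lines))
  if (length(ts) > 1) {
    d <- diff(as.numeric(ts))
    if (any(d <= 0))
      stop(sprintf("non-monotonic timestamps at line %d", which(d <= 0)[1] + 1))
    if (any(d != 60))
      warning(sprintf("%d gap(s) in the 1-min timestamp grid (first at line %d); gaps kept, not filled",
                      sum(d != 60), which(d != 60)[1] + 1))
  }
  light <- suppressWarnings(as.integer(tab[, 10]))
  if (anyNA(light))
    stop(sprintf("non-integer light-status value at line %d",
                 which(is.na(light))[1]))
  storage.mode(cnt) <- "integer"
  suppressWarnings(
    damRecord(cnt, ts, lightStatus = light,
              monitor = monitor %||% sub("\\.[^.]*$", "", basename(path)),
              meta = list(ztStart = ztStart)))
}

# header keys written/expected by the trace dialect
.TRACE_META_KEYS <- c("genotype", "wavelength", "intensity", "ztHour",
                      "cellId", "sweep")

#' Write a voltage trace file
#'
#' Self-describing columnar text format: a block of \code{# key: value}
#' header lines (sampling rate, protocol durations, recording metadata)
#' followed by one voltage sample (mV) per line. Doubles are written in
#' shortest round-trip representation, so
#' \code{readTraceFile(writeTraceFile(x))} reproduces the values exactly.
#'
#' @param trace a \code{\link{VoltageTrace}}
#' @param path output file path
#' @return \code{path}, invisibly
#' @seealso \code{\link{readTraceFile}}
#' @export
writeTraceFile <- function(trace, path) {
  stopifnot(is(trace, "VoltageTrace"))
  validObject(trace)
  p <- trace@protocol
  hdr <- c(
    "# lnvlight-trace v1",
    sprintf("# sampling_rate: %.10g", trace@samplingRate),
    sprintf("# n_samples: %d", length(trace@voltage)),
    sprintf("# pre_dark: %.10g", p@preDark),
    sprintf("# light_on: %.10g", p@lightOn),
    sprintf("# post_dark: %.10g", p@postDark),
    sprintf("# n_sweeps: %.10g", p@nSweeps),
    sprintf("# bin_width: %.10g", p@binWidth),
    sprintf("# protocol_wavelength: %.10g", p@wavelength),
    sprintf("# protocol_intensity: %.10g", p@intensity))
  for (k in .TRACE_META_KEYS) {
    v <- trace@meta[[k]]
    if (!is.null(v) && !is.na(v)) hdr <- c(hdr, sprintf("# %s: %s", k, v))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  # %.17g guarantees exact double round-trip through the reader
  writeLines(sprintf("%.17g", trace@voltage), con)
  invisible(path)
}

#' Read a voltage trace file
#'
#' Counterpart of \code{\link{writeTraceFile}}. The header must declare a
#' sampling rate; NaN or non-finite samples abort with their indices; a
#' missing wavelength is tolerated with a warning (marked \code{NA} in
#' the metadata). When the header declares the protocol, the sample count
#' must match the protocol duration to within one sample.
#'
#' @param path trace file path
#' @return a \code{\link{VoltageTrace}}
#' @export
readTraceFile <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path))
  con <- file(path, open = "r")
  hdr <- character()
  repeat {
    ln <- readLines(con, n = 1)
    if (length(ln) == 0 || !startsWith(ln, "#")) break
    hdr <- c(hdr, ln)
  }
  close(con)
  kv <- regmatches(hdr, regexec("^# *([A-Za-z_]+): *(.*)$", hdr))
  kv <- Filter(function(x) length(x) == 3, kv)
  keys <- vapply(kv, `[`, "", 2)
  vals <- vapply(kv, `[`, "", 3)
  getv <- function(k) if (k %in% keys) vals[match(k, keys)] else NULL
  sr <- getv("sampling_rate")
  if (is.null(sr)) stop("trace header lacks sampling_rate")
  sr <- as.numeric(sr)
  volt <- data.table::fread(path, skip = length(hdr), header = FALSE,
                            sep = "\n")[[1]]
  bad <- which(!is.finite(volt))
  if (length(bad))
    stop(sprintf("non-finite voltage samples at indices: %s%s",
                 paste(head(bad, 10), collapse = ", "),
                 if (length(bad) > 10) ", ..." else ""))
  num <- function(k, default = NA_real_) {
    v <- getv(k); if (is.null(v)) default else as.numeric(v)
  }
  protocol <- sweepProtocol(
    preDark = num("pre_dark", 50), lightOn = num("light_on", 5),
    postDark = num("post_dark", 95), nSweeps = num("n_sweeps", 5),
    binWidth = num("bin_width", 10),
    wavelength = num("protocol_wavelength", 450),
    intensity = num("protocol_intensity", 200))
  expected <- protocolDuration(protocol) * sr
  if (abs(length(volt) - expected) > 1)
    stop(sprintf("trace length %d inconsistent with declared duration (%g samples expected)",
                 length(volt), expected))
  wl <- num("wavelength")
  if (is.na(wl))
    warning(sprintf("'%s': header lacks wavelength; marked absent",
                    basename(path)))
  meta <- list(genotype = getv("genotype"), wavelength = wl,
               intensity = num("intensity"), ztHour = num("ztHour"),
               cellId = getv("cellId"), sweep = num("sweep"))
  voltageTrace(volt, samplingRate = sr, protocol = protocol, meta = meta)
}

#' Write a results table as tab-separated text
#'
#' Shared writer for the pipeline's per-cell, per-group and comparison
#' tables. Byte-stable for identical input.
#'
#' @param df a data.frame
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeResultsTsv <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, eol = "\n",
                     na = "NA")
  invisible(path)
}
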