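#' Write EEG to a BrainVision triplet
#'
#' Writes `<base>.vhdr` (header), `<base>.vmrk` (markers) and `<base>.eeg`
#' (IEEE float32, multiplexed, little-endian, microvolts).
#'
#' @param eeg a [ContinuousEEG-class].
#' @param base output path without extension.
#' @return the `.vhdr` path, invisibly.
#' @export
writeBrainVision <- function(eeg, base) {
  stopifnot(is(eeg, "ContinuousEEG"))
  vhdr <- paste0(base, ".vhdr")
  vmrk <- paste0(base, ".vmrk")
  dat <- paste0(base, ".eeg")
  nch <- length(eeg@channels)
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "", "[Common Infos]", "Codepage=UTF-8",
    paste0("DataFile=", basename(dat)),
    paste0("MarkerFile=", basename(vmrk)),
    "DataFormat=BINARY", "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nch),
    paste0("SamplingInterval=", format(1e6 / eeg@srate, scientific = FALSE)),
    "", "[Binary Infos]", "BinaryFormat=IEEE_FLOAT_32",
    "", "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(nch), eeg@channels))
  writeLines(hdr, vhdr, useBytes = FALSE)
  mk <- c("Brain Vision Data Exchange Marker File, Version 1.0",
          "", "[Common Infos]", "Codepage=UTF-8",
          paste0("DataFile=", basename(dat)),
          "", "[Marker Infos]",
          "Mk1=New Segment,,1,1,0")
  if (nrow(eeg@events))
    mk <- c(mk, sprintf("Mk%d=Stimulus,%s,%d,1,0",
                        seq_len(nrow(eeg@events)) + 1L,
                        eeg@events$code, eeg@events$sample))
  writeLines(mk, vmrk)
  con <- file(dat, "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(eeg@data)), con, size = 4, endian = "little")
  invisible(vhdr)
}

.bv_section <- function(lines, name) {
  i <- grep(sprintf("^\\[%s\\]", name), lines)
  if (!length(i)) return(character())
  j <- grep("^\\[", lines)
  end <- j[j > i[1]]
  lines[(i[1] + 1):(if (length(end)) end[1] - 1 else length(lines))]
}

.bv_value <- function(lines, key) {
  l <- grep(paste0("^", key, "="), lines, value = TRUE)
  if (!length(l)) stop("BrainVision header missing ", key)
  sub(paste0("^", key, "="), "", l[1])
}

#' Read a BrainVision recording
#'
#' Supports the subset written by [writeBrainVision()]: binary
#' IEEE_FLOAT_32 or INT_16, multiplexed orientation.
#'
#' @param vhdr path to the `.vhdr` header file.
#' @return A [ContinuousEEG-class].
#' @export
readBrainVision <- function(vhdr) {
  stopifnot(file.exists(vhdr))
  lines <- readLines(vhdr, encoding = "UTF-8", warn = FALSE)
  common <- .bv_section(lines, "Common Infos")
  stopifnot(.bv_value(common, "DataOrientation") == "MULTIPLEXED")
  nch <- as.integer(.bv_value(common, "NumberOfChannels"))
  srate <- 1e6 / as.numeric(.bv_value(common, "SamplingInterval"))
  fmt <- .bv_value(.bv_section(lines, "Binary Infos"), "BinaryFormat")
  chlines <- grep("^Ch[0-9]+=", .bv_section(lines, "Channel Infos"),
                  value = TRUE)
  chinfo <- strsplit(sub("^Ch[0-9]+=", "", chlines), ",")
  channels <- vapply(chinfo, `[`, "", 1)
  resolution <- vapply(chinfo, function(x)
    if (length(x) >= 3 && nzchar(x[3])) as.numeric(x[3]) else 1, numeric(1))
  dat <- file.path(dirname(vhdr), .bv_value(common, "DataFile"))
  sz <- file.info(dat)$size
  con <- file(dat, "rb")
  on.exit(close(con))
  if (fmt == "IEEE_FLOAT_32") {
    raw <- readBin(con, "numeric", n = sz / 4, size = 4, endian = "little")
  } else if (fmt == "INT_16") {
    raw <- readBin(con, "integer", n = sz / 2, size = 2, signed = TRUE,
                   endian = "little")
  } else stop("unsupported BinaryFormat: ", fmt)
  nsamp <- length(raw) %/% nch
  x <- t(matrix(raw[seq_len(nsamp * nch)], nrow = nch))
  x <- sweep(x, 2, resolution, "*")
  colnames(x) <- channels
  events <- data.frame(sample = integer(), code = character())
  vmrk <- file.path(dirname(vhdr), .bv_value(common, "MarkerFile"))
  if (file.exists(vmrk)) {
    ml <- grep("^Mk[0-9]+=", readLines(vmrk, warn = FALSE), value = TRUE)
    parts <- strsplit(sub("^Mk[0-9]+=", "", ml), ",")
    type <- vapply(parts, `[`, "", 1)
    stim <- type == "Stimulus"
    if (any(stim))
      events <- data.frame(
        sample = as.integer(vapply(parts[stim], `[`, "", 3)),
        code = vapply(parts[stim], `[`, "", 2))
  }
  new("ContinuousEEG", data = x, channels = channels, srate = srate,
      events = events)
}

#' Read / write probe events as BIDS-style TSV
#'
#' Columns `onset` (s), `duration` (s), `trial_type`.
#'
#' @param x a [ProbeTrain-class] (writer).
#' @param path file path.
#' @return reader: a [ProbeTrain-class]; writer: `path` invisibly.
#' @export
writeEventsTsv <- function(x, path) {
  d <- data.frame(onset = sprintf("%.4f", probeOnsets(x)),
                  duration = sprintf("%.4f", x@toneDur),
                  trial_type = "probe")
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEventsTsv
#' @param toneFreq tone frequency metadata to attach on read, Hz.
#' @export
readEventsTsv <- function(path, toneFreq = 440) {
  d <- utils::read.delim(path, sep = "\t", header = TRUE)
  stopifnot(all(c("onset", "duration") %in% names(d)))
  new("ProbeTrain", onsets = as.numeric(d$onset), toneFreq = toneFreq,
      toneDur = as.numeric(d$duration[1]))
}

#' Export a load series as CSV
#'
#' Columns `time_s` plus one `load_<method>` column per series (all series
#' must share a subject/direction; times are the union of breakpoints,
#' each series interpolated onto it).
#'
#' @param seriesList named list of [LoadSeries-class] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeLoadSeriesCsv <- function(seriesList, path) {
  tt <- sort(unique(unlist(lapply(seriesList, function(s) s@time))))
  d <- data.frame(time_s = tt)
  for (nm in names(seriesList))
    d[[paste0("load_", tolower(nm))]] <- interpolateLoad(seriesList[[nm]], tt)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
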