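# BrainVision (.vhdr/.vmrk/.eeg) I/O. The trio of a plain-text header, a
# plain-text marker file, and a raw binary data file is simple enough to
# read and write directly, and doubles as the package's on-disk exchange
# format for EEG (positions travel in an optional JSON sidecar).

#' Write an EEG recording in BrainVision format
#'
#' Writes `<stem>.vhdr`, `<stem>.vmrk` and `<stem>.eeg`
#' (multiplexed IEEE float32, little-endian), plus `<stem>.pos.json` with
#' electrode positions and the bad-channel list when present.
#'
#' @param rec an [eeg_recording()].
#' @param stem output path without extension.
#' @export
write_brainvision <- function(rec, stem) {
  stopifnot(inherits(rec, "eeg_recording"))
  base <- basename(stem)
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nrow(rec$data)),
    paste0("SamplingInterval=", format(1e6 / rec$rate, digits = 12)),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(nrow(rec$data)), rec$labels))
  writeLines(hdr, paste0(stem, ".vhdr"), useBytes = TRUE)
  writeLines(c("Brain Vision Data Exchange Marker File, Version 1.0",
               "[Common Infos]", paste0("DataFile=", base, ".eeg"),
               "[Marker Infos]",
               "Mk1=New Segment,,1,1,0"),
             paste0(stem, ".vmrk"))
  con <- file(paste0(stem, ".eeg"), "wb")
  writeBin(as.numeric(rec$data), con, size = 4, endian = "little")
  close(con)
  side <- list(labels = rec$labels, bad = rec$bad)
  if (!is.null(rec$positions))
    side$positions <- unname(lapply(seq_len(nrow(rec$positions)),
                                    function(i) rec$positions[i, ]))
  jsonlite::write_json(side, paste0(stem, ".pos.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' Read a BrainVision recording
#'
#' Supports multiplexed and vectorized binary data in IEEE float32 or
#' signed 16-bit integer encoding, applying per-channel resolution.
#'
#' @param vhdr path to the `.vhdr` header file.
#' @return an [eeg_recording()] (positions attached when a `.pos.json`
#'   sidecar is found next to the header).
#' @export
read_brainvision <- function(vhdr) {
  lines <- readLines(vhdr, warn = FALSE, encoding = "UTF-8")
  get <- function(key) {
    ln <- grep(paste0("^", key, "="), lines, value = TRUE)
    if (!length(ln)) return(NA_character_)
    sub(paste0("^", key, "="), "", ln[1])
  }
  data_file <- get("DataFile")
  n_chan <- as.integer(get("NumberOfChannels"))
  samp_int <- as.numeric(get("SamplingInterval"))   # microseconds
  fmt <- get("BinaryFormat")
  orient <- get("DataOrientation")
  if (is.na(n_chan) || is.na(samp_int))
    stop("malformed BrainVision header: ", vhdr, call. = FALSE)

  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  parts <- strsplit(sub("^Ch[0-9]+=", "", ch_lines), ",")
  labels <- vapply(parts, `[`, character(1), 1L)
  res <- vapply(parts, function(p)
    if (length(p) >= 3 && nzchar(p[3])) as.numeric(p[3]) else 1, numeric(1))

  path <- file.path(dirname(vhdr), data_file)
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  if (identical(fmt, "IEEE_FLOAT_32")) {
    x <- readBin(con, "numeric", sz / 4, size = 4, endian = "little")
  } else if (identical(fmt, "INT_16")) {
    x <- readBin(con, "integer", sz / 2, size = 2, signed = TRUE,
                 endian = "little")
  } else stop("unsupported BinaryFormat: ", fmt, call. = FALSE)

  n_samp <- length(x) %/% n_chan
  data <- if (identical(orient, "VECTORIZED"))
    matrix(x[seq_len(n_chan * n_samp)], nrow = n_chan, byrow = TRUE)
  else matrix(x[seq_len(n_chan * n_samp)], nrow = n_chan)
  data <- data * res

  positions <- NULL; bad <- character(0)
  sidecar <- paste0(sub("\\.vhdr$", "", vhdr), ".pos.json")
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    bad <- as.character(side$bad %||% character(0))
    if (!is.null(side$positions)) positions <- as.matrix(side$positions)
  }
  eeg_recording(data, rate = 1e6 / samp_int, labels = labels,
                positions = positions, bad = bad)
}
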