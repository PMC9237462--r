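#' Read a BrainVision Core recording
#'
#' Parses the `.vhdr` header, the binary `.eeg` data file (multiplexed
#' IEEE float32 or 16-bit integer with per-channel resolution) and the
#' `.vmrk` marker file. Stimulus markers (`Mk<n>=Stimulus,S<id>,...`)
#' become events; the numeric part of the stimulus description is used as
#' the stream id unless a `marker_map` translates descriptions to stream
#' ids/conditions.
#'
#' @param path Path to the `.vhdr` header.
#' @param marker_map Optional data frame with columns `description`,
#'   `stream` and (optionally) `condition`, `is_filler`.
#' @return An [eeg_recording].
#' @export
read_brainvision <- function(path, marker_map = NULL) {
  lines <- readLines(path, warn = FALSE)
  get_field <- function(key) {
    i <- grep(paste0("^", key, "="), lines)
    if (!length(i)) return(NA_character_)
    sub(paste0("^", key, "="), "", lines[i[1L]])
  }
  data_file <- get_field("DataFile")
  marker_file <- get_field("MarkerFile")
  n_chan <- as.integer(get_field("NumberOfChannels"))
  samp_int <- as.numeric(get_field("SamplingInterval"))  # microseconds
  fmt <- get_field("BinaryFormat")
  orient <- get_field("DataOrientation")
  if (is.na(n_chan) || is.na(samp_int))
    stop("malformed BrainVision header (line ",
         grep("NumberOfChannels|SamplingInterval", lines)[1L],
         "): channel count or sampling interval missing")
  if (!is.na(orient) && toupper(orient) != "MULTIPLEXED")
    stop("only MULTIPLEXED data orientation is supported")
  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  ch_fields <- strsplit(sub("^Ch[0-9]+=", "", ch_lines), ",")
  ch_names <- vapply(ch_fields, `[`, character(1), 1L)
  resol <- vapply(ch_fields, function(f)
    if (length(f) >= 3L && nzchar(f[3L])) as.numeric(f[3L]) else 1,
    numeric(1))
  if (length(ch_names) != n_chan)
    stop("header declares ", n_chan, " channels but lists ",
         length(ch_names), " channel entries")
  rate <- 1e6 / samp_int
  eeg_path <- file.path(dirname(path), data_file)
  sz <- file.info(eeg_path)$size
  if (is.na(sz)) stop("data file not found: ", eeg_path)
  if (grepl("FLOAT_32", fmt)) {
    raw_vals <- readBin(eeg_path, "double", n = sz / 4L, size = 4L,
                        endian = "little")
  } else if (grepl("INT_16", fmt)) {
    raw_vals <- readBin(eeg_path, "integer", n = sz / 2L, size = 2L,
                        endian = "little")
  } else stop("unsupported BinaryFormat: ", fmt)
  if (length(raw_vals) %% n_chan != 0L)
    stop("data length ", length(raw_vals),
         " is not a multiple of the declared ", n_chan, " channels")
  dat <- matrix(raw_vals, nrow = n_chan)
  dat <- dat * resol
  events <- data.frame(sample = integer(), stream = character())
  if (!is.na(marker_file)) {
    vmrk_path <- file.path(dirname(path), marker_file)
    if (file.exists(vmrk_path)) {
      ml <- grep("^Mk[0-9]+=", readLines(vmrk_path, warn = FALSE),
                 value = TRUE)
      mf <- strsplit(sub("^Mk[0-9]+=", "", ml), ",")
      typ <- vapply(mf, `[`, character(1), 1L)
      desc <- vapply(mf, `[`, character(1), 2L)
      pos <- as.integer(vapply(mf, `[`, character(1), 3L))
      keep <- typ == "Stimulus"
      desc <- trimws(desc[keep]); pos <- pos[keep]
      if (!is.null(marker_map)) {
        idx <- match(desc, marker_map$description)
        events <- data.frame(sample = pos[!is.na(idx)],
                             stream = marker_map$stream[idx[!is.na(idx)]])
        if ("condition" %in% names(marker_map))
          events$condition <-
            marker_map$condition[idx[!is.na(idx)]]
        if ("is_filler" %in% names(marker_map))
          events$is_filler <-
            marker_map$is_filler[idx[!is.na(idx)]]
      } else {
        events <- data.frame(sample = pos,
                             stream = sub("^S\\s*", "", desc))
      }
    }
  }
  eeg_recording(dat, rate, ch_names, events)
}

#' Write a BrainVision Core recording
#'
#' Writes the `.vhdr`/`.eeg`/`.vmrk` triplet (multiplexed IEEE float32),
#' with one stimulus marker per event.
#'
#' @param rec An [eeg_recording].
#' @param basepath Output path without extension.
#' @return The `.vhdr` path, invisibly.
#' @export
write_brainvision <- function(rec, basepath) {
  stopifnot(inherits(rec, "eeg_recording"))
  vhdr <- paste0(basepath, ".vhdr")
  vmrk <- paste0(basepath, ".vmrk")
  eeg <- paste0(basepath, ".eeg")
  base <- basename(basepath)
  hdr <- c("Brain Vision Data Exchange Header File Version 1.0",
           "[Common Infos]",
           paste0("DataFile=", base, ".eeg"),
           paste0("MarkerFile=", base, ".vmrk"),
           "DataFormat=BINARY",
           "DataOrientation=MULTIPLEXED",
           paste0("NumberOfChannels=", nrow(rec$data)),
           paste0("SamplingInterval=", format(1e6 / rec$rate,
                                              scientific = FALSE)),
           "[Binary Infos]",
           "BinaryFormat=IEEE_FLOAT_32",
           "[Channel Infos]",
           paste0("Ch", seq_len(nrow(rec$data)), "=",
                  rec$channel_names, ",,1,µV"))
  writeLines(hdr, vhdr)
  mk <- c("Brain Vision Data Exchange Marker File, Version 1.0",
          "[Marker Infos]")
  if (nrow(rec$events))
    mk <- c(mk, paste0("Mk", seq_len(nrow(rec$events)), "=Stimulus,S ",
                       rec$events$stream, ",", rec$events$sample,
                       ",1,0"))
  writeLines(mk, vmrk)
  con <- file(eeg, "wb")
  writeBin(as.numeric(rec$data), con, size = 4L, endian = "little")
  close(con)
  invisible(vhdr)
}

#' Write a raw-binary EEG recording with a JSON sidecar
#'
#' Fallback format: little-endian float32, channels x samples in channel-
#' major order, plus `<basepath>.json` holding the rate, channel names and
#' events.
#'
#' @param rec An [eeg_recording].
#' @param basepath Output path without extension.
#' @return The `.bin` path, invisibly.
#' @export
write_raw_eeg <- function(rec, basepath) {
  stopifnot(inherits(rec, "eeg_recording"))
  bin <- paste0(basepath, ".bin")
  con <- file(bin, "wb")
  writeBin(as.numeric(t(rec$data)), con, size = 4L, endian = "little")
  close(con)
  jsonlite::write_json(
    list(rate = rec$rate, channel_names = rec$channel_names,
         n_samples = ncol(rec$data), events = rec$events),
    paste0(basepath, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(bin)
}

#' Read a raw-binary EEG recording written by [write_raw_eeg()]
#'
#' @param basepath Path without extension.
#' @return An [eeg_recording].
#' @export
read_raw_eeg <- function(basepath) {
  meta <- jsonlite::read_json(paste0(basepath, ".json"),
                              simplifyVector = TRUE)
  n_ch <- length(meta$channel_names)
  vals <- readBin(paste0(basepath, ".bin"), "double",
                  n = n_ch * meta$n_samples, size = 4L,
                  endian = "little")
  dat <- t(matrix(vals, ncol = n_ch))
  ev <- as.data.frame(meta$events)
  if (!nrow(ev)) ev <- data.frame(sample = integer(), stream = integer())
  eeg_recording(dat, meta$rate, meta$channel_names, ev)
}
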