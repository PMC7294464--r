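# BrainVision (.vhdr/.vmrk/.eeg) I/O. Supported dialect: binary,
# multiplexed, INT_16 or IEEE_FLOAT_32, little-endian — what actiChamp-family
# amplifiers export. Vectorized and ASCII dialects are rejected explicitly.

.bv_parse_ini <- function(lines) {
  # header files are INI-like: [Section] then Key=Value; ';' starts a comment
  lines <- sub("^﻿", "", lines)
  lines <- lines[!grepl("^\\s*;", lines)]
  out <- list(); section <- ""
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (is.null(out[[section]])) out[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      eq <- regexpr("=", ln, fixed = TRUE)
      key <- trimws(substr(ln, 1L, eq - 1L))
      val <- substr(ln, eq + 1L, nchar(ln))
      out[[section]][[key]] <- val
    }
  }
  out
}

#' Read a BrainVision recording
#'
#' Reads the `.vhdr` header, the binary `.eeg` payload and the `.vmrk`
#' markers of a BrainVision-format recording and returns a
#' [continuous_recording] in microvolts (per-channel resolutions applied).
#' Only the multiplexed binary dialect with `INT_16` or `IEEE_FLOAT_32`
#' samples is supported; other dialects raise an error. Companion-file
#' names in the header are resolved relative to the header's directory and
#' are slash-direction agnostic.
#'
#' @param header_path path to the `.vhdr` file.
#' @return A [continuous_recording].
#' @export
read_brainvision <- function(header_path) {
  if (!file.exists(header_path))
    stop("header file not found: ", header_path)
  hdr <- .bv_parse_ini(readLines(header_path, warn = FALSE))
  ci <- hdr[["Common Infos"]]
  if (is.null(ci)) stop("malformed .vhdr: no [Common Infos] section")
  fmt <- toupper(ci$DataFormat %||% "BINARY")
  orient <- toupper(ci$DataOrientation %||% "MULTIPLEXED")
  if (fmt != "BINARY")
    stop("unsupported BrainVision dialect: DataFormat=", fmt,
         " (only BINARY is supported)")
  if (orient != "MULTIPLEXED")
    stop("unsupported BrainVision dialect: DataOrientation=", orient,
         " (only MULTIPLEXED is supported)")
  nchan <- as.integer(ci$NumberOfChannels)
  if (is.na(nchan) || nchan < 1L) stop("malformed .vhdr: NumberOfChannels")
  # SamplingInterval is in microseconds
  srate <- 1e6 / as.numeric(ci$SamplingInterval)

  dirn <- dirname(header_path)
  companion <- function(name) {
    name <- gsub("\\\\", "/", name)
    p <- file.path(dirn, basename(name))
    if (!file.exists(p)) stop("missing companion file: ", p)
    p
  }
  data_path <- companion(ci$DataFile %||% stop("malformed .vhdr: DataFile"))

  bi <- hdr[["Binary Infos"]]
  bfmt <- toupper((bi$BinaryFormat) %||% "INT_16")
  if (!bfmt %in% c("INT_16", "IEEE_FLOAT_32"))
    stop("unsupported BrainVision dialect: BinaryFormat=", bfmt)

  chinfo <- hdr[["Channel Infos"]]
  if (is.null(chinfo) || length(chinfo) < nchan)
    stop("malformed .vhdr: [Channel Infos] incomplete")
  names_res <- lapply(seq_len(nchan), function(i) {
    parts <- strsplit(chinfo[[paste0("Ch", i)]], ",", fixed = TRUE)[[1L]]
    res <- suppressWarnings(as.numeric(parts[3L]))
    list(name = parts[1L], res = if (is.na(res)) 1 else res)
  })
  ch_names <- vapply(names_res, `[[`, "", "name")
  resolutions <- vapply(names_res, `[[`, 0, "res")

  sz <- file.size(data_path)
  bytes <- if (bfmt == "INT_16") 2L else 4L
  n_total <- sz %/% (bytes * nchan)
  con <- file(data_path, "rb"); on.exit(close(con))
  raw_vals <- if (bfmt == "INT_16") {
    readBin(con, integer(), n = n_total * nchan, size = 2L,
            signed = TRUE, endian = "little")
  } else {
    readBin(con, numeric(), n = n_total * nchan, size = 4L,
            endian = "little")
  }
  mat <- matrix(as.numeric(raw_vals), nrow = nchan)  # multiplexed: ch fastest
  mat <- mat * resolutions                           # recycle down columns

  events <- data.frame(sample = integer(), code = character())
  if (!is.null(ci$MarkerFile)) {
    marker_path <- companion(ci$MarkerFile)
    mk <- .bv_parse_ini(readLines(marker_path, warn = FALSE))[["Marker Infos"]]
    if (!is.null(mk) && length(mk)) {
      rows <- lapply(mk, function(v) {
        parts <- strsplit(v, ",", fixed = TRUE)[[1L]]
        if (length(parts) < 3L) return(NULL)
        data.frame(sample = as.integer(parts[3L]), code = parts[2L])
      })
      rows <- rows[!vapply(rows, is.null, TRUE)]
      if (length(rows)) events <- do.call(rbind, rows)
      rownames(events) <- NULL
    }
  }
  m <- montage(ch_names, reference_label = "as-recorded")
  continuous_recording(m, mat, srate, events)
}

#' Write a BrainVision fixture
#'
#' Writes a [continuous_recording] as a BrainVision triplet
#' (`.vhdr`/`.vmrk`/`.eeg`), multiplexed binary. Mainly for building test
#' fixtures and for exporting synthetic recordings to other EEG software.
#'
#' @param rec a [continuous_recording] (data in uV).
#' @param base_path output path without extension.
#' @param binary_format `"IEEE_FLOAT_32"` (lossless for float32 data) or
#'   `"INT_16"`.
#' @param resolution per-channel scaling in uV per raw unit used with
#'   `INT_16` (recycled across channels).
#' @return `base_path`, invisibly.
#' @export
write_brainvision <- function(rec, base_path,
                              binary_format = c("IEEE_FLOAT_32", "INT_16"),
                              resolution = 0.1) {
  stopifnot(inherits(rec, "continuous_recording"))
  binary_format <- match.arg(binary_format)
  nchan <- nrow(rec$data)
  resolution <- rep_len(resolution, nchan)
  stem <- basename(base_path)

  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", stem, ".eeg"),
    paste0("MarkerFile=", stem, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nchan),
    sprintf("SamplingInterval=%.10g", 1e6 / rec$srate),
    "[Binary Infos]",
    paste0("BinaryFormat=", binary_format),
    "[Channel Infos]",
    vapply(seq_len(nchan), function(i)
      sprintf("Ch%d=%s,,%.10g,µV", i, rec$montage$channel_names[i],
              if (binary_format == "INT_16") resolution[i] else 1),
      ""))
  writeLines(hdr, paste0(base_path, ".vhdr"), useBytes = TRUE)

  mrk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", stem, ".eeg"),
    "[Marker Infos]")
  if (nrow(rec$events))
    mrk <- c(mrk, vapply(seq_len(nrow(rec$events)), function(i)
      sprintf("Mk%d=Stimulus,%s,%d,1,0", i, rec$events$code[i],
              rec$events$sample[i]), ""))
  writeLines(mrk, paste0(base_path, ".vmrk"), useBytes = TRUE)

  con <- file(paste0(base_path, ".eeg"), "wb"); on.exit(close(con))
  if (binary_format == "INT_16") {
    raw_vals <- as.integer(round(sweep(rec$data, 1L, resolution, "/")))
    writeBin(as.vector(raw_vals), con, size = 2L, endian = "little")
  } else {
    writeBin(as.vector(rec$data), con, size = 4L, endian = "little")
  }
  invisible(base_path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
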