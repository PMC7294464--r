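# Epochs container: a JSON sidecar describing the tensor plus a raw
# little-endian float32 payload. Deliberately simple and dependency-free so
# epoched data can round-trip through text-auditable fixtures.

#' Write an epoch_set to disk
#'
#' Serializes an [epoch_set] as `epochs.json` (montage, labels, sampling
#' rate, time axis, tensor shape, byte order) plus `epochs.dat`, the raw
#' trials x channels x samples tensor as little-endian float32 in R's
#' column-major order. `read_epochs(write_epochs(e))` reproduces `e` up to
#' float32 rounding.
#'
#' @param e an [epoch_set].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @seealso [read_epochs()]
#' @export
write_epochs <- function(e, dir) {
  stopifnot(inherits(e, "epoch_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sidecar <- list(
    format = "chunkdyn-epochs-v1",
    subject_id = e$subject_id,
    srate = e$srate,
    time_ms = e$time_ms,
    condition = e$condition,
    shape = dim(e$data),
    order = "column_major",
    dtype = "float32",
    endianness = "little",
    montage = list(channel_names = e$montage$channel_names,
                   reference_label = e$montage$reference_label,
                   eog_channels = e$montage$eog_channels))
  jsonlite::write_json(sidecar, file.path(dir, "epochs.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  con <- file(file.path(dir, "epochs.dat"), "wb"); on.exit(close(con))
  writeBin(as.vector(e$data), con, size = 4L, endian = "little")
  invisible(dir)
}

#' Read an epoch_set from disk
#'
#' Counterpart of [write_epochs()]. The payload size is checked against the
#' sidecar's declared shape; any mismatch is an integrity error.
#'
#' @param dir directory holding `epochs.json` and `epochs.dat`.
#' @return An [epoch_set].
#' @export
read_epochs <- function(dir) {
  json_path <- file.path(dir, "epochs.json")
  dat_path <- file.path(dir, "epochs.dat")
  if (!file.exists(json_path) || !file.exists(dat_path))
    stop("not an epochs container (epochs.json / epochs.dat missing): ", dir)
  sc <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  if (!identical(sc$format, "chunkdyn-epochs-v1"))
    stop("unrecognized epochs container format: ", sc$format)
  shape <- as.integer(sc$shape)
  if (length(shape) != 3L) stop("sidecar shape must have 3 dimensions")
  n_expected <- prod(shape)
  sz <- file.size(dat_path)
  if (sz != n_expected * 4L)
    stop(sprintf(
      "integrity error: sidecar declares %d x %d x %d (%d bytes) but payload has %d bytes",
      shape[1L], shape[2L], shape[3L], n_expected * 4L, sz))
  if (length(sc$condition %||% character()) != shape[1L])
    stop("integrity error: condition labels do not match trial count")
  con <- file(dat_path, "rb"); on.exit(close(con))
  vals <- readBin(con, numeric(), n = n_expected, size = 4L,
                  endian = "little")
  if (length(vals) != n_expected)
    stop("integrity error: truncated payload")
  m <- montage(sc$montage$channel_names,
               reference_label = sc$montage$reference_label,
               eog_channels = sc$montage$eog_channels %||% character())
  epoch_set(m, sc$subject_id, array(vals, dim = shape),
            as.numeric(sc$time_ms),
            as.character(sc$condition %||% character()), sc$srate)
}

#' Read a behavioral trial table from CSV
#'
#' Reads a CSV with the columns of [trial_table()] and validates every row
#' against the design's enumerations and the 3-second response deadline.
#' Offending row numbers are reported in the error message.
#'
#' @param csv_path path to the CSV file.
#' @return A validated [trial_table].
#' @export
read_trial_table <- function(csv_path) {
  if (!file.exists(csv_path)) stop("file not found: ", csv_path)
  df <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  trial_table(df)
}

#' Write a trial table to CSV
#' @param t a [trial_table]
#' @param csv_path output path
#' @return `csv_path`, invisibly
#' @export
write_trial_table <- function(t, csv_path) {
  utils::write.csv(as.data.frame(t), csv_path, row.names = FALSE)
  invisible(csv_path)
}
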