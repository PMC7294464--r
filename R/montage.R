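#' Electrode montage
#'
#' A montage names the scalp channels in recording order and marks which of
#' them sit over the eyes (used for blink simulation and, optionally, for
#' restricting artifact rejection). The number of channels is the
#' dimensionality of every topography vector downstream: a topography at one
#' time point is a vector with one amplitude per channel.
#'
#' @param channel_names character vector of unique channel labels, in the
#'   order channels appear in the data matrices.
#' @param reference_label label of the (online) reference, e.g. `"Cz"` or
#'   `"average"`. Informational only; re-referencing is an explicit step.
#' @param eog_channels subset of `channel_names` that monitor eye movements
#'   (typically the frontopolar pair).
#' @return An object of class `"montage"`: a list with `channel_names`,
#'   `n_channels`, `reference_label`, `eog_channels`.
#' @examples
#' m <- montage(c("Fp1", "Fp2", "Cz"), eog_channels = c("Fp1", "Fp2"))
#' m$n_channels
#' @export
montage <- function(channel_names, reference_label = "average",
                    eog_channels = character()) {
  channel_names <- as.character(channel_names)
  if (length(channel_names) < 1L)
    stop("montage needs at least one channel")
  if (anyDuplicated(channel_names))
    stop("channel names must be unique")
  if (!all(eog_channels %in% channel_names))
    stop("eog_channels must be a subset of channel_names")
  structure(
    list(channel_names = channel_names,
         n_channels = length(channel_names),
         reference_label = as.character(reference_label)[1L],
         eog_channels = as.character(eog_channels)),
    class = "montage")
}

#' Standard 32-channel active-electrode montage
#'
#' The conventional 32-channel 10-20 layout of actiCAP-family caps, recorded
#' online against Cz, with Fp1/Fp2 monitoring vertical eye movements. This is
#' the default montage of the synthetic generator and gives the electrode
#' family size (32) used by the per-window FDR correction.
#'
#' @return A [montage] with 32 channels.
#' @export
actichamp_montage <- function() {
  montage(
    c("Fp1", "Fz", "F3", "F7", "FT9", "FC5", "FC1", "C3",
      "T7", "TP9", "CP5", "CP1", "Pz", "P3", "P7", "O1",
      "Oz", "O2", "P4", "P8", "TP10", "CP6", "CP2", "Cz",
      "C4", "T8", "FT10", "FC6", "FC2", "F4", "F8", "Fp2"),
    reference_label = "Cz",
    eog_channels = c("Fp1", "Fp2"))
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf("<montage> %d channels, reference %s\n",
              x$n_channels, x$reference_label))
  cat("  ", paste(x$channel_names, collapse = " "), "\n", sep = "")
  if (length(x$eog_channels))
    cat("  EOG: ", paste(x$eog_channels, collapse = " "), "\n", sep = "")
  invisible(x)
}
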