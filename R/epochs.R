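#' @useDynLib coherwalk, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# classed conditions so callers can distinguish configuration problems
# from data problems
cw_stop <- function(class, msg, ...) {
  stop(structure(
    list(message = sprintf(msg, ...), call = sys.call(-1)),
    class = c(class, "coherwalk_error", "error", "condition")
  ))
}

#' EEG epoch container
#'
#' A single task-locked epoch for one player in one game: a channels x
#' samples matrix of scalp potentials with its sampling rate and ordered
#' electrode labels (10-20 system names such as Fp1, Cz, O2).
#'
#' @param data numeric matrix, channels x samples (microvolts).
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector, one label per row of `data`.
#' @param player_id,game_id optional identifiers carried through the
#'   pipeline.
#' @return An object of class `eeg_epoch`.
#' @export
eeg_epoch <- function(data, fs, channel_labels = rownames(data),
                      player_id = NA_character_, game_id = NA_character_) {
  data <- as.matrix(data)
  if (is.null(channel_labels)) {
    channel_labels <- paste0("ch", seq_len(nrow(data)))
  }
  if (length(channel_labels) != nrow(data)) {
    cw_stop("coherwalk_config_error",
            "channel_labels length (%d) != number of channels (%d)",
            length(channel_labels), nrow(data))
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    cw_stop("coherwalk_config_error", "fs must be a positive scalar")
  }
  if (anyNA(data)) cw_stop("coherwalk_data_error", "epoch contains missing values")
  storage.mode(data) <- "double"
  rownames(data) <- channel_labels
  structure(list(data = data, fs = as.numeric(fs),
                 channel_labels = as.character(channel_labels),
                 player_id = player_id, game_id = game_id),
            class = "eeg_epoch")
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf("<eeg_epoch> %d channels x %d samples @ %g Hz (player=%s, game=%s)\n",
              nrow(x$data), ncol(x$data), x$fs, x$player_id, x$game_id))
  invisible(x)
}

#' Preprocessing configuration
#'
#' Defaults condition a 512 Hz recording to a 1-second, 64 Hz epoch:
#' zero-phase Butterworth band-pass (1-32 Hz, compatible with the 32 Hz
#' Nyquist of the target rate), re-referencing to the common average,
#' integer decimation, and per-channel epoch-mean baseline correction.
#'
#' @param bandpass_low,bandpass_high band-pass corner frequencies in Hz.
#' @param target_fs output sampling rate in Hz; must divide the input rate.
#' @param epoch_length epoch duration in seconds.
#' @param baseline_mode `"epoch_mean"` (subtract each channel's temporal
#'   mean) or `"none"`.
#' @param filter_order Butterworth order (applied forward and backward, so
#'   the effective attenuation is doubled).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(bandpass_low = 1, bandpass_high = 32,
                              target_fs = 64, epoch_length = 1,
                              baseline_mode = c("epoch_mean", "none"),
                              filter_order = 4) {
  baseline_mode <- match.arg(baseline_mode)
  if (!(0 < bandpass_low && bandpass_low < bandpass_high &&
        bandpass_high <= target_fs / 2)) {
    cw_stop("coherwalk_config_error",
            "require 0 < bandpass_low < bandpass_high <= target_fs/2")
  }
  structure(list(bandpass_low = bandpass_low, bandpass_high = bandpass_high,
                 target_fs = target_fs, epoch_length = epoch_length,
                 baseline_mode = baseline_mode, filter_order = filter_order),
            class = "preprocess_config")
}

#' Condition a raw EEG epoch
#'
#' Applies, in order: zero-phase band-pass filtering, re-referencing to
#' the average reference, integer decimation to the target rate, and
#' (optionally) per-channel epoch-mean baseline correction. The epoch is
#' truncated to exactly `epoch_length` seconds from its first sample
#' (task onset). Independent component analysis for artifact rejection is
#' deliberately not part of this function: component selection is a
#' manual step; insert it before calling if needed.
#'
#' @param raw an [eeg_epoch()].
#' @param cfg a [preprocess_config()].
#' @return An [eeg_epoch()] at `cfg$target_fs` with
#'   `target_fs * epoch_length` samples; at every sample the mean across
#'   channels is ~0.
#' @export
preprocess_epoch <- function(raw, cfg = preprocess_config()) {
  stopifnot(inherits(raw, "eeg_epoch"), inherits(cfg, "preprocess_config"))
  if (raw$fs < 2 * cfg$bandpass_high) {
    cw_stop("coherwalk_config_error",
            "sampling rate %g Hz below Nyquist for bandpass_high = %g Hz",
            raw$fs, cfg$bandpass_high)
  }
  dec <- raw$fs / cfg$target_fs
  if (abs(dec - round(dec)) > 1e-9) {
    cw_stop("coherwalk_config_error",
            "target_fs %g does not divide fs %g (non-integer decimation)",
            cfg$target_fs, raw$fs)
  }
  dec <- as.integer(round(dec))
  n_need <- as.integer(round(cfg$epoch_length * raw$fs))
  if (ncol(raw$data) < n_need) {
    cw_stop("coherwalk_truncation_error",
            "epoch has %d samples, need %d for %g s at %g Hz",
            ncol(raw$data), n_need, cfg$epoch_length, raw$fs)
  }
  x <- raw$data[, seq_len(n_need), drop = FALSE]

  bf <- signal::butter(cfg$filter_order,
                       c(cfg$bandpass_low, cfg$bandpass_high) / (raw$fs / 2),
                       type = "pass")
  x <- t(apply(x, 1L, function(ch) signal::filtfilt(bf, ch)))

  # common average reference: per-sample mean across channels is zero
  x <- sweep(x, 2L, colMeans(x))
  # decimate (band-pass already confines energy below the new Nyquist)
  x <- x[, seq(1L, ncol(x), by = dec), drop = FALSE]
  if (cfg$baseline_mode == "epoch_mean") {
    x <- sweep(x, 1L, rowMeans(x))
  }
  eeg_epoch(x, cfg$target_fs, raw$channel_labels, raw$player_id, raw$game_id)
}
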