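#' Describe an EEG acquisition device
#'
#' A device profile records the electrode montage (10-20 labels, in channel
#' order), the per-channel sampling rate, the ADC resolution and the reference
#' electrodes. The default profile matches a 14-channel consumer headset
#' sampled at 128 Hz with saline electrodes referenced at P3/P4.
#'
#' @param channel_names Character vector of unique 10-20 electrode labels, in
#'   channel order.
#' @param sampling_rate_hz Sampling rate per channel in Hz (positive).
#' @param adc_bits ADC resolution in bits.
#' @param reference_labels 10-20 labels of the reference electrodes.
#'
#' @return An object of class `device_profile`.
#' @examples
#' device_profile()
#' @export
device_profile <- function(channel_names = c(
                             "AF3", "F7", "F3", "FC5", "T7", "P7", "O1",
                             "O2", "P8", "T8", "FC6", "F4", "F8", "AF4"
                           ),
                           sampling_rate_hz = 128,
                           adc_bits = 16L,
                           reference_labels = c("P3", "P4")) {
  if (!is.character(channel_names) || length(channel_names) == 0) {
    abort("`channel_names` must be a non-empty character vector.")
  }
  if (anyDuplicated(channel_names)) {
    abort("`channel_names` must be unique.")
  }
  assert_scalar_number(sampling_rate_hz, "sampling_rate_hz", positive = TRUE)
  structure(
    list(
      channel_names = channel_names,
      sampling_rate_hz = sampling_rate_hz,
      adc_bits = as.integer(adc_bits),
      reference_labels = reference_labels
    ),
    class = "device_profile"
  )
}

#' @export
print.device_profile <- function(x, ...) {
  cat(sprintf(
    "<device_profile> %d channels @ %g Hz (%d-bit ADC, ref %s)\n",
    length(x$channel_names), x$sampling_rate_hz, x$adc_bits,
    paste(x$reference_labels, collapse = "/")
  ))
  cat("  ", paste(x$channel_names, collapse = " "), "\n")
  invisible(x)
}
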