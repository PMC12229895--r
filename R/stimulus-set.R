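#' Construct the auditory stimulus set
#'
#' Builds the table describing the stimulus battery used throughout the
#' pipeline: a bank of short pure-tone (PT) pips on a geometric frequency
#' ladder plus a set of complex sounds (CS). The default reproduces the
#' standard 34-stimulus set: 19 pure tones of 50 ms covering 2-45 kHz in
#' quarter-octave steps, and 15 complex sounds of 70 ms. Complex sounds carry
#' no spectral descriptor here; only their identity and duration matter to the
#' downstream statistics.
#'
#' @param n_pt number of pure tones (>= 1).
#' @param n_cs number of complex sounds (>= 0).
#' @param f0 lowest pure-tone frequency in kHz (> 0).
#' @param step frequency step between consecutive tones, in octaves, so that
#'   tone k has frequency `f0 * 2^((k - 1) * step)`.
#' @param pt_duration,cs_duration stimulus durations in ms.
#' @return A data.frame of class `stimulus_set` with columns `stimulus_id`
#'   (1..n_pt + n_cs), `class` ("PT"/"CS"), `pt_frequency` (kHz, NA for CS)
#'   and `duration` (ms).
#' @examples
#' ss <- build_stimulus_set()
#' nrow(ss)                     # 34
#' max(ss$pt_frequency, na.rm = TRUE)  # 45.25 kHz
#' @export
build_stimulus_set <- function(n_pt = 19, n_cs = 15, f0 = 2, step = 1 / 4,
                               pt_duration = 50, cs_duration = 70) {
  if (n_pt < 1 || n_cs < 0 || f0 <= 0 || step <= 0) {
    dm_stop("driftmap_invalid_argument",
            "build_stimulus_set: need n_pt >= 1, n_cs >= 0, f0 > 0, step > 0")
  }
  freqs <- f0 * 2^((seq_len(n_pt) - 1) * step)
  out <- data.frame(
    stimulus_id = seq_len(n_pt + n_cs),
    class = rep(c("PT", "CS"), c(n_pt, n_cs)),
    pt_frequency = c(freqs, rep(NA_real_, n_cs)),
    duration = rep(c(pt_duration, cs_duration), c(n_pt, n_cs)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("stimulus_set", "data.frame")
  out
}

#' @export
print.stimulus_set <- function(x, ...) {
  pt <- x$class == "PT"
  cat(sprintf("<stimulus_set> %d stimuli: %d PT (%.3g-%.3g kHz), %d CS\n",
              nrow(x), sum(pt),
              if (any(pt)) min(x$pt_frequency[pt]) else NA,
              if (any(pt)) max(x$pt_frequency[pt]) else NA,
              sum(!pt)))
  invisible(x)
}

#' In-plane displacement corresponding to a pixel shift
#'
#' Converts an ROI displacement in pixels into micrometres given the imaging
#' field geometry (default: a 367 um field sampled at 256 px across), e.g. the
#' 2-pixel local matching tolerance of the ROI tracking step equals 2.87 um.
#'
#' @param pixels displacement in pixels.
#' @param fov_um field width in micrometres.
#' @param fov_px field width in pixels.
#' @return Displacement in micrometres.
#' @export
pixel_displacement_um <- function(pixels = 2, fov_um = 367, fov_px = 256) {
  pixels * fov_um / fov_px
}
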