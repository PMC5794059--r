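# Beat analysis: amplitude modulation of an oscillatory signal, measured on
# the heights of its carrier peaks.  When two oscillations of nearby
# frequencies f1 and f2 superpose, the envelope oscillates at |f1 - f2|
# (sum-to-product identity).

carrier_peaks <- function(time, signal, t_transient = 0,
                          min_prominence = 0.05) {
  sel <- time >= t_transient
  y <- signal[sel]
  tt <- time[sel]
  pk <- find_peaks(y, min_prominence = min_prominence * (max(y) - min(y)))
  list(time = tt[pk], height = y[pk])
}

#' Envelope (beat) frequency of an amplitude-modulated signal
#'
#' Extracts the carrier peaks of the signal, treats the peak heights as a
#' slow series, and measures the spacing of that series' own maxima: the
#' envelope period.  For the superposition of two unit tones at `f1` and
#' `f2` this recovers `|f1 - f2|`.
#'
#' @param time,signal Numeric vectors of equal length.
#' @param t_transient Initial window to discard (min).
#' @param min_prominence Carrier-peak prominence threshold as a fraction of
#'   the signal range.
#' @return Envelope frequency (1/min).
#' @export
beat_envelope_frequency <- function(time, signal, t_transient = 0,
                                    min_prominence = 0.05) {
  cp <- carrier_peaks(time, signal, t_transient, min_prominence)
  if (length(cp$time) < 6)
    stop("too few carrier peaks to resolve an envelope", call. = FALSE)
  h <- cp$height
  epk <- find_peaks(h, min_prominence = 0.1 * (max(h) - min(h)))
  if (length(epk) < 3)
    stop("too few envelope maxima to estimate a beat frequency",
         call. = FALSE)
  1 / mean(diff(cp$time[epk]))
}

#' Amplitude-modulation depth of an oscillatory signal
#'
#' Coefficient of variation of the carrier peak heights after the
#' transient.  A strictly periodic signal has depth ~0; beats give a
#' sizeable depth.
#'
#' @inheritParams beat_envelope_frequency
#' @return Nonnegative number (sd of peak heights / mean peak height).
#' @export
modulation_depth <- function(time, signal, t_transient = 0,
                             min_prominence = 0.05) {
  cp <- carrier_peaks(time, signal, t_transient, min_prominence)
  if (length(cp$height) < 4)
    stop("too few carrier peaks to measure modulation", call. = FALSE)
  stats::sd(cp$height) / mean(cp$height)
}
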