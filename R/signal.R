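#' Low-pass FIR envelope filter specification
#'
#' Linear-phase windowed-sinc (Hamming) low-pass filter used to turn
#' rectified sEMG into its integrated-EMG (IEMG) envelope. Tap design is
#' delegated to [signal::fir1()]; the default is a 101-tap filter with 3 Hz
#' cutoff at a 500 Hz sampling rate and unit DC gain, so a constant input
#' passes unchanged at steady state. Coefficients can also be supplied
#' directly (e.g. loaded from a config) to swap in a different envelope
#' filter.
#'
#' @param cutoff Cutoff frequency in Hz.
#' @param fs Sampling rate in Hz.
#' @param order Filter order (taps = order + 1).
#' @param coefficients Optional explicit tap vector overriding the design.
#' @return An object of class `fir_spec`: list with `coefficients` and
#'   `dc_gain` (= sum of taps).
#' @export
#' @examples
#' spec <- fir_lowpass()
#' length(spec$coefficients)
fir_lowpass <- function(cutoff = 3, fs = 500, order = 100,
                        coefficients = NULL) {
  if (is.null(coefficients)) {
    stopifnot(cutoff > 0, fs > 2 * cutoff, order >= 1)
    coefficients <- as.numeric(signal::fir1(order, cutoff / (fs / 2), "low"))
    coefficients <- coefficients / sum(coefficients) # exact unit DC gain
  }
  if (length(coefficients) == 0 || any(!is.finite(coefficients))) {
    abort("FIR coefficients must be nonempty and finite.")
  }
  structure(
    list(coefficients = as.numeric(coefficients),
         dc_gain = sum(coefficients)),
    class = "fir_spec"
  )
}

#' Full-wave rectification
#'
#' @param x Numeric vector or matrix of raw sEMG samples.
#' @return `abs(x)`; idempotent.
#' @export
rectify <- function(x) abs(x)

#' Causal FIR filtering with carried streaming state
#'
#' Filters each channel with the causal convolution
#' `y[t] = sum_j b[j] * x[t - j + 1]`, carrying the last `length(b) - 1`
#' input samples per channel between calls so that filtering a stream window
#' by window is bit-identical to filtering the concatenated stream at once.
#' At stream start the state is zeros (cold start): the first
#' `length(b) - 1` outputs are warm-up.
#'
#' @param x Numeric matrix (rows = samples, columns = channels) or vector.
#' @param spec A [fir_lowpass()] specification.
#' @param state Optional matrix of the last `length(b) - 1` inputs per
#'   channel from the preceding call; `NULL` means stream start.
#' @return List with `values` (filtered matrix, same shape as `x`) and
#'   `state` (matrix to pass to the next call).
#' @export
fir_filter <- function(x, spec, state = NULL) {
  x <- as.matrix(x)
  b <- spec$coefficients
  nb <- length(b)
  nc <- ncol(x)
  if (is.null(state)) {
    state <- matrix(0, nrow = nb - 1L, ncol = nc)
  } else {
    state <- as.matrix(state)
    if (ncol(state) != nc || nrow(state) != nb - 1L) {
      abort(sprintf(
        "Filter state must be %d x %d (got %d x %d).",
        nb - 1L, nc, nrow(state), ncol(state)
      ))
    }
  }
  xx <- rbind(state, x)
  y <- stats::filter(xx, b, method = "convolution", sides = 1)
  y <- as.matrix(y)[-seq_len(nb - 1L), , drop = FALSE]
  dimnames(y) <- dimnames(x)
  new_state <- if (nb > 1L) {
    xx[nrow(xx) - (nb - 2L):0, , drop = FALSE]
  } else {
    matrix(0, 0L, nc)
  }
  list(values = y, state = new_state)
}

#' Rectify and filter a raw EMG stream into its IEMG envelope
#'
#' @param emg Raw EMG tibble (`time` + channel columns) as from
#'   [synthesize_emg()] or [read_stream_tsv()].
#' @param spec A [fir_lowpass()] specification.
#' @return Tibble of the same layout holding the IEMG envelope.
#' @export
compute_iemg <- function(emg, spec = fir_lowpass()) {
  ch <- emg_columns(emg)
  filt <- fir_filter(rectify(as.matrix(emg[, ch])), spec)
  out <- emg[, "time"]
  out[ch] <- as_tibble(filt$values, .name_repair = "minimal")
  out
}

emg_columns <- function(df) {
  grep("^ch[0-9]+$", names(df), value = TRUE)
}

#' Per-channel MVC normalization profile
#'
#' Processes an MVC recording exactly like the live signal (rectify +
#' low-pass FIR), then records per channel the minimum and maximum of the
#' integrated MVC envelope. The first two filter lengths of output (cold
#' start warm-up plus a guard of equal length) are excluded, so neither the
#' start-up transient nor leading silence in the recording can masquerade
#' as the minimum.
#'
#' @param mvc Raw MVC EMG tibble.
#' @param spec A [fir_lowpass()] specification.
#' @return Tibble of class `mvc_profile` with columns `channel`, `min`,
#'   `max`.
#' @export
compute_mvc_profile <- function(mvc, spec = fir_lowpass()) {
  ch <- emg_columns(mvc)
  nb <- length(spec$coefficients)
  settle <- 2L * (nb - 1L)
  if (nrow(mvc) <= settle + 1L) {
    abort("MVC recording is shorter than the filter settle time.")
  }
  filt <- fir_filter(rectify(as.matrix(mvc[, ch])), spec)
  settled <- filt$values[-seq_len(settle), , drop = FALSE]
  mins <- apply(settled, 2, min)
  maxs <- apply(settled, 2, max)
  flat <- which(maxs <= mins)
  if (length(flat) > 0) {
    abort(paste0(
      "Degenerate MVC channel(s) with max <= min: ",
      paste(ch[flat], collapse = ", ")
    ))
  }
  out <- tibble(channel = ch, min = unname(mins), max = unname(maxs))
  class(out) <- c("mvc_profile", class(out))
  out
}

#' Min-max normalize an IEMG window against an MVC profile
#'
#' Applies `(IEMG - min) / (max - min)` per channel, then clips to
#' `[0, 1]`: live activation can exceed the calibrated maximum, and the
#' downstream regressor expects inputs on the calibrated scale.
#'
#' @param iemg Numeric matrix (samples x channels) or IEMG tibble.
#' @param profile An [compute_mvc_profile()] result.
#' @return Same shape as the input, values in `[0, 1]`.
#' @export
normalize_iemg <- function(iemg, profile) {
  stopifnot(all(profile$max > profile$min))
  is_df <- is.data.frame(iemg)
  if (is_df) {
    ch <- emg_columns(iemg)
    mat <- as.matrix(iemg[, ch])
  } else {
    mat <- as.matrix(iemg)
  }
  if (ncol(mat) != nrow(profile)) {
    abort("Channel count of input and MVC profile differ.")
  }
  scaled <- sweep(mat, 2, profile$min, "-")
  scaled <- sweep(scaled, 2, profile$max - profile$min, "/")
  scaled <- pmin(pmax(scaled, 0), 1)
  if (is_df) {
    out <- iemg[, "time"]
    out[ch] <- as_tibble(scaled, .name_repair = "minimal")
    out
  } else {
    scaled
  }
}

#' Process one raw 120 ms window into normalized IEMG
#'
#' The per-cycle composition the real-time loop runs: rectify, causal FIR
#' with carried state, MVC min-max normalization. Output shape equals input
#' shape (60 x 32 for the standard 120 ms window at 500 Hz).
#'
#' @param raw Numeric matrix, samples x channels (60 x 32 in the standard
#'   configuration).
#' @param profile An [compute_mvc_profile()] result.
#' @param spec A [fir_lowpass()] specification.
#' @param state Filter state carried from the previous window (`NULL` at
#'   stream start). NOTE: the state holds *rectified* samples.
#' @return List with `values` (normalized matrix) and `state`.
#' @export
process_window <- function(raw, profile, spec = fir_lowpass(), state = NULL) {
  filt <- fir_filter(rectify(as.matrix(raw)), spec, state = state)
  list(values = normalize_iemg(filt$values, profile), state = filt$state)
}

#' Full-stream normalized IEMG
#'
#' Offline equivalent of running [process_window()] over a whole recording:
#' rectify, filter, normalize every sample.
#'
#' @inheritParams compute_iemg
#' @param profile An [compute_mvc_profile()] result.
#' @return Tibble (`time` + channel columns) of normalized IEMG in `[0, 1]`.
#' @export
process_stream <- function(emg, profile, spec = fir_lowpass()) {
  normalize_iemg(compute_iemg(emg, spec), profile)
}
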