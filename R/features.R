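#' Sliding-window grid over the encoding epoch
#'
#' Default: fourteen 200-ms windows at 100-ms steps spanning 0-1500 ms
#' post-stimulus: `[0,200), [100,300), ..., [1300,1500)`.
#'
#' @param span analysis span in ms.
#' @param length_ms window length.
#' @param step_ms step between window starts.
#' @return integer matrix with columns `start`, `end` (half-open, ms).
#' @export
window_grid <- function(span = c(0, 1500), length_ms = 200, step_ms = 100) {
  stopifnot(span[2] - span[1] >= length_ms, length_ms > 0, step_ms > 0)
  starts <- seq(span[1], span[2] - length_ms, by = step_ms)
  cbind(start = starts, end = starts + length_ms)
}

# Sample indices of an epoch time axis falling in [a, b) ms.
.window_idx <- function(t0, srate, n_samp, window) {
  t <- t0 + (seq_len(n_samp) - 1) * 1000 / srate
  which(t >= window[1] & t < window[2])
}

#' Baseline-correct voltage epochs
#'
#' Subtracts, per trial and channel, the mean voltage within the baseline
#' window from the entire epoch.  The convention follows the recording
#' pipeline: memory epochs use `[-600, -400)` ms and source-task epochs
#' `[-400, -200)` ms before stimulus onset.
#'
#' @param epochs an `epoch_set`.
#' @param window baseline window `[a, b)` in ms.
#' @return the corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs, window = c(-600, -400)) {
  stopifnot(inherits(epochs, "epoch_set"), window[1] < window[2])
  n_samp <- dim(epochs$data)[3]
  idx <- .window_idx(epochs$t0, epochs$srate, n_samp, window)
  if (length(idx) == 0)
    stop("baseline window [", window[1], ", ", window[2],
         ") is outside the epoch span")
  bl <- apply(epochs$data[, , idx, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - array(bl, dim = dim(epochs$data))
  epochs
}

#' Morlet frequency grid
#'
#' @param f_lo,f_hi frequency range in Hz.
#' @param n_freqs number of linearly spaced frequencies (default 78, giving
#'   a 1-Hz grid from 3 to 80 Hz).
#' @return numeric vector of frequencies.
#' @export
morlet_frequencies <- function(f_lo = 3, f_hi = 80, n_freqs = 78) {
  seq(f_lo, f_hi, length.out = n_freqs)
}

#' Default frequency-band definitions (Hz)
#' @export
default_bands <- function() {
  list(theta = c(6, 8), alpha = c(8, 12), beta = c(13, 30), gamma = c(35, 80))
}

# Complex Morlet wavelet at frequency f (Hz), n cycles, sampled at srate.
# Support out to 3 SD of the Gaussian envelope; L2-normalized.
.morlet_kernel <- function(f, cycles, srate) {
  sd_t <- cycles / (2 * pi * f)
  half <- ceiling(3 * sd_t * srate)
  t <- (-half:half) / srate
  w <- exp(2i * pi * f * t) * exp(-t^2 / (2 * sd_t^2))
  w / sqrt(sum(Mod(w)^2))
}

# Morlet power of a single time series: n_freqs x n_samples matrix.
# FFT-based "same" convolution over all frequencies at once.
.morlet_power_one <- function(x, srate, freqs, cycles) {
  n <- length(x)
  kerns <- lapply(freqs, .morlet_kernel, cycles = cycles, srate = srate)
  maxk <- max(vapply(kerns, length, 1L))
  nfft <- stats::nextn(n + maxk - 1, 2)
  fx <- stats::fft(c(x, rep(0, nfft - n)))
  km <- vapply(kerns, function(k) {
    half <- (length(k) - 1L) / 2L
    # circularly shift so the kernel center sits at lag 0
    kp <- rep(0 + 0i, nfft)
    kp[seq_along(k)] <- k
    stats::fft(kp) * exp(2i * pi * half * (0:(nfft - 1)) / nfft)
  }, complex(nfft))
  conv <- stats::mvfft(km * fx, inverse = TRUE) / nfft
  t(Mod(conv[seq_len(n), , drop = FALSE])^2)
}

#' Morlet band-power streams for an epoch set
#'
#' Convolves every trial and channel with complex Morlet wavelets (5 cycles,
#' 78 linearly spaced frequencies from 3 to 80 Hz by default), log-transforms
#' the power of each frequency, averages within each band, and downsamples
#' the band series to `power_srate` (50 Hz).  The transform runs on the full
#' epoch so later windowing introduces no per-window edge artifacts.
#'
#' @param epochs an `epoch_set`.
#' @param f_lo,f_hi,n_freqs frequency grid (see [morlet_frequencies()]).
#' @param cycles wavelet cycles.
#' @param bands named list of band ranges in Hz.
#' @param power_srate output sampling rate of the band series.
#' @return list of band arrays (trials x channels x downsampled samples)
#'   with attributes `srate` and `t0`.
#' @export
morlet_bandpower <- function(epochs, f_lo = 3, f_hi = 80, n_freqs = 78,
                             cycles = 5, bands = default_bands(),
                             power_srate = 50) {
  stopifnot(inherits(epochs, "epoch_set"))
  freqs <- morlet_frequencies(f_lo, f_hi, n_freqs)
  for (b in bands)
    if (b[1] < f_lo || b[2] > f_hi)
      stop("band [", b[1], ", ", b[2], "] outside the frequency grid")
  dec <- round(epochs$srate / power_srate)
  stopifnot(dec >= 1)
  dn <- dim(epochs$data)
  n_tr <- dn[1]; n_ch <- dn[2]; n_samp <- dn[3]
  keep <- seq(1, n_samp, by = dec)
  band_idx <- lapply(bands, function(b) which(freqs >= b[1] & freqs <= b[2]))
  out <- lapply(bands, function(b)
    array(0, dim = c(n_tr, n_ch, length(keep))))
  for (i in seq_len(n_tr)) {
    for (ch in seq_len(n_ch)) {
      pw <- .morlet_power_one(epochs$data[i, ch, ], epochs$srate, freqs, cycles)
      lp <- log(pmax(pw, .Machine$double.xmin))
      for (bn in names(bands)) {
        bm <- colMeans(lp[band_idx[[bn]], , drop = FALSE])
        out[[bn]][i, ch, ] <- bm[keep]
      }
    }
  }
  for (bn in names(bands)) {
    attr(out[[bn]], "srate") <- epochs$srate / dec
    attr(out[[bn]], "t0") <- epochs$t0
  }
  out
}

#' Build the five per-trial signal streams
#'
#' Combines the 250-Hz voltage stream with the four log band-power streams
#' (50 Hz) into a single container consumed by the windowing and CSP
#' stages.  `streams` can restrict the set (e.g. `"voltage"` only for fast
#' simulations).
#'
#' @param epochs an `epoch_set` (voltage already baseline-corrected if
#'   desired).
#' @param streams character vector among `"voltage"`, `"theta"`, `"alpha"`,
#'   `"beta"`, `"gamma"`.
#' @param ... passed to [morlet_bandpower()].
#' @return an object of class `"stream_set"`.
#' @export
signal_streams <- function(epochs, streams = c("voltage", "theta", "alpha",
                                               "beta", "gamma"), ...) {
  stopifnot(inherits(epochs, "epoch_set"))
  streams <- match.arg(streams, several.ok = TRUE)
  out <- list()
  if ("voltage" %in% streams) {
    v <- epochs$data
    attr(v, "srate") <- epochs$srate
    attr(v, "t0") <- epochs$t0
    out$voltage <- v
  }
  pbands <- setdiff(streams, "voltage")
  if (length(pbands) > 0) {
    bp <- morlet_bandpower(epochs, bands = default_bands()[pbands], ...)
    out <- c(out, bp)
  }
  structure(list(streams = out[streams], channels = epochs$channels,
                 task_id = epochs$task_id, trials = epochs$trials),
            class = "stream_set")
}

#' Cut one time window out of a stream set
#'
#' Uses the half-open convention `[start, end)` in ms; at the default rates
#' a 200-ms window yields 50 voltage samples and 10 power samples per
#' channel.
#'
#' @param streams a `stream_set`.
#' @param window numeric `[start, end)` in ms.
#' @return an object of class `"signal_stack"`: list of per-stream arrays
#'   (trials x channels x window samples) plus the window and metadata.
#' @export
stream_window <- function(streams, window) {
  stopifnot(inherits(streams, "stream_set"), window[1] < window[2])
  cut <- lapply(streams$streams, function(a) {
    idx <- .window_idx(attr(a, "t0"), attr(a, "srate"), dim(a)[3], window)
    if (length(idx) == 0)
      stop("window [", window[1], ", ", window[2], ") outside stream span")
    out <- a[, , idx, drop = FALSE]
    attr(out, "srate") <- attr(a, "srate")
    out
  })
  structure(list(streams = cut, window = window, channels = streams$channels,
                 task_id = streams$task_id, trials = streams$trials),
            class = "signal_stack")
}

#' Slice a stream set into a list of windows
#'
#' @param streams a `stream_set`.
#' @param grid a [window_grid()] matrix.
#' @return list of `signal_stack` objects, one per grid row.
#' @export
slice_windows <- function(streams, grid) {
  stopifnot(is.matrix(grid))
  if (nrow(grid) == 0) stop("empty window grid")
  lapply(seq_len(nrow(grid)), function(i) stream_window(streams, grid[i, ]))
}
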