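# Morlet wavelet time-frequency decomposition with log-ratio baselining
# and band-averaged power time courses.

# L2-normalized complex Morlet wavelet at frequency f with n_cycles
# cycles; Gaussian SD in time = cycles / (2 pi f)
.morlet_wavelet <- function(f, n_cycles, fs) {
  sigma_t <- n_cycles / (2 * pi * f)
  t <- seq(-4 * sigma_t, 4 * sigma_t, by = 1 / fs)
  w <- exp(2i * pi * f * t) * exp(-t^2 / (2 * sigma_t^2))
  w / sqrt(sum(Mod(w)^2))
}

# complex convolution via FFT, 'same' alignment
.fft_convolve <- function(x, w) {
  n <- length(x) + length(w) - 1L
  nfft <- stats::nextn(n, 2)
  y <- stats::fft(stats::fft(c(x, rep(0, nfft - length(x)))) *
                    stats::fft(c(w, rep(0, nfft - length(w)))),
                  inverse = TRUE) / nfft
  start <- (length(w) - 1L) %/% 2L + 1L
  y[start:(start + length(x) - 1L)]
}

#' Morlet wavelet time-frequency decomposition
#'
#' Power is the squared magnitude of the complex Morlet convolution at
#' each frequency, with the number of cycles set to one third of the
#' center frequency. The first and last `edge` seconds are trimmed to
#' eliminate wavelet edge artifacts. Input may be an `epoch_set` (power
#' averaged across epochs unless `average = FALSE`), an `evoked`, or a
#' plain matrix.
#'
#' @param epochs An `epoch_set`, `evoked`, or channels x samples matrix.
#' @param freqs Analysis frequencies \[Hz\] (default 3-40 in 1 Hz
#'   steps).
#' @param n_cycles_rule Function mapping frequency to cycle count
#'   (default `f/3`).
#' @param edge Edge trim \[s\].
#' @param average Average power across epochs (default TRUE).
#' @param times Time axis, required for matrix input.
#' @param sample_rate Sampling rate, required for matrix input.
#' @return Object of class `tfr_array`: `power`
#'   (channels x freqs x samples, or epochs x channels x freqs x samples
#'   when `average = FALSE`), `freqs`, `times` (trimmed), `baseline`
#'   (NULL until baselined), `log_ratio = FALSE`.
#' @export
morlet_tfr <- function(epochs, freqs = 3:40,
                       n_cycles_rule = function(f) f / 3,
                       edge = 0.2, average = TRUE, times = NULL,
                       sample_rate = NULL) {
  if (inherits(epochs, "epoch_set")) {
    dat <- epochs$data
    times <- epochs$times
    fs <- epochs$sample_rate
    ch_names <- epochs$channel_names
  } else if (inherits(epochs, "evoked")) {
    dat <- array(epochs$data, c(1, dim(epochs$data)))
    times <- epochs$times
    fs <- epochs$sample_rate
    ch_names <- epochs$channel_names
  } else {
    stopifnot(!is.null(times), !is.null(sample_rate))
    dat <- array(epochs, c(1, dim(epochs)))
    fs <- sample_rate
    ch_names <- rownames(epochs)
  }
  n_t <- length(times)
  wavelets <- lapply(freqs, function(f) {
    w <- .morlet_wavelet(f, n_cycles_rule(f), fs)
    if (length(w) > n_t)
      stop(sprintf("wavelet at %g Hz longer than the epoch", f))
    w
  })
  keep <- which(times >= times[1] + edge & times <= times[n_t] - edge)
  n_ep <- dim(dat)[1]; n_ch <- dim(dat)[2]
  # shared FFT grid: transform each signal once, reuse across wavelets
  wmax <- max(vapply(wavelets, length, 0L))
  nfft <- stats::nextn(n_t + wmax - 1L, 2)
  Wf <- vapply(wavelets, function(w)
    stats::fft(c(w, rep(0, nfft - length(w)))),
    complex(nfft))
  starts <- vapply(wavelets,
                   function(w) (length(w) - 1L) %/% 2L + 1L, 0L)
  # one batched inverse FFT across all wavelets per signal
  conv_power <- function(x) {
    Xf <- stats::fft(c(x, rep(0, nfft - n_t)))
    Y <- stats::mvfft(Wf * Xf, inverse = TRUE) / nfft
    vapply(seq_along(wavelets), function(fi)
      Mod(Y[(starts[fi] + keep - 1L), fi])^2, numeric(length(keep)))
  }
  if (average) {
    power <- array(0, c(n_ch, length(freqs), length(keep)))
    for (k in seq_len(n_ep)) for (ci in seq_len(n_ch)) {
      p <- conv_power(dat[k, ci, ])       # keep x freqs
      power[ci, , ] <- power[ci, , ] + t(p)
    }
    power <- power / n_ep
  } else {
    power <- array(0, c(n_ep, n_ch, length(freqs), length(keep)))
    for (k in seq_len(n_ep)) for (ci in seq_len(n_ch))
      power[k, ci, , ] <- t(conv_power(dat[k, ci, ]))
  }
  structure(list(power = power, freqs = freqs, times = times[keep],
                 channel_names = ch_names, averaged = average,
                 baseline = NULL, log_ratio = FALSE),
            class = "tfr_array")
}

#' Log-ratio baseline correction of a TFR
#'
#' `value(f, t) = log10(power(f, t) / mean(power(f, baseline)))`; the
#' result is invariant to any global gain applied to the recording.
#'
#' @param tfr An averaged `tfr_array`.
#' @param window Baseline window \[s\] within the trimmed time axis.
#' @return The `tfr_array` with log-ratio values and `baseline`
#'   recorded.
#' @export
baseline_log_ratio <- function(tfr, window = c(-1.0, -0.5)) {
  stopifnot(inherits(tfr, "tfr_array"))
  if (tfr$log_ratio) stop("already baselined")
  if (!tfr$averaged) stop("baseline the epoch-averaged TFR")
  idx <- which(tfr$times >= window[1] & tfr$times <= window[2])
  if (!length(idx)) stop("baseline window outside trimmed time axis")
  bl <- apply(tfr$power[, , idx, drop = FALSE], c(1, 2), mean)
  if (any(bl <= 0)) stop("zero baseline power")
  tfr$power <- log10(tfr$power / outer(bl, rep(1, length(tfr$times))))
  tfr$baseline <- window
  tfr$log_ratio <- TRUE
  tfr
}

#' Band-averaged power time course
#'
#' Mean over the band's frequencies (endpoints inclusive; 15 Hz belongs
#' to both the mu and beta bands, as those ranges overlap) at each time
#' point.
#'
#' @param tfr An averaged `tfr_array`.
#' @param band Length-2 frequency band \[Hz\], e.g. `c(8, 15)` (mu) or
#'   `c(15, 30)` (beta).
#' @return Matrix channels x time of band power (or log-ratio) values.
#' @export
band_timecourse <- function(tfr, band) {
  stopifnot(inherits(tfr, "tfr_array"), tfr$averaged)
  fi <- which(tfr$freqs >= band[1] & tfr$freqs <= band[2])
  if (!length(fi)) stop("empty frequency band")
  out <- apply(tfr$power[, fi, , drop = FALSE], c(1, 3), mean)
  rownames(out) <- tfr$channel_names
  out
}
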