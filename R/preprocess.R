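# Filtering, bad-channel detection, reference regression, and order-1
# homogeneous field correction. All filters are applied forward-backward
# (zero phase): SEF peak latency is the headline measurement and must
# not be shifted by preprocessing.

# RBJ-cookbook second-order IIR notch, returned as an Arma filter
.notch_biquad <- function(freq, fs, Q = 30) {
  w0 <- 2 * pi * freq / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  signal::Arma(b = b / a[1], a = a / a[1])
}

.apply_rows <- function(data, fun) {
  out <- data
  for (i in seq_len(nrow(data))) out[i, ] <- fun(data[i, ])
  out
}

#' Zero-phase notch filtering of line noise
#'
#' Second-order IIR notches (Q = 30) at each frequency, applied
#' forward-backward with [signal::filtfilt()].
#'
#' @param session An `opm_session`.
#' @param freqs Notch frequencies \[Hz\]; default the 60 Hz line
#'   fundamental and its first two harmonics.
#' @return The session with filtered data.
#' @export
notch_filter <- function(session, freqs = c(60, 120, 180)) {
  fs <- session$sample_rate
  if (any(freqs >= fs / 2)) stop("notch frequency at or above Nyquist")
  for (f in freqs) {
    flt <- .notch_biquad(f, fs)
    session$data <- .apply_rows(session$data,
                                function(x) signal::filtfilt(flt, x))
  }
  session
}

#' Zero-phase band-pass filtering
#'
#' Fourth-order Butterworth high-pass and low-pass sections applied
#' forward-backward (cascaded sections are better conditioned than a
#' single narrow band-pass polynomial at a 1000 Hz rate).
#'
#' @param session An `opm_session`.
#' @param low,high Band edges \[Hz\].
#' @return The session with filtered data.
#' @export
bandpass_filter <- function(session, low = 3, high = 150) {
  fs <- session$sample_rate
  if (!(low > 0 && low < high && high < fs / 2))
    stop("require 0 < low < high < Nyquist")
  hp <- signal::butter(4, low / (fs / 2), type = "high")
  lp <- signal::butter(4, high / (fs / 2), type = "low")
  session$data <- .apply_rows(session$data, function(x)
    signal::filtfilt(lp, signal::filtfilt(hp, x)))
  session
}

#' Welch amplitude spectrum
#'
#' Hann-windowed segment-averaged amplitude spectral density.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate \[Hz\].
#' @param seg_len Segment length in seconds.
#' @param overlap Fractional segment overlap.
#' @return List with `freq` \[Hz\] and `amplitude` \[input units /
#'   sqrt(Hz)\].
#' @export
welch_amplitude <- function(x, fs, seg_len = 2, overlap = 0.5) {
  nper <- round(seg_len * fs)
  if (length(x) < nper) nper <- length(x)
  step <- max(1, round(nper * (1 - overlap)))
  starts <- seq(1, length(x) - nper + 1, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nper) / (nper + 1))
  u <- sum(win^2)
  nf <- floor(nper / 2) + 1
  psd <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nper - 1)] * win
    X <- stats::fft(seg)[seq_len(nf)]
    psd <- psd + Mod(X)^2
  }
  psd <- psd / (length(starts) * u * fs)
  psd[2:(nf - 1)] <- 2 * psd[2:(nf - 1)]  # one-sided
  list(freq = (seq_len(nf) - 1) * fs / nper, amplitude = sqrt(psd))
}

#' Detect bad channels by high-frequency spectral amplitude
#'
#' Each scalp channel's Welch amplitude spectrum (2 s Hann segments, 50%
#' overlap) is averaged over the 120-145 Hz band and z-scored across
#' channels; channels with z above the threshold are flagged. Reference
#' channels are never flagged.
#'
#' @param session An `opm_session`.
#' @param band Frequency band \[Hz\].
#' @param threshold Z-score criterion.
#' @return List of class `bad_channel_report`: `band_amplitude`,
#'   `z`, `flagged`, `threshold`.
#' @export
detect_bad_channels <- function(session, band = c(120, 145),
                                threshold = 2.0) {
  scalp <- which(!session$array$is_reference)
  if (length(scalp) < 3) stop("need at least 3 scalp channels")
  amp <- vapply(scalp, function(i) {
    w <- welch_amplitude(session$data[i, ], session$sample_rate)
    mean(w$amplitude[w$freq >= band[1] & w$freq <= band[2]])
  }, 0)
  names(amp) <- session$array$names[scalp]
  z <- as.numeric(scale(amp))
  names(z) <- names(amp)
  z[is.na(z)] <- 0
  structure(list(band_amplitude = amp, z = z,
                 flagged = names(amp)[z > threshold],
                 threshold = threshold, band = band),
            class = "bad_channel_report")
}

#' Drop channels from a session
#'
#' @param session An `opm_session`.
#' @param names Channel names to remove.
#' @return The session without those channels.
#' @export
drop_channels <- function(session, names) {
  if (!length(names)) return(session)
  keep <- !(session$array$names %in% names)
  session$data <- session$data[keep, , drop = FALSE]
  a <- session$array
  session$array <- sensor_array(a$names[keep],
                                a$positions[keep, , drop = FALSE],
                                a$orientations[keep, , drop = FALSE],
                                a$is_reference[keep])
  session
}

#' Reference-array regression
#'
#' Each scalp channel is replaced by its residual after ordinary
#' least-squares regression on the three reference time courses plus an
#' intercept, removing signal components correlated with the reference
#' array.
#'
#' @param session An `opm_session` with exactly 3 reference channels.
#' @return The session with reference-adjusted scalp channels.
#' @export
reference_regression <- function(session) {
  refs <- which(session$array$is_reference)
  if (length(refs) != 3) stop("exactly 3 reference channels required")
  R <- t(session$data[refs, , drop = FALSE])
  if (any(apply(R, 2, stats::sd) == 0))
    stop("reference channel has zero variance")
  X <- cbind(1, R)
  qrX <- qr(X)
  scalp <- which(!session$array$is_reference)
  Y <- t(session$data[scalp, , drop = FALSE])
  session$data[scalp, ] <- t(qr.resid(qrX, Y))
  session
}

#' Order-1 homogeneous field correction
#'
#' Projects out of the scalp channels the subspace a spatially uniform
#' ambient field can express given the sensor orientations: with model
#' matrix N (scalp orientations, n x 3), the corrected data are
#' `P x = (I - N N^+) x`. The per-source lead-field attenuation fraction
#' `1 - ||P l|| / ||l||` quantifies the brain signal lost, which grows
#' as coverage shrinks.
#'
#' @param session An `opm_session`.
#' @param lead Optional `lead_field` for attenuation accounting.
#' @param rank_tol Relative singular-value threshold for the
#'   pseudo-inverse.
#' @return List of class `hfc_result`: corrected `session`, `projector`,
#'   `basis`, `rank`, and `attenuation` (NULL without `lead`).
#' @export
hfc <- function(session, lead = NULL, rank_tol = 1e-8) {
  scalp <- which(!session$array$is_reference)
  N <- session$array$orientations[scalp, , drop = FALSE]
  sv <- svd(N)
  rank <- sum(sv$d > rank_tol * sv$d[1])
  if (rank < 3)
    warning(sprintf(
      "homogeneous-field model rank %d < 3; reduced-rank projector",
      rank))
  U <- sv$u[, seq_len(rank), drop = FALSE]
  P <- diag(length(scalp)) - U %*% t(U)
  session$data[scalp, ] <- P %*% session$data[scalp, , drop = FALSE]
  attenuation <- NULL
  if (!is.null(lead)) {
    cn <- sqrt(colSums(lead$matrix^2))
    pn <- sqrt(colSums((P %*% lead$matrix)^2))
    attenuation <- 1 - pn / cn
  }
  structure(list(session = session, projector = P, basis = N,
                 rank = rank, attenuation = attenuation),
            class = "hfc_result")
}

#' Full preprocessing chain
#'
#' Notch filtering, band-pass filtering, bad-channel removal, reference
#' regression, and (optionally) homogeneous field correction, in that
#' order.
#'
#' @param session An `opm_session`.
#' @param notch_freqs Notch frequencies \[Hz\].
#' @param band Band-pass edges \[Hz\].
#' @param bad_threshold Bad-channel z criterion.
#' @param use_hfc Logical; disable to run the HFC-omission comparison
#'   arm.
#' @param lead Optional `lead_field` for HFC attenuation accounting (its
#'   rows are subset to the surviving channels).
#' @param drop_bad Optional fixed character vector of channels to drop
#'   (to keep both comparison arms on identical channels); if NULL the
#'   detector's flags are used.
#' @return List of class `preprocess_result`: `session`, `bad_report`,
#'   `hfc` (or NULL), `lead` (row-subset), `stages`.
#' @export
preprocess_all <- function(session, notch_freqs = c(60, 120, 180),
                           band = c(3, 150), bad_threshold = 2.0,
                           use_hfc = TRUE, lead = NULL,
                           drop_bad = NULL) {
  session <- notch_filter(session, notch_freqs)
  session <- bandpass_filter(session, band[1], band[2])
  report <- detect_bad_channels(session, threshold = bad_threshold)
  to_drop <- if (is.null(drop_bad)) report$flagged else drop_bad
  session <- drop_channels(session, to_drop)
  if (!is.null(lead)) {
    keep <- lead$channel_names %in%
      session$array$names[!session$array$is_reference]
    lead$matrix <- lead$matrix[keep, , drop = FALSE]
    lead$channel_names <- lead$channel_names[keep]
  }
  session <- reference_regression(session)
  hfc_res <- NULL
  if (use_hfc) {
    hfc_res <- hfc(session, lead)
    session <- hfc_res$session
    hfc_res$session <- NULL
  }
  structure(list(session = session, bad_report = report, hfc = hfc_res,
                 lead = lead,
                 stages = c("notch", "bandpass", "bad_channels",
                            "reference_regression",
                            if (use_hfc) "hfc")),
            class = "preprocess_result")
}

#' Write preprocessing reports
#'
#' Bad-channel metrics and HFC attenuation as CSV, plus a JSON
#' provenance sidecar (stages, parameters, flagged channels).
#'
#' @param result A `preprocess_result`.
#' @param dir Output directory.
#' @export
write_preprocess_reports <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rep <- result$bad_report
  utils::write.csv(
    data.frame(channel = names(rep$band_amplitude),
               band_amplitude = rep$band_amplitude, z = rep$z,
               flagged = names(rep$band_amplitude) %in% rep$flagged,
               row.names = NULL),
    file.path(dir, "bad_channels.csv"), row.names = FALSE)
  if (!is.null(result$hfc) && !is.null(result$hfc$attenuation))
    utils::write.csv(
      data.frame(source = seq_along(result$hfc$attenuation),
                 attenuation = result$hfc$attenuation),
      file.path(dir, "hfc_attenuation.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(stages = result$stages, threshold = rep$threshold,
         band = rep$band, flagged = rep$flagged),
    file.path(dir, "preprocess_provenance.json"), auto_unbox = TRUE)
  invisible(dir)
}
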