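# Event-locked segmentation, baseline correction, peak-to-peak epoch
# rejection, evoked averaging, and evoked subtraction.

#' Segment a session into event-locked epochs
#'
#' One epoch per event; sample 0 of the epoch clock is aligned to the
#' event sample, windows are closed at both ends at sample resolution.
#' Epochs whose window exceeds the recording bounds are dropped with a
#' warning.
#'
#' @param session An `opm_session`.
#' @param tmin,tmax Epoch window relative to the event \[s\] (short-MNS
#'   default -0.2 to +0.5 s).
#' @return An object of class `epoch_set`: `data`
#'   (epochs x channels x samples), `times`, `tmin`, `tmax`,
#'   `sample_rate`, `channel_names`, `array`, `kept`, `rejected`,
#'   `baseline`.
#' @export
make_epochs <- function(session, tmin = -0.2, tmax = 0.5) {
  fs <- session$sample_rate
  n_pre <- round(-tmin * fs)
  n_post <- round(tmax * fs)
  n_samp <- n_pre + n_post + 1L
  n_total <- ncol(session$data)
  ok <- (session$events - n_pre >= 1) &
    (session$events + n_post <= n_total)
  if (any(!ok))
    warning(sprintf("%d epoch(s) outside recording bounds dropped",
                    sum(!ok)))
  events <- session$events[ok]
  n_ch <- nrow(session$data)
  data <- array(NA_real_, c(length(events), n_ch, n_samp))
  for (k in seq_along(events)) {
    idx <- (events[k] - n_pre):(events[k] + n_post)
    data[k, , ] <- session$data[, idx]
  }
  structure(list(data = data,
                 times = (seq_len(n_samp) - 1L - n_pre) / fs,
                 tmin = tmin, tmax = tmax, sample_rate = fs,
                 channel_names = rownames(session$data),
                 array = session$array,
                 kept = seq_along(events), rejected = integer(0),
                 baseline = NULL),
            class = "epoch_set")
}

#' Baseline-correct epochs
#'
#' Subtracts, per epoch and channel, the mean over the baseline window
#' from the entire epoch.
#'
#' @param epochs An `epoch_set`.
#' @param window Length-2 numeric baseline window \[s\], closed at both
#'   ends.
#' @return The corrected `epoch_set` (baseline window recorded).
#' @export
baseline_correct <- function(epochs, window = c(-0.2, -0.1)) {
  idx <- which(epochs$times >= window[1] & epochs$times <= window[2])
  if (!length(idx)) stop("empty baseline window")
  bl <- apply(epochs$data[, , idx, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - outer(bl, rep(1, dim(epochs$data)[3]))
  epochs$baseline <- window
  epochs
}

#' Reject epochs by peak-to-peak amplitude
#'
#' Epochs whose peak-to-peak amplitude on any scalp channel exceeds the
#' threshold are dropped. An optional exclusion window (e.g. around the
#' stimulus artifact, which is present in every epoch) is ignored by the
#' metric.
#'
#' @param epochs An `epoch_set`.
#' @param ptp_threshold Peak-to-peak ceiling \[T\] (default 5 pT).
#' @param exclude Optional length-2 window \[s\] excluded from the
#'   peak-to-peak computation.
#' @param adaptive_factor If non-NULL, the ceiling is instead this
#'   multiple of the session's median per-epoch peak-to-peak amplitude
#'   (robust to between-subject amplitude differences, as a visual
#'   inspector implicitly is).
#' @return The `epoch_set` with `kept`/`rejected` indices (relative to
#'   the input epochs) and `rejection_fraction` recorded.
#' @export
reject_epochs <- function(epochs, ptp_threshold = 5e-12,
                          exclude = NULL, adaptive_factor = NULL) {
  if (is.null(adaptive_factor) && ptp_threshold <= 0)
    stop("threshold must be positive")
  use_t <- rep(TRUE, length(epochs$times))
  if (!is.null(exclude))
    use_t[epochs$times >= exclude[1] & epochs$times <= exclude[2]] <- FALSE
  scalp <- if (!is.null(epochs$array))
    which(!epochs$array$is_reference) else seq_len(dim(epochs$data)[2])
  n_ep <- dim(epochs$data)[1]
  ptp <- vapply(seq_len(n_ep), function(k) {
    m <- matrix(epochs$data[k, scalp, use_t], nrow = length(scalp))
    max(apply(m, 1, function(ch) diff(range(ch))))
  }, 0)
  if (!is.null(adaptive_factor))
    ptp_threshold <- adaptive_factor * stats::median(ptp)
  bad <- which(ptp > ptp_threshold)
  if (length(bad) == n_ep) stop("all epochs rejected")
  if (length(bad)) {
    epochs$data <- epochs$data[-bad, , , drop = FALSE]
    epochs$rejected <- bad
    epochs$kept <- setdiff(seq_len(n_ep), bad)
  }
  epochs$rejection_fraction <- length(bad) / n_ep
  epochs
}

#' Average epochs into an evoked response
#'
#' @param epochs An `epoch_set` with at least one kept epoch.
#' @return Object of class `evoked`: `data` (channels x samples),
#'   `times`, `n_epochs`, `channel_names`, `array`, `sample_rate`.
#' @export
average_evoked <- function(epochs) {
  if (dim(epochs$data)[1] < 1) stop("no epochs to average")
  structure(list(data = apply(epochs$data, c(2, 3), mean),
                 times = epochs$times,
                 n_epochs = dim(epochs$data)[1],
                 channel_names = epochs$channel_names,
                 array = epochs$array,
                 sample_rate = epochs$sample_rate),
            class = "evoked")
}

#' Subtract the evoked response from every epoch
#'
#' Removes the phase-locked (evoked) component so time-frequency
#' analysis reflects induced oscillatory power.
#'
#' @param epochs An `epoch_set` with at least two kept epochs.
#' @return The `epoch_set` of residual (induced) epochs.
#' @export
subtract_evoked <- function(epochs) {
  if (dim(epochs$data)[1] < 2) stop("need at least 2 epochs")
  ev <- average_evoked(epochs)$data
  for (k in seq_len(dim(epochs$data)[1]))
    epochs$data[k, , ] <- epochs$data[k, , ] - ev
  epochs
}
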