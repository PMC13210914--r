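# Regularized minimum-norm source estimation on the six-ROI patch, with
# first-principal-component ROI time-course extraction.

#' Estimate the noise covariance from baseline samples
#'
#' Empirical covariance of baseline-window samples pooled across epochs,
#' with diagonal loading for conditioning.
#'
#' @param epochs An `epoch_set`.
#' @param window Baseline window \[s\].
#' @param loading Diagonal loading as a fraction of the mean diagonal
#'   (default 0.1).
#' @return Object of class `noise_covariance`: `matrix` (scalp channels
#'   only), `channel_names`, `window`, `loading`.
#' @export
estimate_noise_covariance <- function(epochs, window = c(-0.2, -0.1),
                                      loading = 0.1) {
  idx <- which(epochs$times >= window[1] & epochs$times <= window[2])
  if (!length(idx)) stop("baseline window outside epochs")
  scalp <- which(!epochs$array$is_reference)
  n_ep <- dim(epochs$data)[1]
  X <- do.call(cbind, lapply(seq_len(n_ep), function(k)
    matrix(epochs$data[k, scalp, idx], nrow = length(scalp))))
  if (ncol(X) < length(scalp) && loading <= 0)
    stop("fewer baseline samples than channels and no loading")
  X <- X - rowMeans(X)
  C <- X %*% t(X) / (ncol(X) - 1)
  C <- C + diag(loading * mean(diag(C)), nrow(C))
  structure(list(matrix = C,
                 channel_names = epochs$channel_names[scalp],
                 window = window, loading = loading),
            class = "noise_covariance")
}

#' Restrict a source grid to named ROIs
#'
#' @param grid A [source_grid()].
#' @param roi A character vector of ROI names to keep.
#' @return The restricted `source_grid` (labels preserved).
#' @export
restrict_grid <- function(grid, roi) {
  keep <- grid$roi_labels %in% roi
  if (!any(keep)) stop("no vertices left after restriction")
  source_grid(grid$vertices[keep, , drop = FALSE],
              grid$orientations[keep, , drop = FALSE],
              grid$roi_labels[keep], grid$head)
}

#' Minimum-norm source estimate
#'
#' Linear inverse `K = L' (L L' + lambda2 C)^-1` with identity source
#' covariance (no depth weighting), `lambda2 = 1 / snr^2`, and the noise
#' covariance rescaled to the lead-field Gram scale so the
#' regularization parameter is dimensionless. Applied identically to an
#' evoked response or to every epoch.
#'
#' @param data An `evoked`, `epoch_set`, or channels x samples matrix
#'   (scalp channels only for matrices).
#' @param lead A `lead_field` whose channels match the data's scalp
#'   channels.
#' @param cov A `noise_covariance` (NULL for an identity covariance).
#' @param snr_param Assumed amplitude SNR; `lambda2 = 1/snr_param^2`
#'   (default 3).
#' @return Object of class `source_estimate`: `activity`
#'   (vertices x samples \[A·m\], or a list of such per epoch), `times`,
#'   `grid`, `kernel`.
#' @export
minimum_norm <- function(data, lead, cov = NULL, snr_param = 3) {
  L <- lead$matrix
  if (inherits(data, "evoked")) {
    scalp <- which(!data$array$is_reference)
    X <- data$data[scalp, , drop = FALSE]
    ch <- data$channel_names[scalp]
    times <- data$times
  } else if (inherits(data, "epoch_set")) {
    scalp <- which(!data$array$is_reference)
    ch <- data$channel_names[scalp]
    times <- data$times
    X <- NULL
  } else {
    X <- as.matrix(data)
    ch <- rownames(X)
    times <- NULL
  }
  if (!is.null(ch) && !identical(ch, lead$channel_names)) {
    if (!all(lead$channel_names %in% ch))
      stop("lead field channels do not match data channels")
    ord <- match(lead$channel_names, ch)
  } else ord <- seq_len(nrow(L))
  n <- nrow(L)
  G <- L %*% t(L)
  Cm <- if (is.null(cov)) diag(n) else cov$matrix
  if (!is.null(cov) && !is.null(cov$channel_names) &&
      !identical(cov$channel_names, lead$channel_names))
    Cm <- Cm[match(lead$channel_names, cov$channel_names),
             match(lead$channel_names, cov$channel_names)]
  # rescale covariance to unit (lead-field Gram) scale
  Cs <- Cm * (sum(diag(G)) / sum(diag(Cm)))
  lambda2 <- 1 / snr_param^2
  K <- t(L) %*% solve(G + lambda2 * Cs)
  if (inherits(data, "epoch_set")) {
    n_ep <- dim(data$data)[1]
    activity <- lapply(seq_len(n_ep), function(k) {
      M <- matrix(data$data[k, scalp, ], nrow = length(scalp))
      K %*% M[ord, , drop = FALSE]
    })
  } else {
    if (nrow(X) != n) stop("dimension mismatch between data and lead")
    activity <- K %*% X[ord, , drop = FALSE]
  }
  structure(list(activity = activity, times = times, grid = lead$grid,
                 kernel = K, snr_param = snr_param),
            class = "source_estimate")
}

#' Representative ROI time course as the first principal component
#'
#' SVD of the time-centered block of ROI vertex time courses (time
#' points as observations); the component is sign-aligned to correlate
#' non-negatively with the ROI mean time course, and the first
#' component's explained variance fraction is recorded.
#'
#' @param stc A `source_estimate` with matrix activity, or a
#'   vertices x samples matrix.
#' @param roi ROI name (used with a `source_estimate`).
#' @param grid Optional `source_grid` for matrix input.
#' @return Numeric time course (attribute `explained_variance`).
#' @export
roi_timecourse <- function(stc, roi = NULL, grid = NULL) {
  if (inherits(stc, "source_estimate")) {
    A <- stc$activity
    grid <- stc$grid
  } else A <- stc
  if (is.list(A)) stop("per-epoch estimates: extract per epoch")
  if (!is.null(roi)) {
    idx <- which(grid$roi_labels == roi)
    if (!length(idx)) stop("empty ROI: ", roi)
    A <- A[idx, , drop = FALSE]
  }
  X <- t(A)                      # time x vertices
  Xc <- sweep(X, 2, colMeans(X))
  if (all(abs(Xc) < .Machine$double.eps * 10))
    stop("constant activity: principal component undefined")
  # PCs from the small vertices x vertices cross-product (time points
  # far outnumber vertices)
  ev <- eigen(crossprod(Xc), symmetric = TRUE)
  pc <- Xc %*% ev$vectors[, 1]
  m <- rowMeans(X)
  if (sum(pc * (m - mean(m))) < 0) pc <- -pc
  out <- as.numeric(pc)
  lam <- pmax(ev$values, 0)
  attr(out, "explained_variance") <- lam[1] / sum(lam)
  out
}
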