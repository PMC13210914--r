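#' Stimulation protocol description
#'
#' @param name `"short_mns"` or `"long_mns"`.
#' @param n_events Number of stimulation events.
#' @param isi_range Length-2 numeric, uniform inter-stimulus-interval
#'   bounds in seconds.
#' @param sample_rate Sampling rate in Hz.
#' @param lead_in Seconds of recording before the first event.
#' @param tail Seconds of recording after the last event (must cover the
#'   longest epoch window).
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(name = c("short_mns", "long_mns"),
                          n_events = NULL, isi_range = NULL,
                          sample_rate = 1000, lead_in = 2,
                          tail = NULL) {
  name <- match.arg(name)
  if (is.null(n_events))
    n_events <- if (name == "short_mns") 300L else 80L
  if (is.null(isi_range))
    isi_range <- if (name == "short_mns") c(1.0, 1.4) else c(5.6, 7.6)
  if (is.null(tail))
    tail <- if (name == "short_mns") 1.0 else 5.5
  stopifnot(isi_range[1] < isi_range[2], n_events >= 1, sample_rate > 0)
  structure(list(name = name, n_events = as.integer(n_events),
                 isi_range = isi_range, sample_rate = sample_rate,
                 lead_in = lead_in, tail = tail),
            class = "protocol_spec")
}

#' Planted source scenario
#'
#' Describes the sensorimotor sources the generator plants: an SEF dipole
#' with three Gaussian lobes (negative lobe at 20 ms, positive lobes at
#' 35 and 60 ms), a mu-rhythm source with post-stimulus ERD, a
#' beta-rhythm source with ERD, and a more anterior beta source carrying
#' the post-stimulus rebound (ERS). Sources are addressed by ROI name and
#' resolved to the grid vertex nearest the 45-degree lateral meridian.
#'
#' @param sef_roi,mu_roi,beta_erd_roi,beta_ers_roi ROI names.
#' @param sef_peaks List of `c(latency, width, amplitude)` triplets
#'   (seconds, seconds, A·m).
#' @param mu_freq,beta_freq Carrier center frequencies \[Hz\].
#' @param mu_amp,beta_erd_amp,beta_ers_amp Baseline RMS source moments
#'   \[A·m\].
#' @param erd_window,ers_window Post-stimulus windows \[s\].
#' @param mu_erd_depth,beta_erd_depth Fractional power-envelope
#'   suppression in `[0, 1)`.
#' @param ers_gain Fractional envelope gain during the rebound.
#' @param latency_jitter_sd Between-subject SEF latency jitter SD \[s\].
#' @param amplitude_jitter_sd Between-subject fractional amplitude jitter
#'   SD.
#' @return An object of class `source_scenario`.
#' @export
source_scenario <- function(sef_roi = "postcentral gyrus",
                            sef_peaks = list(c(0.020, 0.005, -20e-9),
                                             c(0.035, 0.008, 10e-9),
                                             c(0.060, 0.012, 20e-9)),
                            mu_roi = "central sulcus", mu_freq = 10,
                            mu_amp = 35e-9, mu_erd_depth = 0.5,
                            beta_erd_roi = "central sulcus",
                            beta_freq = 21, beta_erd_amp = 20e-9,
                            beta_erd_depth = 0.3,
                            beta_ers_roi = "precentral gyrus",
                            beta_ers_amp = 20e-9, ers_gain = 0.3,
                            erd_window = c(0.2, 0.4),
                            ers_window = c(0.5, 1.0),
                            latency_jitter_sd = 0.001,
                            amplitude_jitter_sd = 0.2) {
  stopifnot(mu_erd_depth >= 0, mu_erd_depth < 1,
            beta_erd_depth >= 0, beta_erd_depth < 1, ers_gain >= 0)
  for (p in sef_peaks) if (p[2] <= 0) stop("peak width must be positive")
  structure(list(sef_roi = sef_roi, sef_peaks = sef_peaks,
                 mu_roi = mu_roi, mu_freq = mu_freq, mu_amp = mu_amp,
                 mu_erd_depth = mu_erd_depth,
                 beta_erd_roi = beta_erd_roi, beta_freq = beta_freq,
                 beta_erd_amp = beta_erd_amp,
                 beta_erd_depth = beta_erd_depth,
                 beta_ers_roi = beta_ers_roi,
                 beta_ers_amp = beta_ers_amp, ers_gain = ers_gain,
                 erd_window = erd_window, ers_window = ers_window,
                 latency_jitter_sd = latency_jitter_sd,
                 amplitude_jitter_sd = amplitude_jitter_sd),
            class = "source_scenario")
}

#' Noise and interference description
#'
#' @param sensor_noise_density White sensor noise density \[T/sqrt(Hz)\].
#' @param interference_rms Per-channel RMS of the homogeneous ambient
#'   interference \[T\].
#' @param interference_bw Interference bandwidth \[Hz\].
#' @param gradient_fraction Fraction of interference RMS carried by a
#'   first-order spatial-gradient term (not removable by order-1 HFC).
#' @param line_freqs Power-line frequencies \[Hz\].
#' @param line_amps Corresponding amplitudes \[T\].
#' @param artifact_amplitude Stimulus-artifact noise SD as a multiple of
#'   the per-sample sensor-noise SD.
#' @param artifact_duration Artifact duration \[s\], centered on each
#'   event.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(sensor_noise_density = 18e-15,
                       interference_rms = 3e-12, interference_bw = 4,
                       gradient_fraction = 0.05,
                       line_freqs = c(60, 120, 180),
                       line_amps = c(1e-12, 5e-13, 3e-13),
                       artifact_amplitude = 10,
                       artifact_duration = 0.010) {
  vals <- c(sensor_noise_density, interference_rms, interference_bw,
            gradient_fraction, line_amps, artifact_amplitude,
            artifact_duration)
  if (any(vals < 0)) stop("noise parameters must be non-negative")
  structure(list(sensor_noise_density = sensor_noise_density,
                 interference_rms = interference_rms,
                 interference_bw = interference_bw,
                 gradient_fraction = gradient_fraction,
                 line_freqs = line_freqs, line_amps = line_amps,
                 artifact_amplitude = artifact_amplitude,
                 artifact_duration = artifact_duration),
            class = "noise_spec")
}

#' Resolve a scenario ROI to its central grid vertex
#'
#' Picks the vertex of the ROI nearest the 45-degree lateral meridian
#' (under the C3/FC3/CP3 sensor column).
#'
#' @param grid A [source_grid()].
#' @param roi ROI name.
#' @return Integer vertex index.
#' @export
central_vertex <- function(grid, roi) {
  idx <- which(grid$roi_labels == roi)
  if (!length(idx)) stop("no vertices in ROI: ", roi)
  r <- grid$head$source_radius
  target <- r * sin(45 * pi / 180)
  lat <- -(grid$vertices[idx, 1] - grid$head$center[1])
  idx[which.min(abs(lat - target))]
}

#' SEF dipole-moment time course
#'
#' Sum of Gaussian-windowed lobes, one per peak triplet
#' `c(latency, width, amplitude)`; each lobe is truncated to
#' latency ± 4 widths so the course is exactly zero outside the peak
#' supports.
#'
#' @param times Time axis \[s\] (0 = stimulus onset).
#' @param peaks List of peak triplets.
#' @return Numeric vector of dipole moments \[A·m\].
#' @export
sef_moment_timecourse <- function(times, peaks) {
  out <- numeric(length(times))
  for (p in peaks) {
    if (p[2] <= 0) stop("peak width must be positive")
    d <- times - p[1]
    inside <- abs(d) <= 4 * p[2]
    out[inside] <- out[inside] + p[3] * exp(-d[inside]^2 / (2 * p[2]^2))
  }
  out
}

# smooth a step envelope with a 0.1 s Hann kernel (unit sum)
.smooth_envelope <- function(env, fs, dur = 0.1) {
  n <- max(3L, round(dur * fs))
  if (n %% 2 == 0) n <- n + 1L
  h <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
  h <- h / sum(h)
  as.numeric(stats::filter(c(rep(env[1], n), env, rep(env[length(env)], n)),
                           h, sides = 2))[(n + 1):(n + length(env))]
}

#' Narrowband oscillatory source moment with event-locked modulation
#'
#' A random-phase narrowband carrier (2 Hz bandwidth around the center
#' frequency, unit RMS) is scaled by an envelope equal to the baseline
#' amplitude, multiplied by `(1 - erd_depth)` inside each event's ERD
#' window and `(1 + ers_gain)` inside each ERS window, with transitions
#' smoothed over 0.1 s.
#'
#' @param times Time axis \[s\] for the whole session.
#' @param events Event onset times \[s\].
#' @param band_params List with `freq`, `amp`, and optionally
#'   `erd_window`, `erd_depth`, `ers_window`, `ers_gain`.
#' @param fs Sampling rate \[Hz\].
#' @return Numeric vector of dipole moments \[A·m\], plus attribute
#'   `envelope`.
#' @export
oscillatory_moment <- function(times, events, band_params, fs = 1000) {
  p <- band_params
  erd_w <- p$erd_window; ers_w <- p$ers_window
  erd_d <- if (is.null(p$erd_depth)) 0 else p$erd_depth
  ers_g <- if (is.null(p$ers_gain)) 0 else p$ers_gain
  # overlap check between consecutive events' modulation windows
  if (length(events) > 1 && (erd_d > 0 || ers_g > 0)) {
    w_start <- min(c(if (erd_d > 0) erd_w[1], if (ers_g > 0) ers_w[1]))
    w_end <- max(c(if (erd_d > 0) erd_w[2], if (ers_g > 0) ers_w[2]))
    if (any(diff(events) + w_start < w_end + 0.1))
      stop("event modulation windows overlap: ISI too short")
  }
  n <- length(times)
  # narrowband carrier: band-pass filtered white noise, unit RMS
  bp <- signal::butter(2, c(max(p$freq - 1, 0.5), p$freq + 1) / (fs / 2),
                       type = "pass")
  carrier <- signal::filtfilt(bp, stats::rnorm(n))
  carrier <- carrier / stats::sd(carrier)
  env <- rep(1, n)
  for (e in events) {
    if (erd_d > 0) {
      idx <- which(times >= e + erd_w[1] & times <= e + erd_w[2])
      env[idx] <- 1 - erd_d
    }
    if (ers_g > 0) {
      idx <- which(times >= e + ers_w[1] & times <= e + ers_w[2])
      env[idx] <- 1 + ers_g
    }
  }
  env <- .smooth_envelope(env, fs)
  out <- p$amp * env * carrier
  attr(out, "envelope") <- p$amp * env
  out
}

#' Homogeneous ambient interference with optional gradient term
#'
#' A low-pass-filtered Gaussian random-walk 3-vector field `b(t)` with
#' the stated per-channel RMS and bandwidth. The returned projection
#' rule maps the field onto a sensor array: channel i receives
#' `orientation_i . b(t)` plus, when `gradient_fraction > 0`, a fixed
#' first-order spatial-gradient term (so order-1 HFC removal is
#' imperfect, as in real recordings).
#'
#' @param n_samples Number of samples.
#' @param spec A [noise_spec()].
#' @param seed Integer RNG seed.
#' @param fs Sampling rate \[Hz\].
#' @return List with `b` (3 x n_samples field \[T\]) and `project(array)`
#'   returning an n_channels x n_samples interference matrix.
#' @export
interference_timecourse <- function(n_samples, spec, seed, fs = 1000) {
  set.seed(seed %% .Machine$integer.max)
  lp <- signal::butter(2, min(spec$interference_bw / (fs / 2), 0.99),
                       type = "low")
  b <- matrix(0, 3, n_samples)
  for (k in 1:3) {
    w <- cumsum(stats::rnorm(n_samples))
    w <- signal::filtfilt(lp, w)
    w <- w - mean(w)
    b[k, ] <- w / stats::sd(w) * spec$interference_rms
  }
  g_t <- signal::filtfilt(lp, cumsum(stats::rnorm(n_samples)))
  g_t <- g_t - mean(g_t)
  g_t <- g_t / stats::sd(g_t)
  # fixed symmetric traceless gradient tensor
  G <- matrix(c(1, 0.5, 0.2,
                0.5, -0.4, 0.3,
                0.2, 0.3, -0.6), 3, 3)
  project <- function(array) {
    n_ch <- length(array$names)
    out <- array$orientations %*% b
    if (spec$gradient_fraction > 0) {
      coef <- rowSums((array$orientations %*% G) * array$positions)
      scale <- mean(abs(coef[!array$is_reference]))
      out <- out + (coef / scale) %o% g_t *
        spec$gradient_fraction * spec$interference_rms
    }
    rownames(out) <- array$names
    out
  }
  list(b = b, project = project)
}

.subject_seed <- function(seed, subject_id) {
  h <- sum(utf8ToInt(as.character(subject_id)) *
             seq_along(utf8ToInt(as.character(subject_id))))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

#' Generate one synthetic OPM session
#'
#' Draws event times with uniform ISI, plants the scenario's SEF and
#' oscillatory sources through the Sarvas lead field, and adds
#' homogeneous interference, power-line sinusoids, white sensor noise,
#' and a broadband stimulus artifact around each event. Fully
#' reproducible from `(seed, subject_id)`.
#'
#' @param protocol A [protocol_spec()].
#' @param scenario A [source_scenario()].
#' @param noise A [noise_spec()].
#' @param array A [sensor_array()].
#' @param head A [sphere_head()].
#' @param subject_id Subject identifier string.
#' @param seed Integer base seed.
#' @param grid Source grid for resolving scenario ROIs; defaults to
#'   [build_default_grid()].
#' @return An object of class `opm_session`: list with `data`
#'   (channels x samples \[T\]), `sample_rate`, `events` (sample
#'   indices), `array`, `head`, `subject_id`, `seed`, and `truth`
#'   (planted vertices and moment time courses).
#' @export
generate_session <- function(protocol, scenario, noise, array, head,
                             subject_id = "S01", seed = 1,
                             grid = build_default_grid(head)) {
  stopifnot(inherits(protocol, "protocol_spec"),
            inherits(scenario, "source_scenario"),
            inherits(noise, "noise_spec"))
  fs <- protocol$sample_rate
  set.seed(.subject_seed(seed, subject_id))
  isi <- stats::runif(protocol$n_events - 1, protocol$isi_range[1],
                      protocol$isi_range[2])
  event_times <- protocol$lead_in + c(0, cumsum(isi))
  n_samples <- ceiling((max(event_times) + protocol$tail) * fs)
  times <- (seq_len(n_samples) - 1) / fs
  event_samples <- round(event_times * fs) + 1L
  if (max(event_samples) > n_samples) stop("session length insufficient")

  # subject-level jitter
  lat_jit <- stats::rnorm(1, 0, scenario$latency_jitter_sd)
  amp_jit <- 1 + stats::rnorm(1, 0, scenario$amplitude_jitter_sd)
  amp_jit <- max(amp_jit, 0.2)

  verts <- c(sef = central_vertex(grid, scenario$sef_roi),
             mu = central_vertex(grid, scenario$mu_roi),
             beta_erd = central_vertex(grid, scenario$beta_erd_roi),
             beta_ers = central_vertex(grid, scenario$beta_ers_roi))

  # moment time courses (4 x n)
  peaks <- lapply(scenario$sef_peaks,
                  function(p) c(p[1] + lat_jit, p[2], p[3] * amp_jit))
  sef <- numeric(n_samples)
  if (length(peaks)) {
    supp <- range(vapply(peaks, function(p) c(p[1] - 4 * p[2],
                                              p[1] + 4 * p[2]),
                         c(0, 0)))
    for (e in (event_samples - 1L) / fs) {
      idx <- which(times >= e + supp[1] & times <= e + supp[2])
      sef[idx] <- sef[idx] +
        sef_moment_timecourse(times[idx] - e, peaks)
    }
  }
  ev_t <- (event_samples - 1L) / fs
  mu <- oscillatory_moment(times, ev_t,
                           list(freq = scenario$mu_freq,
                                amp = scenario$mu_amp * amp_jit,
                                erd_window = scenario$erd_window,
                                erd_depth = scenario$mu_erd_depth), fs)
  beta_erd <- oscillatory_moment(times, ev_t,
                                 list(freq = scenario$beta_freq,
                                      amp = scenario$beta_erd_amp * amp_jit,
                                      erd_window = scenario$erd_window,
                                      erd_depth = scenario$beta_erd_depth),
                                 fs)
  beta_ers <- oscillatory_moment(times, ev_t,
                                 list(freq = scenario$beta_freq,
                                      amp = scenario$beta_ers_amp * amp_jit,
                                      ers_window = scenario$ers_window,
                                      ers_gain = scenario$ers_gain), fs)
  moments <- rbind(sef = sef, mu = mu, beta_erd = as.numeric(beta_erd),
                   beta_ers = as.numeric(beta_ers))

  # lead columns for the four planted sources, all channels (references
  # see the tiny far field too)
  n_ch <- length(array$names)
  Lp <- matrix(0, n_ch, 4)
  for (j in 1:4) {
    v <- verts[j]
    for (i in seq_len(n_ch)) {
      B <- sarvas_field(grid$vertices[v, ], grid$orientations[v, ],
                        array$positions[i, ], head)
      Lp[i, j] <- sum(array$orientations[i, ] * B)
    }
  }
  data <- Lp %*% moments

  # interference + gradient
  if (noise$interference_rms > 0) {
    interf <- interference_timecourse(n_samples, noise,
                                      .subject_seed(seed, subject_id) + 1L,
                                      fs)
    data <- data + interf$project(array)
  }
  # line noise: homogeneous fields along fixed directions
  if (length(noise$line_freqs) && any(noise$line_amps > 0)) {
    dirs <- rbind(c(0.6, 0.6, 0.53), c(-0.3, 0.9, 0.32),
                  c(0.7, -0.5, 0.51))
    dirs <- dirs / sqrt(rowSums(dirs^2))
    for (k in seq_along(noise$line_freqs)) {
      ph <- stats::runif(1, 0, 2 * pi)
      s <- noise$line_amps[k] *
        sin(2 * pi * noise$line_freqs[k] * times + ph)
      d <- dirs[1 + (k - 1) %% 3, ]
      data <- data + (array$orientations %*% d) %*% t(s)
    }
  }
  # white sensor noise
  if (noise$sensor_noise_density > 0) {
    sd_samp <- noise$sensor_noise_density * sqrt(fs / 2)
    data <- data + matrix(stats::rnorm(n_ch * n_samples, 0, sd_samp),
                          n_ch, n_samples)
    # broadband stimulus artifact around each event
    if (noise$artifact_amplitude > 0 && noise$artifact_duration > 0) {
      half <- round(noise$artifact_duration / 2 * fs)
      for (e in event_samples) {
        idx <- max(1, e - half):min(n_samples, e + half)
        data[, idx] <- data[, idx] +
          matrix(stats::rnorm(n_ch * length(idx), 0,
                              noise$artifact_amplitude * sd_samp),
                 n_ch, length(idx))
      }
    }
  }
  rownames(data) <- array$names
  structure(list(data = data, sample_rate = fs, events = event_samples,
                 array = array, head = head, subject_id = subject_id,
                 seed = seed,
                 truth = list(vertices = verts, moments = moments,
                              lead = Lp, grid = grid)),
            class = "opm_session")
}

#' @export
print.opm_session <- function(x, ...) {
  cat(sprintf(
    "<opm_session> %s: %d ch x %d samples @ %g Hz, %d events\n",
    x$subject_id, nrow(x$data), ncol(x$data), x$sample_rate,
    length(x$events)))
  invisible(x)
}

#' Generate a multi-subject cohort
#'
#' One short-MNS and one long-MNS session per subject, with distinct
#' subject-derived seeds.
#'
#' @param n_subjects Number of subjects (at least 2; paired statistics
#'   are undefined otherwise).
#' @param scenario,noise,array,head,grid Shared generator components.
#' @param short,long Protocol specs for the two runs.
#' @param seed Integer base seed.
#' @return List of per-subject lists with elements `short` and `long`.
#' @export
generate_cohort <- function(n_subjects = 12,
                            scenario = source_scenario(),
                            noise = noise_spec(),
                            head = sphere_head(),
                            array = build_default_array(head),
                            grid = build_default_grid(head),
                            short = protocol_spec("short_mns"),
                            long = protocol_spec("long_mns"),
                            seed = 1) {
  if (n_subjects < 2) stop("need at least 2 subjects")
  ids <- sprintf("S%02d", seq_len(n_subjects))
  out <- lapply(ids, function(id) {
    list(short = generate_session(short, scenario, noise, array, head,
                                  id, seed, grid),
         long = generate_session(long, scenario, noise, array, head,
                                 id, seed + 500000L, grid))
  })
  names(out) <- ids
  out
}

#' Write / read a session container
#'
#' Serializes the session (data matrix, events, metadata, array) to a
#' single RDS file.
#'
#' @param session An `opm_session`.
#' @param path File path.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "opm_session"))
  saveRDS(session, path)
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  x <- readRDS(path)
  stopifnot(inherits(x, "opm_session"))
  x
}
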