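# Configuration and end-to-end orchestration: synthetic cohort ->
# preprocessing -> evoked / time-frequency -> source estimation ->
# Bayes-factor table and SNR summary.

#' Default run configuration
#'
#' Nested list of every pipeline parameter with its default. Values in
#' a YAML file loaded through [load_config()] override these defaults.
#'
#' @return Named list (schema id in `$schema`).
#' @export
default_config <- function() {
  list(
    schema = "opmpipe-config-1",
    cohort = list(n_subjects = 12, seed = 1),
    head = list(scalp_radius = 0.09, source_radius = 0.07,
                standoff = 0.01),
    protocols = list(
      short = list(n_events = 300, isi = c(1.0, 1.4),
                   sample_rate = 1000),
      long = list(n_events = 80, isi = c(5.6, 7.6),
                  sample_rate = 1000)),
    scenario = list(),    # overrides for source_scenario()
    noise = list(),       # overrides for noise_spec()
    preprocess = list(hfc = TRUE, notch = c(60, 120, 180),
                      band = c(3, 150), bad_threshold = 2.0),
    epochs = list(
      short = list(tmin = -0.2, tmax = 0.5, baseline = c(-0.2, -0.1)),
      long = list(tmin = -1.2, tmax = 5.2, baseline = c(-1.0, -0.5))),
    reject = list(ptp = 5e-12, adaptive_factor = 2,
                  exclude = c(-0.010, 0.015)),
    tfr = list(fmin = 3, fmax = 40, edge = 0.2,
               mu_band = c(8, 15), beta_band = c(15, 30)),
    inverse = list(snr = 3, loading = 0.1),
    stats = list(centers = c(N20m = 0.020, P35m = 0.035, P60m = 0.060),
                 half_width = 0.005, erd_window = c(0.2, 0.4),
                 ers_window = c(0.5, 1.0),
                 osc_baseline = c(-1.0, -0.5),
                 prior_scale = sqrt(2) / 2))
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Load a YAML run configuration
#'
#' @param path YAML file; missing entries fall back to
#'   [default_config()].
#' @return Configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    over <- yaml::read_yaml(path)
    cfg <- .merge_config(cfg, over)
  }
  cfg
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

.build_geometry <- function(config) {
  head <- sphere_head(scalp_radius = config$head$scalp_radius,
                      source_radius = config$head$source_radius)
  array <- build_default_array(head, standoff = config$head$standoff)
  grid <- build_default_grid(head)
  list(head = head, array = array, grid = grid,
       lead = compute_lead_field(array, grid, head))
}

.make_protocol <- function(name, p) {
  protocol_spec(name, n_events = p$n_events, isi_range = p$isi,
                sample_rate = p$sample_rate)
}

# Short-MNS arm for one subject: preprocess, epoch, evoked, source ROI
# time courses.
.process_short <- function(session, config, geom, use_hfc = TRUE,
                           drop_bad = NULL) {
  pp <- preprocess_all(session, config$preprocess$notch,
                       config$preprocess$band,
                       config$preprocess$bad_threshold,
                       use_hfc = use_hfc, lead = geom$lead,
                       drop_bad = drop_bad)
  ep <- make_epochs(pp$session, config$epochs$short$tmin,
                    config$epochs$short$tmax)
  ep <- baseline_correct(ep, config$epochs$short$baseline)
  ep <- reject_epochs(ep, config$reject$ptp, config$reject$exclude,
                      config$reject$adaptive_factor)
  ev <- average_evoked(ep)
  cov <- estimate_noise_covariance(ep, config$epochs$short$baseline,
                                   config$inverse$loading)
  stc <- minimum_norm(ev, pp$lead, cov, config$inverse$snr)
  rois <- roi_names()
  roi_tc <- t(vapply(rois, function(r) roi_timecourse(stc, r),
                     numeric(length(ev$times))))
  rownames(roi_tc) <- rois
  # heavy payloads (raw/preprocessed data, epoch tensors) are dropped:
  # a cohort of retained sessions would not fit in memory
  list(bad_report = pp$bad_report, hfc_attenuation = pp$hfc$attenuation,
       rejection = list(kept = ep$kept, rejected = ep$rejected,
                        fraction = ep$rejection_fraction),
       evoked = ev, stc = stc, roi_tc = roi_tc)
}

# Long-MNS arm: preprocess, epoch, evoked subtraction, per-epoch source
# ROI time courses, ROI-level TFR, band time courses.
.process_long <- function(session, config, geom, use_hfc = TRUE,
                          drop_bad = NULL) {
  pp <- preprocess_all(session, config$preprocess$notch,
                       config$preprocess$band,
                       config$preprocess$bad_threshold,
                       use_hfc = use_hfc, lead = geom$lead,
                       drop_bad = drop_bad)
  ep <- make_epochs(pp$session, config$epochs$long$tmin,
                    config$epochs$long$tmax)
  ep <- baseline_correct(ep, config$epochs$long$baseline)
  ep <- reject_epochs(ep, config$reject$ptp, config$reject$exclude,
                      config$reject$adaptive_factor)
  ep <- subtract_evoked(ep)
  cov <- estimate_noise_covariance(ep, config$epochs$long$baseline,
                                   config$inverse$loading)
  # kernel once; per-epoch ROI extraction to bound memory
  stc0 <- minimum_norm(matrix(0, length(pp$lead$channel_names), 1),
                       pp$lead, cov, config$inverse$snr)
  K <- stc0$kernel
  scalp <- which(!ep$array$is_reference)
  ord <- match(pp$lead$channel_names, ep$channel_names[scalp])
  rois <- roi_names()
  n_ep <- dim(ep$data)[1]
  roi_ep <- array(0, c(n_ep, length(rois), length(ep$times)))
  for (k in seq_len(n_ep)) {
    M <- matrix(ep$data[k, scalp, ], nrow = length(scalp))
    A <- K %*% M[ord, , drop = FALSE]
    for (ri in seq_along(rois))
      roi_ep[k, ri, ] <- roi_timecourse(A, rois[ri], geom$grid)
  }
  roi_epochs <- structure(
    list(data = roi_ep, times = ep$times, tmin = ep$tmin,
         tmax = ep$tmax, sample_rate = ep$sample_rate,
         channel_names = rois, array = NULL,
         kept = seq_len(n_ep), rejected = integer(0),
         baseline = ep$baseline),
    class = "epoch_set")
  tfr <- morlet_tfr(roi_epochs,
                    freqs = config$tfr$fmin:config$tfr$fmax,
                    edge = config$tfr$edge)
  tfr <- baseline_log_ratio(tfr, config$stats$osc_baseline)
  list(bad_report = pp$bad_report,
       rejection = list(kept = ep$kept, rejected = ep$rejected,
                        fraction = ep$rejection_fraction),
       mu = band_timecourse(tfr, config$tfr$mu_band),
       beta = band_timecourse(tfr, config$tfr$beta_band),
       tfr_times = tfr$times)
}

# grand average over a list of matrices with identical dimnames
.grand_average <- function(mats) {
  Reduce("+", mats) / length(mats)
}

# grand average over row-named matrices whose row sets may differ
# (bad-channel removal): each row averaged over the matrices holding it
.grand_average_union <- function(mats) {
  units <- Reduce(union, lapply(mats, rownames))
  acc <- matrix(0, length(units), ncol(mats[[1]]),
                dimnames = list(units, NULL))
  cnt <- integer(length(units))
  for (m in mats) {
    i <- match(rownames(m), units)
    acc[i, ] <- acc[i, ] + m
    cnt[i] <- cnt[i] + 1L
  }
  acc / cnt
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Generates the configured cohort, preprocesses every session, and
#' produces the study's output set: per-sensor evoked grand averages,
#' sensitivity-map tables, source-localized ROI evoked responses and
#' peak magnitudes, mu/beta band power-change time courses, a 6 ROI x 6
#' condition Bayes-factor table, and N20m SNR summaries, with optional
#' HFC-omission comparison arm. Deterministic given the config seed.
#'
#' @param config Configuration list from [default_config()] /
#'   [load_config()].
#' @param out_dir Output directory for CSV/JSON artifacts (NULL for
#'   none).
#' @param hfc_comparison Also run the HFC-omission arm and emit the
#'   comparison table.
#' @return List with `sensor` (grand-average evoked, SNR), `source`
#'   (ROI evoked, band time courses, peak windows, BF table, SNR),
#'   `sensitivity`, `comparison` (or NULL), `provenance`.
#' @export
run_full <- function(config = default_config(), out_dir = NULL,
                     hfc_comparison = FALSE) {
  geom <- .build_geometry(config)
  scenario <- do.call(source_scenario, config$scenario)
  noise <- do.call(noise_spec, config$noise)
  proto_short <- .make_protocol("short_mns", config$protocols$short)
  proto_long <- .make_protocol("long_mns", config$protocols$long)
  seed <- config$cohort$seed
  ids <- sprintf("S%02d", seq_len(config$cohort$n_subjects))
  rois <- roi_names()

  # sessions are generated, processed, and discarded one at a time:
  # a full cohort of raw recordings would not fit in memory
  gen_short <- function(id)
    generate_session(proto_short, scenario, noise, geom$array,
                     geom$head, id, seed, geom$grid)
  short_res <- list(); long_res <- list()
  for (id in ids) {
    short_res[[id]] <- tryCatch(
      .process_short(gen_short(id), config, geom),
      error = function(e) stop("stage short_mns, subject ", id, ": ",
                               conditionMessage(e)))
    long_sess <- generate_session(proto_long, scenario, noise,
                                  geom$array, geom$head, id,
                                  seed + 500000L, geom$grid)
    long_res[[id]] <- tryCatch(
      .process_long(long_sess, config, geom),
      error = function(e) stop("stage long_mns, subject ", id, ": ",
                               conditionMessage(e)))
    rm(long_sess)
  }

  ## sensor level: grand-average evoked, each channel averaged over the
  ## subjects that retained it
  ev_times <- short_res[[1]]$evoked$times
  subj_mats <- lapply(short_res, function(r) {
    scalp <- which(!r$evoked$array$is_reference)
    m <- r$evoked$data[scalp, , drop = FALSE]
    rownames(m) <- r$evoked$channel_names[scalp]
    m
  })
  sens_evoked <- .grand_average_union(subj_mats)

  ## source level: grand-average ROI evoked + peak windows
  roi_evoked <- .grand_average(lapply(short_res, `[[`, "roi_tc"))
  pw <- define_peak_windows(roi_evoked, ev_times,
                            centers = config$stats$centers,
                            half_width = config$stats$half_width)

  ## Bayes table: SEF components
  bf <- matrix(NA_real_, length(rois), 6,
               dimnames = list(rois, c("N20m", "P35m", "P60m",
                                       "mu_erd", "beta_erd",
                                       "beta_ers")))
  bl_short <- config$epochs$short$baseline
  for (comp in names(config$stats$centers)) {
    wtab <- pw$windows[[comp]]
    for (ri in seq_along(rois)) {
      w <- c(wtab$refined_lo[ri], wtab$refined_hi[ri])
      x <- vapply(short_res, function(r)
        window_mean(r$roi_tc[rois[ri], ], ev_times, w), 0)
      y <- vapply(short_res, function(r)
        window_mean(r$roi_tc[rois[ri], ], ev_times, bl_short), 0)
      bf[ri, comp] <- jzs_paired_bf(
        x, y, side = wtab$direction[ri],
        r = config$stats$prior_scale)$BF10
    }
  }
  ## oscillatory conditions on log-ratio band time courses
  tfr_times <- long_res[[1]]$tfr_times
  osc_bl <- config$stats$osc_baseline
  osc <- list(mu_erd = list(band = "mu",
                            window = config$stats$erd_window,
                            side = "left"),
              beta_erd = list(band = "beta",
                              window = config$stats$erd_window,
                              side = "left"),
              beta_ers = list(band = "beta",
                              window = config$stats$ers_window,
                              side = "right"))
  osc_means <- list()
  for (cond in names(osc)) {
    o <- osc[[cond]]
    m <- matrix(NA_real_, length(long_res), length(rois),
                dimnames = list(names(long_res), rois))
    for (ri in seq_along(rois)) {
      x <- vapply(long_res, function(r)
        window_mean(r[[o$band]][rois[ri], ], tfr_times, o$window), 0)
      y <- vapply(long_res, function(r)
        window_mean(r[[o$band]][rois[ri], ], tfr_times, osc_bl), 0)
      m[, ri] <- x
      bf[ri, cond] <- jzs_paired_bf(x, y, side = o$side,
                                    r = config$stats$prior_scale)$BF10
    }
    osc_means[[cond]] <- m
  }

  ## SNR: sensor and source level, N20m refined window from the grand
  ## average at the maximal unit
  snr_win <- function(gr_avg, times) {
    ap <- c(config$stats$centers[["N20m"]] - config$stats$half_width,
            config$stats$centers[["N20m"]] + config$stats$half_width)
    idx <- which(times >= ap[1] & times <= ap[2])
    unit <- which.max(apply(abs(gr_avg[, idx, drop = FALSE]), 1, max))
    pk <- idx[which.max(abs(gr_avg[unit, idx]))]
    c(times[pk] - 0.001, times[pk] + 0.001)
  }
  sens_win <- snr_win(sens_evoked, ev_times)
  src_win <- snr_win(roi_evoked, ev_times)
  snr_sensor <- snr_n20m(subj_mats, ev_times, sens_win, bl_short)
  snr_source <- snr_n20m(lapply(short_res, `[[`, "roi_tc"),
                         ev_times, src_win, bl_short)

  ## sensitivity map
  sens_map <- sensitivity_map(geom$lead)

  ## optional HFC-omission arm (identical bad channels and epochs)
  comparison <- NULL
  if (hfc_comparison) {
    mk_arm <- function(use_hfc) {
      res <- list()
      for (id in ids) {
        drop_bad <- short_res[[id]]$bad_report$flagged
        res[[id]] <- .process_short(gen_short(id), config, geom,
                                    use_hfc = use_hfc,
                                    drop_bad = drop_bad)
      }
      ga <- .grand_average(lapply(res, `[[`, "roi_tc"))
      w <- snr_win(ga, ev_times)
      snr <- snr_n20m(lapply(res, `[[`, "roi_tc"), ev_times, w,
                      bl_short)
      n20 <- vapply(names(res), function(id) {
        tc <- res[[id]]$roi_tc["postcentral gyrus", ]
        abs(window_mean(tc, ev_times, w) -
              window_mean(tc, ev_times, bl_short))
      }, 0)
      list(sef_magnitude = n20, band_change = rep(1, length(res)),
           max_snr = snr$max, argmax = snr$argmax)
    }
    comparison <- compare_hfc_impact(mk_arm(TRUE), mk_arm(FALSE))
  }

  rejection_log <- do.call(rbind, lapply(ids, function(id) {
    rs <- short_res[[id]]$rejection
    rl <- long_res[[id]]$rejection
    data.frame(subject = id,
               protocol = c("short_mns", "long_mns"),
               n_epochs = c(length(rs$kept) + length(rs$rejected),
                            length(rl$kept) + length(rl$rejected)),
               n_rejected = c(length(rs$rejected), length(rl$rejected)),
               fraction = c(rs$fraction, rl$fraction))
  }))

  result <- list(
    sensor = list(evoked = sens_evoked, times = ev_times,
                  snr = snr_sensor),
    source = list(roi_evoked = roi_evoked, peak_windows = pw,
                  roi_tc_subjects = lapply(short_res, `[[`, "roi_tc"),
                  bf_table = bf, snr = snr_source,
                  osc_means = osc_means,
                  mu = lapply(long_res, `[[`, "mu"),
                  beta = lapply(long_res, `[[`, "beta"),
                  tfr_times = tfr_times),
    sensitivity = sens_map,
    rejection_log = rejection_log,
    comparison = comparison,
    provenance = list(config = config,
                      config_hash = .config_hash(config),
                      n_subjects = length(ids)))
  if (!is.null(out_dir)) write_results(result, out_dir)
  result
}

#' Grand-average SEF latencies at the maximal-SNR sensor
#'
#' Identifies the sensor with the highest grand-average SNR (baseline
#' contrast over baseline SD) and reports the latency of the most
#' negative deflection in the early (N20m) a-priori window and of the
#' largest positive deflection in the late (P60m) a-priori window.
#'
#' The SEF field pattern is dipolar, so half the array sees the complex
#' with inverted polarity; the best sensor is chosen among sensors
#' showing the canonical morphology (negative early extremum), the same
#' convention used when a representative sensor is reported for real
#' recordings.
#'
#' @param sens_evoked Grand-average evoked matrix (channels x samples,
#'   named rows), e.g. `run_full()$sensor$evoked`.
#' @param times Epoch time axis \[s\].
#' @param centers N20m / P60m a-priori window centers \[s\].
#' @param half_width A-priori half-width \[s\].
#' @param baseline Baseline window \[s\].
#' @return List with `best_sensor`, `n20m_latency_ms`,
#'   `p60m_latency_ms`, and the per-sensor grand-average `snr`.
#' @export
sef_latency_summary <- function(sens_evoked, times,
                                centers = c(0.020, 0.060),
                                half_width = 0.005,
                                baseline = c(-0.2, -0.1)) {
  bl <- which(times >= baseline[1] & times <= baseline[2])
  early <- which(times >= centers[1] - half_width &
                   times <= centers[1] + half_width)
  late <- which(times >= centers[2] - half_width &
                  times <= centers[2] + half_width)
  snr <- apply(sens_evoked, 1, function(x)
    abs(mean(x[early]) - mean(x[bl])) / stats::sd(x[bl]))
  # restrict to sensors on the negative lobe of the dipolar pattern
  neg <- apply(sens_evoked, 1, function(x)
    x[early][which.max(abs(x[early]))] < 0)
  cand <- if (any(neg)) snr[neg] else snr
  best <- names(which.max(cand))
  x <- sens_evoked[best, ]
  list(best_sensor = best,
       n20m_latency_ms = times[early][which.min(x[early])] * 1000,
       p60m_latency_ms = times[late][which.max(x[late])] * 1000,
       snr = snr)
}

#' Write pipeline results as CSV/JSON artifacts
#'
#' @param result Output of [run_full()].
#' @param out_dir Directory (created if needed).
#' @export
write_results <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, f) utils::write.csv(df, file.path(out_dir, f),
                                        row.names = FALSE)
  ev <- result$sensor$evoked
  w(data.frame(time = rep(result$sensor$times, each = nrow(ev)),
               channel = rep(rownames(ev), ncol(ev)),
               value = as.vector(ev)), "evoked_sensor.csv")
  re <- result$source$roi_evoked
  w(data.frame(time = rep(result$sensor$times, each = nrow(re)),
               roi = rep(rownames(re), ncol(re)),
               value = as.vector(re)), "evoked_roi.csv")
  band_rows <- do.call(rbind, lapply(c("mu", "beta"), function(b) {
    do.call(rbind, lapply(names(result$source[[b]]), function(id) {
      m <- result$source[[b]][[id]]
      data.frame(subject = id, band = b,
                 roi = rep(rownames(m), ncol(m)),
                 time = rep(result$source$tfr_times, each = nrow(m)),
                 value = as.vector(m))
    }))
  }))
  w(band_rows, "band_timecourses.csv")
  w(result$sensitivity$roi, "sensitivity_roi.csv")
  w(result$rejection_log, "rejection_log.csv")
  bf <- result$source$bf_table
  w(data.frame(roi = rownames(bf), bf), "bf_table.csv")
  jsonlite::write_json(
    list(sensor = list(mean = mean(result$sensor$snr$max),
                       median = stats::median(result$sensor$snr$max),
                       range = range(result$sensor$snr$max)),
         source = list(mean = mean(result$source$snr$max),
                       median = stats::median(result$source$snr$max),
                       range = range(result$source$snr$max))),
    file.path(out_dir, "snr_summary.json"), auto_unbox = TRUE,
    digits = NA)
  if (!is.null(result$comparison))
    w(result$comparison$table, "hfc_comparison.csv")
  jsonlite::write_json(result$provenance[c("config_hash",
                                           "n_subjects")],
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE)
  invisible(out_dir)
}
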