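rms <- function(x) sqrt(mean(x^2))

test_that("notch filtering removes line components and spares the passband", {
  fs <- 1000
  t <- (0:19999) / fs
  # steady-state samples, away from the filter warm-up edges
  core <- which(t > 2 & t < max(t) - 2)
  s60 <- matrix_session(matrix(sin(2 * pi * 60 * t), 16,
                               length(t), byrow = TRUE))
  out <- notch_filter(s60)
  expect_lt(rms(out$data[1, core]), 0.01 * rms(s60$data[1, core]))
  s25 <- matrix_session(matrix(sin(2 * pi * 25 * t), 16,
                               length(t), byrow = TRUE))
  out25 <- notch_filter(s25)
  expect_equal(rms(out25$data[1, core]), rms(s25$data[1, core]),
               tolerance = 0.01)
  mix <- sin(2 * pi * 60 * t) + sin(2 * pi * 120 * t) +
    sin(2 * pi * 180 * t)
  smix <- matrix_session(matrix(mix, 16, length(t), byrow = TRUE))
  outm <- notch_filter(smix)
  expect_lt(rms(outm$data[1, core]), 0.02 * rms(mix[core]))
  expect_error(notch_filter(s60, freqs = 600), "Nyquist")
})

test_that("band-pass filtering is zero-phase with the stated band edges", {
  fs <- 1000
  t <- (0:9999) / fs
  s1 <- matrix_session(matrix(sin(2 * pi * 1 * t), 16, length(t),
                              byrow = TRUE))
  expect_lt(rms(bandpass_filter(s1)$data[1, ]),
            0.1 * rms(s1$data[1, ]))
  s20 <- matrix_session(matrix(sin(2 * pi * 20 * t), 16, length(t),
                               byrow = TRUE))
  expect_equal(rms(bandpass_filter(s20)$data[1, ]),
               rms(s20$data[1, ]), tolerance = 0.05)
  # symmetric pulse peak is not shifted
  pulse <- exp(-(t - 5)^2 / (2 * 0.01^2))
  sp <- matrix_session(matrix(pulse, 16, length(t), byrow = TRUE))
  out <- bandpass_filter(sp)
  expect_equal(which.max(out$data[1, ]), which.max(pulse))
  expect_error(bandpass_filter(s20, low = 200, high = 100), "Nyquist")
})

test_that("bad channels are flagged by high-frequency spectral amplitude", {
  set.seed(31)
  fs <- 1000
  n <- 20000
  t <- (0:(n - 1)) / fs
  base <- matrix(stats::rnorm(16 * n, 0, 1e-12), 16, n)
  base[4, ] <- base[4, ] + 10 * 1e-12 * sin(2 * pi * 130 * t)
  s <- matrix_session(base)
  rep <- detect_bad_channels(s)
  expect_identical(rep$flagged, fix_array$names[4])
  # references never flagged even if noisy
  expect_false(any(fix_array$names[fix_array$is_reference] %in%
                     names(rep$z)))
  # infinite threshold flags nothing
  expect_length(detect_bad_channels(s, threshold = Inf)$flagged, 0)
  # statistically identical channels: nothing flagged
  same <- matrix(rep(stats::rnorm(n, 0, 1e-12), each = 16), 16,
                 byrow = FALSE)
  expect_length(detect_bad_channels(matrix_session(same))$flagged, 0)
})

test_that("reference regression removes reference-correlated signal only", {
  set.seed(32)
  n <- 5000
  refs <- matrix(stats::rnorm(3 * n), 3, n)
  # a signal exactly orthogonal to the references (and the intercept)
  indep <- qr.resid(qr(cbind(1, t(refs))), stats::rnorm(n))
  data <- matrix(stats::rnorm(16 * n, 0, 0.1), 16, n)
  refi <- which(fix_array$is_reference)
  data[refi, ] <- refs
  data[1, ] <- refs[1, ]                       # pure reference copy
  data[2, ] <- indep                           # orthogonal signal
  data[3, ] <- 0.5 * refs[1, ] - 2 * refs[2, ] + indep
  out <- reference_regression(matrix_session(data))
  expect_lt(rms(out$data[1, ]), 1e-12 * rms(data[1, ]))
  expect_lt(max(abs(out$data[2, ] - (indep - mean(indep)))), 1e-6)
  got <- out$data[3, ]
  want <- indep - mean(indep)
  expect_lt(rms(got - want) / rms(want), 1e-6)
  # residuals decorrelated from every reference
  for (k in 1:3)
    expect_lt(abs(stats::cor(out$data[3, ], refs[k, ])), 1e-8)
  # scalp variance never increases
  v_in <- apply(data[1:13, ], 1, stats::var)
  v_out <- apply(out$data[1:13, ], 1, stats::var)
  expect_true(all(v_out <= v_in + 1e-20))
  bad <- data; bad[refi[1], ] <- 1
  expect_error(reference_regression(matrix_session(bad)),
               "zero variance")
})

test_that("HFC annihilates homogeneous interference and is idempotent", {
  spec <- noise_spec(gradient_fraction = 0)
  intf <- interference_timecourse(5000, spec, seed = 7)
  s <- matrix_session(intf$project(fix_array))
  res <- hfc(s)
  scalp <- which(!fix_array$is_reference)
  expect_lt(rms(res$session$data[scalp, ]),
            1e-9 * rms(s$data[scalp, ]))
  # projector symmetric and idempotent
  P <- res$projector
  expect_lt(max(abs(P - t(P))), 1e-12)
  expect_lt(max(abs(P %*% P - P)), 1e-9)
  res2 <- hfc(res$session)
  expect_equal(res2$session$data, res$session$data, tolerance = 1e-12)
})

test_that("HFC attenuation fractions match a brute-force projection oracle", {
  s <- matrix_session(matrix(stats::rnorm(16 * 100), 16, 100))
  res <- hfc(s, lead = fix_lead)
  N <- fix_array$orientations[!fix_array$is_reference, ]
  # independent projector via QR of the orientation basis
  Q <- qr.Q(qr(N))
  brute <- vapply(seq_len(ncol(fix_lead$matrix)), function(j) {
    l <- fix_lead$matrix[, j]
    1 - sqrt(sum((l - Q %*% crossprod(Q, l))^2)) / sqrt(sum(l^2))
  }, 0)
  expect_lt(max(abs(res$attenuation - brute)), 1e-12)
  expect_true(all(res$attenuation >= 0 & res$attenuation <= 1))
})

test_that("signals orthogonal to the homogeneous subspace pass HFC unchanged", {
  set.seed(33)
  N <- fix_array$orientations[!fix_array$is_reference, ]
  x <- stats::rnorm(13)
  x <- x - N %*% solve(crossprod(N), crossprod(N, x))  # orthogonalize
  data <- matrix(0, 16, 50)
  data[1:13, ] <- x %*% t(stats::rnorm(50))
  res <- hfc(matrix_session(data))
  expect_lt(max(abs(res$session$data[1:13, ] - data[1:13, ])),
            1e-9 * max(abs(data)))
  expect_equal(res$rank, 3)
})

test_that("rank-deficient orientation sets yield a reduced-rank projector with warning", {
  a <- sensor_array(sprintf("s%d", 1:4),
                    cbind(0.1 * diag(3)[c(1, 2, 3, 1), ]),
                    matrix(rep(c(0, 0, 1), 4), 4, byrow = TRUE),
                    rep(FALSE, 4))
  s <- structure(list(data = matrix(stats::rnorm(4 * 20), 4, 20),
                      sample_rate = 1000, events = integer(0),
                      array = a), class = "opm_session")
  rownames(s$data) <- a$names
  expect_warning(res <- hfc(s), "rank")
  expect_equal(res$rank, 1)
})

test_that("full preprocessing suppresses interference and preserves SEF latency", {
  scen <- source_scenario(latency_jitter_sd = 0,
                          amplitude_jitter_sd = 0)
  # interference-only session
  noi_i <- noise_spec(sensor_noise_density = 0, line_amps = c(0, 0, 0),
                      artifact_amplitude = 0, gradient_fraction = 0)
  scen0 <- source_scenario(sef_peaks = list(), mu_amp = 0,
                           beta_erd_amp = 0, beta_ers_amp = 0)
  s_int <- generate_session(tiny_protocol(8), scen0, noi_i, fix_array,
                            fix_head, "S01", 13, fix_grid)
  scalp <- which(!fix_array$is_reference)
  v_in <- stats::var(as.vector(s_int$data[scalp, ]))
  pp_on <- preprocess_all(s_int, use_hfc = TRUE)
  v_on <- stats::var(as.vector(pp_on$session$data[
    !pp_on$session$array$is_reference, ]))
  expect_lt(v_on, 0.01 * v_in)
  pp_off <- preprocess_all(s_int, use_hfc = FALSE)
  v_off <- stats::var(as.vector(pp_off$session$data[
    !pp_off$session$array$is_reference, ]))
  expect_gt(v_off, v_on)
  # SEF-only session with a small white noise floor (the floor keeps
  # the far-field SEF copy at the references negligible, as in real
  # recordings): N20m latency unchanged by preprocessing
  noi0 <- noise_spec(sensor_noise_density = 2e-15,
                     interference_rms = 0, line_amps = c(0, 0, 0),
                     artifact_amplitude = 0)
  scen_sef <- source_scenario(mu_amp = 0, beta_erd_amp = 0,
                              beta_ers_amp = 0, latency_jitter_sd = 0,
                              amplitude_jitter_sd = 0)
  s_sef <- generate_session(tiny_protocol(6), scen_sef, noi0,
                            fix_array, fix_head, "S01", 17, fix_grid)
  ep_raw <- baseline_correct(make_epochs(s_sef, -0.2, 0.5),
                             c(-0.2, -0.1))
  ev_raw <- average_evoked(ep_raw)
  pp <- preprocess_all(s_sef)
  ep_pp <- baseline_correct(make_epochs(pp$session, -0.2, 0.5),
                            c(-0.2, -0.1))
  ev_pp <- average_evoked(ep_pp)
  idx <- which(ev_raw$times >= 0.01 & ev_raw$times <= 0.03)
  lat <- function(ev) {
    scalp <- which(!ev$array$is_reference)
    amp <- colSums(abs(ev$data[scalp, idx, drop = FALSE]))
    ev$times[idx][which.max(amp)]
  }
  expect_equal(lat(ev_pp), lat(ev_raw))
})

test_that("partial coverage loses more lead field to HFC than a whole-head cap", {
  cap <- build_whole_cap_array(fix_head, n = 64)
  cap_lead <- compute_lead_field(cap, fix_grid, fix_head)
  proj_att <- function(array, lead) {
    N <- array$orientations[!array$is_reference, , drop = FALSE]
    Q <- qr.Q(qr(N))
    vapply(seq_len(ncol(lead$matrix)), function(j) {
      l <- lead$matrix[, j]
      1 - sqrt(sum((l - Q %*% crossprod(Q, l))^2)) / sqrt(sum(l^2))
    }, 0)
  }
  expect_gt(mean(proj_att(fix_array, fix_lead)),
            mean(proj_att(cap, cap_lead)))
})
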