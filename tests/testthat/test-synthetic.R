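test_that("SEF moment time course is a signed sum of Gaussian lobes", {
  t <- seq(-0.1, 0.2, by = 1e-3)
  expect_equal(sef_moment_timecourse(t, list()), numeric(length(t)))
  peaks <- list(c(0.020, 0.005, -20e-9), c(0.035, 0.008, 10e-9),
                c(0.060, 0.012, 20e-9))
  q <- sef_moment_timecourse(t, peaks)
  # global minimum at the 20 ms lobe, within one sample
  expect_equal(t[which.min(q)], 0.020, tolerance = 1.0001e-3)
  # value at 60 ms equals the analytic three-Gaussian sum
  expected <- sum(vapply(peaks, function(p)
    p[3] * exp(-(0.060 - p[1])^2 / (2 * p[2]^2)), 0))
  expect_equal(q[t == 0.060], expected, tolerance = 1e-12)
  # zero outside the lobe supports
  expect_identical(q[t < -0.001], numeric(sum(t < -0.001)))
  expect_error(sef_moment_timecourse(t, list(c(0.02, 0, 1))),
               "width")
})

test_that("oscillatory envelope expresses ERD and ERS window statistics", {
  fs <- 1000
  times <- seq(0, 120, by = 1 / fs)
  events <- seq(5, 110, by = 6.5)
  msq_win <- function(x, w) {
    idx <- unlist(lapply(events, function(e)
      which(times >= e + w[1] & times <= e + w[2])))
    mean(x[idx]^2)
  }
  set.seed(21)
  # no modulation: envelope constant
  m0 <- oscillatory_moment(times, events, list(freq = 21, amp = 1e-9),
                           fs)
  expect_equal(diff(range(attr(m0, "envelope"))), 0)
  # beta defaults: ERS window envelope power above baseline
  m_ers <- oscillatory_moment(times, events,
                              list(freq = 21, amp = 1e-9,
                                   erd_window = c(0.2, 0.4),
                                   erd_depth = 0.3,
                                   ers_window = c(0.5, 1.0),
                                   ers_gain = 0.3), fs)
  env <- attr(m_ers, "envelope")
  expect_gt(msq_win(env, c(0.5, 1.0)), msq_win(env, c(-1.0, -0.5)))
  expect_lt(msq_win(env, c(0.2, 0.4)), msq_win(env, c(-1.0, -0.5)))
  expect_gt(msq_win(m_ers, c(0.5, 1.0)), msq_win(m_ers, c(-1.0, -0.5)))
  # mu defaults: ERD suppression in the generated signal
  m_mu <- oscillatory_moment(times, events,
                             list(freq = 10, amp = 1e-9,
                                  erd_window = c(0.2, 0.4),
                                  erd_depth = 0.5), fs)
  expect_lt(msq_win(m_mu, c(0.2, 0.4)), msq_win(m_mu, c(-1.0, -0.5)))
  # too-short ISI for the modulation windows
  expect_error(oscillatory_moment(times, c(5, 5.5),
                                  list(freq = 21, amp = 1e-9,
                                       ers_window = c(0.5, 1.0),
                                       ers_gain = 0.3), fs),
               "overlap")
})

test_that("homogeneous interference spans three dimensions and hits its RMS", {
  spec <- noise_spec(gradient_fraction = 0)
  intf <- interference_timecourse(20000, spec, seed = 5)
  X <- intf$project(fix_array)
  expect_lte(qr(X)$rank, 3)
  # two channels with identical orientations get identical traces
  a2 <- sensor_array(c("a", "b"),
                     rbind(c(0, 0, 0.1), c(0, 0.05, 0.1)),
                     rbind(c(0, 0, 1), c(0, 0, 1)), c(FALSE, FALSE))
  X2 <- intf$project(a2)
  expect_equal(X2[1, ], X2[2, ])
  # per-channel RMS within 20% of the orientation-projected target
  rms <- sqrt(rowMeans(X^2))
  expect_true(all(abs(rms - spec$interference_rms) <
                    0.2 * spec$interference_rms))
})

test_that("sessions honor event counts, ISI bounds, and determinism", {
  scen <- source_scenario()
  noi <- silent_noise()
  s_short <- generate_session(tiny_protocol(25), scen, noi, fix_array,
                              fix_head, "S01", 3, fix_grid)
  expect_equal(length(s_short$events), 25)
  isi <- diff(s_short$events) / s_short$sample_rate
  expect_true(all(isi >= 1.0 - 1e-3 & isi <= 1.4 + 1e-3))
  long <- protocol_spec("long_mns", n_events = 5)
  s_long <- generate_session(long, scen, noi, fix_array, fix_head,
                             "S01", 3, fix_grid)
  expect_equal(length(s_long$events), 5)
  isi_l <- diff(s_long$events) / 1000
  expect_true(all(isi_l >= 5.6 - 1e-3 & isi_l <= 7.6 + 1e-3))
  # byte-identical regeneration from (seed, subject_id)
  s_again <- generate_session(tiny_protocol(25), scen, noi, fix_array,
                              fix_head, "S01", 3, fix_grid)
  expect_identical(s_short$data, s_again$data)
  expect_identical(s_short$events, s_again$events)
  # a different subject gives different data
  s_other <- generate_session(tiny_protocol(25), scen, noi, fix_array,
                              fix_head, "S02", 3, fix_grid)
  expect_false(identical(s_short$events, s_other$events))
})

test_that("with all noise zeroed, sensor data equals lead field times moments", {
  s <- generate_session(tiny_protocol(10), source_scenario(),
                        silent_noise(), fix_array, fix_head, "S07", 9,
                        fix_grid)
  expect_identical(unname(s$data),
                   unname(s$truth$lead %*% s$truth$moments))
})

test_that("default protocols encode the two stimulation paradigms", {
  p_s <- protocol_spec("short_mns")
  expect_equal(p_s$n_events, 300L)
  expect_equal(p_s$isi_range, c(1.0, 1.4))
  p_l <- protocol_spec("long_mns")
  expect_equal(p_l$n_events, 80L)
  expect_equal(p_l$isi_range, c(5.6, 7.6))
  expect_equal(p_l$sample_rate, 1000)
})

test_that("cohorts pair short and long runs with distinct subject seeds", {
  coh <- generate_cohort(n_subjects = 2, noise = silent_noise(),
                         head = fix_head, array = fix_array,
                         grid = fix_grid,
                         short = tiny_protocol(5),
                         long = protocol_spec("long_mns", n_events = 3),
                         seed = 4)
  expect_length(coh, 2)
  expect_named(coh[[1]], c("short", "long"))
  expect_false(identical(coh$S01$short$data, coh$S02$short$data))
  expect_error(generate_cohort(n_subjects = 1), "2 subjects")
})

test_that("session container round-trips through serialization", {
  s <- generate_session(tiny_protocol(5), source_scenario(),
                        silent_noise(), fix_array, fix_head, "S01", 2,
                        fix_grid)
  f <- tempfile(fileext = ".rds")
  write_session(s, f)
  s2 <- read_session(f)
  expect_identical(s2$data, s$data)
  expect_identical(s2$events, s$events)
})

test_that("a jitter-free cohort has identical subject and grand-average peak latency", {
  scen0 <- source_scenario(latency_jitter_sd = 0,
                           amplitude_jitter_sd = 0, mu_amp = 0,
                           beta_erd_amp = 0, beta_ers_amp = 0)
  evs <- lapply(c("S01", "S02"), function(id) {
    s <- generate_session(tiny_protocol(8), scen0, silent_noise(),
                          fix_array, fix_head, id, 6, fix_grid)
    ep <- baseline_correct(make_epochs(s, -0.2, 0.5), c(-0.2, -0.1))
    average_evoked(ep)
  })
  lat <- vapply(evs, function(e) {
    idx <- which(e$times >= 0.015 & e$times <= 0.025)
    scalp <- which(!e$array$is_reference)
    amp <- colSums(abs(e$data[scalp, idx]))
    e$times[idx][which.max(amp)]
  }, 0)
  expect_equal(lat[1], lat[2])
  ga <- (evs[[1]]$data + evs[[2]]$data) / 2
  idx <- which(evs[[1]]$times >= 0.015 & evs[[1]]$times <= 0.025)
  scalp <- which(!evs[[1]]$array$is_reference)
  expect_equal(evs[[1]]$times[idx][which.max(colSums(abs(ga[scalp, idx])))],
               lat[1])
})
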