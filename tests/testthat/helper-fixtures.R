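# Shared small fixtures: default geometry plus a quiet noise spec and a
# short test protocol so unit tests stay fast.

fix_head <- sphere_head()
fix_array <- build_default_array(fix_head)
fix_grid <- build_default_grid(fix_head)
fix_lead <- compute_lead_field(fix_array, fix_grid, fix_head)

silent_noise <- function() {
  noise_spec(sensor_noise_density = 0, interference_rms = 0,
             line_amps = c(0, 0, 0), artifact_amplitude = 0)
}

tiny_protocol <- function(n_events = 20)
  protocol_spec("short_mns", n_events = n_events)

# wrap a plain channels x samples matrix as an opm_session for the
# preprocessing operators; channels map onto the default array
matrix_session <- function(data, events = integer(0), fs = 1000,
                           array = fix_array) {
  stopifnot(nrow(data) == length(array$names))
  rownames(data) <- array$names
  structure(list(data = data, sample_rate = fs, events = events,
                 array = array, head = fix_head, subject_id = "TST",
                 seed = 0L),
            class = "opm_session")
}

# free-space (primary current only) dipole field: independent oracle for
# the radial-field identity of the conducting-sphere solution
biot_savart_dipole <- function(dipole_pos, dipole_moment, field_point) {
  a <- field_point - dipole_pos
  q <- dipole_moment
  1e-7 * c(q[2] * a[3] - q[3] * a[2],
           q[3] * a[1] - q[1] * a[3],
           q[1] * a[2] - q[2] * a[1]) / sum(a^2)^1.5
}

# minimal epoch_set constructor for operator-level tests
make_epoch_set <- function(data, tmin = -0.2, fs = 1000,
                           channel_names = NULL) {
  n_samp <- dim(data)[3]
  structure(list(data = data,
                 times = (seq_len(n_samp) - 1) / fs + tmin,
                 tmin = tmin, tmax = tmin + (n_samp - 1) / fs,
                 sample_rate = fs,
                 channel_names = channel_names %||%
                   sprintf("ch%02d", seq_len(dim(data)[2])),
                 array = NULL, kept = seq_len(dim(data)[1]),
                 rejected = integer(0), baseline = NULL),
            class = "epoch_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent Bayes-factor oracle: fine-grid trapezoid quadrature over
# the effect size, truncated Cauchy prior, noncentral-t likelihood. The
# grid stops at |delta| = 20: beyond that the noncentral-t likelihood
# of any moderate t is vanishingly small, far below the 1e-4
# comparison tolerance.
bf_quadrature <- function(t_stat, n, side, r = sqrt(2) / 2,
                          lim = 20, ngrid = 20001) {
  df <- n - 1
  grid <- switch(side,
                 right = seq(0, lim, length.out = ngrid),
                 left = seq(-lim, 0, length.out = ngrid),
                 two = seq(-lim, lim, length.out = ngrid))
  dens <- stats::dcauchy(grid, 0, r)
  if (side != "two") dens <- dens * 2
  f <- suppressWarnings(stats::dt(t_stat, df, ncp = grid * sqrt(n))) *
    dens
  h <- diff(grid[1:2])
  m1 <- h * (sum(f) - (f[1] + f[length(f)]) / 2)
  m1 / stats::dt(t_stat, df)
}
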