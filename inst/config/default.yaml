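# Default run configuration. Values mirror the package defaults; any
# field may be omitted (defaults are merged in by load_config()).
#
# Protocol geometry, filtering, epoching, band and window definitions
# follow the study protocol the pipeline reproduces. Generator source
# amplitudes and noise magnitudes are simulation defaults chosen so that
# the default cohort lands in a realistic sensor-level SNR regime; they
# are not measured quantities.
schema: opmpipe-config-1
cohort:
  n_subjects: 12
  seed: 1
head:
  scalp_radius: 0.09      # m
  source_radius: 0.07     # m
  standoff: 0.01          # m, scalp-to-sensor cell
protocols:
  short:
    n_events: 300
    isi: [1.0, 1.4]       # s, uniform
    sample_rate: 1000     # Hz
  long:
    n_events: 80
    isi: [5.6, 7.6]
    sample_rate: 1000
scenario: {}              # overrides for source_scenario(); amplitudes
                          # in A*m are simulation defaults
noise: {}                 # overrides for noise_spec()
preprocess:
  hfc: true
  notch: [60, 120, 180]   # Hz
  band: [3, 150]          # Hz
  bad_threshold: 2.0      # z-score on 120-145 Hz spectral amplitude
epochs:
  short: {tmin: -0.2, tmax: 0.5, baseline: [-0.2, -0.1]}
  long: {tmin: -1.2, tmax: 5.2, baseline: [-1.0, -0.5]}
reject:
  ptp: 5.0e-12            # T, any-channel peak-to-peak ceiling (ignored
                          # when adaptive_factor is set)
  adaptive_factor: 2      # ceiling = factor x median per-epoch peak-to-peak
  exclude: [-0.010, 0.015] # s, stimulus-artifact window ignored by the metric
tfr:
  fmin: 3
  fmax: 40
  edge: 0.2               # s trimmed from each end
  mu_band: [8, 15]
  beta_band: [15, 30]
inverse:
  snr: 3                  # lambda^2 = 1/snr^2
  loading: 0.1            # diagonal loading fraction
stats:
  centers: {N20m: 0.020, P35m: 0.035, P60m: 0.060}
  half_width: 0.005       # s, a-priori window half-width
  erd_window: [0.2, 0.4]
  ers_window: [0.5, 1.0]
  osc_baseline: [-1.0, -0.5]
  prior_scale: 0.7071068  # Cauchy scale sqrt(2)/2
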