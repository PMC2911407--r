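# Frozen calibration constants for the default E2A parameter set.
#
# Produced by calibrate_defaults() against the regular-fiber anchors
# (nearest-neighbour distance 51.00 +/- 0.63 nm, <r_2> = 37.55 +/- 7.16 nm,
# <r_10> = 125.06 nm, persistence length 280 nm) and, for the released
# opening-angle interval, the disturbed-fiber persistence length (140 nm).
# The same values are recorded in inst/extdata/e2a_defaults.cfg; a unit test
# keeps file and constants in sync.

.e2a_cal <- list(
  linker_length_nm = 57.56001,
  linker_length_sd_nm = 0.55976,
  alpha_mean = 0.79361,
  alpha_sd = 0.14176,
  beta_mean = 1.70066,
  beta_sd = 0.30517,
  lh_alpha_range = c(0.19234, 1.39488)
)
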