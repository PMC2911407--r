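# Calibrated default constants of the extended two-angle model
# version 2; produced by calibrate_defaults() from the regular-fiber
# anchors (r1 51.00 +/- 0.63 nm, r2 37.55 +/- 7.16 nm, r10 125.06 nm,
# Lp 280 nm) and the disturbed-fiber persistence length (140 nm).
linker_length_nm = 57.56001
linker_length_sd_nm = 0.55976
alpha_mean = 0.79361
alpha_sd = 0.14176
beta_mean = 1.70066
beta_sd = 0.30517
lh_alpha_range = 0.19234 1.39488
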