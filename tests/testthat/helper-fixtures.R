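# Shared fixtures for the test suite. Everything is generated in code;
# heavier objects are built once per test run.

ref_geom <- tool_geometry() # D = 7.94 mm, h = 0.3302 mm

# the 60 bar / 2 mm granule batch
gsd_60_2 <- bimodal_weibull(0.46, 541, 2.24, 1170, 4.98)

# condition-level noise-free model chain over the 24 reference conditions
noiseless_conditions <- function() {
  predict_tablet_cqas(campaign_conditions())
}

# relative error helper
rel_err <- function(x, ref) abs(x / ref - 1)
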