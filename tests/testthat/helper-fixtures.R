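# Shared lazily-computed fixtures (calibrations and MH fits are expensive;
# several test files reuse them through this cache).
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Calibrated ground-truth observers (common random numbers inside; seeds fixed)
calibrated <- function(model, condition) {
  fixture(paste0("cal_", model, "_", condition), {
    calibrate_ground_truth(ground_truth_spec(model, condition))
  })
}

# A quick exponential-slope fit
slope_of <- function(data) fit_weights(data, shape = "exponential")$slope_beta
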