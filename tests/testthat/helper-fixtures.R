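# Shared fixtures, built once per test run and memoized. All phantoms use
# the acquisition geometry of the standard protocol: 512 frames at 229 ms
# (497 analysed after the 15-frame steady-state discard), 0.25 Hz breathing.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name) {
  if (!exists(name, envir = .fixture_env)) {
    val <- switch(name,
      defects = phantom_study_defects(),
      # noiseless validation phantom with the canonical defect regions
      phantom_clean = generate_phantom(
        phantom_config(noise_sigma = 0, defects = fixture("defects"))),
      # same phantom at SNR 20 (Rician noise, sigma = tissue mean / 20)
      phantom_snr20 = generate_phantom(
        phantom_config(noise_sigma = 3, defects = fixture("defects"))),
      run_clean_V = run_pipeline(fixture("phantom_clean")$series,
                                 run_config(), modality = "V"),
      run_snr20_V = run_pipeline(fixture("phantom_snr20")$series,
                                 run_config(), modality = "V"),
      stop("unknown fixture: ", name)
    )
    assign(name, val, envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# logical map marking a defect region restricted to lung truth + analysis mask
region_mask <- function(defect, truth, mask) {
  z <- matrix(FALSE, nrow(truth$lung_mask), ncol(truth$lung_mask))
  z[defect$rows, defect$cols] <- TRUE
  z & truth$lung_mask & mask$mask
}

# one frame of lag corresponds to this % of the respiratory cycle
lag_pct_per_frame <- function(result) {
  result$maps$frame_interval_s * result$maps$reference_freq_hz * 100
}
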