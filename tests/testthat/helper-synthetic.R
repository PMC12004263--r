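# shared fixtures: small, fast synthetic conditions used across test files

ref_geom <- function() geometry(130, 15)

# default study-condition truth for one charge state
test_truth <- function(pH = 13, ...) alanine_truth(pH, ...)

# truth with no chirality, no flux imbalance: + and - identical (noise-free)
null_truth <- function(pH = 13) {
  alanine_truth(pH, b1_true = c(C1 = 0, C2 = 0, C3 = 0), flux_imbalance = 1)
}

# run one polarization pair through scale -> background -> joint fit
fit_pair <- function(pair, beta_assumed = 0.5, geom = ref_geom()) {
  hv <- pair$plus$meta$hv_eV
  truth <- attr(pair, "truth")
  centers <- hv - truth$sites$be_eV
  sc <- scale_to_baseline(pair$plus, pair$minus, peak_centers = centers)
  bp <- subtract_background(sc$plus)
  bm <- subtract_background(sc$minus)
  fp <- suppressWarnings(fit_peaks(sc$plus, centers = centers,
                                   background = "exp_const",
                                   bg_start = bp$params))
  fm <- suppressWarnings(fit_peaks(sc$minus, centers = centers,
                                   background = "exp_const",
                                   bg_start = bm$params))
  list(scale = sc, fit_plus = fp, fit_minus = fm,
       bgsub_plus = bp, bgsub_minus = bm)
}

pair_b1 <- function(pair, site = "C1", beta_assumed = 0.5, geom = ref_geom()) {
  pr <- fit_pair(pair, beta_assumed, geom)
  estimate_b1(pr$fit_plus, pr$fit_minus, site = site, geom = geom,
              beta_assumed = beta_assumed,
              pair_id = pair$plus$meta$pair_id)
}

# a bare spectrum holding a single EMG peak on a flat grid (no background)
single_emg_spectrum <- function(center = 11.75, sigma = 0.45, asym = 0.25,
                                area = 1e4, ke = seq(6, 18, 0.05),
                                meta = list()) {
  y <- emg_profile(ke, center, sigma, asym, area = area, tail = "lower") *
    mean(diff(ke))
  pecd_spectrum(ke, y, meta = meta, sigma = sqrt(pmax(y, 1)), nonneg = FALSE)
}
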