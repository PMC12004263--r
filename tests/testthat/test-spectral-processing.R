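# baseline scaling, background subtraction, constrained EMG fitting

test_that("baseline scaling recovers the flux-imbalance factor", {
  ke <- seq(7, 20, 0.05)
  bg <- scattering_background(ke, list(amplitude = 1e6, decay_eV = 2.5,
                                       offset = 500)) * 0.05
  a <- pecd_spectrum(ke, bg)
  b <- pecd_spectrum(ke, bg * 1.02)
  # identical spectra scale by exactly 1
  expect_equal(scale_to_baseline(a, a)$factor, 1)
  # a global 2% imbalance inverts to 1/1.02
  sc <- scale_to_baseline(a, b)
  expect_equal(sc$factor, 1 / 1.02, tolerance = 1e-6)
  expect_equal(sc$minus$counts, a$counts, tolerance = 1e-9)
  # scaling is idempotent
  sc2 <- scale_to_baseline(sc$plus, sc$minus)
  expect_lt(abs(sc2$factor - 1), 1e-10)
})

test_that("generator flux imbalance round-trips through baseline scaling", {
  tr <- test_truth(13, flux_imbalance = 1.025)
  pair <- generate_pair(tr, 305, "L", seed = 1, noise = FALSE)
  sc <- scale_to_baseline(pair$plus, pair$minus)
  expect_equal(sc$factor, 1 / 1.025, tolerance = 1e-6)
})

test_that("edge windows reject peak contamination and empty intensity", {
  ke <- seq(7, 20, 0.05)
  a <- pecd_spectrum(ke, rep(10, length(ke)))
  expect_error(scale_to_baseline(a, a, peak_centers = 8),
               "overlaps a peak region")
  z <- pecd_spectrum(ke, rep(0, length(ke)))
  expect_error(scale_to_baseline(z, z), "zero intensity")
})

test_that("background subtraction recovers the generator background", {
  tr <- test_truth(13)
  # noise-free: recovered curve matches generator truth to 0.5% RMS on edges
  pair <- generate_pair(tr, 305, "L", seed = 1, noise = FALSE)
  bs <- subtract_background(pair$plus)
  truth_bg <- scattering_background(pair$plus$ke, tr$background) * 0.05
  ke <- pair$plus$ke
  m <- (ke >= bs$edges$low[1] & ke <= bs$edges$low[2]) |
    (ke >= bs$edges$high[1] & ke <= bs$edges$high[2])
  rms <- sqrt(mean((bs$background[m] - truth_bg[m])^2)) / mean(truth_bg[m])
  expect_lt(rms, 0.005)
  # residuals on the edges are consistent with zero within shot noise
  expect_lt(mean(abs(bs$spectrum$counts[m])),
            2 * mean(bs$spectrum$sigma[m]))
})

test_that("a peak-free noisy spectrum subtracts to pure shot noise", {
  ke <- seq(7, 20, 0.05)
  lam <- scattering_background(ke, list(amplitude = 6e8, decay_eV = 2.5,
                                        offset = 1e5)) * 0.05
  set.seed(99)
  s <- pecd_spectrum(ke, rpois(length(ke), lam), sigma = sqrt(lam))
  bs <- subtract_background(s)
  chi2 <- mean((bs$spectrum$counts / bs$spectrum$sigma)^2)
  expect_gt(chi2, 0.5)
  expect_lt(chi2, 1.5)
})

test_that("linear and spline background models are selectable", {
  ke <- seq(7, 20, 0.05)
  lin <- 1000 - 30 * ke
  s <- pecd_spectrum(ke, lin)
  bs <- subtract_background(s, model = "linear")
  expect_equal(bs$background, lin, tolerance = 1e-8)
  expect_s3_class(subtract_background(s, model = "spline")$spectrum,
                  "pecd_spectrum")
  expect_error(
    subtract_background(pecd_spectrum(ke, 30 * ke - 250, nonneg = FALSE),
                        model = "linear"), "negative")
})

test_that("a noise-free EMG self-fit recovers parameters exactly", {
  s <- single_emg_spectrum(center = 11.75, sigma = 0.45, asym = 0.25,
                           area = 1e4)
  f <- fit_peaks(s, n_peaks = 1, centers = 11.75)
  expect_equal(f$peaks$center_ke, 11.75, tolerance = 1e-6)
  expect_equal(f$peaks$sigma, 0.45, tolerance = 1e-6)
  expect_equal(f$peaks$asym, 0.25, tolerance = 1e-6)
  expect_equal(f$peaks$area, 1e4, tolerance = 1e-2)
  # bound constraints inactive at the optimum for truth inside the bounds
  expect_gt(f$peaks$asym, 0.201)
  expect_lt(f$peaks$asym, 0.299)
})

test_that("three-peak fits on realistic noisy spectra recover Table-1 truth", {
  tr <- test_truth(1)                      # cationic: 1 : 1.09 : 1.13
  hv <- 305
  pair <- generate_pair(tr, hv, "L", seed = 42)
  sc <- scale_to_baseline(pair$plus, pair$minus)
  # the dichroic modulation cancels in the polarization sum, so the fitted
  # ratios estimate the intrinsic relative areas
  spec <- polarization_sum(sc$plus, sc$minus)
  bs <- subtract_background(spec)
  f <- fit_peaks(spec, centers = hv - tr$sites$be_eV,
                 background = "exp_const", bg_start = bs$params)
  # centers within +/-0.05 eV of the reference binding energies
  expect_true(all(abs(f$peaks$be_eV - c(294.64, 292.12, 290.53)) < 0.05))
  # area ratios recover generator truth within 3 propagated sigma
  r <- peak_area_ratios(f)
  expect_true(all(abs(r$ratio - c(1, 1.09, 1.13)) <= 3 * pmax(r$se, 1e-12) +
                    c(1e-9, 0, 0)))
  expect_lt(f$redchi, 2)
})

test_that("auto-seeded centers find the three resolved cationic peaks", {
  tr <- test_truth(1)
  pair <- generate_pair(tr, 305, "L", seed = 7, noise = FALSE)
  bs <- subtract_background(pair$plus)
  f <- fit_peaks(bs$spectrum, n_peaks = 3)
  expect_equal(f$peaks$center_ke, 305 - tr$sites$be_eV, tolerance = 1e-2)
})

test_that("overlapping anionic C2/C3 peaks are flagged", {
  tr <- test_truth(13)
  pair <- generate_pair(tr, 305, "L", seed = 3, noise = FALSE)
  bs <- subtract_background(pair$plus)
  expect_warning(fit_peaks(bs$spectrum, centers = 305 - tr$sites$be_eV),
                 "overlap")
})

test_that("fitted areas conserve the integrated spectrum", {
  tr <- test_truth(6)
  pair <- generate_pair(tr, 305, "L", seed = 5)
  bs <- subtract_background(pair$plus)
  f <- suppressWarnings(fit_peaks(bs$spectrum,
                                  centers = 305 - tr$sites$be_eV))
  total <- sum(bs$spectrum$counts)
  shot <- sqrt(sum(bs$spectrum$sigma^2))
  expect_lte(sum(f$peaks$area), total + 3 * shot)
})

test_that("joint three-pH fitting ties the peak widths within 5%", {
  hv <- 305
  specs <- list(); centers <- list()
  for (i in seq_along(c(1, 6, 13))) {
    pH <- c(1, 6, 13)[i]
    tr <- test_truth(pH)
    pair <- generate_pair(tr, hv, "L", seed = 10 + i, noise = FALSE)
    bs <- subtract_background(pair$plus)
    specs[[i]] <- bs$spectrum
    centers[[i]] <- hv - tr$sites$be_eV
  }
  jf <- suppressWarnings(fit_peaks_joint(specs, centers))
  sig <- do.call(rbind, lapply(jf$fits, function(f) f$peaks$sigma))
  ratio <- apply(sig, 2, function(s) max(s) / min(s))
  expect_true(all(ratio <= 1.05 + 1e-9))
  for (i in 1:3)
    expect_equal(jf$fits[[i]]$peaks$center_ke, centers[[i]], tolerance = 5e-3)
})

test_that("peak-area ratios divide through by C1 with uncertainties", {
  fit <- structure(list(
    peaks = data.frame(site = c("C1", "C2", "C3"), area = c(2, 2.18, 2.26)),
    vcov = diag(1e-8, 12)), class = "pecd_peakfit")
  r <- peak_area_ratios(fit)
  expect_equal(r$ratio, c(1, 1.09, 1.13))
  expect_error(peak_area_ratios(structure(list(
    peaks = data.frame(site = "C1", area = 0), vcov = diag(1e-8, 4)),
    class = "pecd_peakfit")), "zero C1")
})

test_that("chemical shifts reproduce the charge-state BE arithmetic", {
  # reference-table arithmetic
  expect_equal(reference_shift("C1", 1, 6), 1.12, tolerance = 1e-12)
  expect_equal(reference_shift("C2", 6, 13), 0.77, tolerance = 1e-12)
  # shifts measured from fitted synthetic spectra
  hv <- 305
  fits <- lapply(c(1, 6, 13), function(pH) {
    tr <- test_truth(pH)
    pair <- generate_pair(tr, hv, "L", seed = pH, noise = FALSE)
    bs <- subtract_background(pair$plus)
    suppressWarnings(fit_peaks(bs$spectrum, centers = hv - tr$sites$be_eV))
  })
  s16 <- chemical_shift(fits[[1]], fits[[2]], "C1")
  expect_equal(s16$shift_eV, 1.12, tolerance = 0.02)
  s613 <- chemical_shift(fits[[2]], fits[[3]], "C2")
  expect_equal(s613$shift_eV, 0.77, tolerance = 0.02)
  # identical fits shift by zero; shifts are additive
  expect_equal(chemical_shift(fits[[1]], fits[[1]], "C1")$shift_eV, 0)
  s113 <- chemical_shift(fits[[1]], fits[[3]], "C1")
  expect_equal(s113$shift_eV,
               chemical_shift(fits[[1]], fits[[2]], "C1")$shift_eV +
                 chemical_shift(fits[[2]], fits[[3]], "C1")$shift_eV,
               tolerance = 1e-12)
})
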