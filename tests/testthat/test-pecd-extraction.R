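# percent difference, b1 estimation, binning, consistency, attenuation

test_that("percent difference matches its closed form", {
  ke <- seq(10, 12, 0.05)
  base <- 1000 + 0 * ke
  a <- pecd_spectrum(ke, base)
  expect_true(all(percent_difference(a, a)$pd == 0))
  # constant asymmetry G = -0.02: I- = I+ (1 + 0.01) / (1 - 0.01)
  g <- -0.02
  b <- pecd_spectrum(ke, base * (1 - g / 2) / (1 + g / 2))
  pd <- percent_difference(a, b)
  expect_equal(pd$pd, rep(100 * g, length(ke)), tolerance = 1e-9)
  # near-zero intensity channels are masked
  lo <- pecd_spectrum(ke, c(rep(0.001, 3), rep(1000, length(ke) - 3)))
  expect_true(anyNA(percent_difference(lo, lo)$pd))
})

test_that("background dilutes the raw percent difference", {
  tr <- test_truth(13)
  hv <- 305
  pair <- generate_pair(tr, hv, "L", seed = 2, noise = FALSE)
  sc <- scale_to_baseline(pair$plus, pair$minus)
  bp <- subtract_background(sc$plus)
  bm <- subtract_background(sc$minus)
  region <- hv - tr$sites$be_eV[1] + c(-0.5, 0.5)
  pd_raw <- percent_difference(sc$plus, sc$minus, region = region)
  pd_sub <- percent_difference(bp$spectrum, bm$spectrum, region = region)
  expect_lt(mean(abs(pd_raw$pd), na.rm = TRUE),
            mean(abs(pd_sub$pd), na.rm = TRUE))
})

test_that("omitting background subtraction strictly shrinks |b1|", {
  tr <- test_truth(13)
  hv <- 305
  geom <- ref_geom()
  shrunk <- logical(20)
  for (i in 1:20) {
    pair <- generate_pair(tr, hv, "L", seed = 100 + i)
    sc <- scale_to_baseline(pair$plus, pair$minus)
    bp <- subtract_background(sc$plus)
    bm <- subtract_background(sc$minus)
    region <- hv - tr$sites$be_eV[1] + c(-0.53, 0.53)  # ~ +/-1 FWHM
    g_raw <- windowed_asymmetry(sc$plus, sc$minus, region)
    g_sub <- windowed_asymmetry(bp$spectrum, bm$spectrum, region)
    b_raw <- b1_from_G(g_raw, geom, 0.5)
    b_sub <- b1_from_G(g_sub, geom, 0.5)
    shrunk[i] <- abs(b_raw) < abs(b_sub)
  }
  expect_true(all(shrunk))
})

test_that("b1 estimation inverts fitted-area asymmetries", {
  mkfit <- function(area, center = 11.75, hv = 305) {
    structure(list(
      peaks = data.frame(site = "C1", center_ke = center, be_eV = hv - center,
                         sigma = 0.45, asym = 0.25, area = area,
                         se_area = 1e-6, se_center = 1e-6),
      vcov = diag(1e-12, 4),
      spectrum = single_emg_spectrum(center = center, area = area * 1e4),
      meta = list(hv_eV = hv, enantiomer = "L", pH = 13)),
      class = "pecd_peakfit")
  }
  # areas (0.99, 1.01) at the backward magic angle: b1 = 0.02 / (2 * 0.57735)
  e <- estimate_b1(mkfit(0.99), mkfit(1.01), "C1", geometry(125.264),
                   beta_assumed = 0)
  expect_equal(e$G, -0.02, tolerance = 1e-12)
  expect_equal(e$b1, 0.017320675, tolerance = 1e-6)
  # equal areas: b1 = 0
  expect_equal(estimate_b1(mkfit(1), mkfit(1), "C1", ref_geom())$b1, 0)
  # non-overlapping peak windows rejected
  expect_error(estimate_b1(mkfit(1), mkfit(1, center = 13.5), "C1",
                           ref_geom()), "do not overlap")
})

test_that("a noise-free pair recovers the effective generator b1", {
  tr <- test_truth(13)
  pair <- generate_pair(tr, 305, "L", seed = 1, noise = FALSE)
  # at zero acceptance the geometry correction is the exact inverse of the
  # generator's point-geometry modulation
  e0 <- pair_b1(pair, geom = geometry(130, 0))
  expect_equal(e0$b1, 0.02, tolerance = 1e-4)
  # with the +/-15 degree acceptance correction the residual mismatch is the
  # (acceptance-averaged vs point) P2 difference, about 0.15%
  e <- pair_b1(pair)
  expect_equal(e$b1, 0.02, tolerance = 3e-3)
})

test_that("kinetic-energy binning combines estimates by inverse variance", {
  one <- data.frame(pair_id = "a", site = "C1", ke = 11.7, b1 = 0.02,
                    sigma_b1 = 0.01, enantiomer = "L", pH = 13, hv_eV = 305)
  b <- bin_b1(one)
  expect_equal(b$b1_mean, 0.02)
  expect_equal(b$combined_sigma, 0.01)
  expect_equal(b$n_pairs, 1L)
  # closed-form weighted mean of (0.02 +/- 0.01) and (0.04 +/- 0.01)
  two <- rbind(one, transform(one, pair_id = "b", b1 = 0.04))
  b2 <- bin_b1(two)
  expect_equal(b2$b1_mean, 0.03)
  expect_equal(b2$combined_sigma, 0.01 / sqrt(2), tolerance = 1e-12)
  # unweighted alternative
  b2u <- bin_b1(two, method = "unweighted")
  expect_equal(b2u$b1_mean, 0.03)
  # half-open bins anchored at zero: 9.10 and 9.30 fall in different bins
  close <- rbind(transform(one, ke = 9.10), transform(one, pair_id = "b", ke = 9.30))
  expect_equal(nrow(bin_b1(close)), 2L)
  expect_equal(sort(bin_b1(close)$bin_center_ke), c(9.0, 9.25))
  # boundary rule: ke = center - width/2 belongs to the bin, + width/2 does not
  expect_equal(bin_b1(transform(one, ke = 9.125))$bin_center_ke, 9.25)
})

test_that("enantiomer consistency validates mirroring and racemic null", {
  set.seed(31)
  truths <- list(`13` = test_truth(13))
  camp <- generate_campaign(truths, hv_eV = 305,
                            enantiomers = c("L", "D", "DL"),
                            replicates = 2, base_seed = 300)
  est <- do.call(rbind, lapply(camp$pairs, pair_b1))
  rep <- enantiomer_consistency(est)
  expect_true(rep$assessable$mirroring)
  expect_true(rep$assessable$racemic)
  expect_true(all(rep$mirroring$pass))
  expect_true(all(rep$racemic$pass))
  # adversarial mislabeling is detected: swap L and DL labels
  bad <- est
  bad$enantiomer[bad$enantiomer == "DL"] <- "tmp"
  bad$enantiomer[bad$enantiomer == "L"] <- "DL"
  bad$enantiomer[bad$enantiomer == "tmp"] <- "L"
  rep_bad <- enantiomer_consistency(bad)
  expect_false(rep_bad$pass)
  # blind mode: labels withheld until the consistency stage
  blind <- est
  blind$enantiomer <- NULL
  labels <- data.frame(pair_id = est$pair_id, enantiomer = est$enantiomer)
  rep_blind <- enantiomer_consistency(blind, labels = labels)
  expect_true(rep_blind$pass)
  expect_error(enantiomer_consistency(blind), "no enantiomer labels")
  # a single-enantiomer campaign cannot assess mirroring
  solo <- enantiomer_consistency(est[est$enantiomer == "L", ])
  expect_false(solo$assessable$mirroring)
})

test_that("the full pipeline is antisymmetric under enantiomer exchange", {
  tr <- test_truth(13)
  eL <- pair_b1(generate_pair(tr, 305, "L", seed = 9, noise = FALSE))
  eD <- pair_b1(generate_pair(tr, 305, "D", seed = 9, noise = FALSE))
  expect_equal(eL$b1, -eD$b1, tolerance = 1e-8)
})

test_that("swapping polarizations is equivalent to swapping enantiomers", {
  tr <- test_truth(13, flux_imbalance = 1)
  pL <- generate_pair(tr, 305, "L", seed = 4, noise = FALSE)
  pD <- generate_pair(tr, 305, "D", seed = 4, noise = FALSE)
  expect_equal(pL$plus$counts, pD$minus$counts, tolerance = 1e-10)
  expect_equal(pL$minus$counts, pD$plus$counts, tolerance = 1e-10)
})

test_that("attenuation back-correction maps onto the pre-scattering interval", {
  expect_equal(attenuation_correct(0.02), c(0.06, 0.10))
  expect_equal(attenuation_correct(0), c(0, 0))
  expect_equal(attenuation_correct(0.02, c(1, 1)), c(0.02, 0.02))
  b <- data.frame(bin_center_ke = 11.75, b1_mean = 0.02,
                  combined_sigma = 0.001, n_pairs = 6)
  bc <- attenuation_correct(b)
  expect_equal(bc$b1_low, 0.06)
  expect_equal(bc$b1_high, 0.10)
  expect_equal(bc$sigma_low, 0.003)
  expect_error(attenuation_correct(0.02, c(0.5, 2)))
})
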