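#' C 1s binding energies of aqueous alanine
#'
#' Reference binding energies (eV) of alanine's three carbon sites — the
#' carboxyl carbon C1, the chiral central carbon C2, and the methyl carbon
#' C3 — for the cationic (pH 1), zwitterionic (pH 6), and anionic (pH 13)
#' forms, as determined from liquid-jet photoemission.
#'
#' @return A data frame with columns `pH`, `C1`, `C2`, `C3` (eV).
#' @export
alanine_be_table <- function() {
  data.frame(pH = c(1, 6, 13),
             C1 = c(294.64, 293.52, 293.25),
             C2 = c(292.12, 291.56, 290.79),
             C3 = c(290.53, 290.19, 289.81))
}

#' Reference C1:C2:C3 peak-area ratios per charge state
#'
#' Measured peak-area ratios normalized to C1 (1 : 1.09 : 1.13 for the
#' cation, 1 : 1.12 : 1.09 for the zwitterion, 1 : 1.23 : 1.07 for the
#' anion). A fully random molecular orientation distribution would give
#' 1 : 1 : 1; deviations reflect partial orientation near the liquid-vapor
#' interface.
#'
#' @param pH one of 1, 6, 13.
#' @return Numeric vector `c(C1, C2, C3)` of relative areas.
#' @export
alanine_area_ratios <- function(pH) {
  ratios <- list(`1` = c(1, 1.09, 1.13),
                 `6` = c(1, 1.12, 1.09),
                 `13` = c(1, 1.23, 1.07))
  key <- as.character(pH)
  if (!key %in% names(ratios)) stop("area ratios tabulated only for pH 1, 6, 13")
  setNames(ratios[[key]], c("C1", "C2", "C3"))
}

#' Binding-energy shift between two charge states, from the reference table
#'
#' @param site `"C1"`, `"C2"`, or `"C3"`.
#' @param pH_from,pH_to charge-state pH labels (1, 6, or 13).
#' @return `BE(pH_from) - BE(pH_to)` in eV; positive when the site shifts
#'   toward lower binding energy going from `pH_from` to `pH_to`.
#' @examples
#' reference_shift("C1", 1, 6)    # 1.12 eV
#' reference_shift("C2", 6, 13)   # 0.77 eV
#' @export
reference_shift <- function(site, pH_from, pH_to) {
  tab <- alanine_be_table()
  stopifnot(site %in% c("C1", "C2", "C3"),
            pH_from %in% tab$pH, pH_to %in% tab$pH)
  tab[tab$pH == pH_from, site] - tab[tab$pH == pH_to, site]
}

#' Ground truth for the synthetic-spectrum generator
#'
#' Defines the study conditions emulated by the forward simulator for one
#' solution charge state: per-carbon binding energies and relative areas
#' (from the reference tables), the true pre-scattering dichroic parameter
#' b1 per site, the assumed anisotropy beta, the in-liquid scattering
#' attenuation divisor applied to b1, the +/- flux imbalance, the
#' inelastic-scattering background parameters, and the lineshape widths.
#'
#' Defaults represent 1 M aqueous alanine: a pre-scattering b1 of 0.08 on C1
#' attenuated by a factor 4 to an effective in-liquid value of 0.02, no
#' detectable dichroism on C2/C3, beta = 0.5 as a conservative upper limit,
#' and a 2% flux imbalance between the two polarization acquisitions.
#'
#' @param pH charge-state label: 1 (cation), 6 (zwitterion), or 13 (anion).
#' @param b1_true named vector of pre-scattering b1 per site.
#' @param beta assumed anisotropy parameter (same for all sites).
#' @param attenuation_factor scattering isotropization divisor on b1, >= 1.
#' @param flux_imbalance multiplicative intensity ratio of the `-` relative
#'   to the `+` acquisition.
#' @param area_C1 integrated C1 intensity per spectrum (counts x eV).
#' @param sigma_eV Gaussian peak width (eV).
#' @param asym EMG asymmetry parameter (tau/sigma).
#' @param background list with `amplitude` (counts/eV at KE = 0), `decay_eV`
#'   (exponential decay constant), `offset` (constant counts/eV).
#' @return An object of class `pecd_truth`.
#' @export
alanine_truth <- function(pH,
                          b1_true = c(C1 = 0.08, C2 = 0, C3 = 0),
                          beta = 0.5,
                          attenuation_factor = 4,
                          flux_imbalance = 1.02,
                          area_C1 = 2e6,
                          sigma_eV = 0.45,
                          asym = 0.25,
                          background = list(amplitude = 6e8,
                                            decay_eV = 2.5, offset = 1e5)) {
  tab <- alanine_be_table()
  if (!pH %in% tab$pH) stop("tabulated truth available only for pH 1, 6, 13")
  stopifnot(attenuation_factor >= 1, flux_imbalance > 0,
            area_C1 > 0, sigma_eV > 0, asym >= 0)
  sites <- data.frame(site = c("C1", "C2", "C3"),
                      be_eV = as.numeric(tab[tab$pH == pH, c("C1", "C2", "C3")]),
                      rel_area = as.numeric(alanine_area_ratios(pH)),
                      b1_true = as.numeric(b1_true[c("C1", "C2", "C3")]),
                      beta = beta)
  structure(list(pH = pH, sites = sites,
                 attenuation_factor = attenuation_factor,
                 flux_imbalance = flux_imbalance,
                 area_C1 = area_C1, sigma_eV = sigma_eV, asym = asym,
                 background = background),
            class = "pecd_truth")
}

#' Inelastically scattered-electron background
#'
#' Smooth background dominating at low kinetic energy, modeling electrons
#' inelastically scattered in the sample bulk: an exponential rise toward
#' low KE plus a constant offset,
#' `amplitude * exp(-ke / decay_eV) + offset` (counts per eV). The background
#' is achiral: the generator applies it identically to both polarizations
#' (up to the flux imbalance).
#'
#' @param grid kinetic energies (eV).
#' @param params list with nonnegative `amplitude`, `decay_eV` (> 0), and
#'   `offset`.
#' @return Background intensity (counts per eV) at each grid point.
#' @export
scattering_background <- function(grid, params) {
  a <- params$amplitude %||% 0
  d <- params$decay_eV %||% 1
  c0 <- params$offset %||% 0
  if (a < 0 || d <= 0 || c0 < 0)
    stop("background parameters must be nonnegative (decay_eV > 0)")
  a * exp(-grid / d) + c0
}

enantiomer_sign <- function(enantiomer) {
  switch(enantiomer, L = 1, D = -1, DL = 0,
         stop("enantiomer must be one of 'L', 'D', 'DL'"))
}

# noise-free model counts for one polarization, in counts per channel
model_counts <- function(truth, grid, hv_eV, enantiomer, p, theta_deg, step) {
  bg <- scattering_background(grid, truth$background)
  dens <- bg
  esign <- enantiomer_sign(enantiomer)
  for (k in seq_len(nrow(truth$sites))) {
    s <- truth$sites[k, ]
    b1_eff <- esign * s$b1_true / truth$attenuation_factor
    coef <- pad_coefficients(b1 = b1_eff, beta = s$beta)
    mod <- pad_intensity(coef, p, theta_deg)
    dens <- dens + truth$area_C1 * s$rel_area * mod *
      emg_profile(grid, center = hv_eV - s$be_eV, sigma = truth$sigma_eV,
                  asym = truth$asym, area = 1, tail = "lower",
                  check_coverage = FALSE)
  }
  dens * step
}

#' Generate a polarization pair of synthetic spectra
#'
#' Forward-simulates the `+` and `-` circular-polarization acquisitions for
#' one (photon energy, enantiomer, charge state) condition. Each carbon's
#' peak area is modulated by the PAD intensity evaluated with the effective
#' in-liquid b1 (`b1_true / attenuation_factor`, sign-flipped for the D
#' enantiomer, zero for racemic DL) and `b2 = -beta/2` at the configured
#' detection angle. The achiral background is identical for both
#' polarizations; the `-` spectrum is scaled by the flux imbalance; Poisson
#' counting noise is applied with the given seed.
#'
#' @param truth a [alanine_truth()] object.
#' @param hv_eV photon energy (eV).
#' @param enantiomer `"L"`, `"D"`, or `"DL"`.
#' @param theta_deg detection angle (degrees from the photon-propagation
#'   axis; 130 = 50 degrees backward).
#' @param seed required integer seed (reproducibility contract).
#' @param noise apply Poisson counting noise?
#' @param ke_step kinetic-energy channel width (eV).
#' @param window optional `c(lo, hi)` KE analysis window; default spans the
#'   outermost peak centers +/- 4.6 eV (at least 8 sigma (1 + asym), so the
#'   grid carries the full EMG mass and the edges are peak-free).
#' @param pair_id optional identifier stored in the metadata.
#' @return A list of class `pecd_pair` with elements `plus` and `minus`
#'   ([pecd_spectrum()] objects). The ground truth travels in
#'   `attr(, "truth")` for test harnesses only.
#' @export
generate_pair <- function(truth, hv_eV, enantiomer = "L", theta_deg = 130,
                          seed, noise = TRUE, ke_step = 0.05, window = NULL,
                          pair_id = NULL) {
  stopifnot(inherits(truth, "pecd_truth"))
  if (missing(seed) || is.null(seed))
    stop("a seed is required: synthetic spectra must be reproducible")
  dom <- dominant_species(truth$pH)
  if (dom$fraction < 0.9)
    warning(sprintf(
      "pH %g is close to a pKa: dominant species holds only %.0f%% of molecules",
      truth$pH, 100 * dom$fraction))
  centers <- hv_eV - truth$sites$be_eV
  if (is.null(window)) window <- c(min(centers) - 4.6, max(centers) + 4.6)
  grid <- seq(window[1L], window[2L], by = ke_step)
  lam_plus <- model_counts(truth, grid, hv_eV, enantiomer, +1, theta_deg, ke_step)
  lam_minus <- model_counts(truth, grid, hv_eV, enantiomer, -1, theta_deg, ke_step) *
    truth$flux_imbalance
  if (noise) {
    set.seed(as.integer(seed))
    cnt_plus <- as.numeric(rpois(length(grid), lam_plus))
    cnt_minus <- as.numeric(rpois(length(grid), lam_minus))
  } else {
    cnt_plus <- lam_plus
    cnt_minus <- lam_minus
  }
  mk <- function(cnt, p) pecd_spectrum(
    grid, cnt,
    meta = list(hv_eV = hv_eV, polarization = p, enantiomer = enantiomer,
                pH = truth$pH, theta_deg = theta_deg, seed = seed,
                pair_id = pair_id %||% NA),
    sigma = sqrt(pmax(cnt, 1)))
  structure(list(plus = mk(cnt_plus, +1), minus = mk(cnt_minus, -1)),
            class = "pecd_pair", truth = truth)
}

#' Generate a measurement campaign of replicate polarization pairs
#'
#' Loops over charge states, enantiomers, photon energies, and replicates,
#' generating one polarization pair per cell with a deterministic
#' per-condition seed (`base_seed + running index`). Optionally writes every
#' spectrum as delimited text plus a truth manifest.
#'
#' @param truths named list of [alanine_truth()] objects, names = pH labels;
#'   a single `pecd_truth` is promoted to a one-element list.
#' @param hv_eV photon energies (eV).
#' @param enantiomers subset of `c("L", "D", "DL")`.
#' @param replicates number of replicate pairs per condition, >= 1.
#' @param base_seed integer; seeds are `base_seed + 1, base_seed + 2, ...`.
#' @param theta_deg detection angle (degrees).
#' @param noise apply Poisson noise?
#' @param outdir if non-`NULL`, write spectra and `manifest.yaml` there.
#' @inheritParams generate_pair
#' @return A list of class `pecd_campaign` with `pairs` (named list of
#'   `pecd_pair`), `manifest` (data frame: pair_id, pH, enantiomer, hv_eV,
#'   replicate, seed), and `truths`.
#' @export
generate_campaign <- function(truths, hv_eV, enantiomers = "L",
                              replicates = 1, base_seed = 1, theta_deg = 130,
                              noise = TRUE, ke_step = 0.05, outdir = NULL) {
  if (inherits(truths, "pecd_truth"))
    truths <- setNames(list(truths), as.character(truths$pH))
  stopifnot(replicates >= 1, length(truths) >= 1)
  pairs <- list()
  rows <- list()
  i <- 0L
  for (pH in names(truths)) {
    for (en in enantiomers) {
      for (hv in hv_eV) {
        for (r in seq_len(replicates)) {
          i <- i + 1L
          seed <- as.integer(base_seed + i)
          pid <- sprintf("pH%s_%s_hv%07.2f_r%02d", pH, en, hv, r)
          pairs[[pid]] <- generate_pair(truths[[pH]], hv, en, theta_deg,
                                        seed = seed, noise = noise,
                                        ke_step = ke_step, pair_id = pid)
          rows[[i]] <- data.frame(pair_id = pid, pH = as.numeric(pH),
                                  enantiomer = en, hv_eV = hv,
                                  replicate = r, seed = seed)
        }
      }
    }
  }
  camp <- structure(list(pairs = pairs, manifest = do.call(rbind, rows),
                         truths = truths),
                    class = "pecd_campaign")
  if (!is.null(outdir)) write_campaign(camp, outdir)
  camp
}

#' Write a campaign to disk
#'
#' One text file per spectrum (`<pair_id>_p+1.dat`, `<pair_id>_p-1.dat`) plus
#' a `manifest.yaml` recording the pair table and the generator ground truth.
#'
#' @param campaign a `pecd_campaign`.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_campaign <- function(campaign, outdir) {
  stopifnot(inherits(campaign, "pecd_campaign"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (pid in names(campaign$pairs)) {
    pr <- campaign$pairs[[pid]]
    write_spectrum(pr$plus, file.path(outdir, paste0(pid, "_p+1.dat")))
    write_spectrum(pr$minus, file.path(outdir, paste0(pid, "_p-1.dat")))
  }
  truths <- lapply(campaign$truths, function(tr) {
    u <- unclass(tr)
    u$sites <- as.list(u$sites)
    u
  })
  yaml::write_yaml(list(manifest = as.list(campaign$manifest), truth = truths),
                   file.path(outdir, "manifest.yaml"))
  invisible(outdir)
}

#' Read a campaign written by [write_campaign()]
#'
#' @param datadir directory holding spectrum files and `manifest.yaml`.
#' @return A `pecd_campaign` (truth restored from the manifest).
#' @export
read_campaign <- function(datadir) {
  mf <- file.path(datadir, "manifest.yaml")
  if (!file.exists(mf)) stop("no manifest.yaml found in ", datadir)
  y <- yaml::read_yaml(mf)
  manifest <- as.data.frame(y$manifest, stringsAsFactors = FALSE)
  truths <- lapply(y$truth, function(u) {
    u$sites <- as.data.frame(u$sites, stringsAsFactors = FALSE)
    class(u) <- "pecd_truth"
    u
  })
  pairs <- list()
  for (pid in manifest$pair_id) {
    plus <- read_spectrum(file.path(datadir, paste0(pid, "_p+1.dat")))
    minus <- read_spectrum(file.path(datadir, paste0(pid, "_p-1.dat")))
    pairs[[pid]] <- structure(list(plus = plus, minus = minus),
                              class = "pecd_pair",
                              truth = truths[[as.character(plus$meta$pH)]])
  }
  structure(list(pairs = pairs, manifest = manifest, truths = truths),
            class = "pecd_campaign")
}
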