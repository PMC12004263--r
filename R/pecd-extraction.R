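#' Percent-difference curve of a polarization pair
#'
#' Pointwise `100 * (I+ - I-) / ((I+ + I-)/2)` over a kinetic-energy region,
#' for a baseline-scaled, grid-aligned pair. Channels whose average intensity
#' falls below `min_frac` of the regional maximum are masked (`NA`) to avoid
#' division by near-zero intensity. Computed on raw spectra the curve is
#' diluted by the achiral background in the denominator; on
#' background-subtracted spectra it reveals the full asymmetry.
#'
#' @param spec_plus,spec_minus scaled [pecd_spectrum()] objects on a common
#'   grid.
#' @param region optional `c(lo, hi)` KE window (eV).
#' @param min_frac masking threshold as a fraction of the maximum average
#'   intensity in the region.
#' @return Data frame with `ke` and `pd` (percent).
#' @export
percent_difference <- function(spec_plus, spec_minus, region = NULL,
                               min_frac = 0.02) {
  rs <- resample_to_common_grid(spec_plus, spec_minus)
  ke <- rs$a$ke
  keep <- if (is.null(region)) rep(TRUE, length(ke)) else
    ke >= region[1L] & ke <= region[2L]
  ke <- ke[keep]
  ip <- rs$a$counts[keep]
  im <- rs$b$counts[keep]
  avg <- (ip + im) / 2
  pd <- 100 * (ip - im) / avg
  pd[abs(avg) < min_frac * max(abs(avg))] <- NA_real_
  data.frame(ke = ke, pd = pd)
}

#' Polarization-summed spectrum
#'
#' The channel-wise average `(I+ + I-)/2` of a baseline-scaled pair. The
#' odd (P1, dichroic) terms of the angular distribution cancel exactly in
#' this combination, so peak areas fitted on the summed spectrum estimate
#' the intrinsic (polarization-free) relative areas.
#'
#' @param spec_plus,spec_minus scaled [pecd_spectrum()] objects on a common
#'   grid.
#' @return A [pecd_spectrum()] with averaged counts and propagated
#'   uncertainties.
#' @export
polarization_sum <- function(spec_plus, spec_minus) {
  rs <- resample_to_common_grid(spec_plus, spec_minus)
  sgp <- rs$a$sigma %||% sqrt(pmax(rs$a$counts, 1))
  sgm <- rs$b$sigma %||% sqrt(pmax(rs$b$counts, 1))
  meta <- rs$a$meta
  meta$polarization <- 0
  pecd_spectrum(rs$a$ke, (rs$a$counts + rs$b$counts) / 2, meta = meta,
                sigma = sqrt(sgp^2 + sgm^2) / 2, nonneg = FALSE)
}

#' Window-integrated asymmetry factor
#'
#' The asymmetry `G = (S+ - S-) / ((S+ + S-)/2)` of trapezoid-integrated
#' counts over a kinetic-energy window. Used to demonstrate the
#' background-dilution bias: evaluated on unsubtracted spectra the achiral
#' background inflates the denominator and shrinks `|G|`.
#'
#' @inheritParams percent_difference
#' @param region `c(lo, hi)` KE integration window (eV).
#' @return The scalar asymmetry factor.
#' @export
windowed_asymmetry <- function(spec_plus, spec_minus, region) {
  rs <- resample_to_common_grid(spec_plus, spec_minus)
  m <- rs$a$ke >= region[1L] & rs$a$ke <= region[2L]
  if (!any(m)) stop("integration window contains no grid points")
  sp <- trapz(rs$a$ke[m], rs$a$counts[m])
  sm <- trapz(rs$b$ke[m], rs$b$counts[m])
  if (sp + sm <= 0) stop("zero average intensity in window")
  (sp - sm) / ((sp + sm) / 2)
}

#' Estimate b1 for one carbon site from a fitted polarization pair
#'
#' Forms the asymmetry factor from the background-subtracted fitted peak
#' areas, `G = (A+ - A-) / ((A+ + A-)/2)`, and inverts it with
#' [b1_from_G()] at the configured geometry including the acceptance-averaged
#' residual-b2 correction.
#'
#' Two uncertainty conventions are available. `"fit"` (default) propagates
#' the fitted area uncertainties through the G-to-b1 map, yielding a
#' calibrated 1-sigma interval. `"percent_diff"` uses the standard deviation
#' of the percent-difference curve within +/-1 FWHM of the peak — the
#' spread shown as error bars in conventional presentations of such data;
#' it reflects per-channel noise and is deliberately conservative for an
#' area-integrated estimate. The percent-difference spread is reported as a
#' diagnostic (`pd_sd`) in either mode.
#'
#' @param fit_plus,fit_minus `pecd_peakfit` objects for the `+` and `-`
#'   spectra of one scaled pair.
#' @param site peak label (`"C1"`, ...).
#' @param geom a [geometry()] object.
#' @param beta_assumed anisotropy assumed for the residual-b2 correction.
#' @param sigma_convention `"fit"` or `"percent_diff"`.
#' @param pair_id optional identifier (taken from metadata when absent).
#' @return One-row data frame with `pair_id`, `site`, `ke` (fitted peak KE),
#'   `b1`, `sigma_b1`, `G`, `sigma_G`, `pd_sd`, `enantiomer`, `pH`, `hv_eV`.
#' @export
estimate_b1 <- function(fit_plus, fit_minus, site = "C1", geom,
                        beta_assumed = 0.5,
                        sigma_convention = c("fit", "percent_diff"),
                        pair_id = NULL) {
  stopifnot(inherits(fit_plus, "pecd_peakfit"),
            inherits(fit_minus, "pecd_peakfit"),
            inherits(geom, "pecd_geometry"))
  sigma_convention <- match.arg(sigma_convention)
  pp <- fit_plus$peaks[fit_plus$peaks$site == site, ]
  pm <- fit_minus$peaks[fit_minus$peaks$site == site, ]
  if (nrow(pp) != 1L || nrow(pm) != 1L) stop("site ", site, " missing from fit")
  fwhm <- 2.3548 * (pp$sigma + pm$sigma) / 2
  if (abs(pp$center_ke - pm$center_ke) > fwhm)
    stop("peak windows of the two polarizations do not overlap")
  Ap <- pp$area; Am <- pm$area
  S <- Ap + Am
  if (S <= 0) stop("zero average area; asymmetry undefined")
  G <- 2 * (Ap - Am) / S
  sigma_G_fit <- 4 * sqrt(Am^2 * pp$se_area^2 + Ap^2 * pm$se_area^2) / S^2
  # the baseline-normalization factor multiplies the whole minus spectrum;
  # its shot-noise uncertainty (recorded by scale_to_baseline) enters G as
  # dG/dln(Am) = -4 Ap Am / S^2
  scale_rel <- fit_minus$meta$scale_rel_sigma %||% 0
  sigma_G_fit <- sqrt(sigma_G_fit^2 + (4 * Ap * Am / S^2 * scale_rel)^2)
  ke0 <- (pp$center_ke + pm$center_ke) / 2
  pd_spec <- function(fit) {
    s <- fit$spectrum
    if (!is.null(fit$background))
      s <- pecd_spectrum(s$ke, s$counts - fit$background, meta = s$meta,
                         sigma = s$sigma, nonneg = FALSE)
    s
  }
  pd <- percent_difference(pd_spec(fit_plus), pd_spec(fit_minus),
                           region = c(ke0 - fwhm, ke0 + fwhm))
  pd_sd <- sd(pd$pd, na.rm = TRUE)
  sigma_G <- if (sigma_convention == "fit") sigma_G_fit else pd_sd / 100
  slope <- abs(b2_correction_factor(beta_assumed, geom) /
                 (2 * cos(geom$theta_deg * pi / 180)))
  meta <- fit_plus$meta %||% list()
  data.frame(pair_id = pair_id %||% (meta$pair_id %||% NA_character_),
             site = site, ke = ke0,
             b1 = b1_from_G(G, geom, beta_assumed),
             sigma_b1 = sigma_G * slope,
             G = G, sigma_G = sigma_G, pd_sd = pd_sd,
             enantiomer = meta$enantiomer %||% NA_character_,
             pH = meta$pH %||% NA_real_,
             hv_eV = meta$hv_eV %||% NA_real_)
}

b1_bin_center <- function(ke, width) floor(ke / width + 0.5) * width

#' Bin b1 estimates in kinetic energy
#'
#' Averages per-pair b1 estimates within kinetic-energy windows (default
#' 250 meV) on a bin grid anchored at 0 eV with half-open intervals
#' `[center - width/2, center + width/2)`. The default combiner is the
#' inverse-variance weighted mean with combined uncertainty
#' `1/sqrt(sum(1/sigma_i^2))`; an unweighted mean is selectable.
#'
#' @param estimates data frame of [estimate_b1()] rows.
#' @param width bin width in eV.
#' @param method `"ivw"` (inverse-variance weighted) or `"unweighted"`.
#' @param by grouping columns kept separate across bins (defaults to
#'   whichever of `site`, `enantiomer`, `pH` are present).
#' @return Data frame with the grouping columns, `bin_center_ke`, `b1_mean`,
#'   `combined_sigma`, `n_pairs`.
#' @export
bin_b1 <- function(estimates, width = 0.25, method = c("ivw", "unweighted"),
                   by = NULL) {
  method <- match.arg(method)
  stopifnot(nrow(estimates) >= 1L, all(estimates$sigma_b1 > 0))
  if (is.null(by))
    by <- intersect(c("site", "enantiomer", "pH"), names(estimates))
  estimates$bin_center_ke <- b1_bin_center(estimates$ke, width)
  keys <- c(by, "bin_center_ke")
  split_idx <- split(seq_len(nrow(estimates)),
                     interaction(estimates[keys], drop = TRUE, lex.order = TRUE))
  rows <- lapply(split_idx, function(ix) {
    e <- estimates[ix, ]
    if (method == "ivw") {
      wt <- 1 / e$sigma_b1^2
      mu <- sum(wt * e$b1) / sum(wt)
      sg <- 1 / sqrt(sum(wt))
    } else {
      mu <- mean(e$b1)
      sg <- sqrt(sum(e$sigma_b1^2)) / length(ix)
    }
    cbind(e[1L, keys, drop = FALSE],
          data.frame(b1_mean = mu, combined_sigma = sg, n_pairs = length(ix)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$bin_center_ke), , drop = FALSE]
}

#' Enantiomer-consistency report
#'
#' Validates the molecular origin of the measured asymmetry: within each
#' matched (site, pH, kinetic-energy bin) cell, the D- and L-enantiomer
#' estimates must mirror (`b1(D) + b1(L) = 0` within combined
#' uncertainties) and racemic DL estimates must be consistent with zero.
#'
#' Supports blind analysis: pass estimates computed without enantiomer
#' labels and supply `labels` (a `pair_id` to enantiomer lookup) to unblind
#' only at the consistency-test stage.
#'
#' @param estimates data frame of [estimate_b1()] rows.
#' @param width kinetic-energy bin width (eV).
#' @param labels optional data frame with columns `pair_id`, `enantiomer`
#'   used to (re)assign labels after blind processing.
#' @param k significance multiple on the combined sigma (default 2).
#' @return An object of class `pecd_consistency`: list with `mirroring` and
#'   `racemic` data frames (per matched cell: values, combined sigma, pass),
#'   `assessable` flags, and overall `pass`.
#' @export
enantiomer_consistency <- function(estimates, width = 0.25, labels = NULL,
                                   k = 2) {
  if (!is.null(labels)) {
    estimates$enantiomer <- labels$enantiomer[
      match(estimates$pair_id, labels$pair_id)]
  }
  if (!"enantiomer" %in% names(estimates) || anyNA(estimates$enantiomer))
    stop("estimates carry no enantiomer labels; supply `labels` to unblind")
  binned <- bin_b1(estimates, width = width,
                   by = intersect(c("site", "pH", "enantiomer"),
                                  names(estimates)))
  keys <- intersect(c("site", "pH", "bin_center_ke"), names(binned))
  cells <- unique(binned[keys])
  mir <- list(); rac <- list()
  for (i in seq_len(nrow(cells))) {
    sel <- binned
    for (kk in keys) sel <- sel[sel[[kk]] == cells[[kk]][i], ]
    dd <- sel[sel$enantiomer == "D", ]
    ll <- sel[sel$enantiomer == "L", ]
    rr <- sel[sel$enantiomer == "DL", ]
    if (nrow(dd) == 1L && nrow(ll) == 1L) {
      s <- sqrt(dd$combined_sigma^2 + ll$combined_sigma^2)
      mir[[length(mir) + 1L]] <- cbind(
        cells[i, , drop = FALSE],
        data.frame(sum_b1 = dd$b1_mean + ll$b1_mean, sigma = s,
                   pass = abs(dd$b1_mean + ll$b1_mean) < k * s))
    }
    if (nrow(rr) == 1L) {
      rac[[length(rac) + 1L]] <- cbind(
        cells[i, , drop = FALSE],
        data.frame(b1 = rr$b1_mean, sigma = rr$combined_sigma,
                   pass = abs(rr$b1_mean) < k * rr$combined_sigma))
    }
  }
  mirroring <- if (length(mir)) do.call(rbind, mir) else NULL
  racemic <- if (length(rac)) do.call(rbind, rac) else NULL
  assessable <- list(mirroring = !is.null(mirroring),
                     racemic = !is.null(racemic))
  pass <- (!assessable$mirroring || all(mirroring$pass)) &&
    (!assessable$racemic || all(racemic$pass))
  structure(list(mirroring = mirroring, racemic = racemic,
                 assessable = assessable, pass = pass, k = k),
            class = "pecd_consistency")
}

#' @export
print.pecd_consistency <- function(x, ...) {
  cat("Enantiomer-consistency report\n")
  if (x$assessable$mirroring) {
    cat(sprintf("  D/L mirroring: %d matched cells, %d pass (|b1(D)+b1(L)| < %g sigma)\n",
                nrow(x$mirroring), sum(x$mirroring$pass), x$k))
  } else cat("  D/L mirroring: not assessable (need both enantiomers)\n")
  if (x$assessable$racemic) {
    cat(sprintf("  racemic null:  %d cells, %d pass (|b1(DL)| < %g sigma)\n",
                nrow(x$racemic), sum(x$racemic$pass), x$k))
  } else cat("  racemic null:  not assessable (no DL data)\n")
  cat(sprintf("  overall: %s\n", if (isTRUE(x$pass)) "PASS" else "FAIL"))
  invisible(x)
}

#' Back-correct binned b1 for in-liquid scattering attenuation
#'
#' Elastic and quasi-elastic electron scattering in the liquid isotropizes
#' the photoelectron angular distribution, attenuating the measured |b1| by
#' an estimated factor of 3-5. This maps measured values onto the implied
#' pre-scattering interval `[b1 * fmin, b1 * fmax]` with uncertainties scaled
#' accordingly.
#'
#' @param binned data frame from [bin_b1()], or a single numeric b1 value.
#' @param factor_range `c(fmin, fmax)` attenuation factors, each >= 1.
#' @return For a data frame input: the input plus `b1_low`, `b1_high`,
#'   `sigma_low`, `sigma_high`. For a numeric input: `c(low, high)`.
#' @examples
#' attenuation_correct(0.02)  # c(0.06, 0.10)
#' @export
attenuation_correct <- function(binned, factor_range = c(3, 5)) {
  stopifnot(length(factor_range) == 2L, all(factor_range >= 1),
            factor_range[1L] <= factor_range[2L])
  if (is.numeric(binned)) {
    return(sort(binned * factor_range))
  }
  stopifnot(is.data.frame(binned))
  iv <- t(vapply(binned$b1_mean, function(b) sort(b * factor_range),
                 numeric(2L)))
  binned$b1_low <- iv[, 1L]
  binned$b1_high <- iv[, 2L]
  binned$sigma_low <- binned$combined_sigma * factor_range[1L]
  binned$sigma_high <- binned$combined_sigma * factor_range[2L]
  binned
}
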