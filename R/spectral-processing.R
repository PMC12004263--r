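#' Default achiral edge windows of the analysis range
#'
#' The outer fraction of the kinetic-energy window on each side, where only
#' the scattered-electron background contributes.
#'
#' @param spec a [pecd_spectrum()].
#' @param frac fraction of the analysis window per edge.
#' @return List with `low` and `high`, each `c(lo, hi)` in eV.
#' @export
default_edge_windows <- function(spec, frac = 0.15) {
  stopifnot(frac > 0, frac < 0.5)
  r <- range(spec$ke)
  span <- diff(r)
  list(low = c(r[1L], r[1L] + frac * span),
       high = c(r[2L] - frac * span, r[2L]))
}

edge_mask <- function(ke, edges) {
  (ke >= edges$low[1L] & ke <= edges$low[2L]) |
    (ke >= edges$high[1L] & ke <= edges$high[2L])
}

check_edges_clear <- function(edges, peak_centers, peak_halfwidth) {
  if (is.null(peak_centers)) return(invisible(TRUE))
  for (w in edges) {
    bad <- peak_centers + peak_halfwidth > w[1L] &
      peak_centers - peak_halfwidth < w[2L]
    if (any(bad))
      stop(sprintf(
        "edge window [%.2f, %.2f] eV overlaps a peak region (center %.2f eV)",
        w[1L], w[2L], peak_centers[which(bad)[1L]]))
  }
  invisible(TRUE)
}

#' Scale a polarization pair to a common achiral baseline
#'
#' The photon fluxes of the two circular-polarization acquisitions differ by
#' a small persistent amount (typically 1-3%). Because the scattered-electron
#' background is achiral, the pair can be normalized by a single
#' multiplicative factor on the `-` spectrum chosen so that its mean
#' intensity over the union of the low- and high-KE edge windows (where only
#' background is present) matches the `+` spectrum.
#'
#' @param spec_plus,spec_minus the `+` and `-` [pecd_spectrum()] objects
#'   (resampled to a common grid if necessary).
#' @param edges edge windows as from [default_edge_windows()]; `NULL` for the
#'   default outer `frac` of the window.
#' @param frac edge fraction used when `edges` is `NULL`.
#' @param peak_centers optional known peak centers (eV KE); an error is
#'   raised if any falls within `peak_halfwidth` of an edge window.
#' @param peak_halfwidth clearance half-width around peak centers (eV).
#' @return List with `plus`, `minus` (scaled), `factor` (applied to the `-`
#'   spectrum), and `edges`.
#' @export
scale_to_baseline <- function(spec_plus, spec_minus, edges = NULL,
                              frac = 0.15, peak_centers = NULL,
                              peak_halfwidth = 1.5) {
  rs <- resample_to_common_grid(spec_plus, spec_minus)
  spec_plus <- rs$a; spec_minus <- rs$b
  if (is.null(edges)) edges <- default_edge_windows(spec_plus, frac)
  check_edges_clear(edges, peak_centers, peak_halfwidth)
  m <- edge_mask(spec_plus$ke, edges)
  if (!any(m)) stop("edge windows contain no grid points")
  mp <- mean(spec_plus$counts[m])
  mm <- mean(spec_minus$counts[m])
  if (mp <= 0 || mm <= 0) stop("zero intensity in edge windows; cannot scale")
  factor <- mp / mm
  # shot-noise uncertainty of the factor, from the edge-window means; this
  # normalization error multiplies the whole minus spectrum and must be
  # carried into downstream asymmetry uncertainties
  sgp <- spec_plus$sigma %||% sqrt(pmax(spec_plus$counts, 1))
  sgm <- spec_minus$sigma %||% sqrt(pmax(spec_minus$counts, 1))
  rel <- sqrt(sum(sgp[m]^2) / (sum(m)^2 * mp^2) +
                sum(sgm[m]^2) / (sum(m)^2 * mm^2))
  minus <- scale_spectrum(spec_minus, factor)
  minus$meta$scale_rel_sigma <- rel
  list(plus = spec_plus, minus = minus,
       factor = factor, factor_rel_sigma = rel, edges = edges)
}

#' Subtract the scattered-electron background
#'
#' Fits a smooth background model to the two achiral edge windows only and
#' interpolates it beneath the peak complex. The default model is the
#' exponential-plus-constant family used by the generator
#' (`A exp(-ke/decay) + offset`); `"linear"` and `"spline"` alternatives are
#' selectable.
#'
#' @param spec a [pecd_spectrum()].
#' @param model background family.
#' @param edges,frac as in [scale_to_baseline()].
#' @param peak_centers,peak_halfwidth as in [scale_to_baseline()].
#' @return List of class `pecd_bgsub` with `spectrum` (background-subtracted;
#'   may contain negative counts), `background` (the fitted curve),
#'   `raw` (the input spectrum), `model`, `params`, `edges`, and
#'   `chi2_dof` (reduced chi-square of the fit over the edge windows, using
#'   shot-noise uncertainties).
#' @export
subtract_background <- function(spec, model = c("exp_const", "linear", "spline"),
                                edges = NULL, frac = 0.15,
                                peak_centers = NULL, peak_halfwidth = 1.5) {
  stopifnot(inherits(spec, "pecd_spectrum"))
  model <- match.arg(model)
  if (is.null(edges)) edges <- default_edge_windows(spec, frac)
  check_edges_clear(edges, peak_centers, peak_halfwidth)
  m <- edge_mask(spec$ke, edges)
  if (sum(m) < 6L) stop("too few grid points in edge windows")
  x <- spec$ke[m]; y <- spec$counts[m]
  params <- NULL
  if (model == "exp_const") {
    x0 <- min(spec$ke)
    lo_m <- mean(y[x <= edges$low[2L]]); xl <- mean(x[x <= edges$low[2L]])
    hi_m <- mean(y[x >= edges$high[1L]]); xh <- mean(x[x >= edges$high[1L]])
    off0 <- max(0.5 * min(y), 0)
    ratio <- max((lo_m - off0) / max(hi_m - off0, 1e-9), 1.001)
    d0 <- min(max((xh - xl) / log(ratio), 0.3), 30)
    a0 <- max(lo_m - off0, 1e-6) / exp(-(xl - x0) / d0)
    fitfun <- function(p) p[1L] * exp(-(x - x0) / p[2L]) + p[3L] - y
    fit <- minpack.lm::nls.lm(par = c(a0, d0, off0), fn = fitfun,
                              lower = c(0, 0.05, 0), upper = c(Inf, 100, Inf),
                              control = minpack.lm::nls.lm.control(maxiter = 200))
    p <- fit$par
    bg <- p[1L] * exp(-(spec$ke - x0) / p[2L]) + p[3L]
    params <- list(amplitude = p[1L], decay_eV = p[2L], offset = p[3L],
                   ke_ref = x0)
  } else if (model == "linear") {
    fit <- lm(y ~ x)
    bg <- as.numeric(predict(fit, newdata = data.frame(x = spec$ke)))
    params <- as.list(coef(fit))
  } else {
    fit <- smooth.spline(x, y, df = min(6, length(unique(x)) - 1))
    bg <- as.numeric(predict(fit, spec$ke)$y)
    params <- list(df = fit$df)
  }
  if (any(bg < 0)) stop("fitted background goes negative; model unsuitable")
  sg <- spec$sigma %||% sqrt(pmax(spec$counts, 1))
  chi2 <- sum(((spec$counts[m] - bg[m]) / sg[m])^2) / max(sum(m) - 3L, 1L)
  sub <- pecd_spectrum(spec$ke, spec$counts - bg, meta = spec$meta,
                       sigma = sg, nonneg = FALSE)
  structure(list(spectrum = sub, background = bg, raw = spec, model = model,
                 params = params, edges = edges, chi2_dof = chi2),
            class = "pecd_bgsub")
}

fit_constraint_defaults <- function(constraints = list()) {
  modifyList(list(asym_bounds = c(0.2, 0.3),
                  sigma_bounds = c(0.15, 1.2),
                  sigma_start = 0.45,
                  asym_start = 0.25,
                  center_window = 0.3,
                  width_ratio = 0.05), constraints)
}

# seed peak centers from local maxima of the lightly smoothed spectrum
auto_centers <- function(spec, n_peaks, min_sep = 0.5) {
  k <- 5L
  sm <- stats::filter(spec$counts, rep(1 / k, k), sides = 2)
  sm[is.na(sm)] <- spec$counts[is.na(sm)]
  n <- length(sm)
  is_max <- c(FALSE, sm[2:(n - 1)] > sm[1:(n - 2)] & sm[2:(n - 1)] >= sm[3:n], FALSE)
  cand <- order(sm, decreasing = TRUE)
  cand <- cand[is_max[cand]]
  picked <- numeric(0)
  for (i in cand) {
    ke <- spec$ke[i]
    if (all(abs(ke - picked) >= min_sep)) picked <- c(picked, ke)
    if (length(picked) == n_peaks) break
  }
  if (length(picked) < n_peaks)
    stop("could not auto-seed ", n_peaks, " peak centers; supply centers")
  sort(picked)
}

# model counts for a parameter matrix (rows = peaks): area, center, sigma, asym
emg_sum_counts <- function(ke, step, pmat) {
  out <- numeric(length(ke))
  for (i in seq_len(nrow(pmat)))
    out <- out + emg_profile(ke, pmat[i, 2L], pmat[i, 3L], pmat[i, 4L],
                             area = pmat[i, 1L], tail = "lower",
                             check_coverage = FALSE)
  out * step
}

warn_overlap <- function(peaks) {
  if (nrow(peaks) < 2L) return(invisible())
  pk <- peaks[order(peaks$center_ke), ]
  for (i in seq_len(nrow(pk) - 1L)) {
    gap <- pk$center_ke[i + 1L] - pk$center_ke[i]
    lim <- 0.5 * 2.3548 * (pk$sigma[i] + pk$sigma[i + 1L]) / 2 * 2  # (FWHM_i+FWHM_j)/2
    if (gap < lim)
      warning(sprintf(
        "substantial overlap of peaks %s and %s (separation %.2f eV < %.2f eV); areas may be degenerate",
        pk$site[i], pk$site[i + 1L], gap, lim))
  }
  invisible()
}

#' Fit a sum of constrained EMG peaks to a background-subtracted spectrum
#'
#' Weighted least squares (Levenberg-Marquardt with box constraints) of
#' `n_peaks` exponentially modified Gaussians. The EMG asymmetry parameter is
#' bounded to the conventional 0.2-0.3 range; peak centers are confined to a
#' window around their initial values. Weights are the spectrum's shot-noise
#' uncertainties when available. Parameter covariances come from the
#' Jacobian at the optimum (unscaled when true count uncertainties are
#' supplied, residual-variance scaled otherwise).
#'
#' Peaks are labeled `C1, C2, C3, ...` in order of increasing kinetic energy,
#' i.e. decreasing binding energy precedence (the carboxyl carbon C1 has the
#' highest binding energy, hence the lowest kinetic energy).
#'
#' @param spec a background-subtracted [pecd_spectrum()] (e.g.
#'   `subtract_background(...)$spectrum`), or — with
#'   `background = "exp_const"` — the raw spectrum, in which case the
#'   background parameters are refined jointly with the peaks so that their
#'   uncertainty propagates into the area covariances.
#' @param n_peaks number of peaks.
#' @param centers initial peak centers in eV KE; `NULL` to auto-seed from
#'   local maxima.
#' @param constraints list overriding any of `asym_bounds`, `sigma_bounds`,
#'   `sigma_start`, `asym_start`, `center_window`.
#' @param background `"none"` (peaks only) or `"exp_const"` (append an
#'   exponential-plus-constant background to the model).
#' @param bg_start starting background parameters (list with `amplitude`,
#'   `decay_eV`, `offset`, optional `ke_ref`), e.g. the `params` of a prior
#'   [subtract_background()] fit.
#' @return An object of class `pecd_peakfit`: list with `peaks` (data frame:
#'   site, center_ke, be_eV, sigma, asym, area and 1-sigma uncertainties),
#'   `vcov` (full parameter covariance, order area/center/sigma/asym per
#'   peak, then any background parameters), `redchi`, `converged`,
#'   `model` (fitted counts), `background` (fitted background counts, or
#'   `NULL`), `spectrum`.
#' @export
fit_peaks <- function(spec, n_peaks = 3, centers = NULL, constraints = list(),
                      background = c("none", "exp_const"), bg_start = NULL) {
  stopifnot(inherits(spec, "pecd_spectrum"))
  background <- match.arg(background)
  cs <- fit_constraint_defaults(constraints)
  if (is.null(centers)) centers <- auto_centers(spec, n_peaks)
  stopifnot(length(centers) == n_peaks)
  centers <- sort(centers)
  step <- ke_step(spec)
  have_sigma <- !is.null(spec$sigma)
  w <- if (have_sigma) 1 / pmax(spec$sigma, 1e-9) else rep(1, length(spec$ke))

  # counts are per channel, so their plain sum estimates the area in counts.eV
  area0 <- vapply(centers, function(ck) {
    m <- abs(spec$ke - ck) <= 1
    max(sum(pmax(spec$counts[m], 0)), 1e-3)
  }, numeric(1L))
  par0 <- as.numeric(t(cbind(area0, centers, cs$sigma_start, cs$asym_start)))
  lower <- as.numeric(t(cbind(0, centers - cs$center_window,
                              cs$sigma_bounds[1L], cs$asym_bounds[1L])))
  upper <- as.numeric(t(cbind(Inf, centers + cs$center_window,
                              cs$sigma_bounds[2L], cs$asym_bounds[2L])))
  np_peak <- length(par0)
  ke_ref <- min(spec$ke)
  if (background == "exp_const") {
    b0 <- bg_start %||% list(amplitude = max(spec$counts[1L], 1),
                             decay_eV = 2.5, offset = 0)
    if (!is.null(b0$ke_ref) && abs(b0$ke_ref - ke_ref) > 1e-9)
      b0$amplitude <- b0$amplitude * exp((b0$ke_ref - ke_ref) / b0$decay_eV)
    par0 <- c(par0, b0$amplitude, b0$decay_eV, b0$offset)
    lower <- c(lower, 0, 0.05, 0)
    upper <- c(upper, Inf, 100, Inf)
  }
  bg_counts <- function(p) {
    if (background == "none") return(0)
    b <- p[np_peak + 1:3]
    (b[1L] * exp(-(spec$ke - ke_ref) / b[2L]) + b[3L]) * step
  }
  resid_fn <- function(p) {
    pmat <- matrix(p[seq_len(np_peak)], ncol = 4L, byrow = TRUE)
    (emg_sum_counts(spec$ke, step, pmat) + bg_counts(p) - spec$counts) * w
  }
  ctrl <- minpack.lm::nls.lm.control(maxiter = 300, maxfev = 100000,
                                     ftol = 1e-8, ptol = 1e-8)
  start <- par0
  dev_prev <- Inf
  for (attempt in 1:3) {
    fit <- suppressWarnings(
      minpack.lm::nls.lm(par = start, fn = resid_fn, lower = lower,
                         upper = upper, control = ctrl))
    if (fit$info %in% 1:4) break
    # iteration budget hit: restart from the current point with a fresh
    # trust region, which typically escapes a collapsed step size; a
    # parameter pinned at a bound can cycle without ever meeting ftol
    if (is.finite(dev_prev) &&
        abs(dev_prev - fit$deviance) <= 1e-8 * max(fit$deviance, 1)) {
      warning("peak fit stopped at the iteration limit with stable deviance; ",
              "a parameter is likely pinned at a constraint bound")
      break
    }
    dev_prev <- fit$deviance
    start <- fit$par
  }
  if (!fit$info %in% 1:4 &&
      !(is.finite(dev_prev) &&
        abs(dev_prev - fit$deviance) <= 1e-8 * max(fit$deviance, 1)))
    stop("peak fit did not converge: ", fit$message)
  p <- fit$par
  npar <- length(p)
  dof <- max(length(spec$ke) - npar, 1L)
  redchi <- fit$deviance / dof
  vc <- safe_vcov(crossprod(num_jacobian(resid_fn, p)))
  if (!have_sigma) vc <- vc * redchi
  se <- suppressWarnings(sqrt(pmax(diag(vc), 0)))
  pmat <- matrix(p[seq_len(np_peak)], ncol = 4L, byrow = TRUE)
  semat <- matrix(se[seq_len(np_peak)], ncol = 4L, byrow = TRUE)
  ord <- order(pmat[, 2L])
  hv <- spec$meta$hv_eV %||% NA_real_
  peaks <- data.frame(site = paste0("C", seq_len(n_peaks)),
                      center_ke = pmat[ord, 2L],
                      be_eV = hv - pmat[ord, 2L],
                      sigma = pmat[ord, 3L], asym = pmat[ord, 4L],
                      area = pmat[ord, 1L],
                      se_area = semat[ord, 1L], se_center = semat[ord, 2L],
                      se_sigma = semat[ord, 3L], se_asym = semat[ord, 4L])
  # covariance reordered to match the site ordering
  perm <- c(as.numeric(t(outer((ord - 1L) * 4L, 1:4, `+`))),
            seq_len(npar - np_peak) + np_peak)
  vc <- vc[perm, perm, drop = FALSE]
  out <- structure(list(peaks = peaks, vcov = vc, redchi = redchi,
                        converged = TRUE,
                        model = emg_sum_counts(spec$ke, step, pmat) +
                          bg_counts(p),
                        background = if (background == "none") NULL else
                          bg_counts(p),
                        spectrum = spec, step = step, meta = spec$meta),
                   class = "pecd_peakfit")
  warn_overlap(peaks)
  out
}

# central-difference Jacobian of a residual function; used to rebuild J'J at
# the optimum (the solver's internal hessian is unreliable after an
# iteration-limited stop)
num_jacobian <- function(fn, par) {
  n <- length(par)
  r0 <- fn(par)
  J <- matrix(0, length(r0), n)
  for (j in seq_len(n)) {
    h <- max(abs(par[j]), 1e-4) * 1e-6
    up <- par; up[j] <- up[j] + h
    dn <- par; dn[j] <- dn[j] - h
    J[, j] <- (fn(up) - fn(dn)) / (2 * h)
  }
  J
}

# invert J'J with diagonal pre-scaling (parameters span many orders of
# magnitude), falling back to a pseudo-inverse of the correlation-scaled
# matrix when a direction is exactly degenerate (e.g. a zero-area peak)
safe_vcov <- function(hess) {
  d <- sqrt(diag(hess))
  ok <- is.finite(d) & d > 0
  ds <- 1 / d[ok]
  H <- hess[ok, ok, drop = FALSE] * (ds %o% ds)
  # clamp near-null curvature directions from below so that degenerate
  # parameter combinations receive large (conservative) variances instead of
  # spuriously small ones
  ev <- eigen(H, symmetric = TRUE)
  floor_ev <- length(ds) * 1e-10
  vals <- pmax(ev$values, floor_ev)
  inv <- ev$vectors %*% diag(1 / vals, length(vals)) %*% t(ev$vectors)
  out <- matrix(NA_real_, nrow(hess), ncol(hess))
  out[ok, ok] <- inv * (ds %o% ds)
  out
}

#' @export
print.pecd_peakfit <- function(x, ...) {
  cat(sprintf("EMG peak fit: %d peaks, reduced chi-square %.3f\n",
              nrow(x$peaks), x$redchi))
  print(format(x$peaks, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Jointly fit three charge-state spectra with tied peak widths
#'
#' Fits each spectrum with `n_peaks` EMG profiles while constraining the
#' peak widths to be consistent across spectra: the width of peak k in
#' spectrum j is `sigma_k * mult_j`, with the per-spectrum multipliers bound
#' so that the max/min width ratio across spectra cannot exceed
#' `1 + width_ratio` (default 5%).
#'
#' @param specs list of background-subtracted [pecd_spectrum()] objects.
#' @param centers list of initial center vectors, one per spectrum.
#' @param n_peaks number of peaks per spectrum.
#' @param constraints as in [fit_peaks()], plus `width_ratio`.
#' @return List with `fits` (one `pecd_peakfit` per spectrum, sharing the
#'   tied widths), `width_multipliers`, and `redchi`.
#' @export
fit_peaks_joint <- function(specs, centers, n_peaks = 3, constraints = list()) {
  cs <- fit_constraint_defaults(constraints)
  J <- length(specs)
  stopifnot(J >= 2L, length(centers) == J)
  centers <- lapply(centers, sort)
  steps <- vapply(specs, ke_step, numeric(1L))
  ws <- lapply(specs, function(s)
    if (!is.null(s$sigma)) 1 / pmax(s$sigma, 1e-9) else rep(1, length(s$ke)))
  have_sigma <- all(vapply(specs, function(s) !is.null(s$sigma), logical(1L)))
  bmul <- sqrt(1 + cs$width_ratio)

  # parameter layout: [sigma_base (n_peaks)] [mult (J-1)] then per spectrum
  # (area, center, asym) x n_peaks
  par0 <- c(rep(cs$sigma_start, n_peaks), rep(1, J - 1L))
  lower <- c(rep(cs$sigma_bounds[1L], n_peaks), rep(1 / bmul, J - 1L))
  upper <- c(rep(cs$sigma_bounds[2L], n_peaks), rep(bmul, J - 1L))
  for (j in seq_len(J)) {
    a0 <- vapply(centers[[j]], function(ck) {
      m <- abs(specs[[j]]$ke - ck) <= 1
      max(sum(pmax(specs[[j]]$counts[m], 0)), 1e-3)
    }, numeric(1L))
    par0 <- c(par0, as.numeric(t(cbind(a0, centers[[j]], cs$asym_start))))
    lower <- c(lower, as.numeric(t(cbind(0, centers[[j]] - cs$center_window,
                                         cs$asym_bounds[1L]))))
    upper <- c(upper, as.numeric(t(cbind(Inf, centers[[j]] + cs$center_window,
                                         cs$asym_bounds[2L]))))
  }
  unpack <- function(p, j) {
    sig_base <- p[seq_len(n_peaks)]
    mult <- c(1, p[n_peaks + seq_len(J - 1L)])
    off <- n_peaks + (J - 1L) + (j - 1L) * 3L * n_peaks
    loc <- matrix(p[off + seq_len(3L * n_peaks)], ncol = 3L, byrow = TRUE)
    cbind(loc[, 1L], loc[, 2L], sig_base * mult[j], loc[, 3L])
  }
  resid_fn <- function(p) {
    unlist(lapply(seq_len(J), function(j) {
      (emg_sum_counts(specs[[j]]$ke, steps[j], unpack(p, j)) -
         specs[[j]]$counts) * ws[[j]]
    }))
  }
  fit <- minpack.lm::nls.lm(par = par0, fn = resid_fn, lower = lower,
                            upper = upper,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 1000, maxfev = 200000, ftol = 1e-9, ptol = 1e-9))
  if (!fit$info %in% 1:4) stop("joint peak fit did not converge: ", fit$message)
  ntot <- sum(vapply(specs, function(s) length(s$ke), integer(1L)))
  dof <- max(ntot - length(par0), 1L)
  redchi <- fit$deviance / dof
  vc <- safe_vcov(crossprod(num_jacobian(resid_fn, fit$par)))
  if (!have_sigma) vc <- vc * redchi
  se <- suppressWarnings(sqrt(pmax(diag(vc), 0)))
  mult <- c(1, fit$par[n_peaks + seq_len(J - 1L)])
  fits <- lapply(seq_len(J), function(j) {
    pmat <- unpack(fit$par, j)
    off <- n_peaks + (J - 1L) + (j - 1L) * 3L * n_peaks
    semat <- matrix(se[off + seq_len(3L * n_peaks)], ncol = 3L, byrow = TRUE)
    ord <- order(pmat[, 2L])
    hv <- specs[[j]]$meta$hv_eV %||% NA_real_
    peaks <- data.frame(site = paste0("C", seq_len(n_peaks)),
                        center_ke = pmat[ord, 2L],
                        be_eV = hv - pmat[ord, 2L],
                        sigma = pmat[ord, 3L], asym = pmat[ord, 4L],
                        area = pmat[ord, 1L],
                        se_area = semat[ord, 1L], se_center = semat[ord, 2L],
                        se_sigma = NA_real_, se_asym = semat[ord, 3L])
    # per-spectrum area/center covariance block from the joint covariance
    idx_ac <- off + as.numeric(t(outer((ord - 1L) * 3L, 1:2, `+`)))
    structure(list(peaks = peaks, vcov = vc[idx_ac, idx_ac, drop = FALSE],
                   vcov_order = "area_center", redchi = redchi,
                   converged = TRUE,
                   model = emg_sum_counts(specs[[j]]$ke, steps[j], pmat),
                   spectrum = specs[[j]], step = steps[j],
                   meta = specs[[j]]$meta),
              class = "pecd_peakfit")
  })
  list(fits = fits, width_multipliers = mult, redchi = redchi)
}

area_cov <- function(fit) {
  n <- nrow(fit$peaks)
  if (identical(fit$vcov_order %||% "full", "area_center")) {
    idx <- (seq_len(n) - 1L) * 2L + 1L
  } else {
    idx <- (seq_len(n) - 1L) * 4L + 1L
  }
  fit$vcov[idx, idx, drop = FALSE]
}

#' Peak-area ratios normalized to C1
#'
#' @param fit a `pecd_peakfit` from [fit_peaks()].
#' @return Data frame with `site`, `ratio` (area / area(C1)), and `se`
#'   (propagated through the fitted area covariance).
#' @export
peak_area_ratios <- function(fit) {
  stopifnot(inherits(fit, "pecd_peakfit"))
  A <- fit$peaks$area
  if (A[1L] <= 0) stop("zero C1 area; ratios undefined")
  V <- area_cov(fit)
  n <- length(A)
  ratio <- A / A[1L]
  se <- vapply(seq_len(n), function(k) {
    if (k == 1L) return(0)
    g <- numeric(n)
    g[k] <- 1 / A[1L]
    g[1L] <- -A[k] / A[1L]^2
    sqrt(max(as.numeric(t(g) %*% V %*% g), 0))
  }, numeric(1L))
  data.frame(site = fit$peaks$site, ratio = ratio, se = se)
}

#' Chemical shift of one carbon site between two fits
#'
#' Binding-energy difference `BE(a) - BE(b)` for the same site in two fitted
#' spectra, with the uncertainty propagated from the fitted centers. Binding
#' energies are nominal (`hv - KE` on the as-measured kinetic-energy axis).
#'
#' @param fit_a,fit_b `pecd_peakfit` objects whose spectra carry `hv_eV`
#'   metadata.
#' @param site peak label present in both fits.
#' @return Data frame with `site`, `shift_eV`, `se`.
#' @export
chemical_shift <- function(fit_a, fit_b, site = "C1") {
  stopifnot(inherits(fit_a, "pecd_peakfit"), inherits(fit_b, "pecd_peakfit"))
  pa <- fit_a$peaks[fit_a$peaks$site == site, ]
  pb <- fit_b$peaks[fit_b$peaks$site == site, ]
  if (nrow(pa) != 1L || nrow(pb) != 1L)
    stop("site ", site, " must be present in both fits")
  if (is.na(pa$be_eV) || is.na(pb$be_eV))
    stop("photon energy unknown; cannot convert to binding energy")
  data.frame(site = site, shift_eV = pa$be_eV - pb$be_eV,
             se = sqrt(pa$se_center^2 + pb$se_center^2))
}
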