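#' Pipeline configuration
#'
#' A single nested configuration drives all stages (simulation, processing,
#' extraction, validation); there are no per-stage hidden defaults. Defaults
#' reproduce the reference measurement conditions: 50-degree backward
#' detection (theta = 130 degrees) with +/-15 degrees acceptance, assumed
#' beta = 0.5, alanine pKa 2.3/9.9, photon energies 302-310 eV, 6 replicate
#' pairs per condition, 250 meV bins.
#'
#' @param ... named overrides merged recursively into the defaults, e.g.
#'   `campaign = list(replicates = 2)`.
#' @return A nested list of class `pecd_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    geometry = list(theta_deg = 130, half_acceptance_deg = 15,
                    beta_assumed = 0.5),
    speciation = list(pKa1 = 2.3, pKa2 = 9.9),
    truth = list(b1_true = c(C1 = 0.08, C2 = 0, C3 = 0),
                 beta = 0.5, attenuation_factor = 4, flux_imbalance = 1.02,
                 area_C1 = 2e6, sigma_eV = 0.45, asym = 0.25,
                 background = list(amplitude = 6e8, decay_eV = 2.5,
                                   offset = 1e5)),
    campaign = list(pH = c(1, 6, 13), enantiomers = c("L", "D", "DL"),
                    hv_eV = seq(302, 310, by = 2), replicates = 6,
                    noise = TRUE),
    processing = list(background_model = "exp_const", edge_frac = 0.15,
                      asym_bounds = c(0.2, 0.3), width_ratio = 0.05,
                      sigma_convention = "fit"),
    binning = list(width_eV = 0.25, method = "ivw"),
    ke_step = 0.05,
    seed = 1
  )
  overrides <- list(...)
  merge_deep <- function(base, over) {
    for (nm in names(over)) {
      if (is.list(base[[nm]]) && is.list(over[[nm]]))
        base[[nm]] <- merge_deep(base[[nm]], over[[nm]])
      else base[[nm]] <- over[[nm]]
    }
    base
  }
  cfg <- merge_deep(defaults, overrides)
  # YAML round trips drop atomic-vector names; restore the site labels
  cfg$truth$b1_true <- setNames(as.numeric(unlist(cfg$truth$b1_true)),
                                c("C1", "C2", "C3"))
  structure(cfg, class = c("pecd_config", "list"))
}

#' Save / load a pipeline configuration (YAML)
#'
#' @param config a [pipeline_config()] object.
#' @param path file path.
#' @return `save_config` returns `path` invisibly; `load_config` returns the
#'   configuration.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$truth$b1_true)) cfg$truth$b1_true <- unlist(cfg$truth$b1_true)
  do.call(pipeline_config, cfg)
}

#' Fingerprint of a configuration
#'
#' Hash of the canonical YAML rendering, recorded in run logs so a report
#' can be traced to the exact configuration and seed list that produced it.
#'
#' @param config a [pipeline_config()] object.
#' @return Hex string.
#' @export
config_hash <- function(config) {
  fnv1a_hash(yaml::as.yaml(unclass(config), precision = 15))
}

config_truths <- function(config) {
  tr <- config$truth
  setNames(lapply(config$campaign$pH, function(p)
    alanine_truth(p, b1_true = tr$b1_true, beta = tr$beta,
                  attenuation_factor = tr$attenuation_factor,
                  flux_imbalance = tr$flux_imbalance, area_C1 = tr$area_C1,
                  sigma_eV = tr$sigma_eV, asym = tr$asym,
                  background = tr$background)),
    as.character(config$campaign$pH))
}

#' Simulate a campaign to disk
#'
#' Generates the full configured campaign (pH x enantiomer x photon energy x
#' replicates) deterministically from `config$seed` and writes spectra plus
#' the truth manifest to `outdir`.
#'
#' @param config a [pipeline_config()] object; `config$seed` must be set.
#' @param outdir writable output directory.
#' @return The `pecd_campaign`, invisibly.
#' @export
run_simulate <- function(config, outdir) {
  stopifnot(inherits(config, "pecd_config"))
  if (is.null(config$seed) || is.na(config$seed))
    stop("config$seed is missing: set an integer seed to make the campaign reproducible")
  message(sprintf("[simulate] config %s, seed %d -> %s",
                  config_hash(config), as.integer(config$seed), outdir))
  camp <- generate_campaign(config_truths(config),
                            hv_eV = config$campaign$hv_eV,
                            enantiomers = config$campaign$enantiomers,
                            replicates = config$campaign$replicates,
                            base_seed = config$seed,
                            theta_deg = config$geometry$theta_deg,
                            noise = config$campaign$noise,
                            ke_step = config$ke_step,
                            outdir = outdir)
  message(sprintf("[simulate] wrote %d spectrum files (%d pairs)",
                  2L * nrow(camp$manifest), nrow(camp$manifest)))
  invisible(camp)
}

process_pair <- function(pair, config, subtract = TRUE) {
  truth <- attr(pair, "truth")
  hv <- pair$plus$meta$hv_eV
  pH <- pair$plus$meta$pH
  tab <- alanine_be_table()
  centers <- if (pH %in% tab$pH)
    as.numeric(hv - tab[tab$pH == pH, c("C1", "C2", "C3")]) else NULL
  sc <- scale_to_baseline(pair$plus, pair$minus, frac = config$processing$edge_frac,
                          peak_centers = centers)
  constraints <- list(asym_bounds = config$processing$asym_bounds)
  if (!subtract) {
    # background deliberately retained: demonstrates the dilution bias
    fit_p <- fit_peaks(sc$plus, n_peaks = 3, centers = centers,
                       constraints = constraints)
    fit_m <- fit_peaks(sc$minus, n_peaks = 3, centers = centers,
                       constraints = constraints)
    return(list(scale = sc, fit_plus = fit_p, fit_minus = fit_m))
  }
  # edge-anchored background fit initializes a joint peaks-plus-background
  # refinement, so the background uncertainty propagates into the areas
  bp <- subtract_background(sc$plus, model = config$processing$background_model,
                            frac = config$processing$edge_frac)
  bm <- subtract_background(sc$minus, model = config$processing$background_model,
                            frac = config$processing$edge_frac)
  fit_p <- fit_peaks(sc$plus, n_peaks = 3, centers = centers,
                     constraints = constraints, background = "exp_const",
                     bg_start = bp$params)
  fit_m <- fit_peaks(sc$minus, n_peaks = 3, centers = centers,
                     constraints = constraints, background = "exp_const",
                     bg_start = bm$params)
  list(scale = sc, fit_plus = fit_p, fit_minus = fit_m,
       bgsub_plus = bp, bgsub_minus = bm)
}

#' Run the extraction pipeline over a campaign
#'
#' Executes scale -> background subtraction -> constrained EMG fitting ->
#' per-site b1 estimation -> kinetic-energy binning -> enantiomer
#' consistency on every polarization pair. Pairs that fail any stage are
#' skipped with a warning and counted in the report.
#'
#' @param config a [pipeline_config()] object.
#' @param datadir directory written by [run_simulate()] (ignored when
#'   `campaign` is given).
#' @param campaign an in-memory `pecd_campaign`.
#' @param sites peak labels to extract b1 for.
#' @param test_mode if `TRUE` and generator truth is available, append a
#'   truth-versus-estimate comparison table.
#' @param blind if `TRUE`, strip enantiomer labels before estimation and
#'   unblind only for the consistency test.
#' @param outdir optional directory for the tabular b1 report
#'   (`b1_report.tsv`), the binned report (`b1_binned.tsv`), and the
#'   consistency text block (`consistency.txt`).
#' @return List of class `pecd_extraction`: `estimates`, `binned`,
#'   `consistency`, `n_failed`, `failed` (pair ids), `config_hash`, and
#'   `truth_comparison` (test mode only).
#' @export
run_extract <- function(config, datadir = NULL, campaign = NULL,
                        sites = "C1", test_mode = FALSE, blind = FALSE,
                        outdir = NULL) {
  stopifnot(inherits(config, "pecd_config"))
  if (is.null(campaign)) {
    if (is.null(datadir)) stop("supply datadir or campaign")
    if (!dir.exists(datadir) || !length(list.files(datadir)))
      stop("no campaign data found in ", datadir %||% "<missing>")
    campaign <- read_campaign(datadir)
  }
  geom <- geometry(config$geometry$theta_deg, config$geometry$half_acceptance_deg)
  conv <- config$processing$sigma_convention
  est <- list(); failed <- character(0)
  labels <- list()
  for (pid in names(campaign$pairs)) {
    pair <- campaign$pairs[[pid]]
    labels[[pid]] <- data.frame(pair_id = pid,
                                enantiomer = pair$plus$meta$enantiomer)
    if (blind) {
      pair$plus$meta$enantiomer <- NA_character_
      pair$minus$meta$enantiomer <- NA_character_
    }
    res <- tryCatch({
      pr <- suppressWarnings(process_pair(pair, config))
      do.call(rbind, lapply(sites, function(s)
        estimate_b1(pr$fit_plus, pr$fit_minus, site = s, geom = geom,
                    beta_assumed = config$geometry$beta_assumed,
                    sigma_convention = conv, pair_id = pid)))
    }, error = function(e) {
      warning(sprintf("pair %s skipped: %s", pid, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (!is.null(res)) est[[pid]] <- res else failed <- c(failed, pid)
  }
  if (!length(est)) stop("no pair could be processed")
  estimates <- do.call(rbind, est)
  rownames(estimates) <- NULL
  label_tab <- do.call(rbind, labels)
  consistency <- tryCatch(
    enantiomer_consistency(estimates, width = config$binning$width_eV,
                           labels = if (blind) label_tab else NULL),
    error = function(e) NULL)
  if (blind)
    estimates$enantiomer <- label_tab$enantiomer[
      match(estimates$pair_id, label_tab$pair_id)]
  binned <- bin_b1(estimates, width = config$binning$width_eV,
                   method = config$binning$method)
  out <- structure(list(estimates = estimates, binned = binned,
                        consistency = consistency,
                        n_failed = length(failed), failed = failed,
                        config_hash = config_hash(config)),
                   class = "pecd_extraction")
  if (test_mode && length(campaign$truths)) {
    cmp <- lapply(names(campaign$truths), function(pH) {
      tr <- campaign$truths[[pH]]
      data.frame(pH = as.numeric(pH), site = tr$sites$site,
                 b1_true_effective = tr$sites$b1_true / tr$attenuation_factor)
    })
    cmp <- do.call(rbind, cmp)
    bl <- binned[binned$enantiomer == "L", c("site", "pH", "bin_center_ke",
                                             "b1_mean", "combined_sigma")]
    out$truth_comparison <- merge(cmp, bl, by = c("pH", "site"),
                                  all.y = TRUE, sort = TRUE)
  }
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write.table(format(estimates, digits = 10),
                file.path(outdir, "b1_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(format(binned, digits = 10),
                file.path(outdir, "b1_binned.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    con <- file(file.path(outdir, "consistency.txt"), "w")
    sink(con); print(consistency)
    cat(sprintf("pairs processed: %d, skipped: %d\nconfig: %s\n",
                nrow(estimates), length(failed), out$config_hash))
    sink(); close(con)
  }
  out
}

#' @export
print.pecd_extraction <- function(x, ...) {
  cat(sprintf("PECD extraction: %d per-pair estimates, %d bins, %d pairs skipped [config %s]\n",
              nrow(x$estimates), nrow(x$binned), x$n_failed, x$config_hash))
  print(format(x$binned, digits = 4), row.names = FALSE)
  if (!is.null(x$consistency)) print(x$consistency)
  invisible(x)
}

#' Validate a campaign end to end
#'
#' Convenience wrapper: runs [run_extract()] (when given a data directory)
#' and returns the enantiomer-consistency report.
#'
#' @inheritParams run_extract
#' @param extraction an existing `pecd_extraction` result (skips re-running).
#' @return A `pecd_consistency` report.
#' @export
run_validate <- function(config, datadir = NULL, campaign = NULL,
                         extraction = NULL) {
  if (is.null(extraction))
    extraction <- run_extract(config, datadir = datadir, campaign = campaign)
  extraction$consistency
}
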