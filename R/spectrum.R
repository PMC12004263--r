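#' Photoelectron spectrum object
#'
#' The atomic unit of all processing: a uniform kinetic-energy grid with
#' counts per channel, acquisition metadata, and (optionally) per-channel
#' count uncertainties.
#'
#' @param ke kinetic energies in eV; strictly increasing, uniform step.
#' @param counts intensities (counts per channel), same length as `ke`.
#' @param meta named list of acquisition metadata. Recognized scalar keys,
#'   written to/read from the on-disk header: `hv_eV` (photon energy),
#'   `polarization` (+1, -1, or 0), `enantiomer` (`"L"`, `"D"`, `"DL"`),
#'   `pH`, `theta_deg`, `seed`, `pair_id`.
#' @param sigma optional 1-sigma count uncertainties per channel.
#' @param nonneg require `counts >= 0` (disable for background-subtracted
#'   spectra, which legitimately fluctuate below zero).
#' @return An object of class `pecd_spectrum`: a list with elements `ke`,
#'   `counts`, `sigma`, `meta`.
#' @export
pecd_spectrum <- function(ke, counts, meta = list(), sigma = NULL,
                          nonneg = TRUE) {
  stopifnot(is.numeric(ke), is.numeric(counts), length(ke) == length(counts),
            length(ke) >= 2L)
  d <- diff(ke)
  if (any(d <= 0)) stop("kinetic-energy grid must be strictly increasing")
  if (diff(range(d)) > 1e-6 * mean(d))
    stop("kinetic-energy grid must have a uniform step")
  if (nonneg && any(counts < 0)) stop("counts must be nonnegative")
  if (!is.null(sigma)) stopifnot(length(sigma) == length(ke), all(sigma >= 0))
  structure(list(ke = as.numeric(ke), counts = as.numeric(counts),
                 sigma = sigma, meta = meta),
            class = "pecd_spectrum")
}

#' @export
print.pecd_spectrum <- function(x, ...) {
  m <- x$meta
  cat(sprintf("PE spectrum: %d channels, KE %.3f-%.3f eV (step %.4g eV)\n",
              length(x$ke), min(x$ke), max(x$ke), ke_step(x)))
  if (length(m)) {
    keys <- intersect(c("hv_eV", "polarization", "enantiomer", "pH",
                        "theta_deg", "seed", "pair_id"), names(m))
    for (k in keys) cat(sprintf("  %s: %s\n", k, format(m[[k]])))
  }
  invisible(x)
}

#' @export
plot.pecd_spectrum <- function(x, ...) {
  graphics::plot(x$ke, x$counts, type = "l",
                 xlab = "kinetic energy (eV)", ylab = "counts", ...)
  invisible(x)
}

#' Grid step of a spectrum
#' @param spec a [pecd_spectrum()].
#' @return The (uniform) kinetic-energy step in eV.
#' @export
ke_step <- function(spec) {
  stopifnot(inherits(spec, "pecd_spectrum"))
  mean(diff(spec$ke))
}

header_keys <- c("hv_eV", "polarization", "enantiomer", "pH", "theta_deg",
                 "seed", "pair_id")

#' Write a spectrum as two-column delimited text
#'
#' Format: `#`-prefixed `key: value` metadata header lines followed by
#' tab-separated `KE <tab> counts` rows.
#'
#' @param spec a [pecd_spectrum()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "pecd_spectrum"))
  m <- spec$meta
  hdr <- vapply(intersect(header_keys, names(m)), function(k)
    sprintf("# %s: %s", k, format(m[[k]], digits = 15, scientific = FALSE)),
    character(1L))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(sprintf("%.6f\t%.6f", spec$ke, spec$counts), con)
  invisible(path)
}

#' Read a spectrum written by [write_spectrum()]
#'
#' @param path input file path.
#' @return A [pecd_spectrum()]. Numeric-looking header values are coerced to
#'   numeric; count uncertainties are reconstructed as `sqrt(max(counts, 1))`
#'   (shot noise).
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  meta <- list()
  for (h in lines[is_hdr]) {
    kv <- sub("^#\\s*", "", h)
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:", "", kv))
    num <- suppressWarnings(as.numeric(val))
    meta[[trimws(key)]] <- if (!is.na(num)) num else val
  }
  dat <- read.table(text = lines[!is_hdr], sep = "\t",
                    col.names = c("ke", "counts"))
  pecd_spectrum(dat$ke, dat$counts, meta = meta,
                sigma = sqrt(pmax(dat$counts, 1)))
}

#' Resample two spectra onto a common kinetic-energy grid
#'
#' If the grids already coincide the pair is returned unchanged; otherwise
#' both are linearly interpolated onto the first spectrum's step over the
#' overlapping range.
#'
#' @param a,b [pecd_spectrum()] objects.
#' @return A list with elements `a` and `b` on a shared grid.
#' @export
resample_to_common_grid <- function(a, b) {
  stopifnot(inherits(a, "pecd_spectrum"), inherits(b, "pecd_spectrum"))
  if (length(a$ke) == length(b$ke) && max(abs(a$ke - b$ke)) < 1e-9)
    return(list(a = a, b = b))
  lo <- max(min(a$ke), min(b$ke))
  hi <- min(max(a$ke), max(b$ke))
  if (hi - lo < 2 * ke_step(a)) stop("spectra do not overlap in kinetic energy")
  grid <- seq(lo, hi, by = ke_step(a))
  resamp <- function(s) {
    cnt <- approx(s$ke, s$counts, xout = grid)$y
    sg <- if (is.null(s$sigma)) NULL else approx(s$ke, s$sigma, xout = grid)$y
    pecd_spectrum(grid, cnt, meta = s$meta, sigma = sg, nonneg = FALSE)
  }
  list(a = resamp(a), b = resamp(b))
}

# scale counts (and uncertainties) by a constant factor
scale_spectrum <- function(spec, factor) {
  spec$counts <- spec$counts * factor
  if (!is.null(spec$sigma)) spec$sigma <- spec$sigma * factor
  spec
}
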