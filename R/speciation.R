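#' Henderson-Hasselbalch speciation of an amino acid
#'
#' Equilibrium fractions of the cationic, zwitterionic, and anionic forms of
#' a diprotic amino acid versus pH, with relative populations
#' `1 : 10^(pH - pKa1) : 10^(2 pH - pKa1 - pKa2)`. Defaults are alanine's
#' thermodynamic pKa values in water: 2.3 (carboxylic acid) and 9.9 (amine).
#' Activities are approximated by concentrations; ionic-strength corrections
#' are not applied.
#'
#' @param pH solution pH (vectorized).
#' @param pKa1 acid dissociation constant of the carboxylic-acid group.
#' @param pKa2 acid dissociation constant of the protonated amine group.
#' @return A data frame of class `speciation_state` with columns `pH`,
#'   `cation`, `zwitterion`, `anion`; fractions sum to 1.
#' @examples
#' species_fractions(c(1, 6, 13))
#' @export
species_fractions <- function(pH, pKa1 = 2.3, pKa2 = 9.9) {
  stopifnot(is.numeric(pH), pKa1 < pKa2)
  # work in log10 relative populations, shifted for overflow safety
  lw <- cbind(0, pH - pKa1, 2 * pH - pKa1 - pKa2)
  lw <- lw - apply(lw, 1L, max)
  w <- 10^lw
  frac <- w / rowSums(w)
  out <- data.frame(pH = pH, cation = frac[, 1L],
                    zwitterion = frac[, 2L], anion = frac[, 3L])
  class(out) <- c("speciation_state", "data.frame")
  out
}

#' Dominant protonation state at a given pH
#'
#' @inheritParams species_fractions
#' @return A data frame with columns `pH`, `species` (one of `"Ala+"`,
#'   `"Ala_zw"`, `"Ala-"`), and `fraction` (the dominant fraction).
#' @examples
#' dominant_species(c(1, 6, 13))
#' @export
dominant_species <- function(pH, pKa1 = 2.3, pKa2 = 9.9) {
  fr <- species_fractions(pH, pKa1, pKa2)
  labels <- c("Ala+", "Ala_zw", "Ala-")
  m <- as.matrix(fr[, c("cation", "zwitterion", "anion")])
  idx <- max.col(m, ties.method = "first")
  data.frame(pH = pH, species = labels[idx], fraction = m[cbind(seq_len(nrow(m)), idx)])
}
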