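#' Monoisotopic mass constants
#'
#' Residue (not free amino-acid) monoisotopic masses for the 20 canonical
#' amino acids, plus the water and proton masses used throughout the
#' package. All values in Dalton.
#'
#' @keywords internal
#' @name mass_constants
NULL

# monoisotopic residue masses (Da), canonical one-letter codes
.RESIDUE_MASSES <- c(
  G =  57.02146374, A =  71.03711379, S =  87.03202841, P =  97.05276385,
  V =  99.06841391, T = 101.04767847, C = 103.00918448, L = 113.08406398,
  I = 113.08406398, N = 114.04292744, D = 115.02694302, Q = 128.05857751,
  K = 128.09496302, E = 129.04259309, M = 131.04048461, H = 137.05891186,
  F = 147.06841391, R = 156.10111102, Y = 163.06332853, W = 186.07931295
)

.WATER_MASS  <- 18.0105646863
.PROTON_MASS <- 1.00727646688

# nuclide mass differences used for stable-isotope label shifts
.C13_MINUS_C12 <- 1.0033548378
.N15_MINUS_N14 <- 0.9970348893

# methylthio (MMTS) adduct on cysteine, the usual fixed modification in
# gel-assisted digests
.METHYLTHIO_C <- 45.98772

#' Amino-acid mass table
#'
#' Builds the table of monoisotopic residue masses driving every m/z
#' computation, optionally with fixed modifications (mass shifts added to
#' every occurrence of a residue).
#'
#' @param fixed_mods named numeric vector of mass shifts in Da, names are
#'   one-letter residue codes (e.g. `c(C = 45.98772)` for methylthio-Cys).
#'   Default: no fixed modifications.
#' @return An object of class `aa_table`: list with `residue_masses`
#'   (named numeric, length 20), `water_mass`, `proton_mass` and
#'   `fixed_mods`.
#' @examples
#' tab <- amino_acid_table()
#' tab$residue_masses[["G"]]
#' @export
amino_acid_table <- function(fixed_mods = numeric()) {
  if (length(fixed_mods)) {
    if (is.null(names(fixed_mods)) || !all(names(fixed_mods) %in% names(.RESIDUE_MASSES)))
      stop("fixed_mods must be named by canonical one-letter residue codes")
    if (!is.numeric(fixed_mods))
      stop("fixed_mods must be numeric mass shifts in Da")
  }
  structure(
    list(
      residue_masses = .RESIDUE_MASSES,
      water_mass     = .WATER_MASS,
      proton_mass    = .PROTON_MASS,
      fixed_mods     = fixed_mods
    ),
    class = "aa_table"
  )
}

#' Fixed methylthio-Cys modification shift (Da)
#'
#' Convenience constant for `amino_acid_table(fixed_mods = c(C = methylthio_mass()))`.
#' @return Mass shift in Da.
#' @export
methylthio_mass <- function() .METHYLTHIO_C

#' Stable-isotope label specification
#'
#' C-terminal heavy labels used for spiked internal-standard peptides:
#' `heavy_K` is \eqn{^{13}C_6\,^{15}N_2}-lysine (+8.0142 Da) and `heavy_E`
#' is \eqn{^{13}C_5\,^{15}N_1}-glutamic acid (+6.0138 Da). `none` denotes
#' the light (unlabeled) channel. Shifts are computed from the
#' \eqn{^{13}C-^{12}C} and \eqn{^{15}N-^{14}N} nuclide mass differences.
#'
#' @param kind one of `"none"`, `"heavy_K"`, `"heavy_E"`.
#' @return An object of class `isotope_label`: list with `kind`,
#'   `mass_shift` (Da) and `residue` (the labeled residue letter, `NA` for
#'   `none`).
#' @examples
#' isotope_label("heavy_K")$mass_shift  # 8.014199
#' @export
isotope_label <- function(kind = c("none", "heavy_K", "heavy_E")) {
  kind <- match.arg(kind)
  shift <- switch(kind,
    none    = 0,
    heavy_K = 6 * .C13_MINUS_C12 + 2 * .N15_MINUS_N14,
    heavy_E = 5 * .C13_MINUS_C12 + 1 * .N15_MINUS_N14
  )
  residue <- switch(kind, none = NA_character_, heavy_K = "K", heavy_E = "E")
  structure(list(kind = kind, mass_shift = shift, residue = residue),
            class = "isotope_label")
}

#' Round half away from zero
#'
#' m/z values are reported to 2 decimals with ties rounded up (the
#' convention instrument software uses), not the round-half-even rule of
#' [base::round()].
#'
#' @param x numeric.
#' @param digits number of decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
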