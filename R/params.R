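#' Thermal energy kBT in pN.nm
#'
#' Boltzmann's constant times absolute temperature, in the piconewton
#' nanometre units used throughout the package. The package default is the
#' value at 23 degrees C, `4.089` pN.nm, matching the buffer temperature of
#' the assays the models describe.
#'
#' @param temp_c temperature in degrees Celsius.
#' @return thermal energy in pN.nm.
#' @examples
#' thermal_energy(23) # ~4.089
#' @export
thermal_energy <- function(temp_c = 23) {
  0.01380649 * (273.15 + temp_c)
}

#' @rdname thermal_energy
#' @format `kbt_default` is the fixed package default, 4.089 pN.nm (23 C).
#' @export
kbt_default <- 4.089

#' Double-stranded DNA worm-like-chain parameters
#'
#' Parameter bundle for the extensible worm-like chain of dsDNA at ~100 mM
#' NaCl: persistence length 51.1 nm, stretch modulus 1006 pN, and a B-form
#' helical rise of 0.34 nm/bp used for nm <-> bp conversion.
#'
#' @param persistence_length dsDNA persistence length, nm.
#' @param stretch_modulus enthalpic stretch modulus, pN.
#' @param rise_per_bp helical rise, nm per base pair.
#' @param kbt thermal energy, pN.nm. Must lie in [3.8, 4.3] (0-40 C).
#' @return an object of class `ds_wlc`.
#' @export
ds_wlc_params <- function(persistence_length = 51.1, stretch_modulus = 1006,
                          rise_per_bp = 0.34, kbt = kbt_default) {
  stopifnot(persistence_length > 0, stretch_modulus > 0, rise_per_bp > 0)
  if (kbt < 3.8 || kbt > 4.3)
    stop("thermal energy must lie in [3.8, 4.3] pN.nm (0-40 C)")
  structure(list(persistence_length = persistence_length,
                 stretch_modulus = stretch_modulus,
                 rise_per_bp = rise_per_bp, kbt = kbt),
            class = "ds_wlc")
}

#' Single-stranded DNA worm-like-chain parameters
#'
#' Inextensible (Marko-Siggia) worm-like-chain parameters for ssDNA at
#' ~100 mM NaCl: persistence length 0.87 nm and contour length 0.69 nm per
#' nucleotide.
#'
#' @param persistence_length ssDNA persistence length, nm.
#' @param contour_per_nt contour length per nucleotide, nm.
#' @param kbt thermal energy, pN.nm.
#' @return an object of class `ss_wlc`.
#' @export
ss_wlc_params <- function(persistence_length = 0.87, contour_per_nt = 0.69,
                          kbt = kbt_default) {
  stopifnot(persistence_length > 0, contour_per_nt > 0, kbt > 0)
  structure(list(persistence_length = persistence_length,
                 contour_per_nt = contour_per_nt, kbt = kbt),
            class = "ss_wlc")
}

#' @export
print.ds_wlc <- function(x, ...) {
  cat(sprintf("dsDNA extensible WLC: Lp = %.1f nm, S = %.0f pN, rise = %.2f nm/bp, kBT = %.3f pN.nm\n",
              x$persistence_length, x$stretch_modulus, x$rise_per_bp, x$kbt))
  invisible(x)
}

#' @export
print.ss_wlc <- function(x, ...) {
  cat(sprintf("ssDNA WLC: Lp = %.2f nm, Lc = %.2f nm/nt, kBT = %.3f pN.nm\n",
              x$persistence_length, x$contour_per_nt, x$kbt))
  invisible(x)
}

#' Nuclear concentration of a dimeric protein from per-cell copy number
#'
#' Converts a per-cell protein copy number and a cell volume into a dimer
#' concentration. Used to place the measured TRF1 dissociation constant in
#' its physiological context: 40 000 TRF1 molecules per cell in 1540 um^3
#' gives 21.6 nM of dimer (43.7 nM at the 760 um^3 lower volume bound).
#'
#' @param molecules_per_cell protein copies per cell (monomers).
#' @param cell_volume_um3 cell volume in cubic micrometres.
#' @param subunits subunits per functional unit (2 for a homodimer).
#' @return concentration in nM.
#' @examples
#' dimer_concentration(40000, 1540) # 21.6 nM
#' @export
dimer_concentration <- function(molecules_per_cell, cell_volume_um3,
                                subunits = 2) {
  stopifnot(molecules_per_cell > 0, cell_volume_um3 > 0, subunits >= 1)
  avogadro <- 6.02214076e23
  litres <- cell_volume_um3 * 1e-15
  (molecules_per_cell / subunits) / (avogadro * litres) * 1e9
}
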