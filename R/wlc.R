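#' Relative extension of dsDNA under force (extensible worm-like chain)
#'
#' High-force interpolation of the extensible worm-like chain,
#' x/Lc = 1 - (1/2) sqrt(kBT / (F Lp)) + F/S. Valid at forces of roughly
#' 0.5 pN and above; the square-root term diverges as F -> 0, so
#' non-positive forces are rejected. The result can exceed 1 at high force
#' (enthalpic stretching beyond the contour length).
#'
#' @param force applied force, pN (> 0). Vectorised.
#' @param params a [ds_wlc_params()] bundle.
#' @return relative extension x/Lc (dimensionless).
#' @examples
#' ds_relative_extension(17) # 0.9826 with default parameters
#' @export
ds_relative_extension <- function(force, params = ds_wlc_params()) {
  if (any(!is.finite(force)) || any(force <= 0))
    stop("force must be strictly positive (the WLC interpolation diverges at F = 0)")
  1 - 0.5 * sqrt(params$kbt / (force * params$persistence_length)) +
    force / params$stretch_modulus
}

#' Extension-per-base-pair conversion factor for dsDNA
#'
#' The force-dependent factor (nm per bp) used to convert measured
#' extensions into base pairs: helical rise times the relative extension at
#' the given force. At 17 pN with the default parameters it rounds to the
#' 0.33 nm/bp used for telomere-length measurement.
#'
#' @inheritParams ds_relative_extension
#' @return nm per base pair at `force`.
#' @export
ds_nm_per_bp <- function(force, params = ds_wlc_params()) {
  params$rise_per_bp * ds_relative_extension(force, params)
}

#' Force on ssDNA at a given relative extension (Marko-Siggia WLC)
#'
#' F = kBT/Lp * ( (1/4) (1 - r)^-2 + r - 1/4 ) with r = x/Lc. Monotone
#' increasing in r on [0, 1); diverges as r -> 1.
#'
#' @param relative_extension r = x/Lc in [0, 1). Vectorised.
#' @param params a [ss_wlc_params()] bundle.
#' @return force in pN.
#' @export
ss_force <- function(relative_extension, params = ss_wlc_params()) {
  r <- relative_extension
  if (any(!is.finite(r)) || any(r < 0) || any(r >= 1))
    stop("relative extension must lie in [0, 1)")
  params$kbt / params$persistence_length *
    (0.25 * (1 - r)^-2 + r - 0.25)
}

#' Relative extension of ssDNA under force (numeric WLC inverse)
#'
#' Unique root in [0, 1) of the Marko-Siggia relation for a given force,
#' found by bracketing bisection to an absolute tolerance of 1e-9.
#'
#' @param force force in pN (>= 0). Vectorised.
#' @param params a [ss_wlc_params()] bundle.
#' @param tol absolute tolerance on the root.
#' @return relative extension r = x/Lc.
#' @export
ss_relative_extension <- function(force, params = ss_wlc_params(), tol = 1e-9) {
  if (any(!is.finite(force)) || any(force < 0))
    stop("force must be non-negative")
  one <- function(f) {
    if (f == 0) return(0)
    stats::uniroot(function(r) ss_force(r, params) - f,
                   lower = 0, upper = 1 - 1e-12, tol = tol)$root
  }
  vapply(force, one, numeric(1))
}

#' ssDNA extension per released nucleotide
#'
#' Contour length per nucleotide times the ssDNA relative extension at the
#' given force; the nm/nt factor used when converting strand-separation
#' extensions to unzipped base pairs.
#'
#' @inheritParams ss_relative_extension
#' @return nm per nucleotide at `force`.
#' @export
ss_nm_per_nt <- function(force, params = ss_wlc_params()) {
  params$contour_per_nt * ss_relative_extension(force, params)
}

#' Convert dsDNA extension to base pairs, and back
#'
#' `extension_to_bp` divides a measured extension by the force-dependent
#' nm/bp factor of the extensible WLC; `bp_to_extension` is its inverse.
#' This is the ruler behind single-molecule telomere-length measurement
#' (extension at 17 pN divided by ~0.33 nm/bp).
#'
#' @param extension extension in nm (>= 0).
#' @param n_bp number of base pairs (>= 0).
#' @param force force in pN (> 0).
#' @param params a [ds_wlc_params()] bundle.
#' @return base pairs (`extension_to_bp`) or nm (`bp_to_extension`).
#' @examples
#' extension_to_bp(835, 17) # ~2500 bp
#' @export
extension_to_bp <- function(extension, force, params = ds_wlc_params()) {
  if (any(extension < 0)) stop("extension must be non-negative")
  extension / ds_nm_per_bp(force, params)
}

#' @rdname extension_to_bp
#' @export
bp_to_extension <- function(n_bp, force, params = ds_wlc_params()) {
  if (any(n_bp < 0)) stop("n_bp must be non-negative")
  n_bp * ds_nm_per_bp(force, params)
}
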