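#' Hill dose-response with residual current
#'
#' Fractional current remaining at a nucleotide concentration under the
#' three-parameter Hill model
#' \deqn{I/I_{max} = 1 - I_{max} + \frac{I_{max}}{1 + 10^{h(\log_{10} c - \log_{10} IC_{50})}}}
#' where \code{Imax} is the maximal inhibited fraction (a residual,
#' nucleotide-insensitive current of \code{1 - Imax} remains at saturation).
#' The zero-concentration limit is handled exactly and returns 1.
#'
#' @param conc Nucleotide concentration(s) in molar; must be >= 0.
#' @param log10_ic50 log10 of the half-maximal inhibitory concentration
#'   (log10 molar).
#' @param h Hill slope (dimensionless).
#' @param imax Maximal inhibited fraction, in \code{[0, 1]}.
#' @return Numeric vector of fractional currents, same length as \code{conc}.
#' @examples
#' hill_fraction(30e-6, log10(30e-6), h = 1, imax = 1)  # midpoint: 0.5
#' hill_fraction(0, -4.5, 1, 1)                         # zero-ligand: 1
#' @export
hill_fraction <- function(conc, log10_ic50, h, imax) {
  stopifnot(is.numeric(conc), is.numeric(log10_ic50), is.numeric(h),
            is.numeric(imax), length(log10_ic50) == 1L, length(h) == 1L,
            length(imax) == 1L)
  if (any(conc < 0)) stop("negative concentration supplied to hill_fraction()")
  if (imax < 0 || imax > 1) stop("imax must lie in [0, 1]")
  out <- rep(1, length(conc))
  pos <- conc > 0
  if (any(pos)) {
    u <- 10^(h * (log10(conc[pos]) - log10_ic50))
    out[pos] <- 1 - imax + imax / (1 + u)
  }
  out
}

#' Validate MWC parameters
#'
#' @param L open/closed equilibrium constant (dimensionless, > 0); the
#'   ligand-free open probability is \code{L / (L + 1)}.
#' @param KA per-site association constant (per molar, > 0).
#' @param D factor by which each bound ligand stabilises the closed state
#'   (dimensionless, in \code{(0, 1]}; \code{D < 1} promotes closure).
#' @noRd
check_mwc_params <- function(L, KA, D) {
  stopifnot(length(L) == 1L, length(KA) == 1L, length(D) == 1L)
  if (!is.finite(L) || L <= 0) stop("MWC parameter L must be finite and > 0")
  if (!is.finite(KA) || KA <= 0) stop("MWC parameter KA must be finite and > 0")
  if (!is.finite(D) || D <= 0 || D > 1) stop("MWC parameter D must lie in (0, 1]")
  invisible(TRUE)
}

#' Fractional fluorescence quenching under the 4-site MWC model
#'
#' Per-site occupancy of a concerted two-conformation (open/closed) allosteric
#' model with four independent, equivalent nucleotide sites. With
#' \eqn{x = K_A T},
#' \deqn{F/F_{max} = \frac{x(1+x)^3 + L D x (1 + Dx)^3}{(1+x)^4 + L(1+Dx)^4}}
#' Quenching of the ANAP fluorophore is taken as directly proportional to
#' TNP-ATP occupancy of the Kir6.2 site, so this quantity rises from 0 (no
#' ligand) towards 1 at saturation.
#'
#' Note on convention: the \code{L}-weighted conformation binds ligand with the
#' reduced affinity \code{D * KA} and is the open state, so that the ligand-free
#' open probability is \code{L/(L+1)} (see \code{\link{popen}}).
#'
#' @param conc Ligand (TNP-ATP) concentration(s), molar, >= 0.
#' @inheritParams check_mwc_params
#' @return Fractional quenching in \code{[0, 1]}, non-decreasing in \code{conc}.
#' @seealso \code{\link{mwc_current}}, \code{\link{popen}}
#' @export
mwc_occupancy <- function(conc, L, KA, D) {
  check_mwc_params(L, KA, D)
  if (any(conc < 0)) stop("negative concentration supplied to mwc_occupancy()")
  x <- KA * conc
  (x * (1 + x)^3 + L * D * x * (1 + D * x)^3) / ((1 + x)^4 + L * (1 + D * x)^4)
}

#' Fractional current under the 4-site MWC model
#'
#' Open probability at ligand concentration T, normalised to the ligand-free
#' open probability \code{L/(L+1)}. With \eqn{x = K_A T},
#' \deqn{I/I_{max} = \frac{L(1+Dx)^4}{(1+x)^4 + L(1+Dx)^4} \cdot \frac{1+L}{L}}
#' Equals 1 at \code{conc = 0} by construction and is monotone non-increasing
#' in concentration when \code{D < 1}; for \code{D = 1} binding is decoupled
#' from gating and the fractional current is identically 1.
#'
#' @inheritParams mwc_occupancy
#' @return Fractional current in \code{(0, 1]}.
#' @export
mwc_current <- function(conc, L, KA, D) {
  check_mwc_params(L, KA, D)
  if (any(conc < 0)) stop("negative concentration supplied to mwc_current()")
  x <- KA * conc
  (L * (1 + D * x)^4 / ((1 + x)^4 + L * (1 + D * x)^4)) * (1 + L) / L
}

#' Ligand-free channel open probability
#'
#' @param L open/closed equilibrium constant, > 0.
#' @return \code{L / (L + 1)}.
#' @export
popen <- function(L) {
  if (any(!is.finite(L) | L <= 0)) stop("L must be finite and > 0")
  L / (L + 1)
}
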