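# pLDDT-derived pseudo-B-factors.

#' Convert pLDDT to an RMSD error estimate
#'
#' AlphaFold's per-residue confidence is mapped to a positional error
#' estimate by the empirical formula
#' \eqn{\Delta = 1.5\,\exp[4(0.5 - \mathrm{pLDDT}/100)]}
#' (\ifelse{html}{\out{&Aring;}}{A}); pLDDT is rescaled from 0-100 to 0-1
#' before the exponent.  \eqn{\Delta} decreases strictly with confidence:
#' pLDDT 50 maps to exactly 1.5 \ifelse{html}{\out{&Aring;}}{A}, the
#' inclusion threshold for the surface-B-factor descriptor.
#'
#' @param plddt Numeric in \[0, 100\].
#' @return RMSD estimate(s) in \ifelse{html}{\out{&Aring;}}{A}.
#' @examples
#' plddt_to_rmsd(50)   # 1.5
#' plddt_to_rmsd(100)  # 1.5 * exp(-2)
#' @export
plddt_to_rmsd <- function(plddt) {
  if (any(!is.finite(plddt)) || any(plddt < 0 | plddt > 100))
    stop("plddt must lie in [0, 100]")
  1.5 * exp(4 * (0.5 - plddt / 100))
}

#' Convert an RMSD estimate to a pseudo-B-factor
#'
#' The Debye-Waller relation \eqn{B = 8\pi^2 \langle u^2 \rangle} with the
#' mean-square displacement spread over three dimensions gives
#' \eqn{B = 8\pi^2 \Delta^2 / 3}
#' (\ifelse{html}{\out{&Aring;&sup2;}}{A^2}).  At the inclusion threshold
#' \eqn{\Delta = 1.5} this evaluates to \eqn{6\pi^2 \approx 59.2}, i.e.
#' the commonly quoted B <= 60 cut.
#'
#' @param delta RMSD estimate(s), \ifelse{html}{\out{&Aring;}}{A}, >= 0.
#' @return Pseudo-B-factor(s), \ifelse{html}{\out{&Aring;&sup2;}}{A^2}.
#' @examples
#' rmsd_to_b(1.5)  # 6 * pi^2
#' @export
rmsd_to_b <- function(delta) {
  if (any(!is.finite(delta)) || any(delta < 0))
    stop("delta must be non-negative")
  8 * pi^2 * delta^2 / 3
}

#' Per-residue pseudo-B-factor records
#'
#' @param s A `ProteinStructure`.
#' @param rmsd_max Inclusion threshold on \eqn{\Delta}
#'   (\ifelse{html}{\out{&Aring;}}{A}).
#' @return Data frame `resno`, `plddt`, `delta`, `b`, `b_norm`,
#'   `included`.  `b_norm` standardizes `b` by the mean and population
#'   standard deviation over the whole structure; when all pLDDT values
#'   are equal (`sd` = 0) every `b_norm` is defined as 0 with a warning.
#' @export
bfactor_records <- function(s, rmsd_max = 1.5) {
  plddt <- s$residues$plddt
  delta <- plddt_to_rmsd(plddt)
  b <- rmsd_to_b(delta)
  mu <- mean(b)
  sigma <- sqrt(mean((b - mu)^2)) # population SD over the whole structure
  if (sigma == 0) {
    warning("all residues share one pLDDT value; normalized B set to 0")
    b_norm <- rep(0, length(b))
  } else {
    b_norm <- (b - mu) / sigma
  }
  data.frame(resno = s$residues$resno, plddt = plddt, delta = delta,
             b = b, b_norm = b_norm, included = delta <= rmsd_max)
}

#' Average normalized surface B-factor (descriptor `norm_s_b`)
#'
#' Pseudo-B-factors are normalized over the whole structure
#' (\eqn{B_{norm} = (B - \langle B \rangle)/\sigma}, population
#' \eqn{\sigma}), then averaged over the surface residues whose error
#' estimate passes \eqn{\Delta \le 1.5}
#' \ifelse{html}{\out{&Aring;}}{A} (about B <= 60).
#'
#' @inheritParams bfactor_records
#' @param mask A `SurfaceMask` from [classify_surface_residues()].
#' @return The mean normalized surface B-factor; `NA` with a warning when
#'   no surface residue passes the filter (descriptor undefined).
#' @export
normalized_surface_b <- function(s, mask, rmsd_max = 1.5) {
  rec <- bfactor_records(s, rmsd_max = rmsd_max)
  stopifnot(nrow(rec) == nrow(mask))
  sel <- mask$surface & rec$included
  if (!any(sel)) {
    warning("no surface residue passes the RMSD filter; norm_s_b undefined")
    return(NA_real_)
  }
  mean(rec$b_norm[sel])
}
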