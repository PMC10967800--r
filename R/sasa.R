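# Solvent-accessible surface area (Shrake-Rupley) and the surface-residue mask.

# Rigid-motion canonicalization: surface estimators sample fixed lattices
# (spiral points, voxel grids), so coordinates are first expressed in a
# frame derived from the atom cloud itself (principal axes, signs fixed by
# third moments).  Any rigid motion of the input then leaves the sampled
# geometry, and hence the estimate, bit-identical.
canonicalize_coords <- function(xyz) {
  n <- nrow(xyz)
  ctr <- colMeans(xyz)
  xc <- sweep(xyz, 2, ctr)
  if (n < 3) {
    if (n == 2) { # align the pair axis with x
      v1 <- xc[2, ] - xc[1, ]
      v1 <- v1 / sqrt(sum(v1^2))
      helper <- if (abs(v1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      v2 <- helper - sum(helper * v1) * v1
      v2 <- v2 / sqrt(sum(v2^2))
      v3 <- c(v1[2] * v2[3] - v1[3] * v2[2],
              v1[3] * v2[1] - v1[1] * v2[3],
              v1[1] * v2[2] - v1[2] * v2[1])
      return(xc %*% cbind(v1, v2, v3))
    }
    return(xc)
  }
  ev <- eigen(stats::cov(xc), symmetric = TRUE)
  v <- ev$vectors # columns ordered by decreasing eigenvalue
  for (k in 1:2) { # fix signs by the third moment (fallback: first atom)
    pr <- xc %*% v[, k]
    m3 <- sum(pr^3)
    sgn <- if (abs(m3) > 1e-8 * max(abs(pr))^3) sign(m3) else
      sign(pr[1] + 0.5 * sign(pr[1] == 0))
    if (sgn < 0) v[, k] <- -v[, k]
  }
  v[, 3] <- c(v[2, 1] * v[3, 2] - v[3, 1] * v[2, 2],
              v[3, 1] * v[1, 2] - v[1, 1] * v[3, 2],
              v[1, 1] * v[2, 2] - v[2, 1] * v[1, 2])
  xc %*% v
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolls a spherical probe of the size of a water molecule (default 1.4
#' \ifelse{html}{\out{&Aring;}}{A}) over the heavy atoms.  Each atom's
#' solvent-expanded sphere is sampled with a deterministic golden-spiral
#' lattice; its accessible area is \eqn{4\pi (r + r_p)^2} times the
#' fraction of lattice points not occluded by any neighbouring expanded
#' sphere.  No random numbers are involved, and coordinates are
#' canonicalized so the result is invariant under rigid motions.
#'
#' @param s A `ProteinStructure` with radii assigned, or a plain list with
#'   `xyz` (n x 3 matrix) and `radii`.
#' @param probe_radius Probe radius in \ifelse{html}{\out{&Aring;}}{A}.
#' @param n_sphere_points Lattice points per atom (>= 12); at the default
#'   960 the isolated-sphere closed form is reproduced exactly.
#' @return A `SasaResult` list: `probe_radius`, `per_atom`
#'   (\ifelse{html}{\out{&Aring;&sup2;}}{A^2}, heavy atoms; hydrogens get
#'   `NA`), `per_residue` (sums over each residue's heavy atoms, when
#'   residue information is available) and `total`.
#' @examples
#' cl <- make_sphere_cluster(matrix(0, 1, 3), 1.7)
#' shrake_rupley_sasa(cl)$total      # 4*pi*(1.7+1.4)^2
#' @export
shrake_rupley_sasa <- function(s, probe_radius = 1.4, n_sphere_points = 960) {
  if (probe_radius <= 0) stop("probe_radius must be positive")
  if (n_sphere_points < 12) stop("n_sphere_points must be >= 12")
  sa <- .surface_atoms(s)
  xyz <- canonicalize_coords(sa$xyz)
  per_heavy <- sasa_shrake_rupley_cpp(xyz, sa$radii, probe_radius,
                                      as.integer(n_sphere_points))
  per_atom <- rep(NA_real_, nrow(s$atoms))
  per_atom[.heavy(s)] <- per_heavy
  per_residue <- as.numeric(
    rowsum(per_heavy, factor(sa$res_index, levels = seq_len(nrow(s$residues))))
  )
  per_residue[is.na(per_residue)] <- 0
  structure(
    list(probe_radius = probe_radius, per_atom = per_atom,
         per_residue = per_residue, total = sum(per_heavy)),
    class = "SasaResult"
  )
}

#' Maximum accessible surface area of a residue type
#'
#' The reference maximum SASA of residue X is defined in a Gly-X-Gly
#' tripeptide.  `mode = "table"` (default) returns the published
#' theoretical value shipped with the package; `mode = "computed"` builds
#' an extended Gly-X-Gly tripeptide with ideal backbone geometry
#' (side chains as CB pseudo-atoms) and measures the central residue with
#' [shrake_rupley_sasa()].  The computed mode underestimates residues with
#' long side chains and serves as a geometry cross-check, not as the
#' default denominator.
#'
#' @param residue_name Three-letter code of a standard residue.
#' @param mode `"table"` or `"computed"`.
#' @param reference_table Data frame `residue`, `max_asa` used in table
#'   mode (defaults to [max_asa_table()]).
#' @param probe_radius,n_sphere_points Passed to [shrake_rupley_sasa()] in
#'   computed mode.
#' @return Maximum SASA in \ifelse{html}{\out{&Aring;&sup2;}}{A^2}.
#' @export
max_sas_reference <- function(residue_name, mode = c("table", "computed"),
                              reference_table = max_asa_table(),
                              probe_radius = 1.4, n_sphere_points = 960) {
  mode <- match.arg(mode)
  residue_name <- toupper(residue_name)
  if (!all(residue_name %in% STANDARD_RESIDUES))
    stop("not a standard residue: ",
         paste(setdiff(residue_name, STANDARD_RESIDUES), collapse = ", "))
  if (mode == "table") {
    i <- match(residue_name, reference_table$residue)
    if (anyNA(i)) stop("residue missing from reference table")
    return(reference_table$max_asa[i])
  }
  vapply(residue_name, function(rn) {
    aa1 <- THREE_TO_ONE[[rn]]
    tri <- make_extended_peptide(paste0("G", aa1, "G"))
    tri <- assign_radii(tri)
    sasa <- shrake_rupley_sasa(tri, probe_radius, n_sphere_points)
    sasa$per_residue[2]
  }, numeric(1), USE.NAMES = FALSE)
}

#' Classify surface versus buried residues
#'
#' A residue is a surface residue when its actual SASA is at least 30% of
#' the maximum SASA its type attains in a Gly-X-Gly tripeptide.
#' Nonstandard residues have no reference maximum and are flagged buried
#' with a warning.
#'
#' @param s A `ProteinStructure`.
#' @param sasa A `SasaResult` from [shrake_rupley_sasa()] at the water
#'   probe (1.4 \ifelse{html}{\out{&Aring;}}{A}).
#' @param threshold Relative-accessibility cut (default 0.30, inclusive).
#' @param reference_table Maximum-SASA reference, see [max_sas_reference()].
#' @return A `SurfaceMask` data frame: `resno`, `resid`, `sasa`,
#'   `max_sas`, `rel_acc`, `surface` (logical).
#' @examples
#' h <- assign_radii(make_ideal_helix(15))
#' mask <- classify_surface_residues(h, shrake_rupley_sasa(h))
#' table(mask$surface)
#' @export
classify_surface_residues <- function(s, sasa, threshold = 0.30,
                                      reference_table = max_asa_table()) {
  res <- s$residues
  max_sas <- rep(NA_real_, nrow(res))
  std <- res$standard
  max_sas[std] <- max_sas_reference(res$resid[std],
                                    reference_table = reference_table)
  if (any(!std))
    warning("nonstandard residue(s) flagged buried: ",
            paste(unique(res$resid[!std]), collapse = ", "))
  rel <- sasa$per_residue / max_sas
  out <- data.frame(
    resno = res$resno, resid = res$resid,
    sasa = sasa$per_residue, max_sas = max_sas,
    rel_acc = rel,
    surface = !is.na(rel) & rel >= threshold,
    stringsAsFactors = FALSE
  )
  class(out) <- c("SurfaceMask", class(out))
  out
}
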