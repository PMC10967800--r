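# The ten surface descriptors plus Henderson-Hasselbalch net surface charge.

NEGATIVE_RESIDUES <- c("ASP", "GLU")
POSITIVE_RESIDUES <- c("LYS", "ARG")

#' Average surface hydrophobicity (descriptor `s_phobic_avg`)
#'
#' Unweighted arithmetic mean of the hydrophobicity-scale values over the
#' surface residues (default scale: normalized consensus,
#' [hydrophobicity_scale()]).  Set `sasa_weighted = TRUE` for a
#' SASA-weighted variant.
#'
#' @param s A `ProteinStructure`.
#' @param mask A `SurfaceMask`.
#' @param scale Named numeric vector over the 20 standard residues.
#' @param sasa_weighted Weight residues by their SASA instead of counting
#'   them equally.
#' @return Mean hydrophobicity; `NA` with a warning when no standard
#'   surface residue exists.
#' @export
avg_surface_hydrophobicity <- function(s, mask, scale = hydrophobicity_scale(),
                                       sasa_weighted = FALSE) {
  if (!all(STANDARD_RESIDUES %in% names(scale)))
    stop("hydrophobicity scale must cover the 20 standard residues")
  sel <- mask$surface & mask$resid %in% STANDARD_RESIDUES
  if (!any(sel)) {
    warning("no standard surface residues; hydrophobicity undefined")
    return(NA_real_)
  }
  vals <- scale[mask$resid[sel]]
  if (sasa_weighted) {
    w <- mask$sasa[sel]
    sum(vals * w) / sum(w)
  } else {
    mean(vals)
  }
}

#' Charged surface-area fractions (`s_pos_area`, `s_neg_area`, `s_charge_avg`)
#'
#' Fractions of the total solvent-accessible surface contributed by
#' negatively charged (Asp, Glu) and positively charged (Lys, Arg)
#' residues at physiological pH; His is excluded from the area fractions
#' (side-chain pKa near 6).  `s_charge_avg` is their sum.
#'
#' @param sasa A `SasaResult` at the water probe.
#' @param s The `ProteinStructure` the SASA was computed for.
#' @return Named vector `(s_pos_area, s_neg_area, s_charge_avg)`.
#' @export
charged_area_fractions <- function(sasa, s) {
  total <- sasa$total
  if (!is.finite(total) || total <= 0) stop("total SASA must be positive")
  resid <- s$residues$resid
  pos <- sum(sasa$per_residue[resid %in% POSITIVE_RESIDUES]) / total
  neg <- sum(sasa$per_residue[resid %in% NEGATIVE_RESIDUES]) / total
  c(s_pos_area = pos, s_neg_area = neg, s_charge_avg = pos + neg)
}

#' Net surface charge by the Henderson-Hasselbalch equation
#'
#' Each ionizable surface residue contributes its fractional
#' protonation-state charge at the given pH: basic groups (Lys, Arg, His)
#' \eqn{+1/(1 + 10^{pH - pK_a})}, acidic groups (Asp, Glu, Cys, Tyr)
#' \eqn{-1/(1 + 10^{pK_a - pH})}.  Chain termini are excluded.
#'
#' @param s A `ProteinStructure`.
#' @param mask A `SurfaceMask`; only surface residues contribute.
#' @param pH Solvent pH (default 7, physiological).
#' @param pka Data frame `residue`, `charge`, `pka` (default
#'   [pka_table()]).
#' @return Net charge in elementary charges.
#' @examples
#' # a single exposed Asp at pH 7 is almost fully deprotonated:
#' # -1 / (1 + 10^(3.65 - 7))
#' @export
net_surface_charge <- function(s, mask, pH = 7.0, pka = pka_table()) {
  sel <- mask$surface
  resid <- mask$resid[sel]
  ionizable <- resid[resid %in% c(NEGATIVE_RESIDUES, POSITIVE_RESIDUES,
                                  "CYS", "TYR", "HIS")]
  if (length(ionizable) == 0) return(0)
  i <- match(ionizable, pka$residue)
  if (anyNA(i))
    stop("missing pKa for residue(s): ",
         paste(unique(ionizable[is.na(i)]), collapse = ", "))
  q <- ifelse(pka$charge[i] > 0,
              1 / (1 + 10^(pH - pka$pka[i])),
              -1 / (1 + 10^(pka$pka[i] - pH)))
  sum(q)
}

#' Compute the full descriptor vector for one structure
#'
#' Orchestrates every descriptor at the water probe (1.4
#' \ifelse{html}{\out{&Aring;}}{A}) for the SASA-based descriptors and the
#' default probe sweep for the SES-based roughness: average surface
#' hydrophobicity, charged-area fractions, surface secondary-structure
#' proportions, surface exposure degree, normalized surface B-factor,
#' fractal dimension and net surface charge.
#'
#' @param s A `ProteinStructure`; radii are assigned automatically when
#'   absent.
#' @param probe_radius Water-probe radius for SASA.
#' @param surface_threshold Relative-accessibility cut for surface
#'   residues.
#' @param fd_radii Probe sweep for [fractal_dimension()].
#' @param voxel Grid spacing for SES and volume.
#' @param n_sphere_points Shrake-Rupley lattice size.
#' @param pH For [net_surface_charge()].
#' @param check_filters Enforce the study inclusion filters
#'   ([passes_inclusion_filters()]); disable for small demonstration
#'   fixtures.
#' @return A `DescriptorVector`: named list with the ten descriptors
#'   (`s_phobic_avg`, `s_pos_area`, `s_neg_area`, `s_charge_avg`, `s_ah`,
#'   `s_bs`, `s_do`, `s_sf`, `norm_s_b`, `fd`), `net_surface_charge`, and
#'   bookkeeping (`id`, `label`, `n_residues`, `n_surface`).
#' @examples
#' v <- compute_descriptor_vector(make_ideal_helix(20), check_filters = FALSE)
#' v$s_charge_avg == v$s_pos_area + v$s_neg_area
#' @export
compute_descriptor_vector <- function(s, probe_radius = 1.4,
                                      surface_threshold = 0.30,
                                      fd_radii = seq(1.0, 3.6, by = 0.2),
                                      voxel = 0.5, n_sphere_points = 960,
                                      pH = 7.0, check_filters = TRUE) {
  if (check_filters) {
    f <- passes_inclusion_filters(s)
    if (!f$pass)
      stop("structure fails inclusion filters: ",
           paste(f$reasons, collapse = "; "))
  }
  if (is.null(s$atoms$vdw)) s <- assign_radii(s)
  sasa <- shrake_rupley_sasa(s, probe_radius, n_sphere_points)
  mask <- classify_surface_residues(s, sasa, threshold = surface_threshold)
  ss <- assign_secondary_structure(s)
  props <- ss_proportions(ss, mask, "surface")
  vol <- protein_volume(s, voxel = voxel)
  rough <- fractal_dimension(s, radii = fd_radii, voxel = voxel)
  out <- list(
    id = s$id,
    s_phobic_avg = avg_surface_hydrophobicity(s, mask),
    s_pos_area = unname(charged_area_fractions(sasa, s)["s_pos_area"]),
    s_neg_area = unname(charged_area_fractions(sasa, s)["s_neg_area"]),
    s_charge_avg = NA_real_,
    s_ah = unname(props["h"]), s_bs = unname(props["e"]),
    s_do = unname(props["l"]),
    s_sf = surface_exposure_degree(sasa$total, vol),
    norm_s_b = normalized_surface_b(s, mask),
    fd = rough$fd,
    net_surface_charge = net_surface_charge(s, mask, pH = pH),
    label = s$label,
    n_residues = n_residues(s),
    n_surface = sum(mask$surface)
  )
  out$s_charge_avg <- out$s_pos_area + out$s_neg_area
  class(out) <- "DescriptorVector"
  out
}

#' @export
print.DescriptorVector <- function(x, ...) {
  cat("DescriptorVector", x$id, sprintf("(%d residues, %d surface)\n",
                                        x$n_residues, x$n_surface))
  vals <- unlist(x[DESCRIPTOR_NAMES])
  print(round(vals, 4))
  cat("net_surface_charge:", round(x$net_surface_charge, 3), "\n")
  invisible(x)
}

DESCRIPTOR_NAMES <- c("s_phobic_avg", "s_pos_area", "s_neg_area",
                      "s_charge_avg", "s_ah", "s_bs", "s_do", "s_sf",
                      "norm_s_b", "fd")

#' Assemble the dataset descriptor table
#'
#' Applies [compute_descriptor_vector()] to a list of structures and
#' binds the results into one data frame (one row per protein).  A
#' structure with any undefined descriptor is excluded with a logged
#' reason, as is any structure failing the inclusion filters.
#'
#' @param structures List of `ProteinStructure` objects.
#' @param labels Optional named vector (by structure id) of class labels,
#'   `1` = HAC, `0` = extracellular; structure-level labels are used when
#'   absent.
#' @param ... Passed to [compute_descriptor_vector()].
#' @return Data frame with columns `id`, the ten descriptors,
#'   `net_surface_charge` and `label`; attribute `exclusions` is a data
#'   frame of dropped ids and reasons.
#' @export
compute_descriptor_table <- function(structures, labels = NULL, ...) {
  rows <- list()
  excl <- list()
  for (s in structures) {
    if (!is.null(labels) && s$id %in% names(labels)) s$label <- labels[[s$id]]
    v <- tryCatch(compute_descriptor_vector(s, ...),
                  error = function(e) conditionMessage(e))
    if (is.character(v)) {
      excl[[length(excl) + 1]] <- data.frame(id = s$id, reason = v)
      next
    }
    nums <- unlist(v[DESCRIPTOR_NAMES])
    if (anyNA(nums)) {
      excl[[length(excl) + 1]] <- data.frame(
        id = s$id,
        reason = paste("undefined descriptor(s):",
                       paste(DESCRIPTOR_NAMES[is.na(nums)], collapse = ", "))
      )
      next
    }
    rows[[length(rows) + 1]] <- data.frame(
      id = v$id, as.list(nums),
      net_surface_charge = v$net_surface_charge,
      label = if (is.null(v$label)) NA_real_ else v$label,
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    stats::setNames(
      data.frame(matrix(nrow = 0, ncol = length(DESCRIPTOR_NAMES) + 3)),
      c("id", DESCRIPTOR_NAMES, "net_surface_charge", "label")
    )
  out <- out[order(out$id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusions") <- if (length(excl) > 0) do.call(rbind, excl) else
    data.frame(id = character(0), reason = character(0))
  out
}
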