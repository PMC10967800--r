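# Secondary-structure assignment (simplified Kabsch-Sander) and
# surface/buried composition fractions.

# Backbone coordinates per residue: N, CA, C, O (NA rows when missing).
.backbone <- function(s) {
  nres <- nrow(s$residues)
  out <- lapply(c("N", "CA", "C", "O"), function(an) {
    m <- matrix(NA_real_, nres, 3)
    sel <- s$atoms$elety == an & .heavy(s)
    m[s$atoms$res_index[sel], ] <- as.matrix(s$atoms[sel, c("x", "y", "z")])
    m
  })
  names(out) <- c("N", "CA", "C", "O")
  out
}

#' Assign secondary structure from backbone geometry
#'
#' A simplified Kabsch-Sander assignment.  Amide hydrogens are
#' reconstructed on each nitrogen 1.0 \ifelse{html}{\out{&Aring;}}{A}
#' along the preceding peptide C=O direction, and the backbone hydrogen
#' bond energy between donor NH(j) and acceptor C=O(i) is
#' \deqn{E = 0.084 \cdot 332 \,
#'   (1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})\ \mathrm{kcal/mol},}
#' with a bond assigned when E < -0.5 kcal/mol.  Two consecutive
#' n-to-n+k turns (k = 3, 4, 5) mark helical residues (`H`; 3-10 and pi
#' helices are folded into H), Kabsch-Sander parallel/antiparallel bridge
#' patterns mark beta structure (`E`), and everything else is
#' loop/disordered (`L`).  Residues with incomplete backbones are labelled
#' `L` with a warning.  The assignment depends only on internal geometry,
#' so it is invariant under rigid motions.
#'
#' @param s A `ProteinStructure`.
#' @param energy_cutoff Hydrogen-bond energy threshold (kcal/mol).
#' @return An `SSAssignment`: factor vector over residues with levels
#'   `H`, `E`, `L`.
#' @examples
#' table(assign_secondary_structure(make_ideal_helix(15)))
#' @export
assign_secondary_structure <- function(s, energy_cutoff = -0.5) {
  nres <- nrow(s$residues)
  bb <- .backbone(s)
  complete <- stats::complete.cases(cbind(bb$N, bb$CA, bb$C, bb$O))
  if (any(!complete) && any(complete))
    warning(sum(!complete), " residue(s) with incomplete backbone labelled L")
  labels <- rep("L", nres)
  if (sum(complete) >= 4) {
    # amide H on residue j from the previous residue's C=O; none for j = 1
    H <- matrix(NA_real_, nres, 3)
    for (j in 2:nres) {
      if (!complete[j] || !complete[j - 1]) next
      v <- bb$C[j - 1, ] - bb$O[j - 1, ]
      H[j, ] <- bb$N[j, ] + v / sqrt(sum(v^2))
    }
    # hb[i, j]: C=O of residue i accepts from N-H of residue j
    q <- 0.084 * 332
    hb <- matrix(FALSE, nres, nres)
    for (i in seq_len(nres)) {
      if (!complete[i]) next
      for (j in seq_len(nres)) {
        if (abs(i - j) < 2 || !complete[j] || anyNA(H[j, ])) next
        rON <- sqrt(sum((bb$O[i, ] - bb$N[j, ])^2))
        rCH <- sqrt(sum((bb$C[i, ] - H[j, ])^2))
        rOH <- sqrt(sum((bb$O[i, ] - H[j, ])^2))
        rCN <- sqrt(sum((bb$C[i, ] - bb$N[j, ])^2))
        if (rON < 0.5 || rOH < 0.5) next # clash guard
        e <- q * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
        hb[i, j] <- e < energy_cutoff
      }
    }
    # helices: two consecutive n -> n+k turns (k = 4 first, then 3, 5)
    for (k in c(4, 3, 5)) {
      turn <- rep(FALSE, nres)
      ok <- seq_len(max(0, nres - k))
      turn[ok] <- hb[cbind(ok, ok + k)]
      for (i in seq_len(max(0, nres - k - 1)))
        if (turn[i] && turn[i + 1])
          labels[(i + 1):(i + k)] <- "H"
    }
    # beta bridges (Kabsch-Sander parallel / antiparallel patterns)
    hbond <- function(i, j) { # N-H of i donates to C=O of j
      if (i < 1 || j < 1 || i > nres || j > nres) return(FALSE)
      hb[j, i]
    }
    for (i in seq_len(nres)) {
      js <- seq_len(nres)
      js <- js[abs(js - i) > 2]
      for (j in js) {
        par <- (hbond(i, j - 1) && hbond(j + 1, i)) ||
               (hbond(j, i - 1) && hbond(i + 1, j))
        anti <- (hbond(i, j) && hbond(j, i)) ||
                (hbond(i - 1, j + 1) && hbond(j - 1, i + 1))
        if ((par || anti) && labels[i] != "H") labels[i] <- "E"
      }
    }
  }
  labels[!complete] <- "L" # contract: incomplete backbone is loop
  structure(factor(labels, levels = c("H", "E", "L")), class = c("SSAssignment", "factor"))
}

#' Secondary-structure proportions in a surface region
#'
#' Fractions of helix, beta structure and loop/disordered residues among
#' the surface (or buried) residues.  For a non-empty region the three
#' fractions sum to one.
#'
#' @param ss An `SSAssignment` from [assign_secondary_structure()].
#' @param mask A `SurfaceMask` from [classify_surface_residues()].
#' @param region `"surface"` or `"buried"`.
#' @return Named numeric vector `(h, e, l)`; all `NA` (with attribute
#'   `empty = TRUE`) when the region holds no residues.
#' @export
ss_proportions <- function(ss, mask, region = c("surface", "buried")) {
  region <- match.arg(region)
  stopifnot(length(ss) == nrow(mask))
  sel <- if (region == "surface") mask$surface else !mask$surface
  if (!any(sel)) {
    warning("no residues in the ", region, " region; fractions undefined")
    return(structure(c(h = NA_real_, e = NA_real_, l = NA_real_),
                     empty = TRUE))
  }
  tab <- table(factor(ss[sel], levels = c("H", "E", "L")))
  p <- as.numeric(tab) / sum(tab)
  c(h = p[1], e = p[2], l = p[3])
}
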