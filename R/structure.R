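# Protein structures in the AlphaFold PDB dialect: one model, one chain,
# per-residue pLDDT (0-100) stored in the B-factor column.

#' Construct a ProteinStructure from an atom table
#'
#' Low-level constructor used by the PDB parser and the synthetic-structure
#' generators.  Atoms are grouped into residues in the order given; the
#' per-residue pLDDT is taken from the CA atom (or the first atom of the
#' residue if no CA is present), and values outside \[0, 100\] are clamped
#' with a warning under the AlphaFold dialect.
#'
#' @param atoms Data frame with columns `elety` (atom name), `elesy`
#'   (element symbol), `resid` (three-letter residue code), `resno`
#'   (author residue numbering), `chain`, `x`, `y`, `z`
#'   (\ifelse{html}{\out{&Aring;}}{A}) and `b` (B-factor column, read as
#'   pLDDT).
#' @param id Identifier for the structure.
#' @param label Optional class label, `1` (HAC) or `0` (extracellular).
#' @param alphafold Logical; validate the B-factor column as pLDDT
#'   (clamped to \[0, 100\], checked for within-residue consistency).
#' @return An object of class `ProteinStructure`: a list with elements
#'   `id`, `atoms` (the atom table, plus a `vdw` column once
#'   [assign_radii()] has run), `residues` (data frame `resno`, `resid`,
#'   `plddt`, `standard`) and `label`.
#' @export
protein_structure <- function(atoms, id = "protein", label = NULL,
                              alphafold = TRUE) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1)
  needed <- c("elety", "elesy", "resid", "resno", "chain", "x", "y", "z", "b")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols) > 0)
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates")
  if (alphafold && any(atoms$b < 0 | atoms$b > 100)) {
    warning("B-factor column outside [0, 100]; clamping (pLDDT scale)")
    atoms$b <- pmin(pmax(atoms$b, 0), 100)
  }
  if (length(unique(atoms$chain)) > 1)
    warning("multiple chains present; residues are concatenated in file order")

  # group into residues in file order (chain + author number)
  key <- paste(atoms$chain, atoms$resno)
  first <- !duplicated(key)
  res_key <- key[first]
  idx <- match(key, res_key)
  inconsistent <- character(0)
  plddt <- vapply(seq_along(res_key), function(i) {
    sel <- which(idx == i)
    bs <- atoms$b[sel]
    if (alphafold && length(unique(round(bs, 4))) > 1)
      inconsistent <<- c(inconsistent, res_key[i])
    ca <- sel[atoms$elety[sel] == "CA"]
    if (length(ca) >= 1) atoms$b[ca[1]] else bs[1]
  }, numeric(1))
  if (length(inconsistent) > 0)
    warning(length(inconsistent), " residue(s) carry several B-factor ",
            "values; using the CA value")
  residues <- data.frame(
    resno = atoms$resno[first],
    resid = atoms$resid[first],
    plddt = plddt,
    standard = atoms$resid[first] %in% STANDARD_RESIDUES,
    stringsAsFactors = FALSE
  )
  if (any(!residues$standard))
    warning("nonstandard residue(s) retained for geometry but excluded from ",
            "residue-type descriptors: ",
            paste(unique(residues$resid[!residues$standard]), collapse = ", "))
  atoms$res_index <- idx
  structure(
    list(id = id, atoms = atoms, residues = residues, label = label),
    class = "ProteinStructure"
  )
}

#' @export
print.ProteinStructure <- function(x, ...) {
  cat("ProteinStructure", x$id, "\n")
  cat(" ", nrow(x$residues), "residues,", nrow(x$atoms), "atoms",
      sprintf("(%d heavy)", sum(x$atoms$elesy != "H")), "\n")
  cat("  mean pLDDT:", round(mean(x$residues$plddt), 2), "\n")
  if (!is.null(x$label)) cat("  label:", x$label, "\n")
  invisible(x)
}

#' Number of residues
#' @param s A `ProteinStructure`.
#' @return Integer residue count.
#' @export
n_residues <- function(s) nrow(s$residues)

.heavy <- function(s) s$atoms$elesy != "H"

.check_atom_lines <- function(lines) {
  rec <- grepl("^(ATOM  |HETATM)", lines)
  bad <- which(rec & nchar(lines) < 54)
  for (i in which(rec)) {
    if (nchar(lines[i]) < 54 ||
        anyNA(suppressWarnings(as.numeric(c(
          substr(lines[i], 31, 38), substr(lines[i], 39, 46),
          substr(lines[i], 47, 54)
        )))))
      stop("malformed ATOM record at line ", i, ": ", trimws(lines[i]))
  }
  if (!any(rec)) stop("no ATOM records found")
  invisible(TRUE)
}

#' Parse a PDB file in the AlphaFold dialect
#'
#' `parse_pdb()` reads PDB-format text; `read_protein_pdb()` reads a file.
#' ATOM records are grouped into residues in file order.  HETATM records
#' are ignored.  Hydrogens are retained but excluded from surface
#' computations by default.  Under the AlphaFold dialect the B-factor
#' column is interpreted as pLDDT (0-100) and validated accordingly.
#'
#' @param text Character scalar or vector of PDB lines.
#' @param path Path to a PDB file.
#' @param id Structure identifier (defaults to the file name for
#'   `read_protein_pdb`).
#' @param label,alphafold Passed to [protein_structure()].
#' @return A [protein_structure()].
#' @examples
#' helix <- make_ideal_helix(12)
#' f <- tempfile(fileext = ".pdb")
#' write_protein_pdb(helix, f)
#' s <- read_protein_pdb(f)
#' n_residues(s)
#' @export
parse_pdb <- function(text, id = "protein", label = NULL, alphafold = TRUE) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  .check_atom_lines(lines)
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  read_protein_pdb(tf, id = id, label = label, alphafold = alphafold)
}

#' @rdname parse_pdb
#' @export
read_protein_pdb <- function(path, id = sub("\\.pdb$", "", basename(path)),
                             label = NULL, alphafold = TRUE) {
  .check_atom_lines(readLines(path, warn = FALSE))
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records found in ", path)
  elesy <- at$elesy
  blank <- is.na(elesy) | elesy == ""
  if (any(blank)) # fall back on the first letter of the atom name
    elesy[blank] <- substr(gsub("[0-9]", "", at$elety[blank]), 1, 1)
  atoms <- data.frame(
    elety = at$elety, elesy = toupper(elesy), resid = at$resid,
    resno = at$resno, chain = at$chain,
    x = at$x, y = at$y, z = at$z, b = at$b,
    stringsAsFactors = FALSE
  )
  protein_structure(atoms, id = id, label = label, alphafold = alphafold)
}

#' Write a ProteinStructure to a PDB file
#'
#' Writes ATOM records with the per-atom B-factor column (pLDDT).
#'
#' @param s A `ProteinStructure`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_pdb <- function(s, path) {
  a <- s$atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    resno = a$resno, resid = a$resid, eleno = seq_len(nrow(a)),
    elety = a$elety, chain = ifelse(is.na(a$chain), "A", a$chain),
    o = rep(1, nrow(a)), b = a$b, elesy = a$elesy
  )
  invisible(path)
}

#' Assign van der Waals radii to atoms
#'
#' Radii are looked up by element.  The default table uses C 1.70, N 1.55,
#' O 1.52, S 1.80 (and H 1.20, though hydrogens are excluded from surface
#' computations by default).
#'
#' @param s A `ProteinStructure`.
#' @param radii_table Named numeric vector, element to radius
#'   (\ifelse{html}{\out{&Aring;}}{A}).
#' @param fallback Optional radius for elements missing from the table;
#'   when `NULL` (default) an unknown element is an error.
#' @return The structure with a `vdw` column on its atom table.
#' @export
assign_radii <- function(s, radii_table = vdw_radii(), fallback = NULL) {
  stopifnot(all(radii_table > 0))
  el <- s$atoms$elesy
  r <- unname(radii_table[el])
  if (anyNA(r)) {
    unknown <- sort(unique(el[is.na(r)]))
    if (is.null(fallback))
      stop("no van der Waals radius for element(s): ",
           paste(unknown, collapse = ", "))
    r[is.na(r)] <- fallback
  }
  s$atoms$vdw <- r
  s
}

#' Study inclusion filters
#'
#' A structure enters the analysis when its modelled length is within
#' 100-700 residues and its mean pLDDT is strictly greater than 50
#' (structures at or below 50 are expected to be largely intrinsically
#' disordered).
#'
#' @param s A `ProteinStructure`.
#' @param min_length,max_length Allowed residue-count range.
#' @param min_plddt Mean pLDDT must exceed this value (strict).
#' @return A list with `pass` (logical) and `reasons` (character vector of
#'   failed filters, empty when passing).
#' @examples
#' h <- make_ideal_helix(120, plddt = 85)
#' passes_inclusion_filters(h)$pass
#' @export
passes_inclusion_filters <- function(s, min_length = 100, max_length = 700,
                                     min_plddt = 50) {
  n <- n_residues(s)
  mp <- mean(s$residues$plddt)
  reasons <- character(0)
  if (n < min_length || n > max_length)
    reasons <- c(reasons, sprintf("length %d outside [%d, %d]",
                                  n, min_length, max_length))
  if (!(mp > min_plddt))
    reasons <- c(reasons, sprintf("mean pLDDT %.2f not > %g", mp, min_plddt))
  list(pass = length(reasons) == 0, reasons = reasons)
}

# Heavy-atom coordinate matrix and radii (the inputs of every surface op).
.surface_atoms <- function(s) {
  if (is.null(s$atoms$vdw))
    stop("assign_radii() must be called before surface computations")
  keep <- .heavy(s)
  list(
    xyz = as.matrix(s$atoms[keep, c("x", "y", "z")]),
    radii = s$atoms$vdw[keep],
    res_index = s$atoms$res_index[keep]
  )
}
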