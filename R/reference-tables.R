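# Reference tables shipped as plain-text data files under inst/extdata.

THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

STANDARD_RESIDUES <- names(THREE_TO_ONE)

.read_table <- local({
  cache <- new.env(parent = emptyenv())
  function(name) {
    if (!exists(name, envir = cache)) {
      path <- system.file("extdata", paste0(name, ".csv"), package = "hacsurf",
                          mustWork = TRUE)
      assign(name, read.csv(path, stringsAsFactors = FALSE), envir = cache)
    }
    get(name, envir = cache)
  }
})

#' Reference scales and tables
#'
#' Accessors for the data files shipped with the package:
#' * `hydrophobicity_scale()`: the normalized consensus hydrophobicity scale
#'   (Eisenberg et al.), a named vector over the 20 standard residues
#'   (maximum ILE 0.73, minimum ARG -1.76).
#' * `max_asa_table()`: theoretical maximum accessible surface areas
#'   (\ifelse{html}{\out{&Aring;&sup2;}}{A^2}) of residue X in an extended
#'   Gly-X-Gly tripeptide (Tien et al. 2013), the denominator of relative
#'   accessibility.
#' * `pka_table()`: side-chain pKa values and unit charges of the ionizable
#'   residues used for Henderson-Hasselbalch net surface charge.
#' * `vdw_radii()`: default van der Waals radii by element
#'   (\ifelse{html}{\out{&Aring;}}{A}).
#'
#' @return A named numeric vector (`hydrophobicity_scale`, `vdw_radii`),
#'   or a data frame (`max_asa_table`, `pka_table`).
#' @examples
#' hydrophobicity_scale()[["ILE"]]
#' max_asa_table()[max_asa_table()$residue == "GLY", "max_asa"]
#' @export
hydrophobicity_scale <- function() {
  tab <- .read_table("eisenberg_hydrophobicity")
  stats::setNames(tab$value, tab$residue)
}

#' @rdname hydrophobicity_scale
#' @export
max_asa_table <- function() .read_table("max_asa_theoretical")

#' @rdname hydrophobicity_scale
#' @export
pka_table <- function() .read_table("sidechain_pka")

#' @rdname hydrophobicity_scale
#' @export
vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20)
}

#' Published reference logistic-model coefficients
#'
#' Coefficient estimates, standard errors, odds ratios and 95% confidence
#' intervals of the seven-descriptor logistic model distinguishing highly
#' abundant cytoplasmic from extracellular human proteins, as reported in
#' the original published analysis of 668 AlphaFold-modelled proteins.
#' Shipped so that the arithmetic relationships between the columns
#' (odds ratio = exp(beta), CI = exp(beta +/- 1.96 SE)) can be recomputed
#' and checked with [wald_table()].
#'
#' @return Data frame with columns `descriptor`, `beta`, `se`, `z`,
#'   `odds_ratio`, `ci_lower`, `ci_upper`.
#' @export
reference_model_coefficients <- function() .read_table("reference_model_coefficients")
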