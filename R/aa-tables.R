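#' Reference tables for the 20 standard amino acids
#'
#' Small lookup tables used across the package: theoretical maximum
#' solvent-accessible surface areas for RSA normalisation, a hydropathy
#' scale, and residue molecular weights. All tables are named by one-letter
#' amino-acid code and cover exactly the 20 standard residues. Each function
#' returns a fresh copy, so callers may modify the result freely; every
#' consumer of these tables also accepts a user-supplied replacement (for
#' example a DSSP-derived max-ASA table).
#'
#' @details
#' `maxAsaTable()` returns theoretical maximum ASA values in squared
#' angstroms (Tien et al. 2013, theoretical column), the standard choice for
#' turning absolute into relative solvent accessibility.
#' `hydrophobicityScale()` returns the Kyte-Doolittle hydropathy index
#' (positive = hydrophobic). `residueMolecularWeights()` returns free
#' amino-acid molecular weights in daltons.
#'
#' @return A named numeric vector of length 20.
#' @examples
#' maxAsaTable()[["A"]]
#' hydrophobicityScale()[["I"]] > hydrophobicityScale()[["D"]]
#' @export
maxAsaTable <- function() {
    c(A = 129, R = 274, N = 195, D = 193, C = 167,
      E = 223, Q = 225, G = 104, H = 224, I = 197,
      L = 201, K = 236, M = 224, F = 240, P = 159,
      S = 155, T = 172, W = 285, Y = 263, V = 174)
}

#' @rdname maxAsaTable
#' @export
hydrophobicityScale <- function() {
    c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
      E = -3.5, Q = -3.5, G = -0.4, H = -3.2, I = 4.5,
      L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
      S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)
}

#' @rdname maxAsaTable
#' @export
residueMolecularWeights <- function() {
    c(A = 89.09, R = 174.20, N = 132.12, D = 133.10, C = 121.16,
      E = 147.13, Q = 146.15, G = 75.07, H = 155.15, I = 131.17,
      L = 131.17, K = 146.19, M = 149.21, F = 165.19, P = 115.13,
      S = 105.09, T = 119.12, W = 204.23, Y = 181.19, V = 117.15)
}

## one-letter alphabet, fixed ordering used by the generators
.AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## van der Waals radii (angstrom) for heavy elements seen in protein PDB
## files; used by the accessible-surface calculation
.atomRadii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)

.elementRadius <- function(element) {
    r <- .atomRadii[toupper(element)]
    r[is.na(r)] <- 1.70  # fall back to carbon for exotic heavy atoms
    unname(r)
}
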