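#' Parse a PDB file into a ProteinComplex
#'
#' Reads coordinate records from a PDB-format file and returns the heavy
#' atoms of the first model. Waters and all other hetero-compounds
#' (`HETATM` records) are excluded, as are hydrogen atoms. Residues are
#' renumbered sequentially (1-based) per chain in file order, which also
#' resolves insertion codes; author numbering is never propagated
#' downstream.
#'
#' @param file Path to a PDB-format file.
#' @param name Display name; defaults to the file name.
#' @return A [ProteinComplex-class] object.
#' @examples
#' f <- tempfile(fileext = ".pdb")
#' writeStructure(generateToyComplex(5, 5, 2, seed = 1)$structure, f)
#' parseStructure(f)
#' @seealso [writeStructure()]
#' @export
parseStructure <- function(file, name = basename(file)) {
    pdb <- bio3d::read.pdb(file, multi = FALSE, verbose = FALSE)
    a <- pdb$atom
    a <- a[a$type == "ATOM", , drop = FALSE]
    if (nrow(a) == 0L) stop("empty-structure: no ATOM records in ", file,
                            call. = FALSE)
    elem <- a$elesy
    blank <- is.na(elem) | elem == ""
    ## fall back to the first letter of the atom name when the element
    ## column is absent (common in minimal files)
    elem[blank] <- substr(gsub("^[0-9]", "", a$elety[blank]), 1L, 1L)
    keep <- toupper(elem) != "H"
    a <- a[keep, , drop = FALSE]
    elem <- elem[keep]
    if (nrow(a) == 0L) stop("empty-structure: only hydrogens in ", file,
                            call. = FALSE)
    chain <- a$chain
    chain[is.na(chain)] <- " "
    ins <- a$insert
    ins[is.na(ins)] <- ""
    rid <- paste(chain, a$resno, ins, sep = "|")
    ## sequential renumbering per chain, in order of first appearance
    pos <- integer(nrow(a))
    for (ch in unique(chain)) {
        i <- chain == ch
        pos[i] <- match(rid[i], unique(rid[i]))
    }
    ProteinComplex(
        atoms = data.frame(chain = chain, pos = pos,
                           resid = bio3d::aa321(a$resid),
                           atom = a$elety, element = toupper(elem),
                           x = a$x, y = a$y, z = a$z,
                           stringsAsFactors = FALSE),
        name = name)
}

#' Write a ProteinComplex as a single-model PDB file
#'
#' Emits standard `ATOM` records (one `MODEL`, `TER` after each chain) so
#' that generated structures round-trip through [parseStructure()] and are
#' readable by any PDB-aware tool.
#'
#' @param x A [ProteinComplex-class].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
writeStructure <- function(x, file) {
    a <- atomTable(x)
    aa3 <- bio3d::aa123(a$resid)
    lines <- c("MODEL        1")
    serial <- 0L
    for (ch in unique(a$chain)) {
        ai <- a[a$chain == ch, , drop = FALSE]
        ai <- ai[order(ai$pos), , drop = FALSE]
        for (i in seq_len(nrow(ai))) {
            serial <- serial + 1L
            lines <- c(lines, sprintf(
                "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                serial, paste0(" ", ai$atom[i]),
                bio3d::aa123(ai$resid[i]), ch, ai$pos[i],
                ai$x[i], ai$y[i], ai$z[i], ai$element[i]))
        }
        lines <- c(lines, "TER")
    }
    lines <- c(lines, "ENDMDL", "END")
    writeLines(lines, file)
    invisible(file)
}

#' Binding-interface residues of a chain pair
#'
#' A residue of one chain is interfacial if its minimum heavy-atom distance
#' to any atom of the partner chain is at most `cutoff` angstrom; the
#' distance between two residues is the minimum over all pairs of their
#' heavy atoms. The default 5 angstrom cutoff is the standard contact
#' threshold in structural biology; 4 and 6 angstrom are common
#' alternatives used for robustness checks.
#'
#' @param x A [ProteinComplex-class].
#' @param chain_a,chain_b Chain identifiers; both must be present.
#' @param cutoff Distance cutoff in angstrom (default 5.0).
#' @return A list with integer vectors `a` and `b`: the 1-based positions
#'   of interfacial residues on each chain (sorted).
#' @examples
#' cx <- generateToyComplex(8, 8, 3, seed = 1)
#' identical(interfaceResidues(cx$structure, "A", "B")$a, cx$interface$A)
#' @export
interfaceResidues <- function(x, chain_a, chain_b, cutoff = 5.0) {
    a <- atomTable(x)
    for (ch in c(chain_a, chain_b)) {
        if (!ch %in% a$chain) stop("missing-chain: ", ch, call. = FALSE)
    }
    A <- a[a$chain == chain_a, , drop = FALSE]
    B <- a[a$chain == chain_b, , drop = FALSE]
    ca <- as.matrix(A[, c("x", "y", "z")])
    cb <- as.matrix(B[, c("x", "y", "z")])
    ## squared cross-distance matrix, atoms of A x atoms of B
    d2 <- outer(rowSums(ca^2), rowSums(cb^2), "+") - 2 * tcrossprod(ca, cb)
    hit <- d2 <= cutoff^2 + 1e-12
    ia <- sort(unique(A$pos[rowSums(hit) > 0L]))
    ib <- sort(unique(B$pos[colSums(hit) > 0L]))
    list(a = as.integer(ia), b = as.integer(ib))
}

#' Residue distance to the protein center, relative to the protein radius
#'
#' For each residue of a chain, the Euclidean distance from the residue's
#' heavy-atom centroid to the chain's all-heavy-atom centroid, divided by
#' the maximum such distance over the chain (the protein "radius"). The
#' farthest residue scores 1; a residue at the centroid scores 0. A
#' single-residue chain is defined to have ratio 0.
#'
#' @param x A [ProteinComplex-class].
#' @param chain Chain identifier.
#' @return Named numeric vector of ratios in `[0, 1]`, indexed by residue
#'   position.
#' @export
centerDistanceRatio <- function(x, chain) {
    a <- atomTable(x)
    if (!chain %in% a$chain) stop("missing-chain: ", chain, call. = FALSE)
    a <- a[a$chain == chain, , drop = FALSE]
    xyz <- as.matrix(a[, c("x", "y", "z")])
    center <- colMeans(xyz)
    pos <- sort(unique(a$pos))
    d <- vapply(pos, function(p) {
        cen <- colMeans(xyz[a$pos == p, , drop = FALSE])
        sqrt(sum((cen - center)^2))
    }, 0)
    r <- max(d)
    out <- if (r <= 0) rep(0, length(d)) else d / r
    names(out) <- pos
    out
}

#' Relative solvent accessibility
#'
#' RSA is the residue's absolute solvent-accessible surface area divided by
#' the maximum ASA of its amino-acid type. Values are not clipped at 1: an
#' observed ASA above the table maximum yields an RSA above 1. The default
#' normalisation table is [maxAsaTable()]; supply `table` to use e.g. a
#' DSSP-derived 99.99th-percentile table instead.
#'
#' @param asa Numeric vector of ASA values in squared angstrom.
#' @param restype One-letter amino-acid codes, recycled against `asa`.
#' @param table Named max-ASA table.
#' @return Numeric vector of RSA values (`>= 0`).
#' @export
relativeSolventAccessibility <- function(asa, restype, table = maxAsaTable()) {
    restype <- rep_len(restype, length(asa))
    unknown <- setdiff(unique(restype), names(table))
    if (length(unknown) > 0L)
        stop("table-miss: no max ASA for residue type(s) ",
             paste(unknown, collapse = ", "), call. = FALSE)
    if (any(asa < 0)) stop("asa must be nonnegative", call. = FALSE)
    unname(asa / table[restype])
}

#' Compare RSA distributions between a group and a background
#'
#' Welch two-sample t-test (two-sided) between a group of residues (for
#' example, residues carrying pathogenic mutations) and a background set
#' (for example, all residues), reporting the display quantities alongside
#' the test: group means and standard errors of the mean.
#'
#' @param group_values,background_values Numeric vectors, each of length
#'   at least 2.
#' @return A list with elements `t`, `p`, `mean_group`, `mean_background`,
#'   `se_group`, `se_background`, `df`.
#' @export
compareRsaDistributions <- function(group_values, background_values) {
    if (length(group_values) < 2L || length(background_values) < 2L)
        stop("both samples must have size >= 2", call. = FALSE)
    if (stats::var(group_values) == 0 && stats::var(background_values) == 0)
        stop("degenerate-input: zero variance in both groups", call. = FALSE)
    ht <- stats::t.test(group_values, background_values,
                        alternative = "two.sided", var.equal = FALSE)
    list(t = unname(ht$statistic), p = ht$p.value,
         mean_group = mean(group_values),
         mean_background = mean(background_values),
         se_group = stats::sd(group_values) / sqrt(length(group_values)),
         se_background = stats::sd(background_values) /
             sqrt(length(background_values)),
         df = unname(ht$parameter))
}
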