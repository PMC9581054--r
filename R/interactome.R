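#' Load a reference interactome edge list
#'
#' Reads a two-column, tab-separated table of protein identifier pairs and
#' returns the deduplicated set of unordered interaction edges.
#' Self-interactions are retained; `(A,B)` and `(B,A)` collapse to one
#' edge.
#'
#' @param x Path to a TSV file (header optional, detected by the literal
#'   column names `protein_a`/`protein_b`) or a two-column `data.frame`.
#' @return A `data.frame` with columns `protein_a`, `protein_b` (the pair
#'   sorted lexicographically) and attribute `n_input` recording the raw
#'   row count.
#' @examples
#' loadInteractome(data.frame(a = c("P1", "P2", "P1"),
#'                            b = c("P2", "P1", "P2")))
#' @export
loadInteractome <- function(x) {
    if (is.character(x)) {
        lines <- readLines(x)
        lines <- lines[nzchar(trimws(lines))]
        parts <- strsplit(lines, "\t", fixed = TRUE)
        bad <- which(lengths(parts) != 2L)
        if (length(bad) > 0L)
            stop("parse-error: line ", bad[1L], " of ", x,
                 " does not have exactly 2 tab-separated fields",
                 call. = FALSE)
        df <- data.frame(protein_a = vapply(parts, `[[`, "", 1L),
                         protein_b = vapply(parts, `[[`, "", 2L),
                         stringsAsFactors = FALSE)
        if (identical(tolower(unlist(df[1L, ])),
                      c("protein_a", "protein_b")))
            df <- df[-1L, , drop = FALSE]
    } else {
        if (ncol(x) < 2L)
            stop("parse-error: edge table needs two columns", call. = FALSE)
        df <- data.frame(protein_a = as.character(x[[1L]]),
                         protein_b = as.character(x[[2L]]),
                         stringsAsFactors = FALSE)
    }
    if (any(!nzchar(df$protein_a) | !nzchar(df$protein_b)))
        stop("parse-error: empty protein identifier", call. = FALSE)
    n_input <- nrow(df)
    a <- pmin(df$protein_a, df$protein_b)
    b <- pmax(df$protein_a, df$protein_b)
    edges <- unique(data.frame(protein_a = a, protein_b = b,
                               stringsAsFactors = FALSE))
    rownames(edges) <- NULL
    attr(edges, "n_input") <- n_input
    edges
}

## expand an alignment record (aligned strings with gaps) into strictly
## increasing (protein_pos, chain_pos) pairs over non-gap columns
.alignmentPairs <- function(qstart, sstart, qseq, sseq) {
    q <- strsplit(qseq, "")[[1]]
    s <- strsplit(sseq, "")[[1]]
    if (length(q) != length(s))
        stop("parse-error: aligned strings differ in length", call. = FALSE)
    qpos <- qstart - 1L + cumsum(q != "-")
    spos <- sstart - 1L + cumsum(s != "-")
    keep <- q != "-" & s != "-"
    cbind(protein_pos = qpos[keep], chain_pos = spos[keep])
}

#' Select the best alignment per (protein, chain) pair
#'
#' Keeps, for every combination of protein and template chain, the
#' alignment with the smallest E-value. Ties are broken by the larger
#' number of aligned residue pairs, then by lexicographic chain
#' identifier, making the choice deterministic.
#'
#' @param alignments `data.frame` with columns `protein`, `chain`,
#'   `evalue`, `qstart`, `qend`, `sstart`, `send`, `qseq`, `sseq`
#'   (aligned strings, `-` for gaps).
#' @param evalue_cutoff Alignments with E-value above this are dropped
#'   first (default `1e-5`).
#' @return The filtered `data.frame`, one row per (protein, chain), with
#'   an added column `n_pairs`.
#' @export
selectBestAlignment <- function(alignments, evalue_cutoff = 1e-5) {
    .assertColumns(alignments, c("protein", "chain", "evalue", "qstart",
                                 "sstart", "qseq", "sseq"), "alignment table")
    al <- alignments[alignments$evalue <= evalue_cutoff, , drop = FALSE]
    if (nrow(al) == 0L) return(cbind(al, n_pairs = integer(0)))
    al$n_pairs <- vapply(seq_len(nrow(al)), function(i) {
        nrow(.alignmentPairs(al$qstart[i], al$sstart[i], al$qseq[i],
                             al$sseq[i]))
    }, 0L)
    key <- paste(al$protein, al$chain, sep = "\r")
    ord <- order(key, al$evalue, -al$n_pairs, al$chain)
    al <- al[ord, , drop = FALSE]
    al <- al[!duplicated(key[ord]), , drop = FALSE]
    rownames(al) <- NULL
    al
}

#' Annotate a PPI with a chain-pair template
#'
#' A PPI is annotated with a template chain pair when (1) the two chains
#' share a binding interface, (2) each protein of the pair aligns to one
#' of the chains, and (3) at least half of each chain's template interface
#' residues map onto the corresponding protein through the alignment.
#' Coverage is the fraction of template interface residues on a chain that
#' have an aligned protein position.
#'
#' Both assignments of proteins to chains are tried; the orientation with
#' the higher `min(coverage_a, coverage_b)` wins (then higher summed
#' coverage).
#'
#' @param protein_a,protein_b Protein identifiers of the edge.
#' @param chain_a,chain_b Template chain identifiers (as used in the
#'   alignment table's `chain` column).
#' @param alignments Output of [selectBestAlignment()].
#' @param interface List with the template interface positions of
#'   `chain_a` and `chain_b` (integer vectors named `a` and `b`, as
#'   returned by [interfaceResidues()]).
#' @param min_coverage Acceptance threshold on both coverages
#'   (default 0.5).
#' @return A list with `accepted` (logical), `reason` (`"ok"` or a
#'   rejection code), `coverage_a`, `coverage_b`, and for accepted
#'   annotations `map_a`, `map_b` -- two-column matrices of
#'   (protein_pos, chain_pos) pairs for protein a/chain and protein
#'   b/chain -- plus the resolved `orientation` (`protein_a` mapped to
#'   `chain_a`, or swapped).
#' @export
annotatePpi <- function(protein_a, protein_b, chain_a, chain_b,
                        alignments, interface, min_coverage = 0.5) {
    if (length(interface$a) == 0L || length(interface$b) == 0L) {
        return(list(accepted = FALSE, reason = "no-template-interface",
                    coverage_a = NA_real_, coverage_b = NA_real_))
    }
    getAl <- function(protein, chain) {
        i <- which(alignments$protein == protein & alignments$chain == chain)
        if (length(i) == 0L) return(NULL)
        alignments[i[1L], , drop = FALSE]
    }
    tryOrient <- function(pa, pb) {
        ala <- getAl(pa, chain_a)
        alb <- getAl(pb, chain_b)
        if (is.null(ala) || is.null(alb)) return(NULL)
        mapa <- .alignmentPairs(ala$qstart, ala$sstart, ala$qseq, ala$sseq)
        mapb <- .alignmentPairs(alb$qstart, alb$sstart, alb$qseq, alb$sseq)
        cov_a <- mean(interface$a %in% mapa[, "chain_pos"])
        cov_b <- mean(interface$b %in% mapb[, "chain_pos"])
        list(coverage_a = cov_a, coverage_b = cov_b,
             map_a = mapa, map_b = mapb, proteins = c(pa, pb))
    }
    cands <- Filter(Negate(is.null),
                    list(tryOrient(protein_a, protein_b),
                         if (protein_a != protein_b)
                             tryOrient(protein_b, protein_a)))
    if (length(cands) == 0L) {
        return(list(accepted = FALSE, reason = "missing-alignment",
                    coverage_a = NA_real_, coverage_b = NA_real_))
    }
    score <- vapply(cands, function(cc)
        min(cc$coverage_a, cc$coverage_b) +
            1e-6 * (cc$coverage_a + cc$coverage_b), 0)
    best <- cands[[which.max(score)]]
    if (best$coverage_a >= min_coverage && best$coverage_b >= min_coverage) {
        list(accepted = TRUE, reason = "ok",
             coverage_a = best$coverage_a, coverage_b = best$coverage_b,
             map_a = best$map_a, map_b = best$map_b,
             orientation = best$proteins)
    } else {
        list(accepted = FALSE, reason = "low-coverage",
             coverage_a = best$coverage_a, coverage_b = best$coverage_b)
    }
}

#' Transfer template interface positions onto a protein
#'
#' Maps chain-level interface positions through an alignment position map
#' to protein coordinates. Template interface positions without an aligned
#' protein position are dropped and counted.
#'
#' @param chain_interface Integer vector of chain positions.
#' @param map Two-column matrix `(protein_pos, chain_pos)` as produced by
#'   [annotatePpi()].
#' @return A list with `positions` (sorted protein positions) and
#'   `dropped` (count of unmapped template interface residues).
#' @export
transferInterface <- function(chain_interface, map) {
    idx <- match(chain_interface, map[, "chain_pos"])
    dropped <- sum(is.na(idx))
    list(positions = sort(as.integer(map[idx[!is.na(idx)], "protein_pos"])),
         dropped = dropped)
}

#' Choose one chain-pair annotation per PPI
#'
#' When several chain-pair templates pass the coverage rule for one PPI,
#' the annotation maximising `min(coverage_a, coverage_b)` is kept, ties
#' broken by summed coverage and then by lexicographic template
#' identifier.
#'
#' @param annotations A list of accepted annotation records, each carrying
#'   `coverage_a`, `coverage_b` and a `template` identifier.
#' @return The selected annotation (or `NULL` for an empty list).
#' @export
selectTemplate <- function(annotations) {
    if (length(annotations) == 0L) return(NULL)
    keys <- vapply(annotations, function(a) {
        sprintf("%.9f|%.9f|%s",
                min(a$coverage_a, a$coverage_b),
                a$coverage_a + a$coverage_b,
                a$template)
    }, "")
    mins <- vapply(annotations, function(a) min(a$coverage_a, a$coverage_b), 0)
    sums <- vapply(annotations, function(a) a$coverage_a + a$coverage_b, 0)
    tmpl <- vapply(annotations, function(a) as.character(a$template), "")
    ord <- order(-mins, -sums, tmpl)
    annotations[[ord[1L]]]
}
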