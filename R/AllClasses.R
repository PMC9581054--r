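#' @import methods
NULL

## ---------------------------------------------------------------------------
## ProteinComplex
## ---------------------------------------------------------------------------

#' Heavy-atom coordinates of a (possibly multi-chain) structure
#'
#' `ProteinComplex` holds the heavy-atom coordinates of a single structural
#' model, organised by chain and by a sequential 1-based residue position.
#' It is the container produced by [parseStructure()] and by the synthetic
#' complex generator, and consumed by all geometry operations. Only one
#' model's coordinates are ever retained; waters, hetero-compounds and
#' hydrogens are excluded at construction time.
#'
#' @slot atoms A `data.frame` with one row per heavy atom and columns
#'   `chain` (chain identifier), `pos` (sequential 1-based residue position
#'   within the chain), `resid` (one-letter amino-acid code), `atom` (atom
#'   name, e.g. `"CA"`), `element` (element symbol) and Cartesian
#'   coordinates `x`, `y`, `z` in angstrom.
#' @slot name A display name for the structure.
#'
#' @seealso [parseStructure()], [generateToyComplex()],
#'   [interfaceResidues()], [residueSasa()]
#' @export
setClass("ProteinComplex",
    representation(atoms = "data.frame", name = "character"),
    prototype(atoms = data.frame(), name = "structure"))

setValidity("ProteinComplex", function(object) {
    need <- c("chain", "pos", "resid", "atom", "element", "x", "y", "z")
    miss <- setdiff(need, names(object@atoms))
    if (length(miss) > 0L)
        return(paste("atoms is missing column(s):", paste(miss, collapse = ", ")))
    a <- object@atoms
    if (nrow(a) == 0L)
        return("empty-structure: no heavy atoms")
    if (!all(is.finite(a$x), is.finite(a$y), is.finite(a$z)))
        return("non-finite coordinates")
    ## each residue must have at least one heavy atom: positions must be a
    ## gap-free 1..n sequence per chain
    for (ch in unique(a$chain)) {
        p <- sort(unique(a$pos[a$chain == ch]))
        if (!identical(p, seq_along(p)))
            return(paste0("chain ", ch, ": residue positions are not 1..n"))
    }
    TRUE
})

#' Construct a ProteinComplex from an atom table
#'
#' @param atoms Atom-level `data.frame`; see the class slot documentation.
#' @param name Display name.
#' @return A [ProteinComplex-class] object.
#' @examples
#' cx <- generateToyComplex(4, 4, 2, seed = 1)$structure
#' chainIds(cx)
#' @export
ProteinComplex <- function(atoms, name = "structure") {
    new("ProteinComplex", atoms = atoms, name = name)
}

#' @describeIn ProteinComplex Chain identifiers present in the structure.
#' @param x,object A `ProteinComplex`.
#' @export
setGeneric("chainIds", function(x) standardGeneric("chainIds"))

#' @rdname ProteinComplex
#' @export
setMethod("chainIds", "ProteinComplex", function(x) {
    unique(x@atoms$chain)
})

#' @describeIn ProteinComplex Number of residues, optionally per chain.
#' @param chain Optional chain identifier.
#' @export
setGeneric("nResidues", function(x, chain = NULL) standardGeneric("nResidues"))

#' @rdname ProteinComplex
#' @export
setMethod("nResidues", "ProteinComplex", function(x, chain = NULL) {
    a <- x@atoms
    if (!is.null(chain)) {
        if (!chain %in% a$chain) stop("missing-chain: ", chain, call. = FALSE)
        a <- a[a$chain == chain, , drop = FALSE]
    }
    nrow(unique(a[, c("chain", "pos")]))
})

#' @describeIn ProteinComplex One-letter residue sequence of a chain.
#' @export
setGeneric("residueSequence",
    function(x, chain) standardGeneric("residueSequence"))

#' @rdname ProteinComplex
#' @export
setMethod("residueSequence", "ProteinComplex", function(x, chain) {
    a <- x@atoms[x@atoms$chain == chain, , drop = FALSE]
    if (nrow(a) == 0L) stop("missing-chain: ", chain, call. = FALSE)
    a <- a[!duplicated(a$pos), , drop = FALSE]
    paste(a$resid[order(a$pos)], collapse = "")
})

#' @describeIn ProteinComplex Atom-level table (a copy).
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' @rdname ProteinComplex
#' @export
setMethod("atomTable", "ProteinComplex", function(x) x@atoms)

setMethod("show", "ProteinComplex", function(object) {
    a <- object@atoms
    ch <- unique(a$chain)
    nres <- vapply(ch, function(c) length(unique(a$pos[a$chain == c])), 0L)
    cat("ProteinComplex \"", object@name, "\": ", length(ch), " chain(s), ",
        sum(nres), " residues, ", nrow(a), " heavy atoms\n", sep = "")
    cat("  ", paste(sprintf("%s (%d res)", ch, nres), collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## EdgotypeProbs
## ---------------------------------------------------------------------------

#' Class-conditional edgotype probabilities
#'
#' Holds, for each phenotype class (non-pathogenic mutations, taken as
#' effectively neutral; pathogenic mutations, taken as mildly deleterious),
#' the probability that a mutation of that class is quasi-wild-type, edgetic
#' or quasi-null, together with the count basis behind each probability and
#' the assumption governing the (unobserved) edgotype distribution of
#' strongly detrimental mutations:
#' Assumption `"I"` -- strongly detrimental mutations are all quasi-null;
#' Assumption `"II"` -- strongly detrimental mutations share the edgotype
#' distribution of mildly deleterious mutations.
#'
#' @slot cond 2x3 numeric matrix of conditional probabilities; rows
#'   `nonpathogenic`, `pathogenic`; columns `quasi-wild-type`, `edgetic`,
#'   `quasi-null`. Each row sums to 1.
#' @slot counts 2x3 numeric matrix of the success counts behind `cond`
#'   (may contain `NA` when probabilities were supplied directly).
#' @slot n Named numeric vector of row totals (`nonpathogenic`,
#'   `pathogenic`); `NA` when unknown.
#' @slot assumption `"I"` or `"II"`.
#' @slot dataset Free-text label of the edgotype data source.
#'
#' @seealso [conditionalProbs()], [edgotypeProbs()], [fitnessPosterior()]
#' @export
setClass("EdgotypeProbs",
    representation(cond = "matrix", counts = "matrix", n = "numeric",
                   assumption = "character", dataset = "character"))

setValidity("EdgotypeProbs", function(object) {
    if (!identical(dim(object@cond), c(2L, 3L)))
        return("cond must be a 2x3 matrix")
    if (!identical(rownames(object@cond), .PHENOTYPES) ||
        !identical(colnames(object@cond), .EDGOTYPES))
        return("cond must have rows nonpathogenic/pathogenic and the three edgotype columns")
    if (any(object@cond < 0))
        return("conditional probabilities must be nonnegative")
    if (any(abs(rowSums(object@cond) - 1) > 1e-9))
        return("each row of cond must sum to 1 (tolerance 1e-9)")
    if (!object@assumption %in% c("I", "II"))
        return("assumption must be \"I\" or \"II\"")
    TRUE
})

#' @describeIn EdgotypeProbs The 2x3 conditional-probability matrix.
#' @param object,x An `EdgotypeProbs` object.
#' @export
setGeneric("conditionals", function(object) standardGeneric("conditionals"))

#' @rdname EdgotypeProbs
#' @export
setMethod("conditionals", "EdgotypeProbs", function(object) object@cond)

#' @describeIn EdgotypeProbs The assumption label (`"I"` or `"II"`).
#' @export
setGeneric("assumption", function(object) standardGeneric("assumption"))

#' @rdname EdgotypeProbs
#' @export
setMethod("assumption", "EdgotypeProbs", function(object) object@assumption)

#' @describeIn EdgotypeProbs Conditional edgotype probabilities of strongly
#'   detrimental mutations implied by the assumption.
#' @export
setGeneric("strongConditionals",
    function(object) standardGeneric("strongConditionals"))

#' @rdname EdgotypeProbs
#' @export
setMethod("strongConditionals", "EdgotypeProbs", function(object) {
    if (object@assumption == "I") {
        c("quasi-wild-type" = 0, "edgetic" = 0, "quasi-null" = 1)
    } else {
        p <- object@cond["pathogenic", ]
        names(p) <- .EDGOTYPES
        p
    }
})

setMethod("show", "EdgotypeProbs", function(object) {
    cat("EdgotypeProbs (", object@dataset, "), Assumption ",
        object@assumption, "\n", sep = "")
    print(round(object@cond, 4))
    if (!all(is.na(object@n)))
        cat("  n =", paste(object@n, collapse = " / "), "\n")
})

## ---------------------------------------------------------------------------
## FitnessPosterior
## ---------------------------------------------------------------------------

#' Posterior fitness-effect probabilities per edgotype
#'
#' The result of propagating class-conditional edgotype probabilities and
#' the genome-wide fitness-class priors through the total-probability /
#' Bayes chain: for each edgotype T, the marginal P(T) and the posteriors
#' P(neutral | T), P(mild | T), P(strong | T), with 95% confidence
#' intervals where a count basis is available.
#'
#' @slot table `data.frame` with one row per (edgotype, fitness class):
#'   columns `edgotype`, `fitness`, `p_t`, `estimate`, `ci_lo`, `ci_hi`.
#' @slot priors Named numeric vector `neutral`/`mild`/`strong`, summing
#'   to 1.
#' @slot assumption `"I"` or `"II"`.
#' @slot dataset Label inherited from the input [EdgotypeProbs-class].
#'
#' @seealso [fitnessPosterior()], [blandCi()], [mergeAssumptions()]
#' @export
setClass("FitnessPosterior",
    representation(table = "data.frame", priors = "numeric",
                   assumption = "character", dataset = "character"))

setValidity("FitnessPosterior", function(object) {
    tb <- object@table
    need <- c("edgotype", "fitness", "p_t", "estimate", "ci_lo", "ci_hi")
    if (!all(need %in% names(tb)))
        return("table is missing required columns")
    if (abs(sum(object@priors) - 1) > 1e-9)
        return("priors must sum to 1")
    ## posteriors must sum to 1 within each edgotype, and marginals to 1
    for (t in unique(tb$edgotype)) {
        s <- sum(tb$estimate[tb$edgotype == t])
        if (abs(s - 1) > 1e-9)
            return(paste0("posteriors for ", t, " sum to ", s, ", not 1"))
    }
    pt <- tb$p_t[!duplicated(tb$edgotype)]
    if (abs(sum(pt) - 1) > 1e-9)
        return("edgotype marginals do not sum to 1")
    TRUE
})

#' @describeIn FitnessPosterior The long-format posterior table.
#' @param object A `FitnessPosterior`.
#' @export
setGeneric("posteriorTable", function(object) standardGeneric("posteriorTable"))

#' @rdname FitnessPosterior
#' @export
setMethod("posteriorTable", "FitnessPosterior", function(object) object@table)

setMethod("show", "FitnessPosterior", function(object) {
    cat("FitnessPosterior (", object@dataset, "), Assumption ",
        object@assumption, "\n", sep = "")
    tb <- object@table
    tb$estimate <- round(tb$estimate, 4)
    tb$ci_lo <- round(tb$ci_lo, 4)
    tb$ci_hi <- round(tb$ci_hi, 4)
    tb$p_t <- round(tb$p_t, 4)
    print(tb, row.names = FALSE)
})
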