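## ---------------------------------------------------------------------------
## SyntheticScenario
## ---------------------------------------------------------------------------

#' Parameters of a synthetic edgotype study
#'
#' A validated parameter object describing one synthetic "study": how many
#' proteins and PPIs to simulate, what fraction of residues per chain is
#' interfacial, the class-conditional edgotype probabilities for
#' non-pathogenic and pathogenic mutations, the class-conditional
#' free-energy-change distributions, and the fraction of mutation records
#' whose transcript flank is deliberately corrupted.
#'
#' @slot seed Integer seed controlling every random draw.
#' @slot nProteins,nPPIs Positive counts.
#' @slot interfaceFraction Fraction in (0, 1) of residues designated
#'   interfacial per chain.
#' @slot edgotypeProbs 2x3 matrix (rows `nonpathogenic`, `pathogenic`;
#'   columns quasi-wild-type / edgetic / quasi-null), each row summing
#'   to 1.
#' @slot ddgParams List of truncated-normal parameters, see
#'   [defaultDdgParams()].
#' @slot flankCorruptionRate Fraction in `[0, 1]`.
#' @seealso [syntheticScenario()], [generateScenarioBundle()]
#' @export
setClass("SyntheticScenario",
    representation(seed = "integer", nProteins = "integer", nPPIs = "integer",
                   interfaceFraction = "numeric", edgotypeProbs = "matrix",
                   ddgParams = "list", flankCorruptionRate = "numeric"))

setValidity("SyntheticScenario", function(object) {
    if (object@nProteins < 1L || object@nPPIs < 1L)
        return("counts must be positive")
    f <- object@interfaceFraction
    if (!(f > 0 && f < 1))
        return("interfaceFraction must lie in (0, 1)")
    p <- object@edgotypeProbs
    if (!identical(dim(p), c(2L, 3L)))
        return("edgotypeProbs must be a 2x3 matrix")
    if (any(p < 0) || any(abs(rowSums(p) - 1) > 1e-12))
        return("each edgotype probability row must sum to 1 (tolerance 1e-12)")
    r <- object@flankCorruptionRate
    if (!(r >= 0 && r <= 1))
        return("flankCorruptionRate must lie in [0, 1]")
    TRUE
})

setMethod("show", "SyntheticScenario", function(object) {
    cat("SyntheticScenario: ", object@nProteins, " proteins, ",
        object@nPPIs, " PPIs, interface fraction ",
        object@interfaceFraction, ", flank corruption ",
        object@flankCorruptionRate, ", seed ", object@seed, "\n", sep = "")
    print(round(object@edgotypeProbs, 4))
})

#' Construct a SyntheticScenario
#'
#' Defaults describe a desk-scale study with the class-conditional
#' edgotype probabilities observed for the Y2H structural interactome
#' (roughly 97/1.5/1.5% of non-pathogenic and 74/13/13% of pathogenic
#' mutations being quasi-wild-type / edgetic / quasi-null).
#'
#' @param seed Integer seed.
#' @param n_proteins,n_ppis Positive counts.
#' @param interface_fraction Fraction in (0, 1).
#' @param edgotype_probs 2x3 matrix as documented for the class.
#' @param ddg_params See [defaultDdgParams()].
#' @param flank_corruption_rate Fraction in `[0, 1]`.
#' @return A [SyntheticScenario-class] object.
#' @examples
#' syntheticScenario(seed = 7)
#' @export
syntheticScenario <- function(seed = 1L,
                              n_proteins = 24L,
                              n_ppis = 30L,
                              interface_fraction = 0.15,
                              edgotype_probs = defaultEdgotypeProbs(),
                              ddg_params = defaultDdgParams(),
                              flank_corruption_rate = 0.05) {
    new("SyntheticScenario", seed = as.integer(seed),
        nProteins = as.integer(n_proteins), nPPIs = as.integer(n_ppis),
        interfaceFraction = interface_fraction,
        edgotypeProbs = edgotype_probs, ddgParams = ddg_params,
        flankCorruptionRate = flank_corruption_rate)
}

#' @rdname syntheticScenario
#' @export
defaultEdgotypeProbs <- function() {
    m <- rbind(nonpathogenic = c(0.97, 0.015, 0.015),
               pathogenic = c(0.74, 0.13, 0.13))
    colnames(m) <- .EDGOTYPES
    m
}

#' Class-conditional free-energy-change distributions
#'
#' Parameters (kcal/mol) of the truncated Gaussians used to draw synthetic
#' folding and binding free-energy changes. The truncation bounds keep the
#' ground truth unambiguous with respect to the classification thresholds:
#' disruptive binding values stay above 0.5 (truncated at 0.6), benign
#' binding values below 0.5 (truncated at 0.45), disruptive folding values
#' at or above 2 and benign folding values well below 2.
#'
#' @return A list with elements `binding_disrupt`, `binding_benign`,
#'   `folding_disrupt`, `folding_benign`; each a named vector with `mean`,
#'   `sd` and a one-sided truncation bound (`lower` or `upper`).
#' @export
defaultDdgParams <- function() {
    list(binding_disrupt = c(mean = 2.5, sd = 1.0, lower = 0.6),
         binding_benign = c(mean = 0.0, sd = 0.3, upper = 0.45),
         folding_disrupt = c(mean = 3.5, sd = 1.0, lower = 2.0),
         folding_benign = c(mean = 0.0, sd = 0.3, upper = 0.45))
}

## ---------------------------------------------------------------------------
## Toy chain-pair complexes
## ---------------------------------------------------------------------------

#' Generate a two-chain toy complex with a known binding interface
#'
#' Builds a two-chain structure in which exactly `n_interface` designated
#' residue pairs are in contact (minimum heavy-atom distance 3.9 angstrom,
#' comfortably below the 5 angstrom interface cutoff) and every other
#' cross-chain residue pair is farther than 6.5 angstrom, so interface
#' recovery by distance scanning is unambiguous under the whole 4-6
#' angstrom cutoff sweep. Each residue carries two heavy atoms: a
#' backbone-like `CA` pseudo-atom and a side-chain-like `CB` offset atom.
#' Non-interface residues fill compact cubic-lattice blocks (4.6 angstrom
#' spacing), one block per chain, separated by 12 angstrom; interior block
#' residues end up solvent-buried (relative accessibility at or below
#' 0.25), giving a buried/exposed mix comparable to globular proteins.
#'
#' @param n_residues_a,n_residues_b Residue counts of chains A and B.
#' @param n_interface Number of interfacial residues per chain; must not
#'   exceed `min(n_residues_a, n_residues_b)`.
#' @param seed Integer seed; fixes residue identities, interface placement
#'   and jitter.
#' @param seq_a,seq_b Optional one-letter sequences for the chains
#'   (lengths must match the residue counts); random sequences are drawn
#'   otherwise.
#' @return A list with `structure` (a [ProteinComplex-class]) and
#'   `interface`, itself a list of sorted integer positions `A` and `B` --
#'   the ground-truth interfacial residues of each chain.
#' @examples
#' cx <- generateToyComplex(10, 10, 3, seed = 1)
#' length(cx$interface$A)
#' @export
generateToyComplex <- function(n_residues_a, n_residues_b, n_interface, seed,
                               seq_a = NULL, seq_b = NULL) {
    nA <- as.integer(n_residues_a); nB <- as.integer(n_residues_b)
    nI <- as.integer(n_interface)
    if (nA < 1L || nB < 1L)
        stop("invalid-scenario: chains need at least one residue", call. = FALSE)
    if (nI < 0L || nI > min(nA, nB))
        stop("invalid-scenario: n_interface exceeds the residues available ",
             "for placement", call. = FALSE)
    set.seed(seed)
    if (is.null(seq_a)) seq_a <- paste(sample(.AA, nA, TRUE), collapse = "")
    if (is.null(seq_b)) seq_b <- paste(sample(.AA, nB, TRUE), collapse = "")
    if (nchar(seq_a) != nA || nchar(seq_b) != nB)
        stop("invalid-scenario: sequence lengths do not match residue counts",
             call. = FALSE)

    s <- 4.6                      # lattice spacing, angstrom
    gap <- 12                     # block separation along x
    sideA <- ceiling(nA^(1 / 3))
    fa <- (sideA - 1) * s         # x extent of block A

    iA <- sort(sample.int(nA, nI))
    iB <- sort(sample.int(nB, nI))

    blockCoords <- function(n, x0) {
        side <- ceiling(n^(1 / 3))
        g <- expand.grid(x = 0:(side - 1), y = 0:(side - 1), z = 0:(side - 1))
        g <- as.matrix(g[seq_len(n), , drop = FALSE]) * s
        g[, 1] <- g[, 1] + x0
        g
    }

    place <- function(n, iface, x_iface, x0) {
        xyz <- matrix(NA_real_, n, 3)
        if (length(iface) > 0L)
            xyz[iface, ] <- cbind(x_iface, (seq_along(iface) - 1) * 6, 0)
        rest <- setdiff(seq_len(n), iface)
        if (length(rest) > 0L) {
            b <- blockCoords(length(rest), x0)
            xyz[rest, ] <- b[sample.int(length(rest)), , drop = FALSE]
        }
        xyz
    }

    ## shared jitter keeps designated pairs at exactly 3.9 angstrom
    jitY <- round(stats::runif(nI, -0.25, 0.25), 3)
    xyzA <- place(nA, iA, fa + 3.8, 0)
    xyzB <- place(nB, iB, fa + 3.8 + 3.9, fa + gap)
    if (nI > 0L) {
        xyzA[iA, 2] <- (seq_len(nI) - 1) * 6 + jitY
        xyzB[iB, 2] <- (seq_len(nI) - 1) * 6 + jitY
    }

    mk <- function(ch, xyz, seqc) {
        n <- nrow(xyz)
        res <- strsplit(seqc, "")[[1]]
        data.frame(chain = ch, pos = rep(seq_len(n), each = 2L),
                   resid = rep(res, each = 2L),
                   atom = rep(c("CA", "CB"), n),
                   element = "C",
                   x = rep(xyz[, 1], each = 2L),
                   y = rep(xyz[, 2], each = 2L),
                   z = rep(xyz[, 3], each = 2L) + rep(c(0, 1.9), n),
                   stringsAsFactors = FALSE)
    }
    structure <- ProteinComplex(rbind(mk("A", xyzA, seq_a),
                                      mk("B", xyzB, seq_b)),
                                name = sprintf("toy_%d_%d_%d", nA, nB, nI))
    list(structure = structure,
         interface = list(A = as.integer(iA), B = as.integer(iB)))
}

## ---------------------------------------------------------------------------
## Mutation tables
## ---------------------------------------------------------------------------

## flanking window of up to 10 residues on each side of `pos`, truncated at
## the sequence ends; returns the window string and its 1-based start
.flankWindow <- function(seq, pos) {
    L <- nchar(seq)
    from <- max(1L, pos - 10L)
    to <- min(L, pos + 10L)
    list(flank = substr(seq, from, to), start = from)
}

#' Generate ClinVar-like and dbSNP-like mutation tables
#'
#' Draws missense mutation records on the supplied protein sequences with
#' every field the downstream filters consume: clinical significance,
#' review stars and conflict flags for the pathogenic set; validation,
#' withdrawal, assertion and minor-allele-frequency fields for the common
#' set; and a transcript flanking sequence (up to 10 residues each side of
#' the mutation, truncated at sequence ends) for flank verification. A
#' requested fraction of records has one flank residue corrupted, so that
#' flank verification rejects them; the `corrupted` column records the
#' ground truth. Mutation positions are unique across both sets.
#'
#' @param protein_sequences Named character vector of one-letter protein
#'   sequences (these also serve as the protein-level transcript
#'   sequences).
#' @param n_per_class Named counts `c(nonpathogenic = , pathogenic = )`.
#' @param flank_corruption_rate Fraction in `[0, 1]`.
#' @param seed Integer seed.
#' @return A list with `data.frame`s `clinvar` and `dbsnp`.
#' @examples
#' seqs <- c(P1 = paste(rep("ACDEFGHIKL", 4), collapse = ""))
#' tabs <- generateMutationTable(seqs, c(nonpathogenic = 5, pathogenic = 3),
#'                               0, seed = 1)
#' nrow(tabs$clinvar)
#' @export
generateMutationTable <- function(protein_sequences,
                                  n_per_class,
                                  flank_corruption_rate = 0,
                                  seed = 1L) {
    if (is.null(names(protein_sequences)) || any(nchar(protein_sequences) == 0))
        stop("invalid-scenario: sequences must be named and nonempty",
             call. = FALSE)
    if (flank_corruption_rate < 0 || flank_corruption_rate > 1)
        stop("invalid-scenario: corruption rate must lie in [0, 1]",
             call. = FALSE)
    nn <- n_per_class[["nonpathogenic"]]
    np <- n_per_class[["pathogenic"]]
    pool <- do.call(rbind, lapply(names(protein_sequences), function(p) {
        data.frame(protein = p, position = seq_len(nchar(protein_sequences[[p]])),
                   stringsAsFactors = FALSE)
    }))
    if (nn + np > nrow(pool))
        stop("invalid-scenario: requested mutations exceed available positions",
             call. = FALSE)
    set.seed(seed)
    picked <- pool[sample.int(nrow(pool), nn + np), , drop = FALSE]
    cls <- rep(c("common-set", "pathogenic-set"), c(nn, np))

    common <- .decorateCommon(.buildMutationRecords(
        picked[cls == "common-set", , drop = FALSE],
        protein_sequences, flank_corruption_rate))
    path <- .decoratePathogenic(.buildMutationRecords(
        picked[cls == "pathogenic-set", , drop = FALSE],
        protein_sequences, flank_corruption_rate))
    list(clinvar = path, dbsnp = common)
}

## wt/mut/flank fields shared by both record flavours; uses the current RNG
## stream (callers set the seed)
.buildMutationRecords <- function(rows, protein_sequences,
                                  flank_corruption_rate, mut_aa = NULL) {
    n <- nrow(rows)
    wt <- mut <- flank <- character(n)
    fstart <- integer(n)
    corrupted <- stats::runif(n) < flank_corruption_rate
    for (i in seq_len(n)) {
        sq <- protein_sequences[[rows$protein[i]]]
        p <- rows$position[i]
        wt[i] <- substr(sq, p, p)
        mut[i] <- if (is.null(mut_aa)) sample(setdiff(.AA, wt[i]), 1L)
                  else mut_aa[i]
        fw <- .flankWindow(sq, p)
        fl <- fw$flank
        if (corrupted[i]) {
            j <- sample.int(nchar(fl), 1L)
            orig <- substr(fl, j, j)
            substr(fl, j, j) <- sample(setdiff(.AA, orig), 1L)
        }
        flank[i] <- fl
        fstart[i] <- fw$start
    }
    out <- cbind(rows, data.frame(wt_aa = wt, mut_aa = mut,
                                  consequence = "missense",
                                  flank = flank, flank_start = fstart,
                                  corrupted = corrupted,
                                  stringsAsFactors = FALSE))
    rownames(out) <- NULL
    out
}

.decorateCommon <- function(df) {
    n <- nrow(df)
    df$source <- "common-set"
    df$validated <- TRUE
    df$withdrawn <- FALSE
    df$assertion <- if (n > 0L) sample(c("benign", "likely benign", ""),
                                       n, TRUE) else character(0)
    df$maf <- round(stats::runif(n, 0.01, 0.5), 4)
    df
}

.decoratePathogenic <- function(df) {
    n <- nrow(df)
    df$source <- "pathogenic-set"
    df$significance <- "pathogenic"
    df$stars <- if (n > 0L) sample(1:4, n, TRUE) else integer(0)
    df$conflict <- FALSE
    df
}

## ---------------------------------------------------------------------------
## Free-energy-change tables
## ---------------------------------------------------------------------------

#' Generate a free-energy-change table from ground-truth edgotypes
#'
#' For each mutation in the truth table, draws a folding free-energy
#' change and (for interfacial mutations) one binding free-energy change
#' per interaction partner, from class-conditional truncated Gaussians
#' whose truncation bounds keep every draw on the correct side of the
#' classification thresholds (binding > 0.5 kcal/mol for disrupted
#' partners, folding >= 2 kcal/mol for quasi-null mutations). Ground-truth
#' edgetic mutations receive at least one disruptive partner value;
#' quasi-null mutations receive a disruptive folding value; quasi-wild-type
#' mutations receive benign values throughout.
#'
#' @param edgotype_truth `data.frame` with columns `protein`, `position`,
#'   `wt_aa`, `mut_aa`, `location` (`interfacial`/`buried`/`exposed`),
#'   `edgotype` and `partners` (`;`-separated partner identifiers, empty
#'   for non-interfacial mutations).
#' @param ddg_params See [defaultDdgParams()].
#' @param seed Integer seed.
#' @return A `data.frame` with columns `protein`, `position`, `wt_aa`,
#'   `mut_aa`, `kind` (`binding`/`folding`), `partner` (`NA` for folding
#'   rows) and `ddg` (kcal/mol).
#' @export
generateDdgTable <- function(edgotype_truth, ddg_params = defaultDdgParams(),
                             seed = 1L) {
    tr <- edgotype_truth
    .assertColumns(tr, c("protein", "position", "wt_aa", "mut_aa",
                         "location", "edgotype", "partners"), "truth table")
    bad <- (tr$edgotype == "edgetic" &
                (tr$location != "interfacial" | tr$partners == "")) |
           (tr$edgotype == "quasi-null" & tr$location != "buried")
    if (any(bad))
        stop("invalid-scenario: edgotype labels inconsistent with locations",
             call. = FALSE)
    set.seed(seed)
    pr <- ddg_params
    rDis <- function(n, p) .rtruncnorm(n, p[["mean"]], p[["sd"]],
                                       lower = p[["lower"]])
    rBen <- function(n, p) .rtruncnorm(n, p[["mean"]], p[["sd"]],
                                       upper = p[["upper"]])
    rows <- vector("list", nrow(tr))
    for (i in seq_len(nrow(tr))) {
        m <- tr[i, ]
        fold <- if (m$edgotype == "quasi-null") rDis(1, pr$folding_disrupt)
                else rBen(1, pr$folding_benign)
        out <- data.frame(protein = m$protein, position = m$position,
                          wt_aa = m$wt_aa, mut_aa = m$mut_aa,
                          kind = "folding", partner = NA_character_,
                          ddg = fold, stringsAsFactors = FALSE)
        if (m$location == "interfacial" && nzchar(m$partners)) {
            partners <- strsplit(m$partners, ";", fixed = TRUE)[[1]]
            k <- length(partners)
            ddg <- rBen(k, pr$binding_benign)
            if (m$edgotype == "edgetic") {
                ndis <- sample.int(k, 1L)
                dis <- sample.int(k, ndis)
                ddg[dis] <- rDis(ndis, pr$binding_disrupt)
            }
            out <- rbind(out, data.frame(
                protein = m$protein, position = m$position,
                wt_aa = m$wt_aa, mut_aa = m$mut_aa, kind = "binding",
                partner = partners, ddg = ddg, stringsAsFactors = FALSE))
        }
        rows[[i]] <- out
    }
    res <- do.call(rbind, rows)
    rownames(res) <- NULL
    res
}

## ---------------------------------------------------------------------------
## Edgotype count tables
## ---------------------------------------------------------------------------

#' Draw a phenotype-by-edgotype count table
#'
#' Multinomial draws of edgotype labels for each phenotype class; the
#' marginal totals equal the requested class sizes exactly.
#'
#' @param n_nonpath,n_path Class sizes.
#' @param edgotype_probs 2x3 probability matrix as in
#'   [defaultEdgotypeProbs()].
#' @param seed Integer seed.
#' @return A 2x3 integer matrix with phenotype rows and edgotype columns.
#' @examples
#' generateEdgotypeCounts(100, 50, defaultEdgotypeProbs(), seed = 1)
#' @export
generateEdgotypeCounts <- function(n_nonpath, n_path,
                                   edgotype_probs = defaultEdgotypeProbs(),
                                   seed = 1L) {
    p <- edgotype_probs
    if (any(p < 0) || any(abs(rowSums(p) - 1) > 1e-12))
        stop("invalid-scenario: probability rows must sum to 1", call. = FALSE)
    set.seed(seed)
    m <- rbind(nonpathogenic = drop(stats::rmultinom(1, n_nonpath, p[1, ])),
               pathogenic = drop(stats::rmultinom(1, n_path, p[2, ])))
    colnames(m) <- .EDGOTYPES
    m
}
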