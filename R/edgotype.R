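#' Classify a mutation's location on the protein structure
#'
#' A mutation is `interfacial` when its position belongs to the binding
#' interface of any interaction partner (interface membership takes
#' priority over solvent accessibility); otherwise it is `exposed` when
#' its relative solvent accessibility exceeds `rsa_cutoff` (default 0.25)
#' and `buried` otherwise (the boundary value is buried).
#'
#' @param position 1-based protein position of the mutation.
#' @param interface_positions Integer vector: the union of interface
#'   positions of the protein across its partners.
#' @param rsa Relative solvent accessibility at the position; required for
#'   non-interfacial mutations.
#' @param rsa_cutoff Exposure threshold (default 0.25).
#' @return `"interfacial"`, `"exposed"` or `"buried"`.
#' @examples
#' classifyLocation(5, c(5, 9), rsa = 0.05)   # interfacial wins
#' classifyLocation(4, c(5, 9), rsa = 0.25)   # boundary is buried
#' @export
classifyLocation <- function(position, interface_positions, rsa,
                             rsa_cutoff = 0.25) {
    if (position %in% interface_positions) return("interfacial")
    if (is.null(rsa) || is.na(rsa))
        stop("incomplete-geometry: RSA required for non-interfacial ",
             "mutations", call. = FALSE)
    if (rsa > rsa_cutoff) "exposed" else "buried"
}

#' Classify a mutation's edgotype
#'
#' An interfacial mutation is `edgetic` when the binding free-energy
#' change exceeds `binding_cutoff` (strictly; default 0.5 kcal/mol) for at
#' least one partner; all partners above the cutoff are reported as
#' disrupted. A buried mutation is `quasi-null` when its folding
#' free-energy change is at least `folding_cutoff` (inclusive; default
#' 2 kcal/mol). Everything else -- interfacial mutations with no disrupted
#' partner, buried mutations below the folding threshold, and all exposed
#' mutations -- is `quasi-wild-type`. Interfacial mutations are never
#' routed to the quasi-null branch, so changing the binding cutoff can
#' never alter a quasi-null call.
#'
#' @param location `"interfacial"`, `"buried"` or `"exposed"`.
#' @param binding_ddg Named numeric vector of per-partner binding
#'   free-energy changes (kcal/mol); required for interfacial mutations.
#' @param folding_ddg Folding free-energy change (kcal/mol); required for
#'   buried mutations.
#' @param binding_cutoff,folding_cutoff Thresholds in kcal/mol.
#' @return A list with `edgotype`, `location` and `disrupted_partners`
#'   (character vector, empty unless edgetic).
#' @examples
#' classifyEdgotype("interfacial", c(P2 = 0.2, P3 = 0.6))$edgotype
#' classifyEdgotype("buried", folding_ddg = 2.0)$edgotype
#' @export
classifyEdgotype <- function(location, binding_ddg = NULL, folding_ddg = NULL,
                             binding_cutoff = 0.5, folding_cutoff = 2.0) {
    if (!location %in% c("interfacial", "buried", "exposed"))
        stop("unknown location class: ", location, call. = FALSE)
    disrupted <- character(0)
    if (location == "interfacial") {
        if (is.null(binding_ddg) || length(binding_ddg) == 0L)
            stop("missing-ddg: interfacial mutation has no binding ",
                 "free-energy record", call. = FALSE)
        hit <- binding_ddg > binding_cutoff
        if (any(hit)) {
            disrupted <- names(binding_ddg)[hit]
            if (is.null(disrupted)) disrupted <- as.character(which(hit))
            return(list(edgotype = "edgetic", location = location,
                        disrupted_partners = disrupted))
        }
        return(list(edgotype = "quasi-wild-type", location = location,
                    disrupted_partners = character(0)))
    }
    if (location == "buried") {
        if (is.null(folding_ddg) || is.na(folding_ddg))
            stop("missing-ddg: buried mutation has no folding ",
                 "free-energy record", call. = FALSE)
        if (folding_ddg >= folding_cutoff)
            return(list(edgotype = "quasi-null", location = location,
                        disrupted_partners = character(0)))
    }
    list(edgotype = "quasi-wild-type", location = location,
         disrupted_partners = character(0))
}

#' Parse a table of free-energy changes
#'
#' Reads either a plain TSV with header columns `protein`, `position`,
#' `wt_aa`, `mut_aa`, `kind`, `partner`, `ddg`, or a FoldX-flavoured
#' dialect in which header/comment lines are skipped and each data row
#' carries a mutation code (`wt` `chain` `position` `mut`, e.g. `KA12G`)
#' followed by the energy difference. Values are kcal/mol.
#'
#' @param file Path to the table.
#' @param format `"tsv"` (default) or `"foldx"`.
#' @param kind For `format = "foldx"`: are these `"binding"` or
#'   `"folding"` values?
#' @param protein,partner For `format = "foldx"`: the protein the file
#'   refers to, and the partner protein for binding values.
#' @return A `data.frame` in the plain-TSV column layout. An empty file
#'   yields an empty table with a warning.
#' @export
parseDdgTable <- function(file, format = c("tsv", "foldx"),
                          kind = "binding", protein = NA_character_,
                          partner = NA_character_) {
    format <- match.arg(format)
    if (format == "tsv") {
        df <- utils::read.delim(file, stringsAsFactors = FALSE,
                                na.strings = c("NA", ""))
        if (nrow(df) == 0L) {
            warning("empty free-energy table: ", file, call. = FALSE)
            return(df)
        }
        .assertColumns(df, c("protein", "position", "wt_aa", "mut_aa",
                             "kind", "partner", "ddg"), "free-energy table")
        bad <- which(!is.finite(suppressWarnings(as.numeric(df$ddg))))
        if (length(bad) > 0L)
            stop("parse-error: unparseable free-energy value at row ",
                 bad[1L], " of ", file, call. = FALSE)
        df$ddg <- as.numeric(df$ddg)
        return(df)
    }
    lines <- readLines(file)
    lines <- lines[nzchar(trimws(lines))]
    data <- grep("^[A-Z][A-Z]?[0-9]+[A-Z]\t", lines, value = TRUE)
    if (length(data) == 0L) {
        warning("empty free-energy table: ", file, call. = FALSE)
        return(data.frame(protein = character(0), position = integer(0),
                          wt_aa = character(0), mut_aa = character(0),
                          kind = character(0), partner = character(0),
                          ddg = numeric(0)))
    }
    parts <- strsplit(data, "\t", fixed = TRUE)
    code <- vapply(parts, `[[`, "", 1L)
    val <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
    if (any(!is.finite(val)))
        stop("parse-error: unparseable free-energy value at row ",
             which(!is.finite(val))[1L], " of ", file, call. = FALSE)
    m <- regmatches(code, regexec("^([A-Z])[A-Z]?([0-9]+)([A-Z])$", code))
    ok <- lengths(m) == 4L
    if (!all(ok))
        stop("parse-error: malformed mutation code at row ",
             which(!ok)[1L], " of ", file, call. = FALSE)
    data.frame(protein = protein,
               position = as.integer(vapply(m, `[[`, "", 3L)),
               wt_aa = vapply(m, `[[`, "", 2L),
               mut_aa = vapply(m, `[[`, "", 4L),
               kind = kind,
               partner = if (kind == "binding") partner else NA_character_,
               ddg = val, stringsAsFactors = FALSE)
}

#' Classify every mapped mutation from a free-energy table
#'
#' Vectorised driver around [classifyLocation()] and
#' [classifyEdgotype()]: joins mutations with their RSA, interface
#' membership and free-energy records, and returns one call per mutation.
#'
#' @param mutations `data.frame` with `protein`, `position`, `wt_aa`,
#'   `mut_aa` (other columns pass through).
#' @param interfaces Named list: per protein, the integer vector of
#'   interfacial positions (union over partners).
#' @param rsa Named list: per protein, a numeric vector of RSA values
#'   indexed by position.
#' @param ddg Free-energy table in the layout of [parseDdgTable()].
#' @param binding_cutoff,folding_cutoff,rsa_cutoff Thresholds.
#' @return `mutations` with added columns `location`, `edgotype`,
#'   `rsa`, `folding_ddg` and `disrupted_partners` (`;`-separated).
#' @export
classifyMutations <- function(mutations, interfaces, rsa, ddg,
                              binding_cutoff = 0.5, folding_cutoff = 2.0,
                              rsa_cutoff = 0.25) {
    n <- nrow(mutations)
    loc <- edg <- dis <- character(n)
    rsav <- foldv <- rep(NA_real_, n)
    mkey <- paste(mutations$protein, mutations$position,
                  mutations$wt_aa, mutations$mut_aa)
    dkey <- paste(ddg$protein, ddg$position, ddg$wt_aa, ddg$mut_aa)
    for (i in seq_len(n)) {
        p <- mutations$protein[i]
        pos <- mutations$position[i]
        iface <- interfaces[[p]]
        if (is.null(iface)) iface <- integer(0)
        rsav[i] <- if (!is.null(rsa[[p]]) && pos <= length(rsa[[p]]))
            rsa[[p]][pos] else NA_real_
        loc[i] <- classifyLocation(pos, iface, rsav[i], rsa_cutoff)
        rows <- ddg[dkey == mkey[i], , drop = FALSE]
        brow <- rows[rows$kind == "binding", , drop = FALSE]
        frow <- rows[rows$kind == "folding", , drop = FALSE]
        bvec <- NULL
        if (nrow(brow) > 0L) {
            bvec <- brow$ddg
            names(bvec) <- brow$partner
        }
        foldv[i] <- if (nrow(frow) > 0L) frow$ddg[1L] else NA_real_
        call <- classifyEdgotype(loc[i], bvec, foldv[i],
                                 binding_cutoff, folding_cutoff)
        edg[i] <- call$edgotype
        dis[i] <- paste(call$disrupted_partners, collapse = ";")
    }
    mutations$location <- loc
    mutations$edgotype <- edg
    mutations$rsa <- rsav
    mutations$folding_ddg <- foldv
    mutations$disrupted_partners <- dis
    mutations
}

#' Tabulate edgotype calls by phenotype class
#'
#' @param edgotypes Character vector of edgotype calls.
#' @param phenotypes Character vector (`nonpathogenic`/`pathogenic`)
#'   parallel to `edgotypes`.
#' @return A list with `counts` (2x3 integer matrix) and `fractions`
#'   (rows renormalised to 1).
#' @export
edgotypeCounts <- function(edgotypes, phenotypes) {
    stopifnot(length(edgotypes) == length(phenotypes))
    counts <- table(factor(phenotypes, levels = .PHENOTYPES),
                    factor(edgotypes, levels = .EDGOTYPES))
    counts <- matrix(as.integer(counts), 2, 3,
                     dimnames = list(.PHENOTYPES, .EDGOTYPES))
    fr <- counts / rowSums(counts)
    list(counts = counts, fractions = fr)
}

#' Enrichment of interactome-disrupting edgotypes among pathogenic
#' mutations
#'
#' Collapses a phenotype-by-edgotype count table to a 2x2 table of
#' (edgetic or quasi-null) versus quasi-wild-type by pathogenic versus
#' non-pathogenic, and applies a two-sided Fisher exact test.
#'
#' @param counts 2x3 matrix as produced by [edgotypeCounts()].
#' @return A list with `p`, `odds_ratio` (conditional MLE) and `table`
#'   (the 2x2 collapse).
#' @export
enrichmentTest <- function(counts) {
    disrupting <- counts[, "edgetic"] + counts[, "quasi-null"]
    tab <- rbind(pathogenic = c(disrupting = disrupting[["pathogenic"]],
                                qw = counts["pathogenic", "quasi-wild-type"]),
                 nonpathogenic = c(disrupting[["nonpathogenic"]],
                                   counts["nonpathogenic", "quasi-wild-type"]))
    if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L))
        stop("degenerate-table: zero margin in the 2x2 collapse",
             call. = FALSE)
    ft <- stats::fisher.test(tab, alternative = "two.sided")
    list(p = ft$p.value, odds_ratio = unname(ft$estimate), table = tab)
}

#' Validate predicted edgotypes against experimental calls
#'
#' One-vs-rest true and false positive rates for the edgetic and
#' quasi-null classes over the mutations present in both call sets, with a
#' two-sided Fisher exact test of the association per class.
#'
#' @param predicted,experimental `data.frame`s with `protein`, `position`,
#'   `wt_aa`, `mut_aa`, `edgotype`.
#' @return A `data.frame` with one row per class (`edgetic`,
#'   `quasi-null`): `tpr`, `fpr`, `p`, `n_overlap`.
#' @export
evaluateAgainstExperiment <- function(predicted, experimental) {
    kp <- paste(predicted$protein, predicted$position, predicted$wt_aa,
                predicted$mut_aa)
    ke <- paste(experimental$protein, experimental$position,
                experimental$wt_aa, experimental$mut_aa)
    common <- intersect(kp, ke)
    if (length(common) == 0L)
        stop("no-overlap: prediction and experiment share no mutations",
             call. = FALSE)
    pred <- predicted$edgotype[match(common, kp)]
    expe <- experimental$edgotype[match(common, ke)]
    out <- lapply(c("edgetic", "quasi-null"), function(cls) {
        pp <- pred == cls
        ep <- expe == cls
        tab <- table(factor(pp, c(TRUE, FALSE)), factor(ep, c(TRUE, FALSE)))
        data.frame(class = cls,
                   tpr = if (sum(ep) > 0L) sum(pp & ep) / sum(ep) else NA_real_,
                   fpr = if (sum(!ep) > 0L) sum(pp & !ep) / sum(!ep)
                         else NA_real_,
                   p = stats::fisher.test(tab)$p.value,
                   n_overlap = length(common),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

#' Physiochemical change summary per edgotype
#'
#' Among deleterious (pathogenic) calls, the fraction per edgotype class
#' whose substitution decreases residue hydrophobicity and the fraction
#' whose substitution increases residue molecular weight.
#'
#' @param calls `data.frame` with `wt_aa`, `mut_aa`, `edgotype` (already
#'   restricted to the mutation set of interest, typically deleterious
#'   calls).
#' @param hydrophobicity,weights Named per-residue property tables;
#'   defaults [hydrophobicityScale()] and [residueMolecularWeights()].
#' @return A `data.frame` with one row per edgotype: `n`,
#'   `frac_hydrophobicity_decrease`, `frac_weight_increase`.
#' @export
propertyChangeSummary <- function(calls,
                                  hydrophobicity = hydrophobicityScale(),
                                  weights = residueMolecularWeights()) {
    aas <- unique(c(calls$wt_aa, calls$mut_aa))
    unknown <- setdiff(aas, intersect(names(hydrophobicity), names(weights)))
    if (length(unknown) > 0L)
        stop("table-miss: no property values for residue(s) ",
             paste(unknown, collapse = ", "), call. = FALSE)
    hdec <- hydrophobicity[calls$mut_aa] < hydrophobicity[calls$wt_aa]
    winc <- weights[calls$mut_aa] > weights[calls$wt_aa]
    out <- lapply(.EDGOTYPES, function(t) {
        i <- calls$edgotype == t
        data.frame(edgotype = t, n = sum(i),
                   frac_hydrophobicity_decrease =
                       if (any(i)) mean(hdec[i]) else NA_real_,
                   frac_weight_increase = if (any(i)) mean(winc[i])
                                          else NA_real_,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

#' Robustness sweep over interface-distance and binding cutoffs
#'
#' Re-runs the classification for every combination of interface distance
#' cutoff and binding free-energy cutoff and reports the two ratio
#' diagnostics whose stability underpins the fitness-effect estimates:
#' P(edgetic | non-pathogenic) / P(edgetic | pathogenic) and
#' P(quasi-wild-type | non-pathogenic) / P(quasi-wild-type | pathogenic).
#'
#' @param mutations Mutation `data.frame` (with `phenotype` column of
#'   `nonpathogenic`/`pathogenic`).
#' @param interfaces_by_cutoff Named list: for each distance cutoff (name
#'   = cutoff value), the per-protein interface-position list.
#' @param rsa,ddg As in [classifyMutations()].
#' @param binding_cutoffs Numeric vector (default `c(0.3, 0.5, 0.7)`).
#' @param folding_cutoff,rsa_cutoff Fixed thresholds.
#' @return A `data.frame` with one row per (distance cutoff, binding
#'   cutoff): the count table columns and the two ratios.
#' @export
cutoffSweep <- function(mutations, interfaces_by_cutoff, rsa, ddg,
                        binding_cutoffs = c(0.3, 0.5, 0.7),
                        folding_cutoff = 2.0, rsa_cutoff = 0.25) {
    .assertColumns(mutations, "phenotype", "mutation table")
    rows <- list()
    for (dc in names(interfaces_by_cutoff)) {
        for (bc in binding_cutoffs) {
            calls <- classifyMutations(mutations, interfaces_by_cutoff[[dc]],
                                       rsa, ddg, binding_cutoff = bc,
                                       folding_cutoff = folding_cutoff,
                                       rsa_cutoff = rsa_cutoff)
            fr <- edgotypeCounts(calls$edgotype, calls$phenotype)$fractions
            rows[[length(rows) + 1L]] <- data.frame(
                distance_cutoff = as.numeric(dc), binding_cutoff = bc,
                ratio_edgetic = fr["nonpathogenic", "edgetic"] /
                    fr["pathogenic", "edgetic"],
                ratio_qw = fr["nonpathogenic", "quasi-wild-type"] /
                    fr["pathogenic", "quasi-wild-type"],
                stringsAsFactors = FALSE)
        }
    }
    do.call(rbind, rows)
}
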