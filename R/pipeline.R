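#' Assemble a structural interactome from edges, alignments and templates
#'
#' For every interaction edge, considers all chain-pair templates in which
#' both proteins align to chains of the same structure, computes the
#' template binding interface, applies the coverage rule
#' ([annotatePpi()]), and keeps the best-scoring accepted template
#' ([selectTemplate()]). Template chain identifiers in the alignment table
#' follow the convention `<structure id>_<chain letter>`, with structure
#' files named `<structure id>.pdb` in `structures_dir`.
#'
#' @param edges Edge `data.frame` from [loadInteractome()].
#' @param alignments Alignment `data.frame` (after
#'   [selectBestAlignment()]).
#' @param structures_dir Directory of PDB template files.
#' @param interface_cutoff Interface distance cutoff in angstrom.
#' @param min_coverage Interface-coverage acceptance threshold.
#' @return A list per accepted edge with the annotation, the parsed
#'   template and transferred interfaces; plus a `log` data.frame of
#'   accept/reject decisions.
#' @export
assembleInteractome <- function(edges, alignments, structures_dir,
                                interface_cutoff = 5.0, min_coverage = 0.5) {
    chainParts <- regmatches(alignments$chain,
                             regexec("^(.+)_([A-Za-z0-9])$",
                                     alignments$chain))
    alignments$struct <- vapply(chainParts, `[[`, "", 2L)
    alignments$chain_letter <- vapply(chainParts, `[[`, "", 3L)

    parsed <- new.env(parent = emptyenv())
    getStruct <- function(sid) {
        if (!is.null(parsed[[sid]])) return(parsed[[sid]])
        f <- file.path(structures_dir, paste0(sid, ".pdb"))
        if (!file.exists(f))
            stop("missing-input: template file ", f, call. = FALSE)
        parsed[[sid]] <- parseStructure(f, name = sid)
        parsed[[sid]]
    }

    accepted <- list()
    log <- list()
    for (i in seq_len(nrow(edges))) {
        pa <- edges$protein_a[i]; pb <- edges$protein_b[i]
        sa <- alignments$struct[alignments$protein == pa]
        sb <- alignments$struct[alignments$protein == pb]
        shared <- intersect(sa, sb)
        cands <- list()
        for (sid in shared) {
            rows <- alignments[alignments$struct == sid, , drop = FALSE]
            chA <- unique(rows$chain_letter[rows$protein == pa])
            chB <- unique(rows$chain_letter[rows$protein == pb])
            for (ca in chA) for (cb in chB) {
                if (ca == cb) next
                st <- getStruct(sid)
                iface <- interfaceResidues(st, ca, cb,
                                           cutoff = interface_cutoff)
                ann <- annotatePpi(pa, pb, paste0(sid, "_", ca),
                                   paste0(sid, "_", cb), alignments, iface,
                                   min_coverage = min_coverage)
                if (ann$accepted) {
                    ann$template <- sid
                    ann$chain_a <- ca
                    ann$chain_b <- cb
                    ann$structure <- st
                    ann$interface <- iface
                    cands[[length(cands) + 1L]] <- ann
                }
            }
        }
        best <- selectTemplate(cands)
        status <- if (is.null(best)) "rejected" else "accepted"
        log[[i]] <- data.frame(protein_a = pa, protein_b = pb,
                               status = status,
                               template = if (is.null(best)) NA_character_
                                          else best$template,
                               stringsAsFactors = FALSE)
        if (!is.null(best)) {
            ta <- transferInterface(best$interface$a, best$map_a)
            tb <- transferInterface(best$interface$b, best$map_b)
            best$protein_interface <- stats::setNames(
                list(ta$positions, tb$positions), best$orientation)
            accepted[[length(accepted) + 1L]] <- best
        }
    }
    list(annotations = accepted, log = do.call(rbind, log))
}

#' Run the full edgotype-to-fitness pipeline
#'
#' Executes assembly, geometry, mutation mapping, edgotype classification
#' and Bayesian fitness inference in order, writing one TSV per stage plus
#' a JSON summary (with md5 checksums of every output) to
#' `config$out_dir`. All computation is deterministic given the inputs.
#'
#' @param config A named list with entries `edges`, `alignments`,
#'   `structures_dir`, `proteins`, `transcripts`, `clinvar`, `dbsnp`,
#'   `ddg` (file paths), `out_dir`, and optional `interface_cutoff` (5),
#'   `rsa_cutoff` (0.25), `binding_cutoff` (0.5), `folding_cutoff` (2),
#'   `priors` ([fitnessPriors()]), `min_coverage` (0.5).
#' @return Invisibly, a list with the per-stage results: `annotations`,
#'   `geometry`, `mutations`, `calls`, `counts`, `posteriors` (one
#'   [FitnessPosterior-class] per assumption), `merged`, and `files`.
#' @seealso [generateScenarioBundle()] for producing a complete synthetic
#'   input set.
#' @export
runPipeline <- function(config) {
    need <- c("edges", "alignments", "structures_dir", "proteins",
              "transcripts", "clinvar", "dbsnp", "ddg", "out_dir")
    miss <- setdiff(need, names(config))
    if (length(miss) > 0L)
        stop("missing-input: config lacks ", paste(miss, collapse = ", "),
             call. = FALSE)
    for (key in setdiff(need, "out_dir")) {
        if (!file.exists(config[[key]]))
            stop("missing-input: ", key, " file not found: ",
                 config[[key]], call. = FALSE)
    }
    cutoff <- function(key, default) {
        if (is.null(config[[key]])) default else config[[key]]
    }
    icut <- cutoff("interface_cutoff", 5.0)
    rcut <- cutoff("rsa_cutoff", 0.25)
    bcut <- cutoff("binding_cutoff", 0.5)
    fcut <- cutoff("folding_cutoff", 2.0)
    mincov <- cutoff("min_coverage", 0.5)
    priors <- if (is.null(config$priors)) fitnessPriors() else config$priors
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

    ## stage 1: assembly
    edges <- loadInteractome(config$edges)
    alignments <- selectBestAlignment(
        utils::read.delim(config$alignments, stringsAsFactors = FALSE))
    asm <- assembleInteractome(edges, alignments, config$structures_dir,
                               interface_cutoff = icut,
                               min_coverage = mincov)

    ## stage 2: geometry -- per protein, union interface + RSA on the
    ## representative (first accepted) chain, monomer context
    interfaces <- list()
    rsa <- list()
    geomRows <- list()
    for (ann in asm$annotations) {
        maps <- stats::setNames(list(ann$map_a, ann$map_b), ann$orientation)
        chains <- stats::setNames(list(ann$chain_a, ann$chain_b),
                                  ann$orientation)
        for (prot in ann$orientation) {
            ip <- ann$protein_interface[[prot]]
            interfaces[[prot]] <- sort(union(interfaces[[prot]], ip))
            if (is.null(rsa[[prot]])) {
                sa <- residueSasa(ann$structure, chains = chains[[prot]])
                rsaChain <- relativeSolventAccessibility(sa$asa, sa$resid)
                cdr <- centerDistanceRatio(ann$structure, chains[[prot]])
                map <- maps[[prot]]
                protPos <- map[match(sa$pos, map[, "chain_pos"]),
                               "protein_pos"]
                keep <- !is.na(protPos)
                v <- rep(NA_real_, max(protPos[keep], 0L))
                v[protPos[keep]] <- rsaChain[keep]
                rsa[[prot]] <- v
                geomRows[[prot]] <- data.frame(
                    protein = prot, position = protPos[keep],
                    resid = sa$resid[keep], asa = sa$asa[keep],
                    rsa = rsaChain[keep],
                    center_distance_ratio = cdr[sa$pos[keep]],
                    stringsAsFactors = FALSE)
            }
        }
    }
    geometry <- if (length(geomRows) > 0L) do.call(rbind, geomRows) else
        data.frame()
    if (nrow(geometry) > 0L) {
        iface <- mapply(function(p, pos) pos %in% interfaces[[p]],
                        geometry$protein, geometry$position)
        geometry$interfacial <- as.logical(iface)
    }

    ## stage 3: mutation mapping
    proteins <- .readFasta(config$proteins)
    transcripts <- .readFasta(config$transcripts)
    clinvar <- filterClinvar(utils::read.delim(config$clinvar,
                                               stringsAsFactors = FALSE))
    dbsnp <- filterDbsnp(utils::read.delim(config$dbsnp,
                                           stringsAsFactors = FALSE))
    vPath <- verifyFlank(clinvar, transcripts, proteins)
    vComm <- verifyFlank(dbsnp, transcripts, proteins)
    path <- dedupePositions(vPath[vPath$mapped, , drop = FALSE])
    comm <- excludeOverlap(
        dedupePositions(vComm[vComm$mapped, , drop = FALSE]), path)
    path$phenotype <- "pathogenic"
    comm$phenotype <- "nonpathogenic"
    shared <- intersect(names(path), names(comm))
    mutations <- rbind(path[, shared, drop = FALSE],
                       comm[, shared, drop = FALSE])
    ## restrict to proteins with structural coverage at the mutated site
    covered <- vapply(seq_len(nrow(mutations)), function(i) {
        p <- mutations$protein[i]; pos <- mutations$position[i]
        (pos %in% interfaces[[p]]) ||
            (!is.null(rsa[[p]]) && pos <= length(rsa[[p]]) &&
                 !is.na(rsa[[p]][pos]))
    }, TRUE)
    mutations <- mutations[covered, , drop = FALSE]

    ## stage 4: classification
    ddg <- parseDdgTable(config$ddg)
    calls <- classifyMutations(mutations, interfaces, rsa, ddg,
                               binding_cutoff = bcut,
                               folding_cutoff = fcut, rsa_cutoff = rcut)
    counts <- edgotypeCounts(calls$edgotype, calls$phenotype)
    enrich <- tryCatch(enrichmentTest(counts$counts),
                       error = function(e) NULL)

    ## stage 5: inference under both assumptions
    posteriors <- lapply(c(I = "I", II = "II"), function(a) {
        fitnessPosterior(conditionalProbs(counts$counts, a,
                                          dataset = "pipeline"),
                         priors = priors)
    })
    merged <- mergeAssumptions(posteriors$I, posteriors$II)

    ## outputs
    out <- function(name) file.path(config$out_dir, name)
    writeTsv <- function(df, name) {
        utils::write.table(df, out(name), sep = "\t", quote = FALSE,
                           row.names = FALSE)
        out(name)
    }
    postTab <- do.call(rbind, lapply(names(posteriors), function(a) {
        tb <- posteriorTable(posteriors[[a]])
        tb$assumption <- a
        tb
    }))
    files <- c(writeTsv(asm$log, "annotations.tsv"),
               writeTsv(geometry, "geometry.tsv"),
               writeTsv(calls, "calls.tsv"),
               writeTsv(as.data.frame(counts$counts), "counts.tsv"),
               writeTsv(postTab, "posteriors.tsv"),
               writeTsv(merged, "merged.tsv"))
    summary <- list(
        config = config[setdiff(names(config), "out_dir")],
        cutoffs = list(interface = icut, rsa = rcut, binding = bcut,
                       folding = fcut, min_coverage = mincov),
        priors = as.list(priors),
        n_edges = nrow(edges),
        n_annotated = sum(asm$log$status == "accepted"),
        n_mutations = as.list(table(mutations$phenotype)),
        counts = counts$counts,
        enrichment = if (is.null(enrich)) NULL else
            list(p = enrich$p, odds_ratio = enrich$odds_ratio),
        checksums = as.list(tools::md5sum(files)))
    jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
    invisible(list(annotations = asm, geometry = geometry,
                   mutations = mutations, calls = calls,
                   counts = counts$counts, enrichment = enrich,
                   posteriors = posteriors, merged = merged,
                   files = c(files, out("summary.json"))))
}

.readFasta <- function(path) {
    x <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                            forceDNAtolower = FALSE)
    stats::setNames(toupper(vapply(x, `[[`, "", 1L)), names(x))
}

#' Reference edgotype datasets used in the worked example
#'
#' The three class-conditional edgotype datasets carried through the
#' worked example: structure-based predictions in the Y2H-derived and
#' literature-derived structural interactomes, and experimentally
#' determined edgotypes, each as published fractions with their class
#' sample sizes.
#'
#' @return A named list of [EdgotypeProbs-class] objects (Assumption I;
#'   switch with [conditionalProbs()] semantics via `assumption` of
#'   [edgotypeProbs()]).
#' @export
referenceEdgotypeData <- function() {
    list(
        "Y2H-SI" = list(nonpath = c(0.97, 0.015, 0.015),
                        path = c(0.74, 0.13, 0.13),
                        n = c(nonpathogenic = 1072, pathogenic = 318)),
        "Lit-SI" = list(nonpath = c(0.95, 0.02, 0.03),
                        path = c(0.69, 0.09, 0.22),
                        n = c(nonpathogenic = 2786, pathogenic = 1202)),
        "experimental" = list(nonpath = c(0.92, 0.04, 0.04),
                              path = c(0.43, 0.31, 0.26),
                              n = c(nonpathogenic = 47, pathogenic = 197)))
}

#' Worked-example fitness-effect report
#'
#' Recomputes, by exact arithmetic from the published conditional
#' fractions and the genome-wide priors, the full set of posterior
#' fitness-effect estimates for the three reference datasets under both
#' assumptions, together with 95% confidence intervals and the merged
#' between-assumption summary intervals.
#'
#' @param priors See [fitnessPriors()].
#' @return A list with `posteriors` (long `data.frame` across dataset,
#'   assumption, edgotype and fitness class) and `merged` (long
#'   `data.frame` of merged intervals per dataset).
#' @examples
#' rep <- workedExampleReport()
#' subset(rep$posteriors, dataset == "Y2H-SI" & assumption == "I" &
#'        edgotype == "quasi-wild-type")
#' @export
workedExampleReport <- function(priors = fitnessPriors()) {
    data <- referenceEdgotypeData()
    post <- list()
    merged <- list()
    for (ds in names(data)) {
        d <- data[[ds]]
        pI <- fitnessPosterior(edgotypeProbs(d$nonpath, d$path, d$n,
                                             assumption = "I",
                                             dataset = ds), priors)
        pII <- fitnessPosterior(edgotypeProbs(d$nonpath, d$path, d$n,
                                              assumption = "II",
                                              dataset = ds), priors)
        for (a in c("I", "II")) {
            tb <- posteriorTable(if (a == "I") pI else pII)
            tb$dataset <- ds
            tb$assumption <- a
            post[[length(post) + 1L]] <- tb
        }
        m <- mergeAssumptions(pI, pII)
        m$dataset <- ds
        merged[[length(merged) + 1L]] <- m
    }
    list(posteriors = do.call(rbind, post), merged = do.call(rbind, merged))
}
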