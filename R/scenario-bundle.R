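#' Write a complete synthetic study to disk
#'
#' Materialises every input the pipeline consumes, with known ground
#' truth: a reference edge list, one toy chain-pair template per PPI (PDB
#' format), identity sequence alignments (BLAST-tabular-style TSV with
#' aligned strings), protein and transcript FASTA files, ClinVar-like and
#' dbSNP-like mutation tables, a free-energy-change table, a ground-truth
#' label table, and a JSON sidecar echoing all parameters and seeds.
#'
#' Ground-truth edgotypes are drawn per phenotype class from the
#' scenario's class-conditional probabilities and placed on structurally
#' compatible positions: edgetic mutations on interfacial residues,
#' quasi-null mutations on buried residues (relative solvent accessibility
#' at most 0.25 on the protein's representative chain), quasi-wild-type
#' mutations preferentially on exposed non-interfacial residues, spilling
#' over to buried and interfacial positions (with benign free-energy
#' draws) when the exposed pool is exhausted. Free-energy values are
#' then drawn so that threshold classification recovers the labels
#' exactly (see [generateDdgTable()]).
#'
#' @param scenario A [SyntheticScenario-class].
#' @param dir Output directory (created if needed).
#' @param n_mutations Named counts
#'   `c(nonpathogenic = 300, pathogenic = 90)`.
#' @return Invisibly, a list with the file `paths`, the `truth` table and
#'   the per-protein ground-truth `interfaces` and `rsa`.
#' @examples
#' \donttest{
#' sc <- syntheticScenario(seed = 3, n_proteins = 8, n_ppis = 8)
#' bundle <- generateScenarioBundle(sc, tempfile(),
#'                                  c(nonpathogenic = 40, pathogenic = 15))
#' }
#' @export
generateScenarioBundle <- function(scenario, dir,
                                   n_mutations = c(nonpathogenic = 300,
                                                   pathogenic = 90)) {
    stopifnot(is(scenario, "SyntheticScenario"))
    dir.create(file.path(dir, "structures"), recursive = TRUE,
               showWarnings = FALSE)
    seed <- scenario@seed
    set.seed(seed)

    np <- scenario@nProteins
    proteins <- sprintf("P%03d", seq_len(np))
    lens <- sample(30:60, np, replace = TRUE)
    seqs <- vapply(lens, function(L) paste(sample(.AA, L, TRUE),
                                           collapse = ""), "")
    names(seqs) <- proteins

    allPairs <- utils::combn(proteins, 2L)
    if (scenario@nPPIs > ncol(allPairs))
        stop("invalid-scenario: more PPIs requested than protein pairs",
             call. = FALSE)
    edgeIdx <- sample.int(ncol(allPairs), scenario@nPPIs)
    edges <- data.frame(protein_a = allPairs[1L, edgeIdx],
                        protein_b = allPairs[2L, edgeIdx],
                        stringsAsFactors = FALSE)

    ifacePos <- stats::setNames(vector("list", np), proteins)
    posPartners <- stats::setNames(vector("list", np), proteins)
    repChain <- stats::setNames(vector("list", np), proteins)
    alignRows <- list()
    structPaths <- character(0)

    for (k in seq_len(nrow(edges))) {
        pa <- edges$protein_a[k]; pb <- edges$protein_b[k]
        la <- nchar(seqs[[pa]]); lb <- nchar(seqs[[pb]])
        nI <- max(1L, round(scenario@interfaceFraction * min(la, lb)))
        cx <- generateToyComplex(la, lb, nI, seed = .subSeed(seed, k),
                                 seq_a = seqs[[pa]], seq_b = seqs[[pb]])
        sid <- sprintf("T%03d", k)
        path <- file.path(dir, "structures", paste0(sid, ".pdb"))
        writeStructure(cx$structure, path)
        structPaths <- c(structPaths, path)
        for (side in c("A", "B")) {
            prot <- if (side == "A") pa else pb
            partner <- if (side == "A") pb else pa
            L <- nchar(seqs[[prot]])
            alignRows[[length(alignRows) + 1L]] <- data.frame(
                protein = prot, chain = paste0(sid, "_", side),
                evalue = 1e-50, qstart = 1L, qend = L, sstart = 1L,
                send = L, qseq = seqs[[prot]], sseq = seqs[[prot]],
                stringsAsFactors = FALSE)
            ip <- cx$interface[[side]]
            ifacePos[[prot]] <- sort(union(ifacePos[[prot]], ip))
            for (p in ip) {
                key <- as.character(p)
                posPartners[[prot]][[key]] <-
                    union(posPartners[[prot]][[key]], partner)
            }
            if (is.null(repChain[[prot]]))
                repChain[[prot]] <- list(structure = cx$structure,
                                         chain = side)
        }
    }

    ## per-protein RSA on the representative chain, monomer context
    rsa <- stats::setNames(vector("list", np), proteins)
    for (prot in proteins) {
        rc <- repChain[[prot]]
        if (is.null(rc)) next
        sa <- residueSasa(rc$structure, chains = rc$chain)
        rsa[[prot]] <- relativeSolventAccessibility(sa$asa, sa$resid)
    }

    ## position pools by location class
    pools <- list(interfacial = list(), buried = list(), exposed = list())
    for (prot in proteins) {
        if (is.null(rsa[[prot]])) next
        L <- nchar(seqs[[prot]])
        ifc <- ifacePos[[prot]]
        if (is.null(ifc)) ifc <- integer(0)
        rest <- setdiff(seq_len(L), ifc)
        buried <- rest[rsa[[prot]][rest] <= 0.25]
        exposed <- setdiff(rest, buried)
        add <- function(class, pos) {
            if (length(pos) > 0L)
                pools[[class]][[length(pools[[class]]) + 1L]] <<-
                    data.frame(protein = prot, position = pos,
                               stringsAsFactors = FALSE)
        }
        add("interfacial", ifc)
        add("buried", buried)
        add("exposed", exposed)
    }
    pools <- lapply(pools, function(x) if (length(x) > 0L)
        do.call(rbind, x) else
        data.frame(protein = character(0), position = integer(0)))

    ## draw ground-truth edgotypes per phenotype class and place them
    drawClass <- function(n, probs) {
        drop(stats::rmultinom(1L, n, probs))
    }
    used <- character(0)
    takeFrom <- function(classes, n) {
        ## draw from the first location class, spilling into the later ones
        ## when exhausted (quasi-wild-type mutations legitimately occur at
        ## any location; the free-energy draws keep them benign)
        out <- list()
        for (class in classes) {
            if (n == 0L) break
            pool <- pools[[class]]
            key <- paste(pool$protein, pool$position)
            pool <- pool[!(key %in% used), , drop = FALSE]
            k <- min(n, nrow(pool))
            if (k == 0L) next
            take <- pool[sample.int(nrow(pool), k), , drop = FALSE]
            take$location <- class
            used <<- c(used, paste(take$protein, take$position))
            out[[length(out) + 1L]] <- take
            n <- n - k
        }
        if (n > 0L)
            stop("invalid-scenario: not enough ",
                 paste(classes, collapse = "/"),
                 " positions for the requested mutations", call. = FALSE)
        do.call(rbind, out)
    }
    locOf <- list("quasi-wild-type" = c("exposed", "buried", "interfacial"),
                  "edgetic" = "interfacial",
                  "quasi-null" = "buried")
    truth <- list()
    ## deleterious-location edgotypes first so spillover cannot starve them
    edgotypeOrder <- c("edgetic", "quasi-null", "quasi-wild-type")
    for (cls in .PHENOTYPES) {
        counts <- drawClass(n_mutations[[cls]], scenario@edgotypeProbs[cls, ])
        names(counts) <- .EDGOTYPES
        for (t in edgotypeOrder) {
            if (counts[[t]] == 0L) next
            rows <- takeFrom(locOf[[t]], counts[[t]])
            rows$edgotype <- t
            rows$phenotype <- cls
            truth[[length(truth) + 1L]] <- rows
        }
    }
    truth <- do.call(rbind, truth)
    truth$partners <- vapply(seq_len(nrow(truth)), function(i) {
        if (truth$location[i] != "interfacial") return("")
        paste(posPartners[[truth$protein[i]]][[
            as.character(truth$position[i])]], collapse = ";")
    }, "")

    ## mutation record tables (flanks, phenotype-specific fields)
    base <- .buildMutationRecords(
        truth[, c("protein", "position"), drop = FALSE], seqs,
        scenario@flankCorruptionRate)
    truth$wt_aa <- base$wt_aa
    truth$mut_aa <- base$mut_aa
    truth$corrupted <- base$corrupted
    clinvar <- .decoratePathogenic(
        base[truth$phenotype == "pathogenic", , drop = FALSE])
    dbsnp <- .decorateCommon(
        base[truth$phenotype == "nonpathogenic", , drop = FALSE])

    ddg <- generateDdgTable(truth, scenario@ddgParams,
                            seed = .subSeed(seed, 999L))

    writeTsv <- function(df, name) {
        path <- file.path(dir, name)
        utils::write.table(df, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        path
    }
    writeFasta <- function(seqs, name) {
        path <- file.path(dir, name)
        seqinr::write.fasta(as.list(seqs), names = names(seqs),
                            file.out = path, as.string = TRUE)
        path
    }
    paths <- list(
        edges = writeTsv(edges, "edges.tsv"),
        alignments = writeTsv(do.call(rbind, alignRows), "alignments.tsv"),
        structures_dir = file.path(dir, "structures"),
        proteins = writeFasta(seqs, "proteins.fasta"),
        transcripts = writeFasta(seqs, "transcripts.fasta"),
        clinvar = writeTsv(clinvar, "clinvar.tsv"),
        dbsnp = writeTsv(dbsnp, "dbsnp.tsv"),
        ddg = writeTsv(ddg, "ddg.tsv"),
        truth = writeTsv(truth, "truth.tsv"))
    sidecar <- list(seed = seed, n_proteins = np, n_ppis = scenario@nPPIs,
                    interface_fraction = scenario@interfaceFraction,
                    edgotype_probs = scenario@edgotypeProbs,
                    flank_corruption_rate = scenario@flankCorruptionRate,
                    ddg_params = scenario@ddgParams,
                    n_mutations = as.list(n_mutations))
    jsonlite::write_json(sidecar, file.path(dir, "scenario.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths$sidecar <- file.path(dir, "scenario.json")
    invisible(list(paths = paths, truth = truth, interfaces = ifacePos,
                   rsa = rsa))
}
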