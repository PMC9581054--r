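test_that("location classification gives interface membership priority", {
    expect_identical(classifyLocation(5L, c(5L, 9L), rsa = 0.05),
                     "interfacial")
    expect_identical(classifyLocation(4L, c(5L, 9L), rsa = 0.30), "exposed")
    expect_identical(classifyLocation(4L, c(5L, 9L), rsa = 0.25), "buried")
    expect_error(classifyLocation(4L, integer(0), rsa = NA_real_),
                 "incomplete-geometry")
})

test_that("edgotype thresholds are strict for binding, inclusive for
           folding", {
    e <- classifyEdgotype("interfacial", c(P2 = 0.2, P3 = 0.6))
    expect_identical(e$edgotype, "edgetic")
    expect_identical(e$disrupted_partners, "P3")

    qw <- classifyEdgotype("interfacial", c(P2 = 0.5, P3 = 0.4))
    expect_identical(qw$edgotype, "quasi-wild-type")

    qn <- classifyEdgotype("buried", folding_ddg = 2.0)
    expect_identical(qn$edgotype, "quasi-null")
    expect_identical(classifyEdgotype("buried",
                                      folding_ddg = 1.99)$edgotype,
                     "quasi-wild-type")
    expect_identical(classifyEdgotype("exposed")$edgotype,
                     "quasi-wild-type")

    expect_error(classifyEdgotype("interfacial"), "missing-ddg")
    expect_error(classifyEdgotype("buried"), "missing-ddg")
})

test_that("free-energy tables parse from plain TSV and the FoldX dialect
           identically", {
    tsv <- tempfile(fileext = ".tsv")
    writeLines(c("protein\tposition\twt_aa\tmut_aa\tkind\tpartner\tddg",
                 "P1\t12\tK\tG\tbinding\tP2\t1.25",
                 "P1\t12\tK\tG\tfolding\tNA\t0.40"), tsv)
    plain <- parseDdgTable(tsv)
    expect_identical(nrow(plain), 2L)
    expect_equal(plain$ddg, c(1.25, 0.40))

    fx <- tempfile(fileext = ".fxout")
    writeLines(c("FoldX output preamble", "Pdb\ttotal energy",
                 "KA12G\t1.25"), fx)
    foldx <- parseDdgTable(fx, format = "foldx", kind = "binding",
                           protein = "P1", partner = "P2")
    cols <- c("protein", "position", "wt_aa", "mut_aa", "kind", "partner",
              "ddg")
    expect_equal(foldx[cols], plain[1, cols], ignore_attr = TRUE)

    empty <- tempfile(fileext = ".tsv")
    writeLines("protein\tposition\twt_aa\tmut_aa\tkind\tpartner\tddg",
               empty)
    expect_warning(out <- parseDdgTable(empty), "empty")
    expect_identical(nrow(out), 0L)

    bad <- tempfile(fileext = ".tsv")
    writeLines(c("protein\tposition\twt_aa\tmut_aa\tkind\tpartner\tddg",
                 "P1\t12\tK\tG\tbinding\tP2\tnot-a-number"), bad)
    expect_error(parseDdgTable(bad), "parse-error")
})

test_that("count tables conserve totals and fractions", {
    ct <- edgotypeCounts(rep("quasi-wild-type", 5),
                         c(rep("nonpathogenic", 3), rep("pathogenic", 2)))
    expect_identical(unname(ct$counts[, "quasi-wild-type"]), c(3L, 2L))
    expect_equal(unname(ct$fractions["nonpathogenic", ]), c(1, 0, 0))

    set.seed(2)
    e <- sample(c("quasi-wild-type", "edgetic", "quasi-null"), 200, TRUE)
    p <- sample(c("nonpathogenic", "pathogenic"), 200, TRUE)
    ct2 <- edgotypeCounts(e, p)
    expect_identical(sum(ct2$counts), 200L)
    expect_equal(unname(rowSums(ct2$counts)), unname(as.vector(table(
        factor(p, c("nonpathogenic", "pathogenic"))))))
})

test_that("the enrichment test is exact and matches enumeration", {
    flat <- rbind(nonpathogenic = c(10L, 5L, 5L),
                  pathogenic = c(10L, 5L, 5L))
    colnames(flat) <- colnames(defaultEdgotypeProbs())
    expect_equal(enrichmentTest(flat)$p, 1)

    extreme <- rbind(nonpathogenic = c(50L, 0L, 0L),
                     pathogenic = c(0L, 25L, 25L))
    colnames(extreme) <- colnames(flat)
    expect_lt(enrichmentTest(extreme)$p, 1e-10)

    set.seed(12)
    for (i in 1:25) {
        counts <- matrix(rpois(6, 5), 2, 3,
                         dimnames = dimnames(flat))
        if (any(rowSums(counts) == 0)) next
        tab <- cbind(counts[, 2] + counts[, 3], counts[, 1])[2:1, ]
        if (any(colSums(tab) == 0)) {
            expect_error(enrichmentTest(counts), "degenerate-table")
            next
        }
        expect_equal(enrichmentTest(counts)$p, enumFisherP(tab),
                     tolerance = 1e-9)
    }
})

test_that("prediction validation reports one-vs-rest rates", {
    mk <- function(edg) data.frame(protein = paste0("P", seq_along(edg)),
                                   position = 1L, wt_aa = "A", mut_aa = "V",
                                   edgotype = edg, stringsAsFactors = FALSE)
    truth <- mk(c(rep("edgetic", 4), rep("quasi-null", 3),
                  rep("quasi-wild-type", 3)))
    perfect <- evaluateAgainstExperiment(truth, truth)
    expect_equal(perfect$tpr, c(1, 1))
    expect_equal(perfect$fpr, c(0, 0))

    ## hand-built confusion fixture: predictions hit 2/4 edgetic, call one
    ## spurious edgetic among the 6 non-edgetic mutations
    pred <- mk(c("edgetic", "edgetic", "quasi-wild-type", "quasi-null",
                 "quasi-null", "quasi-wild-type", "quasi-wild-type",
                 "edgetic", "quasi-wild-type", "quasi-wild-type"))
    ev <- evaluateAgainstExperiment(pred, truth)
    expect_equal(ev$tpr[ev$class == "edgetic"], 2 / 4)
    expect_equal(ev$fpr[ev$class == "edgetic"], 1 / 6)
    expect_equal(ev$tpr[ev$class == "quasi-null"], 1 / 3)
    expect_equal(ev$fpr[ev$class == "quasi-null"], 1 / 7)

    ## label-shuffled predictions are uninformative: TPR tracks FPR
    set.seed(5)
    edg <- sample(c("edgetic", "quasi-wild-type"), 4000, TRUE)
    big <- mk(edg)
    shuf <- mk(sample(edg))
    evs <- evaluateAgainstExperiment(shuf, big)
    expect_lt(abs(evs$tpr[1] - evs$fpr[1]), 0.05)

    expect_error(evaluateAgainstExperiment(mk("edgetic"),
                                           transform(mk("edgetic"),
                                                     protein = "ZZ")),
                 "no-overlap")
})

test_that("physiochemical summaries count the documented directions", {
    calls <- data.frame(wt_aa = c("I", "G", "A"), mut_aa = c("D", "W", "A"),
                        edgotype = c("quasi-null", "edgetic",
                                     "quasi-wild-type"),
                        stringsAsFactors = FALSE)
    s <- propertyChangeSummary(calls)
    expect_equal(s$frac_hydrophobicity_decrease[s$edgotype == "quasi-null"],
                 1)                                 # I -> D
    expect_equal(s$frac_weight_increase[s$edgotype == "edgetic"], 1) # G -> W

    flatTab <- setNames(rep(1, 20), names(hydrophobicityScale()))
    s0 <- propertyChangeSummary(calls, flatTab, flatTab)
    expect_true(all(s0$frac_hydrophobicity_decrease[s0$n > 0] == 0))
    expect_true(all(s0$frac_weight_increase[s0$n > 0] == 0))

    expect_error(propertyChangeSummary(
        data.frame(wt_aa = "X", mut_aa = "A", edgotype = "edgetic")),
        "table-miss")
})

test_that("classification is order-invariant and cutoff-monotone", {
    set.seed(14)
    n <- 120
    muts <- data.frame(protein = paste0("P", 1:n),
                       position = 5L, wt_aa = "A", mut_aa = "V",
                       phenotype = sample(c("nonpathogenic", "pathogenic"),
                                          n, TRUE),
                       stringsAsFactors = FALSE)
    interfaces <- setNames(lapply(1:n, function(i)
        if (i %% 3 == 0) 5L else integer(0)), muts$protein)
    rsa <- setNames(lapply(1:n, function(i) rep(runif(1), 10)),
                    muts$protein)
    ddg <- do.call(rbind, lapply(1:n, function(i) rbind(
        data.frame(protein = muts$protein[i], position = 5L, wt_aa = "A",
                   mut_aa = "V", kind = "folding", partner = NA_character_,
                   ddg = runif(1, 0, 4)),
        data.frame(protein = muts$protein[i], position = 5L, wt_aa = "A",
                   mut_aa = "V", kind = "binding", partner = c("X", "Y"),
                   ddg = runif(2, 0, 1.5)))))

    base <- classifyMutations(muts, interfaces, rsa, ddg)
    perm <- sample.int(n)
    shuffled <- classifyMutations(muts[perm, ], interfaces, rsa,
                                  ddg[sample.int(nrow(ddg)), ])
    expect_identical(shuffled$edgotype[order(perm)], base$edgotype)

    ## raising the binding cutoff can only move edgetic -> quasi-wild-type,
    ## and never touches quasi-null calls
    for (bc in c(0.3, 0.7, 1.2)) {
        alt <- classifyMutations(muts, interfaces, rsa, ddg,
                                 binding_cutoff = bc)
        if (bc > 0.5) {
            expect_true(all(alt$edgotype[base$edgotype == "quasi-wild-type"]
                            == "quasi-wild-type"))
        }
        expect_identical(alt$edgotype == "quasi-null",
                         base$edgotype == "quasi-null")
    }
})

test_that("the cutoff sweep reports stable ratio diagnostics", {
    sc <- syntheticScenario(seed = 23, n_proteins = 10, n_ppis = 12)
    bundle <- generateScenarioBundle(sc, tempfile(),
                                     c(nonpathogenic = 60, pathogenic = 30))
    tr <- bundle$truth
    muts <- tr[, c("protein", "position", "wt_aa", "mut_aa", "phenotype")]
    ddg <- generateDdgTable(tr, seed = 4)
    ifaces <- setNames(lapply(names(bundle$interfaces), function(p) {
        v <- bundle$interfaces[[p]]
        if (is.null(v)) integer(0) else v
    }), names(bundle$interfaces))
    sweep <- cutoffSweep(muts,
                         list("4" = ifaces, "5" = ifaces, "6" = ifaces),
                         bundle$rsa, ddg)
    expect_identical(nrow(sweep), 9L)
    ## the toy geometry is margin-guarded for the 4-6 angstrom sweep, so at
    ## a fixed binding cutoff the ratios cannot depend on the distance cutoff
    for (bc in unique(sweep$binding_cutoff)) {
        rows <- sweep[sweep$binding_cutoff == bc, ]
        expect_equal(length(unique(round(rows$ratio_qw, 10))), 1L)
        expect_equal(length(unique(round(rows$ratio_edgetic, 10))), 1L)
    }
})
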