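test_that("toy complexes realise exactly the designated interface", {
    cx <- generateToyComplex(10, 10, 3, seed = 1)
    bf <- bruteForceInterface(cx$structure, "A", "B", 5.0)
    expect_identical(bf$a, cx$interface$A)
    expect_identical(bf$b, cx$interface$B)
    expect_length(bf$a, 3L)

    none <- generateToyComplex(5, 5, 0, seed = 2)
    bf0 <- bruteForceInterface(none$structure, "A", "B", 5.0)
    expect_identical(bf0$a, integer(0))
    expect_identical(bf0$b, integer(0))

    full <- generateToyComplex(4, 4, 4, seed = 3)
    bff <- bruteForceInterface(full$structure, "A", "B", 5.0)
    expect_identical(bff$a, 1:4)
    expect_identical(bff$b, 1:4)
})

test_that("non-designated cross-chain pairs keep a safety margin", {
    cx <- generateToyComplex(12, 9, 4, seed = 5)
    at <- atomTable(cx$structure)
    A <- as.matrix(at[at$chain == "A", c("x", "y", "z")])
    B <- as.matrix(at[at$chain == "B", c("x", "y", "z")])
    d <- sqrt(outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B))
    posA <- at$pos[at$chain == "A"]
    posB <- at$pos[at$chain == "B"]
    pairMin <- tapply(as.vector(d),
                      list(factor(rep(posA, ncol(d)), levels = 1:12),
                           factor(rep(posB, each = nrow(d)), levels = 1:9)),
                      min)
    ## contacts are realised pairwise: k-th interface residue of A against
    ## the k-th of B
    designated <- matrix(FALSE, 12, 9)
    designated[cbind(cx$interface$A, cx$interface$B)] <- TRUE
    expect_true(all(pairMin[designated] <= 5.0))
    expect_true(all(pairMin[!designated] > 6.5))
})

test_that("impossible interface requests are rejected", {
    expect_error(generateToyComplex(3, 5, 4, seed = 1), "invalid-scenario")
    expect_error(generateToyComplex(0, 5, 0, seed = 1), "invalid-scenario")
})

test_that("generation is reproducible: same seed, byte-identical output", {
    f1 <- tempfile(fileext = ".pdb")
    f2 <- tempfile(fileext = ".pdb")
    writeStructure(generateToyComplex(8, 7, 2, seed = 42)$structure, f1)
    writeStructure(generateToyComplex(8, 7, 2, seed = 42)$structure, f2)
    expect_identical(readLines(f1), readLines(f2))
})

test_that("flank corruption rate drives verification acceptance", {
    seqs <- vapply(1:6, function(i) {
        paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I"), 50, TRUE),
              collapse = "")
    }, "")
    names(seqs) <- paste0("P", 1:6)

    clean <- generateMutationTable(seqs, c(nonpathogenic = 30,
                                           pathogenic = 20), 0, seed = 1)
    v <- verifyFlank(rbind(clean$dbsnp[, c("protein", "position", "wt_aa",
                                           "flank")],
                           clean$clinvar[, c("protein", "position", "wt_aa",
                                             "flank")]),
                     seqs, seqs)
    expect_true(all(v$mapped))

    broken <- generateMutationTable(seqs, c(nonpathogenic = 30,
                                            pathogenic = 20), 1, seed = 2)
    vb <- verifyFlank(broken$dbsnp[, c("protein", "position", "wt_aa",
                                       "flank")], seqs, seqs)
    expect_false(any(vb$mapped))
})

test_that("realised corruption matches the requested rate", {
    set.seed(99)
    seqs <- vapply(1:12, function(i) paste(sample(LETTERS[c(1, 3:9)], 60,
                                                  TRUE), collapse = ""), "")
    names(seqs) <- paste0("Q", 1:12)
    tabs <- generateMutationTable(seqs, c(nonpathogenic = 350,
                                          pathogenic = 150), 0.2, seed = 7)
    recs <- rbind(tabs$dbsnp[, c("protein", "position", "wt_aa", "flank")],
                  tabs$clinvar[, c("protein", "position", "wt_aa", "flank")])
    v <- verifyFlank(recs, seqs, seqs)
    accept <- mean(v$mapped)
    se <- sqrt(0.8 * 0.2 / 500)
    expect_lt(abs(accept - 0.8), 3 * se)
})

test_that("free-energy draws keep ground-truth edgotypes unambiguous", {
    set.seed(3)
    n <- 400
    loc <- sample(c("interfacial", "buried", "exposed"), n, TRUE)
    edg <- ifelse(loc == "interfacial",
                  sample(c("edgetic", "quasi-wild-type"), n, TRUE),
                  ifelse(loc == "buried",
                         sample(c("quasi-null", "quasi-wild-type"), n, TRUE),
                         "quasi-wild-type"))
    truth <- data.frame(protein = paste0("P", seq_len(n)), position = 10L,
                        wt_aa = "A", mut_aa = "V", location = loc,
                        edgotype = edg,
                        partners = ifelse(loc == "interfacial", "X;Y", ""),
                        stringsAsFactors = FALSE)
    ddg <- generateDdgTable(truth, seed = 11)
    recovered <- vapply(seq_len(n), function(i) {
        rows <- ddg[ddg$protein == truth$protein[i], , drop = FALSE]
        b <- rows$ddg[rows$kind == "binding"]
        names(b) <- rows$partner[rows$kind == "binding"]
        f <- rows$ddg[rows$kind == "folding"]
        classifyEdgotype(truth$location[i],
                         if (length(b)) b else NULL, f)$edgotype
    }, "")
    expect_identical(recovered, truth$edgotype)

    bind <- ddg$ddg[ddg$kind == "binding"]
    expect_true(all(bind <= 0.45 | bind >= 0.6))
    fold <- ddg$ddg[ddg$kind == "folding"]
    expect_true(all(fold <= 0.45 | fold >= 2.0))
})

test_that("inconsistent truth labels are refused", {
    bad <- data.frame(protein = "P1", position = 1L, wt_aa = "A",
                      mut_aa = "V", location = "exposed",
                      edgotype = "edgetic", partners = "")
    expect_error(generateDdgTable(bad), "invalid-scenario")
})

test_that("edgotype count draws respect margins, probabilities and seeds", {
    degenerate <- rbind(nonpathogenic = c(1, 0, 0), pathogenic = c(1, 0, 0))
    colnames(degenerate) <- colnames(defaultEdgotypeProbs())
    m <- generateEdgotypeCounts(50, 20, degenerate, seed = 1)
    expect_identical(unname(m[, "quasi-wild-type"]), c(50L, 20L))
    expect_identical(unname(m[, "edgetic"]), c(0L, 0L))

    m1 <- generateEdgotypeCounts(100, 40, seed = 5)
    m2 <- generateEdgotypeCounts(100, 40, seed = 5)
    expect_identical(m1, m2)
    expect_identical(unname(rowSums(m1)), c(100, 40))

    big <- generateEdgotypeCounts(1e6, 1e6, seed = 9)
    fr <- big / rowSums(big)
    probs <- defaultEdgotypeProbs()
    for (r in rownames(probs)) {
        for (cc in colnames(probs)) {
            se <- sqrt(probs[r, cc] * (1 - probs[r, cc]) / 1e6)
            expect_lt(abs(fr[r, cc] - probs[r, cc]), 3 * se + 1e-12)
        }
    }
})

test_that("scenario validation enforces the documented invariants", {
    expect_error(syntheticScenario(interface_fraction = 1.2), "interface")
    badp <- rbind(nonpathogenic = c(0.9, 0.2, 0.1),
                  pathogenic = c(0.74, 0.13, 0.13))
    colnames(badp) <- colnames(defaultEdgotypeProbs())
    expect_error(syntheticScenario(edgotype_probs = badp), "sum to 1")
    expect_error(syntheticScenario(n_proteins = 0), "positive")
})
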