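test_that("conditional probabilities come straight from count rows", {
    counts <- rbind(nonpathogenic = c(1040L, 16L, 16L),
                    pathogenic = c(235L, 41L, 42L))
    colnames(counts) <- colnames(defaultEdgotypeProbs())
    cp <- conditionalProbs(counts)
    expect_equal(conditionals(cp)["nonpathogenic", "quasi-wild-type"],
                 1040 / 1072)
    expect_equal(round(conditionals(cp)["nonpathogenic",
                                        "quasi-wild-type"], 2), 0.97)
    expect_equal(round(conditionals(cp)["pathogenic",
                                        "quasi-wild-type"], 2), 0.74)

    uni <- matrix(10L, 2, 3, dimnames = dimnames(counts))
    expect_true(all(abs(conditionals(conditionalProbs(uni)) - 1 / 3) < 1e-12))

    zero <- counts
    zero["pathogenic", ] <- 0L
    expect_error(conditionalProbs(zero), "empty-class")
})

test_that("the assumption fixes the strongly-detrimental conditionals", {
    ep1 <- edgotypeProbs(c(0.97, 0.015, 0.015), c(0.74, 0.13, 0.13),
                         assumption = "I")
    expect_equal(unname(strongConditionals(ep1)), c(0, 0, 1))
    ep2 <- edgotypeProbs(c(0.97, 0.015, 0.015), c(0.74, 0.13, 0.13),
                         assumption = "II")
    expect_equal(unname(strongConditionals(ep2)), c(0.74, 0.13, 0.13))
})

test_that("the Bayes chain reproduces the published worked example", {
    ep <- edgotypeProbs(c(0.97, 0.015, 0.015), c(0.74, 0.13, 0.13),
                        assumption = "I", dataset = "Y2H-SI")
    tb <- posteriorTable(fitnessPosterior(ep))
    qw <- tb[tb$edgotype == "quasi-wild-type", ]
    ## P(QW) = 0.97*0.27 + 0.74*0.53 = 0.6541; published rounding 65.5%
    expect_equal(qw$p_t[1], 0.97 * 0.27 + 0.74 * 0.53, tolerance = 1e-12)
    expect_equal(round(qw$estimate[qw$fitness == "neutral"], 2), 0.40)
    expect_equal(round(qw$estimate[qw$fitness == "mild"], 2), 0.60)
    expect_equal(qw$estimate[qw$fitness == "strong"], 0)
})

test_that("uninformative conditionals return the priors", {
    ep <- edgotypeProbs(c(1 / 3, 1 / 3, 1 / 3), c(1 / 3, 1 / 3, 1 / 3),
                        assumption = "II")
    tb <- posteriorTable(fitnessPosterior(ep))
    pri <- fitnessPriors()
    for (f in names(pri)) {
        expect_equal(tb$estimate[tb$fitness == f],
                     rep(pri[[f]], 3), tolerance = 1e-12)
    }
})

test_that("Assumption II quasi-null chain matches direct evaluation", {
    ep <- edgotypeProbs(c(0.97, 0.015, 0.015), c(0.74, 0.13, 0.13),
                        assumption = "II")
    tb <- posteriorTable(fitnessPosterior(ep))
    qn <- tb[tb$edgotype == "quasi-null", ]
    oracle <- oracleBayes(0.015, 0.13, 0.13, c(0.27, 0.53, 0.20))
    expect_equal(qn$p_t[1], 0.09895, tolerance = 1e-12)
    expect_equal(qn$estimate[qn$fitness == "mild"],
                 unname(oracle[["mild"]]), tolerance = 1e-12)
    expect_equal(round(qn$estimate[qn$fitness == "mild"], 1), 0.7)
    expect_equal(round(qn$estimate[qn$fitness == "strong"], 3), 0.263)
})

test_that("law of total probability and Bayes consistency hold for random
           conditionals", {
    set.seed(10)
    for (i in 1:25) {
        pn <- as.vector(rmultinom(1, 1000, runif(3))) / 1000
        pm <- as.vector(rmultinom(1, 1000, runif(3))) / 1000
        if (any(pn == 0) || any(pm == 0)) next
        for (a in c("I", "II")) {
            ep <- edgotypeProbs(pn, pm, assumption = a)
            tb <- posteriorTable(fitnessPosterior(ep))
            pt <- tb$p_t[!duplicated(tb$edgotype)]
            expect_equal(sum(pt), 1, tolerance = 1e-9)
            ## P(N|T) P(T) == P(T|N) P(N) at machine precision
            sc <- strongConditionals(ep)
            for (t in unique(tb$edgotype)) {
                r <- tb[tb$edgotype == t, ]
                expect_equal(r$estimate[r$fitness == "neutral"] * r$p_t[1],
                             conditionals(ep)["nonpathogenic", t] * 0.27,
                             tolerance = 1e-14)
                expect_equal(r$estimate[r$fitness == "strong"] * r$p_t[1],
                             sc[[t]] * 0.20, tolerance = 1e-14)
            }
            ## Assumption II algebraic identity: P(S|T)/P(M|T) = P(S)/P(M)
            if (a == "II") {
                s <- tb$estimate[tb$fitness == "strong"]
                m <- tb$estimate[tb$fitness == "mild"]
                expect_equal(s / m, rep(0.20 / 0.53, 3), tolerance = 1e-9)
            }
        }
    }
})

test_that("ratio-form intervals match the frozen hand computation", {
    ## QW/neutral, counts 1040/1072 and 235/318: log-ratio SE arithmetic
    ## evaluated by hand gives [0.38498, 0.41675]
    ep <- edgotypeProbs(c(1040, 16, 16) / 1072, c(235, 41, 42) / 318,
                        n = c(nonpathogenic = 1072, pathogenic = 318),
                        assumption = "I")
    ci <- blandCi(ep, "quasi-wild-type", "neutral")
    expect_equal(ci, c(0.38498, 0.41675), tolerance = 2e-4)
    ## matches the published interval of about 38-42% after rounding
    expect_equal(round(100 * ci), c(38, 42))
})

test_that("interval width vanishes as the count basis grows", {
    widths <- vapply(c(1e3, 1e5, 1e7), function(n) {
        ep <- edgotypeProbs(c(0.97, 0.015, 0.015), c(0.74, 0.13, 0.13),
                            n = c(nonpathogenic = n, pathogenic = n),
                            assumption = "I")
        diff(blandCi(ep, "quasi-wild-type", "neutral"))
    }, 0)
    expect_true(all(diff(widths) < 0))
    expect_lt(widths[3], 1e-3)
    ## and the interval brackets the point estimate
    ep <- edgotypeProbs(c(0.97, 0.015, 0.015), c(0.74, 0.13, 0.13),
                        n = c(nonpathogenic = 1e7, pathogenic = 1e7),
                        assumption = "I")
    ci <- blandCi(ep, "quasi-wild-type", "neutral")
    est <- posteriorTable(fitnessPosterior(ep))
    point <- est$estimate[est$edgotype == "quasi-wild-type" &
                          est$fitness == "neutral"]
    expect_true(ci[1] <= point && point <= ci[2])
})

test_that("zero counts trigger the continuity correction with a warning", {
    ep <- edgotypeProbs(c(0.9, 0, 0.1), c(0.7, 0.2, 0.1),
                        n = c(nonpathogenic = 100, pathogenic = 50),
                        assumption = "I")
    expect_warning(ci <- blandCi(ep, "edgetic", "mild"), "continuity")
    expect_true(all(is.finite(ci)))
    expect_true(ci[1] >= 0 && ci[2] <= 1)
})

test_that("intervals are truncated to the probability scale", {
    ep <- edgotypeProbs(c(0.5, 0.25, 0.25), c(0.5, 0.25, 0.25),
                        n = c(nonpathogenic = 5, pathogenic = 5),
                        assumption = "I")
    for (t in c("quasi-wild-type", "edgetic", "quasi-null")) {
        for (f in c("neutral", "mild", "strong")) {
            ci <- blandCi(ep, t, f)
            expect_true(all(ci >= 0 & ci <= 1))
        }
    }
})

test_that("posteriors recovered from finite counts match the truth within
           sampling error", {
    truthN <- c(0.97, 0.015, 0.015)
    truthM <- c(0.74, 0.13, 0.13)
    n <- 1e5
    counts <- generateEdgotypeCounts(n, n, rbind(nonpathogenic = truthN,
                                                 pathogenic = truthM),
                                     seed = 123)
    for (a in c("I", "II")) {
        est <- posteriorTable(fitnessPosterior(conditionalProbs(counts, a)))
        tru <- posteriorTable(fitnessPosterior(edgotypeProbs(
            truthN, truthM, assumption = a)))
        ciTab <- posteriorTable(fitnessPosterior(conditionalProbs(counts, a)))
        ## use the analytic interval half-width as the scale of 1 SE * 1.96
        for (i in seq_len(nrow(est))) {
            se <- (ciTab$ci_hi[i] - ciTab$ci_lo[i]) / (2 * 1.959964)
            expect_lt(abs(est$estimate[i] - tru$estimate[i]),
                      3 * max(se, 1e-6))
        }
    }
})

test_that("merging the assumptions spans AI to the AI/AII midpoint", {
    ep <- function(a) edgotypeProbs(c(0.97, 0.015, 0.015),
                                    c(0.74, 0.13, 0.13), assumption = a)
    pI <- fitnessPosterior(ep("I"))
    pII <- fitnessPosterior(ep("II"))
    m <- mergeAssumptions(pI, pII)
    qnS <- m[m$edgotype == "quasi-null" & m$fitness == "strong", ]
    ## AI = 0.2/0.27295 = 0.7327..., AII = 0.026/0.09895 = 0.2628...
    expect_equal(qnS$estimate_I, 0.2 / 0.27295, tolerance = 1e-9)
    expect_equal(qnS$estimate_II, 0.026 / 0.09895, tolerance = 1e-9)
    expect_equal(c(qnS$lo, qnS$hi),
                 c((qnS$estimate_I + qnS$estimate_II) / 2, qnS$estimate_I),
                 tolerance = 1e-12)
    ## merged intervals always lie between the two inputs
    tbI <- posteriorTable(pI)
    tbII <- posteriorTable(pII)
    expect_true(all(m$lo >= pmin(tbI$estimate, tbII$estimate) - 1e-12))
    expect_true(all(m$hi <= pmax(tbI$estimate, tbII$estimate) + 1e-12))
})

test_that("identical assumption posteriors merge to a degenerate interval", {
    ## when all pathogenic mutations are quasi-null, Assumption II equals
    ## Assumption I and the merged interval collapses to a point
    ep <- function(a) edgotypeProbs(c(0.9, 0.05, 0.05), c(0, 0, 1),
                                    assumption = a)
    m <- mergeAssumptions(fitnessPosterior(ep("I")),
                          fitnessPosterior(ep("II")))
    expect_equal(m$lo, m$hi, tolerance = 1e-12)
})
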