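## Independent oracles used across the suite. These deliberately take the
## slow, literal route so they share no code path with the package.

## O(n^2) brute-force interface scan: loop over all cross-chain residue
## pairs, min over all atom pairs
bruteForceInterface <- function(structure, chain_a, chain_b, cutoff = 5.0) {
    at <- atomTable(structure)
    A <- at[at$chain == chain_a, , drop = FALSE]
    B <- at[at$chain == chain_b, , drop = FALSE]
    ia <- integer(0)
    ib <- integer(0)
    for (pa in unique(A$pos)) {
        for (pb in unique(B$pos)) {
            xa <- A[A$pos == pa, c("x", "y", "z"), drop = FALSE]
            xb <- B[B$pos == pb, c("x", "y", "z"), drop = FALSE]
            dmin <- Inf
            for (i in seq_len(nrow(xa))) {
                for (j in seq_len(nrow(xb))) {
                    d <- sqrt(sum((as.numeric(xa[i, ]) -
                                   as.numeric(xb[j, ]))^2))
                    if (d < dmin) dmin <- d
                }
            }
            if (dmin <= cutoff) {
                ia <- union(ia, pa)
                ib <- union(ib, pb)
            }
        }
    }
    list(a = sort(as.integer(ia)), b = sort(as.integer(ib)))
}

## exhaustive two-sided Fisher p for a 2x2 table with fixed margins:
## sum the probabilities of all tables no more probable than the observed
enumFisherP <- function(tab) {
    m <- sum(tab[1, ])
    n <- sum(tab[2, ])
    k <- sum(tab[, 1])
    x <- tab[1, 1]
    support <- max(0, k - n):min(k, m)
    probs <- dhyper(support, m, n, k)
    pObs <- dhyper(x, m, n, k)
    sum(probs[probs <= pObs * (1 + 1e-7)])
}

## parametric bootstrap CI for the posterior P(neutral | T) under
## Assumption I with P(T|S) = 0 (pure-ratio case): plain arithmetic on
## binomial redraws, percentile interval
bootstrapNeutralCi <- function(x1, n1, x2, n2, priors, B = 1e6) {
    p1 <- x1 / n1
    p2 <- x2 / n2
    b1 <- rbinom(B, n1, p1) / n1
    b2 <- rbinom(B, n2, p2) / n2
    num <- b1 * priors[["neutral"]]
    den <- num + b2 * priors[["mild"]]
    unname(quantile(num / den, c(0.025, 0.975)))
}

## direct evaluation of the total-probability / Bayes chain, kept separate
## from the package implementation
oracleBayes <- function(p_tn, p_tm, p_ts, priors) {
    pt <- p_tn * priors[[1]] + p_tm * priors[[2]] + p_ts * priors[[3]]
    c(p_t = pt, neutral = p_tn * priors[[1]] / pt,
      mild = p_tm * priors[[2]] / pt, strong = p_ts * priors[[3]] / pt)
}
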