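#' Genome-wide fitness-class priors for new missense mutations
#'
#' Probabilities for a new missense mutation to be effectively neutral,
#' mildly deleterious or strongly detrimental. The defaults (27%, 53%,
#' 20%) are the population-genetics estimates the Bayesian calculation is
#' anchored on.
#'
#' @param neutral,mild,strong Probabilities summing to 1 (tolerance
#'   1e-12).
#' @return Named numeric vector of length 3.
#' @examples
#' fitnessPriors()
#' @export
fitnessPriors <- function(neutral = 0.27, mild = 0.53, strong = 0.20) {
    p <- c(neutral = neutral, mild = mild, strong = strong)
    if (any(p < 0) || abs(sum(p) - 1) > 1e-12)
        stop("priors must be nonnegative and sum to 1 (tolerance 1e-12)",
             call. = FALSE)
    p
}

#' Class-conditional edgotype probabilities from a count table
#'
#' Converts a phenotype-by-edgotype count table into conditional
#' probabilities: the non-pathogenic row (common mutations, taken as
#' effectively neutral) yields P(T | neutral) and the pathogenic row
#' (taken as mildly deleterious) yields P(T | mild), for each edgotype T.
#' The edgotype distribution of strongly detrimental mutations is fixed by
#' the chosen assumption (see [EdgotypeProbs-class]).
#'
#' @param counts 2x3 matrix (rows `nonpathogenic`, `pathogenic`; columns
#'   quasi-wild-type / edgetic / quasi-null).
#' @param assumption `"I"` or `"II"`.
#' @param dataset Label for display.
#' @return An [EdgotypeProbs-class] object.
#' @examples
#' conditionalProbs(generateEdgotypeCounts(1000, 300, seed = 1))
#' @export
conditionalProbs <- function(counts, assumption = c("I", "II"),
                             dataset = "counts") {
    assumption <- match.arg(assumption)
    if (!identical(dim(counts), c(2L, 3L)))
        stop("counts must be a 2x3 matrix", call. = FALSE)
    if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
    n <- rowSums(counts)
    if (any(n == 0))
        stop("empty-class: a phenotype row has zero total", call. = FALSE)
    cond <- counts / n
    dimnames(cond) <- list(.PHENOTYPES, .EDGOTYPES)
    cm <- matrix(as.numeric(counts), 2, 3,
                 dimnames = list(.PHENOTYPES, .EDGOTYPES))
    new("EdgotypeProbs", cond = cond, counts = cm,
        n = c(nonpathogenic = n[[1L]], pathogenic = n[[2L]]),
        assumption = assumption, dataset = dataset)
}

#' Class-conditional edgotype probabilities from printed fractions
#'
#' Builds an [EdgotypeProbs-class] directly from conditional fractions
#' (for example, percentages printed in a report) together with the class
#' sample sizes needed for confidence intervals. Success counts are taken
#' as fraction times n and may be non-integer.
#'
#' @param nonpath,path Length-3 vectors of quasi-wild-type / edgetic /
#'   quasi-null fractions, each summing to 1 within 1e-9.
#' @param n Named vector `c(nonpathogenic = , pathogenic = )`; use `NA`
#'   when intervals are not needed.
#' @param assumption `"I"` or `"II"`.
#' @param dataset Label for display.
#' @return An [EdgotypeProbs-class] object.
#' @examples
#' edgotypeProbs(c(0.97, 0.015, 0.015), c(0.74, 0.13, 0.13),
#'               n = c(nonpathogenic = 1072, pathogenic = 318))
#' @export
edgotypeProbs <- function(nonpath, path,
                          n = c(nonpathogenic = NA_real_,
                                pathogenic = NA_real_),
                          assumption = c("I", "II"), dataset = "fractions") {
    assumption <- match.arg(assumption)
    cond <- rbind(nonpathogenic = nonpath, pathogenic = path)
    colnames(cond) <- .EDGOTYPES
    counts <- cond * rep(c(n[["nonpathogenic"]], n[["pathogenic"]]), 3)
    new("EdgotypeProbs", cond = cond, counts = counts,
        n = c(nonpathogenic = as.numeric(n[["nonpathogenic"]]),
              pathogenic = as.numeric(n[["pathogenic"]])),
        assumption = assumption, dataset = dataset)
}

## the total-probability / Bayes chain for one edgotype, exact arithmetic
.bayesChain <- function(p_tn, p_tm, p_ts, priors) {
    p_t <- p_tn * priors[["neutral"]] + p_tm * priors[["mild"]] +
        p_ts * priors[["strong"]]
    if (p_t <= 0)
        stop("undefined-posterior: marginal edgotype probability is zero",
             call. = FALSE)
    c(p_t = p_t,
      neutral = p_tn * priors[["neutral"]] / p_t,
      mild = p_tm * priors[["mild"]] / p_t,
      strong = p_ts * priors[["strong"]] / p_t)
}

#' Posterior fitness effect per edgotype
#'
#' Applies the law of total probability and Bayes' theorem to the
#' class-conditional edgotype probabilities: for each edgotype T, the
#' marginal P(T) = P(T|N)P(N) + P(T|M)P(M) + P(T|S)P(S), and the
#' posteriors P(N|T), P(M|T), P(S|T) by Bayes inversion, where N/M/S are
#' the effectively-neutral, mildly-deleterious and strongly-detrimental
#' fitness classes. 95% confidence intervals are attached via [blandCi()]
#' whenever the object carries a count basis.
#'
#' @param object An [EdgotypeProbs-class] object.
#' @param priors See [fitnessPriors()].
#' @param level Confidence level for the intervals (default 0.95; only
#'   the 95% normal quantile is tabulated, other levels use `qnorm`).
#' @return A [FitnessPosterior-class] object.
#' @examples
#' ep <- edgotypeProbs(c(0.97, 0.015, 0.015), c(0.74, 0.13, 0.13))
#' posteriorTable(fitnessPosterior(ep))
#' @export
fitnessPosterior <- function(object, priors = fitnessPriors(), level = 0.95) {
    stopifnot(is(object, "EdgotypeProbs"))
    ps <- strongConditionals(object)
    cond <- conditionals(object)
    haveCounts <- !any(is.na(object@n))
    rows <- list()
    for (t in .EDGOTYPES) {
        ch <- .bayesChain(cond["nonpathogenic", t], cond["pathogenic", t],
                          ps[[t]], priors)
        ci <- matrix(NA_real_, 3, 2,
                     dimnames = list(.FITNESS, c("lo", "hi")))
        if (haveCounts) {
            for (f in .FITNESS) {
                ci[f, ] <- blandCi(object, t, f, priors, level)
            }
        }
        rows[[t]] <- data.frame(
            edgotype = t, fitness = .FITNESS, p_t = ch[["p_t"]],
            estimate = c(ch[["neutral"]], ch[["mild"]], ch[["strong"]]),
            ci_lo = ci[, "lo"], ci_hi = ci[, "hi"],
            stringsAsFactors = FALSE)
    }
    tb <- do.call(rbind, rows)
    rownames(tb) <- NULL
    new("FitnessPosterior", table = tb, priors = priors,
        assumption = object@assumption, dataset = object@dataset)
}

#' Merge the two assumption extremes into interval estimates
#'
#' The two assumptions bracket the unknown edgotype distribution of
#' strongly detrimental mutations; the merged summary for each (edgotype,
#' fitness class) spans from the Assumption-I estimate to the average of
#' the Assumption-I and Assumption-II estimates, ordered.
#'
#' @param posterior_I,posterior_II [FitnessPosterior-class] objects
#'   computed from the same conditionals under the two assumptions.
#' @return A `data.frame` with columns `edgotype`, `fitness`, `lo`, `hi`,
#'   `estimate_I`, `estimate_II`.
#' @export
mergeAssumptions <- function(posterior_I, posterior_II) {
    stopifnot(assumptionOf(posterior_I) == "I",
              assumptionOf(posterior_II) == "II")
    a <- posteriorTable(posterior_I)
    b <- posteriorTable(posterior_II)
    stopifnot(identical(a$edgotype, b$edgotype),
              identical(a$fitness, b$fitness))
    mid <- (a$estimate + b$estimate) / 2
    data.frame(edgotype = a$edgotype, fitness = a$fitness,
               lo = pmin(a$estimate, mid), hi = pmax(a$estimate, mid),
               estimate_I = a$estimate, estimate_II = b$estimate,
               stringsAsFactors = FALSE)
}

#' @rdname mergeAssumptions
#' @param object A [FitnessPosterior-class].
#' @export
assumptionOf <- function(object) object@assumption
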