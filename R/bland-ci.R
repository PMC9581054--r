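#' Confidence interval for a posterior fitness-effect probability
#'
#' Each posterior probability can be written as the reciprocal of one plus
#' a combination of the two estimated conditionals p1 = P(T | neutral) and
#' p2 = P(T | mild) (the strongly-detrimental conditional is fixed by the
#' assumption, not estimated independently). Whenever that combination
#' reduces to a constant plus a constant multiple of a ratio of the two
#' proportions, the interval comes from the standard log-scale treatment
#' of a ratio of proportions: the log ratio has standard error
#' `sqrt((1/x1 - 1/n1) + (1/x2 - 1/n2))`, the interval on the ratio is
#' transformed through the (monotone) expression for the posterior. When a
#' constant additive term prevents the ratio reduction (Assumption I for
#' the quasi-null edgotype, where P(T|S) = 1 enters the numerator), the
#' combination's variance is propagated to first order from the binomial
#' variances `p(1-p)/n` of the two conditionals and the interval is
#' normal-theory on that transformed scale. Intervals are truncated to
#' `[0, 1]`.
#'
#' A zero success count triggers a continuity correction (one half is
#' added to the count) with a warning. Under Assumption II the
#' strongly-detrimental conditional is the *same estimate* as P(T | mild)
#' (perfect dependence), so it contributes no independent variance.
#'
#' @param object An [EdgotypeProbs-class] with a count basis.
#' @param edgotype One of `"quasi-wild-type"`, `"edgetic"`,
#'   `"quasi-null"`.
#' @param fitness One of `"neutral"`, `"mild"`, `"strong"`.
#' @param priors See [fitnessPriors()].
#' @param level Confidence level (default 0.95).
#' @return Numeric vector `c(lo, hi)`.
#' @examples
#' ep <- edgotypeProbs(c(0.97, 0.015, 0.015), c(0.74, 0.13, 0.13),
#'                     n = c(nonpathogenic = 1072, pathogenic = 318))
#' round(blandCi(ep, "quasi-wild-type", "neutral"), 3)
#' @export
blandCi <- function(object, edgotype, fitness, priors = fitnessPriors(),
                    level = 0.95) {
    stopifnot(is(object, "EdgotypeProbs"))
    if (any(is.na(object@n)))
        stop("confidence intervals require explicit sample sizes",
             call. = FALSE)
    t <- match.arg(edgotype, .EDGOTYPES)
    f <- match.arg(fitness, .FITNESS)
    z <- if (identical(level, 0.95)) .Z95 else
        stats::qnorm(1 - (1 - level) / 2)

    n1 <- object@n[["nonpathogenic"]]
    n2 <- object@n[["pathogenic"]]
    x1 <- object@counts["nonpathogenic", t]
    x2 <- object@counts["pathogenic", t]
    if (x1 == 0) { warning("continuity correction: zero count in the ",
                           "non-pathogenic class", call. = FALSE)
                   x1 <- 0.5 }
    if (x2 == 0) { warning("continuity correction: zero count in the ",
                           "pathogenic class", call. = FALSE)
                   x2 <- 0.5 }
    p1 <- x1 / n1
    p2 <- x2 / n2
    pn <- priors[["neutral"]]; pm <- priors[["mild"]]
    ps <- priors[["strong"]]
    aII <- object@assumption == "II"
    s <- if (aII) NA_real_ else if (t == "quasi-null") 1 else 0

    ## log-scale CI for a ratio of two proportions num/den
    ratioCi <- function(xn, nn, xd, nd) {
        r <- (xn / nn) / (xd / nd)
        se <- sqrt((1 / xn - 1 / nn) + (1 / xd - 1 / nd))
        c(r * exp(-z * se), r * exp(z * se))
    }
    ## posterior from the transformed scale: P = 1 / (c0 + c1 * r),
    ## decreasing in r
    fromRatio <- function(c0, c1, rci) {
        lo <- 1 / (c0 + c1 * rci[2L])
        hi <- 1 / (c0 + c1 * rci[1L])
        c(lo, hi)
    }
    clip <- function(ci) pmin(pmax(ci, 0), 1)

    if (!aII && s == 0 && f == "strong") return(c(0, 0))

    ci <-
        if (f == "neutral") {
            if (aII) {
                ## 1/P = 1 + ((pm + ps)/pn) * (p2/p1)
                fromRatio(1, (pm + ps) / pn, ratioCi(x2, n2, x1, n1))
            } else if (s == 0) {
                ## 1/P = 1 + (pm/pn) * (p2/p1)
                fromRatio(1, pm / pn, ratioCi(x2, n2, x1, n1))
            } else {
                ## 1/P = 1 + ((pm/pn) p2 + ps/pn) / p1 : delta method
                a <- pm / pn; b <- ps / pn
                g <- (a * p2 + b) / p1
                v <- (a / p1)^2 * p2 * (1 - p2) / n2 +
                     ((a * p2 + b) / p1^2)^2 * p1 * (1 - p1) / n1
                c(1 / (1 + g + z * sqrt(v)), 1 / (1 + g - z * sqrt(v)))
            }
        } else if (f == "mild") {
            if (aII) {
                ## 1/P = 1 + ps/pm + (pn/pm) * (p1/p2)
                fromRatio(1 + ps / pm, pn / pm, ratioCi(x1, n1, x2, n2))
            } else if (s == 0) {
                ## 1/P = 1 + (pn/pm) * (p1/p2)
                fromRatio(1, pn / pm, ratioCi(x1, n1, x2, n2))
            } else {
                ## 1/P = 1 + ((pn/pm) p1 + ps/pm) / p2 : delta method
                a <- pn / pm; b <- ps / pm
                g <- (a * p1 + b) / p2
                v <- (a / p2)^2 * p1 * (1 - p1) / n1 +
                     ((a * p1 + b) / p2^2)^2 * p2 * (1 - p2) / n2
                c(1 / (1 + g + z * sqrt(v)), 1 / (1 + g - z * sqrt(v)))
            }
        } else {                       # strong
            if (aII) {
                ## 1/P = 1 + pm/ps + (pn/ps) * (p1/p2)
                fromRatio(1 + pm / ps, pn / ps, ratioCi(x1, n1, x2, n2))
            } else {
                ## s == 1: 1/P = 1 + (pn p1 + pm p2)/ps : delta on the sum
                a <- pn / ps; b <- pm / ps
                g <- a * p1 + b * p2
                v <- a^2 * p1 * (1 - p1) / n1 + b^2 * p2 * (1 - p2) / n2
                c(1 / (1 + g + z * sqrt(v)), 1 / (1 + g - z * sqrt(v)))
            }
        }
    clip(ci)
}
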