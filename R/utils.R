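## internal helpers shared across modules

.EDGOTYPES <- c("quasi-wild-type", "edgetic", "quasi-null")
.PHENOTYPES <- c("nonpathogenic", "pathogenic")
.FITNESS <- c("neutral", "mild", "strong")

## 95% two-sided normal quantile, fixed for determinism
.Z95 <- 1.959964

.assertColumns <- function(df, cols, what = "table") {
    missing <- setdiff(cols, names(df))
    if (length(missing) > 0L) {
        stop("schema-error: ", what, " is missing column(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
    }
    invisible(TRUE)
}

.isProbability <- function(x) {
    is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

## deterministic seed derivation for sub-streams; stays well below 2^31
.subSeed <- function(seed, k) {
    (as.integer(seed) %% 1000003L) * 1009L + as.integer(k)
}

## truncated-normal sampler via inverse CDF (exact, no rejection loops)
.rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
    plo <- stats::pnorm(lower, mean, sd)
    phi <- stats::pnorm(upper, mean, sd)
    stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}
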