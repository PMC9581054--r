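#' Filter ClinVar-style records down to high-confidence pathogenic
#' missense mutations
#'
#' Keeps records that are missense, labelled exactly `"pathogenic"`
#' (case-insensitive; "likely pathogenic" and compound labels are
#' dropped), supported by at least one review star, and free of
#' conflicting interpretations.
#'
#' @param records `data.frame` with columns `consequence`, `significance`,
#'   `stars`, `conflict` (plus identifying columns, which pass through).
#' @return The filtered `data.frame`, with attribute `n_dropped`.
#' @examples
#' df <- data.frame(protein = "P1", position = 1:2, wt_aa = "A",
#'                  mut_aa = "V", consequence = "missense",
#'                  significance = c("pathogenic", "likely pathogenic"),
#'                  stars = 2L, conflict = FALSE)
#' nrow(filterClinvar(df))
#' @export
filterClinvar <- function(records) {
    .assertColumns(records, c("consequence", "significance", "stars",
                              "conflict"), "ClinVar-style table")
    keep <- records$consequence == "missense" &
        tolower(trimws(records$significance)) == "pathogenic" &
        records$stars >= 1L &
        !records$conflict
    out <- records[keep, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "n_dropped") <- sum(!keep)
    out
}

#' Filter dbSNP-style records down to common non-pathogenic missense
#' mutations
#'
#' Keeps records that are missense, validated, not withdrawn, carry no
#' pathogenic- or uncertain-type assertion, and have a minor allele
#' frequency of at least `maf_min` (default 1%). Records with a missing
#' MAF are dropped (conservatively, since commonness cannot be
#' established).
#'
#' @param records `data.frame` with columns `consequence`, `validated`,
#'   `withdrawn`, `assertion`, `maf`.
#' @param maf_min Minimum minor allele frequency (default 0.01).
#' @param excluded_assertions Assertion labels that disqualify a record.
#' @return The filtered `data.frame`, with attribute `n_dropped`.
#' @export
filterDbsnp <- function(records, maf_min = 0.01,
                        excluded_assertions = c("pathogenic",
                                                "likely pathogenic",
                                                "drug-response",
                                                "uncertain significance",
                                                "other")) {
    .assertColumns(records, c("consequence", "validated", "withdrawn",
                              "assertion", "maf"), "dbSNP-style table")
    assertion <- tolower(trimws(records$assertion))
    keep <- records$consequence == "missense" &
        records$validated &
        !records$withdrawn &
        !(assertion %in% tolower(excluded_assertions)) &
        !is.na(records$maf) &
        records$maf >= maf_min
    out <- records[keep, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "n_dropped") <- sum(!keep)
    out
}

#' Verify mutation records against transcript and protein sequences
#'
#' For every record, the mutation flanking sequence -- the first 10
#' residues on each side of the mutation site, or all residues when the
#' sequence is shorter, with the wild-type residue at the site -- must
#' occur in the transcript at the reported position *and* in the protein
#' sequence at the same position. Records failing either check are
#' rejected; records whose position lies beyond either sequence are
#' rejected with reason `"coordinate-error"`.
#'
#' @param records `data.frame` with columns `protein`, `position`,
#'   `wt_aa`, `flank`.
#' @param transcripts,proteins Named character vectors of protein-level
#'   sequences (transcript translations and reference protein sequences).
#' @return `records` with added columns `mapped` (logical) and `reason`
#'   (`"ok"`, `"flank-mismatch"`, `"missing-sequence"` or
#'   `"coordinate-error"`).
#' @export
verifyFlank <- function(records, transcripts, proteins) {
    .assertColumns(records, c("protein", "position", "wt_aa", "flank"),
                   "mutation table")
    n <- nrow(records)
    mapped <- logical(n)
    reason <- character(n)
    for (i in seq_len(n)) {
        p <- records$protein[i]
        pos <- records$position[i]
        tr <- if (p %in% names(transcripts)) transcripts[[p]] else NULL
        pr <- if (p %in% names(proteins)) proteins[[p]] else NULL
        if (is.null(tr) || is.null(pr)) {
            reason[i] <- "missing-sequence"
            next
        }
        if (pos < 1L || pos > nchar(tr) || pos > nchar(pr)) {
            reason[i] <- "coordinate-error"
            next
        }
        from <- max(1L, pos - 10L)
        to_t <- min(nchar(tr), pos + 10L)
        to_p <- min(nchar(pr), pos + 10L)
        okT <- identical(substr(tr, from, to_t), records$flank[i])
        okP <- identical(substr(pr, from, to_p), records$flank[i])
        if (okT && okP) {
            mapped[i] <- TRUE
            reason[i] <- "ok"
        } else {
            reason[i] <- "flank-mismatch"
        }
    }
    records$mapped <- mapped
    records$reason <- reason
    records
}

#' Keep one mutation per (protein, position)
#'
#' For multiple mutations mapping to the same protein position, the first
#' record in stable input order is retained. Set `policy = "stars"` to
#' instead prefer the record with the highest review-star level (ties back
#' to input order).
#'
#' @param records Mutation `data.frame` with `protein` and `position`.
#' @param policy `"first"` (default) or `"stars"`.
#' @return Deduplicated `data.frame` with attribute `n_dropped`.
#' @export
dedupePositions <- function(records, policy = c("first", "stars")) {
    policy <- match.arg(policy)
    key <- paste(records$protein, records$position, sep = "\r")
    if (policy == "stars" && "stars" %in% names(records)) {
        idx <- seq_len(nrow(records))
        ord <- order(key, -records$stars)
        records <- records[ord, , drop = FALSE]
        key <- key[ord]
        idx <- idx[ord]
        keep <- !duplicated(key)
        out <- records[keep, , drop = FALSE]
        out <- out[order(idx[keep]), , drop = FALSE]
    } else {
        keep <- !duplicated(key)
        out <- records[keep, , drop = FALSE]
    }
    rownames(out) <- NULL
    attr(out, "n_dropped") <- sum(!keep)
    out
}

#' Remove common mutations that share a position with pathogenic ones
#'
#' @param common,pathogenic Deduplicated mutation `data.frame`s.
#' @return The filtered common set, with attribute `n_dropped`.
#' @export
excludeOverlap <- function(common, pathogenic) {
    keyC <- paste(common$protein, common$position, sep = "\r")
    keyP <- paste(pathogenic$protein, pathogenic$position, sep = "\r")
    keep <- !(keyC %in% keyP)
    out <- common[keep, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "n_dropped") <- sum(!keep)
    out
}
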