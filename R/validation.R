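#' Convert a PCR fragment length to repeat copies
#'
#' Capillary-electrophoresis genotypes arrive as amplified fragment
#' lengths in base pairs; the repeat copy number is
#' \eqn{c = \lfloor r + (w - l)/s \rfloor} where `r` is the reference
#' repeat count, `w` the measured fragment length, `l` the reference
#' amplicon length and `s` the motif length. Negative results are masked
#' (`NA`), flagging an inconsistent measurement.
#'
#' @param w fragment length(s) in bp.
#' @param l reference amplicon length in bp.
#' @param s motif length in bp (>= 1).
#' @param r reference repeat count.
#' @return integer repeat copies (floored), `NA` where negative.
#' @examples
#' pcrToRepeats(103, 100, 3, 10)  # 11
#' @export
pcrToRepeats <- function(w, l, s, r) {
    stopifnot(s >= 1, all(w >= 0), all(l >= 0))
    c_ <- floor(r + (w - l) / s)
    c_[c_ < 0] <- NA
    c_
}

# credit one call under one candidate offset:
# 1    — offset applied to the caller genotype recovers both truth alleles
# 0.5  — caller call homozygous, offset recovers exactly one truth allele
# 0.25 — caller call heterozygous, offset recovers exactly one truth allele
scoreCall <- function(caller, truth, offset) {
    shifted <- sort(caller + offset)
    truth <- sort(truth)
    if (identical(as.numeric(shifted), as.numeric(truth))) return(1)
    hom <- caller[1L] == caller[2L]
    nrec <- length(intersect(shifted, truth))
    if (hom && nrec >= 1L) return(0.5)
    if (!hom && nrec == 1L) return(0.25)
    0
}

#' Score per-locus genotype offsets across callers
#'
#' For every locus and caller, each call is scored against every
#' candidate offset with credits 1 / 0.5 / 0.25 (both alleles recovered /
#' one from a homozygous call / one from a heterozygous call). A locus
#' adopts an offset iff that offset is the top-scoring one for *every*
#' caller present and the locus has at least `minCalls` calls; ties in
#' score break toward smaller |offset|, then negative before positive,
#' so adoption is deterministic.
#'
#' @param callers named list of caller [GenotypeTable]s (one per
#'   genotyping tool).
#' @param truth the reference-truth [GenotypeTable] (same samples and
#'   loci).
#' @param offsets candidate offsets (default -10:10).
#' @param minCalls minimum calls per locus to consider (default 20).
#' @return list: `scores` (data.frame locus, caller, offset, score_sum,
#'   n_calls, top), `adopted` (named vector of adopted offsets per
#'   locus; loci without an adopted offset are absent).
#' @export
scoreOffsets <- function(callers, truth, offsets = -10:10, minCalls = 20) {
    if (is(callers, "GenotypeTable")) callers <- list(caller = callers)
    loci <- colnames(truth@allele1)
    scoreRows <- list()
    topPerCaller <- list()
    for (cn in names(callers)) {
        cl <- callers[[cn]]
        for (lo in loci) {
            c1 <- cl@allele1[, lo]; c2 <- cl@allele2[, lo]
            t1 <- truth@allele1[, lo]; t2 <- truth@allele2[, lo]
            ok <- !is.na(c1) & !is.na(t1)
            n <- sum(ok)
            sums <- vapply(offsets, function(d) {
                s <- 0
                for (i in which(ok))
                    s <- s + scoreCall(c(c1[i], c2[i]), c(t1[i], t2[i]), d)
                s
            }, numeric(1))
            # deterministic tie-break: smaller |offset|, negative first
            o <- order(-sums, abs(offsets), offsets)
            top <- offsets[o[1L]]
            scoreRows[[length(scoreRows) + 1L]] <- data.frame(
                locus = lo, caller = cn, offset = offsets,
                score_sum = sums, n_calls = n, top = offsets == top)
            topPerCaller[[lo]] <- c(topPerCaller[[lo]],
                                    stats::setNames(top, cn))
        }
    }
    scores <- do.call(rbind, scoreRows)
    adopted <- c()
    for (lo in loci) {
        tops <- topPerCaller[[lo]]
        n <- max(scores$n_calls[scores$locus == lo])
        # adopting offset 0 is a no-op, so only nonzero offsets are kept
        if (n >= minCalls && length(unique(tops)) == 1L && tops[1L] != 0)
            adopted[lo] <- tops[1L]
    }
    list(scores = scores, adopted = adopted)
}

#' Genotype concordance between a caller and a truth set
#'
#' Strict concordance compares the summed repeat dosage of each call
#' with the truth exactly; tolerant concordance allows a difference of
#' at most one repeat unit. An unordered per-allele pair comparison is
#' available via `mode = "pair"` (strict: both alleles equal as a
#' multiset; tolerant: each allele within +/-1 under the best pairing).
#'
#' @param caller,truth [GenotypeTable]s sharing samples and loci.
#' @param mode `"dosage"` (default) or `"pair"`.
#' @return list: `per_locus` (data.frame locus, n_calls, strict,
#'   tolerant), `aggregate` (named vector strict/tolerant over all
#'   calls).
#' @export
concordance <- function(caller, truth, mode = c("dosage", "pair")) {
    mode <- match.arg(mode)
    loci <- intersect(colnames(caller@allele1), colnames(truth@allele1))
    samples <- intersect(rownames(caller@allele1), rownames(truth@allele1))
    if (!length(loci) || !length(samples)) stop("no shared calls")
    c1 <- caller@allele1[samples, loci, drop = FALSE]
    c2 <- caller@allele2[samples, loci, drop = FALSE]
    t1 <- truth@allele1[samples, loci, drop = FALSE]
    t2 <- truth@allele2[samples, loci, drop = FALSE]
    ok <- !is.na(c1) & !is.na(t1)
    if (!any(ok)) stop("no shared calls")
    if (mode == "dosage") {
        dc <- c1 + c2; dt <- t1 + t2
        strict <- ok & dc == dt
        tol <- ok & abs(dc - dt) <= 1
    } else {
        lo1 <- pmin(c1, c2); hi1 <- pmax(c1, c2)
        lo2 <- pmin(t1, t2); hi2 <- pmax(t1, t2)
        strict <- ok & lo1 == lo2 & hi1 == hi2
        tol <- ok & abs(lo1 - lo2) <= 1 & abs(hi1 - hi2) <= 1
    }
    per_locus <- data.frame(
        locus = loci,
        n_calls = colSums(ok),
        strict = colSums(strict) / pmax(1, colSums(ok)),
        tolerant = colSums(tol) / pmax(1, colSums(ok)))
    rownames(per_locus) <- NULL
    list(per_locus = per_locus,
         aggregate = c(strict = sum(strict) / sum(ok),
                       tolerant = sum(tol) / sum(ok)))
}
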