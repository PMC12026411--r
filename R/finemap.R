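#' Squared Pearson correlation of dosages (LD)
#'
#' @param a,b numeric dosage vectors (summed repeat dosage for TRs,
#'   non-reference allele count for SNVs); missing entries dropped
#'   pairwise.
#' @return r-squared in \[0, 1\].
#' @export
ldR2 <- function(a, b) {
    keep <- !is.na(a) & !is.na(b)
    if (sum(keep) < 3L) stop("need at least 3 complete-case pairs")
    a <- a[keep]; b <- b[keep]
    if (stats::var(a) == 0 || stats::var(b) == 0)
        stop("LD undefined for a constant dosage vector")
    stats::cor(a, b)^2
}

#' Log approximate Bayes factor for a single association
#'
#' Wakefield's closed form: with \eqn{V = se^2}, \eqn{z = \beta/se} and
#' prior effect variance `W`, \eqn{\log ABF = \frac12 \log(V/(V+W)) +
#' \frac12 z^2 W/(V+W)}. Positive values favor a real effect.
#'
#' @param beta effect estimate(s).
#' @param se standard error(s), positive.
#' @param W prior variance of the true effect, positive.
#' @return log Bayes factor (vectorized).
#' @export
logABF <- function(beta, se, W) {
    stopifnot(all(se > 0), W > 0)
    V <- se^2
    z2 <- (beta / se)^2
    0.5 * log(V / (V + W)) + 0.5 * z2 * W / (V + W)
}

logSumExp <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(-Inf)
    m <- max(x)
    if (!is.finite(m)) return(m)
    m + log(sum(exp(x - m)))
}

#' Single-causal-variant fine-mapping from summary statistics
#'
#' Assumes at most one causal variant in the window with a uniform prior
#' over variants. For each candidate prior variance in `Wgrid`, computes
#' per-variant log approximate Bayes factors; the prior variance
#' maximizing the average Bayes factor (the marginal likelihood under the
#' one-causal model) is selected, and posterior inclusion probabilities
#' are the softmax of the log ABFs at that value. The credible set is the
#' smallest PIP-ranked set with cumulative PIP at least `level`; variants
#' outside it are flagged `pruned` (their PIPs are reported, not zeroed).
#'
#' @param stats data.frame with columns variant, beta, se.
#' @param Wgrid candidate prior variances (default
#'   0.001, 0.005, 0.01, 0.0225, 0.05, 0.1).
#' @param level credible-set coverage (default 0.95).
#' @return list of class `FinemapResult`: `pip` (data.frame variant, pip,
#'   in_credible_set, pruned), `credible_set` (variant ids), `W_star`.
#' @export
singleEffectFinemap <- function(stats,
                                Wgrid = c(0.001, 0.005, 0.01, 0.0225,
                                          0.05, 0.1),
                                level = 0.95) {
    ok <- !is.na(stats$beta) & !is.na(stats$se) & stats$se > 0
    stats <- stats[ok, , drop = FALSE]
    if (nrow(stats) == 0L) stop("all variants degenerate")
    J <- nrow(stats)
    marg <- vapply(Wgrid, function(W)
        logSumExp(logABF(stats$beta, stats$se, W)) - log(J), numeric(1))
    W_star <- Wgrid[which.max(marg)]
    l <- logABF(stats$beta, stats$se, W_star)
    pip <- exp(l - logSumExp(l))
    o <- order(pip, decreasing = TRUE)
    cum <- cumsum(pip[o])
    csize <- which(cum >= level - 1e-12)[1L]
    if (is.na(csize)) csize <- J
    in_cs <- logical(J)
    in_cs[o[seq_len(csize)]] <- TRUE
    res <- list(pip = data.frame(variant = stats$variant, pip = pip,
                                 in_credible_set = in_cs, pruned = !in_cs),
                credible_set = stats$variant[o[seq_len(csize)]],
                W_star = W_star, level = level)
    class(res) <- "FinemapResult"
    res
}

#' Candidate-causal call for an sc-eTR
#'
#' An sc-eTR is candidate causal iff it is the lead variant of its eGene
#' (strongest signal in the window, TRs and SNVs jointly) and its
#' fine-mapped posterior inclusion probability is at least `minPIP`.
#'
#' @param finemap a `FinemapResult` (see [singleEffectFinemap]).
#' @param trVariant the sc-eTR variant id.
#' @param leadVariant the window's lead variant id.
#' @param minPIP PIP threshold (default 0.7).
#' @return list: pip, is_lead, passes.
#' @export
callCandidateCausal <- function(finemap, trVariant, leadVariant,
                                minPIP = 0.7) {
    pip <- finemap$pip$pip[match(trVariant, finemap$pip$variant)]
    is_lead <- identical(trVariant, leadVariant)
    list(variant = trVariant, pip = pip, is_lead = is_lead,
         passes = isTRUE(is_lead) && !is.na(pip) && pip >= minPIP)
}

#' Conditional association
#'
#' Re-tests a variant with another variant's dosage appended to the
#' covariates; reports whether the signal persists at genome-wide
#' significance.
#'
#' @param y phenotype vector (transformed expression).
#' @param gTest dosage of the variant under test.
#' @param gCondition dosage of the conditioning variant.
#' @param W optional covariate matrix.
#' @param threshold persistence threshold (default 5e-8).
#' @return one-row data.frame: beta, se, p, n, persists.
#' @export
conditionalAssociation <- function(y, gTest, gCondition, W = NULL,
                                   threshold = 5e-8) {
    r2 <- tryCatch(ldR2(gTest, gCondition), error = function(e) NA_real_)
    if (!is.na(r2) && r2 > 0.999)
        stop("test and conditioning variants are collinear (r2 > 0.999)")
    W2 <- cbind(W, condition = gCondition)
    st <- fitAssociation(y, gTest, W2)
    st$persists <- st$p < threshold
    st
}

#' Remove indels that re-encode TR alleles
#'
#' Applies [isTRIndel] to every indel against the TR loci it falls in;
#' indels composed of whole (possibly rotated) motif copies inside a
#' cataloged locus are removed before fine-mapping so the repeat signal
#' is represented once, by the TR itself.
#'
#' @param indels data.frame: chrom, pos, ref, alt (pure indels).
#' @param catalog a [TRCatalog].
#' @return list: `retained` and `removed` subsets of `indels`.
#' @export
pruneTRIndels <- function(indels, catalog) {
    if (nrow(indels) == 0L)
        return(list(retained = indels, removed = indels))
    gr <- GRanges(indels$chrom, IRanges(indels$pos, indels$pos))
    hits <- findOverlaps(gr, catalog)
    remove <- rep(FALSE, nrow(indels))
    for (h in seq_along(queryHits(hits))) {
        i <- queryHits(hits)[h]; j <- subjectHits(hits)[h]
        if (remove[i]) next
        remove[i] <- tryCatch(
            isTRIndel(indels$pos[i], indels$ref[i], indels$alt[i],
                      catalog[j]),
            error = function(e) FALSE)
    }
    list(retained = indels[!remove, , drop = FALSE],
         removed = indels[remove, , drop = FALSE])
}
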