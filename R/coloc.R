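# log(exp(a) - exp(b)) for a >= b; -Inf when equal within tolerance
logDiffExp <- function(a, b) {
    if (b == -Inf) return(a)
    if (a - b < 1e-12) return(-Inf)
    a + log1p(-exp(b - a))
}

#' Enumeration-based colocalization of two association signals
#'
#' Implements the approximate-Bayes-factor colocalization model: each
#' study has at most one causal variant; configurations are enumerated
#' over which variant (if any) is causal in each study, giving posterior
#' probabilities of the five hypotheses H0 (no association), H1/H2
#' (association in one study only), H3 (two distinct causal variants)
#' and H4 (one shared causal variant). All sums are evaluated in log
#' space. With a single shared variant the H3 configuration space is
#' empty and PP H3 is exactly 0.
#'
#' @param stats1,stats2 data.frames with columns variant, beta, se, for
#'   the same harmonized variant set (matched by the `variant` column).
#' @param p1,p2 prior probability a variant is causal in study 1/2
#'   (defaults 1e-4).
#' @param p12 prior probability a variant is causal in both (default
#'   1e-5).
#' @param W1,W2 prior effect variances; for a quantitative trait with
#'   expression standardized to unit variance W = (0.15 * sdY)^2 with
#'   sdY = 1, i.e. 0.0225 (default); use 0.04 for binary traits on the
#'   log-odds scale.
#' @return list of class `ColocResult`: `pp` (named H0..H4, sums to 1),
#'   `n_variants`, per-variant log ABFs.
#' @export
colocABF <- function(stats1, stats2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                     W1 = 0.0225, W2 = 0.0225) {
    shared <- intersect(stats1$variant, stats2$variant)
    if (length(shared) == 0L) stop("no shared variants")
    s1 <- stats1[match(shared, stats1$variant), , drop = FALSE]
    s2 <- stats2[match(shared, stats2$variant), , drop = FALSE]
    l1 <- logABF(s1$beta, s1$se, W1)
    l2 <- logABF(s2$beta, s2$se, W2)
    lse1 <- logSumExp(l1)
    lse2 <- logSumExp(l2)
    lse12 <- logSumExp(l1 + l2)
    lH0 <- 0
    lH1 <- log(p1) + lse1
    lH2 <- log(p2) + lse2
    lH3 <- log(p1) + log(p2) + logDiffExp(lse1 + lse2, lse12)
    lH4 <- log(p12) + lse12
    lv <- c(H0 = lH0, H1 = lH1, H2 = lH2, H3 = lH3, H4 = lH4)
    pp <- exp(lv - logSumExp(lv))
    res <- list(pp = pp / sum(pp), n_variants = length(shared),
                labf1 = stats::setNames(l1, shared),
                labf2 = stats::setNames(l2, shared))
    class(res) <- "ColocResult"
    res
}

#' Gate a colocalization result with the candidate-causal criteria
#'
#' A gene x trait pair passes iff (1) PP H4 is at least `minH4`, (2) the
#' sc-eTR is candidate causal (lead variant with PIP >= 0.7, see
#' [callCandidateCausal]), (3) the sc-eTR is in at least moderate LD
#' (r2 >= `minR2`) with some variant cataloged in the GWAS window, and
#' (4) the window contains a genome-wide significant GWAS signal
#' (P < `gwasP`) — without (4) the pair is ineligible rather than
#' failed.
#'
#' @param coloc a `ColocResult`.
#' @param candidate a candidate-causal call ([callCandidateCausal]).
#' @param gwasP_values GWAS p-values of variants in the window.
#' @param r2ToGwas vector of r2 between the sc-eTR and each cataloged
#'   GWAS variant.
#' @param minH4,minPIPr2,minR2,gwasP thresholds (defaults 0.8, 0.7, 0.5,
#'   5e-8).
#' @return list: passes, eligible, reasons (named logical vector).
#' @export
gateColocalization <- function(coloc, candidate, gwasP_values, r2ToGwas,
                               minH4 = 0.8, minR2 = 0.5, gwasP = 5e-8) {
    eligible <- any(gwasP_values < gwasP, na.rm = TRUE)
    reasons <- c(
        pp_h4 = unname(coloc$pp["H4"] >= minH4),
        candidate_causal = isTRUE(candidate$passes),
        ld = any(r2ToGwas >= minR2, na.rm = TRUE),
        gwas_signal = eligible)
    list(passes = eligible && all(reasons), eligible = eligible,
         reasons = reasons)
}

#' Harmonize variant identifiers between two studies
#'
#' TR loci match iff their intervals intersect and their motifs are
#' equal up to cyclic rotation and/or reverse complement
#' ([canonicalMotif]). SNVs match on (chrom, pos) with identical allele
#' sets; records listed ref/alt versus alt/ref are matched with the
#' study-2 effect sign flipped. Unmatched variants are dropped and
#' counted.
#'
#' @param eqtl,gwas data.frames. TR rows need chrom, start, end, motif;
#'   SNV rows need chrom, pos, ref, alt. Both need variant, beta, se and
#'   a `type` column ("TR"/"SNV").
#' @return list: `map` (data.frame variant_eqtl, variant_gwas,
#'   flip), `gwas_harmonized` (gwas subset renamed to eQTL ids, signs
#'   flipped where needed), `n_unmatched`.
#' @export
harmonizeVariants <- function(eqtl, gwas) {
    maps <- list()
    e_tr <- eqtl[eqtl$type == "TR", , drop = FALSE]
    g_tr <- gwas[gwas$type == "TR", , drop = FALSE]
    if (nrow(e_tr) && nrow(g_tr)) {
        ge <- GRanges(e_tr$chrom, IRanges(e_tr$start, e_tr$end))
        gg <- GRanges(g_tr$chrom, IRanges(g_tr$start, g_tr$end))
        hits <- findOverlaps(ge, gg)
        if (length(hits)) {
            q <- queryHits(hits); s <- subjectHits(hits)
            same <- canonicalMotif(e_tr$motif[q]) ==
                canonicalMotif(g_tr$motif[s])
            if (any(same))
                maps[[length(maps) + 1L]] <- data.frame(
                    variant_eqtl = e_tr$variant[q[same]],
                    variant_gwas = g_tr$variant[s[same]],
                    flip = FALSE)
        }
    }
    e_sn <- eqtl[eqtl$type == "SNV", , drop = FALSE]
    g_sn <- gwas[gwas$type == "SNV", , drop = FALSE]
    if (nrow(e_sn) && nrow(g_sn)) {
        ek <- paste(e_sn$chrom, e_sn$pos)
        gk <- paste(g_sn$chrom, g_sn$pos)
        mi <- match(ek, gk)
        hit <- !is.na(mi)
        if (any(hit)) {
            i <- which(hit); j <- mi[hit]
            direct <- e_sn$ref[i] == g_sn$ref[j] & e_sn$alt[i] == g_sn$alt[j]
            flipped <- e_sn$ref[i] == g_sn$alt[j] & e_sn$alt[i] == g_sn$ref[j]
            keep <- direct | flipped
            if (any(keep))
                maps[[length(maps) + 1L]] <- data.frame(
                    variant_eqtl = e_sn$variant[i[keep]],
                    variant_gwas = g_sn$variant[j[keep]],
                    flip = flipped[keep])
        }
    }
    map <- if (length(maps)) do.call(rbind, maps) else
        data.frame(variant_eqtl = character(),
                   variant_gwas = character(), flip = logical())
    map <- map[!duplicated(map$variant_eqtl), , drop = FALSE]
    gh <- gwas[match(map$variant_gwas, gwas$variant), , drop = FALSE]
    if (nrow(gh)) {
        gh$beta <- ifelse(map$flip, -gh$beta, gh$beta)
        gh$variant <- map$variant_eqtl
    }
    list(map = map, gwas_harmonized = gh,
         n_unmatched = c(eqtl = nrow(eqtl) - nrow(map),
                         gwas = nrow(gwas) - nrow(map)))
}

#' Read GWAS summary statistics from TSV
#'
#' Expects columns variant, beta, se, p and either (chrom, pos, ref,
#' alt) for SNVs or (chrom, start, end, motif) for TRs; a `type` column
#' is inferred when absent (rows with a motif are TRs).
#'
#' @param path TSV path with a header.
#' @return data.frame of summary statistics.
#' @export
readGWAS <- function(path) {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("variant", "beta", "se", "p")
    if (!all(need %in% names(d)))
        stop("GWAS TSV must have columns: ", paste(need, collapse = ", "))
    if (is.null(d$type))
        d$type <- ifelse(!is.null(d$motif) & !is.na(d$motif), "TR", "SNV")
    d
}
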