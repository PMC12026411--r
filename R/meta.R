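#' DerSimonian-Laird random-effects meta-analysis
#'
#' Pools per-study effect estimates with the moment-based between-study
#' variance estimator: fixed-effect weights \eqn{w_i = 1/se_i^2},
#' Cochran's \eqn{Q = \sum w_i (\beta_i - \beta_{FE})^2},
#' \eqn{\tau^2 = \max(0, (Q - (k-1)) / (\sum w_i - \sum w_i^2/\sum w_i))},
#' random-effects weights \eqn{w^*_i = 1/(se_i^2 + \tau^2)}, pooled
#' estimate \eqn{\sum w^* \beta / \sum w^*}, pooled standard error
#' \eqn{(\sum w^*)^{-1/2}}, and a two-sided normal p-value on
#' \eqn{z = \beta_{pooled}/se_{pooled}}.
#'
#' @param beta numeric vector of per-study effect sizes (k >= 1).
#' @param se matching standard errors, all positive.
#' @return list: beta_pooled, se_pooled, p, tau2, Q, k.
#' @examples
#' dlMeta(c(0.5, 0.1), c(0.1, 0.1))  # Q=8, tau2=0.07, beta=0.3, se=0.2
#' @export
dlMeta <- function(beta, se) {
    k <- length(beta)
    if (k == 0L) stop("at least one study required")
    stopifnot(length(se) == k, all(se > 0))
    w <- 1 / se^2
    bfe <- sum(w * beta) / sum(w)
    Q <- sum(w * (beta - bfe)^2)
    tau2 <- if (k == 1L) 0 else
        max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
    ws <- 1 / (se^2 + tau2)
    bp <- sum(ws * beta) / sum(ws)
    sep <- 1 / sqrt(sum(ws))
    z <- bp / sep
    list(beta_pooled = bp, se_pooled = sep,
         p = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
         tau2 = tau2, Q = Q, k = k)
}

# vectorized two-study DL meta over aligned stat vectors (pipeline speed)
dlMeta2Vec <- function(beta1, se1, beta2, se2) {
    w1 <- 1 / se1^2; w2 <- 1 / se2^2
    sw <- w1 + w2
    bfe <- (w1 * beta1 + w2 * beta2) / sw
    Q <- w1 * (beta1 - bfe)^2 + w2 * (beta2 - bfe)^2
    tau2 <- pmax(0, (Q - 1) / (sw - (w1^2 + w2^2) / sw))
    ws1 <- 1 / (se1^2 + tau2); ws2 <- 1 / (se2^2 + tau2)
    bp <- (ws1 * beta1 + ws2 * beta2) / (ws1 + ws2)
    sep <- 1 / sqrt(ws1 + ws2)
    data.frame(beta_pooled = bp, se_pooled = sep,
               p = 2 * stats::pnorm(abs(bp / sep), lower.tail = FALSE),
               tau2 = tau2, Q = Q, k = 2L)
}

#' Meta-analyse per-cohort association tables
#'
#' Joins two or more cohort-level association tables on
#' (variant, gene, cell_type) and pools each test with [dlMeta]. Tests
#' present in only one cohort are passed through with k = 1.
#'
#' @param statsList list of association data.frames (columns variant,
#'   gene, cell_type, beta, se, p, n).
#' @return data.frame with pooled beta, se, p plus tau2, Q, k.
#' @export
metaAnalyse <- function(statsList) {
    stopifnot(length(statsList) >= 1L)
    all_ <- do.call(rbind, lapply(statsList, function(d)
        d[, c("variant", "gene", "cell_type", "beta", "se")]))
    key <- paste(all_$variant, all_$gene, all_$cell_type, sep = "\r")
    idx <- split(seq_len(nrow(all_)), key)
    rows <- lapply(idx, function(ii) {
        m <- dlMeta(all_$beta[ii], all_$se[ii])
        data.frame(variant = all_$variant[ii[1L]], gene = all_$gene[ii[1L]],
                   cell_type = all_$cell_type[ii[1L]],
                   beta = m$beta_pooled, se = m$se_pooled, p = m$p,
                   tau2 = m$tau2, Q = m$Q, k = m$k)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out[order(out$cell_type, out$gene, out$variant), , drop = FALSE]
}

#' Permutation calibration of the association + meta pipeline
#'
#' Permutes the sample identifiers of the genotypes (expression and
#' covariates fixed) within each cohort, re-runs the per-cohort
#' association and the two-cohort meta-analysis, and reports the
#' empirical type-I error at nominal levels together with a
#' Kolmogorov-Smirnov test of p-value uniformity.
#'
#' @param dosageByCohort list (per cohort) of samples x variants summed
#'   dosage matrices.
#' @param pbByCohort list (per cohort) of [PseudobulkMatrix] objects for
#'   one cell type, sample-aligned with the dosage matrices.
#' @param windows named list mapping each gene to the variant ids in its
#'   cis window.
#' @param seed integer seed for the permutation.
#' @param alphas nominal levels (default 0.01, 0.05, 0.1).
#' @return list: `p` (meta p-values), `rates` (data.frame alpha /
#'   empirical rate / binomial se), `ks_p`.
#' @export
permutationCalibration <- function(dosageByCohort, pbByCohort, windows,
                                   seed, alphas = c(0.01, 0.05, 0.1)) {
    set.seed(seed)
    perm <- lapply(dosageByCohort, function(d)
        d[sample(nrow(d)), , drop = FALSE])
    stats <- lapply(seq_along(perm), function(i) {
        pb <- pbByCohort[[i]]
        do.call(rbind, lapply(names(windows), function(g)
            mapGene(g, windows[[g]], perm[[i]], pb)))
    })
    meta <- metaAnalyse(stats)
    p <- meta$p
    m <- length(p)
    rates <- data.frame(
        alpha = alphas,
        rate = vapply(alphas, function(a) mean(p < a), numeric(1)),
        binom_se = sqrt(alphas * (1 - alphas) / m))
    ks <- stats::ks.test(p, "punif")$p.value
    list(p = p, rates = rates, ks_p = ks, n_tests = m)
}

#' Pairwise cell-type specificity of a significant sc-eTR
#'
#' For each eligible comparison cell type (gene expressed in at least 1%
#' of its cells), a two-study DerSimonian-Laird meta-analysis pools the
#' origin-cell-type statistics with the comparison statistics. The
#' sc-eTR is *shared* with a cell type if the meta p-value is lower than
#' the origin p-value, and *cell-type-specific* iff the meta p-value is
#' higher than the origin p-value for every eligible comparison. Exact
#' ties count as neither.
#'
#' @param origin one-row data.frame (beta, se, p) in the origin cell
#'   type.
#' @param others data.frame of the same sc-eTR's statistics in other
#'   cell types (columns cell_type, beta, se, expressed_fraction).
#' @param minExpressedFraction eligibility filter (default 0.01).
#' @return list: `comparisons` (per-cell-type meta p and shared flag),
#'   `n_shared`, `specific` (logical), `defined` (FALSE when no eligible
#'   comparison exists).
#' @export
classifySpecificity <- function(origin, others,
                                minExpressedFraction = 0.01) {
    stopifnot(nrow(origin) == 1L)
    if (!is.null(others$expressed_fraction))
        others <- others[others$expressed_fraction >= minExpressedFraction,
                         , drop = FALSE]
    if (nrow(others) == 0L)
        return(list(comparisons = data.frame(), n_shared = 0L,
                    specific = FALSE, defined = FALSE))
    mm <- dlMeta2Vec(rep(origin$beta, nrow(others)),
                     rep(origin$se, nrow(others)),
                     others$beta, others$se)
    comparisons <- data.frame(cell_type = others$cell_type,
                              p_meta = mm$p, p_origin = origin$p,
                              shared = mm$p < origin$p)
    list(comparisons = comparisons,
         n_shared = sum(comparisons$shared),
         specific = all(mm$p > origin$p),
         defined = TRUE)
}

#' Sign-discordant significant pairs
#'
#' Convenience report of sc-eTRs whose effect signs differ between two
#' cell types with both associations nominally significant; flags
#' opposite-direction regulation for follow-up.
#'
#' @param stats data.frame of per-cell-type statistics for one variant x
#'   gene (columns cell_type, beta, p).
#' @param alpha per-cell-type significance cutoff (default 0.05).
#' @return data.frame of discordant cell-type pairs (possibly 0 rows).
#' @export
signDiscordantPairs <- function(stats, alpha = 0.05) {
    sig <- stats[stats$p < alpha, , drop = FALSE]
    out <- data.frame(cell_type_a = character(), cell_type_b = character(),
                      beta_a = numeric(), beta_b = numeric())
    if (nrow(sig) < 2L) return(out)
    cmb <- utils::combn(nrow(sig), 2)
    for (i in seq_len(ncol(cmb))) {
        a <- cmb[1, i]; b <- cmb[2, i]
        if (sign(sig$beta[a]) * sign(sig$beta[b]) < 0)
            out <- rbind(out, data.frame(
                cell_type_a = sig$cell_type[a],
                cell_type_b = sig$cell_type[b],
                beta_a = sig$beta[a], beta_b = sig$beta[b]))
    }
    out
}
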