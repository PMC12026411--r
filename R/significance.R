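#' ACAT Cauchy combination of p-values
#'
#' Combines variant-level p-values into a gene-level p-value via the
#' Cauchy combination: \eqn{T = \sum_i w_i \tan((0.5 - p_i)\pi)/\sum w_i}
#' and combined \eqn{p = P(\mathrm{Cauchy} > T) = 0.5 - \arctan(T)/\pi}.
#' For p below 1e-15 the summand uses the stabilized small-p form
#' \eqn{1/(p\pi)}; the output tail is evaluated with the exact Cauchy
#' survival function so extreme statistics do not underflow.
#'
#' @param p p-values in (0,1); values outside are clipped to
#'   \[1e-300, 1-1e-16\] with a warning.
#' @param weights nonnegative weights, not all zero (default equal).
#' @return combined p-value.
#' @examples
#' acatCombine(c(0.01, 0.5, 0.9))  # ~0.033
#' @export
acatCombine <- function(p, weights = NULL) {
    stopifnot(length(p) >= 1L)
    if (any(p <= 0 | p >= 1)) {
        warning("p-values outside (0,1) clipped")
        p <- pmin(pmax(p, 1e-300), 1 - 1e-16)
    }
    if (is.null(weights)) weights <- rep(1, length(p))
    stopifnot(all(weights >= 0), any(weights > 0),
              length(weights) == length(p))
    w <- weights / sum(weights)
    small <- p < 1e-15
    term <- numeric(length(p))
    term[small] <- 1 / (p[small] * pi)
    # tan((0.5 - p) * pi) = cot(pi p), evaluated with tanpi so no
    # precision is lost for small or near-1 p
    mid <- !small & p != 0.5
    term[mid] <- 1 / tanpi(p[mid])
    term[!small & p == 0.5] <- 0
    T_ <- sum(w * term)
    stats::pcauchy(T_, lower.tail = FALSE)
}

#' Storey q-values
#'
#' Estimates the null proportion \eqn{\hat\pi_0 = \min(1,
#' \#\{p > \lambda\} / (m(1-\lambda)))} at a single fixed
#' \eqn{\lambda} (default 0.5) and computes
#' \eqn{q_i = \min_{j: p_{(j)} \ge p_{(i)}} \hat\pi_0\, m\, p_{(j)}/j}.
#' With \eqn{\hat\pi_0 = 1} this reproduces Benjamini-Hochberg adjusted
#' p-values exactly.
#'
#' @param p p-values in (0, 1\].
#' @param lambda tuning parameter for the null-proportion estimate.
#' @param pi0 optional override of the estimated null proportion.
#' @return list: `q` (q-values, input order), `pi0`.
#' @export
storeyQvalues <- function(p, lambda = 0.5, pi0 = NULL) {
    m <- length(p)
    if (m == 0L) stop("empty p-value vector")
    stopifnot(all(p > 0 & p <= 1))
    if (is.null(pi0))
        pi0 <- min(1, sum(p > lambda) / (m * (1 - lambda)))
    o <- order(p, decreasing = TRUE)
    q_sorted <- cummin(pi0 * m * p[o] / rank(p, ties.method = "max")[o])
    q <- numeric(m)
    q[o] <- pmin(1, q_sorted)
    list(q = q, pi0 = pi0)
}

#' Top eTR and lead variant per gene and cell type
#'
#' The top eTR is the TR with the lowest nominal p-value for the gene in
#' the cell type; the lead variant is the lowest-p variant among TRs and
#' SNVs jointly. Exact p ties break toward the smaller coordinate, then
#' the lexicographically smaller id, so selection is deterministic.
#'
#' @param stats data.frame for one gene x cell type: columns variant,
#'   type ("TR"/"SNV"), p, pos (coordinate).
#' @return list: `top_eTR` (id or NA), `lead_variant`,
#'   `lead_is_tr`, `p_top_eTR`, `p_lead`.
#' @export
selectTopAndLead <- function(stats) {
    stopifnot(nrow(stats) >= 1L)
    pick <- function(d) {
        o <- order(d$p, d$pos, d$variant)
        d[o[1L], , drop = FALSE]
    }
    trs <- stats[stats$type == "TR", , drop = FALSE]
    top <- if (nrow(trs)) pick(trs) else NULL
    lead <- pick(stats)
    list(top_eTR = if (is.null(top)) NA_character_ else top$variant,
         p_top_eTR = if (is.null(top)) NA_real_ else top$p,
         lead_variant = lead$variant,
         p_lead = lead$p,
         lead_is_tr = lead$type == "TR")
}

#' Gene-level significance table
#'
#' Combines the TR variant-level p-values of each gene with ACAT
#' ([acatCombine]), applies Storey q-values across genes within each cell
#' type, and records the top eTR and the lead variant of every window.
#'
#' @param metaStats meta-analysis (or single-cohort) association
#'   data.frame: variant, gene, cell_type, p, plus `type` and `pos`
#'   columns (see [selectTopAndLead]); rows lacking `type` are treated
#'   as TRs.
#' @param fdr significance threshold on the q-value (default 0.05).
#' @return data.frame per gene x cell type: p_gene, q, top_eTR,
#'   lead_variant, lead_is_tr, significant.
#' @export
geneLevelSignificance <- function(metaStats, fdr = 0.05) {
    if (is.null(metaStats$type)) metaStats$type <- "TR"
    if (is.null(metaStats$pos)) metaStats$pos <- 0
    key <- paste(metaStats$gene, metaStats$cell_type, sep = "\r")
    idx <- split(seq_len(nrow(metaStats)), key)
    rows <- lapply(idx, function(ii) {
        d <- metaStats[ii, , drop = FALSE]
        trp <- d$p[d$type == "TR"]
        sel <- selectTopAndLead(d)
        data.frame(gene = d$gene[1L], cell_type = d$cell_type[1L],
                   p_gene = if (length(trp)) acatCombine(trp) else NA_real_,
                   top_eTR = sel$top_eTR, p_top_eTR = sel$p_top_eTR,
                   lead_variant = sel$lead_variant, p_lead = sel$p_lead,
                   lead_is_tr = sel$lead_is_tr)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out$q <- NA_real_
    for (ctp in unique(out$cell_type)) {
        ii <- which(out$cell_type == ctp & !is.na(out$p_gene))
        if (length(ii))
            out$q[ii] <- storeyQvalues(out$p_gene[ii])$q
    }
    out$significant <- !is.na(out$q) & out$q < fdr
    out[order(out$cell_type, out$gene), , drop = FALSE]
}
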