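#' Inverse normal (quantile) transform
#'
#' Maps values to standard-normal quantiles at rank/(n+1) (Weibull
#' plotting position; Blom's offset available), with ties given the
#' average rank and missing values preserved.
#'
#' @param x numeric vector with at least 3 non-missing, not all equal.
#' @param offset `"weibull"` (rank/(n+1), default) or `"blom"`
#'   ((rank-3/8)/(n+1/4)).
#' @return transformed vector, mean ~ 0 and sd ~ 1.
#' @examples
#' inverseNormalTransform(c(3, 1, 2))  # 0.674, -0.674, 0
#' @export
inverseNormalTransform <- function(x, offset = c("weibull", "blom")) {
    offset <- match.arg(offset)
    ok <- !is.na(x)
    n <- sum(ok)
    if (n < 3L) stop("need at least 3 non-missing values")
    if (length(unique(x[ok])) == 1L)
        stop("all values equal: ranks undefined")
    r <- rank(x[ok], ties.method = "average")
    u <- if (offset == "weibull") r / (n + 1) else (r - 3 / 8) / (n + 1 / 4)
    out <- rep(NA_real_, length(x))
    out[ok] <- stats::qnorm(u)
    out
}

# OLS of y on [1, W, g]; returns stats for the g coefficient.
# QR-based; classical homoskedastic standard error, two-sided t p-value.
olsStat <- function(y, g, W = NULL) {
    X <- cbind(`(Intercept)` = 1, W, g = g)
    n <- length(y)
    p <- ncol(X)
    if (n < p + 1L) stop("too few samples for the model")
    qr_ <- qr(X)
    if (qr_$rank < p) stop("design matrix is rank deficient (collinearity)")
    coefs <- qr.coef(qr_, y)
    res <- y - drop(X %*% coefs)
    df <- n - p
    sigma2 <- sum(res^2) / df
    R <- qr.R(qr_)
    XtXinv <- chol2inv(R)
    se <- sqrt(sigma2 * XtXinv[p, p])
    beta <- coefs[p]
    tval <- beta / se
    pval <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
    list(beta = unname(beta), se = se, p = pval, n = n, df = df,
         sigma2 = sigma2)
}

#' Per-variant association of dosage with normalized expression
#'
#' Fits the linear model `y = W alpha + g beta + epsilon` by ordinary
#' least squares, where `y` is (inverse-normal transformed) expression,
#' `g` the summed TR repeat dosage (or SNV dosage) and `W` covariates.
#' Samples with missing dosage or expression are dropped (per-variant
#' complete case).
#'
#' @param y numeric phenotype vector (already transformed).
#' @param g numeric dosage vector aligned with `y`.
#' @param W optional covariate matrix (samples x covariates), no
#'   intercept column.
#' @return one-row data.frame: beta, se, p, n.
#' @export
fitAssociation <- function(y, g, W = NULL) {
    if (!is.null(W)) W <- as.matrix(W)
    keep <- !is.na(y) & !is.na(g)
    if (!is.null(W)) keep <- keep & stats::complete.cases(W)
    y <- y[keep]; g <- g[keep]
    if (!is.null(W)) W <- W[keep, , drop = FALSE]
    if (stats::var(g) == 0)
        stop("degenerate variant: dosage constant after missingness")
    st <- olsStat(y, g, W)
    data.frame(beta = st$beta, se = st$se, p = st$p, n = st$n)
}

#' Map all variants in a gene's cis window in one cell type/cohort
#'
#' Skips the gene if its expressed-cell fraction in this cell type is
#' below `minExpressedFraction`; otherwise tests every variant in the
#' window and returns one association row per testable variant.
#' Degenerate variants (constant dosage) are skipped and counted.
#'
#' @param gene gene identifier (must be a row of `pb`).
#' @param variantIds variant ids in the gene's window (columns of
#'   `dosage`).
#' @param dosage samples x variants summed-dosage matrix.
#' @param pb a [PseudobulkMatrix].
#' @param minExpressedFraction expression filter (default 0.01).
#' @return data.frame of association statistics (possibly 0 rows), with
#'   attribute `n_skipped` counting degenerate variants.
#' @export
mapGene <- function(gene, variantIds, dosage, pb,
                    minExpressedFraction = 0.01) {
    stopifnot(is(pb, "PseudobulkMatrix"))
    ef <- expressedFraction(pb)[gene]
    empty <- data.frame(variant = character(), gene = character(),
                        cell_type = character(), cohort = character(),
                        beta = numeric(), se = numeric(), p = numeric(),
                        n = integer())
    if (is.na(ef) || ef < minExpressedFraction) {
        attr(empty, "skipped_gene") <- TRUE
        return(empty)
    }
    y <- exprMatrix(pb)[gene, ]
    W <- covariateMatrix(pb)
    n_skipped <- 0L
    rows <- lapply(variantIds, function(v) {
        st <- tryCatch(fitAssociation(y, dosage[, v], W),
                       error = function(e) NULL)
        if (is.null(st)) {
            n_skipped <<- n_skipped + 1L
            return(NULL)
        }
        cbind(data.frame(variant = v, gene = gene,
                         cell_type = cellType(pb), cohort = cohort(pb)),
              st)
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) out <- empty
    attr(out, "n_skipped") <- n_skipped
    out
}

#' TR-methylation association at nearby CpG sites
#'
#' CpG sites whose methylation standard deviation is at or below `sdMin`
#' are excluded; retained sites are inverse-normal transformed and tested
#' against the summed repeat dosage of every TR within `window` bases,
#' with Bonferroni correction over the TR-CpG pairs tested.
#'
#' @param methylation samples x CpG-sites matrix of methylation
#'   probabilities in \[0,1\].
#' @param cpgPos numeric vector of CpG site positions (same order as
#'   columns).
#' @param trDosage samples x TR summed-dosage matrix.
#' @param trPos numeric vector of TR positions (locus midpoints).
#' @param W optional covariate matrix.
#' @param window pairing distance in bases (default 5000).
#' @param sdMin minimum methylation standard deviation (default 0.02).
#' @param alpha Bonferroni-adjusted significance level (default 0.05).
#' @return data.frame per tested TR-CpG pair: tr, cpg, beta, se, p,
#'   p_bonferroni, significant.
#' @export
mapMethylation <- function(methylation, cpgPos, trDosage, trPos, W = NULL,
                           window = 5000, sdMin = 0.02, alpha = 0.05) {
    methylation <- as.matrix(methylation)
    stopifnot(all(methylation >= 0 & methylation <= 1, na.rm = TRUE))
    sds <- apply(methylation, 2, stats::sd, na.rm = TRUE)
    keep <- which(sds > sdMin)
    rows <- list()
    for (j in keep) {
        y <- inverseNormalTransform(methylation[, j])
        near <- which(abs(trPos - cpgPos[j]) <= window)
        for (v in near) {
            st <- tryCatch(fitAssociation(y, trDosage[, v], W),
                           error = function(e) NULL)
            if (is.null(st)) next
            rows[[length(rows) + 1L]] <- cbind(
                data.frame(tr = colnames(trDosage)[v],
                           cpg = colnames(methylation)[j]), st)
        }
    }
    if (!length(rows))
        return(data.frame(tr = character(), cpg = character(),
                          beta = numeric(), se = numeric(), p = numeric(),
                          n = integer(), p_bonferroni = numeric(),
                          significant = logical()))
    out <- do.call(rbind, rows)
    out$p_bonferroni <- pmin(1, out$p * nrow(out))
    out$significant <- out$p_bonferroni < alpha
    out
}
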