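#' Expected heterozygosity from allele frequencies
#'
#' The probability that two randomly drawn alleles differ,
#' \eqn{H = 1 - \sum_k p_k^2}. At a locus with non-major allele frequency
#' 0.5% this equals 0.00995, the value used as the polymorphism filter.
#'
#' @param freqs numeric vector of allele frequencies, nonnegative and
#'   summing to 1 (tolerance 1e-9).
#' @return expected heterozygosity in \[0, 1).
#' @examples
#' expectedHeterozygosity(c(0.995, 0.005))  # 0.00995
#' @export
expectedHeterozygosity <- function(freqs) {
    if (any(freqs < 0)) stop("allele frequencies must be nonnegative")
    if (abs(sum(freqs) - 1) > 1e-9)
        stop("allele frequencies must sum to 1")
    1 - sum(freqs^2)
}

# per-locus modal allele; ties broken toward the smaller allele
modeAllele <- function(a1, a2) {
    av <- c(a1, a2)
    av <- av[!is.na(av)]
    if (!length(av)) return(NA_real_)
    tab <- table(av)
    as.numeric(names(tab)[which.max(tab)])  # which.max: first = smallest
}

#' Mask genotype calls far from the locus mode allele
#'
#' Alleles more than `below` repeats less or `above` repeats greater than
#' the locus modal allele are treated as genotyping artifacts; the whole
#' diploid call is set missing (a summed dosage with one voided allele is
#' undefined).
#'
#' @param gt a TR [GenotypeTable].
#' @param below,above window bounds relative to the mode (defaults 30
#'   below, 20 above).
#' @return list with `genotypes` (masked table) and `n_masked` per locus.
#' @export
maskOutlierCalls <- function(gt, below = 30, above = 20) {
    stopifnot(is(gt, "GenotypeTable"))
    a1 <- gt@allele1; a2 <- gt@allele2
    n_masked <- integer(ncol(a1))
    for (j in seq_len(ncol(a1))) {
        m <- modeAllele(a1[, j], a2[, j])
        if (is.na(m)) next
        bad <- (!is.na(a1[, j]) &
                (a1[, j] < m - below | a1[, j] > m + above)) |
               (!is.na(a2[, j]) &
                (a2[, j] < m - below | a2[, j] > m + above))
        n_masked[j] <- sum(bad)
        a1[bad, j] <- NA
        a2[bad, j] <- NA
    }
    out <- gt
    out@allele1 <- a1; out@allele2 <- a2
    list(genotypes = out, n_masked = n_masked)
}

#' Per-locus genotype QC report
#'
#' Computes, for every locus: call rate, allele frequencies, expected
#' heterozygosity (1 - sum p^2), observed heterozygote fraction, the
#' Hardy-Weinberg exact binomial p-value (observed heterozygote count vs
#' Binomial(n_called, H_expected), two-sided), and the mode allele.
#' Multiallelic loci collapse to heterozygote-vs-homozygote for the HWE
#' test.
#'
#' @param gt a TR [GenotypeTable].
#' @return data.frame, one row per locus.
#' @export
locusQC <- function(gt) {
    stopifnot(is(gt, "GenotypeTable"))
    a1 <- gt@allele1; a2 <- gt@allele2
    n <- nrow(a1)
    res <- lapply(seq_len(ncol(a1)), function(j) {
        called <- !is.na(a1[, j])
        nc <- sum(called)
        if (nc == 0L)
            return(data.frame(locus = colnames(a1)[j], call_rate = 0,
                              het_expected = NA_real_, het_observed = NA_real_,
                              hwe_p = NA_real_, mode_allele = NA_real_,
                              n_alleles = 0L))
        av <- c(a1[called, j], a2[called, j])
        freqs <- as.numeric(table(av)) / length(av)
        he <- 1 - sum(freqs^2)
        nhet <- sum(a1[called, j] != a2[called, j])
        hwe <- if (he <= 0) as.numeric(nhet == 0)
               else stats::binom.test(nhet, nc, he)$p.value
        data.frame(locus = colnames(a1)[j], call_rate = nc / n,
                   het_expected = he, het_observed = nhet / nc,
                   hwe_p = hwe, mode_allele = modeAllele(a1[, j], a2[, j]),
                   n_alleles = length(freqs))
    })
    do.call(rbind, res)
}

#' Locus-level TR filters
#'
#' Drops loci failing any of: call rate below `minCallRate`, expected
#' heterozygosity below `minHet` (0.00995 corresponds to a non-major
#' allele frequency of 0.5%), or Hardy-Weinberg exact binomial p-value
#' below `hweP`. Boundaries are inclusive on the passing side. Masking
#' ([maskOutlierCalls]) should be applied first.
#'
#' @param gt a TR [GenotypeTable].
#' @param minCallRate minimum call rate (default 0.90).
#' @param minHet minimum expected heterozygosity (default 0.00995).
#' @param hweP HWE p-value threshold (default 1e-6); loci with p below
#'   this are dropped.
#' @return list with `genotypes` (filtered) and `report` (per-locus QC
#'   with a `pass` column).
#' @export
filterTRLoci <- function(gt, minCallRate = 0.90, minHet = 0.00995,
                         hweP = 1e-6) {
    stopifnot(is(gt, "GenotypeTable"))
    if (ncol(gt@allele1) == 0L) stop("empty genotype table")
    rep_ <- locusQC(gt)
    pass <- !is.na(rep_$het_expected) &
        rep_$call_rate >= minCallRate &
        rep_$het_expected >= minHet &
        rep_$hwe_p >= hweP
    rep_$pass <- pass
    list(genotypes = gt[, which(pass)], report = rep_)
}

#' Summed dosage matrix
#'
#' For TRs, the summed repeat length across both alleles; for SNVs, the
#' non-reference allele count. Missing if either allele is missing.
#'
#' @param gt a [GenotypeTable].
#' @return numeric matrix, samples x variants.
#' @export
summedDosage <- function(gt) {
    stopifnot(is(gt, "GenotypeTable"))
    gt@allele1 + gt@allele2
}

#' Minor allele frequency filter for SNVs
#'
#' Retains biallelic SNVs with minor allele frequency at or above
#' `minMAF`; monomorphic variants are dropped.
#'
#' @param gt an SNV [GenotypeTable] (biallelic; multiallelics split at
#'   ingest).
#' @param minMAF threshold (default 0.01).
#' @return filtered [GenotypeTable].
#' @export
filterSNVs <- function(gt, minMAF = 0.01) {
    stopifnot(is(gt, "GenotypeTable"), gt@variantType == "SNV")
    dos <- summedDosage(gt)
    af <- colMeans(dos, na.rm = TRUE) / 2
    maf <- pmin(af, 1 - af)
    maf[is.nan(maf)] <- 0
    gt[, which(maf >= minMAF)]
}
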