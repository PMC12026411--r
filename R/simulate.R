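#' Simulation configuration for a synthetic sc-eTR study
#'
#' Defines the generative conditions for a two-cohort, multi-cell-type
#' cohort with tandem repeat genotypes under a stepwise mutation model,
#' tag SNVs in tunable LD with each TR, pseudobulk expression with
#' planted eTR effects, covariates, and CpG methylation linked to repeat
#' length. Defaults mirror a population-scale paired WGS + scRNA-seq
#' immune study: two cohorts of 950 and 975 individuals, 28 cell types,
#' and moderate TR-SNV LD.
#'
#' @param n_samples_per_cohort integer vector, samples per cohort
#'   (default c(950, 975)).
#' @param n_cell_types number of cell types (default 28).
#' @param n_tr_loci,n_snv_loci numbers of TR loci and SNVs (each TR gets
#'   one tag SNV; extra SNVs are independent).
#' @param mode_alleles modal repeat count per TR locus (default: sampled
#'   in 8..25).
#' @param motifs repeat motif per locus (default: sampled short motifs).
#' @param step_prob per-meiosis-equivalent probability parameter of the
#'   stepwise model: the number of +/-1 steps per allele is
#'   Geometric(1 - step_prob) (default 0.3, giving a tight mode-centred
#'   allele distribution).
#' @param missing_rate per-call missingness (default 0.02).
#' @param ld_target desired r-squared between each TR's summed dosage
#'   and its tag SNV dosage (default 0.45, moderate TR-SNV LD).
#' @param effect_table data.frame of planted effects with columns locus
#'   (index or id), gene (id), cell_type (label or index), beta; NULL
#'   for a null cohort.
#' @param noise_sd residual expression standard deviation (default 1).
#' @param expressed_fraction fraction of cells expressing each gene in
#'   each cell type (scalar or genes x cell-types matrix; default 0.2).
#' @param n_geno_pcs,n_expr_pcs numbers of genotype-PC and
#'   expression-PC surrogate covariates (defaults 12 and 6).
#' @param batch_shift cohort-specific intercept shift emulating batch
#'   effects (default 0.2).
#' @param locus_spacing bases between successive TR loci on the
#'   artificial chromosome (default 250000, so cis windows are
#'   disjoint).
#' @param window cis window used to place genes (default 1e5).
#' @param n_cpg number of CpG methylation sites (default 0).
#' @param seed integer seed; a fixed seed makes all generator output
#'   reproducible.
#' @return a validated `SimulationConfig` list.
#' @export
SimulationConfig <- function(n_samples_per_cohort = c(950, 975),
                             n_cell_types = 28,
                             n_tr_loci = 10, n_snv_loci = 10,
                             mode_alleles = NULL, motifs = NULL,
                             step_prob = 0.3, missing_rate = 0.02,
                             ld_target = 0.45, effect_table = NULL,
                             noise_sd = 1, expressed_fraction = 0.2,
                             n_geno_pcs = 12, n_expr_pcs = 6,
                             batch_shift = 0.2,
                             locus_spacing = 250000, window = 1e5,
                             n_cpg = 0, seed = 1L) {
    stopifnot(all(n_samples_per_cohort >= 1), n_cell_types >= 1,
              n_tr_loci >= 1, n_snv_loci >= 0,
              step_prob >= 0, step_prob < 1,
              missing_rate >= 0, missing_rate <= 1,
              ld_target >= 0, ld_target <= 1, noise_sd >= 0)
    seed <- as.integer(seed)
    rng <- local({set.seed(seed); list(
        modes = if (is.null(mode_alleles))
            sample(8:25, n_tr_loci, replace = TRUE) else mode_alleles,
        mot = if (is.null(motifs))
            sample(c("A", "AC", "AT", "AG", "AAT", "CAG", "AGAT"),
                   n_tr_loci, replace = TRUE) else motifs)})
    mode_alleles <- rep_len(rng$modes, n_tr_loci)
    motifs <- rep_len(rng$mot, n_tr_loci)
    if (any(mode_alleles <= 0)) stop("mode alleles must be positive")
    cfg <- list(n_samples_per_cohort = as.integer(n_samples_per_cohort),
                n_cohorts = length(n_samples_per_cohort),
                n_cell_types = as.integer(n_cell_types),
                n_tr_loci = as.integer(n_tr_loci),
                n_snv_loci = as.integer(n_snv_loci),
                mode_alleles = mode_alleles, motifs = motifs,
                step_prob = step_prob, missing_rate = missing_rate,
                ld_target = ld_target, effect_table = effect_table,
                noise_sd = noise_sd,
                expressed_fraction = expressed_fraction,
                n_geno_pcs = as.integer(n_geno_pcs),
                n_expr_pcs = as.integer(n_expr_pcs),
                batch_shift = batch_shift,
                locus_spacing = locus_spacing, window = window,
                n_cpg = as.integer(n_cpg), seed = seed)
    class(cfg) <- "SimulationConfig"
    cfg
}

#' @export
print.SimulationConfig <- function(x, ...) {
    cat(sprintf(paste0("SimulationConfig: %s samples in %d cohorts, ",
                       "%d cell types, %d TR loci, %d SNVs, seed %d\n"),
        paste(x$n_samples_per_cohort, collapse = "+"), x$n_cohorts,
        x$n_cell_types, x$n_tr_loci, x$n_snv_loci, x$seed))
    invisible(x)
}

#' TR catalog of the synthetic genome
#'
#' Loci are placed on one artificial chromosome at the configured
#' spacing, each with its motif and a reference repeat count equal to
#' the modal allele.
#'
#' @param config a [SimulationConfig].
#' @return a [TRCatalog] with `locus_id`s `TR1..TRn`.
#' @export
simulatedCatalog <- function(config) {
    starts <- seq_len(config$n_tr_loci) * config$locus_spacing
    widths <- nchar(config$motifs) * config$mode_alleles
    TRCatalog("chrS", starts, starts + widths - 1L,
              motif = config$motifs, ref_repeats = config$mode_alleles,
              locus_id = paste0("TR", seq_len(config$n_tr_loci)))
}

#' Gene placements of the synthetic genome
#'
#' One gene per TR locus, with TSS 20 kb downstream of the locus, so
#' every planted (locus, gene) pair lies inside the cis window.
#'
#' @param config a [SimulationConfig].
#' @return data.frame: gene, chrom, tss, tes.
#' @export
simulatedGenes <- function(config) {
    starts <- seq_len(config$n_tr_loci) * config$locus_spacing
    data.frame(gene = paste0("G", seq_len(config$n_tr_loci)),
               chrom = "chrS", tss = starts + 20000,
               tes = starts + 21000)
}

# draw one cohort's diploid repeat alleles under the stepwise model:
# number of +/-1 unit steps per allele ~ Geometric(1 - step_prob),
# each step up or down with equal probability; truncated at 1 repeat
stepwiseAlleles <- function(n, mode, step_prob) {
    if (step_prob == 0) return(rep(mode, n))
    k <- stats::rgeom(n, 1 - step_prob)
    steps <- vapply(k, function(ki)
        if (ki == 0L) 0L else sum(sample(c(-1L, 1L), ki, replace = TRUE)),
        integer(1))
    pmax(1L, mode + steps)
}

#' Simulate diploid TR genotypes for one cohort
#'
#' Each allele is the locus modal allele plus a signed sum of
#' geometrically-many unit steps (see [SimulationConfig]), truncated at
#' one repeat; calls are set missing at the configured rate.
#'
#' @param config a [SimulationConfig].
#' @param cohortIndex which cohort to generate (default 1).
#' @return a TR [GenotypeTable] with samples `c<idx>_s<i>`.
#' @export
simulateTRGenotypes <- function(config, cohortIndex = 1L) {
    stopifnot(cohortIndex >= 1L, cohortIndex <= config$n_cohorts)
    if (any(config$mode_alleles <= 0))
        stop("mode alleles must be positive")
    set.seed(config$seed + 1000L * cohortIndex)
    n <- config$n_samples_per_cohort[cohortIndex]
    L <- config$n_tr_loci
    a1 <- matrix(NA_real_, n, L)
    a2 <- matrix(NA_real_, n, L)
    for (j in seq_len(L)) {
        a1[, j] <- stepwiseAlleles(n, config$mode_alleles[j],
                                   config$step_prob)
        a2[, j] <- stepwiseAlleles(n, config$mode_alleles[j],
                                   config$step_prob)
        if (config$missing_rate > 0) {
            miss <- stats::runif(n) < config$missing_rate
            a1[miss, j] <- NA; a2[miss, j] <- NA
        }
    }
    rownames(a1) <- rownames(a2) <- sprintf("c%d_s%d", cohortIndex,
                                            seq_len(n))
    GenotypeTable(a1, a2, simulatedCatalog(config), "TR")
}

# solve the haplotype flip probability so that corr(summed TR dosage,
# tag SNV dosage)^2 hits ld_target; analytic in the empirical moments
solveFlipProb <- function(a_hap, x_hap, ld_target) {
    q <- mean(x_hap)
    if (q == 0 || q == 1) return(0)
    ca <- stats::cov(a_hap, x_hap)
    va <- stats::var(a_hap)
    if (va == 0 || ca == 0) return(0)
    rTarget <- sqrt(ld_target)
    rOf <- function(f) {
        es <- f + (1 - 2 * f) * q
        (1 - 2 * f) * ca / sqrt(va * es * (1 - es))
    }
    if (abs(rOf(0)) <= rTarget) return(0)  # max achievable LD
    stats::uniroot(function(f) abs(rOf(f)) - rTarget,
                   c(0, 0.4999))$root
}

#' Simulate tag SNVs in tunable LD with each TR
#'
#' Each TR locus gets one biallelic tag SNV whose haplotype allele is
#' the indicator of the TR allele exceeding the locus mode, flipped with
#' a probability solved so the realized dosage r-squared matches
#' `ld_target`. Additional SNVs beyond the number of TR loci are
#' independent Binomial draws at a random allele frequency.
#'
#' @param config a [SimulationConfig].
#' @param trGt the cohort's TR [GenotypeTable].
#' @param cohortIndex cohort index (seeds the flips).
#' @return an SNV [GenotypeTable]; tag SNVs are named `SNV<j>_tagTR<j>`
#'   and placed 1 kb from their TR.
#' @export
simulateTagSNVs <- function(config, trGt, cohortIndex = 1L) {
    set.seed(config$seed + 1000L * cohortIndex + 500L)
    al <- alleles(trGt)
    n <- nrow(al$allele1)
    L <- config$n_tr_loci
    nExtra <- max(0L, config$n_snv_loci - L)
    s1 <- matrix(NA_real_, n, L + nExtra)
    s2 <- matrix(NA_real_, n, L + nExtra)
    modes <- config$mode_alleles
    for (j in seq_len(L)) {
        ok <- !is.na(al$allele1[, j])
        ah <- c(al$allele1[ok, j], al$allele2[ok, j])
        xh <- as.numeric(ah > modes[j])
        f <- solveFlipProb(ah, xh, config$ld_target)
        flip1 <- stats::runif(n) < f
        flip2 <- stats::runif(n) < f
        x1 <- as.numeric(al$allele1[, j] > modes[j])
        x2 <- as.numeric(al$allele2[, j] > modes[j])
        s1[, j] <- ifelse(flip1, 1 - x1, x1)
        s2[, j] <- ifelse(flip2, 1 - x2, x2)
        s1[!ok, j] <- x1[!ok]  # NA propagates
        s2[!ok, j] <- x2[!ok]
    }
    for (j in seq_len(nExtra)) {
        af <- stats::runif(1, 0.1, 0.5)
        s1[, L + j] <- stats::rbinom(n, 1, af)
        s2[, L + j] <- stats::rbinom(n, 1, af)
    }
    starts <- c(seq_len(L) * config$locus_spacing + 1000,
                if (nExtra) seq_len(nExtra) * 137 + 10)
    gr <- GRanges("chrS", IRanges(starts, starts))
    mcols(gr)$locus_id <- c(paste0("SNV", seq_len(L), "_tagTR",
                                   seq_len(L)),
                            if (nExtra) paste0("SNVx", seq_len(nExtra)))
    rownames(s1) <- rownames(s2) <- rownames(al$allele1)
    GenotypeTable(s1, s2, gr, "SNV")
}

#' Simulate pseudobulk expression with planted eTR effects
#'
#' Expression of each gene in each cell type is a covariate signal plus
#' the planted genetic effect on the centred summed repeat dosage plus a
#' cohort intercept shift and Gaussian noise:
#' `y = W alpha + g beta + shift + N(0, noise_sd)`.
#'
#' @param config a [SimulationConfig].
#' @param trGt the cohort's TR [GenotypeTable].
#' @param covariates samples x covariates data.frame (see
#'   [simulateCovariates]).
#' @param cohortIndex cohort index (sets the batch shift and the noise
#'   stream).
#' @return named list of [PseudobulkMatrix], one per cell type.
#' @export
simulateExpression <- function(config, trGt, covariates,
                               cohortIndex = 1L) {
    set.seed(config$seed + 1000L * cohortIndex + 7000L)
    genes <- simulatedGenes(config)
    dos <- summedDosage(trGt)
    n <- nrow(dos)
    W <- as.matrix(covariates)
    cellTypes <- paste0("CT", seq_len(config$n_cell_types))
    ef <- config$expressed_fraction
    efMat <- if (is.matrix(ef)) ef else
        matrix(ef, nrow(genes), config$n_cell_types)
    dimnames(efMat) <- list(genes$gene, cellTypes)
    et <- normalizeEffectTable(config, genes, cellTypes)
    if (nrow(et)) {
        untestable <- vapply(unique(et$gene), function(g)
            all(efMat[g, ] < 0.01), logical(1))
        if (any(untestable))
            warning("planted effect on gene(s) expressed in <1% of ",
                    "cells in every cell type: ",
                    paste(unique(et$gene)[untestable], collapse = ", "))
    }
    # per-gene covariate loadings, common across cell types and cohorts
    set.seed(config$seed + 31L)
    alpha <- matrix(stats::rnorm(nrow(genes) * ncol(W), 0, 0.2),
                    nrow(genes), ncol(W))
    set.seed(config$seed + 1000L * cohortIndex + 7000L)
    shift <- config$batch_shift * (cohortIndex - 1)
    out <- list()
    for (ct in seq_along(cellTypes)) {
        y <- matrix(0, nrow(genes), n,
                    dimnames = list(genes$gene, rownames(dos)))
        for (gi in seq_len(nrow(genes))) {
            mu <- drop(W %*% alpha[gi, ]) + shift
            rows <- et[et$gene == genes$gene[gi] &
                       et$cell_type == cellTypes[ct], , drop = FALSE]
            for (k in seq_len(nrow(rows))) {
                g <- dos[, rows$locus[k]]
                gc <- g - mean(g, na.rm = TRUE)
                gc[is.na(gc)] <- 0  # missing dosage: no genetic shift
                mu <- mu + rows$beta[k] * gc
            }
            y[gi, ] <- mu + stats::rnorm(n, 0, config$noise_sd)
        }
        out[[cellTypes[ct]]] <- PseudobulkMatrix(
            y, efMat[, ct], covariates,
            cellType = cellTypes[ct],
            cohort = paste0("cohort", cohortIndex))
    }
    out
}

# resolve locus/gene/cell-type references in an effect table to ids
normalizeEffectTable <- function(config, genes, cellTypes) {
    et <- config$effect_table
    if (is.null(et) || nrow(et) == 0L)
        return(data.frame(locus = character(), gene = character(),
                          cell_type = character(), beta = numeric()))
    et <- as.data.frame(et)
    if (is.numeric(et$locus)) et$locus <- paste0("TR", et$locus)
    if (is.numeric(et$gene)) et$gene <- paste0("G", et$gene)
    if (is.numeric(et$cell_type)) et$cell_type <- paste0("CT", et$cell_type)
    stopifnot(all(et$gene %in% genes$gene),
              all(et$cell_type %in% cellTypes))
    et
}

#' Simulate covariates
#'
#' Sex (0/1), age, and directly generated genotype-PC and expression-PC
#' surrogate covariates (standard normal); principal components are not
#' derived from the simulated genotypes, the surrogates stand in for
#' them.
#'
#' @param config a [SimulationConfig].
#' @param cohortIndex cohort index.
#' @return data.frame, samples x covariates.
#' @export
simulateCovariates <- function(config, cohortIndex = 1L) {
    set.seed(config$seed + 1000L * cohortIndex + 300L)
    n <- config$n_samples_per_cohort[cohortIndex]
    cv <- data.frame(sex = stats::rbinom(n, 1, 0.5),
                     age = stats::rnorm(n, 50, 12))
    for (k in seq_len(config$n_geno_pcs))
        cv[[paste0("gPC", k)]] <- stats::rnorm(n)
    for (k in seq_len(config$n_expr_pcs))
        cv[[paste0("ePC", k)]] <- stats::rnorm(n)
    rownames(cv) <- sprintf("c%d_s%d", cohortIndex, seq_len(n))
    cv
}

#' Simulate CpG methylation linked to TR length
#'
#' Each CpG site sits 2 kb from one of the first `n_cpg` TR loci; its
#' methylation probability is a logistic transform of a baseline plus a
#' linear effect of the centred summed repeat dosage plus noise, so
#' values stay in \[0, 1\].
#'
#' @param config a [SimulationConfig] with `n_cpg` > 0.
#' @param trGt a TR [GenotypeTable].
#' @param betaMeth latent-scale effect of one repeat unit (default
#'   0.15); 0 gives null sites.
#' @return list: `methylation` (samples x sites), `sites` (data.frame
#'   cpg, pos, locus, beta).
#' @export
simulateMethylation <- function(config, trGt, betaMeth = 0.15) {
    stopifnot(config$n_cpg >= 1)
    set.seed(config$seed + 9000L)
    dos <- summedDosage(trGt)
    nsite <- config$n_cpg
    loci <- rep_len(seq_len(config$n_tr_loci), nsite)
    meth <- matrix(NA_real_, nrow(dos), nsite,
                   dimnames = list(rownames(dos),
                                   paste0("cpg", seq_len(nsite))))
    beta <- rep_len(betaMeth, nsite)
    for (s in seq_len(nsite)) {
        g <- dos[, loci[s]]
        gc <- g - mean(g, na.rm = TRUE)
        gc[is.na(gc)] <- 0
        latent <- stats::qlogis(0.5) + beta[s] * gc +
            stats::rnorm(nrow(dos), 0, 0.4)
        meth[, s] <- stats::plogis(latent)
    }
    sites <- data.frame(cpg = colnames(meth),
                        pos = loci * config$locus_spacing + 2000,
                        locus = paste0("TR", loci), beta = beta)
    list(methylation = meth, sites = sites)
}

#' Simulate a complete synthetic cohort study
#'
#' Generates, per cohort: TR genotypes, tag SNVs, covariates and
#' per-cell-type pseudobulk expression with the configured planted
#' effects; plus methylation (cohort 1) when `n_cpg` > 0. The planted
#' effect table is carried as the truth set.
#'
#' @param config a [SimulationConfig].
#' @return list of class `SyntheticCohort`: `tr` and `snv` (per-cohort
#'   [GenotypeTable] lists), `expression` (per-cohort lists of
#'   [PseudobulkMatrix]), `covariates`, `methylation`, `genes`,
#'   `catalog`, `truth`, `config`.
#' @export
simulateCohort <- function(config) {
    tr <- lapply(seq_len(config$n_cohorts), function(i)
        simulateTRGenotypes(config, i))
    snv <- lapply(seq_len(config$n_cohorts), function(i)
        simulateTagSNVs(config, tr[[i]], i))
    cov <- lapply(seq_len(config$n_cohorts), function(i)
        simulateCovariates(config, i))
    expr <- lapply(seq_len(config$n_cohorts), function(i)
        simulateExpression(config, tr[[i]], cov[[i]], i))
    meth <- if (config$n_cpg > 0) simulateMethylation(config, tr[[1L]])
            else NULL
    genes <- simulatedGenes(config)
    out <- list(tr = tr, snv = snv, covariates = cov, expression = expr,
                methylation = meth, genes = genes,
                catalog = simulatedCatalog(config),
                truth = normalizeEffectTable(
                    config, genes, paste0("CT", seq_len(config$n_cell_types))),
                config = config)
    class(out) <- "SyntheticCohort"
    out
}

#' @export
print.SyntheticCohort <- function(x, ...) {
    cat(sprintf(paste0("SyntheticCohort: %d cohorts, %d cell types, ",
                       "%d TR loci, %d planted effects\n"),
        x$config$n_cohorts, x$config$n_cell_types,
        x$config$n_tr_loci, nrow(x$truth)))
    invisible(x)
}

#' Simulate a caller/truth genotype pair with planted offsets
#'
#' Generates a truth table under the stepwise model, then a caller table
#' equal to the truth minus a per-locus constant offset plus sporadic
#' random errors — so applying the planted offset to the caller genotype
#' recovers the truth, and the offset-scoring machinery should adopt
#' exactly the planted map.
#'
#' @param config a [SimulationConfig] (one cohort is used).
#' @param offsets integer vector of per-locus constant offsets
#'   (recycled; default 0).
#' @param errorRate probability a call gets an additional random
#'   +/-1..3 error on one allele (default 0).
#' @return list: `caller`, `truth` ([GenotypeTable]s), `offsets` (named
#'   by locus).
#' @export
simulateTruthset <- function(config, offsets = 0, errorRate = 0) {
    truth <- simulateTRGenotypes(config, 1L)
    set.seed(config$seed + 4000L)
    offsets <- rep_len(offsets, config$n_tr_loci)
    names(offsets) <- locusIds(variantsGR(truth))
    a1 <- truth@allele1; a2 <- truth@allele2
    for (j in seq_len(ncol(a1))) {
        a1[, j] <- a1[, j] - offsets[j]
        a2[, j] <- a2[, j] - offsets[j]
        if (errorRate > 0) {
            err <- stats::runif(nrow(a1)) < errorRate & !is.na(a1[, j])
            mag <- sample(c(-3:-1, 1:3), sum(err), replace = TRUE)
            a1[err, j] <- pmax(1, a1[err, j] + mag)
        }
    }
    caller <- truth
    caller@allele1 <- pmax(a1, 1)
    caller@allele2 <- pmax(a2, 1)
    list(caller = caller, truth = truth, offsets = offsets)
}

# variants slot accessor usable before the generic is attached
variantsGR <- function(gt) gt@variants

#' Simulate a TR with a ladder of tag SNVs
#'
#' Generates summed dosages for one stepwise-model TR and a set of tag
#' SNVs whose haplotype alleles copy the TR's above-mode indicator with
#' per-SNV flip probabilities, giving a ladder of LD strengths from
#' moderate down to weak — the variant panel used in fine-mapping and
#' colocalization recovery experiments.
#'
#' @param n samples.
#' @param nTags number of tag SNVs (default 14).
#' @param mode modal repeat count (default 20).
#' @param step_prob stepwise-model parameter (default 0.3).
#' @param flips per-SNV haplotype flip probabilities (default an even
#'   ladder from 0.1 to 0.35, realized r-squared roughly 0.5 down to
#'   0.1).
#' @param seed integer seed.
#' @param prefix variant-id prefix (ids `<prefix>TR`,
#'   `<prefix>S1..<prefix>S<nTags>`).
#' @return samples x (1 + nTags) dosage matrix; column 1 is the TR.
#' @export
simulateTaggedTR <- function(n, nTags = 14, mode = 20, step_prob = 0.3,
                             flips = seq(0.1, 0.35,
                                         length.out = nTags),
                             seed = 1L, prefix = "v") {
    set.seed(seed)
    a1 <- stepwiseAlleles(n, mode, step_prob)
    a2 <- stepwiseAlleles(n, mode, step_prob)
    x1 <- as.numeric(a1 > mode)
    x2 <- as.numeric(a2 > mode)
    out <- matrix(0, n, 1L + nTags)
    out[, 1L] <- a1 + a2
    for (i in seq_len(nTags)) {
        f1 <- stats::runif(n) < flips[i]
        f2 <- stats::runif(n) < flips[i]
        out[, 1L + i] <- ifelse(f1, 1 - x1, x1) + ifelse(f2, 1 - x2, x2)
    }
    colnames(out) <- c(paste0(prefix, "TR"),
                       paste0(prefix, "S", seq_len(nTags)))
    out
}
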