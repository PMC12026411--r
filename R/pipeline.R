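#' Analysis thresholds
#'
#' All pipeline thresholds with their standard defaults: 100 kb cis
#' window, 90% call rate, 0.00995 heterozygosity (non-major allele
#' frequency 0.5%), HWE binomial p 1e-6, mode-window masking -30/+20
#' repeats, SNV MAF 1%, 1% expressed-cell fraction, 5% FDR, PIP 0.7,
#' PP H4 0.8, LD r2 0.5, genome-wide significance 5e-8. The list
#' round-trips losslessly through YAML.
#'
#' @param ... named overrides of any default.
#' @return named list of thresholds.
#' @export
pipelineThresholds <- function(...) {
    def <- list(window = 1e5, min_call_rate = 0.90, min_het = 0.00995,
                hwe_p = 1e-6, mask_below = 30, mask_above = 20,
                min_maf = 0.01, min_expressed_fraction = 0.01,
                fdr = 0.05, min_pip = 0.7, min_pp_h4 = 0.8,
                min_r2 = 0.5, genomewide_p = 5e-8,
                methylation_window = 5000, methylation_min_sd = 0.02)
    ov <- list(...)
    bad <- setdiff(names(ov), names(def))
    if (length(bad)) stop("unknown threshold(s): ",
                          paste(bad, collapse = ", "))
    utils::modifyList(def, ov)
}

#' Write/read an association statistics table as TSV
#'
#' The TSV interchange format shared by all stages (variant, gene,
#' cell_type, cohort, beta, se, p, n, plus any extra columns).
#'
#' @param stats data.frame of statistics.
#' @param path file path.
#' @return `path` (write) or the data.frame (read).
#' @export
writeStatsTSV <- function(stats, path) {
    utils::write.table(stats, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeStatsTSV
#' @export
readStatsTSV <- function(path) {
    utils::read.delim(path, stringsAsFactors = FALSE)
}

# inverse-normal transform every gene row of a PseudobulkMatrix
transformExpression <- function(pb) {
    y <- exprMatrix(pb)
    yt <- t(apply(y, 1, inverseNormalTransform))
    dimnames(yt) <- dimnames(y)
    PseudobulkMatrix(yt, expressedFraction(pb),
                     as.data.frame(SummarizedExperiment::colData(pb)),
                     cellType(pb), cohort(pb))
}

#' Simulate external GWAS summary statistics
#'
#' Draws an independent sample from the same generative process as the
#' synthetic cohort (so LD structure carries over), assigns the trait a
#' genetic effect at the given causal variant, and returns marginal
#' per-variant association statistics in the GWAS summary format, with
#' the coordinates and motifs needed for harmonization.
#'
#' @param config the cohort's [SimulationConfig].
#' @param causalLocus locus id of the causal variant (TR or tag SNV
#'   id), or NA for a null trait.
#' @param beta trait effect per unit dosage (default 0.3).
#' @param n GWAS sample size (default 2000).
#' @param seedOffset offset added to the config seed so the GWAS sample
#'   is independent of the cohorts (default 77).
#' @return data.frame: variant, type, chrom, start, end, pos, motif,
#'   ref, alt, beta, se, p.
#' @export
simulateGWASStats <- function(config, causalLocus, beta = 0.3, n = 2000,
                              seedOffset = 77L) {
    cfg <- config
    cfg$seed <- config$seed + as.integer(seedOffset)
    cfg$n_samples_per_cohort <- rep(as.integer(n), config$n_cohorts)
    tr <- simulateTRGenotypes(cfg, 1L)
    snv <- simulateTagSNVs(cfg, tr, 1L)
    dos <- cbind(summedDosage(tr), summedDosage(snv))
    set.seed(cfg$seed + 12L)
    if (!is.na(causalLocus)) {
        g <- dos[, causalLocus]
        gc <- g - mean(g, na.rm = TRUE); gc[is.na(gc)] <- 0
        y <- beta * gc + stats::rnorm(n)
    } else y <- stats::rnorm(n)
    cat_ <- simulatedCatalog(config)
    snvGr <- variantsGR(snv)
    rows <- lapply(colnames(dos), function(v) {
        st <- tryCatch(fitAssociation(y, dos[, v]),
                       error = function(e) NULL)
        if (is.null(st)) return(NULL)
        isTR <- v %in% locusIds(cat_)
        if (isTR) {
            i <- match(v, locusIds(cat_))
            meta <- data.frame(type = "TR", chrom = "chrS",
                               start = start(cat_)[i], end = end(cat_)[i],
                               pos = start(cat_)[i], motif = motifs(cat_)[i],
                               ref = NA, alt = NA)
        } else {
            i <- match(v, locusIds(snvGr))
            meta <- data.frame(type = "SNV", chrom = "chrS",
                               start = start(snvGr)[i],
                               end = end(snvGr)[i],
                               pos = start(snvGr)[i], motif = NA,
                               ref = "A", alt = "G")
        }
        cbind(data.frame(variant = v), meta, st)
    })
    do.call(rbind, rows)
}

# association stage for one cohort x cell type on QC'd dosages
assocStage <- function(pb, dosage, windows, minEF) {
    pbT <- transformExpression(pb)
    do.call(rbind, lapply(names(windows), function(g) {
        ids <- intersect(windows[[g]], colnames(dosage))
        if (!length(ids)) return(NULL)
        mapGene(g, ids, dosage, pbT, minExpressedFraction = minEF)
    }))
}

#' Run the full sc-eTR analysis pipeline on a synthetic cohort
#'
#' Executes the stages in order — genotype QC, per-cohort per-cell-type
#' association, two-cohort meta-analysis, gene-level significance,
#' cell-type specificity, fine-mapping, conditional analysis, and
#' colocalization — writing each stage's output as TSV into `outdir`
#' together with a JSON manifest (config hash, seed, per-stage row
#' counts). Rerunning with the same inputs reproduces identical
#' outputs.
#'
#' @param cohort a `SyntheticCohort` (see [simulateCohort]).
#' @param outdir output directory (created if needed).
#' @param thresholds threshold list from [pipelineThresholds].
#' @param gwas optional GWAS summary statistics data.frame (see
#'   [simulateGWASStats]); NULL simulates one trait per planted locus,
#'   or skips colocalization for a null cohort.
#' @param cellTypes subset of cell types to run (default: all).
#' @return invisibly, a list of the per-stage data.frames plus the
#'   manifest.
#' @export
runPipeline <- function(cohort, outdir,
                        thresholds = pipelineThresholds(),
                        gwas = NULL, cellTypes = NULL) {
    stopifnot(inherits(cohort, "SyntheticCohort"))
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    th <- thresholds
    cfg <- cohort$config
    if (is.null(cellTypes))
        cellTypes <- paste0("CT", seq_len(cfg$n_cell_types))
    manifest <- list(package = "sceTR",
                     version = as.character(utils::packageVersion("sceTR")),
                     seed = cfg$seed, thresholds = th, stages = list())
    yaml::write_yaml(th, file.path(outdir, "thresholds.yaml"))
    manifest$config_hash <- unname(tools::md5sum(
        file.path(outdir, "thresholds.yaml")))

    ## stage 1: genotype QC
    qc <- lapply(cohort$tr, function(gt) {
        masked <- maskOutlierCalls(gt, th$mask_below, th$mask_above)
        filterTRLoci(masked$genotypes, th$min_call_rate, th$min_het,
                     th$hwe_p)
    })
    snvQC <- lapply(cohort$snv, filterSNVs, minMAF = th$min_maf)
    qcReport <- do.call(rbind, lapply(seq_along(qc), function(i)
        cbind(cohort = paste0("cohort", i), qc[[i]]$report)))
    writeStatsTSV(qcReport, file.path(outdir, "qc_report.tsv"))
    manifest$stages$qc <- nrow(qcReport)

    # loci retained in every cohort define the analysis set
    keptTR <- Reduce(intersect, lapply(qc, function(x)
        colnames(x$genotypes@allele1)))
    keptSNV <- Reduce(intersect, lapply(snvQC, function(x)
        colnames(x@allele1)))
    trDos <- lapply(qc, function(x) summedDosage(x$genotypes)[, keptTR,
                                                             drop = FALSE])
    snvDos <- lapply(snvQC, function(x) summedDosage(x)[, keptSNV,
                                                        drop = FALSE])
    dosage <- lapply(seq_along(trDos), function(i)
        cbind(trDos[[i]], snvDos[[i]]))

    allGr <- c(granges2keep(cohort$catalog),
               variantsGR(cohort$snv[[1L]]))
    allIds <- c(locusIds(cohort$catalog),
                locusIds(variantsGR(cohort$snv[[1L]])))
    vtype <- stats::setNames(
        c(rep("TR", length(cohort$catalog)),
          rep("SNV", length(variantsGR(cohort$snv[[1L]])))), allIds)
    vpos <- stats::setNames(start(allGr), allIds)
    windows <- lapply(seq_len(nrow(cohort$genes)), function(gi)
        allIds[!is.na(GenomicRanges::findOverlaps(
            allGr,
            GRanges("chrS", IRanges(
                max(1, cohort$genes$tss[gi] - th$window),
                cohort$genes$tes[gi] + th$window)),
            select = "first"))])
    names(windows) <- cohort$genes$gene

    ## stage 2: association per cohort per cell type
    assoc <- do.call(rbind, lapply(seq_along(dosage), function(i)
        do.call(rbind, lapply(cellTypes, function(ct)
            assocStage(cohort$expression[[i]][[ct]], dosage[[i]],
                       windows, th$min_expressed_fraction)))))
    writeStatsTSV(assoc, file.path(outdir, "assoc.tsv"))
    manifest$stages$assoc <- nrow(assoc)

    ## stage 3: meta-analysis
    meta <- metaAnalyse(split(assoc, assoc$cohort))
    meta$type <- vtype[meta$variant]
    meta$pos <- vpos[meta$variant]
    writeStatsTSV(meta, file.path(outdir, "meta.tsv"))
    manifest$stages$meta <- nrow(meta)

    ## stage 4: gene-level significance
    sig <- geneLevelSignificance(meta, fdr = th$fdr)
    writeStatsTSV(sig, file.path(outdir, "gene_significance.tsv"))
    manifest$stages$significance <- nrow(sig)

    ## stage 5: cell-type specificity of significant sc-eTRs
    specRows <- list()
    sigHits <- sig[sig$significant & !is.na(sig$top_eTR), , drop = FALSE]
    for (r in seq_len(nrow(sigHits))) {
        g <- sigHits$gene[r]; ct <- sigHits$cell_type[r]
        v <- sigHits$top_eTR[r]
        origin <- meta[meta$variant == v & meta$gene == g &
                       meta$cell_type == ct, , drop = FALSE]
        others <- meta[meta$variant == v & meta$gene == g &
                       meta$cell_type != ct, , drop = FALSE]
        others$expressed_fraction <- vapply(
            others$cell_type, function(oct)
                expressedFraction(cohort$expression[[1L]][[oct]])[g],
            numeric(1))
        cl <- classifySpecificity(origin, others,
                                  th$min_expressed_fraction)
        specRows[[length(specRows) + 1L]] <- data.frame(
            sc_eTR = v, gene = g, origin = ct,
            n_comparisons = nrow(cl$comparisons),
            n_shared = cl$n_shared, specific = cl$specific,
            defined = cl$defined)
    }
    spec <- if (length(specRows)) do.call(rbind, specRows) else
        data.frame(sc_eTR = character(), gene = character(),
                   origin = character(), n_comparisons = integer(),
                   n_shared = integer(), specific = logical(),
                   defined = logical())
    writeStatsTSV(spec, file.path(outdir, "specificity.tsv"))
    manifest$stages$specificity <- nrow(spec)

    ## stage 6: fine-mapping of significant genes (meta summary stats)
    fmRows <- list(); candRows <- list()
    for (r in seq_len(nrow(sigHits))) {
        g <- sigHits$gene[r]; ct <- sigHits$cell_type[r]
        win <- meta[meta$gene == g & meta$cell_type == ct, , drop = FALSE]
        fm <- tryCatch(singleEffectFinemap(win), error = function(e) NULL)
        if (is.null(fm)) next
        fmRows[[length(fmRows) + 1L]] <- cbind(
            data.frame(gene = g, cell_type = ct, W_star = fm$W_star),
            fm$pip)
        cand <- callCandidateCausal(fm, sigHits$top_eTR[r],
                                    sigHits$lead_variant[r], th$min_pip)
        candRows[[length(candRows) + 1L]] <- data.frame(
            gene = g, cell_type = ct, sc_eTR = cand$variant,
            pip = cand$pip, is_lead = cand$is_lead,
            candidate_causal = cand$passes)
    }
    finemap <- if (length(fmRows)) do.call(rbind, fmRows) else
        data.frame()
    candidates <- if (length(candRows)) do.call(rbind, candRows) else
        data.frame(gene = character(), cell_type = character(),
                   sc_eTR = character(), pip = numeric(),
                   is_lead = logical(), candidate_causal = logical())
    writeStatsTSV(finemap, file.path(outdir, "finemap.tsv"))
    writeStatsTSV(candidates, file.path(outdir, "candidates.tsv"))
    manifest$stages$finemap <- nrow(finemap)

    ## stage 7: conditional analysis of candidate causal sc-eTRs on the
    ## lead SNV, per cohort, pooled by DL meta
    condRows <- list()
    cc <- candidates[candidates$candidate_causal, , drop = FALSE]
    for (r in seq_len(nrow(cc))) {
        g <- cc$gene[r]; ct <- cc$cell_type[r]; v <- cc$sc_eTR[r]
        win <- meta[meta$gene == g & meta$cell_type == ct &
                    meta$type == "SNV", , drop = FALSE]
        if (!nrow(win)) next
        leadSNV <- win$variant[order(win$p, win$pos, win$variant)[1L]]
        per <- lapply(seq_along(dosage), function(i) {
            pbT <- transformExpression(cohort$expression[[i]][[ct]])
            tryCatch(conditionalAssociation(
                exprMatrix(pbT)[g, ], dosage[[i]][, v],
                dosage[[i]][, leadSNV],
                covariateMatrix(pbT), th$genomewide_p),
                error = function(e) NULL)
        })
        per <- per[!vapply(per, is.null, logical(1))]
        if (!length(per)) next
        mm <- dlMeta(vapply(per, `[[`, numeric(1), "beta"),
                     vapply(per, `[[`, numeric(1), "se"))
        condRows[[length(condRows) + 1L]] <- data.frame(
            gene = g, cell_type = ct, sc_eTR = v,
            conditioned_on = leadSNV, beta = mm$beta_pooled,
            se = mm$se_pooled, p = mm$p,
            persists = mm$p < th$genomewide_p)
    }
    conditional <- if (length(condRows)) do.call(rbind, condRows) else
        data.frame(gene = character(), cell_type = character(),
                   sc_eTR = character(), conditioned_on = character(),
                   beta = numeric(), se = numeric(), p = numeric(),
                   persists = logical())
    writeStatsTSV(conditional, file.path(outdir, "conditional.tsv"))
    manifest$stages$conditional <- nrow(conditional)

    ## stage 8: colocalization of candidate-causal eGenes with traits
    if (is.null(gwas) && nrow(cohort$truth)) {
        loci <- unique(cohort$truth$locus)
        gwas <- do.call(rbind, lapply(loci, function(lo)
            cbind(trait = paste0("trait_", lo),
                  simulateGWASStats(cfg, lo))))
    }
    colocRows <- list()
    if (!is.null(gwas) && nrow(cc)) {
        if (is.null(gwas$trait)) gwas$trait <- "trait"
        for (r in seq_len(nrow(cc))) {
            g <- cc$gene[r]; ct <- cc$cell_type[r]; v <- cc$sc_eTR[r]
            eq <- meta[meta$gene == g & meta$cell_type == ct, ,
                       drop = FALSE]
            eq$chrom <- "chrS"
            ti <- match(eq$variant, locusIds(cohort$catalog))
            eq$start <- ifelse(!is.na(ti), start(cohort$catalog)[ti],
                               eq$pos)
            eq$end <- ifelse(!is.na(ti), end(cohort$catalog)[ti], eq$pos)
            eq$motif <- ifelse(!is.na(ti), motifs(cohort$catalog)[ti], NA)
            eq$ref <- "A"; eq$alt <- "G"
            for (tr_ in unique(gwas$trait)) {
                gw <- gwas[gwas$trait == tr_, , drop = FALSE]
                winIds <- windows[[g]]
                gwWin <- gw[gw$variant %in% winIds |
                            gw$pos %in% vpos[winIds], , drop = FALSE]
                if (!nrow(gwWin)) next
                hz <- harmonizeVariants(eq, gwWin)
                if (nrow(hz$map) < 1L) next
                co <- tryCatch(colocABF(eq, hz$gwas_harmonized),
                               error = function(e) NULL)
                if (is.null(co)) next
                r2g <- vapply(hz$map$variant_eqtl, function(u)
                    tryCatch(ldR2(dosage[[1L]][, v], dosage[[1L]][, u]),
                             error = function(e) NA_real_), numeric(1))
                gate <- gateColocalization(
                    co,
                    list(passes = cc$candidate_causal[r]),
                    gwWin$p, r2g, th$min_pp_h4, th$min_r2,
                    th$genomewide_p)
                colocRows[[length(colocRows) + 1L]] <- data.frame(
                    gene = g, cell_type = ct, trait = tr_, sc_eTR = v,
                    pp_h0 = co$pp["H0"], pp_h1 = co$pp["H1"],
                    pp_h2 = co$pp["H2"], pp_h3 = co$pp["H3"],
                    pp_h4 = co$pp["H4"], n_variants = co$n_variants,
                    eligible = gate$eligible, passes = gate$passes)
            }
        }
    }
    coloc <- if (length(colocRows)) do.call(rbind, colocRows) else
        data.frame(gene = character(), cell_type = character(),
                   trait = character(), sc_eTR = character(),
                   pp_h0 = numeric(), pp_h1 = numeric(),
                   pp_h2 = numeric(), pp_h3 = numeric(),
                   pp_h4 = numeric(), n_variants = integer(),
                   eligible = logical(), passes = logical())
    rownames(coloc) <- NULL
    writeStatsTSV(coloc, file.path(outdir, "coloc.tsv"))
    manifest$stages$coloc <- nrow(coloc)

    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(list(qc = qcReport, assoc = assoc, meta = meta,
                   significance = sig, specificity = spec,
                   finemap = finemap, candidates = candidates,
                   conditional = conditional, coloc = coloc,
                   manifest = manifest))
}
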