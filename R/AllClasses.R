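#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps
#'   pintersect mcols mcols<- granges
#' @importFrom IRanges IRanges subsetByOverlaps
#' @importFrom S4Vectors queryHits subjectHits DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

#' TRCatalog: a catalog of tandem repeat loci
#'
#' A [GenomicRanges::GRanges] subclass in which every range is a tandem
#' repeat locus annotated with its repeat `motif` (uppercase DNA) and,
#' optionally, `ref_repeats`, the number of motif copies in the reference
#' genome. Ranges follow the Bioconductor convention (1-based, closed);
#' BED input/output converts coordinates at the boundary.
#'
#' @slot .Data inherited GRanges representation.
#' @export
setClass("TRCatalog", contains = "GRanges")

setValidity("TRCatalog", function(object) {
    m <- mcols(object)
    if (is.null(m$motif))
        return("TRCatalog requires a 'motif' metadata column")
    motif <- as.character(m$motif)
    if (any(is.na(motif)) || any(nchar(motif) < 1L))
        return("motifs must be non-empty strings")
    if (any(grepl("[^ACGT]", motif)))
        return("motifs must be uppercase DNA over {A,C,G,T}")
    TRUE
})

#' Construct a TR catalog
#'
#' @param chrom character vector of chromosome names (or a `GRanges`, in
#'   which case `start`/`end` are ignored).
#' @param start,end 1-based closed locus coordinates.
#' @param motif repeat motif per locus, uppercase DNA.
#' @param ref_repeats optional reference repeat-copy number per locus.
#' @param locus_id optional locus identifiers; defaults to
#'   `chrom:start-end`.
#' @return A [TRCatalog] object.
#' @examples
#' TRCatalog("chr1", 101, 130, motif = "AT", ref_repeats = 15)
#' @export
TRCatalog <- function(chrom, start = NULL, end = NULL, motif,
                      ref_repeats = NA_real_, locus_id = NULL) {
    if (is(chrom, "GRanges")) {
        gr <- granges(chrom)
    } else {
        gr <- GRanges(chrom, IRanges(start, end))
    }
    mcols(gr)$motif <- toupper(as.character(motif))
    mcols(gr)$ref_repeats <- as.numeric(ref_repeats)
    if (is.null(locus_id))
        locus_id <- sprintf("%s:%d-%d", as.character(seqnames(gr)),
                            start(gr), end(gr))
    mcols(gr)$locus_id <- as.character(locus_id)
    new("TRCatalog", gr)
}

#' @describeIn TRCatalog motif accessor.
#' @param x a `TRCatalog`.
#' @export
motifs <- function(x) as.character(mcols(x)$motif)

#' @describeIn TRCatalog locus identifier accessor.
#' @export
locusIds <- function(x) as.character(mcols(x)$locus_id)

#' GenotypeTable: diploid repeat-length or SNV allele calls
#'
#' Samples-by-variants genotype storage. For tandem repeats the two allele
#' matrices hold repeat counts; for SNVs they hold non-reference allele
#' indicators (0/1), so that the summed dosage is the non-reference allele
#' count. Missing calls are `NA` in both allele matrices.
#'
#' @slot allele1,allele2 numeric matrices, samples x variants; both `NA`
#'   where the call is missing.
#' @slot variants a `GRanges` describing the variants (for TRs usually a
#'   [TRCatalog]); `names`/`locus_id` align with matrix columns.
#' @slot variantType `"TR"` or `"SNV"`.
#' @export
setClass("GenotypeTable",
    representation(allele1 = "matrix", allele2 = "matrix",
                   variants = "GRanges", variantType = "character"))

setValidity("GenotypeTable", function(object) {
    a1 <- object@allele1; a2 <- object@allele2
    if (!identical(dim(a1), dim(a2)))
        return("allele matrices must have identical dimensions")
    if (!identical(is.na(a1), is.na(a2)))
        return("missingness must be call-level: NA in both alleles or neither")
    if (ncol(a1) != length(object@variants))
        return("number of variant columns must match length(variants)")
    if (!object@variantType %in% c("TR", "SNV"))
        return("variantType must be 'TR' or 'SNV'")
    vals <- c(a1[!is.na(a1)], a2[!is.na(a2)])
    if (length(vals) && any(vals < 0))
        return("allele values must be nonnegative")
    if (object@variantType == "SNV" && length(vals) && any(!vals %in% c(0, 1)))
        return("SNV alleles must be 0/1 (biallelic, split upstream)")
    TRUE
})

#' Construct a genotype table
#'
#' @param allele1,allele2 numeric matrices (samples x variants) of repeat
#'   counts (TR) or 0/1 alleles (SNV); `NA` in both marks a missing call.
#' @param variants `GRanges` (or [TRCatalog]) of variant definitions, one
#'   per column.
#' @param variantType `"TR"` or `"SNV"`.
#' @return A [GenotypeTable].
#' @export
GenotypeTable <- function(allele1, allele2, variants,
                          variantType = c("TR", "SNV")) {
    variantType <- match.arg(variantType)
    allele1 <- as.matrix(allele1); allele2 <- as.matrix(allele2)
    ids <- if (!is.null(mcols(variants)$locus_id))
        as.character(mcols(variants)$locus_id) else names(variants)
    if (!is.null(ids)) colnames(allele1) <- colnames(allele2) <- ids
    new("GenotypeTable", allele1 = allele1, allele2 = allele2,
        variants = granges2keep(variants), variantType = variantType)
}

# keep metadata columns when coercing TRCatalog -> GRanges slot
granges2keep <- function(x) {
    if (is(x, "TRCatalog")) as(x, "GRanges") else x
}

#' @describeIn GenotypeTable variant definitions.
#' @param object a `GenotypeTable`.
#' @export
setGeneric("variants", function(object) standardGeneric("variants"))

#' @rdname GenotypeTable-class
#' @export
setMethod("variants", "GenotypeTable", function(object) object@variants)

#' @describeIn GenotypeTable sample identifiers.
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))

#' @rdname GenotypeTable-class
#' @export
setMethod("sampleIds", "GenotypeTable", function(object)
    rownames(object@allele1))

#' @describeIn GenotypeTable allele matrices as a list.
#' @export
setGeneric("alleles", function(object) standardGeneric("alleles"))

#' @rdname GenotypeTable-class
#' @export
setMethod("alleles", "GenotypeTable", function(object)
    list(allele1 = object@allele1, allele2 = object@allele2))

setMethod("show", "GenotypeTable", function(object) {
    cat(sprintf("GenotypeTable: %d samples x %d %s variants (%.1f%% missing)\n",
        nrow(object@allele1), ncol(object@allele1), object@variantType,
        100 * mean(is.na(object@allele1))))
})

setMethod("show", "TRCatalog", function(object) {
    cat(sprintf("TRCatalog with %d loci\n", length(object)))
    callNextMethod()
})

#' @describeIn GenotypeTable number of variants.
#' @export
setMethod("length", "GenotypeTable", function(x) length(x@variants))

#' Subset a genotype table by variant
#'
#' @param x a [GenotypeTable]; `i` selects samples, `j` variants.
#' @param i,j,...,drop standard matrix-style subsetting arguments.
#' @export
setMethod("[", "GenotypeTable", function(x, i, j, ..., drop = FALSE) {
    if (missing(i)) i <- seq_len(nrow(x@allele1))
    if (missing(j)) j <- seq_len(ncol(x@allele1))
    if (is.character(j)) j <- match(j, colnames(x@allele1))
    new("GenotypeTable",
        allele1 = x@allele1[i, j, drop = FALSE],
        allele2 = x@allele2[i, j, drop = FALSE],
        variants = x@variants[j], variantType = x@variantType)
})

#' PseudobulkMatrix: per cell type, per cohort pseudobulk expression
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one `expression`
#' assay (genes x samples), a `expressed_fraction` rowData column (the
#' fraction of cells of this type expressing each gene), covariates in
#' `colData`, and `cellType`/`cohort` labels in `metadata`.
#'
#' @export
setClass("PseudobulkMatrix", contains = "SummarizedExperiment")

setValidity("PseudobulkMatrix", function(object) {
    if (!"expression" %in% SummarizedExperiment::assayNames(object))
        return("assay 'expression' is required")
    if (is.null(rowData(object)$expressed_fraction))
        return("rowData column 'expressed_fraction' is required")
    ef <- rowData(object)$expressed_fraction
    if (any(ef < 0 | ef > 1, na.rm = TRUE))
        return("expressed_fraction must lie in [0,1]")
    if (is.null(metadata(object)$cellType) || is.null(metadata(object)$cohort))
        return("metadata must carry cellType and cohort labels")
    TRUE
})

#' Construct a pseudobulk expression matrix
#'
#' @param expression genes x samples numeric matrix.
#' @param expressed_fraction per-gene fraction of cells expressing, in
#'   \[0,1\].
#' @param covariates samples x covariates data.frame or matrix
#'   (sex, age, genotype-PC and expression-PC surrogates, ...).
#' @param cellType,cohort labels for this slice of the study.
#' @return A [PseudobulkMatrix].
#' @export
PseudobulkMatrix <- function(expression, expressed_fraction, covariates,
                             cellType, cohort) {
    se <- SummarizedExperiment(
        assays = list(expression = as.matrix(expression)),
        rowData = DataFrame(expressed_fraction = expressed_fraction),
        colData = DataFrame(covariates))
    metadata(se)$cellType <- cellType
    metadata(se)$cohort <- cohort
    new("PseudobulkMatrix", se)
}

#' @describeIn PseudobulkMatrix expression assay (genes x samples).
#' @param object a `PseudobulkMatrix`.
#' @export
setGeneric("exprMatrix", function(object) standardGeneric("exprMatrix"))

#' @rdname PseudobulkMatrix-class
#' @export
setMethod("exprMatrix", "PseudobulkMatrix", function(object)
    assay(object, "expression"))

#' @describeIn PseudobulkMatrix named vector of expressed-cell fractions.
#' @export
setGeneric("expressedFraction", function(object)
    standardGeneric("expressedFraction"))

#' @rdname PseudobulkMatrix-class
#' @export
setMethod("expressedFraction", "PseudobulkMatrix", function(object) {
    ef <- rowData(object)$expressed_fraction
    names(ef) <- rownames(object)
    ef
})

#' @describeIn PseudobulkMatrix covariate matrix (samples x covariates).
#' @export
setGeneric("covariateMatrix", function(object)
    standardGeneric("covariateMatrix"))

#' @rdname PseudobulkMatrix-class
#' @export
setMethod("covariateMatrix", "PseudobulkMatrix", function(object)
    as.matrix(as.data.frame(colData(object))))

#' @describeIn PseudobulkMatrix cell type label.
#' @export
setGeneric("cellType", function(object) standardGeneric("cellType"))

#' @rdname PseudobulkMatrix-class
#' @export
setMethod("cellType", "PseudobulkMatrix", function(object)
    metadata(object)$cellType)

#' @describeIn PseudobulkMatrix cohort label.
#' @export
setGeneric("cohort", function(object) standardGeneric("cohort"))

#' @rdname PseudobulkMatrix-class
#' @export
setMethod("cohort", "PseudobulkMatrix", function(object)
    metadata(object)$cohort)
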