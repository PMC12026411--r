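#' Canonical motif class representative
#'
#' Two TR motifs describe the same repeat if one is a cyclic rotation
#' and/or the reverse complement of the other (the locus may be annotated
#' from either strand with an arbitrary phase). The class representative
#' is the lexicographically smallest string over all cyclic rotations of
#' the motif and of its reverse complement, so two motifs harmonize iff
#' their representatives are equal.
#'
#' @param motif character vector of uppercase DNA motifs.
#' @return character vector of canonical representatives.
#' @examples
#' canonicalMotif("GCA")               # "AGC"
#' canonicalMotif("CAG") == canonicalMotif("CTG")  # TRUE (revcomp)
#' @export
canonicalMotif <- function(motif) {
    motif <- toupper(as.character(motif))
    if (any(is.na(motif)) || any(nchar(motif) < 1L))
        stop("motifs must be non-empty strings")
    if (any(grepl("[^ACGT]", motif)))
        stop("motif contains non-ACGT characters")
    vapply(motif, function(m) {
        rc <- reverseComplementStr(m)
        min(c(rotationsOf(m), rotationsOf(rc)))
    }, character(1), USE.NAMES = FALSE)
}

rotationsOf <- function(m) {
    k <- nchar(m)
    if (k == 1L) return(m)
    dd <- paste0(m, m)
    vapply(seq_len(k), function(i) substr(dd, i, i + k - 1L), character(1))
}

reverseComplementStr <- function(m) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(m)))
}

#' Merge TR catalogs sequentially with an overlap + motif-class rule
#'
#' Catalogs are parsed in order; a candidate locus is excluded iff some
#' already-included locus covers at least `minOverlap` (default 66%) of
#' the candidate's length *and* shares its canonical motif class.
#' Overlapping loci with different motif classes are all retained, as are
#' same-class loci below the overlap threshold. The overlap fraction is
#' measured relative to the candidate locus by default; `"reciprocal"`
#' requires the threshold in both directions.
#'
#' @param catalogs list of [TRCatalog] objects, each sorted by position.
#' @param minOverlap overlap fraction threshold (default 0.66).
#' @param denominator `"candidate"` (default) or `"reciprocal"`.
#' @return A merged, position-sorted [TRCatalog].
#' @export
mergeCatalogs <- function(catalogs, minOverlap = 0.66,
                          denominator = c("candidate", "reciprocal")) {
    denominator <- match.arg(denominator)
    if (is(catalogs, "TRCatalog")) catalogs <- list(catalogs)
    stopifnot(length(catalogs) >= 1L)
    for (ct in catalogs) {
        if (!is(ct, "TRCatalog")) stop("all inputs must be TRCatalog objects")
        if (length(ct) > 1L) {
            o <- order(as.integer(seqnames(ct)), start(ct))
            if (is.unsorted(o))
                stop("catalogs must be sorted by (chrom, start)")
        }
    }
    all_ <- do.call(c, lapply(catalogs, function(ct) {
        gr <- as(ct, "GRanges")
        mcols(gr)$.class <- canonicalMotif(motifs(ct))
        gr
    }))
    keep <- logical(length(all_))
    included <- all_[0]
    for (i in seq_along(all_)) {
        cand <- all_[i]
        excl <- FALSE
        hits <- findOverlaps(cand, included)
        if (length(hits)) {
            s <- subjectHits(hits)
            ow <- width(pintersect(rep(cand, length(s)), included[s]))
            frac <- ow / width(cand)
            if (denominator == "reciprocal")
                frac <- pmin(frac, ow / width(included)[s])
            same <- mcols(cand)$.class == mcols(included)$.class[s]
            excl <- any(frac >= minOverlap & same)
        }
        if (!excl) {
            keep[i] <- TRUE
            included <- c(included, cand)
        }
    }
    included <- all_[keep]
    o <- order(as.integer(seqnames(included)), start(included),
               end(included), mcols(included)$.class)
    included <- included[o]
    mcols(included)$.class <- NULL
    new("TRCatalog", included)
}

#' Is an indel an alternate encoding of a TR allele?
#'
#' An insertion or deletion re-encodes a TR allele (and must be pruned
#' before fine-mapping, or the same signal enters twice) iff its position
#' lies inside the TR locus and the inserted/deleted sequence is a nonzero
#' whole number of copies of some cyclic rotation of the locus motif.
#' Indels that are not perfect motif multiples are retained.
#'
#' @param pos 1-based indel position (position of the REF anchor base,
#'   VCF style).
#' @param ref,alt REF and ALT alleles; one must be a prefix of the other
#'   (pure indel).
#' @param locus a single-locus [TRCatalog] (or GRanges with a motif).
#' @return `TRUE` iff the indel represents whole TR motif copies inside
#'   the locus.
#' @export
isTRIndel <- function(pos, ref, alt, locus) {
    ref <- toupper(ref); alt <- toupper(alt)
    if (nchar(ref) == nchar(alt))
        stop("substitution passed in: indel required")
    shorter <- if (nchar(ref) < nchar(alt)) ref else alt
    longer <- if (nchar(ref) < nchar(alt)) alt else ref
    if (substr(longer, 1L, nchar(shorter)) != shorter)
        stop("not a pure indel: one allele must be a prefix of the other")
    seqd <- substr(longer, nchar(shorter) + 1L, nchar(longer))
    if (pos < start(locus)[1L] || pos > end(locus)[1L]) return(FALSE)
    motif <- toupper(as.character(mcols(locus)$motif[1L]))
    k <- nchar(motif)
    n <- nchar(seqd)
    if (n == 0L || n %% k != 0L) return(FALSE)
    reps <- n %/% k
    any(vapply(rotationsOf(motif), function(rot)
        identical(strrep(rot, reps), seqd), logical(1)))
}

#' Variants in a gene's cis window
#'
#' Returns the variants whose interval intersects the closed window
#' extending `window` bases upstream of the transcription start site and
#' `window` bases downstream of the transcription end site.
#'
#' @param tss,tes gene transcription start/end positions (TSS <= TES on
#'   the strandless projection).
#' @param variantGr `GRanges`/[TRCatalog] of variants on the gene's
#'   chromosome.
#' @param chrom chromosome of the gene (default: first seqlevel of
#'   `variantGr`).
#' @param window flank size in bases (default 100000).
#' @return the subset of `variantGr` inside the window.
#' @export
windowVariants <- function(tss, tes, variantGr,
                           chrom = as.character(seqnames(variantGr))[1L],
                           window = 1e5) {
    stopifnot(tss <= tes)
    win <- GRanges(chrom, IRanges(max(1, tss - window), tes + window))
    subsetByOverlaps(variantGr, win)
}

#' Read a TR catalog from BED4+
#'
#' Column 4 is the motif; an optional numeric column 5 is interpreted as
#' the reference repeat count. BED half-open 0-based coordinates are
#' converted to the 1-based closed convention used internally.
#'
#' @param path BED file path.
#' @return A [TRCatalog].
#' @export
readTRCatalog <- function(path) {
    bed <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
    if (ncol(bed) < 4L) stop("BED4+ required: chrom,start,end,motif")
    TRCatalog(bed[[1L]], bed[[2L]] + 1L, bed[[3L]],
              motif = bed[[4L]],
              ref_repeats = if (ncol(bed) >= 5L) as.numeric(bed[[5L]])
                            else NA_real_)
}

#' Write a TR catalog as BED4+
#'
#' @param catalog a [TRCatalog].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTRCatalog <- function(catalog, path) {
    df <- data.frame(chrom = as.character(seqnames(catalog)),
                     start = start(catalog) - 1L, end = end(catalog),
                     motif = motifs(catalog),
                     ref_repeats = mcols(catalog)$ref_repeats)
    if (all(is.na(df$ref_repeats))) df$ref_repeats <- NULL
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read indel records from a VCF
#'
#' Extracts pure insertions/deletions (REF/ALT of unequal length, one a
#' prefix of the other) for TR-representing-indel pruning.
#'
#' @param path VCF file path.
#' @return data.frame with chrom, pos, ref, alt, id.
#' @export
readIndelsVCF <- function(path) {
    vcf <- VariantAnnotation::readVcf(path)
    rr <- SummarizedExperiment::rowRanges(vcf)
    ref <- as.character(VariantAnnotation::ref(vcf))
    altl <- VariantAnnotation::alt(vcf)
    out <- do.call(rbind, lapply(seq_along(rr), function(i) {
        alts <- as.character(altl[[i]])
        data.frame(chrom = as.character(seqnames(rr)[i]),
                   pos = start(rr)[i], ref = ref[i], alt = alts,
                   id = names(rr)[i], stringsAsFactors = FALSE)
    }))
    keep <- nchar(out$ref) != nchar(out$alt) &
        (substr(out$ref, 1, pmin(nchar(out$ref), nchar(out$alt))) ==
             substr(out$alt, 1, pmin(nchar(out$ref), nchar(out$alt))))
    out[keep, , drop = FALSE]
}
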