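# small in-code fixtures shared across test files

# genotype table from allele vectors; one locus unless matrices given
makeGT <- function(a1, a2, type = "TR", ids = NULL) {
    a1 <- as.matrix(a1); a2 <- as.matrix(a2)
    L <- ncol(a1)
    if (is.null(ids)) ids <- paste0("L", seq_len(L))
    gr <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(seq_len(L) * 1000, seq_len(L) * 1000 + 50))
    S4Vectors::mcols(gr)$locus_id <- ids
    rownames(a1) <- rownames(a2) <- paste0("s", seq_len(nrow(a1)))
    GenotypeTable(a1, a2, gr, type)
}

smallCatalog <- function() {
    TRCatalog(c("chr1", "chr1", "chr2"),
              c(101, 501, 101), c(140, 540, 160),
              motif = c("AT", "CAG", "AC"),
              ref_repeats = c(20, 13, 30),
              locus_id = c("trA", "trB", "trC"))
}

# random DNA motif of length 1..maxLen
randomMotif <- function(maxLen = 30) {
    paste(sample(c("A", "C", "G", "T"), sample.int(maxLen, 1),
                 replace = TRUE), collapse = "")
}

# base-R reverse complement, independent of the package's Biostrings path
revcompOracle <- function(m) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(comp[strsplit(m, "")[[1]]]), collapse = "")
}
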