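test_that("canonical motif representative enumerates rotations and revcomp", {
    # the class of GCA is {AGC,GCA,CAG} u {TGC,GCT,CTG}; smallest is AGC
    expect_identical(canonicalMotif("GCA"), "AGC")
    expect_identical(canonicalMotif(c("AGC", "GCA", "CAG", "GCT", "CTG",
                                      "TGC")),
                     rep("AGC", 6))
    # reverse-complement harmonization: CAG and CTG are the same repeat
    expect_identical(canonicalMotif("CAG"), canonicalMotif("CTG"))
    # palindromic class collapses onto itself
    expect_identical(canonicalMotif("AT"), "AT")
    expect_error(canonicalMotif("ACGU"), "non-ACGT")
    expect_error(canonicalMotif(""), "non-empty")
})

test_that("canonical motif defines an equivalence relation", {
    set.seed(42)
    for (i in 1:2000) {
        m <- randomMotif()
        cm <- canonicalMotif(m)
        k <- nchar(m)
        rot <- sample.int(k, 1)
        rotated <- paste0(substr(m, rot, k), substr(m, 1, rot - 1))
        expect_identical(canonicalMotif(rotated), cm)
        rc <- revcompOracle(m)
        expect_identical(canonicalMotif(rc), cm)
        # the representative is itself in the class and a fixed point
        expect_identical(canonicalMotif(cm), cm)
        # revcomp is an involution
        expect_identical(revcompOracle(rc), m)
    }
})

test_that("catalog merge applies the 66% overlap + same motif-class rule", {
    # identical loci in successive catalogs collapse to one
    c1 <- TRCatalog("chr1", 101, 160, motif = "AT")
    c2 <- TRCatalog("chr1", 101, 160, motif = "AT")
    expect_equal(length(mergeCatalogs(list(c1, c2))), 1L)
    # identical span, motif stated from the other strand: still one locus
    c2rc <- TRCatalog("chr1", 101, 160, motif = "TA")
    expect_equal(length(mergeCatalogs(list(c1, c2rc))), 1L)
    # 50% overlap with the same motif is below threshold: both retained
    a <- TRCatalog("chr1", 101, 200, motif = "AC")
    b <- TRCatalog("chr1", 151, 250, motif = "AC")
    expect_equal(length(mergeCatalogs(list(a, b))), 2L)
    # full overlap but different motif class: both retained
    d <- TRCatalog("chr1", 101, 200, motif = "AG")
    expect_equal(length(mergeCatalogs(list(a, d))), 2L)
    # 66% covered, same class: candidate excluded
    e <- TRCatalog("chr1", 101, 166, motif = "AC")  # 66/66 of e inside a
    expect_equal(length(mergeCatalogs(list(a, e))), 1L)
})

test_that("catalog merge is idempotent and requires sorted input", {
    set.seed(7)
    starts <- sort(sample.int(10000, 20))
    cat1 <- TRCatalog("chr1", starts, starts + sample(20:80, 20, TRUE),
                      motif = sample(c("A", "AT", "CAG"), 20, TRUE))
    merged <- mergeCatalogs(list(cat1))
    again <- mergeCatalogs(list(merged, merged))
    expect_equal(start(again), start(merged))
    expect_equal(end(again), end(merged))
    expect_identical(motifs(again), motifs(merged))
    unsorted <- TRCatalog("chr1", c(500, 100), c(560, 160),
                          motif = c("AT", "AT"))
    expect_error(mergeCatalogs(list(unsorted)), "sorted")
})

test_that("TR-representing indels are whole motif copies inside the locus", {
    locus <- TRCatalog("chr1", 101, 140, motif = "AT")
    # deletion of two whole AT copies inside the locus
    expect_true(isTRIndel(110, "GATAT", "G", locus))
    # partial copy (1.5 motifs) is retained
    expect_false(isTRIndel(110, "G", "GATA", locus))
    # cyclic rotation TA counts as the same repeat
    expect_true(isTRIndel(110, "G", "GTA", locus))
    # same indel outside the locus interval
    expect_false(isTRIndel(500, "GATAT", "G", locus))
    # substitutions are rejected outright
    expect_error(isTRIndel(110, "A", "T", locus), "substitution")
})

test_that("TR-indel detection is invariant under motif rotation", {
    set.seed(11)
    for (i in 1:200) {
        motif <- randomMotif(6)
        k <- nchar(motif)
        reps <- sample(1:4, 1)
        rot <- sample.int(k, 1)
        rotated <- paste0(substr(motif, rot, k), substr(motif, 1, rot - 1))
        loc1 <- TRCatalog("chr1", 101, 200, motif = motif)
        loc2 <- TRCatalog("chr1", 101, 200, motif = rotated)
        ins <- paste0("G", strrep(motif, reps))
        expect_identical(isTRIndel(150, "G", ins, loc1),
                         isTRIndel(150, "G", ins, loc2))
        expect_true(isTRIndel(150, "G", ins, loc1))
    }
})

test_that("cis window membership is a closed interval around TSS/TES", {
    vr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
        c(900000, 899999, 1050000, 1150000, 850000),
        c(900000, 899999, 1050000, 1150000, 850000)))
    # gene at TSS=1,000,000, TES=1,000,000 (point gene)
    hit <- windowVariants(1000000, 1000000, vr, chrom = "chr1")
    # exactly at TSS - 100000 is included; one base further is not
    expect_true(900000 %in% start(hit))
    expect_false(899999 %in% start(hit))
    # +/- 50 kb retained, +/- 150 kb dropped: two variants in window
    expect_equal(length(hit), 2L)
})

test_that("catalogs round-trip through BED4+ with coordinate conversion", {
    cat1 <- smallCatalog()
    path <- withr::local_tempfile(fileext = ".bed")
    writeTRCatalog(cat1, path)
    bed <- read.table(path, sep = "\t")
    expect_equal(bed[[2]], start(cat1) - 1L)  # BED is 0-based half-open
    expect_equal(bed[[3]], end(cat1))
    back <- readTRCatalog(path)
    expect_equal(start(back), start(cat1))
    expect_equal(end(back), end(cat1))
    expect_identical(motifs(back), motifs(cat1))
    expect_equal(S4Vectors::mcols(back)$ref_repeats,
                 S4Vectors::mcols(cat1)$ref_repeats)
})
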