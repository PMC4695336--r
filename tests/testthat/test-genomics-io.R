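test_that("GFF3 exon rows become exons and a derived intron", {
    gff <- c("##gff-version 3",
             "##sequence-region chr1 1 1000",
             "chr1\ttoy\tgene\t101\t400\t.\t+\t.\tID=gA;fclass=mRNA",
             "chr1\ttoy\texon\t101\t200\t.\t+\t.\tParent=gA",
             "chr1\ttoy\texon\t301\t400\t.\t+\t.\tParent=gA",
             "chr1\ttoy\tgene\t501\t700\t.\t+\t.\tID=gB;fclass=ncRNA")
    p <- withr::local_tempfile(fileext = ".gff3")
    writeLines(gff, p)
    anno <- readAnnotation(p)
    ex <- exonRanges(anno)[["gA"]]
    expect_equal(start(ex), c(101, 301))
    expect_equal(end(ex), c(200, 400))
    intr <- intronRanges(anno)[["gA"]]
    expect_equal(start(intr), 201)
    expect_equal(end(intr), 300)
    expect_equal(width(intr), 100)
    # single-exon gene has no intron
    expect_length(intronRanges(anno)[["gB"]], 0)
    expect_equal(unname(featureClass(anno)), c("mRNA", "ncRNA"))
    expect_equal(unname(chromLengths(anno)["chr1"]), 1000)
})

test_that("minus-strand gene keeps the same genomic intron", {
    gff <- c("##gff-version 3",
             "chr1\ttoy\tgene\t101\t400\t.\t-\t.\tID=gA;fclass=mRNA",
             "chr1\ttoy\texon\t101\t200\t.\t-\t.\tParent=gA",
             "chr1\ttoy\texon\t301\t400\t.\t-\t.\tParent=gA")
    p <- withr::local_tempfile(fileext = ".gff3")
    writeLines(gff, p)
    anno <- readAnnotation(p)
    intr <- intronRanges(anno)[["gA"]]
    expect_equal(c(start(intr), end(intr)), c(201, 300))
    expect_equal(as.character(strand(intr)), "-")
})

test_that("records with unknown class or overlapping exons are rejected", {
    gff <- c("##gff-version 3",
             "chr1\ttoy\tgene\t101\t400\t.\t+\t.\tID=gA;fclass=mystery",
             "chr1\ttoy\tgene\t501\t700\t.\t+\t.\tID=gB;fclass=mRNA",
             "chr1\ttoy\texon\t501\t600\t.\t+\t.\tParent=gB",
             "chr1\ttoy\texon\t550\t700\t.\t+\t.\tParent=gB",
             "chr1\ttoy\tgene\t801\t900\t.\t+\t.\tID=gC;fclass=mRNA")
    p <- withr::local_tempfile(fileext = ".gff3")
    writeLines(gff, p)
    expect_message(expect_message(anno <- readAnnotation(p),
                                  "unknown feature class"),
                   "overlapping exons")
    expect_equal(names(featureRanges(anno)), "gC")
})

test_that("fclass falls back to the GFF3 type column when known", {
    gff <- c("##gff-version 3",
             "chr1\ttoy\tncRNA\t101\t400\t.\t+\t.\tID=gA")
    p <- withr::local_tempfile(fileext = ".gff3")
    writeLines(gff, p)
    anno <- readAnnotation(p)
    expect_equal(unname(featureClass(anno)), "ncRNA")
})

test_that("deriveIntrons returns gaps and rejects overlap", {
    ex <- IRanges::IRanges(start = c(1, 81, 151), end = c(50, 120, 200))
    intr <- deriveIntrons(ex)
    expect_equal(start(intr), c(51, 121))
    expect_equal(end(intr), c(80, 150))
    expect_length(deriveIntrons(IRanges::IRanges(1, 50)), 0)
    expect_error(deriveIntrons(IRanges::IRanges(c(1, 40), c(50, 90))),
                 "overlapping")
})

test_that("deriveIntrons matches a per-base membership oracle", {
    set.seed(71)
    for (rep in 1:20) {
        n <- sample(2:10, 1)
        starts <- sort(sample(seq(1, 2000, by = 25), n))
        ends <- starts + sample(5:20, n, replace = TRUE)
        ex <- IRanges::IRanges(starts, ends)
        if (!IRanges::isDisjoint(ex)) next
        intr <- deriveIntrons(ex)
        # oracle: bases in span but in no exon
        span <- min(starts):max(ends)
        inExon <- span %in% unlist(lapply(seq_len(n),
                                          function(i) starts[i]:ends[i]))
        gapBases <- span[!inExon]
        expect_equal(sum(width(intr)), length(gapBases))
        expect_true(all(unlist(lapply(seq_along(intr), function(i)
            start(intr)[i]:end(intr)[i])) %in% gapBases))
    }
})

test_that("annotation round-trips through GFF3", {
    anno <- tinyAnnotation()
    p <- withr::local_tempfile(fileext = ".gff3")
    writeAnnotation(anno, p)
    anno2 <- readAnnotation(p)
    ids <- names(featureRanges(anno))
    expect_setequal(ids, names(featureRanges(anno2)))
    for (id in ids) {
        expect_equal(unname(as.character(featureRanges(anno)[id])),
                     unname(as.character(featureRanges(anno2)[id])))
        expect_identical(ranges(exonRanges(anno)[[id]]),
                         ranges(exonRanges(anno2)[[id]]))
        expect_identical(ranges(intronRanges(anno)[[id]]),
                         ranges(intronRanges(anno2)[[id]]))
    }
    expect_equal(featureClass(anno)[ids], featureClass(anno2)[ids])
    expect_equal(chromLengths(anno2)[names(chromLengths(anno))],
                 chromLengths(anno))
})

test_that("mirror reflection preserves intron count and lengths", {
    anno <- tinyAnnotation()
    L <- 2001L  # reflect about chromosome midpoint: pos -> L - pos
    feats <- featureRanges(anno)
    flip <- function(gr) {
        GenomicRanges::GRanges(
            GenomeInfoDb::seqnames(gr),
            IRanges::IRanges(L - end(gr), L - start(gr)),
            strand = ifelse(as.character(strand(gr)) == "+", "-",
                            ifelse(as.character(strand(gr)) == "-", "+",
                                   "*")))
    }
    feats2 <- flip(feats)
    names(feats2) <- names(feats)
    feats2$fclass <- feats$fclass
    ex2 <- S4Vectors::endoapply(exonRanges(anno), flip)
    anno2 <- GenomeAnnotation(feats2, ex2)
    for (id in names(feats)) {
        w1 <- sort(width(intronRanges(anno)[[id]]))
        w2 <- sort(width(intronRanges(anno2)[[id]]))
        expect_equal(w1, w2)
    }
})

test_that("BED6 import keeps reads and drops out-of-bounds ones", {
    bed <- c("chrA\t10\t50\tr1\t0\t+",
             "chrA\t100\t140\tr2\t0\t-",
             "chrB\t20\t60\tr3\t0\t+")
    p <- withr::local_tempfile(fileext = ".bed")
    writeLines(bed, p)
    aln <- readAlignments(p)
    expect_s4_class(aln, "AlignmentSet")
    expect_length(reads(aln), 3)
    expect_equal(totalMapped(aln), 3)
    # BED is 0-based half-open; first read is 1-based [11,50]
    expect_equal(start(reads(aln))[1], 11)
    expect_equal(end(reads(aln))[1], 50)
    # one read beyond chrB length (1000): rejected but still in totalMapped
    bed2 <- c(bed, "chrB\t990\t1030\tr4\t0\t+")
    writeLines(bed2, p)
    expect_message(aln2 <- readAlignments(p, annotation = tinyAnnotation()),
                   "out-of-bounds")
    expect_length(reads(aln2), 3)
    expect_equal(totalMapped(aln2), 4)
})

test_that("SAM import keeps only primary mapped records", {
    skip_if_not_installed("Rsamtools")
    skip_if_not_installed("GenomicAlignments")
    sam <- c("@HD\tVN:1.6\tSO:coordinate",
             "@SQ\tSN:chrA\tLN:2000",
             "r1\t0\tchrA\t101\t60\t40M\t*\t0\t0\t*\t*",
             "r2\t16\tchrA\t301\t60\t40M\t*\t0\t0\t*\t*",
             "r3\t2048\tchrA\t501\t60\t40M\t*\t0\t0\t*\t*",  # supplementary
             "r4\t256\tchrA\t701\t60\t40M\t*\t0\t0\t*\t*",   # secondary
             "r5\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*")             # unmapped
    p <- withr::local_tempfile(fileext = ".sam")
    writeLines(sam, p)
    aln <- readAlignments(p)
    expect_length(reads(aln), 2)
    expect_equal(start(reads(aln)), c(101, 301))
    expect_equal(as.character(strand(reads(aln))), c("+", "-"))
})

test_that("fetchSequence returns sense-strand sequence", {
    g <- Biostrings::DNAStringSet(c(chr1 = "TTAAACGGTT"))
    plus <- fetchSequence(g, GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(1, 6), "+"))
    expect_equal(as.character(plus), "TTAAAC", ignore_attr = TRUE)
    minus <- fetchSequence(g, GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(1, 6), "-"))
    expect_equal(as.character(minus), "GTTTAA", ignore_attr = TRUE)
    # involution: fetch(+) is the reverse complement of fetch(-)
    set.seed(5)
    rg <- Biostrings::DNAStringSet(c(c1 = paste(
        sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")))
    iv <- GenomicRanges::GRanges("c1", IRanges::IRanges(3, 42))
    sp <- fetchSequence(rg, `strand<-`(iv, value = "+"))
    sm <- fetchSequence(rg, `strand<-`(iv, value = "-"))
    expect_equal(as.character(Biostrings::reverseComplement(sm)),
                 as.character(sp), ignore_attr = TRUE)
    expect_error(fetchSequence(rg, GenomicRanges::GRanges(
        "c1", IRanges::IRanges(40, 60))), "bounds")
})
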