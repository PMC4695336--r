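test_that("reads are assigned to same-strand features, intergenic, antisense", {
    anno <- tinyAnnotation()
    # g1 is + [101,600]; g2 is - [1001,1400]; int1 is * [1501,1800]
    aln <- makeReads("chrA", c(150, 1600, 1100), width = 40L,
                     strand = c("+", "+", "+"))
    res <- assignReadsToFeatures(aln, anno)
    expect_equal(unname(res$counts["g1"]), 1L)     # sense overlap
    expect_equal(unname(res$counts["int1"]), 1L)   # intergenic catch-all
    expect_equal(unname(res$counts["g2"]), 0L)     # antisense only
    expect_equal(unname(res$antisense["g2"]), 1L)
    expect_equal(res$unassigned, 0L)
})

test_that("assignment matches the brute-force oracle on random reads", {
    anno <- tinyAnnotation()
    set.seed(33)
    for (rep in 1:5) {
        aln <- makeReads(
            sample(c("chrA", "chrB"), 100, TRUE,
                   prob = c(0.8, 0.2)),
            sample(1:1900, 100, TRUE), width = 30L,
            strand = sample(c("+", "-"), 100, TRUE),
            seqlengths = c(chrA = 2000L, chrB = 1000L))
        got <- assignReadsToFeatures(aln, anno)
        want <- oracleAssign(aln, anno)
        expect_equal(got$counts, want$counts)
        expect_equal(got$antisense, want$antisense)
        expect_equal(got$unassigned, want$unassigned)
        # conservation: every read lands in exactly one tally
        expect_equal(sum(got$counts) + sum(got$antisense) + got$unassigned,
                     length(reads(aln)))
    }
})

test_that("stacked reads form clusters respecting height and length", {
    aln <- makeReads("chrA", rep(101, 10), width = 40L)
    cl <- callClusters(aln, minHeight = 5L, minLength = 12L)
    expect_length(cl, 1)
    expect_equal(c(start(cl), end(cl)), c(101, 140))
    expect_equal(cl$height, 10L)
    expect_equal(cl$nReads, 10L)
    # below min height: nothing
    aln4 <- makeReads("chrA", rep(101, 4), width = 40L)
    expect_length(callClusters(aln4, minHeight = 5L), 0)
})

test_that("cluster calling matches the per-base coverage oracle", {
    set.seed(91)
    for (rep in 1:5) {
        aln <- makeReads("chrA", sample(1:4000, 400, TRUE),
                         width = sample(20:50, 400, TRUE),
                         strand = sample(c("+", "-"), 400, TRUE))
        cl <- callClusters(aln)
        want <- oracleClusters(aln)
        expect_equal(length(cl), nrow(want))
        if (nrow(want)) {
            o <- order(as.character(seqnames(cl)),
                       as.character(strand(cl)), start(cl))
            expect_equal(start(cl)[o], want$start)
            expect_equal(end(cl)[o], want$end)
            expect_equal(cl$height[o], as.integer(want$height))
        }
    }
})

test_that("a shuffle-invariant cluster yields z = NA and pEmp = 1", {
    km <- kmerEnrichment("AAAAAAAA", k = 6L, nShuffles = 20L, seed = 1)
    expect_equal(km$kmer, "AAAAAA")
    expect_true(is.na(km$z))
    expect_equal(km$pEmp, 1)
})

test_that("planted hexamer ranks first and unplanted clusters stay null", {
    set.seed(17)
    bg <- vapply(1:30, function(i)
        paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = ""), "")
    planted <- vapply(bg[1:15], function(s)
        paste0(substr(s, 1, 10), "TTAAAC", substr(s, 17, 40)), "")
    km <- kmerEnrichment(c(planted, bg[16:30]), nShuffles = 100L, seed = 2)
    expect_equal(km$kmer[1], "TTAAAC")
    # duplication of every cluster leaves the top-ranked k-mer unchanged
    km2 <- kmerEnrichment(rep(c(planted, bg[16:30]), 2), nShuffles = 100L,
                          seed = 2)
    expect_equal(km2$kmer[1], "TTAAAC")
    # null clusters: minimum BH-adjusted q should not reach significance
    nullQ <- vapply(1:20, function(s) {
        set.seed(100 + s)
        cl <- vapply(1:20, function(i)
            paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = ""),
            "")
        min(kmerEnrichment(cl, nShuffles = 50L, seed = 200 + s)$q)
    }, 0)
    expect_gte(mean(nullQ > 0.05), 0.95)
})

test_that("all-short clusters are an error", {
    expect_error(kmerEnrichment(c("ACG", "TTT"), k = 6L), "length")
})

test_that("enrichment normalises counts by abundance with pseudocount", {
    counts <- c(gA = 100, gB = 50, gC = 10)
    ab <- c(gA = 10, gB = 50)
    expect_message(enr <- computeEnrichment(counts, ab), "missing")
    expect_equal(enr$enrichment[enr$feature_id == "gA"], 100 / 10.1,
                 tolerance = 1e-12)
    expect_true(is.na(enr$enrichment[enr$feature_id == "gC"]))
    # equal abundances: enrichment ranking equals raw-count ranking
    ab2 <- c(gA = 5, gB = 5, gC = 5)
    enr2 <- computeEnrichment(counts, ab2)
    expect_equal(enr2$feature_id, c("gA", "gB", "gC"))
})

test_that("pA classification thresholds at the 5-fold cutoff", {
    pa <- c(a = 10, b = 0.5, c = 3)
    tot <- c(a = 10, b = 10, c = 10)
    got <- classifyPolyA(pa, tot, cutoff = 5)
    expect_equal(unname(got["a"]), "pA+")   # R = 1
    expect_equal(unname(got["b"]), "pA-")   # R = 0.05, 20-fold depleted
    # scaling either table leaves the classification unchanged
    expect_equal(classifyPolyA(pa * 37, tot, cutoff = 5), got)
    expect_equal(classifyPolyA(pa, tot * 0.01, cutoff = 5), got)
    # the alternative reading: pA+ requires >= 5-fold enrichment; neutral
    # features pin the medians so feature a sits at R = 6
    pa3 <- c(a = 60, b = 10, c = 10, d = 10, e = 10)
    tot3 <- c(a = 10, b = 10, c = 10, d = 10, e = 10)
    got2 <- classifyPolyA(pa3, tot3, direction = "enrichment")
    expect_equal(unname(got2["a"]), "pA+")
    expect_equal(unname(got2["b"]), "pA-")
    # absent feature -> NA
    got3 <- classifyPolyA(c(a = 1, b = 1), c(a = 1, b = 1, d = 2))
    expect_true(is.na(got3["d"]))
})

test_that("intronic binding fraction counts read midpoints", {
    anno <- tinyAnnotation()   # g1 intron is [201,300] on +
    inAll <- makeReads("chrA", c(rep(230, 5), rep(110, 5)), width = 20L)
    expect_equal(intronicBindingFraction("g1", anno, inAll), 0.5)
    onlyIntron <- makeReads("chrA", rep(230, 10), width = 20L)
    expect_equal(intronicBindingFraction("g1", anno, onlyIntron), 1.0)
    expect_error(intronicBindingFraction("g3", anno, inAll), "intron")
    none <- makeReads("chrB", 300, width = 20L, strand = "-")
    expect_true(is.na(intronicBindingFraction("g1", anno, none)))
    # brute-force midpoint oracle on random reads
    set.seed(12)
    aln <- makeReads("chrA", sample(50:650, 200, TRUE), width = 21L)
    mids <- start(reads(aln)) + 10L
    inFeat <- mids >= 101 & mids <= 600
    inIntr <- mids >= 201 & mids <= 300
    expect_equal(intronicBindingFraction("g1", anno, aln),
                 sum(inIntr) / sum(inFeat))
})
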