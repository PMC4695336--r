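test_that("the generator is deterministic under a fixed seed", {
    cfg <- smallConfig(seed = 9)
    a <- simulateGenome(cfg)
    b <- simulateGenome(cfg)
    expect_identical(as.character(a$genome), as.character(b$genome))
    expect_identical(a$truth$genes, b$truth$genes)
    expect_identical(a$truth$motifs, b$truth$motifs)
    cracA <- simulateCracReads(a$genome, a$annotation, a$truth, cfg)
    cracB <- simulateCracReads(b$genome, b$annotation, b$truth, cfg)
    expect_identical(as.data.frame(reads(cracA)),
                     as.data.frame(reads(cracB)))
    # and the emitted files are byte-identical
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    simA <- runSimulation(cfg); simB <- runSimulation(cfg)
    f1 <- writeSimulation(simA, d1); f2 <- writeSimulation(simB, d2)
    for (nm in names(f1))
        expect_identical(unname(tools::md5sum(f1[nm])),
                         unname(tools::md5sum(f2[nm])), label = nm)
})

test_that("no decay intron is flagged when none is requested", {
    sim <- simulateGenome(smallConfig(seed = 2, nDecayIntrons = 0L))
    expect_false(any(sim$truth$genes$isDecayIntron))
    expect_true(all(sim$truth$genes$irCategory != "stabilized",
                    na.rm = TRUE))
})

test_that("flagged introns carry their planted motif copies in the FASTA", {
    cfg <- smallConfig(seed = 8)
    sim <- runSimulation(cfg)
    d <- withr::local_tempdir()
    f <- writeSimulation(sim, d)
    # independent scan: re-read the emitted FASTA with Biostrings, take the
    # sense-strand intron sequence by hand, and regex-count DSR matches
    genome <- Biostrings::readDNAStringSet(f["genome"])
    names(genome) <- sub("\\s.*", "", names(genome))
    tg <- sim$truth$genes
    planted <- sim$truth$planted
    for (id in tg$feature_id[tg$isDecayIntron]) {
        introns <- intronRanges(sim$annotation)[[id]]
        nHits <- 0L
        for (i in seq_along(introns)) {
            ch <- as.character(seqnames(introns))[i]
            sq <- substr(as.character(genome[[ch]]), start(introns)[i],
                         end(introns)[i])
            if (as.character(strand(introns))[i] == "-") {
                comp <- chartr("ACGT", "TGCA", sq)
                sq <- paste(rev(strsplit(comp, "")[[1]]), collapse = "")
            }
            nHits <- nHits + length(
                gregexpr("(?=T[TCG]AAAC)", sq, perl = TRUE)[[1]]) *
                (gregexpr("(?=T[TCG]AAAC)", sq, perl = TRUE)[[1]][1] > 0)
        }
        expect_gte(nHits, sum(planted$gene_id == id))
    }
})

test_that("CRAC reads follow affinity x expression and pile on motifs", {
    # limit case: all affinities baseline -> counts proportional to
    # expression within multinomial error
    cfg <- smallConfig(seed = 4, targetAffinity = 1)
    sim <- simulateGenome(cfg)
    crac <- simulateCracReads(sim$genome, sim$annotation, sim$truth, cfg)
    cnt <- assignReadsToFeatures(crac, sim$annotation)$counts
    tg <- sim$truth$genes
    expected <- tg$expression / sum(tg$expression) * totalMapped(crac)
    big <- expected[match(names(cnt), tg$feature_id)] >= 50
    relErr <- abs(cnt[big] - expected[big]) / expected[big]
    expect_lt(stats::median(relErr), 0.25)
    expect_gt(stats::cor(cnt, expected[match(names(cnt), tg$feature_id)]),
              0.95)
    # with affinity on, a decay gene's reads concentrate in its intron
    cfg2 <- smallConfig(seed = 4)
    sim2 <- simulateGenome(cfg2)
    crac2 <- simulateCracReads(sim2$genome, sim2$annotation, sim2$truth,
                               cfg2)
    tg2 <- sim2$truth$genes
    dg <- tg2$feature_id[tg2$isDecayIntron][1]
    rd <- reads(crac2)
    gene <- featureRanges(sim2$annotation)[dg]
    rdGene <- rd[overlapsAny(rd, gene)]
    fracOverlap <- mean(overlapsAny(rdGene,
                                    intronRanges(sim2$annotation)[[dg]]))
    expect_gt(fracOverlap, 0.8)
})

test_that("enrichment anticorrelates with abundance for planted targets", {
    cfg <- smallConfig(seed = 14)
    sim <- simulateGenome(cfg)
    crac <- simulateCracReads(sim$genome, sim$annotation, sim$truth, cfg)
    cnt <- assignReadsToFeatures(crac, sim$annotation)$counts
    enr <- suppressMessages(
        computeEnrichment(cnt, sim$truth$abundanceTotal))
    tg <- sim$truth$genes
    aff <- tg$affinity[match(enr$feature_id, tg$feature_id)]
    ok <- !is.na(enr$enrichment) & !is.na(aff)
    expect_gt(stats::cor(enr$enrichment[ok], aff[ok], method = "spearman"),
              0.5)
})

test_that("simulated counts match the NB mean-variance relationship", {
    # many genes, more replicates, so the pooled moment check is sharp
    cfg <- simConfig(seed = 6, nChrom = 2L, chromLength = 700000L,
                     nMRNA = 500L, nNcRNA = 10L, nSnoRNA = 0L, nSnRNA = 0L,
                     nPseudogene = 0L, nDecayIntrons = 5L,
                     nExonicTargets = 5L, nSplicingDefect = 2L,
                     nExtraUp = 2L, nExtraDown = 2L,
                     nReadthroughPerClass = 1L, cracDepth = 1000L,
                     rnaseqDepth = 400000L, nReplicates = 10L)
    sim <- simulateGenome(cfg)
    wt <- simulateRnaSeq(sim$annotation, sim$truth, "WT", cfg)
    cnt <- wt$counts
    mu <- rowMeans(cnt)
    v <- apply(cnt, 1, stats::var)
    keep <- mu >= 20
    expect_gt(sum(keep), 500)
    # regression of (var - mu) on mu^2 recovers the dispersion; the pooled
    # standardized discrepancy must sit within 3 standard errors
    dispHat <- sum((v[keep] - mu[keep]) * mu[keep]^2) / sum(mu[keep]^4)
    expect_equal(dispHat, cfg@nbDispersion, tolerance = 0.2)
    z <- (v[keep] - (mu[keep] + cfg@nbDispersion * mu[keep]^2)) /
        ((mu[keep] + cfg@nbDispersion * mu[keep]^2) * sqrt(2 / (10 - 1)))
    expect_lt(abs(mean(z)) / (stats::sd(z) / sqrt(sum(keep))), 3.5)
})

test_that("planted IR and readthrough phenotypes appear in the reads", {
    cfg <- smallConfig(seed = 10)
    sim <- simulateGenome(cfg)
    wt <- simulateRnaSeq(sim$annotation, sim$truth, "WT", cfg)
    mut <- simulateRnaSeq(sim$annotation, sim$truth, "mutant", cfg)
    wtPool <- poolAlignments(wt$alignments, "WT")
    mutPool <- poolAlignments(mut$alignments, "mutant")
    tg <- sim$truth$genes
    # across stabilized genes, pooled 5'SS boundary reads more than double
    dg <- tg$feature_id[tg$irCategory == "stabilized" & !is.na(tg$irCategory)]
    bWT <- sum(vapply(dg, function(g)
        countBoundaryReads(wtPool, intronRanges(sim$annotation)[[g]][1])$count,
        0L))
    bMut <- sum(vapply(dg, function(g)
        countBoundaryReads(mutPool, intronRanges(sim$annotation)[[g]][1])$count,
        0L))
    expect_gt((rpmValue <- function(n, t) n / t * 1e6)(bMut,
                  totalMapped(mutPool)) /
              max(rpmValue(bWT, totalMapped(wtPool)), 0.1), 2)
    # class 3: downstream signal up while the body counts drop
    g3 <- tg$feature_id[tg$rtClass == "3"][1]
    dWT <- downstreamSignal(wtPool, g3, sim$annotation)$rpm
    dMut <- downstreamSignal(mutPool, g3, sim$annotation)$rpm
    expect_gt(dMut, dWT)
    expect_lt(sum(mut$counts[g3, ]), sum(wt$counts[g3, ]) / 2)
})
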