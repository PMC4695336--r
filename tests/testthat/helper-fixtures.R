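suppressPackageStartupMessages({
    library(GenomicRanges)
    library(IRanges)
    library(Biostrings)
})

# Shared fixtures: a tiny hand-built annotation and read constructors.

# two chromosomes, genes on both strands, one intron-containing gene per
# strand, one ncRNA, one intergenic feature
tinyAnnotation <- function() {
    feats <- GenomicRanges::GRanges(
        c("chrA", "chrA", "chrA", "chrB"),
        IRanges::IRanges(start = c(101, 1001, 1501, 201),
                         end = c(600, 1400, 1800, 900)),
        strand = c("+", "-", "*", "-"))
    names(feats) <- c("g1", "g2", "int1", "g3")
    feats$fclass <- c("mRNA", "mRNA", "intergenic", "ncRNA")
    exons <- GenomicRanges::GRangesList(
        g1 = GenomicRanges::GRanges("chrA",
            IRanges::IRanges(c(101, 301), c(200, 600)), "+"),
        g2 = GenomicRanges::GRanges("chrA",
            IRanges::IRanges(c(1001, 1301), c(1200, 1400)), "-"))
    GenomeAnnotation(feats, exons,
                     seqlengths = c(chrA = 2000L, chrB = 1000L))
}

# reads as an AlignmentSet from parallel vectors
makeReads <- function(chrom, start, width = 40L, strand = "+",
                      totalMapped = NULL, seqlengths = NULL) {
    n <- max(length(chrom), length(start))
    ch <- rep(chrom, length.out = n)
    st <- rep(start, length.out = n)
    en <- st + rep(width, length.out = n) - 1L
    if (!is.null(seqlengths)) {  # keep random reads inside the chromosome
        st <- pmin(st, unname(seqlengths[ch]))
        en <- pmin(en, unname(seqlengths[ch]))
    }
    gr <- GenomicRanges::GRanges(ch, IRanges::IRanges(st, en),
                                 strand = rep(strand, length.out = n))
    if (!is.null(seqlengths)) {
        GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
        GenomeInfoDb::seqlengths(gr) <- seqlengths
    }
    AlignmentSet(gr, totalMapped = if (is.null(totalMapped)) n else
        totalMapped, libraryId = "test")
}

# a small, fast simulation config for unit tests (the acceptance suite uses
# the package defaults)
smallConfig <- function(seed = 1L, ...) {
    args <- list(seed = seed, nChrom = 2L, chromLength = 120000L,
                 nMRNA = 40L, nNcRNA = 16L, nSnoRNA = 4L, nSnRNA = 2L,
                 nPseudogene = 2L, nDecayIntrons = 6L, nExonicTargets = 10L,
                 nSplicingDefect = 3L, nExtraUp = 4L, nExtraDown = 5L,
                 nReadthroughPerClass = 2L, cracDepth = 20000L,
                 rnaseqDepth = 80000L)
    over <- list(...)
    args[names(over)] <- over
    do.call(simConfig, args)
}

# independent brute-force assignment oracle: per read, same-strand maximal
# overlap, ties to smaller then lexicographically first feature
oracleAssign <- function(alignments, annotation) {
    rd <- reads(alignments)
    feats <- featureRanges(annotation)
    ids <- names(feats)
    counts <- stats::setNames(integer(length(ids)), ids)
    anti <- stats::setNames(integer(length(ids)), ids)
    unassigned <- 0L
    for (i in seq_along(rd)) {
        r <- rd[i]
        ov <- rep(0L, length(feats))
        for (j in seq_along(feats)) {
            f <- feats[j]
            if (as.character(GenomeInfoDb::seqnames(f)) !=
                as.character(GenomeInfoDb::seqnames(r))) next
            sameStrand <- as.character(BiocGenerics::strand(f)) %in%
                c("*", as.character(BiocGenerics::strand(r)))
            o <- min(BiocGenerics::end(r), BiocGenerics::end(f)) -
                max(BiocGenerics::start(r), BiocGenerics::start(f)) + 1L
            if (o > 0L && sameStrand) ov[j] <- o
        }
        if (any(ov > 0L)) {
            cand <- which(ov == max(ov))
            if (length(cand) > 1L) {
                w <- BiocGenerics::width(feats)[cand]
                cand <- cand[w == min(w)]
                cand <- cand[order(ids[cand])]
            }
            counts[cand[1]] <- counts[cand[1]] + 1L
        } else {
            hit <- FALSE
            ovA <- rep(0L, length(feats))
            for (j in seq_along(feats)) {
                f <- feats[j]
                if (as.character(GenomeInfoDb::seqnames(f)) !=
                    as.character(GenomeInfoDb::seqnames(r))) next
                o <- min(BiocGenerics::end(r), BiocGenerics::end(f)) -
                    max(BiocGenerics::start(r), BiocGenerics::start(f)) + 1L
                if (o > 0L) ovA[j] <- o
            }
            if (any(ovA > 0L)) {
                cand <- which(ovA == max(ovA))
                if (length(cand) > 1L) {
                    w <- BiocGenerics::width(feats)[cand]
                    cand <- cand[w == min(w)]
                    cand <- cand[order(ids[cand])]
                }
                anti[cand[1]] <- anti[cand[1]] + 1L
                hit <- TRUE
            }
            if (!hit) unassigned <- unassigned + 1L
        }
    }
    list(counts = counts, antisense = anti, unassigned = unassigned)
}

# brute-force per-base cluster oracle
oracleClusters <- function(alignments, minHeight = 5L, minLength = 12L,
                           mergeGap = 3L, chromLen = 5000L) {
    rd <- reads(alignments)
    out <- list()
    for (st in c("+", "-")) {
        for (ch in unique(as.character(GenomeInfoDb::seqnames(rd)))) {
            sub <- rd[as.character(GenomeInfoDb::seqnames(rd)) == ch &
                          as.character(BiocGenerics::strand(rd)) == st]
            if (length(sub) == 0L) next
            cov <- integer(chromLen)
            for (i in seq_along(sub)) {
                s <- BiocGenerics::start(sub)[i]
                e <- min(BiocGenerics::end(sub)[i], chromLen)
                cov[s:e] <- cov[s:e] + 1L
            }
            above <- cov >= minHeight
            # merge gaps shorter than mergeGap
            r <- rle(above)
            pos <- cumsum(r$lengths)
            idx <- which(!r$values & r$lengths < mergeGap)
            for (k in idx) {
                if (k > 1L && k < length(r$values)) {
                    s <- pos[k - 1L] + 1L
                    above[s:pos[k]] <- TRUE
                }
            }
            r2 <- rle(above)
            e2 <- cumsum(r2$lengths)
            s2 <- e2 - r2$lengths + 1L
            keep <- r2$values & r2$lengths >= minLength
            if (any(keep))
                out[[paste(ch, st)]] <- data.frame(
                    chrom = ch, start = s2[keep], end = e2[keep],
                    strand = st,
                    height = vapply(which(keep), function(k)
                        max(cov[s2[k]:e2[k]]), 0L))
        }
    }
    if (length(out) == 0L)
        return(data.frame(chrom = character(), start = integer(),
                          end = integer(), strand = character(),
                          height = integer()))
    res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
    res[order(res$chrom, res$strand, res$start), , drop = FALSE]
}
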