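# Shared small helpers (internal).

# round-half-up to integer; base round() is round-half-even
roundHalfUp <- function(x) floor(x + 0.5)

rpmValue <- function(count, totalMapped) count / totalMapped * 1e6

# 1-based midpoint of read intervals, used wherever a read must be counted
# in exactly one of several adjacent regions
readMidpoints <- function(gr) {
    (BiocGenerics::start(gr) + BiocGenerics::end(gr)) %/% 2L
}

# midpoint-in-interval counting against a target GRanges (strand-aware when
# the target strand is set; "*" matches both)
countMidpointsIn <- function(readGr, target) {
    if (length(readGr) == 0L || length(target) == 0L) return(0L)
    mids <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(readGr),
                                   IRanges::IRanges(readMidpoints(readGr),
                                                    width = 1L),
                                   strand = BiocGenerics::strand(readGr))
    sum(IRanges::overlapsAny(mids, target))
}
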