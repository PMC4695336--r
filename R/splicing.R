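#' Count 5' splice-site boundary reads
#'
#' A boundary read spans the exon-intron junction at the transcript 5' end
#' of the intron with at least `minOverhang` nt on each side.  On the plus
#' strand the junction sits at the intron start; on the minus strand at the
#' intron end.  Only reads on the intron's strand are counted.
#'
#' @param alignments an [AlignmentSet-class].
#' @param intron single-range `GRanges` (a derived intron).
#' @param minOverhang minimum nt of the read on each side of the junction
#'   (default 3).
#' @return List with `count` and `rpm` (per million `totalMapped`).
#' @export
countBoundaryReads <- function(alignments, intron, minOverhang = 3L) {
    stopifnot(length(intron) == 1L)
    rd <- reads(alignments)
    st <- as.character(strand(intron))
    rd <- rd[strand(rd) == st &
                 as.character(seqnames(rd)) == as.character(seqnames(intron))]
    if (st == "-") {
        e <- end(intron)
        n <- sum(start(rd) <= e - minOverhang + 1L & end(rd) >= e + minOverhang)
    } else {
        s <- start(intron)
        n <- sum(start(rd) <= s - minOverhang & end(rd) >= s + minOverhang - 1L)
    }
    list(count = n, rpm = rpmValue(n, totalMapped(alignments)))
}

#' Fragments per kilobase per million mapped reads
#'
#' `FPKM = count * 1e9 / (length * totalMapped)`.
#'
#' @param count reads attributed to the region.
#' @param lengthNt region length in nt (> 0).
#' @param totalMapped library size (> 0).
#' @return FPKM value.
#' @examples
#' fpkmValue(10, 500, 1e6)  # 20
#' @export
fpkmValue <- function(count, lengthNt, totalMapped) {
    stopifnot(all(lengthNt > 0), all(totalMapped > 0))
    count * 1e9 / (lengthNt * totalMapped)
}

#' Per-intron retention metrics for one library
#'
#' For every intron of every intron-containing feature: the 5' splice-site
#' boundary reads per million, the intron FPKM, the FPKM over the union of
#' the gene's exons, and their ratio (`NA` when the exon FPKM is 0, with a
#' warning).  Reads are attributed to intron/exon space by midpoint so each
#' read counts once.
#'
#' @param annotation a [GenomeAnnotation-class].
#' @param alignments an [AlignmentSet-class] (pool replicates before calling
#'   if replicate-level resolution is not needed).
#' @param minOverhang see [countBoundaryReads()].
#' @return `data.frame` with one row per intron: `intron_id`, `gene_id`,
#'   `boundaryCount`, `boundaryRpm`, `intronFpkm`, `exonFpkm`, `ratio`,
#'   `libraryId`.
#' @export
intronMetrics <- function(annotation, alignments, minOverhang = 3L) {
    introns <- intronRanges(annotation)
    geneIds <- names(introns)[lengths(introns) > 0L]
    if (length(geneIds) == 0L) stop("annotation has no intron")
    total <- totalMapped(alignments)
    rd <- reads(alignments)
    mids <- GRanges(seqnames(rd), IRanges(readMidpoints(rd), width = 1L),
                    strand = strand(rd))
    flat <- unlist(introns[geneIds])
    nPer <- lengths(introns[geneIds])
    gid <- rep(geneIds, nPer)
    iid <- paste0(gid, ".I", unlist(lapply(nPer, seq_len)))
    # a boundary read fully covers the 2*minOverhang window centred on the
    # 5' splice site (intron start on +, intron end on -)
    neg <- as.character(strand(flat)) == "-"
    js <- ifelse(neg, end(flat) - minOverhang + 1L, start(flat) - minOverhang)
    jWin <- GRanges(seqnames(flat),
                    IRanges(js, width = 2L * minOverhang),
                    strand = strand(flat))
    bCount <- GenomicRanges::countOverlaps(jWin, rd, type = "within")
    inCount <- GenomicRanges::countOverlaps(flat, mids)
    exSub <- exonRanges(annotation)[geneIds]
    exCount <- GenomicRanges::countOverlaps(exSub, mids)
    exLen <- sum(width(exSub))
    exFpkm <- fpkmValue(exCount, exLen, total)[gid]
    inFpkm <- fpkmValue(inCount, width(flat), total)
    ratio <- ifelse(exFpkm > 0, inFpkm / exFpkm, NA_real_)
    res <- data.frame(intron_id = iid, gene_id = gid,
                      boundaryCount = bCount,
                      boundaryRpm = rpmValue(bCount, total),
                      intronFpkm = inFpkm, exonFpkm = exFpkm,
                      ratio = ratio, libraryId = libraryId(alignments),
                      row.names = NULL)
    if (anyNA(res$ratio))
        warning(sum(is.na(res$ratio)), " intron(s) with exon FPKM 0")
    res
}

#' Intron/exon FPKM ratio
#'
#' @param intronFpkm,exonFpkm FPKM values.
#' @return `intronFpkm / exonFpkm`, `NA` (with a warning) when
#'   `exonFpkm` is 0.
#' @export
intronExonRatio <- function(intronFpkm, exonFpkm) {
    out <- ifelse(exonFpkm > 0, intronFpkm / exonFpkm, NA_real_)
    if (anyNA(out)) warning("exon FPKM of 0 yields NA ratio")
    out
}

#' Classify intron-retention changes between WT and mutant
#'
#' An intron whose 5' splice-site boundary reads (per million) rise more
#' than `boundaryThreshold`-fold in the mutant is either *stabilized*
#' (precursor accumulates but splicing efficiency is unchanged: the
#' intron/exon FPKM ratio does not also rise) or a *splicing_defect* (the
#' ratio rises more than `ratioThreshold`-fold as well).  Anything below
#' the boundary threshold is *unchanged*.  A pseudocount of 0.1 RPM (and
#' 0.01 on the ratio) keeps folds finite.
#'
#' @param wt,mut `data.frame`s from [intronMetrics()] for the two
#'   conditions.
#' @param boundaryThreshold fold threshold on boundary RPM (default 2).
#' @param ratioThreshold fold threshold on the intron/exon ratio (default 2).
#' @param normFactors optional length-2 numeric `c(wt, mut)` of
#'   median-of-ratios size factors (e.g. from [estimateSizeFactors()] on the
#'   pooled count matrix).  Per-million normalisation alone is biased when
#'   the two transcriptomes differ in composition; dividing each library's
#'   RPM by its factor removes that bias.  `NULL` (default) uses raw RPM.
#' @param minCount minimum boundary-read evidence: a call other than
#'   `unchanged` requires the larger of the two boundary counts to reach
#'   this value (default 5; a 2-fold call from fewer reads is
#'   indistinguishable from Poisson noise).  Set to 0 to disable.
#' @return `data.frame` with `intron_id`, `gene_id`, `boundaryRpmWT`,
#'   `boundaryRpmMut`, `boundaryFold`, `ratioWT`, `ratioMut`, `ratioFold`,
#'   `call`.
#' @export
classifyIRChange <- function(wt, mut, boundaryThreshold = 2,
                             ratioThreshold = 2, normFactors = NULL,
                             minCount = 5L) {
    m <- merge(wt, mut, by = c("intron_id", "gene_id"),
               suffixes = c("WT", "Mut"))
    nf <- if (is.null(normFactors)) c(1, 1) else normFactors
    bFold <- (m$boundaryRpmMut / nf[2] + 0.1) /
        (m$boundaryRpmWT / nf[1] + 0.1)
    rWT <- ifelse(is.na(m$ratioWT), 0, m$ratioWT)
    rMut <- ifelse(is.na(m$ratioMut), 0, m$ratioMut)
    rFold <- (rMut + 0.01) / (rWT + 0.01)
    informative <- pmax(m$boundaryCountWT, m$boundaryCountMut) >= minCount
    call <- ifelse(bFold > boundaryThreshold & informative,
                   ifelse(rFold > ratioThreshold, "splicing_defect",
                          "stabilized"),
                   "unchanged")
    data.frame(intron_id = m$intron_id, gene_id = m$gene_id,
               boundaryRpmWT = m$boundaryRpmWT,
               boundaryRpmMut = m$boundaryRpmMut,
               boundaryFold = bFold,
               ratioWT = m$ratioWT, ratioMut = m$ratioMut,
               ratioFold = rFold, call = call)
}
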