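#' Signal downstream of a gene's annotated 3' end
#'
#' Measures reads-per-million in a window of `windowNt` nt past the 3' end
#' in transcript orientation, truncated at the first same-strand annotated
#' gene feature (intergenic features never truncate) so signal from an
#' adjacent gene cannot bleed in.  Reads are counted by midpoint.  A window
#' fully occluded by an adjacent same-strand gene yields `NA`.
#'
#' @param alignments an [AlignmentSet-class].
#' @param geneId feature id whose downstream region is measured.
#' @param annotation a [GenomeAnnotation-class].
#' @param windowNt window size, nt (default 300).
#' @return List with `window` (`GRanges`, the region actually used; zero
#'   width when occluded), `count` and `rpm` (`NA` when occluded).
#' @export
downstreamSignal <- function(alignments, geneId, annotation,
                             windowNt = 300L) {
    win <- .downstreamWindow(geneId, annotation, windowNt)
    if (length(win) == 0L)
        return(list(window = win, count = NA_integer_, rpm = NA_real_))
    n <- countMidpointsIn(reads(alignments), win)
    list(window = win, count = n, rpm = rpmValue(n, totalMapped(alignments)))
}

# the effective downstream window: [3' end + 1, 3' end + windowNt] in
# transcript orientation, truncated at the first same-strand gene feature;
# zero-length GRanges when fully occluded
.downstreamWindow <- function(geneId, annotation, windowNt = 300L) {
    feats <- featureRanges(annotation)
    gene <- feats[geneId]
    st <- as.character(strand(gene))
    if (!(st %in% c("+", "-"))) stop("gene must be stranded")
    chrom <- as.character(seqnames(gene))
    others <- feats[names(feats) != geneId &
                        feats$fclass != "intergenic" &
                        as.character(strand(feats)) == st &
                        as.character(seqnames(feats)) == chrom]
    if (st == "+") {
        ws <- end(gene) + 1L
        we <- end(gene) + windowNt
        lim <- seqlengths(gene)[chrom]
        if (!is.na(lim)) we <- min(we, lim)
        nxt <- start(others)[start(others) >= ws]
        if (length(nxt)) we <- min(we, min(nxt) - 1L)
    } else {
        we <- start(gene) - 1L
        ws <- start(gene) - windowNt
        ws <- max(ws, 1L)
        nxt <- end(others)[end(others) <= we]
        if (length(nxt)) ws <- max(ws, max(nxt) + 1L)
    }
    if (we < ws) return(GRanges())
    GRanges(chrom, IRanges(ws, we), strand = st,
            seqinfo = GenomeInfoDb::seqinfo(feats))
}

# vectorised downstream RPM for many genes against one library
.downstreamTable <- function(alignments, geneIds, annotation,
                             windowNt = 300L) {
    wins <- lapply(geneIds, .downstreamWindow, annotation = annotation,
                   windowNt = windowNt)
    occluded <- lengths(wins) == 0L
    rd <- reads(alignments)
    mids <- GRanges(seqnames(rd), IRanges(readMidpoints(rd), width = 1L),
                    strand = strand(rd))
    n <- rep(NA_integer_, length(geneIds))
    if (any(!occluded)) {
        winGr <- do.call(c, wins[!occluded])
        n[!occluded] <- GenomicRanges::countOverlaps(winGr, mids)
    }
    data.frame(gene_id = geneIds,
               count = n,
               rpm = rpmValue(n, totalMapped(alignments)),
               row.names = NULL)
}

#' Classify transcription readthrough downstream of 3' ends
#'
#' Genes whose downstream signal rises more than `rtThreshold`-fold in the
#' mutant fall into three classes keyed to the gene-body differential
#' expression call: class 1 -- the gene body itself is strongly up; class 2
#' -- body levels unchanged (leaky termination products normally removed);
#' class 3 -- body down while downstream signal rises, indicative of a
#' transcription termination defect.  Everything else is `none`.  A
#' pseudocount of 0.1 RPM keeps folds finite; `NA` downstream signal gives
#' `none` with `flagged = TRUE`.
#'
#' @param geneIds character vector of gene ids.
#' @param downstreamWT,downstreamMut numeric vectors of downstream RPM per
#'   gene (same order as `geneIds`).
#' @param bodyCall character vector of DE calls (`up`/`down`/`unchanged`)
#'   for the gene bodies, e.g. from [nbWaldTest()].
#' @param rtThreshold fold threshold on downstream RPM (default 2).
#' @param normFactors optional length-2 `c(wt, mut)` composition-correction
#'   factors, as in [classifyIRChange()].
#' @param countWT,countMut optional raw downstream read counts; when given,
#'   a class other than `none` additionally requires the larger of the two
#'   counts to reach `minCount`.
#' @param minCount minimum downstream-read evidence (default 5), as in
#'   [classifyIRChange()].
#' @return `data.frame` with `gene_id`, `downstreamRpmWT`,
#'   `downstreamRpmMut`, `downstreamFold`, `bodyCall`, `rtClass`
#'   (`"1"`, `"2"`, `"3"` or `"none"`), `flagged`.
#' @export
classifyReadthrough <- function(geneIds, downstreamWT, downstreamMut,
                                bodyCall, rtThreshold = 2,
                                normFactors = NULL, countWT = NULL,
                                countMut = NULL, minCount = 5L) {
    stopifnot(length(downstreamWT) == length(geneIds),
              length(downstreamMut) == length(geneIds),
              length(bodyCall) == length(geneIds))
    nf <- if (is.null(normFactors)) c(1, 1) else normFactors
    fold <- (downstreamMut / nf[2] + 0.1) / (downstreamWT / nf[1] + 0.1)
    flagged <- is.na(fold)
    rt <- rep("none", length(geneIds))
    over <- !is.na(fold) & fold > rtThreshold
    if (!is.null(countWT) && !is.null(countMut))
        over <- over & pmax(countWT, countMut) >= minCount
    rt[over & bodyCall == "up"] <- "1"
    rt[over & bodyCall == "unchanged"] <- "2"
    rt[over & bodyCall == "down"] <- "3"
    data.frame(gene_id = geneIds, downstreamRpmWT = downstreamWT,
               downstreamRpmMut = downstreamMut, downstreamFold = fold,
               bodyCall = bodyCall, rtClass = rt, flagged = flagged)
}
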