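#' Assign CRAC reads to annotated features
#'
#' Each read is assigned to exactly one feature it overlaps on the same
#' strand (intergenic features, which are unstranded, match reads of either
#' strand).  Ties are broken by maximal overlap, then by the smaller feature
#' (a specific annotation beats a broad one), then by lexicographic id.
#' Reads overlapping annotated features only on the opposite strand are
#' tallied separately as antisense counts -- antisense CRAC signal is real
#' (a handful of regulon genes show it) and must never be merged into sense
#' counts.
#'
#' @param alignments an [AlignmentSet-class].
#' @param annotation a [GenomeAnnotation-class].
#' @return A list with `counts` (named integer vector over all features,
#'   including intergenic ones), `antisense` (named vector of antisense-only
#'   tallies per gene feature) and `unassigned` (reads touching nothing).
#' @export
assignReadsToFeatures <- function(alignments, annotation) {
    rd <- reads(alignments)
    feats <- featureRanges(annotation)
    ids <- names(feats)
    counts <- stats::setNames(integer(length(ids)), ids)
    anti <- stats::setNames(integer(length(ids)), ids)
    if (length(rd) == 0L)
        return(list(counts = counts, antisense = anti, unassigned = 0L))
    # strand-sensitive overlap: "*" features match both strands
    hits <- GenomicRanges::findOverlaps(rd, feats)
    if (length(hits)) {
        q <- S4Vectors::queryHits(hits)
        s <- S4Vectors::subjectHits(hits)
        ov <- width(IRanges::pintersect(ranges(rd)[q], ranges(feats)[s]))
        o <- order(q, -ov, width(feats)[s], ids[s])
        best <- !duplicated(q[o])
        pick <- s[o][best]
        tab <- table(factor(ids[pick], levels = ids))
        counts <- counts + as.integer(tab)
        names(counts) <- ids
    }
    senseHit <- unique(S4Vectors::queryHits(hits))
    rest <- setdiff(seq_along(rd), senseHit)
    unassigned <- 0L
    if (length(rest)) {
        hAnti <- GenomicRanges::findOverlaps(rd[rest], feats,
                                             ignore.strand = TRUE)
        if (length(hAnti)) {
            q <- S4Vectors::queryHits(hAnti)
            s <- S4Vectors::subjectHits(hAnti)
            ov <- width(IRanges::pintersect(ranges(rd[rest])[q],
                                            ranges(feats)[s]))
            o <- order(q, -ov, width(feats)[s], ids[s])
            best <- !duplicated(q[o])
            pick <- s[o][best]
            tab <- table(factor(ids[pick], levels = ids))
            anti <- anti + as.integer(tab)
            names(anti) <- ids
        }
        unassigned <- length(rest) - length(unique(S4Vectors::queryHits(hAnti)))
    }
    list(counts = counts, antisense = anti, unassigned = unassigned)
}

#' Call read clusters from stacked CRAC coverage
#'
#' A cluster is a maximal run of per-base, same-strand read coverage at or
#' above `minHeight`; runs separated by fewer than `mergeGap` uncovered
#' bases are merged, and clusters shorter than `minLength` are discarded.
#' When a genome is supplied, the sense-strand sequence of each cluster is
#' attached (minus-strand clusters are reverse-complemented) so the result
#' can feed straight into [kmerEnrichment()].
#'
#' @param alignments an [AlignmentSet-class].
#' @param genome optional `DNAStringSet`.
#' @param minHeight minimum read depth supporting a cluster (default 5).
#' @param minLength minimum cluster width in nt (default 12).
#' @param mergeGap clusters separated by a gap smaller than this many nt are
#'   merged (default 3).
#' @return `GRanges` of clusters with metadata columns `height`, `nReads`
#'   and (if a genome was given) `seq`.
#' @export
callClusters <- function(alignments, genome = NULL, minHeight = 5L,
                         minLength = 12L, mergeGap = 3L) {
    rd <- reads(alignments)
    out <- GRanges()
    for (st in c("+", "-")) {
        sub <- rd[strand(rd) == st]
        if (length(sub) == 0L) next
        cov <- GenomicRanges::coverage(sub)
        for (ch in names(cov)) {
            sl <- IRanges::slice(cov[[ch]], lower = minHeight,
                                 rangesOnly = TRUE)
            if (length(sl) == 0L) next
            sl <- IRanges::reduce(sl, min.gapwidth = mergeGap)
            sl <- sl[width(sl) >= minLength]
            if (length(sl) == 0L) next
            height <- max(IRanges::Views(cov[[ch]], sl))
            gr <- GRanges(ch, sl, strand = st)
            gr$height <- as.integer(height)
            gr$nReads <- GenomicRanges::countOverlaps(gr, sub)
            suppressWarnings(out <- c(out, gr))
        }
    }
    if (!is.null(genome) && length(out))
        out$seq <- as.character(fetchSequence(genome, out))
    out
}

#' Hexamer (k-mer) enrichment in clusters against shuffled backgrounds
#'
#' Counts every overlapping k-mer occurrence across the cluster sequences,
#' then rebuilds the count `nShuffles` times after independently
#' mononucleotide-shuffling each cluster sequence.  The background preserves
#' per-cluster base composition, so a k-mer can only score by arrangement,
#' not by composition.  For each k-mer with at least one observed
#' occurrence:
#' \itemize{
#'   \item `z` = (observed - background mean) / background SD (`NA` when the
#'     SD is 0, e.g. a homopolymer cluster whose count is shuffle-invariant);
#'   \item `pEmp` = (1 + # shuffles with count >= observed) / (1 + nShuffles),
#'     the add-one empirical p-value, never exactly 0;
#'   \item `q` = Benjamini-Hochberg adjusted `pEmp` across reported k-mers.
#' }
#' Rows are ordered by decreasing `z`.
#'
#' @param clusters result of [callClusters()] with a `seq` column, or a
#'   character vector / `DNAStringSet` of cluster sequences.
#' @param k k-mer length (default 6, the length of the DSR hexamer).
#' @param nShuffles shuffles per cluster (default 100).
#' @param seed optional integer seed for the shuffles.
#' @return `data.frame` with columns `kmer`, `observed`, `bgMean`, `bgSd`,
#'   `z`, `pEmp`, `q`.
#' @export
kmerEnrichment <- function(clusters, k = 6L, nShuffles = 100L, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    seqs <- if (is(clusters, "GRanges")) clusters$seq else as.character(clusters)
    seqs <- seqs[!is.na(seqs) & nchar(seqs) >= k]
    if (length(seqs) == 0L) stop("no cluster sequence of length >= k")
    dss <- DNAStringSet(seqs)
    observed <- oligonucleotideFrequency(dss, width = k,
                                         simplify.as = "collapse")
    chars <- strsplit(seqs, "", fixed = TRUE)
    bg <- matrix(0, nrow = nShuffles, ncol = length(observed),
                 dimnames = list(NULL, names(observed)))
    for (s in seq_len(nShuffles)) {
        shuf <- vapply(chars, function(x) paste(sample(x), collapse = ""), "")
        bg[s, ] <- oligonucleotideFrequency(DNAStringSet(shuf), width = k,
                                            simplify.as = "collapse")
    }
    keep <- observed > 0L
    obs <- observed[keep]
    bgk <- bg[, keep, drop = FALSE]
    bgMean <- colMeans(bgk)
    bgSd <- apply(bgk, 2L, stats::sd)
    z <- ifelse(bgSd > 0, (obs - bgMean) / bgSd, NA_real_)
    pEmp <- (1 + colSums(bgk >= rep(obs, each = nrow(bgk)))) / (1 + nShuffles)
    res <- data.frame(kmer = names(obs), observed = as.integer(obs),
                      bgMean = bgMean, bgSd = bgSd, z = z, pEmp = pEmp,
                      q = bhAdjust(pEmp), row.names = NULL)
    res[order(-res$z, res$pEmp, na.last = TRUE), , drop = FALSE]
}

#' Abundance-normalised CRAC enrichment
#'
#' Normalises uniquely mapped cDNA counts to transcript abundance:
#' `enrichment = cracCount / (abundance + pseudocount)`.  The pseudocount
#' bounds the ratio for transcripts undetected in the abundance table;
#' features entirely missing from the table get `NA` abundance, are excluded
#' from ranking, and their number is reported with a message.
#'
#' @param counts named numeric vector of per-feature CRAC counts (e.g.
#'   `assignReadsToFeatures(...)$counts`).
#' @param abundance named numeric vector of transcript abundances (oligo-dT
#'   or total RNA quantification).
#' @param pseudocount added to abundance before division (default 0.1).
#' @return `data.frame` with `feature_id`, `cracCount`, `abundance`,
#'   `enrichment`, sorted by decreasing enrichment (NA abundance last).
#' @export
computeEnrichment <- function(counts, abundance, pseudocount = 0.1) {
    ab <- abundance[match(names(counts), names(abundance))]
    if (any(is.na(ab)))
        message(sum(is.na(ab)),
                " feature(s) missing from the abundance table")
    enr <- ifelse(is.na(ab), NA_real_, counts / (ab + pseudocount))
    res <- data.frame(feature_id = names(counts),
                      cracCount = as.numeric(counts),
                      abundance = as.numeric(ab),
                      enrichment = enr, row.names = NULL)
    res[order(-res$enrichment, na.last = TRUE), , drop = FALSE]
}

#' Classify transcripts as pA+ or pA-
#'
#' Compares per-feature abundance in an oligo-dT-selected library with
#' abundance in total RNA.  Both tables are first normalised by their median
#' over the shared features (so the classification is invariant to scaling
#' either library), then the ratio `R = oligo-dT / total` is thresholded at
#' the classical 5.0-fold cutoff.  The default reading is that depletion
#' from the oligo-dT fraction defines pA- (`R <= 1/cutoff`); set
#' `direction = "enrichment"` for the opposite convention, where pA+
#' requires `R >= cutoff`.
#'
#' @param abundancePolyA named abundances from the oligo-dT-selected fraction.
#' @param abundanceTotal named abundances from total RNA.
#' @param cutoff fold cutoff, must be > 1 (default 5.0).
#' @param direction `"depletion"` (default) or `"enrichment"`, see above.
#' @return Named character vector over the union of features: `"pA+"`,
#'   `"pA-"`, or `NA` for features absent from either table.
#' @export
classifyPolyA <- function(abundancePolyA, abundanceTotal, cutoff = 5,
                          direction = c("depletion", "enrichment")) {
    direction <- match.arg(direction)
    stopifnot(cutoff > 1)
    shared <- intersect(names(abundancePolyA), names(abundanceTotal))
    if (length(shared) == 0L) stop("no shared features between tables")
    pa <- abundancePolyA / stats::median(abundancePolyA[shared])
    tot <- abundanceTotal / stats::median(abundanceTotal[shared])
    all <- union(names(abundancePolyA), names(abundanceTotal))
    R <- pa[match(all, names(pa))] / tot[match(all, names(tot))]
    status <- rep(NA_character_, length(all))
    ok <- !is.na(R)
    status[ok] <- if (direction == "depletion")
        ifelse(R[ok] <= 1 / cutoff, "pA-", "pA+")
    else
        ifelse(R[ok] >= cutoff, "pA+", "pA-")
    stats::setNames(status, all)
}

#' Fraction of a feature's CRAC reads bound within its introns
#'
#' A read belongs to the intron (or the feature) when its midpoint falls
#' inside; each read therefore counts once even when it spans a junction.
#'
#' @param featureId id of an intron-containing feature.
#' @param annotation a [GenomeAnnotation-class].
#' @param alignments an [AlignmentSet-class].
#' @return Fraction in `[0,1]`, or `NA` if no read midpoint falls in the
#'   feature.
#' @export
intronicBindingFraction <- function(featureId, annotation, alignments) {
    intr <- intronRanges(annotation)[[featureId]]
    if (is.null(intr)) stop("unknown feature: ", featureId)
    if (length(intr) == 0L)
        stop("feature '", featureId, "' has no intron")
    feat <- featureRanges(annotation)[featureId]
    rd <- reads(alignments)
    rd <- rd[strand(rd) == as.character(strand(feat))]
    nFeat <- countMidpointsIn(rd, feat)
    if (nFeat == 0L) return(NA_real_)
    countMidpointsIn(rd, intr) / nFeat
}
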