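#' @import methods
#' @importFrom GenomicRanges GRanges GRangesList
#' @importFrom S4Vectors mcols mcols<-
NULL

.FEATURE_CLASSES <- c("mRNA", "ncRNA", "snRNA", "snoRNA", "rRNA", "tRNA",
                      "pseudogene", "intergenic")

#' Stranded gene models with exons, derived introns and feature classes
#'
#' A `GenomeAnnotation` holds one range per feature (gene-level span) together
#' with its exon structure and the introns derived from the gaps between
#' consecutive exons.  Feature classes follow the transcript categories used
#' in fission-yeast annotation: mRNA, ncRNA, sn/snoRNA, rRNA, tRNA,
#' pseudogene, and intergenic regions (the un-annotated gaps between genes,
#' which are quantified as features in their own right).
#'
#' @slot features [GenomicRanges::GRanges] of gene-level spans, named by
#'   feature id, with an `fclass` metadata column.
#' @slot exons [GenomicRanges::GRangesList] of exon ranges per feature,
#'   parallel to `features`.
#' @slot introns [GenomicRanges::GRangesList] of intron ranges per feature
#'   (gaps between consecutive exons, in genomic order; empty for single-exon
#'   features).
#'
#' @seealso [readAnnotation()], [featureRanges()], [intronRanges()]
#' @export
setClass("GenomeAnnotation",
         slots = c(features = "GRanges",
                   exons    = "GRangesList",
                   introns  = "GRangesList"))

setValidity("GenomeAnnotation", function(object) {
    msg <- character()
    ids <- names(object@features)
    if (is.null(ids) || anyDuplicated(ids))
        msg <- c(msg, "feature ids must be present and unique")
    if (!"fclass" %in% colnames(mcols(object@features)))
        msg <- c(msg, "features must carry an 'fclass' metadata column")
    else if (!all(object@features$fclass %in% .FEATURE_CLASSES))
        msg <- c(msg, "unknown feature class in 'fclass'")
    if (!identical(names(object@exons), ids) ||
        !identical(names(object@introns), ids))
        msg <- c(msg, "exons and introns must be named parallel to features")
    lens <- GenomeInfoDb::seqlengths(object@features)
    if (any(!is.na(lens))) {
        ends <- BiocGenerics::end(object@features)
        lim <- lens[as.character(GenomeInfoDb::seqnames(object@features))]
        if (any(!is.na(lim) & ends > lim))
            msg <- c(msg, "feature beyond chromosome bounds")
    }
    if (length(msg)) msg else TRUE
})

#' Stranded read intervals with a per-million denominator
#'
#' An `AlignmentSet` is the reduced representation of a sequencing library
#' used throughout the package: one stranded genomic interval per uniquely
#' mapped read, plus the total number of uniquely mapped reads in the
#' library.  The total is kept separately from `length(reads(x))` because
#' reads outside the annotated chromosomes may be dropped at import while the
#' per-million normalisation (RPM/FPKM) must still use the full library size.
#'
#' @slot reads [GenomicRanges::GRanges], one range per uniquely mapped read.
#' @slot totalMapped single number, total uniquely mapped reads in the
#'   library; denominator for reads-per-million.
#' @slot libraryId single string identifying the library.
#'
#' @seealso [readAlignments()], [reads()], [totalMapped()]
#' @export
setClass("AlignmentSet",
         slots = c(reads = "GRanges",
                   totalMapped = "numeric",
                   libraryId = "character"))

setValidity("AlignmentSet", function(object) {
    msg <- character()
    if (length(object@totalMapped) != 1L || is.na(object@totalMapped) ||
        object@totalMapped < length(object@reads))
        msg <- c(msg, "totalMapped must be a single number >= number of reads")
    if (length(object@libraryId) != 1L)
        msg <- c(msg, "libraryId must be a single string")
    lens <- GenomeInfoDb::seqlengths(object@reads)
    if (any(!is.na(lens)) && length(object@reads)) {
        lim <- lens[as.character(GenomeInfoDb::seqnames(object@reads))]
        if (any(!is.na(lim) & BiocGenerics::end(object@reads) > lim))
            msg <- c(msg, "read beyond chromosome bounds")
    }
    if (length(msg)) msg else TRUE
})

#' Construct an AlignmentSet
#'
#' @param reads `GRanges` of uniquely mapped read intervals (strand set).
#' @param totalMapped total uniquely mapped reads in the library; defaults to
#'   `length(reads)`.
#' @param libraryId library identifier.
#' @return An [AlignmentSet-class] object.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1:3, width = 10), "+")
#' AlignmentSet(gr, libraryId = "demo")
#' @export
AlignmentSet <- function(reads, totalMapped = length(reads),
                         libraryId = "library") {
    new("AlignmentSet", reads = reads, totalMapped = as.numeric(totalMapped),
        libraryId = libraryId)
}

#' Simulation configuration for the synthetic benchmark
#'
#' Bundles every knob of the synthetic-data generator: genome and annotation
#' geometry, planted CRAC binding (DSR-motif copies inside "decay-promoting"
#' introns), RNA-seq depth and negative-binomial dispersion, planted fold
#' changes in the deletion mutant, planted intron-retention and readthrough
#' classes, and the pA- fraction of ncRNAs.  Build one with [simConfig()],
#' which supplies the default study design.
#'
#' @seealso [simConfig()], [simulateGenome()]
#' @export
setClass("SimConfig",
         slots = c(seed = "integer",
                   nChrom = "integer", chromLength = "integer",
                   nMRNA = "integer", nNcRNA = "integer", nSnoRNA = "integer",
                   nSnRNA = "integer", nPseudogene = "integer",
                   fractionIntronContaining = "numeric",
                   nDecayIntrons = "integer", motifCopiesRange = "integer",
                   nExonicTargets = "integer",
                   nSplicingDefect = "integer",
                   nExtraUp = "integer", nExtraDown = "integer",
                   nReadthroughPerClass = "integer",
                   cracDepth = "integer", rnaseqDepth = "integer",
                   readLength = "integer", nReplicates = "integer",
                   nbDispersion = "numeric",
                   log2fcUp = "numeric", log2fcDown = "numeric",
                   stabilizationFold = "numeric",
                   splicingDefectFactor = "numeric",
                   precursorFracWT = "numeric",
                   readthroughFrac = "numeric",
                   targetAffinity = "numeric", cracSigma = "numeric",
                   pAMinusFraction = "numeric", pADepletion = "numeric"))

setValidity("SimConfig", function(object) {
    msg <- character()
    cnt <- c(object@nChrom, object@chromLength, object@nMRNA, object@nNcRNA,
             object@cracDepth, object@rnaseqDepth, object@readLength,
             object@nReplicates)
    if (any(cnt <= 0L)) msg <- c(msg, "counts and depths must be > 0")
    if (object@nbDispersion <= 0) msg <- c(msg, "nbDispersion must be > 0")
    if (object@fractionIntronContaining < 0 ||
        object@fractionIntronContaining > 1)
        msg <- c(msg, "fractionIntronContaining must lie in [0,1]")
    if (object@pAMinusFraction < 0 || object@pAMinusFraction > 1)
        msg <- c(msg, "pAMinusFraction must lie in [0,1]")
    if (length(object@motifCopiesRange) != 2L ||
        object@motifCopiesRange[1] < 1L)
        msg <- c(msg, "motifCopiesRange must be c(min, max) with min >= 1")
    if (length(msg)) msg else TRUE
})

#' @describeIn SimConfig-class Constructor with the default study design:
#'   2 chromosomes of 250 kb, 150 genes (90 mRNA, 40 ncRNA, 10 snoRNA,
#'   5 snRNA, 5 pseudogene), half of mRNAs intron-containing, 12
#'   decay-intron genes carrying 1-6 DSR motif copies in one intron, 50k CRAC
#'   reads, 200k RNA-seq reads per library in triplicate, NB dispersion 0.05.
#'
#' @param seed integer seed controlling every random draw of the generator.
#' @param nChrom,chromLength genome geometry (chromosomes and their length, nt).
#' @param nMRNA,nNcRNA,nSnoRNA,nSnRNA,nPseudogene genes per feature class.
#' @param fractionIntronContaining fraction of mRNAs given introns.
#' @param nDecayIntrons genes whose widest intron receives planted
#'   T(T/C/G)AAAC motif copies and a stabilised-precursor phenotype.
#' @param motifCopiesRange integer range of motif copies per target.
#' @param nExonicTargets intronless genes (mRNA or ncRNA) that carry planted
#'   motif copies in their longest exon -- the bulk of the binding targets,
#'   mirroring a regulon in which only a minority of bound motifs are
#'   intronic.
#' @param nSplicingDefect intron-containing genes planted with a genuine
#'   splicing defect (intron/exon ratio increase) in the mutant.
#' @param nExtraUp,nExtraDown additional intronless genes planted up/down.
#' @param nReadthroughPerClass genes planted per readthrough class (1,2,3).
#' @param cracDepth,rnaseqDepth reads per CRAC library / per RNA-seq library.
#' @param readLength read length, nt.
#' @param nReplicates RNA-seq replicates per condition.
#' @param nbDispersion negative-binomial dispersion (variance = mu + disp*mu^2).
#' @param log2fcUp,log2fcDown planted log2 fold changes (mutant vs WT).
#' @param stabilizationFold fold stabilisation of decay-intron precursors in
#'   the mutant (drives both the gene-level up-regulation and the boundary
#'   read increase).
#' @param splicingDefectFactor factor by which the precursor fraction rises
#'   in the mutant for splicing-defect genes.
#' @param precursorFracWT fraction of a gene's reads drawn from unspliced
#'   precursor in the wild type.
#' @param readthroughFrac downstream reads in the mutant as a fraction of the
#'   gene-body count, for readthrough genes.
#' @param targetAffinity CRAC affinity multiplier of motif-containing targets
#'   over the baseline of 1.
#' @param cracSigma SD (nt) of CRAC read starts around planted motifs.
#' @param pAMinusFraction fraction of ncRNAs planted pA-.
#' @param pADepletion fold depletion of pA- transcripts in the oligo-dT
#'   abundance table.
#' @return A validated `SimConfig`.
#' @examples
#' cfg <- simConfig(seed = 1, cracDepth = 5000L)
#' @export
simConfig <- function(seed = 1L,
                      nChrom = 2L, chromLength = 250000L,
                      nMRNA = 90L, nNcRNA = 40L, nSnoRNA = 10L,
                      nSnRNA = 5L, nPseudogene = 5L,
                      fractionIntronContaining = 0.5,
                      nDecayIntrons = 12L, motifCopiesRange = c(1L, 6L),
                      nExonicTargets = 30L,
                      nSplicingDefect = 5L,
                      nExtraUp = 10L, nExtraDown = 15L,
                      nReadthroughPerClass = 5L,
                      cracDepth = 50000L, rnaseqDepth = 200000L,
                      readLength = 40L, nReplicates = 3L,
                      nbDispersion = 0.05,
                      log2fcUp = 2, log2fcDown = -2,
                      stabilizationFold = 5,
                      splicingDefectFactor = 5,
                      precursorFracWT = 0.1,
                      readthroughFrac = 0.3,
                      targetAffinity = 50, cracSigma = 15,
                      pAMinusFraction = 0.5, pADepletion = 20) {
    new("SimConfig", seed = as.integer(seed),
        nChrom = as.integer(nChrom), chromLength = as.integer(chromLength),
        nMRNA = as.integer(nMRNA), nNcRNA = as.integer(nNcRNA),
        nSnoRNA = as.integer(nSnoRNA), nSnRNA = as.integer(nSnRNA),
        nPseudogene = as.integer(nPseudogene),
        fractionIntronContaining = fractionIntronContaining,
        nDecayIntrons = as.integer(nDecayIntrons),
        motifCopiesRange = as.integer(motifCopiesRange),
        nExonicTargets = as.integer(nExonicTargets),
        nSplicingDefect = as.integer(nSplicingDefect),
        nExtraUp = as.integer(nExtraUp), nExtraDown = as.integer(nExtraDown),
        nReadthroughPerClass = as.integer(nReadthroughPerClass),
        cracDepth = as.integer(cracDepth),
        rnaseqDepth = as.integer(rnaseqDepth),
        readLength = as.integer(readLength),
        nReplicates = as.integer(nReplicates),
        nbDispersion = nbDispersion,
        log2fcUp = log2fcUp, log2fcDown = log2fcDown,
        stabilizationFold = stabilizationFold,
        splicingDefectFactor = splicingDefectFactor,
        precursorFracWT = precursorFracWT,
        readthroughFrac = readthroughFrac,
        targetAffinity = targetAffinity, cracSigma = cracSigma,
        pAMinusFraction = pAMinusFraction, pADepletion = pADepletion)
}

setMethod("show", "GenomeAnnotation", function(object) {
    tab <- table(object@features$fclass)
    cat("GenomeAnnotation with", length(object@features), "features\n")
    cat("  classes:",
        paste(names(tab), as.integer(tab), sep = ":", collapse = " "), "\n")
    nInt <- sum(lengths(object@introns) > 0)
    cat("  intron-containing features:", nInt, "\n")
})

setMethod("show", "AlignmentSet", function(object) {
    cat("AlignmentSet '", object@libraryId, "': ", length(object@reads),
        " reads kept, ", format(object@totalMapped, big.mark = ","),
        " total mapped\n", sep = "")
})

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig: seed", object@seed, "|", object@nChrom, "chrom x",
        object@chromLength, "nt |",
        object@nMRNA + object@nNcRNA + object@nSnoRNA + object@nSnRNA +
            object@nPseudogene, "genes |",
        object@nDecayIntrons, "decay introns |",
        object@cracDepth, "CRAC reads |", object@rnaseqDepth,
        "RNA-seq reads x", object@nReplicates, "reps\n")
})
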