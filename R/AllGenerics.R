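#' Accessors for GenomeAnnotation and AlignmentSet
#'
#' `featureRanges()` returns the gene-level spans (named `GRanges` with an
#' `fclass` column), `exonRanges()`/`intronRanges()` the per-feature exon and
#' intron structure (`GRangesList`), `featureClass()` the named class vector,
#' and `chromLengths()` the chromosome lengths.  `reads()`, `totalMapped()`
#' and `libraryId()` access the read intervals, the per-million denominator
#' and the identifier of an [AlignmentSet-class].
#'
#' @param x a [GenomeAnnotation-class] or [AlignmentSet-class] object.
#' @return See the individual accessor descriptions.
#' @name annotation-accessors
#' @examples
#' sim <- simulateGenome(simConfig(seed = 1, nMRNA = 10L, nNcRNA = 4L,
#'                                 nSnoRNA = 0L, nSnRNA = 0L,
#'                                 nPseudogene = 0L, nDecayIntrons = 2L,
#'                                 nSplicingDefect = 1L, nExtraUp = 1L,
#'                                 nExtraDown = 1L, nReadthroughPerClass = 1L,
#'                                 chromLength = 60000L))
#' length(featureRanges(sim$annotation))
NULL

#' @rdname annotation-accessors
#' @export
setGeneric("featureRanges", function(x) standardGeneric("featureRanges"))
#' @rdname annotation-accessors
#' @export
setGeneric("exonRanges", function(x) standardGeneric("exonRanges"))
#' @rdname annotation-accessors
#' @export
setGeneric("intronRanges", function(x) standardGeneric("intronRanges"))
#' @rdname annotation-accessors
#' @export
setGeneric("featureClass", function(x) standardGeneric("featureClass"))
#' @rdname annotation-accessors
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))
#' @rdname annotation-accessors
#' @export
setGeneric("reads", function(x) standardGeneric("reads"))
#' @rdname annotation-accessors
#' @export
setGeneric("totalMapped", function(x) standardGeneric("totalMapped"))
#' @rdname annotation-accessors
#' @export
setGeneric("libraryId", function(x) standardGeneric("libraryId"))

#' @rdname annotation-accessors
setMethod("featureRanges", "GenomeAnnotation", function(x) x@features)
#' @rdname annotation-accessors
setMethod("exonRanges", "GenomeAnnotation", function(x) x@exons)
#' @rdname annotation-accessors
setMethod("intronRanges", "GenomeAnnotation", function(x) x@introns)
#' @rdname annotation-accessors
setMethod("featureClass", "GenomeAnnotation", function(x) {
    stats::setNames(x@features$fclass, names(x@features))
})
#' @rdname annotation-accessors
setMethod("chromLengths", "GenomeAnnotation", function(x) {
    GenomeInfoDb::seqlengths(x@features)
})
#' @rdname annotation-accessors
setMethod("reads", "AlignmentSet", function(x) x@reads)
#' @rdname annotation-accessors
setMethod("totalMapped", "AlignmentSet", function(x) x@totalMapped)
#' @rdname annotation-accessors
setMethod("libraryId", "AlignmentSet", function(x) x@libraryId)
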