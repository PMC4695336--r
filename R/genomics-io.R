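#' @importFrom BiocGenerics start end width strand strand<- sort
#' @importFrom GenomeInfoDb seqnames seqlengths seqlengths<- seqlevels
#'   seqlevels<- seqinfo
#' @importFrom IRanges IRanges ranges overlapsAny
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   reverseComplement subseq oligonucleotideFrequency
NULL

#' Construct a GenomeAnnotation from feature spans and exon structure
#'
#' Introns are derived as the gaps between consecutive exons; the feature
#' span is (re)set to the range covered by its exons so that
#' exons + introns tile the span exactly.
#'
#' @param features named `GRanges` of features with an `fclass` metadata
#'   column (one of mRNA, ncRNA, snRNA, snoRNA, rRNA, tRNA, pseudogene,
#'   intergenic).
#' @param exons named `GRangesList` of exons per feature.  Features absent
#'   from `exons` are treated as single-exon (exon = span).
#' @param seqlengths optional named chromosome lengths.
#' @return A [GenomeAnnotation-class].
#' @export
GenomeAnnotation <- function(features, exons = NULL, seqlengths = NULL) {
    ids <- names(features)
    if (is.null(ids)) stop("features must be named by feature id")
    if (is.null(exons)) exons <- GRangesList()
    if (!is(exons, "GRangesList")) exons <- GRangesList(as.list(exons))
    have <- intersect(ids, names(exons))
    miss <- setdiff(ids, names(exons))
    exl <- exons[have]
    if (length(miss)) {
        single <- GenomicRanges::granges(features[miss])
        mcols(single) <- NULL
        exl <- c(exl, S4Vectors::split(single, factor(miss, levels = miss)))
    }
    exl <- exl[ids]
    flat <- unlist(exl, use.names = FALSE)
    mcols(flat) <- NULL
    exl <- IRanges::relist(flat, exl)
    exl <- BiocGenerics::sort(exl)
    bad <- !IRanges::isDisjoint(exl)
    if (any(bad))
        stop("overlapping exons within feature '",
             ids[which(bad)[1]], "'")
    spanL <- BiocGenerics::unlist(range(exl), use.names = FALSE)
    if (length(spanL) != length(ids))
        stop("exons of one feature must share a chromosome and strand")
    spans <- spanL
    names(spans) <- ids
    strand(spans) <- strand(features)
    intrL <- GenomicRanges::psetdiff(spans, exl)
    spans$fclass <- features$fclass
    intrl <- intrL
    names(intrl) <- ids
    if (!is.null(seqlengths)) {
        for (nm in c("spans", "exl", "intrl")) {
            obj <- get(nm)
            GenomeInfoDb::seqlevels(obj) <- names(seqlengths)
            seqlengths(obj) <- seqlengths
            assign(nm, obj)
        }
    }
    new("GenomeAnnotation", features = spans, exons = exl, introns = intrl)
}

#' Derive introns from an ordered set of exons
#'
#' Returns the gaps between consecutive exons in genomic order; a single
#' exon yields no intron.  Exon order on the minus strand is still genomic
#' here -- transcript orientation only matters downstream (e.g. for the 5'
#' splice site, which sits at the genomic *end* of a minus-strand intron).
#'
#' @param exons `GRanges` (one feature's exons) or `IRanges`; must be
#'   non-overlapping.
#' @return Object of the same class as `exons` holding the introns.
#' @examples
#' ex <- IRanges::IRanges(start = c(1, 81, 151), end = c(50, 120, 200))
#' deriveIntrons(ex)  # [51,80] and [121,150]
#' @export
deriveIntrons <- function(exons) {
    isGR <- is(exons, "GRanges")
    ir <- if (isGR) ranges(exons) else exons
    if (length(ir) == 0L) stop("at least one exon required")
    o <- order(start(ir))
    ir <- ir[o]
    if (length(ir) > 1L &&
        any(start(ir)[-1L] <= end(ir)[-length(ir)]))
        stop("overlapping exons")
    gapIr <- IRanges::gaps(ir, start = min(start(ir)), end = max(end(ir)))
    if (!isGR) return(gapIr)
    out <- GenomicRanges::GRanges(rep(seqnames(exons)[1], length(gapIr)),
                                  gapIr,
                                  strand = rep(strand(exons)[1],
                                               length(gapIr)),
                                  seqinfo = GenomeInfoDb::seqinfo(exons))
    out
}

#' Read a genome FASTA
#'
#' @param path FASTA file.
#' @return A `DNAStringSet` named by the first token of each header.
#' @export
readGenome <- function(path) {
    g <- readDNAStringSet(path)
    names(g) <- sub("\\s.*$", "", names(g))
    g
}

#' Read a GFF3 annotation
#'
#' Accepts the dialect used throughout the package: gene-level records carry
#' `ID=` and a feature class in the `fclass=` attribute (falling back to the
#' GFF3 type column when it already names a known class); exon records carry
#' `Parent=`.  Records with an unknown feature class, and features whose
#' exons overlap, are rejected with a message.  Features without exon
#' children are treated as single-exon.
#'
#' @param path GFF3 file (1-based closed coordinates, converted on import).
#' @param genome optional `DNAStringSet`; its widths become the chromosome
#'   bounds against which features are validated.
#' @return A [GenomeAnnotation-class].
#' @export
readAnnotation <- function(path, genome = NULL) {
    gff <- rtracklayer::import.gff3(path)
    type <- as.character(gff$type)
    isExon <- type == "exon"
    feats <- gff[!isExon]
    ids <- as.character(feats$ID)
    if (anyNA(ids)) stop("gene record without ID attribute")
    fc <- rep(NA_character_, length(feats))
    if ("fclass" %in% colnames(mcols(feats)))
        fc <- as.character(feats$fclass)
    ftype <- as.character(feats$type)
    useType <- is.na(fc) & ftype %in% .FEATURE_CLASSES
    fc[useType] <- ftype[useType]
    bad <- is.na(fc) | !(fc %in% .FEATURE_CLASSES)
    if (any(bad)) {
        message("rejected ", sum(bad),
                " record(s) with unknown feature class: ",
                paste(utils::head(ids[bad], 5), collapse = ", "))
        feats <- feats[!bad]; ids <- ids[!bad]; fc <- fc[!bad]
    }
    exRows <- gff[isExon]
    exParent <- vapply(as.list(exRows$Parent), function(x)
        if (length(x)) x[1] else NA_character_, "")
    exl <- S4Vectors::split(GenomicRanges::granges(exRows), exParent)
    # reject features whose exon children overlap one another
    ovl <- vapply(seq_along(ids), function(i) {
        id <- ids[i]
        id %in% names(exl) && !IRanges::isDisjoint(exl[[id]])
    }, logical(1))
    if (any(ovl)) {
        message("rejected ", sum(ovl),
                " feature(s) with overlapping exons: ",
                paste(utils::head(ids[ovl], 5), collapse = ", "))
        feats <- feats[!ovl]; ids <- ids[!ovl]; fc <- fc[!ovl]
    }
    spans <- GenomicRanges::granges(feats)
    names(spans) <- ids
    spans$fclass <- fc
    sl <- seqlengths(gff)
    if (all(is.na(sl))) {
        # rtracklayer does not parse ##sequence-region pragmas
        hdr <- grep("^##sequence-region", readLines(path, n = 1000L),
                    value = TRUE)
        if (length(hdr)) {
            parts <- strsplit(hdr, "[[:space:]]+")
            sl <- stats::setNames(
                vapply(parts, function(x) as.numeric(x[4]), 0),
                vapply(parts, function(x) x[2], ""))
            sl <- sl[names(sl) %in% GenomeInfoDb::seqlevels(gff)]
            if (length(sl) == 0L) sl <- NA
        }
    }
    if (!is.null(genome)) sl <- stats::setNames(width(genome), names(genome))
    GenomeAnnotation(spans, exl[names(exl) %in% ids],
                     seqlengths = if (all(is.na(sl))) NULL else sl)
}

#' Write a GenomeAnnotation as GFF3
#'
#' Inverse of [readAnnotation()]: gene rows with `ID=` and `fclass=`, exon
#' rows with `Parent=` (only for multi-exon features; single-exon features
#' round-trip through their span).
#'
#' @param annotation a [GenomeAnnotation-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeAnnotation <- function(annotation, path) {
    feats <- featureRanges(annotation)
    g <- GenomicRanges::granges(feats)
    g$type <- "gene"
    g$ID <- names(feats)
    g$fclass <- feats$fclass
    multi <- names(feats)[lengths(exonRanges(annotation)) > 1L]
    exl <- exonRanges(annotation)[multi]
    ex <- unlist(exl, use.names = FALSE)
    if (length(ex)) {
        ex$type <- "exon"
        ex$ID <- NA_character_
        ex$fclass <- NA_character_
        ex$Parent <- rep(multi, lengths(exl))
        names(ex) <- NULL
        names(g) <- NULL
        out <- c(g, ex)
    } else {
        names(g) <- NULL
        out <- g
    }
    rtracklayer::export.gff3(BiocGenerics::sort(out, ignore.strand = TRUE),
                             path)
    sl <- chromLengths(annotation)
    sl <- sl[!is.na(sl)]
    if (length(sl)) {
        lines <- readLines(path)
        pragma <- sprintf("##sequence-region %s 1 %d", names(sl),
                          as.integer(sl))
        writeLines(append(lines, pragma, after = 1L), path)
    }
    invisible(path)
}

#' Read uniquely mapped read intervals
#'
#' BED6 is read directly; SAM/BAM are accepted at the I/O boundary and
#' reduced to stranded intervals of primary, uniquely mapped records
#' (unmapped, secondary and supplementary alignments are excluded).  Reads
#' extending beyond the chromosome bounds of `annotation`/`genome` are
#' dropped with a message stating how many.
#'
#' @param path BED6 (`.bed`), SAM (`.sam`) or BAM (`.bam`) file.
#' @param totalMapped library-size denominator for per-million
#'   normalisation; defaults to the number of reads read from the file
#'   (before bounds filtering).
#' @param annotation optional [GenomeAnnotation-class] providing chromosome
#'   bounds.
#' @param libraryId library identifier; defaults to the file name.
#' @return An [AlignmentSet-class].
#' @export
readAlignments <- function(path, totalMapped = NULL, annotation = NULL,
                           libraryId = basename(path)) {
    ext <- tolower(tools::file_ext(path))
    if (ext == "bed") {
        gr <- rtracklayer::import.bed(path)
        mcols(gr) <- NULL
    } else if (ext %in% c("sam", "bam")) {
        for (pkg in c("Rsamtools", "GenomicAlignments"))
            if (!requireNamespace(pkg, quietly = TRUE))
                stop("package '", pkg, "' is required to read SAM/BAM")
        bam <- path
        if (ext == "sam")
            bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                                    indexDestination = FALSE)
        param <- Rsamtools::ScanBamParam(
            flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                          isSecondaryAlignment = FALSE,
                                          isSupplementaryAlignment = FALSE))
        gr <- GenomicRanges::granges(
            GenomicAlignments::readGAlignments(bam, param = param))
    } else stop("unsupported alignment format: ", ext)
    n0 <- length(gr)
    if (is.null(totalMapped)) totalMapped <- n0
    if (!is.null(annotation)) {
        sl <- chromLengths(annotation)
        known <- as.character(seqnames(gr)) %in% names(sl)
        inb <- known & end(gr) <= sl[as.character(seqnames(gr))] & start(gr) >= 1L
        if (any(!inb))
            message("dropped ", sum(!inb), " out-of-bounds read(s)")
        gr <- gr[inb]
        GenomeInfoDb::seqlevels(gr) <- names(sl)
        seqlengths(gr) <- sl
    }
    AlignmentSet(gr, totalMapped = totalMapped, libraryId = libraryId)
}

#' Extract sense-strand sequence for genomic intervals
#'
#' Minus-strand intervals are reverse-complemented so the returned sequence
#' reads 5' to 3' along the transcript.
#'
#' @param genome `DNAStringSet` named by chromosome.
#' @param interval `GRanges`.
#' @return `DNAStringSet`, one sequence per interval.
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "TTAAACGG"))
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 6), "-")
#' as.character(fetchSequence(g, gr))  # "GTTTAA"
#' @export
fetchSequence <- function(genome, interval) {
    ch <- as.character(seqnames(interval))
    if (any(!(ch %in% names(genome))))
        stop("chromosome absent from genome: ",
             paste(unique(ch[!(ch %in% names(genome))]), collapse = ", "))
    lim <- width(genome)[match(ch, names(genome))]
    if (any(start(interval) < 1L | end(interval) > lim))
        stop("interval out of chromosome bounds")
    res <- subseq(genome[ch], start = start(interval), end = end(interval))
    neg <- as.character(strand(interval)) == "-"
    if (any(neg)) res[neg] <- reverseComplement(res[neg])
    names(res) <- names(interval)
    res
}

#' Write an AlignmentSet as BED6
#'
#' @param alignments an [AlignmentSet-class].
#' @param path output BED file.
#' @return `path`, invisibly.
#' @export
writeAlignments <- function(alignments, path) {
    gr <- reads(alignments)
    gr$name <- "."
    gr$score <- 0L
    rtracklayer::export.bed(gr, path)
    invisible(path)
}
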