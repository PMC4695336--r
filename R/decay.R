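.MOTIF_PATTERNS <- c(TNAAAC = "T[ACGT]AAAC", DSR = "T[TCG]AAAC")

#' Scan a sequence for the Mmi1 binding hexamer
#'
#' Two patterns are available: `"TNAAAC"`, the broad hexamer (N any base),
#' and `"DSR"`, the strict determinant-of-selective-removal form
#' T(T/C/G)AAAC (the DNA sense-strand rendering of U(U/C/G)AAAC).
#' Matches may overlap; `N` in the sequence never matches any pattern
#' position.
#'
#' @param sequence a single character string, `DNAString`, or a character
#'   vector / `DNAStringSet` (scanned element-wise).
#' @param patternId `"TNAAAC"` (default) or `"DSR"`.
#' @return `data.frame` with `seq_index`, `start` (1-based within the
#'   sequence), `end`, `matched`.
#' @examples
#' scanMotif("TTAAACTAAAAC", "DSR")     # one hit at 1
#' scanMotif("TTAAACTAAAAC", "TNAAAC")  # hits at 1 and 7
#' @export
scanMotif <- function(sequence, patternId = c("TNAAAC", "DSR")) {
    patternId <- match.arg(patternId)
    pat <- paste0("(?=", .MOTIF_PATTERNS[[patternId]], ")")
    seqs <- as.character(sequence)
    rows <- lapply(seq_along(seqs), function(i) {
        m <- gregexpr(pat, seqs[i], perl = TRUE)[[1]]
        st <- as.integer(m[m > 0])
        if (length(st) == 0L) return(NULL)
        data.frame(seq_index = i, start = st, end = st + 5L,
                   matched = substring(seqs[i], st, st + 5L))
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows) == 0L)
        return(data.frame(seq_index = integer(), start = integer(),
                          end = integer(), matched = character()))
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Census of introns carrying the binding motif
#'
#' Fraction of introns whose sense-strand sequence contains at least one
#' motif hit.
#'
#' @param annotation a [GenomeAnnotation-class] with at least one intron.
#' @param genome `DNAStringSet`.
#' @param patternId `"TNAAAC"` (default, the broad census) or `"DSR"`.
#' @return List with `nIntrons`, `nWithMotif`, `fraction`, and `perIntron`
#'   (named logical vector of intron ids).
#' @export
intronMotifCensus <- function(annotation, genome,
                              patternId = c("TNAAAC", "DSR")) {
    patternId <- match.arg(patternId)
    introns <- intronRanges(annotation)
    geneIds <- names(introns)[lengths(introns) > 0L]
    if (length(geneIds) == 0L) stop("annotation has no intron")
    flat <- unlist(introns[geneIds])
    iid <- paste0(rep(geneIds, lengths(introns[geneIds])), ".I",
                  unlist(lapply(lengths(introns[geneIds]), seq_len)))
    seqs <- as.character(fetchSequence(genome, flat))
    hasMotif <- vapply(seqs, function(s)
        nrow(scanMotif(s, patternId)) > 0L, logical(1), USE.NAMES = FALSE)
    names(hasMotif) <- iid
    list(nIntrons = length(iid), nWithMotif = sum(hasMotif),
         fraction = sum(hasMotif) / length(iid), perIntron = hasMotif)
}

#' Motif hit counts per intron
#'
#' Convenience wrapper returning the number of sense-strand motif hits in
#' each intron, named `<gene>.I<k>`.
#'
#' @inheritParams intronMotifCensus
#' @return Named integer vector over intron ids.
#' @export
intronMotifCounts <- function(annotation, genome,
                              patternId = c("TNAAAC", "DSR")) {
    patternId <- match.arg(patternId)
    introns <- intronRanges(annotation)
    geneIds <- names(introns)[lengths(introns) > 0L]
    if (length(geneIds) == 0L) stop("annotation has no intron")
    flat <- unlist(introns[geneIds])
    iid <- paste0(rep(geneIds, lengths(introns[geneIds])), ".I",
                  unlist(lapply(lengths(introns[geneIds]), seq_len)))
    seqs <- as.character(fetchSequence(genome, flat))
    counts <- vapply(seqs, function(s) nrow(scanMotif(s, patternId)),
                     integer(1), USE.NAMES = FALSE)
    stats::setNames(counts, iid)
}

#' Call decay-promoting introns
#'
#' Combines three lines of evidence per intron: the fraction of the gene's
#' CRAC reads bound within intronic sequence (>= `fMin`), the presence of at
#' least one binding motif in the intron (a single motif suffices), and
#' stabilisation of the unspliced precursor in the mutant (an IR call of
#' `stabilized` or `splicing_defect`).  The verdict is the conjunction of
#' the three; missing evidence counts as failing that criterion and is
#' flagged.
#'
#' @param evidence `data.frame` with columns `intron_id`,
#'   `intronicFraction`, `motifCount`, `irCall` (one row per intron;
#'   `NA`s allowed).
#' @param fMin minimum intronic binding fraction (default 0.5).
#' @return The input with added logical columns `evBinding`, `evMotif`,
#'   `evStabilized`, `missingEvidence`, and `verdict`, sorted by decreasing
#'   intronic fraction.
#' @export
callDecayIntrons <- function(evidence, fMin = 0.5) {
    stopifnot(all(c("intron_id", "intronicFraction", "motifCount",
                    "irCall") %in% colnames(evidence)))
    ev <- evidence
    ev$evBinding <- !is.na(ev$intronicFraction) & ev$intronicFraction >= fMin
    ev$evMotif <- !is.na(ev$motifCount) & ev$motifCount >= 1L
    ev$evStabilized <- !is.na(ev$irCall) &
        ev$irCall %in% c("stabilized", "splicing_defect")
    ev$missingEvidence <- is.na(ev$intronicFraction) | is.na(ev$motifCount) |
        is.na(ev$irCall)
    ev$verdict <- ev$evBinding & ev$evMotif & ev$evStabilized
    ev[order(-ifelse(is.na(ev$intronicFraction), -1, ev$intronicFraction)), ,
       drop = FALSE]
}
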