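#' Simulate a toy genome, annotation and truth set
#'
#' Generates an i.i.d. uniform background genome and places genes of every
#' feature class without same-strand overlap, separated by at least 200 nt
#' of intergenic sequence (the gaps become intergenic features in their own
#' right).  A configured number of intron-containing mRNAs are designated
#' decay-intron genes: one intron receives 1-6 planted copies of the DSR
#' hexamer T(T/C/G)AAAC on the sense strand.  A larger set of intronless
#' genes ("exonic targets") carries motif copies in the longest exon,
#' mirroring a regulon in which only a minority of bound motifs are
#' intronic.  No other motif is planted; background occurrences arising by
#' chance are recorded in the truth by a scan of the finished sequence.
#' Planted mutant phenotypes (fold changes, intron-retention categories,
#' readthrough classes) and pA status are assigned to disjoint gene sets
#' and recorded per gene.
#'
#' @param config a [SimConfig-class]; `config@seed` drives every draw.
#' @return List with `genome` (`DNAStringSet`), `annotation`
#'   ([GenomeAnnotation-class]), and `truth` (list with per-gene
#'   `data.frame` `genes`, the intron motif-hit table `motifs` from a scan
#'   of the finished sequence, the `planted` motif positions, abundance
#'   vectors `abundancePolyA` / `abundanceTotal`, and the `config`).
#' @export
simulateGenome <- function(config) {
    stopifnot(is(config, "SimConfig"))
    set.seed(config@seed)
    nGenes <- config@nMRNA + config@nNcRNA + config@nSnoRNA +
        config@nSnRNA + config@nPseudogene
    fclass <- rep(c("mRNA", "ncRNA", "snoRNA", "snRNA", "pseudogene"),
                  c(config@nMRNA, config@nNcRNA, config@nSnoRNA,
                    config@nSnRNA, config@nPseudogene))
    ids <- sprintf("%s_%03d", fclass, seq_len(nGenes))

    # --- gene structures -------------------------------------------------
    nIntronGenes <- round(config@fractionIntronContaining * config@nMRNA)
    intronGene <- ids[fclass == "mRNA"][seq_len(nIntronGenes)]
    if (config@nDecayIntrons > nIntronGenes)
        stop("nDecayIntrons exceeds the number of intron-containing genes")
    decayGenes <- sample(intronGene, config@nDecayIntrons)
    sdPool <- setdiff(intronGene, decayGenes)
    sdGenes <- sample(sdPool, min(config@nSplicingDefect, length(sdPool)))
    intronless <- setdiff(ids[fclass == "mRNA"], intronGene)
    pool <- sample(c(intronless, ids[fclass == "ncRNA"]))
    take <- function(n) {
        if (n > length(pool)) stop("not enough unassigned genes to plant")
        out <- pool[seq_len(n)]; pool <<- pool[-seq_len(n)]; out
    }
    exTargets <- take(config@nExonicTargets)
    rt1 <- take(config@nReadthroughPerClass)
    rt2 <- take(config@nReadthroughPerClass)
    rt3 <- take(config@nReadthroughPerClass)
    extraUp <- take(config@nExtraUp)
    extraDown <- take(config@nExtraDown)

    exonLens <- intronLens <- vector("list", nGenes)
    names(exonLens) <- names(intronLens) <- ids
    for (i in seq_len(nGenes)) {
        id <- ids[i]
        if (fclass[i] == "mRNA" && id %in% intronGene) {
            nEx <- sample(2:3, 1)
            exonLens[[id]] <- sample(200:500, nEx, replace = TRUE)
            lo <- if (id %in% decayGenes) 120L else 60L
            intronLens[[id]] <- sample(lo:200, nEx - 1L, replace = TRUE)
        } else {
            len <- switch(fclass[i],
                          mRNA = sample(800:1600, 1),
                          ncRNA = sample(300:900, 1),
                          snoRNA = sample(100:200, 1),
                          snRNA = sample(120:180, 1),
                          pseudogene = sample(400:800, 1))
            exonLens[[id]] <- len
            intronLens[[id]] <- integer()
        }
    }

    # --- placement -------------------------------------------------------
    chroms <- sprintf("chr%d", seq_len(config@nChrom))
    cursor <- stats::setNames(rep(1L, config@nChrom), chroms)
    geneChrom <- chroms[(seq_len(nGenes) - 1L) %% config@nChrom + 1L]
    geneStrand <- sample(c("+", "-"), nGenes, replace = TRUE)
    spanStart <- spanEnd <- integer(nGenes)
    exGene <- character(0); exChrom <- character(0)
    exStrand <- character(0); exS <- integer(0); exE <- integer(0)
    for (i in seq_len(nGenes)) {
        ch <- geneChrom[i]
        gap <- sample(200:800, 1)
        s <- cursor[ch] + gap
        lens <- exonLens[[i]]
        ilens <- intronLens[[i]]
        total <- sum(lens) + sum(ilens)
        if (s + total - 1L > config@chromLength - 200L)
            stop("genes do not fit on chromosomes; increase chromLength")
        pos <- s
        exs <- integer(0); exe <- integer(0)
        for (k in seq_along(lens)) {
            exs <- c(exs, pos); exe <- c(exe, pos + lens[k] - 1L)
            pos <- pos + lens[k]
            if (k <= length(ilens)) pos <- pos + ilens[k]
        }
        exGene <- c(exGene, rep(ids[i], length(exs)))
        exChrom <- c(exChrom, rep(ch, length(exs)))
        exStrand <- c(exStrand, rep(geneStrand[i], length(exs)))
        exS <- c(exS, exs); exE <- c(exE, exe)
        spanStart[i] <- s; spanEnd[i] <- s + total - 1L
        cursor[ch] <- spanEnd[i]
    }
    exFlat <- GRanges(exChrom, IRanges(exS, exE), strand = exStrand)
    exList <- S4Vectors::split(exFlat, factor(exGene, levels = ids))

    # intergenic features: gaps of the gene cover, >= 100 nt
    geneSpans <- GRanges(geneChrom, IRanges(spanStart, spanEnd))
    intIds <- character(0)
    intGr <- GRanges()
    for (ch in chroms) {
        sub <- ranges(geneSpans[as.character(seqnames(geneSpans)) == ch])
        g <- IRanges::gaps(sub, start = 1L, end = config@chromLength)
        g <- g[width(g) >= 100L]
        if (length(g)) {
            nm <- sprintf("INT_%s_%02d", ch, seq_along(g))
            intIds <- c(intIds, nm)
            suppressWarnings(intGr <- c(intGr, GRanges(ch, g, strand = "*")))
        }
    }

    feats <- GRanges(geneChrom, IRanges(spanStart, spanEnd),
                     strand = geneStrand)
    names(feats) <- ids
    feats$fclass <- fclass
    names(intGr) <- intIds
    intGr$fclass <- rep("intergenic", length(intGr))
    allFeats <- suppressWarnings(c(feats, intGr))
    sl <- stats::setNames(rep(config@chromLength, config@nChrom), chroms)
    annotation <- GenomeAnnotation(allFeats, exList, seqlengths = sl)

    # --- background sequence + planted motifs ----------------------------
    seqChars <- lapply(chroms, function(ch)
        sample(c("A", "C", "G", "T"), config@chromLength, replace = TRUE))
    names(seqChars) <- chroms
    planted <- list()
    plantInto <- function(id, tgt) {
        copies <- sample(seq(config@motifCopiesRange[1],
                             config@motifCopiesRange[2]), 1)
        w <- width(tgt)
        offs <- roundHalfUp(seq(5, w - 11, length.out = copies))
        ch <- as.character(seqnames(tgt))
        st <- as.character(strand(tgt))
        for (o in offs) {
            motif <- paste0("T", sample(c("T", "C", "G"), 1), "AAAC")
            gpos <- start(tgt) + o - 1L
            letters6 <- strsplit(if (st == "-")
                as.character(reverseComplement(DNAStringSet(motif)))
                else motif, "")[[1]]
            seqChars[[ch]][gpos:(gpos + 5L)] <<- letters6
            planted[[length(planted) + 1L]] <<- data.frame(
                gene_id = id, gstart = gpos, gend = gpos + 5L, strand = st)
        }
    }
    for (id in decayGenes) {
        intr <- intronRanges(annotation)[[id]]
        plantInto(id, intr[which.max(width(intr))])
    }
    for (id in exTargets) {
        ex <- exonRanges(annotation)[[id]]
        plantInto(id, ex[which.max(width(ex))])
    }
    planted <- do.call(rbind, planted)
    genome <- DNAStringSet(vapply(seqChars, paste, "", collapse = ""))
    names(genome) <- chroms

    # truth motif table: full scan of every intron (planted + background)
    introns <- intronRanges(annotation)
    withIntron <- names(introns)[lengths(introns) > 0L]
    flat <- unlist(introns[withIntron])
    gidPer <- rep(withIntron, lengths(introns[withIntron]))
    iidPer <- paste0(gidPer, ".I",
                     unlist(lapply(lengths(introns[withIntron]), seq_len)))
    hits <- scanMotif(as.character(fetchSequence(genome, flat)), "TNAAAC")
    motifs <- data.frame(gene_id = gidPer[hits$seq_index],
                         intron_id = iidPer[hits$seq_index],
                         start = hits$start, end = hits$end,
                         matched = hits$matched)

    # --- per-gene truth --------------------------------------------------
    expression <- 10^stats::runif(nGenes, 0, 3)
    names(expression) <- ids
    # genes whose phenotype must be measurable get mid-range expression;
    # exonic targets sit low -- in the wild type Mmi1 keeps them degraded,
    # which is what makes them stand out in abundance-normalised CRAC
    special <- c(decayGenes, sdGenes, rt1, rt2, rt3)
    expression[special] <- 10^stats::runif(length(special), 1.5, 2.5)
    expression[exTargets] <- 10^stats::runif(length(exTargets), 0, 1.5)
    intExpr <- 10^stats::runif(length(intIds), -1, 1)
    names(intExpr) <- intIds

    log2FC <- stats::setNames(rep(0, nGenes), ids)
    log2FC[decayGenes] <- log2(config@stabilizationFold)
    log2FC[c(rt1, extraUp, exTargets)] <- config@log2fcUp
    log2FC[c(rt3, extraDown)] <- config@log2fcDown
    irCat <- stats::setNames(rep("unchanged", nGenes), ids)
    irCat[!(ids %in% intronGene)] <- NA
    irCat[decayGenes] <- "stabilized"
    irCat[sdGenes] <- "splicing_defect"
    rtClass <- stats::setNames(rep("none", nGenes), ids)
    rtClass[rt1] <- "1"; rtClass[rt2] <- "2"; rtClass[rt3] <- "3"
    affinity <- stats::setNames(rep(1, nGenes), ids)
    affinity[c(decayGenes, exTargets)] <- config@targetAffinity
    targetType <- stats::setNames(rep("none", nGenes), ids)
    targetType[decayGenes] <- "decay_intron"
    targetType[exTargets] <- "exonic"
    pA <- stats::setNames(rep("pA+", nGenes), ids)
    nc <- ids[fclass == "ncRNA"]
    paMinus <- sample(nc, round(config@pAMinusFraction * length(nc)))
    pA[paMinus] <- "pA-"
    pA[fclass %in% c("snRNA", "snoRNA")] <- "pA-"
    precFracWT <- stats::setNames(rep(NA_real_, nGenes), ids)
    precFracWT[intronGene] <- config@precursorFracWT
    precFracMut <- precFracWT
    precFracMut[sdGenes] <- pmin(0.8, config@precursorFracWT *
                                     config@splicingDefectFactor)

    genes <- data.frame(
        feature_id = ids, fclass = fclass, chrom = geneChrom,
        strand = geneStrand, start = spanStart, end = spanEnd,
        expression = expression, affinity = affinity,
        targetType = targetType,
        isDecayIntron = ids %in% decayGenes,
        pA = pA, log2FC = log2FC, irCategory = irCat, rtClass = rtClass,
        precursorFracWT = precFracWT, precursorFracMut = precFracMut,
        row.names = NULL)
    intRows <- data.frame(
        feature_id = intIds, fclass = "intergenic",
        chrom = as.character(seqnames(intGr)), strand = "*",
        start = start(intGr), end = end(intGr),
        expression = intExpr, affinity = 1, targetType = "none",
        isDecayIntron = FALSE,
        pA = "pA+", log2FC = 0, irCategory = NA, rtClass = "none",
        precursorFracWT = NA_real_, precursorFracMut = NA_real_,
        row.names = NULL)
    genes <- rbind(genes, intRows)

    abundanceTotal <- stats::setNames(genes$expression, genes$feature_id)
    abundancePolyA <- abundanceTotal
    dep <- genes$feature_id[genes$pA == "pA-"]
    abundancePolyA[dep] <- abundancePolyA[dep] / config@pADepletion

    list(genome = genome, annotation = annotation,
         truth = list(genes = genes, motifs = motifs, planted = planted,
                      abundancePolyA = abundancePolyA,
                      abundanceTotal = abundanceTotal,
                      config = config))
}

#' Simulate a CRAC library
#'
#' Reads are apportioned between features with multinomial probability
#' proportional to affinity x expression, so motif-containing targets
#' dominate independently of their abundance.  Target-gene reads start at
#' Normal(motif position, `cracSigma`) truncated to the feature; all other
#' reads are uniform over exons (intergenic reads uniform over the region,
#' random strand).
#'
#' @param genome,annotation,truth from [simulateGenome()].
#' @param config the same [SimConfig-class].
#' @param seed seed for this library (default `config@seed + 1`).
#' @return An [AlignmentSet-class] with `totalMapped = config@cracDepth`.
#' @export
simulateCracReads <- function(genome, annotation, truth, config,
                              seed = config@seed + 1L) {
    set.seed(seed)
    g <- truth$genes
    w <- g$affinity * g$expression
    nPer <- as.integer(stats::rmultinom(1, config@cracDepth, w))
    L <- config@readLength
    accS <- list(); accC <- list(); accT <- list()
    exl <- exonRanges(annotation)
    for (i in seq_len(nrow(g))) {
        n <- nPer[i]
        if (n == 0L) next
        id <- g$feature_id[i]
        if (g$affinity[i] > 1 && any(truth$planted$gene_id == id)) {
            gpos <- truth$planted$gstart[truth$planted$gene_id == id]
            ctr <- gpos[sample.int(length(gpos), n, replace = TRUE)]
            s <- roundHalfUp(stats::rnorm(n, ctr - L %/% 2L,
                                          config@cracSigma))
            s <- pmin(pmax(s, g$start[i]), g$end[i] - L + 1L)
            st <- rep(g$strand[i], n)
        } else {
            ex <- exl[[id]]
            pick <- sample.int(length(ex), n, replace = TRUE,
                               prob = width(ex))
            s <- start(ex)[pick] +
                floor(stats::runif(n) * pmax(width(ex)[pick] - L + 1L, 1L))
            st <- if (g$strand[i] == "*")
                sample(c("+", "-"), n, replace = TRUE)
            else rep(g$strand[i], n)
        }
        j <- length(accS) + 1L
        accS[[j]] <- s; accC[[j]] <- rep(g$chrom[i], n); accT[[j]] <- st
    }
    starts <- unlist(accS); chs <- unlist(accC); sts <- unlist(accT)
    sl <- chromLengths(annotation)
    ends <- pmin(starts + L - 1L, sl[chs])
    starts <- pmax(starts, 1L)
    gr <- GRanges(chs, IRanges(starts, ends), strand = sts,
                  seqlengths = sl)
    AlignmentSet(gr, totalMapped = config@cracDepth, libraryId = "CRAC")
}

#' Simulate RNA-seq libraries for one condition
#'
#' Per-gene expected counts scale expression to the configured depth, with
#' planted fold changes applied in the mutant; counts are drawn
#' NegativeBinomial (`var = mu + disp * mu^2`).  Reads of intron-containing
#' genes are split between spliced mRNA (uniform over exons, clipped at exon
#' boundaries) and unspliced precursor (uniform over the whole span, hence
#' junction-spanning), with the precursor fraction from the truth set --
#' raised in the mutant for splicing-defect genes.  Readthrough genes emit
#' additional downstream-window reads in the mutant.
#'
#' @param annotation,truth from [simulateGenome()].
#' @param condition `"WT"` or `"mutant"`.
#' @param config the same [SimConfig-class].
#' @param seed seed for this condition's replicates (defaults derive from
#'   `config@seed`).
#' @return List with `counts` (feature x replicate integer matrix of gene-
#'   body counts) and `alignments` (list of [AlignmentSet-class], one per
#'   replicate).
#' @export
simulateRnaSeq <- function(annotation, truth, condition = c("WT", "mutant"),
                           config,
                           seed = config@seed +
                               ifelse(condition[1] == "WT", 2L, 3L) * 1000L) {
    condition <- match.arg(condition)
    set.seed(seed)
    g <- truth$genes
    rel <- g$expression
    if (condition == "mutant") rel <- rel * 2^g$log2FC
    # sequencing depth is fixed by the library, not by the transcriptome:
    # expected counts are renormalised so each library sums to the depth
    mu <- rel / sum(rel) * config@rnaseqDepth
    size <- 1 / config@nbDispersion
    L <- config@readLength
    exl <- exonRanges(annotation)
    sl <- chromLengths(annotation)
    counts <- matrix(0L, nrow(g), config@nReplicates,
                     dimnames = list(g$feature_id,
                                     paste0(condition, "_rep",
                                            seq_len(config@nReplicates))))
    alns <- vector("list", config@nReplicates)
    pFrac <- if (condition == "mutant") g$precursorFracMut else
        g$precursorFracWT
    for (r in seq_len(config@nReplicates)) {
        cnt <- stats::rnbinom(nrow(g), mu = mu, size = size)
        counts[, r] <- cnt
        accS <- list(); accE <- list(); accC <- list(); accT <- list()
        push <- function(s, e, ch, st) {
            i <- length(accS) + 1L
            accS[[i]] <<- s; accE[[i]] <<- e
            accC[[i]] <<- ch; accT[[i]] <<- st
        }
        for (i in seq_len(nrow(g))) {
            n <- cnt[i]
            rtExtra <- 0L
            if (condition == "mutant" && g$rtClass[i] != "none")
                rtExtra <- roundHalfUp(config@readthroughFrac * n)
            if (n == 0L && rtExtra == 0L) next
            id <- g$feature_id[i]
            nPre <- 0L
            if (!is.na(pFrac[i]) && n > 0L)
                nPre <- stats::rbinom(1, n, pFrac[i])
            nM <- n - nPre
            if (nPre > 0L) {  # precursor: uniform over the unspliced span
                s <- g$start[i] +
                    floor(stats::runif(nPre) *
                              max(g$end[i] - g$start[i] - L + 2L, 1L))
                push(s, pmin(s + L - 1L, g$end[i]),
                     rep(g$chrom[i], nPre), rep(g$strand[i], nPre))
            }
            if (nM > 0L) {    # mature: uniform over exons, exon-clipped
                ex <- exl[[id]]
                pick <- sample.int(length(ex), nM, replace = TRUE,
                                   prob = width(ex))
                s <- start(ex)[pick] +
                    floor(stats::runif(nM) *
                              pmax(width(ex)[pick] - L + 1L, 1L))
                st <- if (g$strand[i] == "*")
                    sample(c("+", "-"), nM, replace = TRUE)
                else rep(g$strand[i], nM)
                push(s, pmin(s + L - 1L, end(ex)[pick]),
                     rep(g$chrom[i], nM), st)
            }
            if (rtExtra > 0L) {  # readthrough: downstream window
                if (g$strand[i] == "-") {
                    we <- g$start[i] - 1L
                    ws <- max(1L, g$start[i] - 300L)
                } else {
                    ws <- g$end[i] + 1L
                    we <- min(sl[g$chrom[i]], g$end[i] + 300L)
                }
                if (we - ws + 1L >= L) {
                    s <- ws + floor(stats::runif(rtExtra) * (we - ws - L + 2L))
                    push(s, s + L - 1L, rep(g$chrom[i], rtExtra),
                         rep(g$strand[i], rtExtra))
                }
            }
        }
        starts <- unlist(accS); ends <- unlist(accE)
        chs <- unlist(accC); sts <- unlist(accT)
        gr <- GRanges(chs, IRanges(pmax(starts, 1L), ends), strand = sts,
                      seqlengths = sl)
        alns[[r]] <- AlignmentSet(gr, totalMapped = length(gr),
                                  libraryId = paste0(condition, "_rep", r))
    }
    list(counts = counts, alignments = alns, condition = condition)
}

#' Pool replicate AlignmentSets
#'
#' Concatenates reads and sums the per-million denominators.
#'
#' @param alignmentList list of [AlignmentSet-class].
#' @param libraryId id for the pooled library.
#' @return An [AlignmentSet-class].
#' @export
poolAlignments <- function(alignmentList, libraryId = "pooled") {
    gr <- do.call(c, lapply(alignmentList, reads))
    AlignmentSet(gr, totalMapped = sum(vapply(alignmentList, totalMapped, 0)),
                 libraryId = libraryId)
}

#' Run the full synthetic-data generator
#'
#' Convenience wrapper: genome + annotation + truth, one CRAC library, and
#' triplicate RNA-seq for WT and mutant, all from one config.
#'
#' @param config a [SimConfig-class].
#' @return List with `genome`, `annotation`, `truth`, `crac`, `rnaseqWT`,
#'   `rnaseqMut`, and the combined `counts` matrix with its `condition`
#'   vector.
#' @export
runSimulation <- function(config) {
    sim <- simulateGenome(config)
    crac <- simulateCracReads(sim$genome, sim$annotation, sim$truth, config)
    wt <- simulateRnaSeq(sim$annotation, sim$truth, "WT", config)
    mut <- simulateRnaSeq(sim$annotation, sim$truth, "mutant", config)
    counts <- cbind(wt$counts, mut$counts)
    condition <- rep(c("WT", "mutant"),
                     c(ncol(wt$counts), ncol(mut$counts)))
    c(sim, list(crac = crac, rnaseqWT = wt, rnaseqMut = mut,
                counts = counts, condition = condition))
}

#' Write simulation artifacts to disk
#'
#' Emits FASTA, GFF3, one BED6 per library, the count matrix and sample
#' sheet as TSV, both abundance tables, and the truth set as JSON -- the
#' on-disk face of the generator, used by the determinism and
#' emitted-truth-consistency checks.
#'
#' @param sim result of [runSimulation()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    f <- c(genome = file.path(dir, "genome.fasta"),
           annotation = file.path(dir, "annotation.gff3"),
           crac = file.path(dir, "crac.bed"),
           counts = file.path(dir, "counts.tsv"),
           samples = file.path(dir, "samples.tsv"),
           abundancePolyA = file.path(dir, "abundance_polyA.tsv"),
           abundanceTotal = file.path(dir, "abundance_total.tsv"),
           truth = file.path(dir, "truth.json"))
    writeXStringSet(sim$genome, f["genome"])
    writeAnnotation(sim$annotation, f["annotation"])
    writeAlignments(sim$crac, f["crac"])
    for (x in c(sim$rnaseqWT$alignments, sim$rnaseqMut$alignments)) {
        p <- file.path(dir, paste0("rnaseq_", libraryId(x), ".bed"))
        writeAlignments(x, p)
        f[paste0("rnaseq_", libraryId(x))] <- p
    }
    utils::write.table(data.frame(feature_id = rownames(sim$counts),
                                  sim$counts, check.names = FALSE),
                       f["counts"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(data.frame(sample = colnames(sim$counts),
                                  condition = sim$condition),
                       f["samples"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    for (nm in c("abundancePolyA", "abundanceTotal"))
        utils::write.table(data.frame(feature_id = names(sim$truth[[nm]]),
                                      abundance = sim$truth[[nm]]),
                           f[nm], sep = "\t", quote = FALSE,
                           row.names = FALSE)
    tr <- sim$truth
    tr$config <- NULL
    jsonlite::write_json(tr, f["truth"], auto_unbox = TRUE, digits = NA,
                         na = "null")
    invisible(f)
}
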