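#' Run the whole analysis end to end on synthetic data
#'
#' Chains the stages in dependency order: simulate -> CRAC binding (read
#' assignment, cluster calling, hexamer enrichment, abundance-normalised
#' enrichment, pA classification, intronic binding fractions) -> NB
#' differential expression with class tallies -> intron-retention calls ->
#' readthrough classes -> decay-promoting-intron verdicts.  Every stage
#' writes its table under `outdir` and every parameter and seed is echoed
#' into `manifest.json`, so a rerun with the same config is byte-identical
#' and each reported number can be recomputed from the stage files.
#'
#' @param config a [SimConfig-class] (seed included).
#' @param outdir output directory; `NULL` skips all file output.
#' @param minHeight,minLength,mergeGap cluster-calling parameters, see
#'   [callClusters()].
#' @param k,nShuffles hexamer-enrichment parameters, see [kmerEnrichment()].
#' @param paCutoff pA classification cutoff, see [classifyPolyA()].
#' @param fold,alpha differential-expression thresholds, see [classifyDE()].
#' @param boundaryThreshold,ratioThreshold intron-retention thresholds, see
#'   [classifyIRChange()].
#' @param windowNt,rtThreshold readthrough parameters, see
#'   [downstreamSignal()] and [classifyReadthrough()].
#' @param fMin minimum intronic binding fraction for the decay-intron
#'   caller, see [callDecayIntrons()].
#' @return List with the stage results: `sim`, `assignment`, `clusters`,
#'   `kmers`, `enrichment`, `polyA`, `intronicFraction`, `de`, `tally`,
#'   `ir`, `readthrough`, `census`, `decay`, `files`.
#' @export
runPipeline <- function(config = simConfig(), outdir = NULL,
                        minHeight = 5L, minLength = 12L, mergeGap = 3L,
                        k = 6L, nShuffles = 100L,
                        paCutoff = 5, fold = 1.5, alpha = 0.05,
                        boundaryThreshold = 2, ratioThreshold = 2,
                        windowNt = 300L, rtThreshold = 2, fMin = 0.5) {
    sim <- runSimulation(config)
    anno <- sim$annotation
    files <- character(0)
    if (!is.null(outdir))
        files <- writeSimulation(sim, file.path(outdir, "sim"))

    ## --- binding stage --------------------------------------------------
    assignment <- assignReadsToFeatures(sim$crac, anno)
    clusters <- callClusters(sim$crac, sim$genome, minHeight = minHeight,
                             minLength = minLength, mergeGap = mergeGap)
    kmers <- kmerEnrichment(clusters, k = k, nShuffles = nShuffles,
                            seed = config@seed + 7L)
    enrichment <- computeEnrichment(assignment$counts,
                                    sim$truth$abundanceTotal)
    polyA <- classifyPolyA(sim$truth$abundancePolyA,
                           sim$truth$abundanceTotal, cutoff = paCutoff)
    introns <- intronRanges(anno)
    intronGenes <- names(introns)[lengths(introns) > 0L]
    intronicFraction <- vapply(intronGenes, intronicBindingFraction,
                               numeric(1), annotation = anno,
                               alignments = sim$crac)

    ## --- differential expression ----------------------------------------
    de <- nbWaldTest(sim$counts, sim$condition, fold = fold, alpha = alpha)
    calls <- stats::setNames(de$call, de$feature_id)
    tally <- tallyClasses(calls, featureClass(anno))

    ## --- intron retention ------------------------------------------------
    wtPool <- poolAlignments(sim$rnaseqWT$alignments, "WT")
    mutPool <- poolAlignments(sim$rnaseqMut$alignments, "mutant")
    irWT <- intronMetrics(anno, wtPool)
    irMut <- intronMetrics(anno, mutPool)
    # composition correction for between-condition per-million folds
    pooledCounts <- cbind(
        WT = rowSums(sim$counts[, sim$condition == "WT", drop = FALSE]),
        mutant = rowSums(sim$counts[, sim$condition == "mutant",
                                    drop = FALSE]))
    # rpm/nf is proportional to count/sizeFactor: nf = sf / totalMapped,
    # rescaled to geometric mean 1
    nf <- estimateSizeFactors(pooledCounts) /
        c(totalMapped(wtPool), totalMapped(mutPool))
    nf <- nf / exp(mean(log(nf)))
    ir <- classifyIRChange(irWT, irMut,
                           boundaryThreshold = boundaryThreshold,
                           ratioThreshold = ratioThreshold,
                           normFactors = nf)

    ## --- readthrough ------------------------------------------------------
    fc <- featureClass(anno)
    rtGenes <- names(fc)[fc != "intergenic"]
    dsWT <- .downstreamTable(wtPool, rtGenes, anno, windowNt)
    dsMut <- .downstreamTable(mutPool, rtGenes, anno, windowNt)
    rt <- classifyReadthrough(rtGenes, dsWT$rpm, dsMut$rpm,
                              calls[rtGenes], rtThreshold = rtThreshold,
                              normFactors = nf, countWT = dsWT$count,
                              countMut = dsMut$count)

    ## --- decay-promoting introns -----------------------------------------
    census <- intronMotifCensus(anno, sim$genome, "TNAAAC")
    motifCounts <- intronMotifCounts(anno, sim$genome, "TNAAAC")
    irByIntron <- stats::setNames(ir$call, ir$intron_id)
    evidence <- data.frame(
        intron_id = names(motifCounts),
        gene_id = sub("\\.I\\d+$", "", names(motifCounts)),
        intronicFraction = intronicFraction[sub("\\.I\\d+$", "",
                                                names(motifCounts))],
        motifCount = as.integer(motifCounts),
        irCall = irByIntron[names(motifCounts)],
        row.names = NULL)
    decay <- callDecayIntrons(evidence, fMin = fMin)

    res <- list(sim = sim, assignment = assignment, clusters = clusters,
                kmers = kmers, enrichment = enrichment, polyA = polyA,
                intronicFraction = intronicFraction, de = de, tally = tally,
                ir = ir, readthrough = rt, census = census, decay = decay,
                files = files)

    if (!is.null(outdir)) {
        tsv <- function(x, name) {
            p <- file.path(outdir, name)
            utils::write.table(x, p, sep = "\t", quote = FALSE,
                               row.names = FALSE)
            p
        }
        dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
        cl <- as.data.frame(clusters)
        files["clusters"] <- tsv(cl, "clusters.tsv")
        files["kmers"] <- tsv(kmers, "kmers.tsv")
        files["enrichment"] <- tsv(enrichment, "enrichment.tsv")
        files["polyA"] <- tsv(data.frame(feature_id = names(polyA),
                                         pA = polyA), "polyA.tsv")
        files["de"] <- tsv(de, "de.tsv")
        files["tally"] <- tsv(tally, "tally.tsv")
        files["ir"] <- tsv(ir, "ir.tsv")
        files["readthrough"] <- tsv(rt, "readthrough.tsv")
        files["decay"] <- tsv(decay, "decay_introns.tsv")
        manifest <- list(
            package = "intronDecay",
            version = as.character(utils::packageVersion("intronDecay")),
            seed = config@seed,
            config = .configAsList(config),
            parameters = list(minHeight = minHeight, minLength = minLength,
                              mergeGap = mergeGap, k = k,
                              nShuffles = nShuffles, paCutoff = paCutoff,
                              fold = fold, alpha = alpha,
                              boundaryThreshold = boundaryThreshold,
                              ratioThreshold = ratioThreshold,
                              windowNt = windowNt,
                              rtThreshold = rtThreshold, fMin = fMin),
            files = as.list(files))
        jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                             auto_unbox = TRUE, digits = NA)
        files["manifest"] <- file.path(outdir, "manifest.json")
        res$files <- files
    }
    invisible(res)
}

.configAsList <- function(config) {
    nm <- methods::slotNames(config)
    stats::setNames(lapply(nm, function(s) methods::slot(config, s)), nm)
}
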