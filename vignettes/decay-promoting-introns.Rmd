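---
title: "Calling exosome targets and decay-promoting introns from CRAC and RNA-seq"
author: "intronDecay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling exosome targets and decay-promoting introns from CRAC and RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intronDecay)
```

## The biological question

In fission yeast, the YTH-family RNA-binding protein Mmi1 recruits the
nuclear exosome to specific transcripts.  Recognition works through
"determinant of selective removal" (DSR) elements enriched for the
hexanucleotide U(U/C/G)AAAC — written T(T/C/G)AAAC on the DNA sense
strand.  When such elements sit inside a poorly spliced intron, the
retained intron itself commits the unspliced precursor to degradation and
thereby lowers the output of spliced mRNA: a *decay-promoting intron*.
This package implements the computational analysis that identifies such
targets from two complementary data types:

* **CRAC** (UV cross-linking and analysis of cDNA): stranded read
  intervals marking where the protein touched RNA in vivo; and
* **RNA-seq** of wild type versus a deletion mutant, in triplicate, which
  reveals what accumulates when the decay factor is gone.

Every stage is a plain, documented function; `runPipeline()` chains them
and writes per-stage tables plus a manifest of every parameter and seed.

## Pipeline model and assumptions

**Cluster calling.** CRAC binding sites appear as stacks of overlapping
reads.  A cluster is a maximal run of same-strand coverage at or above
`minHeight` (default 5 reads), merging runs separated by fewer than 3
uncovered bases, and discarding clusters shorter than 12 nt.  These
parameters are deliberate defaults, not published constants: published
CRAC work does not state its exact peak-calling settings, so all three are
exposed as arguments.

**Hexamer enrichment.** Observed counts are all (overlapping) k-mer
occurrences across cluster sequences.  The background re-counts after
independently mononucleotide-shuffling each cluster 100 times, so base
composition is preserved per cluster and only arrangement can score.  The
statistic is `z = (observed - shuffled mean) / shuffled SD`; the add-one
empirical p-value `(1 + #{shuffle >= observed}) / (1 + n)` is never 0, and
BH adjustment runs across all observed k-mers.  A homopolymer cluster is
shuffle-invariant; its SD is 0 and its `z` is reported `NA` rather than
infinite.  A dinucleotide-preserving shuffle would be preferable for real
genomes with strong dinucleotide structure; the mononucleotide background
matches the composition bias the simulation models and is the default.

**Abundance-normalised enrichment and pA classes.** Raw CRAC counts
scale with expression, so binding specificity is visible only after
dividing by transcript abundance (`enrichment = count / (abundance +
0.1)`; the pseudocount bounds ratios for undetected transcripts).
Transcripts are split into pA+ and pA− by the ratio of oligo-dT-selected
to total-RNA abundance at the classical 5.0-fold cutoff, after dividing
each table by its median over shared features so that the classification
is scale-invariant.  The literature leaves the *direction* of that cutoff
ambiguous; this package reads it as "pA− transcripts are ≥5-fold depleted
from the oligo-dT fraction", and exposes `direction = "enrichment"` for
the opposite reading.

**Differential expression.** Published analyses of this kind use DESeq2;
re-implementing DESeq2 wholesale would be out of proportion, so the
package defines a self-contained negative-binomial Wald test with the same
skeleton: median-of-ratios size factors, method-of-moments dispersion per
gene shrunk toward a mean-expression trend (20 bins, prior weight
`priorDf = 10` against 4 residual degrees of freedom), fold changes from
normalised means with a 0.5 pseudocount, delta-method standard errors,
and a two-sided normal reference.  Two details matter numerically: the
trend is an **arithmetic** bin mean — on the log scale, the many genes
whose sample variance falls at or below the Poisson floor would drag the
trend toward zero and make the test badly anticonservative — and raw
dispersion estimates are clamped to [0, 10].  The test is validated by
calibration, not by numeric equality with DESeq2: on null simulations
(3 vs 3, 2,000 genes) the fraction of p < 0.05 sits near 0.05–0.06, and
planted 4-fold changes at mean 100 are detected essentially always.
Calls use the strict `>1.5`-fold and `p < 0.05` convention.

**Intron retention.** For every derived intron the package reports 5′
splice-site boundary reads per million — a read counts if it covers the
exon–intron junction with at least 3 nt on each side (no overhang rule is
published; 3 nt is configurable) — plus intron and exon FPKM and their
ratio.  Between conditions, a boundary increase >2-fold with an
unchanged intron/exon ratio is called *stabilized* (the precursor
accumulates, splicing efficiency unchanged); an increase in both is a
*splicing_defect*.  The ratio threshold of 2.0 quantifies "did not change
noticeably", which the source analyses leave verbal.  Only the 5′SS is
counted; whether 3′SS boundary reads were also used is not stated
anywhere, so they are not.

**Readthrough.** Downstream signal is measured in a 300-nt window past
the annotated 3′ end (no window size is published; truncation at the
first same-strand gene prevents bleed-through; midpoint counting avoids
double-counting boundary reads).  Windows fully occluded by an adjacent
same-strand gene give `NA`.  Genes whose downstream signal rises >2-fold
fall into three classes keyed to the gene-body DE call: body up (class 1),
body unchanged (class 2), or body down — indicative of a termination
defect (class 3).

**Two cross-cutting numerical choices.** First, "per million reads" is
biased between libraries whose transcriptomes differ in composition: when
the mutant accumulates large amounts of RNA, everything else is deflated.
`classifyIRChange()` and `classifyReadthrough()` therefore accept
median-of-ratios normalisation factors (`normFactors`), which
`runPipeline()` derives from the gene-body count matrix — the same
correction the DE stage applies; without factors the functions reproduce
plain per-million behaviour.  Second, both classifiers require the larger
of the two compared read counts to reach `minCount = 5` before making a
non-trivial call: at shallow depth a single stray read is 1–2 RPM and
sails past any fold threshold, whereas a 2-fold claim supported by five
or more reads is no longer compatible with Poisson noise
(P(X ≥ 5 | λ ≤ 1) < 0.4%).  Fold thresholds and pseudocounts themselves
are untouched.

**The decay-promoting-intron caller.** Three lines of evidence join per
intron: the fraction of the gene's CRAC reads whose midpoint is intronic
(≥ `fMin = 0.5`; the observation "bound within intronic regions" comes
with no printed cutoff, so half is the package's operationalisation),
at least one intronic TNAAAC motif (a single motif suffices — reporter
assays once suggested six repeats, but the genetics of single-motif
targets shows one is enough), and an IR call of *stabilized* or
*splicing_defect*.  The verdict is the conjunction; missing evidence
fails its criterion and is flagged.  The criteria behind the original
"about two dozen" list were never published, so this three-way rule is a
defined stand-in, not a reconstruction.

## What the synthetic data emulates

Real raw sequencing data for this analysis is not packaged, so the
generator builds a study in miniature with a known truth set: 2
chromosomes × 250 kb, 150 genes (90 mRNA, 40 ncRNA, 10 snoRNA, 5 snRNA,
5 pseudogene) placed without same-strand overlap and ≥200 nt apart, the
gaps becoming intergenic features.  Half the mRNAs carry introns.  Twelve
genes are decay-intron targets: one intron (≥120 nt) receives 1–6 DSR
copies and the stabilized-precursor phenotype (5-fold up in the mutant).
Thirty intronless genes are exonic/ncRNA targets — the majority of real
binding targets are not intronic — with motifs in their longest exon,
drawn from the *low* end of the expression range because in the wild type
these transcripts are constitutively degraded; that is also what plants
the characteristic anticorrelation between CRAC enrichment and abundance.
Five intron genes get a genuine splicing defect (precursor fraction 0.1 →
0.5, total unchanged), five genes per readthrough class, ten extra up and
fifteen extra down genes, and half the ncRNAs are pA− (oligo-dT abundance
divided by 20, far from the 5-fold cutoff).

CRAC reads (50k) are multinomial with weight affinity × expression
(targets 50×), starts Normal(motif, 15 nt); non-target reads are uniform
over exons.  RNA-seq (200k reads/library, triplicate) draws NB counts
with `var = μ + 0.05 μ²`; expected counts renormalise to the configured
depth per library — sequencing depth is a property of the run, not of the
transcriptome — so composition shifts must be (and are) recovered by size
factors.  Reads of intron genes split between spliced mRNA (exon-clipped)
and unspliced precursor (uniform over the span, hence junction-spanning);
readthrough genes emit extra downstream-window reads in the mutant.

What it does **not** model: sequencing errors, fragment-length and GC
biases, exon–exon junction reads, multi-mapping, overlapping genes,
dinucleotide composition structure, and cross-link-site micro-deletions.
Passing the recovery checks therefore demonstrates that the
implementation is faithful to its own model, not that the thresholds are
optimal for any particular real dataset.

Problem sizes used in the shipped checks — 100 simulated CRAC runs for
motif recovery, 2,000-gene null and power runs for DE calibration, one
default-scale run for the recovery metrics — keep a full check run in the
minutes range on a single CPU; they are the package's chosen operating
point, and all scale linearly if enlarged.

## Degenerate inputs and tie-breaks

* Reads overlapping several same-strand features go to the maximal
  overlap; ties to the smaller feature (specific beats broad), then to
  the lexicographically first id — deterministic, and stated nowhere in
  the source analyses, which are silent on the case.
* Antisense-only overlaps are tallied separately and never merged into
  sense counts (a handful of real regulon genes show genuine antisense
  CRAC signal).
* Features missing from an abundance table are excluded from enrichment
  ranking with a message; absent pA evidence gives status `NA`.
* Zero-read features give `NA` intronic fractions; intronless features
  are an error for intron-specific operations.
* `N` bases never match any motif position and never count toward any
  k-mer.

## Known limitations

The NB test has no covariates, no outlier handling and no shrunken fold
changes; the pA cutoff direction is a documented choice, not a fact; the
decay-intron rule is a defined stand-in for an unpublished list; and all
genome-wide numbers from the original study (e.g. 445 down-regulated
transcripts, the 4.8% genome intron census) require the original genome
and raw reads, which this package deliberately does not depend on.
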