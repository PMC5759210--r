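---
title: "Quantifying A-to-I RNA editing from targeted amplicon reads"
author: "editscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying A-to-I RNA editing from targeted amplicon reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editscope)
```

## The measurement model

A-to-I editing converts adenosine to inosine in double-stranded RNA;
reverse transcription and sequencing read inosine as guanosine. At a known
editing site the data are therefore a binomial experiment: of the `n`
fragments covering the site, `count_G` carry the edited base, and the
editing level is estimated as

$$\hat p = \frac{\mathrm{count}_G}{\mathrm{count}_A + \mathrm{count}_G + \mathrm{count}_{other}}.$$

The denominator is the *total* number of covering fragments, including
fragments showing neither A nor G (sequencing errors, discordant mate
pairs). This keeps coverage interpretable as fragments; an `AG`-only
denominator is available through `editingLevels(..., denominator = "AG")`
for users who prefer to condition on informative reads. At typical error
rates the two differ by well under one part in a thousand.

Sites are only quantified at coverage ≥ 50 fragments (below that the
binomial standard error exceeds ~0.07 and estimates are reported as
missing), and two study-level filters follow: samples missing more than
30% of sites are dropped (oocyte samples are exempt — editing is
legitimately detectable at far fewer sites there), then sites with fewer
than 3 non-missing biological replicates in either comparison group are
dropped. The sample rule runs first: a failing sample should not cost a
site its replicate count. All thresholds are arguments with these
defaults.

## Read processing

Amplicon panels make alignment simple and that simplicity is deliberate:
reads are scanned ungapped, in both orientations, over every amplicon and
offset, and placed at the unique best-scoring position with at most 9
mismatches per read. Ties are rejected — on a designed panel a
multi-mapping read indicates an amplicon-design collision, not a
biological signal — and no indels are modeled, since the assay amplifies
fixed templates. Demultiplexing is by exact 6 nt barcode prefix on mate 1;
with 6 nt codes the edit-distance margin between barcodes is too thin for
a safe 1-mismatch rescue, so none is attempted. Fragment semantics: the
two mates of a pair vote once per site; if both cover a site and disagree,
the fragment is counted as `other` rather than giving either allele half a
vote.

## The Htr2c editing cluster

Five editable adenosines (A–E) sit in the codons for amino acids 156–160
of the serotonin receptor 2C transcript. Because all five fit inside one
read, each fragment yields a complete editing haplotype, and the sample's
isoform distribution is a direct per-read measurement rather than an
inference from marginals. A fragment is retained only if every cluster
site is covered and every observed base there is A or G; fragments with a
non-A/G base are excluded entirely so that every retained read is a
complete, trustworthy haplotype. The E site is collapsed away before
tallying by default (editing is typically undetected there by this assay);
collapsing before or after tallying provably commutes, which the tests
assert.

Translation uses the standard genetic code on the three affected codons:
position 156 gives I (unedited), V (A edited, with or without B) or M (B
alone); position 158 gives N, D (E), S (C) or G (E+C); position 160 gives
I or V (D). Exhaustive enumeration of the $2^5 = 32$ mRNA variants yields
24 distinct proteins; the only collisions are A-edited combinations with
and without B. The cluster sequence built by the generator is synthetic —
codons ATA/AAT/ATT with the editable positions placed so that A→G
substitutions reproduce exactly this table — and the tests verify the
naming both against `Biostrings::translate` on the actual variant
sequences and against the 32→24 collision structure.

A second, independent route assigns each read to one of the 32 variant
reference sequences (the cluster amplicon with sites toggled), unique best
hit at ≤ 6 mismatches. On error-free reads the two routes agree exactly;
at realistic error rates their total-variation distance stays below 0.02.
The agreement of two methods with different failure modes is the
cross-validation, so the package keeps both rather than collapsing them
into one.

The base-quality filter for externally sequenced cluster reads keeps a
read only when strictly more than 80% of its bases exceed Q20. The
threshold is applied to *read bases*; an alternative reading of the rule
("sites" = the five editing sites only) is accommodated by passing the
site-restricted quality substring to the same function.

## Synthetic data: what it emulates, and what it does not

The generator is the package's test bed and defines the conditions under
which its guarantees are demonstrated. It emulates: a panel of 48
amplicons of 150–350 bp carrying 146 sites (the default preset, matching
a realistic multiplex editing panel; one amplicon carries the phased
cluster), 76 bp paired-end reads with the 6 nt barcode occupying the
first six cycles of mate 1, per-site editing probabilities, *joint*
drawing of cluster-site states as complete isoforms from a frequency
vector (the linkage the cluster analysis measures — simulating cluster
sites independently would make the isoform analysis trivially wrong),
uniform substitution errors at a per-base rate ε (each alternative base
at ε/3; defaults 0–0.001, the regime of modern short-read platforms),
and configurable per-amplicon depth. Site positions are placed only
inside mate-covered windows, so every designed site is quantifiable —
real panels achieve the same by primer placement.

Deliberately not modeled: quality-score variation (flat Q37), PCR
duplicates and chimeras, indels, splice junctions, real genome
coordinates, and depth heterogeneity beyond the per-amplicon setting.
Passing tests therefore demonstrate correctness of the *computation* under
a clean generative model, not robustness to library-preparation artifacts;
per-amplicon depth in real data is heavy-tailed (a lognormal around 1000×
is a reasonable stand-in when one is needed), and none of the package's
estimators depend on the depth distribution beyond the coverage threshold.

Auxiliary signals mirror their assays at the level the estimators need:
Sanger peak areas with `G/(G+A)` equal to the true fraction before
multiplicative noise; gel band intensities with `upper/(upper+lower)`
equal to the splice fraction; Ct values as `baseline − log2(expression) +
noise`, so a 2× expression ratio shifts dCt by −1 cycle.

## Statistics

Group comparisons use the Mann-Whitney U test: U counts pairs won by the
first group with half-credit for ties. For `min(n1, n2) ≤ 8` the two-sided
p value comes from the exact permutation distribution over all group
relabelings — computed by enumeration, which remains valid under ties,
where the classical exact tables do not. Larger groups use the normal
approximation with tie correction and continuity correction. The
crossover at 8 keeps the test exact at the replicate counts targeted
amplicon studies actually have (typically 3–12 per group).

Multiple testing uses the Benjamini–Hochberg step-up rule at q = 0.1,
applied per comparison family (one grouping factor, one contrast, all
sites surviving the filters); the family definition is recorded on the
result object because pooling contrasts into one correction changes the
outcome and should be a visible choice. Directions (which group is
higher) are annotated post hoc from group medians; the tests themselves
are two-sided. Under a complete null the expected false-discovery
proportion is bounded by q, and with 5+5 samples the exact test's
granularity (minimum two-sided p of 2/252) makes rejections at 140-site
families essentially impossible — the null simulations in the acceptance
suite confirm the bound comfortably.

Pearson correlation and equal-variance one-way ANOVA are delegated to
`stats::cor.test` and `stats::oneway.test`; the package adds only input
validation and a stable return shape. The two-way designs, MANOVA and
post-hoc tests that accompany such studies are out of scope.

## qPCR normalization

`dCt = Ct_target − Ct_reference` (HPRT or GAPDH as reference). The
displayed normalization is the literal arithmetic `10 − dCt`, matching
how such data are commonly plotted; because the conventional quantity is
the relative expression `2^(−dCt)`, both are provided
(`qpcrNormalize(..., method = "log2")`), with the literal form as the
default. The contamination check for choroid-plexus marker F5 flags
`low_expression` only when Ct > 32 *and* dCt > 11.4, both strict — a
boundary value is treated as possible contamination, the conservative
direction for a quality-control gate.

## Numerical and design choices

* **Determinism.** Every stochastic entry point takes a seed and is
  byte-reproducible; the pipeline writes its thresholds into a log file.
* **Degenerate inputs.** Zero-coverage cells are missing, not zero;
  both-zero peak areas or band intensities raise an error rather than
  returning 0/0; an empty post-filter matrix and an empty isoform
  distribution raise classed conditions (`editscope_empty_filter`,
  `editscope_empty_distribution`) so callers can distinguish "nothing
  survived" from failure.
* **Tie-breaks.** Alignment ties are rejected (never randomly placed);
  rank ties in the U statistic take half-credit; equal medians are
  reported as direction `equal`.
* **Problem sizes in the test suite.** Unit tests run panels of 1–4
  amplicons at depths 30–10,000 chosen so that each assertion's
  statistical tolerance (3σ binomial or multinomial bands) is meaningful;
  the acceptance suite uses 10 sites × 10 samples at depth 1000 over three
  replicate experiments for parameter recovery, 50 replicates of a
  140-site null for FDR control, and depth-1000 technical replicates for
  reproducibility (r > 0.99). These sizes are the package's own choice of
  smallest-informative scale.
* **Recovery oracle under sequencing error.** Parameter recovery is
  judged against the error-model-implied expected G fraction
  $p(1-\varepsilon) + (1-p)\varepsilon/3$; at wholly unedited sites the
  naive band around $p = 0$ has zero width while any positive error rate
  guarantees a positive G fraction, so the naive comparison would reject
  a correct pipeline.

## Limitations

Barcode errors silently drop reads (exact matching), so demultiplexing
efficiency degrades at roughly 6ε per read — negligible at the default
error rates, visible at ε near the allowed maximum of 0.1. The aligner is
deliberately not a genome mapper: reads from sequences absent from the
panel will be forced onto their closest amplicon if within 9 mismatches.
SAM input is not parsed; alignments enter through the package's own
aligner or as in-memory fragment tables. The isoform machinery assumes
the cluster fits within one read — true for the Htr2c A–E cluster and
76 bp reads, not for arbitrarily wide clusters.
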