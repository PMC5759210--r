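# editscope

Site-level quantification of A-to-I RNA editing from targeted amplicon
sequencing, with per-read phasing of the serotonin receptor 2C (*Htr2c*)
editing cluster.

ADAR enzymes deaminate adenosine to inosine in double-stranded RNA;
sequencers read inosine as guanosine, so editing shows up as an A→G signal
at known sites. Multiplexed amplicon assays (such as microfluidic multiplex
PCR followed by deep sequencing) measure editing at a panel of pre-selected
sites across many barcoded samples at once. `editscope` implements the full
analysis for such assays, for researchers studying editing differences
between brain regions, developmental stages or experimental conditions:

* **Synthetic data generator** — amplicon panels, barcoded 76 bp paired-end
  reads with *linked* editing states across cluster sites (complete
  isoforms drawn from a frequency vector, never independent sites),
  uniform substitution errors, plus Sanger-style peak areas, splicing gel
  bands and qPCR Ct values — everything with ground-truth tables, so every
  stage is testable without external data.
* **Editing quantification** — exact 6 nt barcode demultiplexing, an
  ungapped both-orientation amplicon aligner (unique best hit, ≤ 9
  mismatches per read), fragment-level pileup (discordant mates count as
  `other`), editing level = `count_G / coverage` at sites with ≥ 50
  fragments, and the study-level filters (drop samples with > 30% of sites
  missing, oocytes exempt; drop sites with < 3 biological replicates per
  comparison group).
* **Cluster isoforms** — per-fragment haplotypes over the five *Htr2c*
  sites A–E (kept only when every site is covered with a clean A/G base),
  isoform tallies after collapsing the E site, protein naming through the
  affected codons (amino acids 156/158/160: INI unedited, VSV edited at
  ABCD, …), and the independent variant-reference assignment route
  (32 references, ≤ 6 mismatches) for cross-method validation.
* **Orthogonal assays** — Sanger peak-area editing
  `100·G/(G+A)`, *Adarb1* alternative-splicing percentage
  `100·upper/(upper+lower)` for the +47 nt self-editing-dependent splice,
  qPCR `dCt` with the displayed `10 − dCt` normalization and the
  F5 choroid-plexus contamination rule (Ct > 32 and dCt > 11.4), and the
  two-step NGS primer-architecture length check (151 bp / 223 bp products).
* **Statistics** — Mann-Whitney U (exact permutation p for small groups,
  ties included; tie-corrected normal approximation otherwise) with
  Benjamini–Hochberg step-up decisions at FDR q = 0.1 per comparison
  family, Pearson correlation, one-way ANOVA, and an end-to-end pipeline
  driver.

## Worked example

Simulate two technical replicates over a 3-amplicon panel carrying the
phased *Htr2c* cluster plus five independent sites, and run the full
pipeline (demultiplex → align → pileup → editing matrix → isoforms):

```r
library(editscope)

panel <- buildPanel(PanelConfig(nAmplicons = 3, nSites = 10, seed = 2))
freqs <- setNames(c(0.35, 0.3, 0.2, 0.15), c("", "AB", "ABCD", "ABD"))
st <- editingSites(panel)
nc <- st$site_id[is.na(st$letter)]
truths <- list(
  SampleTruth("ctrl1", "AACCGG",
              setNames(c(0.30, 0.45, 0.20, 0.60, 0.10), nc), freqs, depth = 500),
  SampleTruth("ctrl2", "TTGGCA",
              setNames(c(0.30, 0.45, 0.20, 0.60, 0.10), nc), freqs, depth = 500))
meta <- data.frame(sample_id = c("ctrl1", "ctrl2"), region = "PFC",
                   condition = "C", replicate_kind = "technical")
res <- runPipeline(panel, truths, meta = meta, minCoverage = 50,
                   minReplicates = 1, seed = 7)
round(editingMatrix(res$editing), 3)
#>           ctrl1 ctrl2
#> Htr2c_A   0.666 0.660
#> Htr2c_B   0.666 0.660
#> Htr2c_E   0.000 0.000
#> Htr2c_C   0.222 0.208
#> Htr2c_D   0.360 0.338
#> amp002_s1 0.300 0.304
#> amp002_s2 0.470 0.458
#> amp002_s3 0.200 0.190
#> amp003_s1 0.612 0.592
#> amp003_s2 0.096 0.096
```

Each cell is the fraction of covering fragments carrying G. The *Htr2c*
marginals follow from the isoform vector: site A is edited in the AB, ABCD
and ABD isoforms, so its true level is 0.3 + 0.2 + 0.15 = 0.65, and both
replicates estimate ≈ 0.66 at depth 500. Site E is never edited.

```r
res$isoforms$ctrl1
#>   protein subscript    label count percent
#> 1     INI                INI   167    33.4
#> 2     VNI        AB   VNI_AB   153    30.6
#> 3     VSV      ABCD VSV_ABCD   111    22.2
#> 4     VNV       ABD  VNV_ABD    69    13.8
```

The per-read phased isoform distribution recovers the simulated
frequencies (0.35/0.30/0.20/0.15); percentages are over fragments covering
all five cluster sites, after collapsing the E site.

```r
enumerateIsoforms()[c("nVariants", "nProteins")]
#> $nVariants  [1] 32
#> $nProteins  [1] 24
expectedAmpliconLengths(primerArchitecture())
#> step1 step2
#>   151   223
```

The five cluster sites generate 32 mRNA variants collapsing to 24 protein
isoforms, and the two-step library design yields the expected 151 bp and
223 bp PCR products.

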