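test_that("demultiplexing assigns by exact barcode and strips it", {
  reads <- data.frame(
    read_id = c("r1", "r2", "r3"),
    seq1 = c(paste0("AACCGG", strrep("A", 70)),
             paste0("TTGGCA", strrep("C", 70)),
             paste0("GGGGGG", strrep("A", 70))),
    qual1 = strrep("F", 76), seq2 = strrep("A", 76),
    qual2 = strrep("F", 76), stringsAsFactors = FALSE)
  dm <- demultiplex(reads, c(s1 = "AACCGG", s2 = "TTGGCA"))
  expect_equal(dm$samples$s1$read_id, "r1")
  expect_equal(dm$samples$s2$read_id, "r2")
  expect_equal(dm$unassigned$read_id, "r3")
  expect_equal(nchar(dm$samples$s1$seq1), 70L)
  expect_error(demultiplex(reads, c(a = "AACCGG", b = "AACCGG")),
               "duplicate")
  expect_error(demultiplex(reads, c(a = "AACC")), "6 nt")
})

test_that("demultiplexed per-sample counts equal simulated depths", {
  panel <- smallPanel(seed = 2)
  trs <- list(makeTruth(panel, "s1", "AACCGG", depth = 40),
              makeTruth(panel, "s2", "TTGGCA", depth = 55),
              makeTruth(panel, "s3", "CAGTCA", depth = 25))
  sim <- simulateReads(panel, trs, seed = 3)
  bcs <- c(s1 = "AACCGG", s2 = "TTGGCA", s3 = "CAGTCA")
  dm <- demultiplex(sim$reads, bcs)
  nAmp <- length(ampliconSeqs(panel))
  expect_equal(vapply(dm$samples, nrow, integer(1)),
               c(s1 = 40L, s2 = 55L, s3 = 25L) * nAmp)
  expect_equal(nrow(dm$unassigned), 0L)
})

test_that("aligner places exact substrings and respects the mismatch cap", {
  panel <- smallPanel(seed = 2)
  amp <- as.character(ampliconSeqs(panel)[[2]])
  ampId <- names(ampliconSeqs(panel))[2]
  read <- substr(amp, 11, 86)
  hit <- alignReads(read, panel)
  expect_equal(hit$amplicon_id, ampId)
  expect_equal(hit$offset, 10L)
  expect_equal(hit$strand, "+")
  expect_equal(hit$mismatches, 0L)
  # reverse-complement maps to the minus strand at the same locus
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  hitRC <- alignReads(rc, panel)
  expect_equal(hitRC$amplicon_id, ampId)
  expect_equal(hitRC$offset, 10L)
  expect_equal(hitRC$strand, "-")
  # 9 substitutions still map, 10 are rejected
  read9 <- mutateAt(read, seq(2, 74, by = 9)[1:9])
  read10 <- mutateAt(read, seq(2, 74, by = 8)[1:10])
  expect_equal(alignReads(read9, panel)$mismatches, 9L)
  expect_true(is.na(alignReads(read10, panel)$amplicon_id))
})

test_that("ambiguous best hits are rejected, confirmed by exhaustive scan", {
  dup <- duplicatePanel()
  read <- substr(as.character(ampliconSeqs(dup)[[1]]), 5, 60)
  # exhaustive mismatch scan over both amplicons finds a tied best score
  scores <- vapply(seq_len(2), function(i) {
    ref <- ampliconSeqs(dup)[[i]]
    min(Biostrings::neditStartingAt(
      Biostrings::DNAString(read), ref,
      starting.at = seq_len(length(ref) - nchar(read) + 1L)))
  }, numeric(1))
  expect_equal(scores[1], scores[2])
  expect_true(is.na(alignReads(read, dup)$amplicon_id))
})

test_that("pileup counts fragments, sends discordant mates to other", {
  panel <- smallPanel(seed = 2)
  st <- editingSites(panel)
  site <- st[st$start < 64, ][1, ]  # a site under mate 1 of both fragments
  expect_false(is.na(site$site_id))
  amp <- site$amplicon_id
  seqA <- as.character(ampliconSeqs(panel)[[amp]])
  L <- nchar(seqA)
  seqG <- mutateAt(seqA, site$start + 1L, "G")
  m1 <- function(s) substr(s, 1, 70)
  m2 <- function(s) substr(s, L - 75, L)
  fr <- makeFragments(amp,
                      sense1 = c(rep(m1(seqG), 40), rep(m1(seqA), 60)),
                      off1 = 0L,
                      sense2 = c(rep(m2(seqG), 40), rep(m2(seqA), 60)),
                      off2 = L - 76L)
  calls <- pileupCounts(fr, panel, "s")
  row <- calls[calls$site_id == site$site_id, ]
  expect_equal(row$count_G, 40L)
  expect_equal(row$count_A, 60L)
  expect_equal(row$count_other, 0L)
  # conservation at every site
  expect_true(all(calls$count_A + calls$count_G + calls$count_other ==
                    calls$coverage))
  # overlapping discordant mates count as other
  frD <- makeFragments(amp, sense1 = m1(seqG), off1 = 0L,
                       sense2 = substr(seqA, 1, 76), off2 = 0L)
  callsD <- pileupCounts(frD, panel, "s")
  rowD <- callsD[callsD$site_id == site$site_id, ]
  expect_equal(rowD$count_other, 1L)
  expect_equal(rowD$coverage, 1L)
})

test_that("pileup equals a brute-force per-read recount on error-free data", {
  panel <- smallPanel(seed = 2)
  trs <- list(makeTruth(panel, "s1", "AACCGG", depth = 80),
              makeTruth(panel, "s2", "TTGGCA", depth = 80))
  sim <- simulateReads(panel, trs, seed = 17)
  dm <- demultiplex(sim$reads, c(s1 = "AACCGG", s2 = "TTGGCA"))
  calls <- do.call(rbind, lapply(names(dm$samples), function(s)
    pileupCounts(alignFragments(dm$samples[[s]], panel), panel, s)))
  bf <- bruteForceCounts(sim, panel)
  key <- function(d) d[order(d$sample_id, d$site_id),
                       c("sample_id", "site_id", "count_A", "count_G",
                         "count_other")]
  a <- key(calls); b <- key(bf)
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("editing levels honour the coverage threshold and the formula", {
  calls <- data.frame(sample_id = "s1",
                      site_id = c("x", "y", "z"),
                      count_A = c(25L, 24L, 10L),
                      count_G = c(25L, 25L, 85L),
                      count_other = c(0L, 0L, 5L),
                      stringsAsFactors = FALSE)
  ee <- editingLevels(calls, minCoverage = 50)
  ed <- editingMatrix(ee)
  expect_equal(ed["x", "s1"], 0.5)       # coverage 50 -> quantified
  expect_true(is.na(ed["y", "s1"]))      # coverage 49 -> missing
  expect_equal(ed["z", "s1"], 0.85)      # other kept in the denominator
  eeAG <- editingLevels(calls, minCoverage = 50, denominator = "AG")
  expect_equal(editingMatrix(eeAG)["z", "s1"], 85 / 95)
  # monotone in count_G at fixed coverage
  cG <- 0:50
  levels <- vapply(cG, function(g) {
    c1 <- data.frame(sample_id = "s", site_id = "x", count_A = 50L - g,
                     count_G = g, count_other = 0L)
    editingMatrix(editingLevels(c1, minCoverage = 50))[1, 1]
  }, numeric(1))
  expect_true(all(diff(levels) > 0))
})

test_that("estimates track truth within binomial error through the pipeline", {
  panel <- buildPanel(PanelConfig(nAmplicons = 2, nSites = 6,
                                  cluster = FALSE, seed = 8))
  st <- editingSites(panel)
  p <- setNames(rep(0.3, nrow(st)), st$site_id)
  tr <- SampleTruth("s1", "AACCGG", p, depth = 1000, errorRate = 0)
  res <- runPipeline(panel, tr, minCoverage = 50, minReplicates = 1,
                     seed = 23)
  ed <- editingMatrix(res$editing)[, "s1"]
  tol <- 3 * sqrt(0.3 * 0.7 / 1000)
  expect_true(all(abs(ed - 0.3) <= tol))
})

test_that("replicate and missingness filters follow the exclusion rules", {
  ed <- matrix(0.5, nrow = 10, ncol = 8,
               dimnames = list(sprintf("site%02d", 1:10),
                               sprintf("s%d", 1:8)))
  # site02: only 2 non-missing replicates in the control group
  ed["site02", c("s1", "s2")] <- NA
  # s7: 40% of sites missing
  ed["site01", ] <- ed["site01", ] + seq(0.01, 0.08, by = 0.01)
  ed[1:4, "s7"] <- NA
  meta <- data.frame(sample_id = sprintf("s%d", 1:8),
                     condition = rep(c("C", "PRS"), each = 4),
                     region = "PFC", replicate_kind = "biological")
  toEE <- function(ed, meta) {
    calls <- data.frame(sample_id = rep(colnames(ed), each = nrow(ed)),
                        site_id = rep(rownames(ed), ncol(ed)),
                        count_A = as.vector(round(100 * (1 - ed))),
                        count_G = as.vector(round(100 * ed)),
                        count_other = 0L)
    calls$count_A[is.na(calls$count_A)] <- 0L
    calls$count_G[is.na(calls$count_G)] <- 0L
    editingLevels(calls, meta = meta, minCoverage = 50)
  }
  ee <- toEE(ed, meta)
  filt <- filterEditing(ee, group = "condition")
  expect_false("s7" %in% colnames(filt))     # sample-level rule first
  expect_false("site02" %in% rownames(filt)) # <3 replicates in group C
  expect_true(all(setdiff(rownames(ee), "site02") %in% rownames(filt)))
  # complete matrix passes unchanged
  edC <- matrix(runif(80), 10, 8,
                dimnames = dimnames(ed))
  eeC <- toEE(round(edC, 2), meta)
  filtC <- filterEditing(eeC, group = "condition")
  expect_equal(dim(filtC), dim(eeC))
  # oocyte samples are exempt from the sample-level rule
  metaO <- meta; metaO$region <- ifelse(meta$sample_id == "s7", "oocyte",
                                        "PFC")
  eeO <- toEE(ed, metaO)
  filtO <- filterEditing(eeO, group = "condition")
  expect_true("s7" %in% colnames(filtO))
  # nothing-survives signal
  edBad <- ed; edBad[] <- NA
  expect_error(filterEditing(toEE(edBad, meta), group = "condition"),
               class = "editscope_empty_filter")
})

test_that("technical replicates from one truth are tightly correlated", {
  panel <- buildPanel(PanelConfig(nAmplicons = 4, nSites = 12,
                                  cluster = FALSE, seed = 10))
  st <- editingSites(panel)
  p <- setNames(seq(0.05, 0.9, length.out = nrow(st)), st$site_id)
  tr <- SampleTruth("t", "AACCGG", p, depth = 1000, errorRate = 0.001)
  ed <- vapply(c(31, 32), function(sd) {
    sim <- simulateReads(panel, tr, seed = sd)
    counts <- bruteForceCounts(sim, panel)
    counts$count_G / counts$coverage
  }, numeric(nrow(st)))
  expect_gt(cor(ed[, 1], ed[, 2]), 0.99)
})
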