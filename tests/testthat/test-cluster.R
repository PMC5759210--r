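test_that("the codon table names known isoforms correctly", {
  expect_equal(translateIsoform("")$name, "INI")
  expect_equal(translateIsoform("")$label, "INI")
  expect_equal(translateIsoform("ABCD")$label, "VSV_ABCD")
  expect_equal(translateIsoform("AB")$label, "VNI_AB")
  expect_equal(translateIsoform("ABD")$label, "VNV_ABD")
  expect_equal(translateIsoform("ABC")$label, "VSI_ABC")
  expect_equal(translateIsoform("BC")$label, "MSI_BC")
  expect_equal(translateIsoform("ABCDE")$name, "VGV")
  expect_equal(translateIsoform("E")$name, "IDI")
  expect_equal(translateIsoform(c(A = TRUE, B = FALSE, C = FALSE,
                                  D = TRUE, E = FALSE))$label, "VNV_AD")
})

test_that("the codon table agrees with translating the cluster sequence", {
  panel <- smallPanel(seed = 2)
  cl <- panelCluster(panel)
  refs <- variantReferences(panel)
  en <- enumerateIsoforms(cl)
  codonStarts <- cl@offsets[c("A", "E", "D")] # first base of each codon
  for (i in seq_len(nrow(en$table))) {
    sub <- en$table$subscript[i]
    nm <- ifelse(nzchar(sub), sub, "unedited")
    s <- refs[[nm]]
    aa <- vapply(codonStarts, function(cs) {
      codon <- Biostrings::subseq(s, cs + 1L, cs + 3L)
      # inosine is read as G by the polymerase/sequencer
      as.character(Biostrings::translate(Biostrings::DNAString(
        as.character(codon))))
    }, character(1))
    expect_equal(paste(aa, collapse = ""), en$table$protein[i])
  }
})

test_that("exhaustive enumeration gives 32 variants and 24 proteins", {
  en <- enumerateIsoforms()
  expect_equal(en$nVariants, 32L)
  expect_equal(en$nProteins, 24L)
  # collision structure: merged pairs differ exactly by {A} vs {A,B}
  dup <- split(en$table$subscript, en$table$protein)
  merged <- dup[lengths(dup) > 1]
  expect_true(all(lengths(merged) == 2))
  for (pair in merged) {
    both <- strsplit(pair, "")
    d1 <- setdiff(both[[2]], both[[1]])
    d2 <- setdiff(both[[1]], both[[2]])
    expect_true(setequal(c(d1, d2), "B"))
    expect_true("A" %in% both[[1]] && "A" %in% both[[2]])
  }
  expect_equal(en$nVariants - en$nProteins, length(merged))
  # 1-site toy cluster
  toy <- enumerateIsoforms("D")
  expect_equal(toy$nVariants, 2L)
  expect_equal(toy$nProteins, 2L)
})

test_that("haplotypes require full coverage and clean A/G bases", {
  panel <- smallPanel(seed = 2)
  cl <- panelCluster(panel)
  amp <- as.character(ampliconSeqs(panel)[["Htr2c"]])
  L <- nchar(amp)
  g <- function(letters) mutateAt(amp, cl@offsets[letters] + 1L, "G")
  m1 <- function(s) substr(s, 1, 70)
  m2 <- function(s) substr(s, L - 75, L)
  full <- function(s, id) makeFragments("Htr2c", m1(s), 0L, m2(s), L - 76L,
                                        ids = id)
  fr <- rbind(full(g(c("A", "B")), "ab"),
              full(amp, "ref"),
              # mate pair that misses the cluster entirely on mate 1
              makeFragments("Htr2c", substr(amp, 41, 110), 40L,
                            m2(amp), L - 76L, ids = "partial"),
              full(mutateAt(amp, cl@offsets[["C"]] + 1L, "T"), "badbase"))
  haps <- readHaplotypes(fr, cl)
  expect_equal(haps$status[haps$read_id == "ab"], "retained")
  expect_equal(haps$haplotype[haps$read_id == "ab"], "AB")
  expect_equal(haps$haplotype[haps$read_id == "ref"], "")
  expect_equal(haps$status[haps$read_id == "partial"], "partial")
  expect_equal(haps$status[haps$read_id == "badbase"], "non_AG")
  # discordant mates exclude the fragment
  frD <- makeFragments("Htr2c", m1(g("A")), 0L, substr(amp, 1, 76), 0L,
                       ids = "disc")
  expect_equal(readHaplotypes(frD, cl)$status, "discordant")
  # exclusions leave the retained tallies untouched
  dist <- isoformDistribution(haps, cl)
  expect_equal(sum(dist$count), 2L)
})

test_that("isoform distribution recovers simulated frequencies", {
  panel <- smallPanel(seed = 2)
  freqs <- setNames(c(0.5, 0.3, 0.2), c("", "AB", "ABCD"))
  tr <- makeTruth(panel, "s1", "AACCGG", p = 0.2, isoformFreq = freqs,
                  depth = 5000)
  sim <- simulateReads(panel, tr, seed = 41)
  dm <- demultiplex(sim$reads, c(s1 = "AACCGG"))
  haps <- readHaplotypes(alignFragments(dm$samples$s1, panel),
                         panel@cluster)
  dist <- isoformDistribution(haps, panel@cluster)
  expect_equal(sum(dist$percent), 100)
  expected <- c(INI = 0.5, VNI_AB = 0.3, VSV_ABCD = 0.2)
  for (lab in names(expected)) {
    p <- expected[[lab]]
    got <- dist$percent[dist$label == lab] / 100
    expect_lt(abs(got - p), 3 * sqrt(p * (1 - p) / 5000))
  }
})

test_that("collapsing the E site merges haplotypes, before or after tally", {
  haps <- c("AB", "ABE", "ABCD", "ABCDE", "", "E")
  d1 <- isoformDistribution(haps, excluded = "E")
  expect_equal(sort(d1$subscript), sort(c("AB", "ABCD", "")))
  expect_equal(d1$count[d1$subscript == "AB"], 2L)
  expect_equal(d1$count[d1$subscript == ""], 2L)
  # collapse-then-tally equals tally-then-merge
  pre <- gsub("E", "", haps)
  d2 <- isoformDistribution(pre, excluded = character())
  expect_equal(d1[order(d1$subscript), c("subscript", "count", "percent")],
               d2[order(d2$subscript), c("subscript", "count", "percent")])
  # empty distribution is an explicit signal
  expect_error(isoformDistribution(character()),
               class = "editscope_empty_distribution")
})

test_that("quality filter keeps reads with >80% of bases above Q20", {
  q <- function(phred, n) strrep(intToUtf8(phred + 33L), n)
  expect_true(qualityFilter(q(30, 50)))
  expect_false(qualityFilter(paste0(q(10, 30), q(30, 20))))  # 40% good
  # exactly 80% above threshold fails the strict inequality
  expect_false(qualityFilter(paste0(q(30, 40), q(20, 10))))
  expect_true(qualityFilter(paste0(q(30, 41), q(10, 9))))
  expect_false(qualityFilter(""))
  # Q20 itself does not count as "above 20"
  expect_false(qualityFilter(q(20, 50)))
})

test_that("variant-reference assignment matches templates and caps mismatches", {
  panel <- smallPanel(seed = 2)
  refs <- variantReferences(panel)
  expect_equal(length(refs), 32L)
  read <- substr(as.character(refs[["ABD"]]), 1, 76)
  expect_equal(assignVariant(read, refs), "ABD")
  # 7 mismatches against the nearest variant -> unassigned
  # (mutate positions away from the cluster so no variant absorbs them)
  far <- seq(50, 74, by = 4)[1:7]
  read7 <- mutateAt(read, far)
  expect_true(is.na(assignVariant(read7, refs, maxMismatches = 6)))
  expect_equal(assignVariant(mutateAt(read, far[1:6]), refs,
                             maxMismatches = 6), "ABD")
})

test_that("haplotype tally and variant assignment agree on clean reads", {
  panel <- smallPanel(seed = 2)
  freqs <- setNames(c(0.45, 0.25, 0.2, 0.1), c("", "AB", "ABCD", "ABD"))
  tr <- makeTruth(panel, "s1", "AACCGG", p = 0.1, isoformFreq = freqs,
                  depth = 1500)
  sim <- simulateReads(panel, tr, seed = 43)
  dm <- demultiplex(sim$reads, c(s1 = "AACCGG"))
  fr <- alignFragments(dm$samples$s1, panel)
  haps <- readHaplotypes(fr, panel@cluster)
  d1 <- isoformDistribution(haps, panel@cluster)
  # variant route: assign the cluster-covering mate of each fragment
  cfr <- fr[fr$amplicon_id == "Htr2c", ]
  refs <- variantReferences(panel)
  v <- assignVariant(cfr$sense1, refs)
  d2 <- variantDistribution(v, panel@cluster)
  key <- function(d) d[order(d$subscript), c("subscript", "count")]
  expect_equal(key(d1), key(d2), ignore_attr = TRUE)
})
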