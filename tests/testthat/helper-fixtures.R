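# Shared fixtures: small panels and truths built in code.

smallPanel <- function(seed = 2L, nAmplicons = 3L, nSites = 11L) {
  buildPanel(PanelConfig(nAmplicons = nAmplicons, nSites = nSites,
                         seed = seed))
}

# uniform truth over the non-cluster sites plus a cluster isoform vector
makeTruth <- function(panel, sampleId, barcode, p = 0.3,
                      isoformFreq = setNames(c(0.5, 0.3, 0.2),
                                             c("", "AB", "ABCD")),
                      depth = 200, errorRate = 0) {
  st <- editingSites(panel)
  nc <- st$site_id[is.na(st$letter)]
  siteP <- if (length(p) == 1L) setNames(rep(p, length(nc)), nc)
           else p
  if (is.null(panel@cluster)) isoformFreq <- numeric()
  SampleTruth(sampleId, barcode, siteP, isoformFreq, depth = depth,
              errorRate = errorRate)
}

# a panel whose two amplicons are identical, to force ambiguous alignments
duplicatePanel <- function(seed = 4L) {
  p <- buildPanel(PanelConfig(nAmplicons = 1L, nSites = 2L, cluster = FALSE,
                              seed = seed))
  seqs <- ampliconSeqs(p)
  dup <- Biostrings::DNAStringSet(c(as.character(seqs[[1]]),
                                    as.character(seqs[[1]])))
  names(dup) <- c("ampA", "ampB")
  st <- editingSites(p)
  st$amplicon_id <- "ampA"
  st$site_id <- paste0("ampA_", seq_len(nrow(st)))
  new("AmpliconPanel", sequences = dup, sites = st, cluster = NULL)
}

# hand-built fragment table rows (sense-strand mate sequences + offsets)
makeFragments <- function(ampliconId, sense1, off1, sense2, off2,
                          ids = sprintf("r%04d", seq_along(sense1))) {
  data.frame(read_id = ids, amplicon_id = ampliconId,
             off1 = off1, sense1 = sense1,
             qual1 = strrep("F", nchar(sense1)),
             off2 = off2, sense2 = sense2,
             qual2 = strrep("F", nchar(sense2)),
             stringsAsFactors = FALSE)
}

# substitute bases at given 1-based positions of a string; base = NULL
# flips to a base guaranteed to differ from the current one
mutateAt <- function(s, pos, base = NULL) {
  for (p in pos) {
    cur <- substr(s, p, p)
    nb <- if (is.null(base)) setdiff(c("A", "C", "G", "T"), cur)[1] else base
    substr(s, p, p) <- nb
  }
  s
}

# independent brute-force editing recount straight from the simulation's
# read table (no aligner, no pileup): uses the truth read layout, mate 1 =
# barcode + amplicon[1..w-6], mate 2 = revcomp(amplicon[L-w+1..L])
bruteForceCounts <- function(sim, panel, readLength = 76L) {
  st <- editingSites(panel)
  lens <- setNames(Biostrings::width(ampliconSeqs(panel)),
                   names(ampliconSeqs(panel)))
  reads <- sim$reads
  out <- list()
  for (sid in unique(reads$sample_id)) {
    rs <- reads[reads$sample_id == sid, ]
    for (i in seq_len(nrow(st))) {
      amp <- st$amplicon_id[i]
      pos <- st$start[i]
      L <- lens[[amp]]
      w <- min(readLength, L)
      rr <- rs[rs$amplicon_id == amp, ]
      b <- rep(NA_character_, nrow(rr))
      in1 <- pos < (w - 6L)
      in2 <- pos >= (L - w)
      if (in1) b <- substr(rr$seq1, 6L + pos + 1L, 6L + pos + 1L)
      if (in2) {
        # mate 2 read position for amplicon position pos (read is revcomp)
        rp <- L - pos
        b2 <- chartr("ACGT", "TGCA", substr(rr$seq2, rp, rp))
        b <- if (in1) ifelse(b == b2, b, "X") else b2
      }
      out[[paste(sid, st$site_id[i])]] <- data.frame(
        sample_id = sid, site_id = st$site_id[i],
        count_A = sum(b == "A", na.rm = TRUE),
        count_G = sum(b == "G", na.rm = TRUE),
        count_other = sum(!is.na(b)) - sum(b %in% c("A", "G")),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res$coverage <- res$count_A + res$count_G + res$count_other
  res
}
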