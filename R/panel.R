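#' Configuration for a synthetic amplicon panel
#'
#' The default preset mirrors a microfluidic multiplex PCR (mmPCR-seq)
#' editing panel: 48 amplicons of 150--350 bp carrying 146 editing sites in
#' total, one amplicon holding the phased Htr2c-like A--E cluster. Sites are
#' placed only inside the windows covered by 76 bp paired-end reads (the
#' first 70 genomic bases after the 6 nt barcode on mate 1, and the last
#' 76 bases under mate 2), so every designed site is quantifiable.
#'
#' @param nAmplicons number of amplicons.
#' @param nSites total number of editing sites across the panel (the phased
#'   cluster contributes its 5 sites to this total).
#' @param lengthRange integer length-2 vector, amplicon length bounds in bp.
#' @param baseComposition probabilities over A/C/G/T for background sequence.
#' @param cluster logical; include the 5-site Htr2c-like phased cluster on
#'   the first amplicon.
#' @param readLength sequencing read length the site-placement windows
#'   assume.
#' @param barcodeLength barcode prefix length on mate 1.
#' @param seed integer seed; the panel is deterministic given the seed.
#' @return A list of class `PanelConfig`.
#' @examples
#' cfg <- PanelConfig(seed = 1)
#' panel <- buildPanel(cfg)
#' @export
PanelConfig <- function(nAmplicons = 48L, nSites = 146L,
                        lengthRange = c(150L, 350L),
                        baseComposition = c(A = 0.25, C = 0.25,
                                            G = 0.25, T = 0.25),
                        cluster = TRUE, readLength = 76L,
                        barcodeLength = 6L, seed = 1L) {
  stopifnot(nAmplicons >= 1L, nSites >= 0L,
            length(lengthRange) == 2L, lengthRange[1] <= lengthRange[2],
            lengthRange[1] >= 60L)
  bc <- baseComposition[c("A", "C", "G", "T")]
  if (anyNA(bc) || any(bc < 0) || sum(bc) <= 0)
    stop("baseComposition must give non-negative probabilities for A,C,G,T")
  structure(list(nAmplicons = as.integer(nAmplicons),
                 nSites = as.integer(nSites),
                 lengthRange = as.integer(lengthRange),
                 baseComposition = bc / sum(bc),
                 cluster = isTRUE(cluster),
                 readLength = as.integer(readLength),
                 barcodeLength = as.integer(barcodeLength),
                 seed = as.integer(seed)),
            class = "PanelConfig")
}

# 15 bp cluster block: codons 156-158-160 (ATA / AAT / ATT) with editable
# adenosines A,B at codon-156 positions 1,3; E,C at codon-158 positions 1,2;
# D at codon-160 position 1. A->G at these positions reproduces the
# I/V/M, N/D/S/G, I/V amino-acid changes of the Htr2c cluster.
.CLUSTER_BLOCK <- "ATACGGAATCCGATT"
.CLUSTER_REL_OFFSETS <- c(A = 0L, B = 2L, E = 6L, C = 7L, D = 12L)

.randomSeq <- function(n, probs) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

#' Build a synthetic amplicon panel
#'
#' Generates amplicon reference sequences and an annotated editing-site
#' table from a [PanelConfig()]. The reference base at every site is forced
#' to A (mRNA sense strand). Deterministic for a fixed seed.
#'
#' @param config a [PanelConfig()].
#' @return An [AmpliconPanel-class].
#' @export
buildPanel <- function(config = PanelConfig()) {
  stopifnot(inherits(config, "PanelConfig"))
  set.seed(config$seed)
  nA <- config$nAmplicons
  lens <- sample(seq(config$lengthRange[1], config$lengthRange[2]),
                 nA, replace = TRUE)
  ids <- sprintf("amp%03d", seq_len(nA))
  clusterSpec <- NULL
  clusterLetters <- character(0)
  if (config$cluster) {
    ids[1] <- "Htr2c"
    clusterLetters <- names(.CLUSTER_REL_OFFSETS)
  }

  # allocate site counts per amplicon: the cluster amplicon carries exactly
  # its 5 phased sites; the rest are spread as evenly as possible
  nFree <- config$nSites - length(clusterLetters)
  if (nFree < 0)
    stop("nSites is smaller than the cluster site count")
  freeAmps <- if (config$cluster) seq_len(nA)[-1] else seq_len(nA)
  if (nFree > 0 && length(freeAmps) == 0)
    stop("no amplicon available for non-cluster sites")
  alloc <- integer(nA)
  if (nFree > 0) {
    base <- nFree %/% length(freeAmps)
    extra <- nFree %% length(freeAmps)
    alloc[freeAmps] <- base + as.integer(seq_along(freeAmps) <= extra)
  }

  # per-amplicon windows guaranteed covered by one of the two mates
  mate1Span <- config$readLength - config$barcodeLength
  margin <- 5L
  seqs <- character(nA)
  siteRows <- vector("list", nA)
  for (i in seq_len(nA)) {
    L <- lens[i]
    s <- .randomSeq(L, config$baseComposition)
    isCluster <- config$cluster && i == 1L
    placed <- integer(0)
    letters_i <- rep(NA_character_, 0)
    if (isCluster) {
      at <- 20L  # cluster block start, inside the mate-1 window
      substr(s, at + 1L, at + nchar(.CLUSTER_BLOCK)) <- .CLUSTER_BLOCK
      placed <- at + .CLUSTER_REL_OFFSETS
      letters_i <- names(.CLUSTER_REL_OFFSETS)
      clusterSpec <- ClusterSpec("Htr2c", sort(placed))
    }
    if (alloc[i] > 0) {
      win <- seq(margin, min(mate1Span - margin, L - margin - 1L))
      w2from <- max(mate1Span - margin + 1L, L - config$readLength + margin)
      w2to <- L - margin - 1L
      if (w2from <= w2to) win <- c(win, seq(w2from, w2to))
      win <- setdiff(unique(win), placed)
      if (length(win) < alloc[i])
        stop(sprintf("amplicon %s: %d sites requested but only %d placeable positions",
                     ids[i], alloc[i], length(win)))
      pos <- sort(sample(win, alloc[i]))
      placed <- c(placed, pos)
      letters_i <- c(letters_i, rep(NA_character_, length(pos)))
    }
    if (length(placed)) {
      for (p in placed) substr(s, p + 1L, p + 1L) <- "A"
      ord <- order(placed)
      siteRows[[i]] <- data.frame(
        amplicon_id = ids[i],
        start = as.integer(placed[ord]),
        letter = letters_i[ord],
        stringsAsFactors = FALSE)
    }
    seqs[i] <- s
  }
  sites <- do.call(rbind, siteRows)
  sites$end <- sites$start + 1L
  sites$site_id <- ifelse(!is.na(sites$letter),
                          paste0(sites$amplicon_id, "_", sites$letter),
                          paste0(sites$amplicon_id, "_s",
                                 stats::ave(sites$start, sites$amplicon_id,
                                            FUN = seq_along)))
  # annotation categories in panel-like proportions (cluster sites recode
  # protein sequence, hence nonsynonymous)
  sites$category <- sample(SITE_CATEGORIES, nrow(sites), replace = TRUE,
                           prob = c(0.45, 0.2, 0.2, 0.05, 0.05, 0.05))
  sites$category[!is.na(sites$letter)] <- "nonsyn"
  sites <- sites[, c("site_id", "amplicon_id", "start", "end",
                     "category", "letter")]
  rownames(sites) <- NULL

  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- ids
  new("AmpliconPanel", sequences = dna, sites = sites, cluster = clusterSpec)
}

#' Write a panel to FASTA plus a BED-like site table
#'
#' @param panel an [AmpliconPanel-class].
#' @param fastaPath output FASTA path for the amplicon sequences.
#' @param sitesPath output path for the 0-based half-open site table
#'   (columns: amplicon_id, start, end, site_id, category, letter).
#' @return Invisibly, the two paths.
#' @export
writePanel <- function(panel, fastaPath, sitesPath) {
  Biostrings::writeXStringSet(panel@sequences, fastaPath)
  st <- panel@sites[, c("amplicon_id", "start", "end", "site_id",
                        "category", "letter")]
  utils::write.table(st, sitesPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta = fastaPath, sites = sitesPath))
}

#' Read a panel back from FASTA plus a site table
#'
#' @param fastaPath FASTA of amplicon sequences.
#' @param sitesPath site table as written by [writePanel()].
#' @param cluster optional [ClusterSpec-class]; if NULL it is reconstructed
#'   from the `letter` column when present.
#' @return An [AmpliconPanel-class].
#' @export
readPanel <- function(fastaPath, sitesPath, cluster = NULL) {
  dna <- Biostrings::readDNAStringSet(fastaPath)
  names(dna) <- sub("\\s.*$", "", names(dna))
  st <- utils::read.delim(sitesPath, stringsAsFactors = FALSE)
  if (!"letter" %in% names(st)) st$letter <- NA_character_
  st$letter[st$letter %in% c("", "NA")] <- NA_character_
  st <- st[, c("site_id", "amplicon_id", "start", "end", "category", "letter")]
  if (is.null(cluster) && any(!is.na(st$letter))) {
    cl <- st[!is.na(st$letter), ]
    cl <- cl[order(cl$start), ]
    cluster <- ClusterSpec(cl$amplicon_id[1],
                           structure(cl$start, names = cl$letter))
  }
  new("AmpliconPanel", sequences = dna, sites = st, cluster = cluster)
}
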