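#' Simulate barcoded paired-end amplicon reads
#'
#' Emulates targeted amplicon sequencing of edited transcripts: for every
#' fragment, cluster sites are drawn *jointly* as a complete isoform from the
#' sample's isoform-frequency vector (the within-read linkage the cluster
#' analysis measures), non-cluster sites independently with their per-site
#' probabilities, G substituted at edited positions, then uniform per-base
#' substitution errors applied at rate `errorRate` (each alternative base
#' with probability `errorRate/3`; no indels -- an ungapped amplicon assay).
#' Mate 1 carries the 6 nt sample barcode followed by the first bases of the
#' amplicon; mate 2 is the reverse complement of the amplicon 3' end. Both
#' mates are `readLength` bases.
#'
#' @param panel an [AmpliconPanel-class].
#' @param truths a [SampleTruth-class] or list of them (one per sample);
#'   reads from all samples are pooled, as after barcode PCR.
#' @param readLength read length in bp (default 76).
#' @param quality flat phred quality for every base (default 37).
#' @param seed integer seed; all randomness is derived from it.
#' @return A list of class `ReadSimulation` with elements
#'   \describe{
#'     \item{reads}{data.frame: read_id, amplicon_id (truth), sample_id
#'       (truth), seq1, qual1, seq2, qual2.}
#'     \item{truth}{list with data.frames `sites` (sample_id, site_id,
#'       true_p) and `isoforms` (sample_id, isoform subscript,
#'       true_frequency).}
#'   }
#' @examples
#' panel <- buildPanel(PanelConfig(nAmplicons = 2, nSites = 7, seed = 1))
#' tr <- SampleTruth("s1", "AACCGG",
#'                   siteP = setNames(rep(0.3, 2),
#'                                    grep("amp", editingSites(panel)$site_id,
#'                                         value = TRUE)),
#'                   isoformFreq = setNames(c(0.6, 0.4), c("", "ABCD")),
#'                   depth = 100)
#' sim <- simulateReads(panel, tr, seed = 7)
#' @export
simulateReads <- function(panel, truths, readLength = 76L, quality = 37L,
                          seed = 1L) {
  if (is(truths, "SampleTruth")) truths <- list(truths)
  stopifnot(length(truths) >= 1L, all(vapply(truths, is, logical(1),
                                             "SampleTruth")))
  set.seed(as.integer(seed))
  cl <- panel@cluster
  ampSeqs <- as.character(panel@sequences)
  ampLens <- nchar(ampSeqs)
  sites <- panel@sites
  qchar <- rawToChar(as.raw(33L + as.integer(quality)))

  readRows <- list()
  truthSites <- list()
  truthIso <- list()
  for (truth in truths) {
    validObject(truth)
    sid <- truth@sampleId
    depth <- truth@depth
    if (length(depth) == 1L && is.null(names(depth)))
      depth <- structure(rep(depth, length(ampSeqs)), names = names(ampSeqs))
    if (!all(names(ampSeqs) %in% names(depth)))
      stop("depth must cover every amplicon (scalar or named vector)")
    if (any(depth[names(ampSeqs)] <= 0)) stop("depth must be positive")

    # record truth marginals: independent sites as given, cluster sites
    # implied by the isoform frequency vector
    pRec <- truth@siteP
    if (!is.null(cl) && length(truth@isoformFreq)) {
      clSites <- sites[!is.na(sites$letter), ]
      pm <- impliedClusterP(truth, letters = clSites$letter)
      pRec <- c(pRec, structure(pm, names = clSites$site_id))
    }
    nonCluster <- sites$site_id[is.na(sites$letter)]
    missing <- setdiff(nonCluster, names(truth@siteP))
    if (length(missing))
      stop("siteP missing for sites: ", paste(utils::head(missing, 3),
                                              collapse = ", "))
    truthSites[[sid]] <- data.frame(sample_id = sid,
                                    site_id = names(pRec),
                                    true_p = unname(pRec),
                                    stringsAsFactors = FALSE)
    if (length(truth@isoformFreq))
      truthIso[[sid]] <- data.frame(sample_id = sid,
                                    isoform = names(truth@isoformFreq),
                                    true_frequency = unname(truth@isoformFreq),
                                    stringsAsFactors = FALSE)

    for (amp in names(ampSeqs)) {
      n <- as.integer(round(depth[[amp]]))
      L <- ampLens[[amp]]
      w <- min(readLength, L)
      st <- sites[sites$amplicon_id == amp, ]
      isClusterAmp <- !is.null(cl) && identical(amp, cl@ampliconId)

      # per-fragment edited status at each site on this amplicon
      edited <- matrix(FALSE, n, nrow(st))
      if (nrow(st)) colnames(edited) <- st$site_id
      if (isClusterAmp && length(truth@isoformFreq)) {
        iso <- sample(names(truth@isoformFreq), n, replace = TRUE,
                      prob = truth@isoformFreq)
        for (k in which(!is.na(st$letter)))
          edited[, k] <- grepl(st$letter[k], iso, fixed = TRUE)
      }
      for (k in which(is.na(st$letter)))
        edited[, k] <- stats::runif(n) < truth@siteP[[st$site_id[k]]]

      # build fragment sequences as a character matrix of single bases
      frag <- matrix(strsplit(ampSeqs[[amp]], "")[[1]], nrow = n, ncol = L,
                     byrow = TRUE)
      for (k in seq_len(nrow(st)))
        frag[edited[, k], st$start[k] + 1L] <- "G"

      m1 <- frag[, seq_len(w - nchar(truth@barcode)), drop = FALSE]
      bc <- matrix(strsplit(truth@barcode, "")[[1]], nrow = n,
                   ncol = nchar(truth@barcode), byrow = TRUE)
      m1 <- cbind(bc, m1)
      m2 <- frag[, seq(L - w + 1L, L), drop = FALSE]
      m2 <- .revcompMatrix(m2)
      if (truth@errorRate > 0) {
        m1 <- .applyErrors(m1, truth@errorRate)
        m2 <- .applyErrors(m2, truth@errorRate)
      }
      readRows[[paste(sid, amp)]] <- data.frame(
        read_id = sprintf("%s:%s:%06d", sid, amp, seq_len(n)),
        amplicon_id = amp, sample_id = sid,
        seq1 = .collapseRows(m1), qual1 = strrep(qchar, ncol(m1)),
        seq2 = .collapseRows(m2), qual2 = strrep(qchar, ncol(m2)),
        stringsAsFactors = FALSE)
    }
  }
  out <- list(reads = do.call(rbind, c(readRows, list(make.row.names = FALSE))),
              truth = list(sites = do.call(rbind, c(truthSites,
                                                    list(make.row.names = FALSE))),
                           isoforms = if (length(truthIso))
                             do.call(rbind, c(truthIso,
                                              list(make.row.names = FALSE)))
                           else NULL))
  class(out) <- "ReadSimulation"
  out
}

.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

.revcompMatrix <- function(m) {
  m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
  matrix(.COMP[m], nrow = nrow(m))
}

.applyErrors <- function(m, eps) {
  hit <- which(stats::runif(length(m)) < eps)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    # uniform substitution to one of the three alternative bases
    repl <- vapply(m[hit], function(b)
      sample(setdiff(bases, b), 1L), character(1))
    m[hit] <- repl
  }
  m
}

.collapseRows <- function(m) {
  apply(m, 1L, paste, collapse = "")
}

#' Write simulated reads as a FASTQ pair
#'
#' @param sim a `ReadSimulation` from [simulateReads()], or any data.frame
#'   with columns read_id, seq1, qual1, seq2, qual2.
#' @param prefix output path prefix; files `<prefix>_R1.fastq` and
#'   `<prefix>_R2.fastq` are written.
#' @param gzip compress the output files.
#' @return Invisibly, the two file paths.
#' @export
writeFastqPair <- function(sim, prefix, gzip = FALSE) {
  reads <- if (is.data.frame(sim)) sim else sim$reads
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  paths <- paste0(prefix, c("_R1", "_R2"), ext)
  for (mate in 1:2) {
    s <- reads[[paste0("seq", mate)]]
    q <- reads[[paste0("qual", mate)]]
    lines <- as.vector(rbind(paste0("@", reads$read_id, "/", mate),
                             s, "+", q))
    con <- if (gzip) gzfile(paths[mate], "wb") else file(paths[mate], "wb")
    writeLines(lines, con)
    close(con)
  }
  invisible(paths)
}

#' Read a FASTQ pair into the in-memory read table
#'
#' @param path1,path2 FASTQ files for mates 1 and 2, matched by order.
#' @return data.frame with read_id, seq1, qual1, seq2, qual2.
#' @export
readFastqPair <- function(path1, path2) {
  r1 <- Biostrings::readDNAStringSet(path1, format = "fastq",
                                     with.qualities = TRUE)
  r2 <- Biostrings::readDNAStringSet(path2, format = "fastq",
                                     with.qualities = TRUE)
  stopifnot(length(r1) == length(r2))
  data.frame(read_id = sub("/[12]$", "", sub("\\s.*$", "", names(r1))),
             seq1 = as.character(r1),
             qual1 = as.character(S4Vectors::mcols(r1)$qualities),
             seq2 = as.character(r2),
             qual2 = as.character(S4Vectors::mcols(r2)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write ground-truth tables
#'
#' @param sim a `ReadSimulation`.
#' @param prefix output prefix; `<prefix>_truth_sites.tsv` and (when a
#'   cluster was simulated) `<prefix>_truth_isoforms.tsv` are written.
#' @return Invisibly, the written paths.
#' @export
writeTruthTables <- function(sim, prefix) {
  p1 <- paste0(prefix, "_truth_sites.tsv")
  utils::write.table(sim$truth$sites, p1, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- p1
  if (!is.null(sim$truth$isoforms)) {
    p2 <- paste0(prefix, "_truth_isoforms.tsv")
    utils::write.table(sim$truth$isoforms, p2, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p2)
  }
  invisible(paths)
}

#' Simulate Sanger-style chromatogram peak areas
#'
#' Per-site A and G peak areas whose noiseless ratio
#' `areaG / (areaG + areaA)` equals the true editing fraction. Multiplicative
#' lognormal-like noise is applied to each area.
#'
#' @param trueEditing numeric vector of true editing fractions in [0, 1],
#'   optionally named by site.
#' @param noiseSd standard deviation of the Gaussian noise on log areas
#'   (0 = noiseless).
#' @param totalArea expected total peak area per site (arbitrary units).
#' @param seed integer seed.
#' @return data.frame with site, area_A, area_G.
#' @export
simulateTrace <- function(trueEditing, noiseSd = 0.05, totalArea = 1000,
                          seed = 1L) {
  stopifnot(all(trueEditing >= 0), all(trueEditing <= 1))
  if (noiseSd < 0) stop("noiseSd must be non-negative")
  set.seed(as.integer(seed))
  n <- length(trueEditing)
  aG <- totalArea * trueEditing
  aA <- totalArea * (1 - trueEditing)
  if (noiseSd > 0) {
    aG <- aG * exp(stats::rnorm(n, 0, noiseSd))
    aA <- aA * exp(stats::rnorm(n, 0, noiseSd))
  }
  data.frame(site = if (is.null(names(trueEditing)))
    sprintf("site%d", seq_len(n)) else names(trueEditing),
    area_A = aA, area_G = aG, stringsAsFactors = FALSE)
}

#' Simulate auxiliary assay signals (splicing gel, qPCR)
#'
#' Band intensities whose noiseless ratio `upper / (upper + lower)` equals
#' the alternative-splicing fraction, and qPCR Ct values generated as
#' `baselineCt - log2(expression) + noise` so that an expression ratio of
#' 2x between groups shifts dCt by -1 cycle.
#'
#' @param spliceFraction per-sample fraction of the +47 nt (alternatively
#'   spliced, inactive) isoform, in [0, 1].
#' @param expression per-sample relative expression of the qPCR target
#'   (positive; 1 = baseline).
#' @param baselineCt Ct of the target at expression 1.
#' @param refCt Ct of the housekeeping reference gene.
#' @param noiseSd Gaussian noise SD applied to band intensities
#'   (multiplicative on log scale) and Ct values (additive, cycles).
#' @param totalIntensity expected total band intensity.
#' @param seed integer seed.
#' @return list with data.frames `gel` (sample, upper, lower) and `qpcr`
#'   (sample, ct_target, ct_reference).
#' @export
simulateAux <- function(spliceFraction, expression = rep(1, length(spliceFraction)),
                        baselineCt = 25, refCt = 20, noiseSd = 0,
                        totalIntensity = 1000, seed = 1L) {
  stopifnot(all(spliceFraction >= 0), all(spliceFraction <= 1),
            all(expression > 0))
  if (noiseSd < 0) stop("noiseSd must be non-negative")
  set.seed(as.integer(seed))
  n <- length(spliceFraction)
  ids <- sprintf("sample%d", seq_len(n))
  upper <- totalIntensity * spliceFraction
  lower <- totalIntensity * (1 - spliceFraction)
  ct <- baselineCt - log2(expression)
  if (noiseSd > 0) {
    upper <- upper * exp(stats::rnorm(n, 0, noiseSd))
    lower <- lower * exp(stats::rnorm(n, 0, noiseSd))
    ct <- ct + stats::rnorm(n, 0, noiseSd)
  }
  list(gel = data.frame(sample = ids, upper = upper, lower = lower,
                        stringsAsFactors = FALSE),
       qpcr = data.frame(sample = ids, ct_target = ct,
                         ct_reference = rep(refCt, n),
                         stringsAsFactors = FALSE))
}
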