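#' Simulate an editing experiment at the count level
#'
#' Draws per-site G counts directly from the binomial sampling model the
#' read-level generator induces at zero sequencing error: at each site and
#' sample, `count_G ~ Binomial(depth, p)` with the remainder as A. Useful
#' for statistical calibration studies (null false-discovery-rate and power
#' simulations) where the full FASTQ round trip adds nothing.
#'
#' @param trueP numeric matrix of true editing probabilities (sites x
#'   samples), or a per-site vector recycled across samples.
#' @param depth fragments per site-sample cell (scalar or matrix).
#' @param meta optional sample metadata (data.frame with sample_id, passed
#'   to [sampleMeta()]).
#' @param minCoverage detection threshold (default 50).
#' @param seed integer seed, or NULL to use the current RNG state.
#' @return An [EditingExperiment-class].
#' @export
simulateEditingExperiment <- function(trueP, depth = 1000L, meta = NULL,
                                      minCoverage = 50L, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (!is.matrix(trueP)) {
    nm <- names(trueP)
    nS <- if (!is.null(meta)) nrow(meta) else 2L
    trueP <- matrix(trueP, nrow = length(trueP), ncol = nS)
    rownames(trueP) <- if (is.null(nm))
      sprintf("site%03d", seq_len(nrow(trueP))) else nm
  }
  if (is.null(rownames(trueP)))
    rownames(trueP) <- sprintf("site%03d", seq_len(nrow(trueP)))
  if (is.null(colnames(trueP)))
    colnames(trueP) <- if (!is.null(meta)) meta$sample_id
                       else sprintf("sample%02d", seq_len(ncol(trueP)))
  stopifnot(all(trueP >= 0 & trueP <= 1))
  dep <- if (is.matrix(depth)) depth
         else matrix(depth, nrow(trueP), ncol(trueP))
  G <- matrix(stats::rbinom(length(trueP), as.vector(dep),
                            as.vector(trueP)),
              nrow(trueP), dimnames = dimnames(trueP))
  calls <- data.frame(
    sample_id = rep(colnames(trueP), each = nrow(trueP)),
    site_id = rep(rownames(trueP), ncol(trueP)),
    count_A = as.vector(dep - G), count_G = as.vector(G),
    count_other = 0L, stringsAsFactors = FALSE)
  editingLevels(calls, meta = meta, minCoverage = minCoverage)
}

#' Run the full editing analysis on simulated or provided reads
#'
#' End-to-end driver: simulate reads (or take them as given), demultiplex
#' by barcode, align mates to the panel, pile up fragment base counts,
#' compute the filtered editing matrix, compare groups site-by-site, and
#' phase the cluster isoform distribution per sample. Deterministic for a
#' fixed seed. When `outdir` is given, the editing matrix, site calls,
#' comparison table, isoform tables and a log recording every threshold are
#' written as TSV.
#'
#' @param panel an [AmpliconPanel-class].
#' @param truths list of [SampleTruth-class] objects (simulated input), or
#'   NULL when `reads` is supplied.
#' @param reads optional pre-made pooled read data.frame (as from
#'   [simulateReads()] or [readFastqPair()]); barcodes are then taken from
#'   `barcodes`.
#' @param barcodes named barcode map (sample id -> 6 nt); defaults to the
#'   truths' barcodes.
#' @param meta sample metadata data.frame (sample_id plus factors).
#' @param compareBy optional colData column for the group comparison.
#' @param minCoverage,minReplicates,maxMissing,q analysis thresholds
#'   (defaults 50, 3, 0.30, 0.1).
#' @param maxMismatches aligner mismatch allowance (default 9).
#' @param seed integer seed for the simulation step.
#' @param outdir optional output directory.
#' @return list with `sim` (when simulated), `demux` counts, `editing`
#'   (unfiltered [EditingExperiment-class]), `filtered`, `comparison`
#'   (or NULL), `isoforms` (per-sample list), `paths` of written files.
#' @export
runPipeline <- function(panel, truths = NULL, reads = NULL, barcodes = NULL,
                        meta = NULL, compareBy = NULL, minCoverage = 50L,
                        minReplicates = 3L, maxMissing = 0.30, q = 0.1,
                        maxMismatches = 9L, seed = 1L, outdir = NULL) {
  if (is.null(truths) && is.null(reads))
    stop("missing input: provide `truths` to simulate or `reads` to analyse")
  sim <- NULL
  if (is.null(reads)) {
    if (is(truths, "SampleTruth")) truths <- list(truths)
    sim <- simulateReads(panel, truths, seed = seed)
    reads <- sim$reads
  }
  if (is.null(barcodes)) {
    if (is.null(truths))
      stop("missing input: `barcodes` is required when reads are supplied")
    barcodes <- vapply(truths, function(t) t@barcode, character(1))
    names(barcodes) <- vapply(truths, function(t) t@sampleId, character(1))
  }
  dm <- demultiplex(reads, barcodes)
  calls <- list()
  haplos <- list()
  isoforms <- list()
  for (sid in names(dm$samples)) {
    fr <- alignFragments(dm$samples[[sid]], panel,
                         maxMismatches = maxMismatches)
    calls[[sid]] <- pileupCounts(fr, panel, sampleId = sid)
    if (!is.null(panel@cluster)) {
      hp <- readHaplotypes(fr, panel@cluster)
      haplos[[sid]] <- hp
      isoforms[[sid]] <- tryCatch(isoformDistribution(hp, panel@cluster),
                                  editscope_empty_distribution = function(e) NULL)
    }
  }
  callsTab <- do.call(rbind, c(calls, list(make.row.names = FALSE)))
  ee <- editingLevels(callsTab, meta = meta, sites = editingSites(panel),
                      minCoverage = minCoverage)
  filtered <- tryCatch(
    filterEditing(ee, group = compareBy, minReplicates = minReplicates,
                  maxMissingFraction = maxMissing),
    editscope_empty_filter = function(e) NULL)
  comparison <- NULL
  if (!is.null(compareBy) && !is.null(filtered))
    comparison <- compareGroups(filtered, compareBy, q = q)

  paths <- character()
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(paths, writeEditingMatrix(
      ee, file.path(outdir, "editing_matrix.tsv"),
      file.path(outdir, "site_calls.tsv")))
    if (!is.null(comparison)) {
      p <- file.path(outdir, "comparison.tsv")
      utils::write.table(comparison, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      paths <- c(paths, p)
    }
    if (length(isoforms)) {
      iso <- do.call(rbind, lapply(names(isoforms), function(s)
        if (!is.null(isoforms[[s]]))
          cbind(sample_id = s, isoforms[[s]], stringsAsFactors = FALSE)))
      if (!is.null(iso)) {
        p <- file.path(outdir, "isoforms.tsv")
        utils::write.table(iso, p, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        paths <- c(paths, p)
      }
    }
    log <- c(sprintf("editscope pipeline log"),
             sprintf("seed: %d", seed),
             sprintf("min_coverage: %d", minCoverage),
             sprintf("min_replicates: %d", minReplicates),
             sprintf("max_missing: %g", maxMissing),
             sprintf("q: %g", q),
             sprintf("max_mismatches: %d", maxMismatches),
             sprintf("samples: %s", paste(names(dm$samples), collapse = ",")),
             sprintf("unassigned_reads: %d", nrow(dm$unassigned)))
    logPath <- file.path(outdir, "pipeline_log.txt")
    writeLines(log, logPath)
    paths <- c(paths, logPath)
  }
  invisible(list(sim = sim,
                 demux = vapply(dm$samples, nrow, integer(1)),
                 calls = callsTab, editing = ee, filtered = filtered,
                 comparison = comparison, haplotypes = haplos,
                 isoforms = isoforms, paths = paths))
}
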