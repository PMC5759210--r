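#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

SITE_CATEGORIES <- c("nonsyn", "syn", "3UTR", "5UTR", "intronic", "intergenic")
BRAIN_REGIONS   <- c("PFC", "AMY", "oocyte", "whole_brain")
AGE_LEVELS      <- c("P0", "P60")
CONDITION_LEVELS <- c("C", "PRS")
GENERATION_LEVELS <- c("F0", "F1", "F2")
REPLICATE_KINDS <- c("biological", "technical")

#' Specification of a linked editing-site cluster
#'
#' Describes a set of co-located editing sites on one amplicon whose per-read
#' editing states are phased jointly, such as the five adenosines (A--E) of
#' the serotonin receptor 2C (Htr2c) transcript within the codons for amino
#' acids 156--160. Site letters are stored in amplicon order together with
#' their 0-based offsets; `excluded` names letters dropped before isoform
#' tallying (the E site by default, where editing is typically undetectable
#' by targeted amplicon sequencing).
#'
#' @slot ampliconId character(1), the amplicon carrying the cluster.
#' @slot letters character, cluster site letters (subset of A--E) in
#'   amplicon order.
#' @slot offsets integer, 0-based offsets of the sites within the amplicon,
#'   named by letter and strictly increasing.
#' @slot excluded character, letters collapsed away before isoform tallying.
#' @exportClass ClusterSpec
setClass("ClusterSpec", representation(
  ampliconId = "character",
  letters = "character",
  offsets = "integer",
  excluded = "character"
))

setValidity("ClusterSpec", function(object) {
  msg <- character()
  if (length(object@ampliconId) != 1L)
    msg <- c(msg, "ampliconId must be a single string")
  if (!all(object@letters %in% LETTERS[1:5]))
    msg <- c(msg, "cluster letters must come from A-E")
  if (anyDuplicated(object@letters))
    msg <- c(msg, "cluster letters must be unique")
  if (length(object@offsets) != length(object@letters) ||
      !identical(names(object@offsets), object@letters))
    msg <- c(msg, "offsets must be named by the cluster letters, in order")
  if (length(object@offsets) > 1L && any(diff(object@offsets) <= 0L))
    msg <- c(msg, "sites must be strictly ordered along the amplicon")
  if (!all(object@excluded %in% object@letters))
    msg <- c(msg, "excluded letters must be cluster letters")
  if (length(msg)) msg else TRUE
})

#' Construct a ClusterSpec
#'
#' @param ampliconId amplicon carrying the cluster.
#' @param offsets named integer vector of 0-based site offsets; names are the
#'   site letters (subset of A--E) and must be in increasing offset order.
#' @param excluded letters excluded from isoform tallying (default `"E"`,
#'   dropped when present among the cluster letters).
#' @return A [ClusterSpec-class] object.
#' @examples
#' ClusterSpec("Htr2c", c(A = 20L, B = 22L, E = 26L, C = 27L, D = 32L))
#' @export
ClusterSpec <- function(ampliconId, offsets, excluded = "E") {
  new("ClusterSpec",
      ampliconId = as.character(ampliconId),
      letters = names(offsets),
      offsets = structure(as.integer(offsets), names = names(offsets)),
      excluded = intersect(excluded, names(offsets)))
}

setMethod("show", "ClusterSpec", function(object) {
  cat("ClusterSpec on amplicon", object@ampliconId, "\n")
  cat("  sites:",
      paste(sprintf("%s@%d", object@letters, object@offsets), collapse = " "),
      "\n")
  if (length(object@excluded))
    cat("  excluded from isoform tallying:",
        paste(object@excluded, collapse = ", "), "\n")
})

#' Amplicon panel with annotated editing sites
#'
#' The assay design: reference amplicon sequences (mRNA sense strand) plus a
#' table of editable adenosines. Every site's reference base is A; editing is
#' always read out as A-to-G on the sense strand, the sequencing signature of
#' A-to-I deamination.
#'
#' @slot sequences [Biostrings::DNAStringSet] of amplicon reference sequences.
#' @slot sites data.frame with columns `site_id`, `amplicon_id`, `start`
#'   (0-based), `end` (half-open, `start + 1`), `category`
#'   (nonsyn/syn/3UTR/5UTR/intronic/intergenic) and `letter`
#'   (cluster letter or NA).
#' @slot cluster a [ClusterSpec-class], or NULL if the panel has no phased
#'   cluster.
#' @exportClass AmpliconPanel
setClass("AmpliconPanel", representation(
  sequences = "DNAStringSet",
  sites = "data.frame",
  cluster = "ANY"
))

setValidity("AmpliconPanel", function(object) {
  msg <- character()
  st <- object@sites
  need <- c("site_id", "amplicon_id", "start", "end", "category")
  if (!all(need %in% names(st)))
    return(paste("sites table must have columns",
                 paste(need, collapse = ", ")))
  if (anyDuplicated(st$site_id))
    msg <- c(msg, "site_id values must be unique")
  if (!all(st$amplicon_id %in% names(object@sequences)))
    msg <- c(msg, "sites refer to amplicons absent from the panel")
  if (!all(st$category %in% SITE_CATEGORIES))
    msg <- c(msg, "site categories must come from the closed annotation set")
  lens <- Biostrings::width(object@sequences)[match(st$amplicon_id,
                                                    names(object@sequences))]
  if (any(st$start < 1L | st$start >= lens - 1L))
    msg <- c(msg, "every site must lie strictly inside its amplicon")
  if (!all(st$end == st$start + 1L))
    msg <- c(msg, "sites are single bases: end must equal start + 1")
  ref <- substring(as.character(object@sequences[st$amplicon_id]),
                   st$start + 1L, st$start + 1L)
  if (!all(ref == "A"))
    msg <- c(msg, "reference base at every editing site must be A (sense strand)")
  if (!is.null(object@cluster)) {
    cl <- object@cluster
    if (!is(cl, "ClusterSpec"))
      msg <- c(msg, "cluster must be a ClusterSpec or NULL")
    else if (!cl@ampliconId %in% names(object@sequences))
      msg <- c(msg, "cluster amplicon is absent from the panel")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "AmpliconPanel", function(object) {
  cat("AmpliconPanel:", length(object@sequences), "amplicons,",
      nrow(object@sites), "editing sites\n")
  w <- Biostrings::width(object@sequences)
  cat("  amplicon lengths:", min(w), "-", max(w), "bp\n")
  cat("  site categories:",
      paste(sprintf("%s=%d", names(table(object@sites$category)),
                    table(object@sites$category)), collapse = " "), "\n")
  if (!is.null(object@cluster))
    cat("  phased cluster on", object@cluster@ampliconId, "(",
        paste(object@cluster@letters, collapse = ""), ")\n")
})

#' @describeIn AmpliconPanel-class amplicon reference sequences.
#' @param panel an AmpliconPanel.
#' @export
ampliconSeqs <- function(panel) panel@sequences

#' @describeIn AmpliconPanel-class the editing-site table.
#' @export
editingSites <- function(panel) panel@sites

#' @describeIn AmpliconPanel-class the phased cluster specification (or NULL).
#' @export
panelCluster <- function(panel) panel@cluster

#' Ground-truth description of one simulated sample
#'
#' Drives the read generator: per-site editing probabilities, the isoform
#' frequency vector for the phased cluster, sequencing depth and a uniform
#' per-base substitution error rate. The marginal editing probability at a
#' cluster site is implied by the isoform frequencies (the probability mass
#' of isoforms edited at that site), never specified separately.
#'
#' @slot sampleId character(1).
#' @slot barcode 6-nt sample barcode (ACGT).
#' @slot siteP named numeric, editing probability per non-cluster site.
#' @slot isoformFreq named numeric over edited-letter subscripts (e.g. ""
#'   for unedited, "AB", "ABCD"); sums to 1. Empty when the panel has no
#'   cluster.
#' @slot depth numeric, fragments per amplicon (scalar, or named by amplicon).
#' @slot errorRate per-base substitution probability in [0, 0.1].
#' @exportClass SampleTruth
setClass("SampleTruth", representation(
  sampleId = "character",
  barcode = "character",
  siteP = "numeric",
  isoformFreq = "numeric",
  depth = "numeric",
  errorRate = "numeric"
))

setValidity("SampleTruth", function(object) {
  msg <- character()
  if (nchar(object@barcode) != 6L ||
      grepl("[^ACGT]", object@barcode))
    msg <- c(msg, "barcode must be a 6-nt ACGT string")
  if (length(object@siteP) && (any(object@siteP < 0) || any(object@siteP > 1)))
    msg <- c(msg, "site editing probabilities must lie in [0, 1]")
  if (length(object@isoformFreq)) {
    if (any(object@isoformFreq < 0))
      msg <- c(msg, "isoform frequencies must be non-negative")
    if (abs(sum(object@isoformFreq) - 1) > 1e-8)
      msg <- c(msg, "isoform frequencies must sum to 1")
  }
  if (any(object@depth <= 0))
    msg <- c(msg, "depth must be positive")
  if (object@errorRate < 0 || object@errorRate > 0.1)
    msg <- c(msg, "errorRate must lie in [0, 0.1]")
  if (length(msg)) msg else TRUE
})

#' Construct a SampleTruth
#'
#' @param sampleId sample identifier.
#' @param barcode 6-nt ACGT barcode.
#' @param siteP named numeric vector of per-site editing probabilities for
#'   non-cluster sites (names are site ids).
#' @param isoformFreq named numeric vector of cluster isoform frequencies;
#'   names are edited-letter subscripts ("" = fully unedited). Must sum to 1.
#' @param depth fragments per amplicon; a scalar or a vector named by
#'   amplicon id.
#' @param errorRate uniform per-base substitution error probability.
#' @return A [SampleTruth-class] object.
#' @examples
#' SampleTruth("s1", "AACCGG", c(site1 = 0.3),
#'             setNames(c(0.5, 0.3, 0.2), c("", "AB", "ABCD")), depth = 1000)
#' @export
SampleTruth <- function(sampleId, barcode, siteP = numeric(),
                        isoformFreq = numeric(), depth = 1000,
                        errorRate = 0) {
  new("SampleTruth", sampleId = as.character(sampleId),
      barcode = toupper(barcode), siteP = siteP,
      isoformFreq = isoformFreq, depth = depth,
      errorRate = errorRate)
}

setMethod("show", "SampleTruth", function(object) {
  cat("SampleTruth", object@sampleId, sprintf("[%s]", object@barcode), "\n")
  cat("  ", length(object@siteP), "independent sites;",
      length(object@isoformFreq), "cluster isoforms; depth",
      paste(object@depth, collapse = "/"),
      "; error rate", object@errorRate, "\n")
})

#' Cluster-site marginal editing probabilities implied by isoform frequencies
#'
#' @param truth a [SampleTruth-class].
#' @param letters cluster letters to report (default A--E letters appearing
#'   in the subscripts).
#' @return Named numeric vector of marginal per-site editing probabilities.
#' @export
impliedClusterP <- function(truth, letters = NULL) {
  fr <- truth@isoformFreq
  if (!length(fr)) return(numeric())
  if (is.null(letters))
    letters <- sort(unique(unlist(strsplit(names(fr), ""))))
  vapply(letters, function(L) sum(fr[grepl(L, names(fr), fixed = TRUE)]),
         numeric(1))
}

#' Container for site-level editing measurements
#'
#' A [SummarizedExperiment::SummarizedExperiment] (sites as rows, samples as
#' columns) with assays `countA`, `countG`, `countOther`, `coverage` and
#' `editing`. Editing levels are the fraction of covering fragments carrying
#' G at the site; cells with coverage below the detection threshold are NA.
#'
#' @exportClass EditingExperiment
setClass("EditingExperiment", contains = "SummarizedExperiment")

setValidity("EditingExperiment", function(object) {
  msg <- character()
  need <- c("countA", "countG", "countOther", "coverage", "editing")
  if (!all(need %in% names(assays(object))))
    return(paste("assays must include", paste(need, collapse = ", ")))
  ed <- assay(object, "editing")
  if (any(ed < 0 | ed > 1, na.rm = TRUE))
    msg <- c(msg, "editing levels must lie in [0, 1] or be NA")
  cov <- assay(object, "coverage")
  tot <- assay(object, "countA") + assay(object, "countG") +
    assay(object, "countOther")
  if (!isTRUE(all.equal(cov, tot)))
    msg <- c(msg, "coverage must equal countA + countG + countOther")
  if (length(msg)) msg else TRUE
})

#' @describeIn EditingExperiment-class the samples-by-sites editing matrix
#'   (sites as rows), NA where coverage fell below threshold.
#' @param x an EditingExperiment.
#' @export
editingMatrix <- function(x) assay(x, "editing")

setMethod("show", "EditingExperiment", function(object) {
  callNextMethod()
  ed <- editingMatrix(object)
  cat(sprintf("editing: %d/%d site-sample cells quantified (%.1f%% missing)\n",
              sum(!is.na(ed)), length(ed), 100 * mean(is.na(ed))))
})

#' Validate a sample-metadata table
#'
#' Checks the experimental factors against their closed level sets and
#' returns a `DataFrame` keyed by sample id, suitable as `colData`.
#'
#' @param df data.frame with column `sample_id` and any of `region`
#'   (PFC/AMY/oocyte/whole_brain), `age` (P0/P60), `condition` (C/PRS),
#'   `generation` (F0/F1/F2), `replicate_kind` (biological/technical).
#' @return A [S4Vectors::DataFrame] with rownames set to sample ids.
#' @export
sampleMeta <- function(df) {
  stopifnot(is.data.frame(df), "sample_id" %in% names(df))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata")
  levsets <- list(region = BRAIN_REGIONS, age = AGE_LEVELS,
                  condition = CONDITION_LEVELS,
                  generation = GENERATION_LEVELS,
                  replicate_kind = REPLICATE_KINDS)
  for (col in intersect(names(levsets), names(df))) {
    bad <- setdiff(unique(as.character(df[[col]])), levsets[[col]])
    if (length(bad))
      stop(sprintf("invalid %s level(s): %s", col, paste(bad, collapse = ", ")))
    df[[col]] <- factor(as.character(df[[col]]), levels = levsets[[col]])
  }
  out <- DataFrame(df)
  rownames(out) <- df$sample_id
  out
}
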