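#' Per-site base counts from aligned fragments
#'
#' One count contribution per fragment per site. A fragment covers a site
#' when either mate overlaps it; when both mates cover the site they must
#' agree, otherwise the fragment is counted as `other` at that site (a
#' discordant observation should not vote for either allele, and keeping it
#' in the denominator leaves coverage interpretable as fragments). Bases are
#' binned as A, G or other on the sense strand.
#'
#' @param fragments data.frame from [alignFragments()].
#' @param panel an [AmpliconPanel-class].
#' @param sampleId sample identifier attached to the output rows.
#' @return data.frame: sample_id, site_id, count_A, count_G, count_other,
#'   coverage. Every panel site appears, with zero counts when uncovered.
#' @export
pileupCounts <- function(fragments, panel, sampleId = "sample") {
  sites <- panel@sites
  ampLens <- structure(Biostrings::width(panel@sequences),
                       names = names(panel@sequences))
  if (any(sites$start >= ampLens[sites$amplicon_id]))
    stop("panel integrity error: site outside its amplicon")
  out <- data.frame(sample_id = sampleId, site_id = sites$site_id,
                    count_A = 0L, count_G = 0L, count_other = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(sites))) {
    fr <- fragments[fragments$amplicon_id == sites$amplicon_id[i], ,
                    drop = FALSE]
    if (nrow(fr) == 0L) next
    pos <- sites$start[i]
    b <- .fragmentBaseAt(fr, pos)
    covered <- !is.na(b)
    out$count_A[i] <- sum(b[covered] == "A")
    out$count_G[i] <- sum(b[covered] == "G")
    out$count_other[i] <- sum(covered) - out$count_A[i] - out$count_G[i]
  }
  out$coverage <- out$count_A + out$count_G + out$count_other
  out
}

# Base observed by a fragment at amplicon position `pos` (0-based):
# the mate base when one mate covers, the agreed base when both do, and
# "X" (counted as other) when the mates disagree. NA = not covered.
.fragmentBaseAt <- function(fr, pos) {
  w1 <- nchar(fr$sense1)
  w2 <- nchar(fr$sense2)
  c1 <- fr$off1 <= pos & pos < fr$off1 + w1
  c2 <- fr$off2 <= pos & pos < fr$off2 + w2
  b1 <- ifelse(c1, substr(fr$sense1, pos - fr$off1 + 1L,
                          pos - fr$off1 + 1L), NA_character_)
  b2 <- ifelse(c2, substr(fr$sense2, pos - fr$off2 + 1L,
                          pos - fr$off2 + 1L), NA_character_)
  out <- ifelse(c1 & c2, ifelse(b1 == b2, b1, "X"),
                ifelse(c1, b1, ifelse(c2, b2, NA_character_)))
  out
}

#' Site-level editing fractions with a coverage threshold
#'
#' Builds an [EditingExperiment-class] from per-sample site calls. The
#' editing level is the fraction of covering fragments carrying G:
#' `count_G / coverage`. Sites covered by fewer than `minCoverage`
#' fragments in a sample are reported as NA (not quantifiable). The
#' denominator includes `count_other` by default (total fragments); set
#' `denominator = "AG"` to divide by A+G fragments only.
#'
#' @param calls data.frame of site calls, the row-bound output of
#'   [pileupCounts()] across samples.
#' @param meta optional sample metadata ([sampleMeta()] input or output).
#' @param sites optional site annotation data.frame (e.g.
#'   `editingSites(panel)`) used as rowData.
#' @param minCoverage minimum fragments for a quantifiable editing level
#'   (default 50).
#' @param denominator "total" (A+G+other, default) or "AG".
#' @return An [EditingExperiment-class]; rows are sites, columns samples.
#' @export
editingLevels <- function(calls, meta = NULL, sites = NULL,
                          minCoverage = 50L, denominator = c("total", "AG")) {
  denominator <- match.arg(denominator)
  stopifnot(all(c("sample_id", "site_id", "count_A", "count_G",
                  "count_other") %in% names(calls)))
  siteIds <- if (!is.null(sites)) sites$site_id else unique(calls$site_id)
  sampleIds <- unique(calls$sample_id)
  shape <- function(col) {
    m <- matrix(0L, length(siteIds), length(sampleIds),
                dimnames = list(siteIds, sampleIds))
    m[cbind(match(calls$site_id, siteIds),
            match(calls$sample_id, sampleIds))] <- calls[[col]]
    m
  }
  A <- shape("count_A"); G <- shape("count_G"); O <- shape("count_other")
  cov <- A + G + O
  den <- if (denominator == "total") cov else A + G
  ed <- ifelse(cov >= minCoverage & den > 0, G / den, NA_real_)
  cd <- if (is.null(meta)) S4Vectors::DataFrame(sample_id = sampleIds,
                                                row.names = sampleIds)
        else {
          md <- if (is.data.frame(meta)) sampleMeta(meta) else meta
          md[sampleIds, , drop = FALSE]
        }
  rd <- if (is.null(sites)) S4Vectors::DataFrame(site_id = siteIds,
                                                 row.names = siteIds)
        else S4Vectors::DataFrame(sites, row.names = sites$site_id)
  se <- SummarizedExperiment(
    assays = list(countA = A, countG = G, countOther = O, coverage = cov,
                  editing = ed),
    rowData = rd, colData = cd)
  metadata(se)$minCoverage <- minCoverage
  metadata(se)$denominator <- denominator
  new("EditingExperiment", se)
}

#' Replicate and missingness filters for an editing matrix
#'
#' Applies the two study-level exclusion rules, sample level first: samples
#' with more than `maxMissingFraction` of editing sites missing are dropped
#' (oocyte samples are exempt), then sites with fewer than `minReplicates`
#' non-missing biological replicates in either level of the comparison
#' grouping are dropped.
#'
#' @param x an [EditingExperiment-class].
#' @param group name of the colData column defining the comparison groups;
#'   NULL treats all samples as one group.
#' @param minReplicates minimum non-missing biological replicates per group
#'   (default 3).
#' @param maxMissingFraction sample-level missingness threshold
#'   (default 0.30, strict >).
#' @return The filtered [EditingExperiment-class].
#' @export
filterEditing <- function(x, group = NULL, minReplicates = 3L,
                          maxMissingFraction = 0.30) {
  stopifnot(is(x, "EditingExperiment"))
  ed <- editingMatrix(x)
  missFrac <- colMeans(is.na(ed))
  exempt <- if ("region" %in% names(colData(x)))
    colData(x)$region %in% "oocyte" else rep(FALSE, ncol(x))
  keepSample <- missFrac <= maxMissingFraction | exempt
  x2 <- x[, keepSample]
  ed <- editingMatrix(x2)
  grp <- if (is.null(group)) factor(rep("all", ncol(x2)))
         else droplevels(factor(colData(x2)[[group]]))
  bio <- if ("replicate_kind" %in% names(colData(x2)))
    colData(x2)$replicate_kind %in% "biological"
  else rep(TRUE, ncol(x2))
  keepSite <- rep(TRUE, nrow(x2))
  for (lv in levels(grp)) {
    n <- rowSums(!is.na(ed[, grp == lv & bio, drop = FALSE]))
    keepSite <- keepSite & n >= minReplicates
  }
  out <- x2[keepSite, ]
  if (nrow(out) == 0L || ncol(out) == 0L)
    stop(structure(class = c("editscope_empty_filter", "error", "condition"),
                   list(message = "nothing survives the replicate/missingness filters",
                        call = sys.call(-1))))
  metadata(out)$filter <- list(group = group, minReplicates = minReplicates,
                               maxMissingFraction = maxMissingFraction)
  out
}

#' Write an editing matrix and its site calls to TSV
#'
#' @param x an [EditingExperiment-class].
#' @param matrixPath path for the samples-by-sites editing matrix (sites as
#'   rows, "NA" for missing cells).
#' @param callsPath optional path for the long-format raw counts table.
#' @return Invisibly, the written paths.
#' @export
writeEditingMatrix <- function(x, matrixPath, callsPath = NULL) {
  ed <- editingMatrix(x)
  df <- data.frame(site_id = rownames(ed), ed, check.names = FALSE)
  utils::write.table(df, matrixPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- matrixPath
  if (!is.null(callsPath)) {
    long <- do.call(rbind, lapply(colnames(ed), function(s)
      data.frame(sample_id = s, site_id = rownames(ed),
                 count_A = assay(x, "countA")[, s],
                 count_G = assay(x, "countG")[, s],
                 count_other = assay(x, "countOther")[, s],
                 coverage = assay(x, "coverage")[, s],
                 editing = ed[, s], stringsAsFactors = FALSE)))
    utils::write.table(long, callsPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, callsPath)
  }
  invisible(paths)
}
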