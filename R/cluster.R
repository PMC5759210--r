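#' Translate a cluster edit combination into a protein isoform name
#'
#' The five editable adenosines of the Htr2c cluster fall in the codons for
#' amino acids 156, 158 and 160; recoding follows the standard genetic code
#' applied to those codons: position 156 I (unedited), V (A edited, with or
#' without B) or M (B alone); position 158 N (unedited), D (E), S (C) or
#' G (E+C); position 160 I (unedited) or V (D). The isoform name is the
#' three-letter amino-acid string (INI = fully unedited) and the subscript
#' lists the edited sites in A--E order (empty for INI).
#'
#' @param edited edited sites, as a character subscript ("ABD"), a character
#'   vector of letters, or a logical vector named by letters.
#' @return list with `name` (e.g. "VNV"), `subscript` (e.g. "ABD") and
#'   `label` ("VNV_ABD"; "INI" carries no subscript).
#' @examples
#' translateIsoform("")$name      # INI, the unedited isoform
#' translateIsoform("ABCD")$label # VSV_ABCD
#' @export
translateIsoform <- function(edited) {
  if (is.logical(edited)) edited <- names(edited)[edited]
  if (length(edited) == 1L && (is.na(edited) || nchar(edited) != 1L ||
                               !edited %in% LETTERS[1:5]))
    edited <- strsplit(edited, "")[[1]]
  stopifnot(all(edited %in% LETTERS[1:5]))
  e <- LETTERS[1:5] %in% edited
  names(e) <- LETTERS[1:5]
  aa156 <- if (e["A"]) "V" else if (e["B"]) "M" else "I"
  aa158 <- if (e["E"] && e["C"]) "G" else if (e["E"]) "D" else
    if (e["C"]) "S" else "N"
  aa160 <- if (e["D"]) "V" else "I"
  name <- paste0(aa156, aa158, aa160)
  subscript <- paste(LETTERS[1:5][e], collapse = "")
  list(name = name, subscript = subscript,
       label = if (nzchar(subscript)) paste(name, subscript, sep = "_")
               else name)
}

#' Enumerate all edit combinations of a cluster
#'
#' Exhaustively enumerates every binary editing configuration over the
#' cluster sites and translates each through the codon table, returning the
#' mRNA variant count, the number of distinct protein isoforms, and the full
#' variant-to-protein table. For the five-site Htr2c cluster this yields 32
#' mRNA variants collapsing to 24 protein isoforms (the only collisions are
#' A-edited combinations with and without B, which both give V at amino
#' acid 156).
#'
#' @param cluster a [ClusterSpec-class], or a character vector of site
#'   letters (default the full A--E cluster).
#' @return list with `nVariants`, `nProteins` and `table` (data.frame:
#'   subscript, protein, label).
#' @examples
#' enumerateIsoforms()$nVariants  # 32
#' enumerateIsoforms()$nProteins  # 24
#' @export
enumerateIsoforms <- function(cluster = LETTERS[1:5]) {
  letters <- if (is(cluster, "ClusterSpec")) cluster@letters else cluster
  letters <- sort(letters)
  n <- length(letters)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  subs <- apply(combos, 1L, function(r) paste(letters[as.logical(r)],
                                              collapse = ""))
  tr <- lapply(subs, translateIsoform)
  tab <- data.frame(subscript = subs,
                    protein = vapply(tr, `[[`, character(1), "name"),
                    label = vapply(tr, `[[`, character(1), "label"),
                    stringsAsFactors = FALSE)
  tab <- tab[order(nchar(tab$subscript), tab$subscript), ]
  rownames(tab) <- NULL
  list(nVariants = nrow(tab), nProteins = length(unique(tab$protein)),
       table = tab)
}

#' Per-fragment editing haplotypes over a cluster
#'
#' Phases the cluster sites on each aligned fragment. A fragment yields a
#' haplotype only if every cluster site is covered by at least one mate and
#' every observed base at a cluster site is A or G; a site covered by both
#' mates must show the same base. Anything else excludes the fragment, with
#' the reason recorded (`partial` = not all sites covered, `non_AG` = a
#' sequencing-error base at a site, `discordant` = mates disagree).
#'
#' @param fragments data.frame from [alignFragments()], restricted
#'   internally to the cluster amplicon.
#' @param cluster a [ClusterSpec-class].
#' @return data.frame: read_id, status ("retained"/"partial"/"non_AG"/
#'   "discordant"), haplotype (edited-letter subscript over all cluster
#'   sites, NA unless retained).
#' @export
readHaplotypes <- function(fragments, cluster) {
  stopifnot(is(cluster, "ClusterSpec"))
  fr <- fragments[fragments$amplicon_id == cluster@ampliconId, ,
                  drop = FALSE]
  n <- nrow(fr)
  if (n == 0L)
    return(data.frame(read_id = character(), status = character(),
                      haplotype = character(), stringsAsFactors = FALSE))
  base <- matrix(NA_character_, n, length(cluster@letters),
                 dimnames = list(NULL, cluster@letters))
  disc <- rep(FALSE, n)
  for (j in seq_along(cluster@letters)) {
    b <- .fragmentBaseAt(fr, cluster@offsets[j])
    disc <- disc | (!is.na(b) & b == "X")
    base[, j] <- b
  }
  covered <- rowSums(is.na(base)) == 0L
  nonAG <- apply(base, 1L, function(r) any(!is.na(r) & !r %in% c("A", "G", "X")))
  status <- ifelse(!covered, "partial",
                   ifelse(disc, "discordant",
                          ifelse(nonAG, "non_AG", "retained")))
  hap <- rep(NA_character_, n)
  ok <- status == "retained"
  if (any(ok))
    hap[ok] <- apply(base[ok, , drop = FALSE], 1L, function(r)
      paste(sort(cluster@letters[r == "G"]), collapse = ""))
  data.frame(read_id = fr$read_id, status = status, haplotype = hap,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Isoform distribution from per-fragment haplotypes
#'
#' Collapses haplotypes over the excluded sites (the E site by default,
#' where editing is not detected) before tallying, translates each retained
#' combination into its protein isoform, and reports counts and percentages
#' of the retained fragments. Percentages sum to 100 exactly.
#'
#' @param haplotypes data.frame from [readHaplotypes()] (or a character
#'   vector of subscripts).
#' @param cluster a [ClusterSpec-class]; its `excluded` letters are dropped.
#' @param excluded override of the letters to collapse away.
#' @return data.frame: protein, subscript, label, count, percent, sorted by
#'   decreasing count.
#' @export
isoformDistribution <- function(haplotypes, cluster = NULL,
                                excluded = NULL) {
  haps <- if (is.data.frame(haplotypes))
    haplotypes$haplotype[haplotypes$status == "retained"]
  else haplotypes
  if (length(haps) == 0L)
    stop(structure(class = c("editscope_empty_distribution", "error",
                             "condition"),
                   list(message = "no retained fragments cover all cluster sites",
                        call = sys.call(-1))))
  if (is.null(excluded))
    excluded <- if (!is.null(cluster)) cluster@excluded else "E"
  for (L in excluded)
    haps <- gsub(L, "", haps, fixed = TRUE)
  counts <- table(haps)
  tr <- lapply(names(counts), translateIsoform)
  out <- data.frame(protein = vapply(tr, `[[`, character(1), "name"),
                    subscript = names(counts),
                    label = vapply(tr, `[[`, character(1), "label"),
                    count = as.integer(counts),
                    stringsAsFactors = FALSE)
  out$percent <- 100 * out$count / sum(out$count)
  out <- out[order(-out$count, out$subscript), ]
  rownames(out) <- NULL
  out
}

#' Base-quality read filter
#'
#' Keeps a read only if strictly more than `minFrac` of its bases have
#' phred quality strictly greater than `qMin`. Reads with an empty quality
#' string are dropped.
#'
#' @param quals character vector of phred+33 quality strings.
#' @param qMin quality threshold (default 20, strict >).
#' @param minFrac required fraction of bases above threshold (default 0.80,
#'   strict >).
#' @return logical vector, TRUE = keep.
#' @export
qualityFilter <- function(quals, qMin = 20L, minFrac = 0.80) {
  vapply(quals, function(q) {
    if (is.na(q) || !nzchar(q)) return(FALSE)
    ph <- utf8ToInt(q) - 33L
    mean(ph > qMin) > minFrac
  }, logical(1), USE.NAMES = FALSE)
}

#' The 32 variant reference sequences of a cluster amplicon
#'
#' Generates every editing variant of the cluster amplicon by toggling the
#' cluster sites between A and G.
#'
#' @param panel an [AmpliconPanel-class] whose cluster is set.
#' @param cluster a [ClusterSpec-class] (default the panel's).
#' @return A named `DNAStringSet`; names are edited-letter subscripts, with
#'   "unedited" for the reference combination.
#' @export
variantReferences <- function(panel, cluster = panelCluster(panel)) {
  stopifnot(is(cluster, "ClusterSpec"))
  ref <- as.character(panel@sequences[[cluster@ampliconId]])
  en <- enumerateIsoforms(cluster)
  seqs <- vapply(en$table$subscript, function(sub) {
    s <- ref
    for (L in strsplit(sub, "")[[1]])
      substr(s, cluster@offsets[[L]] + 1L, cluster@offsets[[L]] + 1L) <- "G"
    s
  }, character(1))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ifelse(nzchar(en$table$subscript), en$table$subscript,
                       "unedited")
  out
}

#' Assign reads to cluster variant references
#'
#' The independent (alignment-based) route to the isoform distribution:
#' each read is scanned, ungapped and in both orientations, against all
#' variant reference sequences; it is assigned to the unique best-matching
#' variant with at most `maxMismatches` mismatches. Ties and poorer matches
#' are left unassigned.
#'
#' @param seqs character vector of read sequences.
#' @param refs variant references from [variantReferences()].
#' @param maxMismatches mismatch allowance (default 6).
#' @return character vector of variant names (subscripts, "unedited"), NA
#'   where unassigned.
#' @export
assignVariant <- function(seqs, refs, maxMismatches = 6L) {
  hits <- alignReads(seqs, maxMismatches = maxMismatches, refs = refs)
  hits$amplicon_id
}

#' Tally variant assignments into an isoform distribution
#'
#' @param variants character vector from [assignVariant()].
#' @param cluster a [ClusterSpec-class] providing the excluded letters.
#' @param excluded override of the letters to collapse away.
#' @return data.frame in the layout of [isoformDistribution()].
#' @export
variantDistribution <- function(variants, cluster = NULL, excluded = NULL) {
  v <- variants[!is.na(variants)]
  v[v == "unedited"] <- ""
  isoformDistribution(v, cluster = cluster, excluded = excluded)
}
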