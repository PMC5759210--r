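#' Demultiplex pooled reads by exact barcode prefix
#'
#' Assigns each read pair to the sample whose 6 nt barcode exactly matches
#' the prefix of mate 1; the barcode bases (and their qualities) are
#' stripped before alignment. Matching is exact -- 6 nt codes leave thin
#' edit-distance margins, so no 1-mismatch rescue is attempted. Reads whose
#' prefix matches no barcode fall into the unassigned bin.
#'
#' @param reads data.frame of read pairs (read_id, seq1, qual1, seq2, qual2),
#'   e.g. `simulateReads(...)$reads` or [readFastqPair()] output.
#' @param barcodes named character vector: sample id -> 6 nt barcode.
#' @return list with `samples` (named list of per-sample read data.frames,
#'   barcode stripped) and `unassigned` (data.frame).
#' @export
demultiplex <- function(reads, barcodes) {
  if (any(nchar(barcodes) != 6L))
    stop("barcodes must be 6 nt")
  if (anyDuplicated(barcodes))
    stop("duplicate barcodes in the barcode map")
  if (is.null(names(barcodes)) || anyDuplicated(names(barcodes)))
    stop("barcodes must be uniquely named by sample id")
  prefix <- substr(reads$seq1, 1L, 6L)
  idx <- match(prefix, barcodes)
  stripped <- reads
  stripped$seq1 <- substr(stripped$seq1, 7L, nchar(stripped$seq1))
  stripped$qual1 <- substr(stripped$qual1, 7L, nchar(stripped$qual1))
  samples <- lapply(seq_along(barcodes), function(i) {
    out <- stripped[!is.na(idx) & idx == i, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
  names(samples) <- names(barcodes)
  un <- reads[is.na(idx), , drop = FALSE]
  rownames(un) <- NULL
  list(samples = samples, unassigned = un)
}

# Ungapped scan of one read against a set of reference sequences, both
# orientations, all offsets. Returns the best hit provided it is unique and
# within maxMismatches, else NA. refs: DNAStringSet.
.scanRead <- function(seq, refs, maxMismatches) {
  best <- maxMismatches + 1L
  nbest <- 0L
  hit <- NULL
  pats <- list(`+` = Biostrings::DNAString(seq),
               `-` = Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  w <- nchar(seq)
  for (r in seq_along(refs)) {
    L <- Biostrings::width(refs)[r]
    if (w > L) next
    for (strand in names(pats)) {
      ned <- Biostrings::neditStartingAt(pats[[strand]], refs[[r]],
                                         starting.at = seq_len(L - w + 1L),
                                         with.indels = FALSE)
      m <- min(ned)
      if (m < best) {
        best <- m
        nbest <- sum(ned == m)
        hit <- list(ref = names(refs)[r], offset = which.min(ned) - 1L,
                    strand = strand, mismatches = m)
      } else if (m == best) {
        nbest <- nbest + sum(ned == m)
      }
    }
  }
  if (is.null(hit) || best > maxMismatches || nbest > 1L)
    return(NULL)
  hit
}

#' Align reads to an amplicon panel
#'
#' Ungapped exhaustive scan of each read, in both orientations, over every
#' amplicon and offset. A read is placed at its unique best-scoring position
#' provided it has at most `maxMismatches` mismatches; reads whose best
#' score is tied across two or more positions are rejected as ambiguous
#' (multi-mapping on an amplicon panel indicates design collision, not
#' biology). No indels are considered.
#'
#' @param seqs character vector of read sequences.
#' @param panel an [AmpliconPanel-class] (or any named `DNAStringSet` via
#'   `refs`).
#' @param maxMismatches maximum mismatches for an acceptable hit
#'   (default 9).
#' @param refs optionally, a `DNAStringSet` of references to use instead of
#'   the panel sequences.
#' @return data.frame with one row per read: amplicon_id, offset (0-based),
#'   strand ("+"/"-"), mismatches; NA row where the read is unmapped or
#'   ambiguous.
#' @export
alignReads <- function(seqs, panel = NULL, maxMismatches = 9L, refs = NULL) {
  if (is.null(refs)) refs <- panel@sequences
  uniq <- unique(seqs)
  hits <- lapply(uniq, function(s) {
    h <- .scanRead(s, refs, maxMismatches)
    if (is.null(h))
      data.frame(amplicon_id = NA_character_, offset = NA_integer_,
                 strand = NA_character_, mismatches = NA_integer_,
                 stringsAsFactors = FALSE)
    else
      data.frame(amplicon_id = h$ref, offset = h$offset, strand = h$strand,
                 mismatches = h$mismatches, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, hits)
  tab[match(seqs, uniq), , drop = FALSE]
}

#' Align read pairs and assemble fragments
#'
#' Aligns both mates of each pair and keeps fragments whose mates land on
#' the same amplicon on opposite strands. For every kept mate the
#' sense-strand sequence and its genomic offset are recorded so that
#' downstream pileup and phasing read bases directly in amplicon
#' coordinates.
#'
#' @param reads per-sample read data.frame (after [demultiplex()]).
#' @param panel an [AmpliconPanel-class].
#' @param maxMismatches per-read mismatch allowance (default 9).
#' @return data.frame of fragments: read_id, amplicon_id, off1, sense1,
#'   qual1, off2, sense2, qual2 (offsets 0-based; `sense*` are the mate
#'   sequences written on the amplicon sense strand).
#' @export
alignFragments <- function(reads, panel, maxMismatches = 9L) {
  if (nrow(reads) == 0L)
    return(data.frame(read_id = character(), amplicon_id = character(),
                      off1 = integer(), sense1 = character(),
                      qual1 = character(), off2 = integer(),
                      sense2 = character(), qual2 = character(),
                      stringsAsFactors = FALSE))
  a1 <- alignReads(reads$seq1, panel, maxMismatches)
  a2 <- alignReads(reads$seq2, panel, maxMismatches)
  keep <- !is.na(a1$amplicon_id) & !is.na(a2$amplicon_id) &
    a1$amplicon_id == a2$amplicon_id & a1$strand != a2$strand
  idx <- which(keep)
  sense <- function(seqs, quals, strands) {
    flip <- strands == "-"
    s <- seqs
    q <- quals
    if (any(flip)) {
      s[flip] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seqs[flip])))
      q[flip] <- vapply(strsplit(quals[flip], ""), function(x)
        paste(rev(x), collapse = ""), character(1))
    }
    list(s = s, q = q)
  }
  s1 <- sense(reads$seq1[idx], reads$qual1[idx], a1$strand[idx])
  s2 <- sense(reads$seq2[idx], reads$qual2[idx], a2$strand[idx])
  data.frame(read_id = reads$read_id[idx],
             amplicon_id = a1$amplicon_id[idx],
             off1 = a1$offset[idx], sense1 = s1$s, qual1 = s1$q,
             off2 = a2$offset[idx], sense2 = s2$s, qual2 = s2$q,
             stringsAsFactors = FALSE, row.names = NULL)
}
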