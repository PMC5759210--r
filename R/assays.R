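#' Editing percentage from Sanger peak areas
#'
#' The chromatogram-based estimator: the peak area of the edited nucleotide
#' (G) as a percentage of the sum of the G and A peak areas at the site.
#'
#' @param areaG,areaA numeric vectors of G and A peak areas (>= 0).
#' @return numeric vector of editing percentages, in [0, 100].
#' @examples
#' sangerEditing(30, 70)  # 30
#' @export
sangerEditing <- function(areaG, areaA) {
  stopifnot(length(areaG) == length(areaA),
            all(areaG >= 0), all(areaA >= 0))
  tot <- areaG + areaA
  if (any(tot == 0))
    stop("editing is undefined where both peak areas are zero")
  100 * areaG / tot
}

#' Percent alternative splicing from gel band intensities
#'
#' The +47 nt (alternatively spliced, inactive) isoform runs as the upper
#' band; percent alternative splicing is the upper-band intensity divided
#' by the total intensity of both bands, times 100.
#'
#' @param upper,lower numeric band intensities (>= 0).
#' @return numeric vector of percentages.
#' @export
splicingPercent <- function(upper, lower) {
  stopifnot(length(upper) == length(lower),
            all(upper >= 0), all(lower >= 0))
  tot <- upper + lower
  if (any(tot == 0))
    stop("splicing percentage is undefined where both bands are zero")
  100 * upper / tot
}

#' RT-PCR product lengths of the self-editing-dependent splice
#'
#' The intron-spanning assay yields a 103 bp product for the unedited
#' (spliced, active) isoform and a 150 bp product for the edited
#' (alternatively spliced) isoform that retains the +47 nt insertion.
#'
#' @param active length of the spliced active-isoform product (bp).
#' @param inactive length of the +47 nt inactive-isoform product (bp).
#' @return Named integer vector: active, inactive, insertion
#'   (= inactive - active).
#' @export
spliceProductLengths <- function(active = 103L, inactive = 150L) {
  stopifnot(inactive > active)
  c(active = as.integer(active), inactive = as.integer(inactive),
    insertion = as.integer(inactive - active))
}

#' qPCR normalization against a housekeeping gene
#'
#' Computes `dCt = Ct_target - Ct_reference` and the displayed normalized
#' expression. The default normalization is the literal arithmetic
#' `10 - dCt`; `method = "log2"` gives the conventional `2^(-dCt)` relative
#' expression instead.
#'
#' @param ctTarget,ctReference numeric Ct vectors (finite).
#' @param sampleId optional sample ids.
#' @param target optional target-gene label.
#' @param method "linear" (10 - dCt, default) or "log2" (2^-dCt).
#' @return data.frame: sample_id, target, ct_target, ct_reference, dct,
#'   normalized.
#' @examples
#' qpcrNormalize(25, 20)$normalized  # 5
#' @export
qpcrNormalize <- function(ctTarget, ctReference,
                          sampleId = sprintf("sample%d", seq_along(ctTarget)),
                          target = "target",
                          method = c("linear", "log2")) {
  method <- match.arg(method)
  stopifnot(length(ctTarget) == length(ctReference),
            all(is.finite(ctTarget)), all(is.finite(ctReference)))
  dct <- ctTarget - ctReference
  normalized <- if (method == "linear") 10 - dct else 2^(-dct)
  data.frame(sample_id = sampleId, target = target,
             ct_target = ctTarget, ct_reference = ctReference,
             dct = dct, normalized = normalized,
             stringsAsFactors = FALSE)
}

#' Choroid-plexus contamination check from an F5 qPCR marker
#'
#' F5 marks choroid plexus tissue; high Ct (> 32) together with high dCt
#' (> 11.4) indicates the marker is essentially unexpressed and the
#' dissection is clean. Anything else flags possible contamination. Both
#' inequalities are strict.
#'
#' @param ct,dct numeric vectors of F5 Ct and dCt values.
#' @param ctMin,dctMin thresholds (defaults 32 and 11.4).
#' @return character vector: "low_expression" or "possible_contamination".
#' @export
contaminationCheck <- function(ct, dct, ctMin = 32, dctMin = 11.4) {
  stopifnot(length(ct) == length(dct), all(is.finite(ct)),
            all(is.finite(dct)))
  ifelse(ct > ctMin & dct > dctMin, "low_expression",
         "possible_contamination")
}

#' Two-step NGS primer architecture
#'
#' Segment lengths of the two-step library design used for the
#' Htr2c-directed sequencing assay: step 1 prepends a partial Read1
#' sequence and a sample barcode to the gene-specific target region; step 2
#' completes the Read1 sequence (overlapping the step-1 tail) and adds the
#' flow-cell adaptors. Defaults are the published design (125 bp target
#' spanning the five editing sites, 20 bp partial Read1, 6 nt barcode,
#' 33 bp full Read1, 5 bp linker, 20 bp forward and 22 bp reverse flow-cell
#' adaptors, 12 bp universal primer).
#'
#' @param targetRegion gene-specific target length in bp, including the
#'   footprints of the gene-specific primers.
#' @param read1Partial partial Read1 length carried by the step-1 forward
#'   primer.
#' @param barcode sample-barcode length.
#' @param read1Full full Read1 primer length added in step 2.
#' @param linker linker length between adaptor and Read1 in step 2.
#' @param flowcellFwd,flowcellRev forward/reverse flow-cell adaptor lengths.
#' @param universalRev universal reverse-primer length added in step 2.
#' @return list of class `PrimerArchitecture`.
#' @export
primerArchitecture <- function(targetRegion = 125L, read1Partial = 20L,
                               barcode = 6L, read1Full = 33L, linker = 5L,
                               flowcellFwd = 20L, flowcellRev = 22L,
                               universalRev = 12L) {
  segs <- c(targetRegion = targetRegion, read1Partial = read1Partial,
            barcode = barcode, read1Full = read1Full, linker = linker,
            flowcellFwd = flowcellFwd, flowcellRev = flowcellRev,
            universalRev = universalRev)
  if (any(segs < 0) || any(segs != round(segs)))
    stop("segment lengths must be non-negative integers")
  structure(as.list(setNames(as.integer(segs), names(segs))),
            class = "PrimerArchitecture")
}

#' Expected product lengths of the two PCR steps
#'
#' Step 1 = target region + partial Read1 + barcode. Step 2 = step 1 + the
#' newly added forward segments (forward flow-cell adaptor, linker, and the
#' part of the full Read1 not already present as the step-1 tail) + the
#' reverse segments (reverse flow-cell adaptor, universal primer). With the
#' published segment lengths this gives the expected 151 bp and 223 bp
#' bands.
#'
#' @param arch a [primerArchitecture()].
#' @return Named numeric vector: step1, step2 (bp).
#' @examples
#' expectedAmpliconLengths(primerArchitecture())  # c(step1 = 151, step2 = 223)
#' @export
expectedAmpliconLengths <- function(arch = primerArchitecture()) {
  stopifnot(inherits(arch, "PrimerArchitecture"))
  if (arch$read1Full < arch$read1Partial)
    stop("architecture error: Read1 overlap longer than the full Read1 sequence")
  step1 <- arch$targetRegion + arch$read1Partial + arch$barcode
  step2 <- step1 +
    (arch$flowcellFwd + arch$linker + (arch$read1Full - arch$read1Partial)) +
    (arch$flowcellRev + arch$universalRev)
  c(step1 = step1, step2 = step2)
}

#' Combine two primer architectures segment-wise
#'
#' Segment lengths add, so expected product lengths add as well.
#'
#' @param a,b [primerArchitecture()] objects.
#' @return A combined `PrimerArchitecture`.
#' @export
combineArchitectures <- function(a, b) {
  stopifnot(inherits(a, "PrimerArchitecture"),
            inherits(b, "PrimerArchitecture"))
  do.call(primerArchitecture, as.list(mapply(`+`, unlist(a), unlist(b))))
}
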