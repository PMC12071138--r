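#' GlycoFeatureSet: aligned LC-MS feature matrix
#'
#' An S4 container for an aligned features-by-samples abundance matrix,
#' extending [SummarizedExperiment::SummarizedExperiment]. Each row is a
#' consensus LC-MS feature with m/z and retention-time coordinates plus
#' provenance flags set by the filtering steps (`is_isotope`, `is_adduct`,
#' `is_fragment`, `cv_fail`, `snr_fail`). Missing observations are stored
#' as 0, never as NA or sentinel negatives. Unassigned (noise or rare)
#' peaks dropped during alignment are retained in
#' `metadata(x)$unassigned_peaks` so the signal-to-noise filter can form a
#' local noise estimate.
#'
#' @slot ... inherits all slots from `SummarizedExperiment`.
#' @export
setClass("GlycoFeatureSet", contains = "SummarizedExperiment")

.FLAG_COLS <- c("is_isotope", "is_adduct", "is_fragment", "cv_fail", "snr_fail")

setValidity("GlycoFeatureSet", function(object) {
  msg <- character()
  rd <- rowData(object)
  if (!all(c("mz", "rt") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain 'mz' and 'rt'")
  else {
    if (!all(is.finite(rd$mz)) || any(rd$mz <= 0))
      msg <- c(msg, "feature m/z values must be finite and positive")
    if (!all(is.finite(rd$rt)) || any(rd$rt < 0))
      msg <- c(msg, "feature retention times must be finite and nonnegative")
  }
  missing_flags <- setdiff(.FLAG_COLS, colnames(rd))
  if (length(missing_flags))
    msg <- c(msg, paste("rowData lacks flag columns:",
                        paste(missing_flags, collapse = ", ")))
  if (!"abundance" %in% names(assays(object)))
    msg <- c(msg, "an 'abundance' assay is required")
  else {
    ab <- assay(object, "abundance")
    if (any(!is.finite(ab)) || any(ab < 0))
      msg <- c(msg, "abundances must be finite and nonnegative (missing = 0)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GlycoFeatureSet
#'
#' @param abundance numeric features-by-samples matrix; missing values as 0.
#' @param mz,rt numeric vectors of consensus feature coordinates (Da, minutes).
#' @param sampleData optional `data.frame`/`DataFrame` of per-sample metadata
#'   (one row per column of `abundance`); a logical `is_qc` column marks QC
#'   replicate injections.
#' @param unassignedPeaks optional data.frame of peaks dropped during
#'   alignment (columns `mz`, `rt`, `intensity`), kept for noise estimation.
#' @return a [GlycoFeatureSet-class] object.
#' @export
GlycoFeatureSet <- function(abundance, mz, rt, sampleData = NULL,
                            unassignedPeaks = NULL) {
  abundance <- as.matrix(abundance)
  if (is.null(rownames(abundance)))
    rownames(abundance) <- sprintf("F%04d", seq_len(nrow(abundance)))
  if (is.null(colnames(abundance)))
    colnames(abundance) <- sprintf("S%03d", seq_len(ncol(abundance)))
  rd <- DataFrame(mz = as.numeric(mz), rt = as.numeric(rt))
  for (fl in .FLAG_COLS) rd[[fl]] <- rep(FALSE, nrow(abundance))
  if (is.null(sampleData))
    sampleData <- DataFrame(row.names = colnames(abundance))
  se <- SummarizedExperiment(
    assays = list(abundance = abundance),
    rowData = rd,
    colData = as(sampleData, "DataFrame")
  )
  obj <- new("GlycoFeatureSet", se)
  if (!is.null(unassignedPeaks))
    metadata(obj)$unassigned_peaks <- unassignedPeaks
  obj
}

#' Accessors for GlycoFeatureSet
#'
#' `featureMz` and `featureRt` return consensus feature coordinates;
#' `featureFlags` returns the logical flag columns as a `DataFrame`;
#' `abundances` returns the abundance matrix; `qcSamples` returns the names
#' of QC replicate columns (per the `is_qc` column of `colData`).
#'
#' @param x a [GlycoFeatureSet-class].
#' @name GlycoFeatureSet-accessors
NULL

#' @rdname GlycoFeatureSet-accessors
#' @export
featureMz <- function(x) rowData(x)$mz

#' @rdname GlycoFeatureSet-accessors
#' @export
featureRt <- function(x) rowData(x)$rt

#' @rdname GlycoFeatureSet-accessors
#' @export
featureFlags <- function(x) rowData(x)[, .FLAG_COLS]

#' @rdname GlycoFeatureSet-accessors
#' @export
abundances <- function(x) assay(x, "abundance")

#' @rdname GlycoFeatureSet-accessors
#' @export
qcSamples <- function(x) {
  cd <- colData(x)
  if (!"is_qc" %in% colnames(cd)) return(character())
  rownames(cd)[cd$is_qc]
}

setMethod("show", "GlycoFeatureSet", function(object) {
  fl <- featureFlags(object)
  n_flagged <- sum(Reduce(`|`, as.list(fl)))
  cat(sprintf("GlycoFeatureSet: %d features x %d samples (%d QC)\n",
              nrow(object), ncol(object), length(qcSamples(object))))
  cat(sprintf("  m/z %.4f..%.4f, RT %.2f..%.2f min, %d features flagged\n",
              min(featureMz(object)), max(featureMz(object)),
              min(featureRt(object)), max(featureRt(object)), n_flagged))
})

#' GlycanComposition: N-glycan monosaccharide composition
#'
#' Counts of hexose (Hex), N-acetylhexosamine (HexNAc), deoxyhexose
#' (dHex, fucose) and N-acetylneuraminic acid (NeuAc, sialic acid) residues.
#' The fully sialylated biantennary complex-type glycan is Hex5HexNAc4NeuAc2;
#' core fucosylation adds one dHex.
#'
#' @slot hex,hexnac,dhex,neuac nonnegative integer residue counts.
#' @export
setClass("GlycanComposition",
         representation(hex = "integer", hexnac = "integer",
                        dhex = "integer", neuac = "integer"))

setValidity("GlycanComposition", function(object) {
  counts <- c(object@hex, object@hexnac, object@dhex, object@neuac)
  if (any(counts < 0)) return("residue counts must be nonnegative")
  if (sum(counts) == 0) return("a glycan must contain at least one residue")
  TRUE
})

#' Construct a GlycanComposition
#'
#' @param hex,hexnac,dhex,neuac nonnegative residue counts.
#' @return a [GlycanComposition-class] object.
#' @examples
#' glycanComposition(hex = 5, hexnac = 4, neuac = 2)  # A2G2S2
#' @export
glycanComposition <- function(hex = 0, hexnac = 0, dhex = 0, neuac = 0) {
  stopifnot(hex == round(hex), hexnac == round(hexnac),
            dhex == round(dhex), neuac == round(neuac))
  new("GlycanComposition", hex = as.integer(hex), hexnac = as.integer(hexnac),
      dhex = as.integer(dhex), neuac = as.integer(neuac))
}

#' Monoisotopic residue mass of a glycan composition
#'
#' The summed monoisotopic mass of the residues as attached (dehydrated),
#' i.e. the mass the glycan adds to a peptide.
#'
#' @param object a [GlycanComposition-class].
#' @return mass in Da.
#' @export
setGeneric("glycanMass", function(object) standardGeneric("glycanMass"))

#' @rdname glycanMass
#' @export
setMethod("glycanMass", "GlycanComposition", function(object) {
  validObject(object)
  object@hex * .GLYCAN_MASS[["hex"]] +
    object@hexnac * .GLYCAN_MASS[["hexnac"]] +
    object@dhex * .GLYCAN_MASS[["dhex"]] +
    object@neuac * .GLYCAN_MASS[["neuac"]]
})

setMethod("show", "GlycanComposition", function(object) {
  cat(sprintf("Hex%d HexNAc%d dHex%d NeuAc%d (residue mass %.5f Da)\n",
              object@hex, object@hexnac, object@dhex, object@neuac,
              glycanMass(object)))
})

#' Composition label, e.g. "Hex5HexNAc4dHex1NeuAc2"
#' @param x a [GlycanComposition-class].
#' @export
glycanLabel <- function(x) {
  parts <- c(Hex = x@hex, HexNAc = x@hexnac, dHex = x@dhex, NeuAc = x@neuac)
  parts <- parts[parts > 0]
  paste0(names(parts), parts, collapse = "")
}
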