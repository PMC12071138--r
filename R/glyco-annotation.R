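#' Monoisotopic neutral mass of a peptide
#'
#' Sum of residue masses plus one water; cysteines carry the fixed
#' carbamidomethyl modification (+57.02146 Da) introduced by iodoacetamide
#' alkylation during sample preparation.
#'
#' @param peptide character vector of sequences over the 20 standard
#'   one-letter amino-acid codes.
#' @param carbamidomethyl apply the fixed Cys modification (default TRUE).
#' @return neutral monoisotopic mass(es) in Da.
#' @examples
#' peptideMass("GK")  # 203.126985
#' @export
peptideMass <- function(peptide, carbamidomethyl = TRUE) {
  vapply(peptide, function(seq) {
    if (!nzchar(seq)) stop("peptide sequence must be nonempty")
    aa <- strsplit(toupper(seq), "")[[1]]
    unknown <- setdiff(aa, names(.RESIDUE_MASS))
    if (length(unknown))
      stop("unknown residue(s): ", paste(unique(unknown), collapse = ", "))
    m <- sum(.RESIDUE_MASS[aa]) + .WATER
    if (carbamidomethyl) m <- m + sum(aa == "C") * .CARBAMIDOMETHYL
    m
  }, numeric(1), USE.NAMES = FALSE)
}

#' Find N-glycosylation sequons
#'
#' Returns the 1-based positions of asparagines in the consensus motif
#' N-X-S/T with X != P.
#'
#' @param sequence a protein or peptide sequence.
#' @return integer vector of Asn positions (possibly empty).
#' @examples
#' findSequons("ANATNVT")  # 2 5
#' @export
findSequons <- function(sequence) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  n <- length(aa)
  if (n < 3) return(integer())
  i <- seq_len(n - 2)
  i[aa[i] == "N" & aa[i + 1] != "P" & aa[i + 2] %in% c("S", "T")]
}

#' Convert between neutral mass and m/z
#'
#' Negative mode (deprotonation): m/z = (M - z * 1.007276) / z; positive
#' mode: m/z = (M + z * 1.007276) / z.
#'
#' @param neutral_mass neutral monoisotopic mass(es), Da (> 0).
#' @param charge charge state (>= 1).
#' @param polarity `"negative"` (default, QTOF glycopeptide acquisition) or
#'   `"positive"`.
#' @return m/z value(s).
#' @examples
#' mzFromNeutral(2000, 2)  # 998.992724
#' @export
mzFromNeutral <- function(neutral_mass, charge, polarity = c("negative", "positive")) {
  polarity <- match.arg(polarity)
  if (any(charge < 1)) stop("charge must be >= 1")
  if (any(neutral_mass <= 0)) stop("neutral mass must be positive")
  s <- if (polarity == "negative") -1 else 1
  mz <- (neutral_mass + s * charge * .PROTON) / charge
  if (any(mz <= 0)) warning("degenerate m/z <= 0 for the given charge")
  mz
}

#' @rdname mzFromNeutral
#' @param mz observed m/z value(s).
#' @export
neutralFromMz <- function(mz, charge, polarity = c("negative", "positive")) {
  polarity <- match.arg(polarity)
  if (any(charge < 1)) stop("charge must be >= 1")
  s <- if (polarity == "negative") -1 else 1
  mz * charge - s * charge * .PROTON
}

#' Default glycan library: biantennary complex-type compositions
#'
#' Hex5HexNAc4 with 0-2 sialic acids, each with and without core fucose
#' (six compositions). The fully sialylated biantennary glycan
#' (Hex5HexNAc4NeuAc2) and its core-fucosylated variant are the compositions
#' carried by the discriminative serum marker glycopeptides.
#'
#' @return list of [GlycanComposition-class] objects, named by composition.
#' @export
defaultGlycanLibrary <- function() {
  out <- list()
  for (neuac in 0:2) for (dhex in 0:1) {
    g <- glycanComposition(hex = 5, hexnac = 4, dhex = dhex, neuac = neuac)
    out[[glycanLabel(g)]] <- g
  }
  out
}

#' Enumerate glycopeptide candidates
#'
#' Cartesian product of (peptide, sequon site, glycan): every glycan in the
#' library attached at every sequon of every peptide (single-site occupancy).
#' Candidate neutral mass is exactly peptide mass + glycan residue mass.
#' Peptides without a sequon contribute nothing (with a warning).
#'
#' @param peptides character vector of peptide sequences.
#' @param glycans list of [GlycanComposition-class] objects (default
#'   [defaultGlycanLibrary()]).
#' @return data.frame sorted ascending by `neutral_mass`, with columns
#'   `peptide`, `site` (1-based Asn index), `glycan`, `neutral_mass`.
#' @export
enumerateCandidates <- function(peptides, glycans = defaultGlycanLibrary()) {
  if (!length(peptides) || !length(glycans))
    stop("peptides and glycans must be nonempty")
  if (is.null(names(glycans)))
    names(glycans) <- vapply(glycans, glycanLabel, character(1))
  gmass <- vapply(glycans, glycanMass, numeric(1))
  rows <- list()
  for (pep in peptides) {
    sites <- findSequons(pep)
    if (!length(sites)) {
      warning("peptide without N-glycosylation sequon skipped: ", pep)
      next
    }
    pm <- peptideMass(pep)
    for (s in sites)
      rows[[length(rows) + 1L]] <- data.frame(
        peptide = pep, site = s, glycan = names(glycans),
        neutral_mass = pm + gmass, row.names = NULL)
  }
  if (!length(rows)) stop("no candidates: no peptide carries a sequon")
  out <- do.call(rbind, rows)
  out[order(out$neutral_mass), , drop = FALSE]
}

#' Match observed masses against candidate glycopeptides
#'
#' For each observed neutral mass, reports every candidate whose theoretical
#' mass lies within `tol` (default 0.03 Da), located by binary search over
#' the mass-sorted candidate list. Observations hitting more than one
#' candidate are flagged `ambiguous`.
#'
#' @param observed_masses numeric neutral masses (Da). Convert observed m/z
#'   first with [neutralFromMz()] at the known charge.
#' @param candidates data.frame from [enumerateCandidates()] (sorted by
#'   `neutral_mass`).
#' @param tol matching tolerance in Da.
#' @return data.frame of matches: `observed_mass`, candidate columns,
#'   `delta` (observed - theoretical), `ambiguous`.
#' @export
matchObserved <- function(observed_masses, candidates, tol = 0.03) {
  stopifnot(tol > 0)
  cm <- candidates$neutral_mass
  if (is.unsorted(cm)) stop("candidates must be sorted by neutral_mass")
  hits <- lapply(seq_along(observed_masses), function(i) {
    m <- observed_masses[i]
    lo <- findInterval(m - tol, cm, left.open = TRUE) + 1L  # first cm >= m - tol
    hi <- findInterval(m + tol, cm)            # last index with cm <= m + tol
    if (hi < lo) return(NULL)
    idx <- lo:hi
    idx <- idx[abs(cm[idx] - m) <= tol]        # guard fp boundaries
    if (!length(idx)) return(NULL)
    cbind(data.frame(observed_mass = m),
          candidates[idx, , drop = FALSE],
          data.frame(delta = m - cm[idx], ambiguous = length(idx) > 1L))
  })
  hits <- hits[!vapply(hits, is.null, logical(1))]
  if (!length(hits))
    return(data.frame(observed_mass = numeric(), peptide = character(),
                      site = integer(), glycan = character(),
                      neutral_mass = numeric(), delta = numeric(),
                      ambiguous = logical()))
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}
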