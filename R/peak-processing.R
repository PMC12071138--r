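#' Align per-sample peak lists into a consensus feature matrix
#'
#' Deterministic greedy intensity-seeded clustering. Candidate features are
#' seeded in descending peak-intensity order (ties broken by m/z, RT, then
#' sample order): a peak joins an existing feature iff its distance to the
#' feature seed satisfies |dmz| <= `mz_tol` and |drt| <= `rt_tol`, and it is
#' assigned to the nearest eligible feature in tolerance-normalized Euclidean
#' distance, ties broken by lower feature index; otherwise it seeds a new
#' feature. Duplicate hits of one sample within one feature are summed.
#' Features observed in fewer than `min_fraction` of samples are dropped and
#' their peaks retained as unassigned (noise) peaks for later noise
#' estimation. Consensus coordinates are intensity-weighted means of the
#' member peaks; features are reported in (m/z, RT) order. Absent
#' observations are 0 in the matrix.
#'
#' @param peaklists named list of per-sample peak data.frames (columns `mz`,
#'   `rt`, `intensity`; an optional `sample_id` column is ignored in favor of
#'   the list names).
#' @param mz_tol,rt_tol alignment tolerances: 0.06 Da and 0.3 min.
#' @param min_fraction minimum fraction of samples a feature must appear in
#'   (default 0.1); set 0 to keep all features.
#' @param sampleData optional per-sample metadata (rows matching the list
#'   names), stored as `colData`.
#' @return a [GlycoFeatureSet-class]; `metadata()$unassigned_peaks` holds the
#'   dropped peaks and `metadata()$n_input_peaks` the input count, so
#'   assigned + dropped = input.
#' @export
alignPeaks <- function(peaklists, mz_tol = 0.06, rt_tol = 0.3,
                       min_fraction = 0.1, sampleData = NULL) {
  stopifnot(mz_tol > 0, rt_tol > 0)
  if (!length(peaklists)) stop("at least one sample is required")
  if (is.null(names(peaklists)))
    names(peaklists) <- sprintf("S%03d", seq_along(peaklists))
  pk <- do.call(rbind, lapply(names(peaklists), function(sid) {
    p <- peaklists[[sid]]
    if (!nrow(p)) return(NULL)
    data.frame(sample = sid, mz = p$mz, rt = p$rt, intensity = p$intensity)
  }))
  if (is.null(pk) || !nrow(pk)) stop("no peaks in input")
  if (any(!is.finite(pk$mz)) || any(!is.finite(pk$rt)) ||
      any(!is.finite(pk$intensity)) || any(pk$mz <= 0) || any(pk$rt < 0) ||
      any(pk$intensity < 0))
    stop("peak coordinates must be finite and nonnegative (m/z > 0)")

  ord <- order(-pk$intensity, pk$mz, pk$rt, match(pk$sample, names(peaklists)))
  n <- nrow(pk)
  assign <- integer(n)
  seed_mz <- numeric(n); seed_rt <- numeric(n)   # grown as features appear
  nf <- 0L
  for (p in ord) {
    if (nf > 0L) {
      fm <- seed_mz[seq_len(nf)]; fr <- seed_rt[seq_len(nf)]
      dmz <- abs(fm - pk$mz[p]); drt <- abs(fr - pk$rt[p])
      elig <- which(dmz <= mz_tol & drt <= rt_tol)
    } else elig <- integer()
    if (length(elig)) {
      d2 <- (dmz[elig] / mz_tol)^2 + (drt[elig] / rt_tol)^2
      assign[p] <- elig[which.min(d2)]   # which.min takes the lowest index on ties
    } else {
      nf <- nf + 1L
      seed_mz[nf] <- pk$mz[p]; seed_rt[nf] <- pk$rt[p]
      assign[p] <- nf
    }
  }

  samples <- names(peaklists)
  si <- match(pk$sample, samples)
  # per-feature presence across samples
  present <- rowsum((!duplicated(paste(assign, si))) * 1L, assign)
  keep_feat <- which(present[, 1] >= min_fraction * length(samples))
  dropped <- !(assign %in% keep_feat)

  ab <- matrix(0, length(keep_feat), length(samples),
               dimnames = list(NULL, samples))
  fidx <- match(assign, keep_feat)
  ok <- which(!dropped)
  for (p in ok) ab[fidx[p], si[p]] <- ab[fidx[p], si[p]] + pk$intensity[p]
  wsum <- rowsum(pk$intensity[ok], fidx[ok])
  cons_mz <- rowsum(pk$intensity[ok] * pk$mz[ok], fidx[ok]) / wsum
  cons_rt <- rowsum(pk$intensity[ok] * pk$rt[ok], fidx[ok]) / wsum

  o <- order(cons_mz[, 1], cons_rt[, 1])
  ab <- ab[o, , drop = FALSE]
  rownames(ab) <- sprintf("F%04d", seq_len(nrow(ab)))
  if (!is.null(sampleData)) sampleData <- sampleData[samples, , drop = FALSE]
  gfs <- GlycoFeatureSet(ab, mz = cons_mz[o, 1], rt = cons_rt[o, 1],
                         sampleData = sampleData,
                         unassignedPeaks = pk[dropped,
                           c("mz", "rt", "intensity"), drop = FALSE])
  metadata(gfs)$n_input_peaks <- n
  metadata(gfs)$n_assigned_peaks <- length(ok)
  # per-peak provenance: which feature each input peak went to (NA = dropped)
  feature_name <- rep(NA_character_, n)
  feature_name[!dropped] <- rownames(ab)[match(fidx[!dropped], o)]
  metadata(gfs)$peak_table <- data.frame(
    sample = pk$sample, mz = pk$mz, rt = pk$rt, intensity = pk$intensity,
    feature = feature_name)
  gfs
}

# TRUE where feature `a` is weaker than feature `b` in the majority of the
# samples where either is observed (total intensity decides when nothing is
# shared).
.weakerThan <- function(ab, a, b) {
  obs <- ab[a, ] > 0 | ab[b, ] > 0
  if (!any(obs)) return(sum(ab[a, ]) < sum(ab[b, ]))
  mean(ab[b, obs] >= ab[a, obs]) > 0.5
}

#' Flag isotope, adduct and fragment features
#'
#' Marks features explainable as satellites of a stronger co-eluting
#' feature; flags are additive and never removed here. A feature is
#' `is_isotope` if a co-eluting feature (|dRT| <= `rt_tol`) sits at
#' -1.00336/z Da (any z in `charge_range`, within `mz_tol`) and is stronger
#' in a majority of shared samples; `is_adduct` if co-eluting at any
#' configured neutral-mass delta (observed as delta/z) below it with a
#' stronger partner; `is_fragment` if co-eluting with smaller m/z than a
#' stronger feature and Pearson-correlated abundance (r >= `frag_cor`).
#'
#' @param x a [GlycoFeatureSet-class].
#' @param charge_range integer charge states considered.
#' @param adduct_deltas named numeric neutral-mass deltas (Da).
#' @param rt_tol co-elution tolerance (minutes).
#' @param mz_tol tolerance on the expected m/z offset (Da).
#' @param frag_cor abundance-correlation threshold for fragment calls;
#'   `NA` disables fragment flagging.
#' @return the object with updated flags.
#' @export
flagFeatures <- function(x, charge_range = 1:3,
                         adduct_deltas = .ADDUCT_DELTAS,
                         rt_tol = 0.3, mz_tol = 0.06, frag_cor = 0.9) {
  stopifnot(is(x, "GlycoFeatureSet"), all(charge_range >= 1))
  ab <- abundances(x)
  mz <- featureMz(x); rt <- featureRt(x)
  n <- nrow(x)
  rd <- rowData(x)
  iso_off <- .ISOTOPE_SPACING / charge_range
  add_off <- if (length(adduct_deltas))
    as.numeric(outer(as.numeric(adduct_deltas), charge_range, `/`)) else numeric()
  for (i in seq_len(n)) {
    co <- which(abs(rt - rt[i]) <= rt_tol & seq_len(n) != i)
    if (!length(co)) next
    dmz <- mz[i] - mz[co]   # positive when candidate i is heavier
    for (j in seq_along(co)) {
      if (!.weakerThan(ab, i, co[j])) next
      if (any(abs(dmz[j] - iso_off) <= mz_tol))
        rd$is_isotope[i] <- TRUE
      if (length(add_off) && any(abs(dmz[j] - add_off) <= mz_tol))
        rd$is_adduct[i] <- TRUE
      if (!is.na(frag_cor) && dmz[j] < -mz_tol) {
        r <- suppressWarnings(cor(ab[i, ], ab[co[j], ]))
        if (!is.na(r) && r >= frag_cor) rd$is_fragment[i] <- TRUE
      }
    }
  }
  rowData(x) <- rd
  x
}

#' QC reproducibility filter (coefficient of variation)
#'
#' Computes each feature's CV (sample SD / mean) over the QC replicate
#' injections and sets `cv_fail` where CV exceeds `cv_max` (the
#' low-reproducibility cut, default 50%). Features never observed in QC
#' (mean 0) fail. The CV is stored in `rowData()$qc_cv`.
#'
#' @param x a [GlycoFeatureSet-class].
#' @param qc_ids QC sample (column) names; defaults to [qcSamples()].
#' @param cv_max maximum tolerated CV (fraction).
#' @return the object with `cv_fail` updated.
#' @export
filterCV <- function(x, qc_ids = qcSamples(x), cv_max = 0.5) {
  stopifnot(is(x, "GlycoFeatureSet"))
  if (length(qc_ids) < 2)
    stop("at least 2 QC replicates are required to compute a CV")
  q <- abundances(x)[, qc_ids, drop = FALSE]
  m <- rowMeans(q)
  s <- apply(q, 1, sd)
  cv <- ifelse(m > 0, s / m, Inf)
  rd <- rowData(x)
  rd$qc_cv <- cv
  rd$cv_fail <- cv > cv_max
  rowData(x) <- rd
  x
}

#' Signal-to-noise filter
#'
#' Sets `snr_fail` where the feature's signal (median of its nonzero
#' abundances) divided by a noise estimate falls below `snr_min` (the
#' low-reliability cut, default 5). When `noise` is NULL the estimate is the
#' median intensity of the unassigned noise peaks within the feature's
#' m/z +- `mz_window` Da and RT +- `rt_window` min neighborhood, falling back
#' to the global unassigned median for empty neighborhoods. The ratio is
#' stored in `rowData()$snr`.
#'
#' @param x a [GlycoFeatureSet-class].
#' @param noise optional explicit per-feature noise estimates (> 0).
#' @param snr_min minimum signal-to-noise ratio.
#' @param mz_window,rt_window local noise neighborhood.
#' @return the object with `snr_fail` updated.
#' @export
filterSNR <- function(x, noise = NULL, snr_min = 5,
                      mz_window = 5, rt_window = 1) {
  stopifnot(is(x, "GlycoFeatureSet"))
  ab <- abundances(x)
  signal <- apply(ab, 1, function(v) if (any(v > 0)) median(v[v > 0]) else 0)
  if (is.null(noise)) {
    np <- metadata(x)$unassigned_peaks
    if (is.null(np) || !nrow(np))
      stop("no unassigned noise peaks available; supply explicit `noise`")
    global <- median(np$intensity)
    noise <- vapply(seq_len(nrow(x)), function(i) {
      sel <- abs(np$mz - featureMz(x)[i]) <= mz_window &
        abs(np$rt - featureRt(x)[i]) <= rt_window
      if (any(sel)) median(np$intensity[sel]) else global
    }, numeric(1))
  }
  if (any(noise <= 0)) stop("noise estimates must be positive")
  rd <- rowData(x)
  rd$snr <- signal / noise
  rd$snr_fail <- rd$snr < snr_min
  rowData(x) <- rd
  x
}

#' Apply the EGP filter cascade
#'
#' Retains features that pass all three screening steps, in the order
#' (i) reproducibility (CV), (ii) reliability (S/N), (iii) removal of
#' isotopes, adducts and fragment ions, and returns them in stable
#' (m/z, RT) order. Per-stage survivor counts are recorded in
#' `metadata()$cascade_counts`; each stage's survivors are a subset of the
#' previous stage's.
#'
#' @param x a [GlycoFeatureSet-class] with flags already computed.
#' @return the filtered [GlycoFeatureSet-class] (possibly empty, with a
#'   warning).
#' @export
applyFilterCascade <- function(x) {
  stopifnot(is(x, "GlycoFeatureSet"))
  fl <- featureFlags(x)
  keep1 <- !fl$cv_fail
  keep2 <- keep1 & !fl$snr_fail
  keep3 <- keep2 & !(fl$is_isotope | fl$is_adduct | fl$is_fragment)
  out <- x[keep3, ]
  o <- order(featureMz(out), featureRt(out))
  out <- out[o, ]
  metadata(out)$cascade_counts <- c(input = nrow(x), cv = sum(keep1),
                                    snr = sum(keep2), satellite = sum(keep3))
  if (!nrow(out)) warning("all features were removed by the filter cascade")
  out
}

#' Normalize abundances to a QC reference and an internal standard
#'
#' Two-step normalization: (1) every abundance is divided by the feature's
#' QC-reference abundance, giving relative expression against the quality
#' control standard; (2) optionally, each sample's values are further divided
#' by that sample's relative expression of a named endogenous
#' internal-standard feature (e.g. a transferrin-derived glycopeptide), whose
#' own normalized value is then 1 in every sample.
#'
#' @param x a [GlycoFeatureSet-class].
#' @param qc_reference per-feature reference abundances (> 0 for retained
#'   features); defaults to the mean over QC replicate columns.
#' @param internal_standard feature (row) name of the internal standard, or
#'   NULL to skip step 2.
#' @return the object with the `abundance` assay replaced by relative
#'   expressions.
#' @export
normalizeToReference <- function(x, qc_reference = NULL,
                                 internal_standard = NULL) {
  stopifnot(is(x, "GlycoFeatureSet"))
  ab <- abundances(x)
  if (is.null(qc_reference)) {
    qc <- qcSamples(x)
    if (length(qc) < 1)
      stop("no QC samples found; supply `qc_reference` explicitly")
    qc_reference <- rowMeans(ab[, qc, drop = FALSE])
  }
  if (any(qc_reference <= 0))
    stop("QC reference abundances must be positive for all retained features")
  rel <- ab / qc_reference
  if (!is.null(internal_standard)) {
    if (!internal_standard %in% rownames(rel))
      stop("internal standard feature not found: ", internal_standard)
    is_rel <- rel[internal_standard, ]
    if (any(is_rel == 0))
      stop("internal standard abundance is zero in sample(s): ",
           paste(colnames(rel)[is_rel == 0], collapse = ", "))
    rel <- sweep(rel, 2, is_rel, `/`)
  }
  assays(x)$abundance <- rel
  x
}

#' Intra- and inter-day assay reproducibility
#'
#' Intra-day CV is the sample SD over mean of the first day's replicate
#' measurements; inter-day CV is the sample SD over mean of the per-day
#' means.
#'
#' @param values numeric replicate measurements.
#' @param days day label per measurement (first level = day 1).
#' @return list with `intra_cv` and `inter_cv` (NA, flagged via
#'   `attr(,"undefined")`, when a mean is 0).
#' @export
replicateCV <- function(values, days) {
  stopifnot(length(values) == length(days))
  days <- factor(days, levels = unique(days))
  day1 <- values[days == levels(days)[1]]
  if (length(day1) < 2) stop("need >= 2 replicates on day 1 for intra-day CV")
  if (nlevels(days) < 2) stop("need >= 2 days for inter-day CV")
  day_means <- tapply(values, days, mean)
  cv <- function(v) {
    if (mean(v) == 0) structure(NA_real_, undefined = TRUE)
    else sd(v) / mean(v)
  }
  list(intra_cv = cv(day1), inter_cv = cv(as.numeric(day_means)))
}
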