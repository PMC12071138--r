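#' Effect size for a target single-feature ROC-AUC
#'
#' For two equal-variance normal populations whose means differ by a
#' standardized shift d, the theoretical ROC-AUC of that feature is
#' Phi(d / sqrt(2)). `effectForAUC` inverts this relationship;
#' `aucForEffect` evaluates it. These calibrate synthetic tumor markers and
#' glycopeptides to prescribed discriminative power.
#'
#' @param auc target ROC-AUC, strictly between 0.5 and 1.
#' @return standardized mean shift d (dimensionless).
#' @examples
#' d <- effectForAUC(0.76)   # ~ 0.999
#' aucForEffect(d)           # 0.76
#' @export
effectForAUC <- function(auc) {
  if (any(auc <= 0.5) || any(auc >= 1))
    stop("target AUC must lie strictly between 0.5 and 1")
  sqrt(2) * qnorm(auc)
}

#' @rdname effectForAUC
#' @param d standardized mean shift (>= 0).
#' @export
aucForEffect <- function(d) pnorm(d / sqrt(2))

# Stage labels and the cohort composition they default to: early-stage-heavy
# (stage I dominates), with a sizeable unclassified group.
.STAGES <- c("0", "I", "II", "III", "IV", "unclassified")
.STAGE_COUNTS <- c(5, 124, 19, 20, 2, 29)

.MARKERS <- c("CEA", "CYFRA", "AFP", "CA19-9", "CA125", "SCC",
              "NCC-ST-439", "CA15-3", "PSA")

# Default per-marker discriminative power expressed as single-marker
# ROC-AUC targets. CEA/CYFRA/SCC/CA19-9/CA125 use observed serum values for
# lung cancer vs healthy; the remaining markers are weak responders.
.MARKER_AUCS <- c(CEA = 0.798, CYFRA = 0.806, AFP = 0.55, `CA19-9` = 0.620,
                  CA125 = 0.636, SCC = 0.684, `NCC-ST-439` = 0.55,
                  `CA15-3` = 0.55, PSA = 0.55)

#' Configuration of a synthetic screening cohort
#'
#' Bundles every tunable of the generator: cohort sizes, per-marker and
#' per-glycopeptide effect sizes on the log scale, stage composition and
#' stage-graded effect scaling, peak-rendering jitter, and dropout. Defaults
#' emulate a retrospective lung-cancer screening cohort: 199 cancer / 590
#' healthy, stage-I-heavy staging, two strong markers (AUC ~ 0.8) among nine,
#' and a small minority of truly discriminative glycopeptides against a
#' large null background.
#'
#' @param n_cancer,n_healthy,n_qc_replicates cohort sizes; QC replicates are
#'   repeated injections of one pooled reference sample.
#' @param n_egp_true,n_egp_null numbers of discriminative and null enriched
#'   glycopeptides (EGPs).
#' @param n_noise_peaks_per_sample uninformative noise peaks rendered per
#'   sample.
#' @param marker_effects named standardized log-scale mean shifts for the 9
#'   tumor markers (cancer minus healthy); defaults calibrated via
#'   [effectForAUC()] to typical observed single-marker AUCs.
#' @param marker_glyco_aucs target AUCs of the two designated marker
#'   glycopeptides (the AT271-FSG / MG70-FSG roles), the first two true EGPs.
#' @param egp_effect_range min/max standardized shift for the remaining
#'   discriminative EGPs (signs randomized: both up- and down-regulation).
#' @param stage_weights probability vector over stages 0, I, II, III, IV,
#'   unclassified for cancer samples; must sum to 1.
#' @param stage_effect_scale named multiplier applied to all effect sizes for
#'   a sample of the given stage (effects grow with stage).
#' @param mz_jitter_sd,rt_jitter_sd rendering jitter SDs (Da, minutes); must
#'   stay below half the alignment tolerances (0.06 Da, 0.3 min) so that all
#'   rendered peaks of one feature remain alignable.
#' @param missing_rate probability that a true feature is below the detection
#'   limit in a given sample (missing values become zeros downstream).
#' @param noise_floor median intensity of rendered noise peaks.
#' @param seed integer RNG seed; identical configs with identical seeds
#'   yield identical cohorts.
#' @return a validated `CohortConfig` list.
#' @export
cohortConfig <- function(n_cancer = 199, n_healthy = 590, n_qc_replicates = 5,
                         n_egp_true = 30, n_egp_null = 1658,
                         n_noise_peaks_per_sample = 200,
                         marker_effects = effectForAUC(.MARKER_AUCS),
                         marker_glyco_aucs = c(0.80, 0.79),
                         egp_effect_range = c(0.8, 2.0),
                         stage_weights = .STAGE_COUNTS / sum(.STAGE_COUNTS),
                         stage_effect_scale = c("0" = 0.5, I = 0.8, II = 1.0,
                                                III = 1.2, IV = 1.5,
                                                unclassified = 1.0),
                         mz_jitter_sd = 0.01, rt_jitter_sd = 0.05,
                         missing_rate = 0.05, noise_floor = 1000,
                         seed = 1L) {
  counts <- c(n_cancer = n_cancer, n_healthy = n_healthy,
              n_qc_replicates = n_qc_replicates, n_egp_true = n_egp_true,
              n_egp_null = n_egp_null,
              n_noise_peaks_per_sample = n_noise_peaks_per_sample)
  if (any(counts < 0)) stop("all counts must be nonnegative")
  if (length(marker_effects) != length(.MARKERS))
    stop("marker_effects must have one entry per marker (", length(.MARKERS), ")")
  if (length(stage_weights) != length(.STAGES) ||
      abs(sum(stage_weights) - 1) > 1e-9)
    stop("stage_weights must be a probability vector over the ",
         length(.STAGES), " stages summing to 1")
  if (!all(.STAGES %in% names(stage_effect_scale)))
    stop("stage_effect_scale must name every stage")
  if (mz_jitter_sd >= 0.06 / 2 || rt_jitter_sd >= 0.3 / 2)
    stop("jitter SDs must stay below half the alignment tolerances ",
         "(mz_jitter_sd < 0.03 Da, rt_jitter_sd < 0.15 min)")
  if (missing_rate < 0 || missing_rate > 1)
    stop("missing_rate must lie in [0, 1]")
  if (n_egp_true > 0 && n_egp_true < length(marker_glyco_aucs))
    stop("n_egp_true must cover the designated marker glycopeptides")
  cfg <- list(
    n_cancer = as.integer(n_cancer), n_healthy = as.integer(n_healthy),
    n_qc_replicates = as.integer(n_qc_replicates),
    n_egp_true = as.integer(n_egp_true), n_egp_null = as.integer(n_egp_null),
    n_noise_peaks_per_sample = as.integer(n_noise_peaks_per_sample),
    marker_effects = setNames(as.numeric(marker_effects), .MARKERS),
    marker_glyco_aucs = marker_glyco_aucs,
    egp_effect_range = as.numeric(egp_effect_range),
    stage_weights = setNames(as.numeric(stage_weights), .STAGES),
    stage_effect_scale = stage_effect_scale[.STAGES],
    mz_jitter_sd = mz_jitter_sd, rt_jitter_sd = rt_jitter_sd,
    missing_rate = missing_rate, noise_floor = noise_floor,
    seed = as.integer(seed)
  )
  class(cfg) <- "CohortConfig"
  cfg
}

# Dispersion (log10 SD) of markers and EGP abundances; standardized shifts
# are expressed in units of these SDs. Measurement noise is the technical
# component seen by repeated QC injections.
.MARKER_SD <- 0.4
.EGP_SD <- 0.35
.QC_NOISE_SD <- 0.05

#' Generate a synthetic screening cohort
#'
#' Draws sample metadata (label, stage, ethnicity, QC flags), log-normal
#' tumor-marker panels, and log-normal true EGP abundances. Cancer samples'
#' log-abundances are shifted by the configured standardized effects, scaled
#' by the stage multiplier of the sample's stage; healthy samples draw from
#' the baseline. QC replicates re-draw one pooled reference sample with
#' measurement noise only. Reproducible given `config$seed`.
#'
#' @param config a [cohortConfig()] object.
#' @return a `Cohort` list: `samples` (metadata data.frame), `markers`
#'   (samples x 9 concentrations), `egp` (samples x EGP true abundance
#'   matrix), `marker_glyco` (samples x 2, the designated marker
#'   glycopeptides), and `truth` (ground-truth list with `true_egp_ids`,
#'   signed `effects`, and per-sample `label`).
#' @export
generateCohort <- function(config) {
  stopifnot(inherits(config, "CohortConfig"))
  if (config$n_cancer == 0 || config$n_healthy == 0)
    stop("both classes must be represented (n_cancer and n_healthy > 0)")
  withSeed(config$seed, {
    n_egp <- config$n_egp_true + config$n_egp_null
    n_study <- config$n_cancer + config$n_healthy
    n_all <- n_study + config$n_qc_replicates

    label <- c(rep("cancer", config$n_cancer), rep("healthy", config$n_healthy),
               rep("healthy", config$n_qc_replicates))
    is_qc <- c(rep(FALSE, n_study), rep(TRUE, config$n_qc_replicates))
    stage <- rep("not-applicable", n_all)
    if (config$n_cancer > 0)
      stage[seq_len(config$n_cancer)] <-
        sample(.STAGES, config$n_cancer, replace = TRUE,
               prob = config$stage_weights)
    ethnicity <- sample(c("Asian", "Caucasian", "African-American", "Hispanic"),
                        n_all, replace = TRUE, prob = c(0.6, 0.17, 0.15, 0.08))
    sample_id <- c(sprintf("S%04d", seq_len(n_study)),
                   sprintf("QC%02d", seq_len(config$n_qc_replicates)))
    scale <- ifelse(label == "cancer", config$stage_effect_scale[stage], 0)

    # signed standardized effects per EGP: the first columns are the true
    # (discriminative) EGPs; the designated marker glycopeptides come first
    # with fixed positive effects, the rest draw from egp_effect_range with
    # random sign (both up- and down-regulation occur).
    egp_effects <- numeric(n_egp)
    n_mg <- min(length(config$marker_glyco_aucs), config$n_egp_true)
    if (n_mg > 0)
      egp_effects[seq_len(n_mg)] <- effectForAUC(config$marker_glyco_aucs[seq_len(n_mg)])
    if (config$n_egp_true > n_mg) {
      idx <- (n_mg + 1):config$n_egp_true
      mag <- runif(length(idx), config$egp_effect_range[1],
                   config$egp_effect_range[2])
      egp_effects[idx] <- mag * sample(c(-1, 1), length(idx), replace = TRUE)
    }
    egp_ids <- sprintf("EGP%04d", seq_len(n_egp))

    # log10 baselines
    marker_mu <- runif(length(.MARKERS), 0.2, 1.2)
    egp_mu <- runif(n_egp, 4, 6)

    z_mark <- matrix(rnorm(n_all * length(.MARKERS)), n_all)
    log_mark <- sweep(z_mark, 2, marker_mu / .MARKER_SD, `+`) +
      outer(scale, config$marker_effects)
    markers <- 10 ^ (log_mark * .MARKER_SD)

    z_egp <- matrix(rnorm(n_all * n_egp), n_all)
    log_egp <- sweep(z_egp, 2, egp_mu / .EGP_SD, `+`) +
      outer(scale, egp_effects)
    egp <- 10 ^ (log_egp * .EGP_SD)

    # QC replicates: one pooled reference (the baseline mean) re-measured
    # with technical noise only
    if (config$n_qc_replicates > 0) {
      qi <- (n_study + 1):n_all
      markers[qi, ] <- 10 ^ (rep(1, length(qi)) %o% marker_mu +
        matrix(rnorm(length(qi) * length(.MARKERS), sd = .QC_NOISE_SD),
               length(qi)))
      egp[qi, ] <- 10 ^ (rep(1, length(qi)) %o% egp_mu +
        matrix(rnorm(length(qi) * n_egp, sd = .QC_NOISE_SD), length(qi)))
    }
    dimnames(markers) <- list(sample_id, .MARKERS)
    dimnames(egp) <- list(sample_id, egp_ids)

    samples <- data.frame(sample_id = sample_id, label = label, stage = stage,
                          ethnicity = ethnicity, is_qc = is_qc,
                          stringsAsFactors = FALSE)
    true_ids <- egp_ids[seq_len(config$n_egp_true)]
    cohort <- list(
      samples = samples, markers = markers, egp = egp,
      marker_glyco = egp[, egp_ids[seq_len(max(n_mg, 0))], drop = FALSE],
      truth = list(true_egp_ids = true_ids,
                   effects = setNames(egp_effects, egp_ids),
                   label = setNames(label, sample_id)),
      config = config
    )
    class(cohort) <- "Cohort"
    cohort
  })
}

#' @export
print.Cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d cancer / %d healthy / %d QC; %d EGPs (%d discriminative)\n",
              sum(x$samples$label == "cancer"),
              sum(x$samples$label == "healthy" & !x$samples$is_qc),
              sum(x$samples$is_qc), ncol(x$egp),
              length(x$truth$true_egp_ids)))
  invisible(x)
}

#' Reference glycopeptide ion library for rendering
#'
#' Deterministically assigns each EGP a neutral monoisotopic mass and a
#' reference retention time, spread over the acquisition window. Masses are
#' spaced so that distinct glycopeptides never collide within the alignment
#' tolerance.
#'
#' @param egp_ids character vector of EGP identifiers.
#' @param mz_range,rt_range acquisition windows (Da for neutral mass before
#'   charge reduction; minutes).
#' @param seed RNG seed for the deterministic scatter.
#' @return data.frame with `egp_id`, `neutral_mass`, `rt`.
#' @export
glycoLibrary <- function(egp_ids, mz_range = c(1500, 5000),
                         rt_range = c(2, 13), seed = 99L) {
  n <- length(egp_ids)
  withSeed(seed, {
    # stratified mass grid + small scatter keeps pairwise spacing > 0.2 Da
    mass <- seq(mz_range[1], mz_range[2], length.out = n + 2)[1 + seq_len(n)]
    mass <- mass + runif(n, -0.05, 0.05)
    rt <- runif(n, rt_range[1], rt_range[2])
    data.frame(egp_id = egp_ids, neutral_mass = mass, rt = round(rt, 3))
  })
}

#' Render per-sample centroided peak lists
#'
#' Turns true EGP abundances into negative-mode centroided peak tables: for
#' each detected glycopeptide a monoisotopic peak at
#' (M - z * 1.007276) / z, isotope peaks spaced +1.00336/z with geometrically
#' decaying intensity, optional adduct peaks at configured neutral-mass
#' deltas, optional a fragment peak (loss of one sialic acid), plus uniform
#' noise peaks. Gaussian m/z and RT jitter is applied to each glycopeptide
#' observation (isotopes/adducts ride on the jittered parent so one ion
#' species stays within the alignment tolerance across samples), and each
#' glycopeptide independently drops out with probability `missing_rate`.
#'
#' @param cohort a [generateCohort()] result.
#' @param library a [glycoLibrary()] data.frame covering the cohort's EGPs.
#' @param charge charge state used for rendering (single state per ion).
#' @param n_isotopes isotope peaks per ion (0 disables).
#' @param isotope_ratio geometric decay ratio of the isotope envelope.
#' @param adducts named numeric neutral-mass deltas (Da); NULL disables.
#' @param adduct_intensity relative intensity of adduct peaks.
#' @param fragments logical; render a sialic-acid-loss fragment ion at 15%
#'   relative intensity.
#' @param noise logical; render uniform noise peaks.
#' @return named list (one element per sample) of data.frames with columns
#'   `sample_id`, `mz`, `rt`, `intensity`; attribute `truth` holds the
#'   reference ion table (per EGP and ion kind: expected m/z and RT).
#' @export
renderPeakLists <- function(cohort, library = NULL, charge = 2L,
                            n_isotopes = 2L, isotope_ratio = 0.6,
                            adducts = .ADDUCT_DELTAS, adduct_intensity = 0.2,
                            fragments = FALSE, noise = TRUE) {
  stopifnot(inherits(cohort, "Cohort"))
  config <- cohort$config
  if (is.null(library)) library <- glycoLibrary(colnames(cohort$egp))
  if (nrow(library) == 0) stop("glycopeptide library must be nonempty")
  if (any(library$neutral_mass <= 0)) stop("library masses must be positive")
  lib <- library[match(colnames(cohort$egp), library$egp_id), ]
  if (any(is.na(lib$neutral_mass)))
    stop("library must cover every EGP in the cohort")

  mono_mz <- mzFromNeutral(lib$neutral_mass, charge, "negative")
  ion_kinds <- data.frame(kind = "mono", dmz = 0, rel = 1)
  if (n_isotopes > 0)
    ion_kinds <- rbind(ion_kinds, data.frame(
      kind = paste0("iso", seq_len(n_isotopes)),
      dmz = seq_len(n_isotopes) * .ISOTOPE_SPACING / charge,
      rel = isotope_ratio ^ seq_len(n_isotopes)))
  if (!is.null(adducts) && length(adducts))
    ion_kinds <- rbind(ion_kinds, data.frame(
      kind = paste0("adduct_", names(adducts)),
      dmz = as.numeric(adducts) / charge, rel = adduct_intensity))
  if (fragments)
    ion_kinds <- rbind(ion_kinds, data.frame(
      kind = "frag_neuac", dmz = -.GLYCAN_MASS[["neuac"]] / charge,
      rel = 0.15))

  truth <- do.call(rbind, lapply(seq_len(nrow(lib)), function(j)
    data.frame(egp_id = lib$egp_id[j], kind = ion_kinds$kind,
               mz = mono_mz[j] + ion_kinds$dmz, rt = lib$rt[j],
               rel = ion_kinds$rel)))

  withSeed(config$seed + 1000003L, {
    out <- lapply(seq_len(nrow(cohort$samples)), function(i) {
      sid <- cohort$samples$sample_id[i]
      ab <- cohort$egp[i, ]
      # below-detection dropout models biological missingness; the pooled QC
      # standard is always detected
      detected <- cohort$samples$is_qc[i] |
        runif(length(ab)) >= config$missing_rate
      idx <- which(detected)
      if (length(idx)) {
        jit_mz <- rnorm(length(idx), sd = config$mz_jitter_sd)
        jit_rt <- rnorm(length(idx), sd = config$rt_jitter_sd)
        # truncate rare tail draws so rendered peaks stay inside tolerance
        jit_mz <- pmax(pmin(jit_mz, 0.0299), -0.0299)
        jit_rt <- pmax(pmin(jit_rt, 0.149), -0.149)
        sig <- do.call(rbind, lapply(seq_along(idx), function(k) {
          j <- idx[k]
          data.frame(sample_id = sid,
                     mz = mono_mz[j] + jit_mz[k] + ion_kinds$dmz,
                     rt = lib$rt[j] + jit_rt[k],
                     intensity = ab[j] * ion_kinds$rel)
        }))
      } else sig <- NULL
      if (noise && config$n_noise_peaks_per_sample > 0) {
        nn <- config$n_noise_peaks_per_sample
        nz <- data.frame(sample_id = sid,
                         mz = runif(nn, min(mono_mz) - 50, max(mono_mz) + 50),
                         rt = runif(nn, 0.5, 14.5),
                         intensity = config$noise_floor *
                           10 ^ rnorm(nn, sd = 0.15))
        sig <- rbind(sig, nz)
      }
      if (is.null(sig))
        sig <- data.frame(sample_id = character(), mz = numeric(),
                          rt = numeric(), intensity = numeric())
      rownames(sig) <- NULL
      sig
    })
    names(out) <- cohort$samples$sample_id
    attr(out, "truth") <- truth
    out
  })
}

#' Write / read peak lists as delimited text
#'
#' One tab-separated file per sample (`<sample_id>.tsv`) with columns
#' `sample_id`, `mz`, `rt`, `intensity`.
#'
#' @param peaklists named list of peak data.frames.
#' @param dir output directory (created if absent).
#' @return `writePeakLists` returns the file paths invisibly;
#'   `readPeakLists` returns a named list of peak data.frames.
#' @export
writePeakLists <- function(peaklists, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(peaklists), function(sid) {
    p <- file.path(dir, paste0(sid, ".tsv"))
    write.table(peaklists[[sid]], p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}

#' @rdname writePeakLists
#' @export
readPeakLists <- function(dir) {
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  if (!length(files)) stop("no .tsv peak lists found in ", dir)
  out <- lapply(files, read.delim)
  names(out) <- sub("\\.tsv$", "", basename(files))
  out
}
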