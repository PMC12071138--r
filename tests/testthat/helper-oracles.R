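# Independent brute-force oracles, kept deliberately naive so they cannot
# share bugs with the package implementations.

# All-pairs greedy clustering oracle for peak alignment: same rule as the
# package (descending-intensity seeding, nearest eligible feature in
# tolerance-normalized distance, lowest index on ties) written as plain
# nested loops over a single flat peak table.
bruteForceAlign <- function(peaks, mz_tol, rt_tol) {
  ord <- order(-peaks$intensity, peaks$mz, peaks$rt, peaks$sample_idx)
  feat_mz <- c()
  feat_rt <- c()
  assign <- integer(nrow(peaks))
  for (p in ord) {
    best <- 0L
    best_d <- Inf
    if (length(feat_mz)) {
      for (f in seq_along(feat_mz)) {
        dmz <- abs(feat_mz[f] - peaks$mz[p])
        drt <- abs(feat_rt[f] - peaks$rt[p])
        if (dmz <= mz_tol && drt <= rt_tol) {
          d <- (dmz / mz_tol)^2 + (drt / rt_tol)^2
          if (d < best_d) { best_d <- d; best <- f }
        }
      }
    }
    if (best == 0L) {
      feat_mz <- c(feat_mz, peaks$mz[p])
      feat_rt <- c(feat_rt, peaks$rt[p])
      best <- length(feat_mz)
    }
    assign[p] <- best
  }
  assign
}

# All-pairs mass matching oracle
bruteForceMatch <- function(observed, theoretical, tol) {
  hits <- list()
  for (i in seq_along(observed))
    for (j in seq_along(theoretical))
      if (abs(observed[i] - theoretical[j]) <= tol)
        hits[[length(hits) + 1L]] <- c(i = i, j = j)
  if (!length(hits)) return(matrix(integer(), ncol = 2,
                                   dimnames = list(NULL, c("i", "j"))))
  do.call(rbind, hits)
}

# Canonical partitions (label vectors up to renaming) for comparing
# clusterings
canonicalPartition <- function(assign) {
  match(assign, unique(assign))
}

# Small rendered cohort used by several alignment tests
smallRenderedCohort <- function(seed = 7, n_cancer = 20, n_healthy = 30,
                                n_egp_true = 5, n_egp_null = 15,
                                noise_peaks = 100, ...) {
  cfg <- cohortConfig(n_cancer = n_cancer, n_healthy = n_healthy,
                      n_qc_replicates = 5, n_egp_true = n_egp_true,
                      n_egp_null = n_egp_null,
                      n_noise_peaks_per_sample = noise_peaks,
                      seed = seed, ...)
  co <- generateCohort(cfg)
  pl <- renderPeakLists(co)
  list(config = cfg, cohort = co, peaklists = pl,
       truth = attr(pl, "truth"),
       sampleData = data.frame(row.names = co$samples$sample_id,
                               is_qc = co$samples$is_qc))
}

# Hand-built 10-feature matrix: 2 CV failures, 1 S/N failure, 3 isotope
# satellites, 4 clean survivors (F7..F10)
handCountedFixture <- function() {
  set.seed(42)
  n_study <- 6
  mz <- c(310.0, 320.0, 330.0,              # F1 F2 F3
          501.00336, 601.00336, 700.50168,  # F4 F5 F6 (isotope positions)
          500.0, 600.0, 700.0, 900.0)       # F7 F8 F9 F10
  rt <- c(1, 1.5, 2, 4, 6, 8, 4, 6, 8, 10)
  ab <- matrix(runif(10 * n_study, 90, 110), 10, n_study)
  ab[4, ] <- ab[7, ] * 0.6   # weaker satellites of their parents
  ab[5, ] <- ab[8, ] * 0.6
  ab[6, ] <- ab[9, ] * 0.6
  qc <- cbind(c(1, 2, rep(10, 8)),
              c(10, 20, rep(10, 8)),
              c(19, 38, rep(10, 8)))   # F1, F2: CV = 0.9; others CV = 0
  abundance <- cbind(ab, qc)
  colnames(abundance) <- c(sprintf("S%d", 1:n_study), sprintf("QC%d", 1:3))
  sd <- data.frame(row.names = colnames(abundance),
                   is_qc = rep(c(FALSE, TRUE), c(n_study, 3)))
  x <- GlycoFeatureSet(abundance, mz = mz, rt = rt, sampleData = sd)
  noise <- rep(10, 10)
  x <- filterCV(x, cv_max = 0.5)
  # F3's signal is pushed to S/N 4 via an explicit noise vector
  noise[3] <- median(abundance[3, 1:n_study]) / 4
  x <- filterSNR(x, noise = noise, snr_min = 5)
  flagFeatures(x, adduct_deltas = NULL, frag_cor = NA)
}
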