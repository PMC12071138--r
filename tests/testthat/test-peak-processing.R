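test_that("alignment merges peaks within tolerance and separates those outside", {
  pl <- list(
    A = data.frame(mz = c(500.00, 500.10), rt = c(5.0, 5.0),
                   intensity = c(10, 8)),
    B = data.frame(mz = 500.04, rt = 5.1, intensity = 9)
  )
  g <- alignPeaks(pl, min_fraction = 0)
  expect_equal(nrow(g), 2)            # 500.00/500.04 merge; 500.10 splits off
  ab <- abundances(g)
  merged <- which(rowSums(ab > 0) == 2)
  expect_length(merged, 1)
  expect_lt(abs(featureMz(g)[merged] - 500.02), 0.03)

  expect_error(alignPeaks(list()), "at least one sample")
  expect_error(alignPeaks(list(A = data.frame(mz = NaN, rt = 1,
                                              intensity = 1))), "finite")
})

test_that("alignment equals the brute-force all-pairs oracle on small instances", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 150
    # clumpy peaks so tolerance decisions are actually exercised
    centers_mz <- runif(25, 400, 410)
    centers_rt <- runif(25, 4, 6)
    pick <- sample(25, n, replace = TRUE)
    peaks <- data.frame(
      sample_idx = sample(3, n, replace = TRUE),
      mz = centers_mz[pick] + rnorm(n, sd = 0.04),
      rt = centers_rt[pick] + rnorm(n, sd = 0.2),
      intensity = runif(n, 1, 100)
    )
    oracle <- canonicalPartition(bruteForceAlign(peaks, 0.06, 0.3))

    pl <- split(peaks[, c("mz", "rt", "intensity")], peaks$sample_idx)
    names(pl) <- paste0("S", names(pl))
    g <- alignPeaks(pl, min_fraction = 0)
    # read the package's partition back through the per-peak provenance table
    pt <- S4Vectors::metadata(g)$peak_table
    key <- function(s, mz, rt, int) paste(s, mz, rt, int)
    idx <- match(key(paste0("S", peaks$sample_idx), peaks$mz, peaks$rt,
                     peaks$intensity),
                 key(pt$sample, pt$mz, pt$rt, pt$intensity))
    pkg_assign <- pt$feature[idx]
    # same partition: peaks grouped together by the oracle are grouped
    # together by the package and vice versa
    expect_equal(canonicalPartition(pkg_assign), oracle)
  }
})

test_that("every input peak is assigned or recorded as dropped", {
  sc <- smallRenderedCohort(seed = 17)
  g <- alignPeaks(sc$peaklists, sampleData = sc$sampleData)
  md <- S4Vectors::metadata(g)
  expect_equal(md$n_assigned_peaks + nrow(md$unassigned_peaks),
               md$n_input_peaks)
  expect_equal(md$n_input_peaks,
               sum(vapply(sc$peaklists, nrow, integer(1))))
  # missing observations are zeros, never NA or negative
  expect_false(anyNA(abundances(g)))
  expect_true(all(abundances(g) >= 0))
})

test_that("isotope, adduct and satellite flagging follows the co-elution rules", {
  # textbook isotope pair at z = 2 spacing
  ab <- rbind(c(100, 110, 90), c(60, 66, 54))
  x <- GlycoFeatureSet(ab, mz = c(999.0, 999.50168), rt = c(5, 5))
  x <- flagFeatures(x, adduct_deltas = NULL, frag_cor = NA)
  expect_false(featureFlags(x)$is_isotope[1])
  expect_true(featureFlags(x)$is_isotope[2])

  # lone feature: nothing co-elutes, no flags
  y <- GlycoFeatureSet(matrix(5, 1, 3), mz = 800, rt = 3)
  y <- flagFeatures(y)
  expect_false(any(as.matrix(featureFlags(y))))

  # full synthetic render: all satellite ions flagged, no monoisotopic flagged
  sc <- smallRenderedCohort(seed = 23)
  g <- alignPeaks(sc$peaklists, sampleData = sc$sampleData)
  g <- flagFeatures(g)
  truth <- sc$truth
  fl <- featureFlags(g)
  sat <- fl$is_isotope | fl$is_adduct | fl$is_fragment
  for (i in seq_len(nrow(g))) {
    hit <- which(abs(truth$mz - featureMz(g)[i]) <= 0.06 &
                   abs(truth$rt - featureRt(g)[i]) <= 0.3)
    kind <- truth$kind[hit[which.min(abs(truth$mz[hit] - featureMz(g)[i]))]]
    if (length(kind)) {
      if (kind == "mono") expect_false(sat[i])
      else expect_true(sat[i])
    }
  }
})

test_that("CV filter computes replicate CV and fails irreproducible features", {
  ab <- cbind(matrix(10, 3, 2),               # two study samples
              rbind(c(10, 10, 10), c(8, 10, 12), c(1, 10, 19)))
  colnames(ab) <- c("S1", "S2", "Q1", "Q2", "Q3")
  sd_ <- data.frame(row.names = colnames(ab),
                    is_qc = c(FALSE, FALSE, TRUE, TRUE, TRUE))
  x <- GlycoFeatureSet(ab, mz = c(500, 600, 700), rt = c(1, 2, 3),
                       sampleData = sd_)
  x <- filterCV(x)
  rd <- SummarizedExperiment::rowData(x)
  expect_equal(unname(rd$qc_cv), c(0, 0.2, 0.9), tolerance = 1e-12)
  expect_identical(unname(rd$cv_fail), c(FALSE, FALSE, TRUE))
  expect_error(filterCV(x, qc_ids = "Q1"), "2 QC replicates")
})

test_that("S/N filter removes weak features against the local noise estimate", {
  ab <- matrix(c(100, 40), 2, 4)
  x <- GlycoFeatureSet(ab, mz = c(500, 900), rt = c(5, 6))
  x <- filterSNR(x, noise = c(10, 10))
  rd <- SummarizedExperiment::rowData(x)
  expect_equal(unname(rd$snr), c(10, 4))
  expect_identical(unname(rd$snr_fail), c(FALSE, TRUE))
  expect_error(filterSNR(x), "noise")  # no unassigned peaks, no estimate
})

test_that("the filter cascade keeps exactly the unflagged features, in (mz, rt) order", {
  x <- handCountedFixture()
  out <- applyFilterCascade(x)
  expect_equal(nrow(out), 4)
  expect_equal(featureMz(out), c(500, 600, 700, 900))
  counts <- S4Vectors::metadata(out)$cascade_counts
  expect_equal(unname(counts), c(10, 8, 7, 4))   # input -> CV -> S/N -> satellites
  expect_true(all(diff(counts) <= 0))            # monotone shrinking

  # identity when nothing is flagged; empty output warns
  clean <- GlycoFeatureSet(matrix(1:6, 2), mz = c(1, 2), rt = c(1, 2))
  expect_equal(nrow(applyFilterCascade(clean)), 2)
  rd <- SummarizedExperiment::rowData(clean)
  rd$cv_fail <- TRUE
  SummarizedExperiment::rowData(clean) <- rd
  expect_warning(applyFilterCascade(clean), "removed")
})

test_that("alignment + cascade recover the ground truth on clean renders", {
  sc <- smallRenderedCohort(seed = 29, noise_peaks = 0)
  g <- alignPeaks(sc$peaklists, sampleData = sc$sampleData)
  g <- flagFeatures(g)
  g <- filterCV(g)
  g <- filterSNR(g, noise = rep(1, nrow(g)))
  out <- applyFilterCascade(g)
  mono <- sc$truth[sc$truth$kind == "mono", ]
  expect_equal(nrow(out), nrow(mono))
  # per-feature abundance matches the generator's truth on observed samples
  for (j in seq_len(nrow(mono))) {
    i <- which(abs(featureMz(out) - mono$mz[j]) <= 0.06 &
                 abs(featureRt(out) - mono$rt[j]) <= 0.3)
    expect_length(i, 1)
    ab <- abundances(out)[i, rownames(sc$sampleData)]
    tr <- sc$cohort$egp[, mono$egp_id[j]]
    obs <- ab > 0
    expect_gt(suppressWarnings(cor(rank(ab[obs]), rank(tr[obs]))), 0.99)
  }
})

test_that("normalization to QC reference and internal standard is exact ratio arithmetic", {
  ab <- matrix(c(2, 4, 8, 2, 4, 8), 3)   # two samples identical to reference
  colnames(ab) <- c("S1", "S2")
  x <- GlycoFeatureSet(ab, mz = 1:3, rt = 1:3)
  n1 <- normalizeToReference(x, qc_reference = c(2, 4, 8))
  expect_true(all(abundances(n1) == 1))

  set.seed(8)
  ab2 <- matrix(runif(12, 1, 10), 3)
  colnames(ab2) <- paste0("S", 1:4)
  x2 <- GlycoFeatureSet(ab2, mz = 1:3, rt = 1:3)
  n2 <- normalizeToReference(x2, qc_reference = c(1, 1, 1),
                             internal_standard = rownames(x2)[2])
  expect_equal(unname(abundances(n2)[2, ]), rep(1, 4))
  # halving the internal standard in one sample doubles the others there
  ab3 <- ab2; ab3[2, 1] <- ab3[2, 1] / 2
  x3 <- GlycoFeatureSet(ab3, mz = 1:3, rt = 1:3)
  n3 <- normalizeToReference(x3, qc_reference = c(1, 1, 1),
                             internal_standard = rownames(x3)[2])
  expect_equal(abundances(n3)[1, 1], abundances(n2)[1, 1] * 2)

  ab4 <- ab2; ab4[2, 3] <- 0
  x4 <- GlycoFeatureSet(ab4, mz = 1:3, rt = 1:3)
  expect_error(normalizeToReference(x4, qc_reference = c(1, 1, 1),
                                    internal_standard = rownames(x4)[2]), "S3")
})

test_that("intra- and inter-day CV follow the replicate design", {
  same <- replicateCV(rep(7, 9), rep(1:3, each = 3))
  expect_equal(same$intra_cv, 0)
  expect_equal(same$inter_cv, 0)

  # intra-day: sample SD 7.906 over mean 100
  r1 <- replicateCV(c(90, 95, 100, 105, 110, 99, 101), c(1, 1, 1, 1, 1, 2, 2))
  expect_equal(r1$intra_cv, 0.0791, tolerance = 1e-3)
  # inter-day: day means 95 / 100 / 105, SD 5 over mean 100
  r2 <- replicateCV(c(94, 96, 99, 101, 104, 106), rep(1:3, each = 2))
  expect_equal(r2$inter_cv, 0.05)

  expect_error(replicateCV(c(1, 2), c(1, 1)), "2 days")
  expect_error(replicateCV(c(1, 1, 2), c(1, 2, 2)), "day 1")
  z <- replicateCV(c(1, -1, 2, -2), c(1, 1, 2, 2))
  expect_true(is.na(z$intra_cv) && isTRUE(attr(z$intra_cv, "undefined")))
})
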