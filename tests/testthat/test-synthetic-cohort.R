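test_that("effect size <-> AUC calibration inverts the binormal ROC formula", {
  # closed form checked numerically: Phi(0.999 / sqrt(2)) = 0.760
  expect_equal(effectForAUC(0.760), 0.999, tolerance = 1e-3)
  expect_equal(aucForEffect(effectForAUC(0.95)), 0.95, tolerance = 1e-12)
  expect_lt(effectForAUC(0.5 + 1e-6), 1e-4)
  expect_error(effectForAUC(0.5))
  expect_error(effectForAUC(1))

  # Monte-Carlo verification of the closed form at d = effectForAUC(0.76)
  set.seed(1)
  d <- effectForAUC(0.76)
  x <- c(rnorm(1e5, d), rnorm(1e5))
  y <- rep(c(1, 0), each = 1e5)
  r <- rank(x)
  auc_mc <- (sum(r[y == 1]) - 1e5 * (1e5 + 1) / 2) / 1e10
  expect_equal(auc_mc, 0.76, tolerance = 0.005)
})

test_that("cohort generation is deterministic and validates its config", {
  cfg <- cohortConfig(n_cancer = 10, n_healthy = 15, n_egp_true = 3,
                      n_egp_null = 7, seed = 5)
  co1 <- generateCohort(cfg)
  co2 <- generateCohort(cfg)
  expect_identical(co1, co2)
  expect_identical(dim(co1$egp), c(30L, 10L))  # 25 study + 5 QC, 10 EGPs
  expect_equal(nrow(co1$samples), 30)
  expect_true(all(co1$samples$stage[co1$samples$label == "healthy"] ==
                    "not-applicable"))
  expect_true(all(co1$markers >= 0), all(co1$egp >= 0))
  expect_identical(co1$truth$true_egp_ids, colnames(co1$egp)[1:3])

  expect_error(cohortConfig(n_cancer = -1), "nonnegative")
  expect_error(cohortConfig(mz_jitter_sd = 0.05), "tolerance")
  expect_error(cohortConfig(rt_jitter_sd = 0.2), "tolerance")
  expect_error(cohortConfig(missing_rate = 1.5), "missing_rate")
  expect_error(cohortConfig(stage_weights = rep(1, 6)), "summing to 1")
  expect_error(generateCohort(cohortConfig(n_cancer = 0)), "classes")
})

test_that("null marker effects give chance-level AUC; calibrated effects hit their target", {
  cfg0 <- cohortConfig(n_cancer = 500, n_healthy = 500, n_qc_replicates = 0,
                       marker_effects = rep(0, 9), marker_glyco_aucs = numeric(0),
                       n_egp_true = 0, n_egp_null = 5, seed = 31)
  co0 <- generateCohort(cfg0)
  auc0 <- rocAUC(co0$markers[, "CEA"], co0$samples$label)$auc
  expect_gt(auc0, 0.45)
  expect_lt(auc0, 0.55)

  eff <- rep(0, 9); eff[1] <- effectForAUC(0.8)
  cfg1 <- cohortConfig(n_cancer = 500, n_healthy = 500, n_qc_replicates = 0,
                       marker_effects = eff, marker_glyco_aucs = numeric(0),
                       n_egp_true = 0, n_egp_null = 5,
                       stage_effect_scale = setNames(rep(1, 6),
                         c("0", "I", "II", "III", "IV", "unclassified")),
                       seed = 32)
  co1 <- generateCohort(cfg1)
  auc1 <- rocAUC(co1$markers[, "CEA"], co1$samples$label)$auc
  expect_equal(auc1, 0.8, tolerance = 0.03)
})

test_that("rendered peak lists honor the m/z formula, dropout and jitter containment", {
  cfg <- cohortConfig(n_cancer = 3, n_healthy = 3, n_qc_replicates = 2,
                      n_egp_true = 0, n_egp_null = 1, missing_rate = 0,
                      n_noise_peaks_per_sample = 0, seed = 9)
  co <- generateCohort(cfg)
  lib <- data.frame(egp_id = colnames(co$egp), neutral_mass = 2000.0, rt = 5)
  pl <- renderPeakLists(co, lib, charge = 2, n_isotopes = 0, adducts = NULL,
                        noise = FALSE)
  # minimal render: exactly one peak per sample at the hand-computed m/z
  expect_true(all(vapply(pl, nrow, integer(1)) == 1))
  mzs <- vapply(pl, function(p) p$mz, numeric(1))
  expect_true(all(abs(mzs - 998.992724) < 0.03))   # jitter-contained

  # total dropout leaves noise only
  cfg1 <- cohortConfig(n_cancer = 3, n_healthy = 3, n_qc_replicates = 0,
                       n_egp_true = 0, n_egp_null = 1, missing_rate = 1,
                       n_noise_peaks_per_sample = 7, seed = 9)
  pl1 <- renderPeakLists(generateCohort(cfg1), lib, noise = TRUE)
  expect_true(all(vapply(pl1, nrow, integer(1)) == 7))

  # jitter containment: every signal peak of a feature within 0.06 Da / 0.3
  # min of its reference ion coordinates
  sc <- smallRenderedCohort(seed = 3, noise_peaks = 0)
  truth <- sc$truth
  for (p in sc$peaklists) {
    if (!nrow(p)) next
    ok <- vapply(seq_len(nrow(p)), function(i)
      any(abs(truth$mz - p$mz[i]) <= 0.06 & abs(truth$rt - p$rt[i]) <= 0.3),
      logical(1))
    expect_true(all(ok))
  }

  expect_error(renderPeakLists(co, lib[0, ]), "nonempty")
})

test_that("peak lists round-trip through delimited text", {
  sc <- smallRenderedCohort(seed = 13, n_cancer = 2, n_healthy = 2,
                            n_egp_true = 0, n_egp_null = 3, noise_peaks = 5)
  dir <- tempfile("peaks")
  writePeakLists(sc$peaklists, dir)
  back <- readPeakLists(dir)
  expect_setequal(names(back), names(sc$peaklists))
  for (sid in names(back))
    expect_equal(back[[sid]]$mz, sc$peaklists[[sid]]$mz, tolerance = 1e-9)
})
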