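test_that("sampleCohort produces the requested group structure", {
  cohort <- sampleCohort(cohortSpec(), seed = 1)
  expect_equal(nrow(cohort), 82)
  expect_equal(sum(cohort$diagnosis == "case"), 52)
  expect_equal(sum(cohort$diagnosis == "control"), 30)
  # exact per-group male counts pool to the overall percentage
  expect_equal(sum(cohort$sex == "M" & cohort$diagnosis == "case"), 41)
  expect_equal(sum(cohort$sex == "M" & cohort$diagnosis == "control"), 26)
  expect_true(all(cohort$age >= 4 & cohort$age <= 6.92))
  # batches balanced for diagnosis within +/- 1
  tb <- table(cohort$batch, cohort$diagnosis)
  expect_lte(diff(range(tb[, "case"])), 1)
  expect_lte(diff(range(tb[, "control"])), 1)
})

test_that("sampleCohort validates input and is deterministic", {
  expect_error(cohortSpec(n_case = 0), "positive")
  expect_error(cohortSpec(sex_ratio_case = 1.2), "\\[0, 1\\]")
  expect_error(cohortSpec(age_range = c(6, 4)), "age_range")
  expect_identical(sampleCohort(seed = 1), sampleCohort(seed = 1))
  expect_false(identical(sampleCohort(seed = 1), sampleCohort(seed = 2)))
})

test_that("generator is bit-identical under a fixed seed", {
  cohort <- sampleCohort(cohortSpec(n_case = 8, n_control = 6), seed = 3)
  plats <- list(platformSpec("HILICpos", 40, c(60, 1000), c(30, 1740),
                             n_internal_standards = 2))
  cfg <- generatorConfig(seed = 9)
  a <- generateFeatureMatrix(cohort, plats, NULL, cfg)
  b <- generateFeatureMatrix(cohort, plats, NULL, cfg)
  expect_identical(areas(a$HILICpos), areas(b$HILICpos))
  expect_identical(featureData(a$HILICpos), featureData(b$HILICpos))
})

test_that("planted fold changes are recovered at large n", {
  n <- 5000L
  cohort <- sampleCohort(cohortSpec(n_case = n, n_control = n), seed = 4)
  eff <- effectSpec("LC", c(2.55, 0.67), base_abundance = 1e5, cv = 0.3)
  sets <- generateFeatureMatrix(
    cohort, list(platformSpec("LC", 10, c(60, 500), c(30, 600),
                              n_internal_standards = 0)),
    eff, generatorConfig(seed = 5, missing_rate = 0, batch_sd = 0,
                         sample_scale_sd = 0,
                         frac_noise_features = 0, frac_low_abundance = 0))
  a <- areas(sets$LC)
  d <- diagnosis(sets$LC)
  ratio <- rowMeans(a[1:2, d == "case"]) / rowMeans(a[1:2, d == "control"])
  expect_equal(ratio[[1]], 2.55, tolerance = 0.02)
  expect_equal(ratio[[2]], 0.67, tolerance = 0.02)
})

test_that("null generator yields uniform Welch p-values", {
  cohort <- sampleCohort(cohortSpec(), seed = 6)
  sets <- generateFeatureMatrix(
    cohort, list(platformSpec("LC", 2000, c(60, 1000), c(30, 1740),
                              n_internal_standards = 0)),
    NULL, generatorConfig(seed = 6, missing_rate = 0, batch_sd = 0,
                          sample_scale_sd = 0, frac_noise_features = 0,
                          frac_low_abundance = 0))
  d <- diagnosis(sets$LC)
  a <- areas(sets$LC)
  p <- welchTest(a[, d == "case"], a[, d == "control"])$p
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("missing rate and artifact classes are honored", {
  cohort <- sampleCohort(cohortSpec(n_case = 30, n_control = 30), seed = 7)
  cfg <- generatorConfig(seed = 7, missing_rate = 0.1,
                         frac_noise_features = 0.2, frac_low_abundance = 0.1,
                         contaminant_mz_list = c(149.02, 391.28))
  sets <- generateFeatureMatrix(
    cohort, list(platformSpec("HILICpos", 500, c(60, 1000), c(30, 1740),
                              n_internal_standards = 5)), NULL, cfg)
  ms <- sets$HILICpos
  cls <- S4Vectors::metadata(ms)$feature_class
  bio <- cls %in% c("biological", "low_abundance", "noise", "contaminant")
  zfrac <- mean(areas(ms)[bio, ] == 0)
  expect_lt(abs(zfrac - 0.1), 3 * sqrt(0.1 * 0.9 / (sum(bio) * 60)))
  expect_equal(sum(cls == "noise"), 100)
  expect_equal(sum(cls == "low_abundance"), 50)
  expect_equal(sum(cls == "contaminant"), 2)
  # noise features sit above the biological mass-defect envelope
  fd <- featureData(ms)
  frac <- fd$mz - floor(fd$mz)
  expect_true(all(frac[cls == "noise"] > 0.3 + 0.001 * fd$mz[cls == "noise"]))
  expect_true(all(frac[cls == "biological"] <=
                  0.3 + 0.001 * fd$mz[cls == "biological"]))
  # feature id convention
  expect_true(all(grepl("^M[0-9]+T[0-9]+", fd$feature_id)))
})

test_that("internal standards have low between-sample cv after normalization", {
  cohort <- sampleCohort(cohortSpec(n_case = 20, n_control = 20), seed = 8)
  sets <- generateFeatureMatrix(
    cohort, list(platformSpec("HILICpos", 100, c(60, 1000), c(30, 1740),
                              n_internal_standards = 5)),
    NULL, generatorConfig(seed = 8, is_cv = 0.05))
  norm <- normalizeInternalStandards(sets$HILICpos)
  is_area <- areas(norm)[isInternalStandard(norm), ]
  cvs <- apply(is_area, 1, function(v) sd(v) / mean(v))
  expect_true(all(cvs < 3 * 0.05))
})

test_that("effects referencing unknown platforms are rejected", {
  cohort <- sampleCohort(cohortSpec(n_case = 4, n_control = 4), seed = 1)
  expect_error(
    generateFeatureMatrix(cohort,
                          list(platformSpec("LC", 10, c(60, 500), c(30, 60))),
                          effectSpec("nope", 2), generatorConfig()),
    "unknown platform")
  expect_error(effectSpec("LC", -1), "positive")
})

test_that("feature tables round-trip through the delimited format", {
  ms <- tinyMetaboSet()
  path <- withr::local_tempfile(fileext = ".tsv")
  writeFeatureTable(ms, path)
  back <- readFeatureTable(path, sampleData = sampleData(ms))
  expect_equal(areas(back), areas(ms), tolerance = 1e-12)
  expect_equal(featureData(back)$feature_id, featureData(ms)$feature_id)
  expect_equal(as.character(diagnosis(back)), as.character(diagnosis(ms)))
})
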