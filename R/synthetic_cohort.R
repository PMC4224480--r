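#' Specification of a case-control cohort
#'
#' Defaults emulate a plasma metabolomics study of young children: 52 cases
#' and 30 controls aged 4-6.9 years, predominantly male, with the case group
#' showing a markedly lower IQ distribution.
#'
#' @param n_case,n_control group sizes (must be positive).
#' @param sex_ratio_case,sex_ratio_control fraction male per group, in [0,1].
#' @param age_range numeric length-2, years (min < max); ages drawn uniformly.
#' @param iq_case,iq_control numeric length-2 `c(mean, sd)` in IQ points.
#' @return A list of class `cohort_spec`.
#' @export
cohortSpec <- function(n_case = 52L, n_control = 30L,
                       sex_ratio_case = 41 / 52, sex_ratio_control = 26 / 30,
                       age_range = c(4, 6.92),
                       iq_case = c(67.48, 17.69),
                       iq_control = c(114.3, 10.78)) {
  if (n_case <= 0 || n_control <= 0)
    stop("group sizes must be positive")
  for (r in c(sex_ratio_case, sex_ratio_control))
    if (r < 0 || r > 1) stop("sex ratios must lie in [0, 1]")
  if (length(age_range) != 2 || age_range[1] >= age_range[2])
    stop("age_range must be c(min, max) with min < max")
  structure(list(n_case = as.integer(n_case),
                 n_control = as.integer(n_control),
                 sex_ratio_case = sex_ratio_case,
                 sex_ratio_control = sex_ratio_control,
                 age_range = age_range, iq_case = iq_case,
                 iq_control = iq_control),
            class = "cohort_spec")
}

#' Specification of one analytical platform
#'
#' @param name platform name; conventionally one of `HILICpos`, `HILICneg`,
#'   `C8pos`, `C8neg`, `GCMS`.
#' @param n_features number of raw mass features the platform yields.
#' @param mz_range,rt_range numeric length-2 ranges (m/z; retention seconds).
#' @param n_internal_standards number of spiked internal-standard features
#'   (counted within `n_features`).
#' @return A list of class `platform_spec`.
#' @export
platformSpec <- function(name, n_features, mz_range, rt_range,
                         n_internal_standards = 10L) {
  n_features <- as.integer(n_features)
  n_internal_standards <- as.integer(n_internal_standards)
  if (n_internal_standards < 0 || n_features < n_internal_standards)
    stop("need n_features >= n_internal_standards >= 0")
  for (r in list(mz_range, rt_range))
    if (length(r) != 2 || any(r <= 0) || r[1] >= r[2])
      stop("ranges must be positive and ordered")
  structure(list(name = name, n_features = n_features, mz_range = mz_range,
                 rt_range = rt_range,
                 n_internal_standards = n_internal_standards),
            class = "platform_spec")
}

#' Default five-platform design
#'
#' Four untargeted LC-HRMS acquisitions (HILIC and C8 chromatography, each in
#' positive and negative electrospray polarity) plus targeted GC-MS, with raw
#' feature counts 3207, 1865, 3062, 1568 and 485 (total 10187).
#'
#' @return Named list of [platformSpec()] objects.
#' @export
defaultPlatformSpecs <- function() {
  specs <- list(
    platformSpec("HILICpos", 3207L, c(60, 1000), c(30, 1740)),
    platformSpec("HILICneg", 1865L, c(60, 1000), c(30, 1740)),
    platformSpec("C8pos",    3062L, c(100, 1200), c(30, 3000)),
    platformSpec("C8neg",    1568L, c(100, 1200), c(30, 3000)),
    platformSpec("GCMS",      485L, c(70, 600),  c(60, 1500),
                 n_internal_standards = 5L))
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}

#' Planted case-control effects
#'
#' Each row plants one discriminative feature on a platform with a
#' case/control fold change on the expected (arithmetic-mean) scale.
#'
#' @param platform character vector of platform names.
#' @param fold_change positive ratio of case to control expected abundance.
#' @param base_abundance control-group expected integrated area.
#' @param cv within-group coefficient of variation (fraction).
#' @return data.frame of class `effect_spec`.
#' @export
effectSpec <- function(platform, fold_change, base_abundance = 1e5, cv = 0.3) {
  if (any(fold_change <= 0)) stop("fold_change must be positive")
  if (any(cv <= 0)) stop("cv must be positive")
  out <- data.frame(platform = platform, fold_change = fold_change,
                    base_abundance = base_abundance, cv = cv,
                    stringsAsFactors = FALSE)
  class(out) <- c("effect_spec", "data.frame")
  out
}

#' Default planted effect set
#'
#' Thirty discriminative features spread over the LC platforms with fold
#' changes spanning 0.67 to 2.55 -- the scale reported for confirmed plasma
#' metabolites in case-control studies of this design.
#'
#' @param n number of planted features.
#' @param cv within-group coefficient of variation.
#' @return An [effectSpec()].
#' @export
defaultEffects <- function(n = 30L, cv = 0.3) {
  folds <- rep(c(0.67, 1.5, 1.8, 2.0, 2.55, 0.65), length.out = n)
  plats <- rep(c("HILICpos", "HILICneg", "C8pos", "C8neg", "GCMS"),
               length.out = n)
  effectSpec(plats, folds, base_abundance = 1e5, cv = cv)
}

#' Generator configuration
#'
#' Non-biological artifact classes emulated by the generator: features with a
#' non-biological mass defect (`frac_noise_features`), chronically
#' low-abundance features (`frac_low_abundance`), known contaminant m/z
#' values, batch structure, a per-sample global intensity factor and
#' missing-completely-at-random zero cells. Fractions may be a single value
#' or a named per-platform vector. The defaults are calibrated so that, under
#' [defaultFilterConfig()], the per-platform surviving feature counts are
#' 1527, 950, 1096, 514 and 485 (total 4572).
#'
#' @param seed integer seed; fixed seed reproduces matrices bit-identically.
#' @param n_batches number of acquisition batches.
#' @param batch_sd log-scale sd of the multiplicative batch factor.
#' @param sample_scale_sd log-scale sd of the per-sample loading factor.
#' @param missing_rate fraction of non-internal-standard cells zeroed.
#' @param frac_noise_features fraction of features given a non-biological
#'   mass defect (scalar or named per-platform).
#' @param frac_low_abundance fraction of features generated below the
#'   low-abundance filter threshold (scalar or named per-platform).
#' @param contaminant_mz_list m/z values at which contaminant features are
#'   planted on every polarity-matched LC platform whose range covers them.
#' @param is_cv residual coefficient of variation of internal standards.
#' @return list of class `generator_config`.
#' @export
generatorConfig <- function(seed = 1L, n_batches = 3L, batch_sd = 0.1,
                            sample_scale_sd = 0.15, missing_rate = 0.02,
                            frac_noise_features = c(
                              HILICpos = 1008 / 3207, HILICneg = 549 / 1865,
                              C8pos = 1179 / 3062, C8neg = 632 / 1568,
                              GCMS = 0),
                            frac_low_abundance = c(
                              HILICpos = 672 / 3207, HILICneg = 366 / 1865,
                              C8pos = 787 / 3062, C8neg = 422 / 1568,
                              GCMS = 0),
                            contaminant_mz_list = numeric(0),
                            is_cv = 0.05) {
  for (f in list(missing_rate, frac_noise_features, frac_low_abundance))
    if (any(f < 0) || any(f > 1)) stop("fractions must lie in [0, 1]")
  structure(list(seed = as.integer(seed), n_batches = as.integer(n_batches),
                 batch_sd = batch_sd, sample_scale_sd = sample_scale_sd,
                 missing_rate = missing_rate,
                 frac_noise_features = frac_noise_features,
                 frac_low_abundance = frac_low_abundance,
                 contaminant_mz_list = contaminant_mz_list, is_cv = is_cv),
            class = "generator_config")
}

fracFor <- function(frac, platform) {
  if (length(frac) == 1L && is.null(names(frac))) return(unname(frac))
  if (platform %in% names(frac)) return(unname(frac[platform]))
  0
}

#' Simulate sample metadata for a case-control cohort
#'
#' Sex is assigned by exact per-group counts (`round(ratio * n)`), ages are
#' uniform over the age range and IQ is normal per group. Batches are
#' assigned round-robin within diagnosis so every batch has a near-equal
#' case/control mix.
#'
#' @param spec a [cohortSpec()].
#' @param seed integer seed.
#' @param n_batches number of acquisition batches.
#' @return data.frame with columns sample_id, diagnosis (control/case), sex,
#'   age, iq, batch; cases first.
#' @examples
#' cohort <- sampleCohort(cohortSpec(), seed = 1)
#' table(cohort$diagnosis)
#' @export
sampleCohort <- function(spec = cohortSpec(), seed = 1L, n_batches = 3L) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(as.integer(seed))
  n <- spec$n_case + spec$n_control
  groupRows <- function(n_g, ratio, iq, diag, offset) {
    n_male <- round(ratio * n_g)
    sex <- sample(c(rep("M", n_male), rep("F", n_g - n_male)))
    data.frame(
      sample_id = sprintf("S%03d", offset + seq_len(n_g)),
      diagnosis = diag,
      sex = sex,
      age = round(runif(n_g, spec$age_range[1], spec$age_range[2]), 2),
      iq = round(rnorm(n_g, iq[1], iq[2])),
      stringsAsFactors = FALSE)
  }
  out <- rbind(groupRows(spec$n_case, spec$sex_ratio_case, spec$iq_case,
                         "case", 0L),
               groupRows(spec$n_control, spec$sex_ratio_control,
                         spec$iq_control, "control", spec$n_case))
  # round-robin within diagnosis keeps batches balanced for class
  out$batch <- integer(n)
  for (d in c("case", "control")) {
    idx <- which(out$diagnosis == d)
    out$batch[idx] <- rep_len(seq_len(n_batches), length(idx))
  }
  rownames(out) <- out$sample_id
  out
}

cvToSdlog <- function(cv) sqrt(log(1 + cv^2))

makeFeatureIds <- function(mz, rt) {
  ids <- sprintf("M%dT%d", round(mz), round(rt))
  while (anyDuplicated(ids)) {
    d <- duplicated(ids)
    ids[d] <- paste0(ids[d], "b")
  }
  ids
}

#' Generate per-platform mass-feature matrices with known ground truth
#'
#' Abundances are log-normal around a per-feature base level with a shared
#' multiplicative batch factor and per-sample loading factor; planted
#' features multiply the case-group expectation by their fold change, so the
#' expected case/control arithmetic-mean ratio equals the planted fold.
#' Internal standards carry the batch and loading factors but no group
#' effect and a low residual cv. Noise features receive a fractional mass
#' above the biological mass-defect envelope `0.3 + 0.001 * mz`; contaminant
#' features sit at the configured m/z values; low-abundance features are
#' generated below the default abundance filter threshold.
#'
#' @param cohort sample metadata from [sampleCohort()] (needs sample_id,
#'   diagnosis, batch).
#' @param platforms list of [platformSpec()]s.
#' @param effects an [effectSpec()] (or NULL for no planted effects).
#' @param config a [generatorConfig()].
#' @return Named list of [MetaboSet-class] objects, one per platform, with
#'   `attr(, "ground_truth")`: a data.frame of planted feature ids and folds.
#'   Each object's `metadata()$feature_class` labels every feature as
#'   biological / planted / internal_standard / noise / low_abundance /
#'   contaminant.
#' @examples
#' cohort <- sampleCohort(cohortSpec(n_case = 6, n_control = 6), seed = 1)
#' sets <- generateFeatureMatrix(
#'   cohort,
#'   platforms = list(platformSpec("HILICpos", 50, c(60, 1000), c(30, 1740))),
#'   effects = effectSpec("HILICpos", 2.0),
#'   config = generatorConfig(seed = 1))
#' sets$HILICpos
#' @export
generateFeatureMatrix <- function(cohort, platforms, effects = NULL,
                                  config = generatorConfig()) {
  stopifnot(is.data.frame(cohort),
            all(c("sample_id", "diagnosis", "batch") %in% colnames(cohort)))
  if (!is.null(effects)) {
    bad <- setdiff(unique(effects$platform),
                   vapply(platforms, `[[`, "", "name"))
    if (length(bad))
      stop("effects reference unknown platform(s): ",
           paste(bad, collapse = ", "))
  }
  set.seed(config$seed)
  n_samp <- nrow(cohort)
  is_case <- cohort$diagnosis == "case"
  sample_log_scale <- rnorm(n_samp, 0, config$sample_scale_sd)
  out <- list()
  truth <- list()
  for (ps in platforms) {
    n <- ps$n_features
    eff <- if (is.null(effects)) NULL else
      effects[effects$platform == ps$name, , drop = FALSE]
    n_eff <- if (is.null(eff)) 0L else nrow(eff)
    n_is <- ps$n_internal_standards
    cont_mz <- config$contaminant_mz_list[
      config$contaminant_mz_list >= ps$mz_range[1] &
      config$contaminant_mz_list <= ps$mz_range[2]]
    if (ps$name == "GCMS") cont_mz <- numeric(0)
    n_cont <- length(cont_mz)
    n_noise <- round(fracFor(config$frac_noise_features, ps$name) * n)
    n_low <- round(fracFor(config$frac_low_abundance, ps$name) * n)
    if (n_is + n_eff + n_cont + n_noise + n_low > n)
      stop("platform ", ps$name, ": feature classes exceed n_features")
    cls <- rep("biological", n)
    i <- 0L
    assign_cls <- function(cls, k, lab, i) {
      if (k > 0) cls[i + seq_len(k)] <- lab
      cls
    }
    cls <- assign_cls(cls, n_is, "internal_standard", i); i <- i + n_is
    cls <- assign_cls(cls, n_eff, "planted", i); i <- i + n_eff
    cls <- assign_cls(cls, n_noise, "noise", i); i <- i + n_noise
    cls <- assign_cls(cls, n_low, "low_abundance", i); i <- i + n_low
    cls <- assign_cls(cls, n_cont, "contaminant", i)

    # m/z: integer part uniform; fractional mass inside the biological
    # envelope except for noise features, which are pushed above it
    nominal <- floor(runif(n, ps$mz_range[1], ps$mz_range[2] - 1))
    is_noise <- cls == "noise"
    nominal[is_noise] <- floor(runif(n_noise, ps$mz_range[1],
                                     min(ps$mz_range[2] - 1, 600)))
    frac <- runif(n, 0, pmin(0.25 + 0.001 * nominal, 0.9))
    frac[is_noise] <- runif(n_noise) *
      (0.98 - (0.32 + 0.001 * nominal[is_noise])) +
      (0.32 + 0.001 * nominal[is_noise])
    mz <- nominal + frac
    mz[cls == "contaminant"] <- cont_mz
    rt <- runif(n, ps$rt_range[1], ps$rt_range[2])

    # abundant biological class kept well clear of the low-abundance class
    base <- pmax(rlnorm(n, log(1e5), 1), 5000)
    cv <- runif(n, 0.2, 0.6)
    fold <- rep(1, n)
    if (n_eff > 0) {
      idx <- which(cls == "planted")
      base[idx] <- eff$base_abundance
      cv[idx] <- eff$cv
      fold[idx] <- eff$fold_change
    }
    base[cls == "low_abundance"] <- rlnorm(n_low, log(100), 0.3)
    base[cls == "internal_standard"] <- 1e6
    cv[cls == "internal_standard"] <- config$is_cv
    sdlog <- cvToSdlog(cv)
    # expectation of exp(noise) is exp(sdlog^2/2); subtract so the
    # arithmetic mean equals base (and base*fold in cases)
    mu <- log(base) - sdlog^2 / 2

    batch_log <- rnorm(config$n_batches, 0, config$batch_sd)
    samp_log <- batch_log[cohort$batch] + sample_log_scale

    noise_mat <- matrix(rnorm(n * n_samp), n, n_samp) * sdlog
    logA <- mu + outer(log(fold), as.numeric(is_case)) + noise_mat
    logA <- sweep(logA, 2, samp_log, `+`)
    area <- exp(logA)
    if (config$missing_rate > 0) {
      zero <- matrix(rbinom(n * n_samp, 1, config$missing_rate) == 1,
                     n, n_samp)
      zero[cls == "internal_standard", ] <- FALSE
      area[zero] <- 0
    }

    ids <- makeFeatureIds(mz, rt)
    if (ps$name == "GCMS") ids <- paste0("GCMS_", ids)
    fd <- data.frame(feature_id = ids, mz = mz, rt_seconds = rt,
                     platform = ps$name,
                     is_internal_standard = cls == "internal_standard",
                     stringsAsFactors = FALSE)
    ms <- MetaboSet(area, fd, cohort)
    metadata(ms)$feature_class <- setNames(cls, ids)
    out[[ps$name]] <- ms
    if (n_eff > 0)
      truth[[ps$name]] <- data.frame(platform = ps$name,
                                     feature_id = ids[cls == "planted"],
                                     fold_change = eff$fold_change,
                                     stringsAsFactors = FALSE)
  }
  gt <- if (length(truth)) do.call(rbind, c(truth, make.row.names = FALSE))
        else data.frame(platform = character(0), feature_id = character(0),
                        fold_change = numeric(0))
  attr(out, "ground_truth") <- gt
  out
}

#' Simulate a screened modeling matrix directly
#'
#' Convenience wrapper producing a single merged [MetaboSet-class] shaped
#' like a post-screening modeling set: `n_features` features on one platform,
#' the first `n_informative` planted with the given fold changes, no
#' artifact features and no missing cells.
#'
#' @param n_case,n_control group sizes.
#' @param n_features total feature count.
#' @param n_informative number of planted discriminative features.
#' @param folds fold changes recycled over the informative features.
#' @param cv within-group coefficient of variation of planted features.
#' @param seed integer seed.
#' @return A [MetaboSet-class]; `metadata()$informative` holds the planted
#'   feature ids.
#' @export
simulateModelingSet <- function(n_case = 39L, n_control = 22L,
                                n_features = 179L, n_informative = 30L,
                                folds = c(0.67, 1.5, 1.8, 2.0, 2.55, 0.65),
                                cv = 0.3, seed = 1L) {
  cohort <- sampleCohort(cohortSpec(n_case = n_case, n_control = n_control),
                         seed = seed)
  eff <- if (n_informative > 0)
    effectSpec("LC", rep_len(folds, n_informative), cv = cv) else NULL
  sets <- generateFeatureMatrix(
    cohort,
    platforms = list(platformSpec("LC", n_features, c(60, 1000), c(30, 1740),
                                  n_internal_standards = 0L)),
    effects = eff,
    config = generatorConfig(seed = seed, missing_rate = 0,
                             frac_noise_features = 0,
                             frac_low_abundance = 0))
  ms <- sets$LC
  metadata(ms)$informative <- attr(sets, "ground_truth")$feature_id
  ms
}

#' Write per-platform feature tables, sample metadata and ground truth
#'
#' Tables are UTF-8, tab-delimited: one file per platform with columns
#' feature_id, mz, rt_seconds, platform, is_internal_standard and one column
#' per sample; plus `samples.tsv` and `ground_truth.tsv`.
#'
#' @param sets result of [generateFeatureMatrix()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeFeatureTables <- function(sets, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(sets)) {
    p <- file.path(dir, paste0("features_", nm, ".tsv"))
    writeFeatureTable(sets[[nm]], p)
    paths <- c(paths, p)
  }
  sp <- file.path(dir, "samples.tsv")
  write.table(sampleData(sets[[1]]), sp, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  gp <- file.path(dir, "ground_truth.tsv")
  write.table(attr(sets, "ground_truth"), gp, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(c(paths, sp, gp))
}

#' @rdname writeFeatureTables
#' @param ms a [MetaboSet-class]
#' @param path output file
#' @export
writeFeatureTable <- function(ms, path) {
  tab <- cbind(featureData(ms)[REQUIRED_FEATURE_COLS], as.data.frame(areas(ms)))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a feature table written by [writeFeatureTable()]
#'
#' @param path feature table path.
#' @param sampleData optional sample metadata data.frame (keyed by sample_id).
#' @return A [MetaboSet-class].
#' @export
readFeatureTable <- function(path, sampleData = NULL) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta_cols <- REQUIRED_FEATURE_COLS
  if (!all(meta_cols %in% colnames(tab)))
    stop("feature table lacks required columns: ",
         paste(setdiff(meta_cols, colnames(tab)), collapse = ", "))
  sample_cols <- setdiff(colnames(tab), meta_cols)
  area <- as.matrix(tab[, sample_cols, drop = FALSE])
  if (!is.null(sampleData)) {
    sampleData <- sampleData[match(sample_cols, sampleData$sample_id), ,
                             drop = FALSE]
    if (anyNA(sampleData$sample_id))
      stop("sample metadata does not cover all table columns")
  }
  MetaboSet(area, tab[meta_cols], sampleData)
}
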