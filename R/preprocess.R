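#' Feature-filter configuration
#'
#' Four per-feature quality rules applied by [filterFeatures()]:
#' \describe{
#'   \item{low abundance}{median integrated area across samples below
#'     `min_median_abundance`.}
#'   \item{mass defect}{fractional mass above the biological envelope
#'     `mass_defect_intercept + mass_defect_slope * mz`. Biological ions have
#'     fractional masses that grow roughly linearly with mass; ions far above
#'     the envelope are instrument noise.}
#'   \item{contaminant}{m/z within `contaminant_tolerance_ppm` of a listed
#'     contaminant mass.}
#'   \item{presence}{nonzero in fewer than `min_presence_fraction` of
#'     samples.}
#' }
#' GC-MS features bypass the mass-defect and contaminant rules (those are
#' electrospray artifacts); internal standards are never removed. Setting a
#' threshold to zero (or an empty contaminant list) disables its rule.
#'
#' @param min_median_abundance area units; 0 disables.
#' @param mass_defect_slope,mass_defect_intercept linear envelope parameters;
#'   `Inf` intercept disables.
#' @param contaminant_mz_list numeric m/z values.
#' @param contaminant_tolerance_ppm ppm window for contaminant matching.
#' @param min_presence_fraction fraction in [0,1]; 0 disables.
#' @param mass_defect_exempt_platforms platforms skipping mass-defect and
#'   contaminant rules.
#' @return list of class `filter_config`.
#' @export
filterConfig <- function(min_median_abundance = 0,
                         mass_defect_slope = 0.001,
                         mass_defect_intercept = Inf,
                         contaminant_mz_list = numeric(0),
                         contaminant_tolerance_ppm = 20,
                         min_presence_fraction = 0,
                         mass_defect_exempt_platforms = "GCMS") {
  if (min_median_abundance < 0 || contaminant_tolerance_ppm < 0 ||
      min_presence_fraction < 0 || min_presence_fraction > 1)
    stop("filter thresholds must be non-negative (presence fraction in [0,1])")
  structure(list(min_median_abundance = min_median_abundance,
                 mass_defect_slope = mass_defect_slope,
                 mass_defect_intercept = mass_defect_intercept,
                 contaminant_mz_list = contaminant_mz_list,
                 contaminant_tolerance_ppm = contaminant_tolerance_ppm,
                 min_presence_fraction = min_presence_fraction,
                 mass_defect_exempt_platforms = mass_defect_exempt_platforms),
            class = "filter_config")
}

#' Default filter configuration
#'
#' Matched to the synthetic generator's artifact classes: abundance threshold
#' 1000 (removes the designed low-abundance class), mass-defect envelope
#' `0.3 + 0.001 * mz`, 20 ppm contaminant window, presence >= 50%.
#'
#' @param contaminant_mz_list contaminant m/z values (defaults to the
#'   generator's, i.e. none).
#' @return A [filterConfig()].
#' @export
defaultFilterConfig <- function(contaminant_mz_list = numeric(0)) {
  filterConfig(min_median_abundance = 1000,
               mass_defect_slope = 0.001, mass_defect_intercept = 0.3,
               contaminant_mz_list = contaminant_mz_list,
               contaminant_tolerance_ppm = 20,
               min_presence_fraction = 0.5)
}

#' Apply feature-level quality filters
#'
#' A feature is removed iff it fails any enabled rule (rule order never
#' changes the removal set); internal standards are always kept. The report
#' attributes each removal to its first failing rule in the fixed order
#' low_abundance, mass_defect, contaminant, presence.
#'
#' @param ms a [MetaboSet-class].
#' @param config a [filterConfig()].
#' @return list with elements `matrix` (filtered [MetaboSet-class]) and
#'   `report` (data.frame per platform: features in, removed per rule,
#'   surviving; removed + surviving = input count).
#' @export
filterFeatures <- function(ms, config = defaultFilterConfig()) {
  stopifnot(is(ms, "MetaboSet"), inherits(config, "filter_config"))
  if (nrow(ms) == 0) stop("empty feature matrix")
  a <- areas(ms)
  fd <- featureData(ms)
  exempt <- fd$platform %in% config$mass_defect_exempt_platforms

  fail_low <- apply(a, 1, median) < config$min_median_abundance
  frac <- fd$mz - floor(fd$mz)
  fail_md <- frac > config$mass_defect_intercept +
    config$mass_defect_slope * fd$mz
  fail_md[exempt] <- FALSE
  fail_cont <- rep(FALSE, nrow(ms))
  if (length(config$contaminant_mz_list)) {
    tol <- config$contaminant_tolerance_ppm
    for (cmz in config$contaminant_mz_list)
      fail_cont <- fail_cont | abs(fd$mz - cmz) / cmz * 1e6 <= tol
    fail_cont[exempt] <- FALSE
  }
  fail_pres <- rowMeans(a > 0) < config$min_presence_fraction

  is_flag <- isInternalStandard(ms)
  rules <- cbind(low_abundance = fail_low, mass_defect = fail_md,
                 contaminant = fail_cont, presence = fail_pres)
  rules[is_flag, ] <- FALSE
  removed <- rowSums(rules) > 0
  first_rule <- rep(NA_character_, nrow(ms))
  first_rule[removed] <- colnames(rules)[
    apply(rules[removed, , drop = FALSE], 1, which.max)]

  plats <- unique(fd$platform)
  report <- do.call(rbind, lapply(plats, function(p) {
    sel <- fd$platform == p
    data.frame(platform = p, features_in = sum(sel),
               removed_low_abundance = sum(sel & removed &
                                           first_rule == "low_abundance",
                                           na.rm = TRUE),
               removed_mass_defect = sum(sel & removed &
                                         first_rule == "mass_defect",
                                         na.rm = TRUE),
               removed_contaminant = sum(sel & removed &
                                         first_rule == "contaminant",
                                         na.rm = TRUE),
               removed_presence = sum(sel & removed &
                                      first_rule == "presence", na.rm = TRUE),
               surviving = sum(sel & !removed),
               stringsAsFactors = FALSE)
  }))
  out <- ms[!removed, ]
  fc <- metadata(ms)$feature_class
  if (!is.null(fc)) metadata(out)$feature_class <- fc[rownames(out)]
  list(matrix = out, report = report,
       removed = setNames(first_rule[removed], rownames(ms)[removed]))
}

#' Normalize samples to the experiment-wide internal-standard median
#'
#' Each sample's areas are multiplied by (experiment-wide median of the
#' per-sample internal-standard medians) / (that sample's internal-standard
#' median), so after normalization every sample's IS median equals the same
#' experiment-wide constant. The operation is idempotent.
#'
#' @param ms a [MetaboSet-class] with at least one internal-standard feature.
#' @return The normalized [MetaboSet-class].
#' @export
normalizeInternalStandards <- function(ms) {
  stopifnot(is(ms, "MetaboSet"))
  is_flag <- isInternalStandard(ms)
  if (!any(is_flag)) stop("no internal-standard features present")
  is_area <- areas(ms)[is_flag, , drop = FALSE]
  samp_med <- apply(is_area, 2, median)
  zero <- samp_med <= 0
  if (any(zero))
    stop("sample(s) with zero internal-standard median: ",
         paste(colnames(ms)[zero], collapse = ", "))
  global <- median(samp_med)
  out <- ms
  assay(out, "area") <- sweep(areas(ms), 2, global / samp_med, `*`)
  out
}

#' Merge per-platform feature matrices into one analysis matrix
#'
#' Features are concatenated with feature ids made globally unique by a
#' platform prefix; samples are canonicalized to a common order (sorted id).
#'
#' @param sets list of [MetaboSet-class] objects sharing one sample set.
#' @return A merged [MetaboSet-class].
#' @export
mergePlatforms <- function(sets) {
  stopifnot(length(sets) >= 1)
  ids <- sort(colnames(sets[[1]]))
  for (ms in sets[-1]) {
    other <- sort(colnames(ms))
    if (!identical(ids, other))
      stop("sample sets differ between platforms: ",
           paste(union(setdiff(ids, other), setdiff(other, ids)),
                 collapse = ", "))
  }
  parts_a <- list(); parts_f <- list(); classes <- character(0)
  for (ms in sets) {
    fd <- featureData(ms)
    pref <- paste0(fd$platform, "_", fd$feature_id)
    # GC-MS ids already carry their platform prefix
    pref <- ifelse(startsWith(fd$feature_id, paste0(fd$platform, "_")),
                   fd$feature_id, pref)
    fd$feature_id <- pref
    a <- areas(ms)[, ids, drop = FALSE]
    rownames(a) <- pref
    parts_a[[length(parts_a) + 1]] <- a
    parts_f[[length(parts_f) + 1]] <- fd
    fc <- metadata(ms)$feature_class
    if (!is.null(fc)) classes <- c(classes, setNames(unname(fc), pref))
  }
  merged <- MetaboSet(do.call(rbind, parts_a), do.call(rbind, parts_f),
                      sampleData(sets[[1]])[ids, , drop = FALSE])
  if (length(classes)) metadata(merged)$feature_class <- classes
  merged
}
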