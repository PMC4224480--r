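ELEMENT_MASSES <- c(
  C = 12.0, H = 1.00782503207, N = 14.0030740048, O = 15.9949146196,
  S = 31.97207100, P = 30.97376163, Na = 22.9897692809, Cl = 34.96885268,
  K = 38.96370668, F = 18.99840322)

PROTON_MASS <- 1.007276467
ELECTRON_MASS <- 0.00054857991

#' Parse a molecular formula in Hill notation
#'
#' @param formula string of element symbols with optional integer counts,
#'   e.g. `"C7H15N3O3"`.
#' @return named integer vector of element counts.
#' @export
parseFormula <- function(formula) {
  if (is.na(formula) || formula == "") return(setNames(integer(0), character(0)))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  tokens <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(nchar(tokens)) != nchar(formula))
    stop("cannot parse formula: ", formula)
  els <- sub("[0-9]+$", "", tokens)
  cnt <- as.integer(ifelse(grepl("[0-9]+$", tokens),
                           sub("^[A-Za-z]+", "", tokens), "1"))
  counts <- tapply(cnt, els, sum)[unique(els)]
  setNames(as.integer(counts), names(counts))
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum of element counts times monoisotopic element masses; supported
#' elements are C, H, N, O, S, P, Na, Cl, K, F. Accuracy is better than
#' 1e-4 Da.
#'
#' @param formula Hill-notation formula string (or a parsed count vector).
#' @return mass in Da; 0 for an empty formula.
#' @examples
#' monoisotopicMass("H2O")        # 18.0106
#' monoisotopicMass("C7H15N3O3")  # homocitrulline, 189.1113
#' @export
monoisotopicMass <- function(formula) {
  counts <- if (is.character(formula)) parseFormula(formula) else formula
  if (!length(counts)) return(0)
  unknown <- setdiff(names(counts), names(ELEMENT_MASSES))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  sum(counts * ELEMENT_MASSES[names(counts)])
}

#' Default electrospray adduct table
#'
#' Singly charged adducts common in positive ([M+H]+, [M+Na]+, [M+NH4]+) and
#' negative ([M-H]-, [M+Cl]-, [M+HCOO]-) mode; mass shifts include the
#' electron so the theoretical m/z is `(M + mass_shift) / |charge|`.
#'
#' @return data.frame with columns name, mass_shift, charge, polarity.
#' @export
defaultAdducts <- function() {
  data.frame(
    name = c("[M+H]+", "[M+Na]+", "[M+NH4]+",
             "[M-H]-", "[M+Cl]-", "[M+HCOO]-"),
    mass_shift = c(PROTON_MASS,
                   ELEMENT_MASSES[["Na"]] - ELECTRON_MASS,
                   monoisotopicMass("NH4") - ELECTRON_MASS,
                   -PROTON_MASS,
                   ELEMENT_MASSES[["Cl"]] + ELECTRON_MASS,
                   monoisotopicMass("CHO2") + ELECTRON_MASS),
    charge = c(1L, 1L, 1L, -1L, -1L, -1L),
    polarity = c("+", "+", "+", "-", "-", "-"),
    stringsAsFactors = FALSE)
}

#' Read a metabolite formula database
#'
#' Tab-delimited text with columns `name`, `formula`, `database_id`
#' (e.g. an HMDB accession). Monoisotopic masses are computed on read.
#'
#' @param path file path.
#' @return data.frame with an added `monoisotopic_mass` column.
#' @export
readMetaboliteDB <- function(path) {
  db <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "formula", "database_id")
  if (!all(need %in% colnames(db)))
    stop("metabolite database needs columns: ", paste(need, collapse = ", "))
  db$monoisotopic_mass <- vapply(db$formula, monoisotopicMass, 0)
  db
}

platformPolarity <- function(platform) {
  ifelse(grepl("pos$|\\+$", platform), "+",
         ifelse(grepl("neg$|-$", platform), "-", NA_character_))
}

#' Annotate mass features by exact-mass adduct matching
#'
#' Emits a candidate hit for every (feature, metabolite, adduct) combination
#' whose adduct polarity matches the feature's platform polarity and whose
#' relative mass error `1e6 * (mz_obs - mz_theo) / mz_theo` is within
#' `tolerance_ppm`, where `mz_theo = (monoisotopic_mass + mass_shift) /
#' |charge|`. Features on platforms without an electrospray polarity (GC-MS)
#' are skipped. Annotations are putative: confidence flags, not filters, mark
#' hits whose feature is present in at least half the samples
#' (`presence_ok`) and, for metabolite/adduct pairs matched by several
#' features, whether the features' retention times agree within
#' `rt_window_seconds` (`rt_consistent`).
#'
#' @param features data.frame with columns feature_id, mz, platform
#'   (optionally presence_fraction and rt_seconds), e.g. `featureData()` of a
#'   [MetaboSet-class].
#' @param db metabolite table from [readMetaboliteDB()] (or with a
#'   `monoisotopic_mass` column).
#' @param adducts adduct table as from [defaultAdducts()].
#' @param tolerance_ppm maximum absolute relative mass error (default 20).
#' @param rt_window_seconds retention-time agreement window (default 35).
#' @return data.frame of hits sorted by |ppm_error|: feature_id, name,
#'   database_id, adduct, theoretical_mz, ppm_error, presence_ok,
#'   rt_consistent.
#' @export
annotateFeatures <- function(features, db, adducts = defaultAdducts(),
                             tolerance_ppm = 20, rt_window_seconds = 35) {
  if (tolerance_ppm < 0) stop("tolerance_ppm must be non-negative")
  if (is(features, "MetaboSet")) features <- featureData(features)
  if (is.null(db$monoisotopic_mass))
    db$monoisotopic_mass <- vapply(db$formula, monoisotopicMass, 0)
  pol <- platformPolarity(features$platform)
  hits <- list()
  for (ai in seq_len(nrow(adducts))) {
    ad <- adducts[ai, ]
    theo <- (db$monoisotopic_mass + ad$mass_shift) / abs(ad$charge)
    f_idx <- which(pol == ad$polarity)
    if (!length(f_idx)) next
    for (mi in seq_along(theo)) {
      ppm <- (features$mz[f_idx] - theo[mi]) / theo[mi] * 1e6
      sel <- which(abs(ppm) <= tolerance_ppm)
      if (!length(sel)) next
      hits[[length(hits) + 1]] <- data.frame(
        feature_id = features$feature_id[f_idx[sel]],
        name = db$name[mi], database_id = db$database_id[mi],
        adduct = ad$name, theoretical_mz = theo[mi],
        ppm_error = ppm[sel],
        presence_ok = if (!is.null(features$presence_fraction))
          features$presence_fraction[f_idx[sel]] >= 0.5 else NA,
        rt = if (!is.null(features$rt_seconds))
          features$rt_seconds[f_idx[sel]] else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(feature_id = character(0), name = character(0),
                      database_id = character(0), adduct = character(0),
                      theoretical_mz = numeric(0), ppm_error = numeric(0),
                      presence_ok = logical(0), rt_consistent = logical(0)))
  out <- do.call(rbind, hits)
  key <- paste(out$name, out$adduct)
  spread <- tapply(out$rt, key, function(r) diff(range(r)))
  out$rt_consistent <- is.na(out$rt) | spread[key] <= rt_window_seconds
  out$rt <- NULL
  out[order(abs(out$ppm_error)), , drop = FALSE]
}
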