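#' @import methods
#' @importFrom stats median quantile rnorm runif rbinom sd var setNames
#'   p.adjust pt qt rlnorm predict
#' @importFrom utils head read.delim write.table packageVersion
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- rowData
#'   rowData<- colData colData<-
NULL

REQUIRED_FEATURE_COLS <- c("feature_id", "mz", "rt_seconds", "platform",
                           "is_internal_standard")

#' MetaboSet: a mass-feature abundance matrix with metadata
#'
#' `MetaboSet` extends [SummarizedExperiment::SummarizedExperiment] and is the
#' central container of the package: a features-by-samples matrix of
#' integrated peak areas (assay `"area"`), feature metadata in `rowData()`
#' (`feature_id`, `mz`, `rt_seconds`, `platform`, `is_internal_standard`) and
#' sample metadata in `colData()` (typically `sample_id`, `diagnosis`, `sex`,
#' `age`, `iq`, `batch`).
#'
#' A mass feature is an ion defined by its mass-to-charge ratio (m/z) and
#' chromatographic retention time; its value per sample is an integrated
#' extracted-ion-chromatogram area (arbitrary units, non-negative).
#'
#' @slot ... inherited from `SummarizedExperiment`.
#' @seealso [MetaboSet()] for construction, [filterFeatures()],
#'   [normalizeInternalStandards()], [mergePlatforms()], [screenFeatures()]
#' @export
setClass("MetaboSet", contains = "SummarizedExperiment")

setValidity("MetaboSet", function(object) {
  msgs <- character()
  if (!"area" %in% SummarizedExperiment::assayNames(object))
    msgs <- c(msgs, "assay 'area' is required")
  rd <- rowData(object)
  missing_cols <- setdiff(REQUIRED_FEATURE_COLS, colnames(rd))
  if (length(missing_cols))
    msgs <- c(msgs, paste0("rowData lacks column(s): ",
                           paste(missing_cols, collapse = ", ")))
  if (!length(msgs)) {
    a <- assay(object, "area")
    if (anyNA(a) || any(a < 0))
      msgs <- c(msgs, "areas must be non-negative and non-missing")
    by_platform <- split(as.character(rd$feature_id), as.character(rd$platform))
    dup <- vapply(by_platform, anyDuplicated, 0L)
    if (any(dup > 0))
      msgs <- c(msgs, paste0("duplicated feature_id within platform(s): ",
                             paste(names(by_platform)[dup > 0], collapse = ", ")))
    if (!is.logical(rd$is_internal_standard))
      msgs <- c(msgs, "is_internal_standard must be logical")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a MetaboSet
#'
#' @param area numeric matrix, features in rows, samples in columns. Row names
#'   are taken from `featureData$feature_id`; column names from
#'   `sampleData$sample_id` when present.
#' @param featureData data.frame with one row per feature; must contain
#'   `feature_id`, `mz`, `rt_seconds`, `platform`, `is_internal_standard`.
#' @param sampleData data.frame with one row per sample (column `sample_id`
#'   recommended; `diagnosis` required by the screening and modeling stages).
#' @return A [MetaboSet-class] object.
#' @examples
#' fm <- MetaboSet(
#'   area = matrix(100, 2, 3, dimnames = list(NULL, paste0("S", 1:3))),
#'   featureData = data.frame(
#'     feature_id = c("M100T10", "M200T20"), mz = c(100.05, 200.1),
#'     rt_seconds = c(10, 20), platform = "HILICpos",
#'     is_internal_standard = c(FALSE, TRUE)),
#'   sampleData = data.frame(sample_id = paste0("S", 1:3)))
#' fm
#' @export
MetaboSet <- function(area, featureData, sampleData = NULL) {
  area <- as.matrix(area)
  featureData <- as.data.frame(featureData)
  if (nrow(featureData) != nrow(area))
    stop("featureData must have one row per area row")
  rownames(area) <- as.character(featureData$feature_id)
  rownames(featureData) <- as.character(featureData$feature_id)
  if (is.null(sampleData)) {
    if (is.null(colnames(area)))
      colnames(area) <- paste0("S", seq_len(ncol(area)))
    sampleData <- data.frame(sample_id = colnames(area))
  }
  sampleData <- as.data.frame(sampleData)
  if (!is.null(sampleData$sample_id)) {
    colnames(area) <- as.character(sampleData$sample_id)
    rownames(sampleData) <- as.character(sampleData$sample_id)
  }
  se <- SummarizedExperiment(
    assays = list(area = area),
    rowData = DataFrame(featureData),
    colData = DataFrame(sampleData))
  methods::new("MetaboSet", se)
}

#' @describeIn MetaboSet-class integrated-area matrix (features x samples)
#' @param x,object a `MetaboSet`
#' @export
areas <- function(x) assay(x, "area")

#' @describeIn MetaboSet-class feature metadata as a plain data.frame
#' @export
featureData <- function(x) as.data.frame(rowData(x))

#' @describeIn MetaboSet-class sample metadata as a plain data.frame
#' @export
sampleData <- function(x) as.data.frame(colData(x))

#' @describeIn MetaboSet-class platform of each feature
#' @export
featurePlatform <- function(x) as.character(rowData(x)$platform)

#' @describeIn MetaboSet-class logical flag per feature
#' @export
isInternalStandard <- function(x) as.logical(rowData(x)$is_internal_standard)

#' @describeIn MetaboSet-class diagnosis factor (levels control, case) or NULL
#' @export
diagnosis <- function(x) {
  d <- colData(x)$diagnosis
  if (is.null(d)) return(NULL)
  factor(as.character(d), levels = c("control", "case"))
}

setMethod("show", "MetaboSet", function(object) {
  rd <- rowData(object)
  cat("MetaboSet:", nrow(object), "features x", ncol(object), "samples\n")
  plat <- table(as.character(rd$platform))
  cat("platforms:", paste(names(plat), plat, sep = "=", collapse = ", "), "\n")
  cat("internal standards:", sum(rd$is_internal_standard), "\n")
  d <- diagnosis(object)
  if (!is.null(d))
    cat("diagnosis:", paste(levels(d), table(d), sep = "=", collapse = ", "),
        "\n")
  invisible(NULL)
})
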