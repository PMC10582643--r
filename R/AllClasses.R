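# S4 containers for the inference chain. VariantTable and VafMatrix extend
# SummarizedExperiment: rows are variant alleles (one row per alternate
# allele after multiallelic decomposition), columns are samples.

#' VariantTable: per-sample allelic depths for an amplicon panel
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with three integer
#' assays: `refDepth` (reads supporting the reference allele), `altDepth`
#' (reads supporting the row's alternate allele) and `siteDepth` (total reads
#' at the site: reference plus every alternate allele). Multiallelic sites
#' are decomposed into one row per alternate allele; rows from the same site
#' share `refDepth`, `siteDepth` and the `site` identifier. Row metadata
#' carries `amplicon`, `chrom`, `pos` (1-based), `ref`, `alt`, `group`
#' (locus group) and `site`.
#'
#' @export
setClass("VariantTable", contains = "SummarizedExperiment")

.validVariantTable <- function(object) {
  msg <- character()
  need <- c("refDepth", "altDepth", "siteDepth")
  if (!all(need %in% assayNames(object)))
    msg <- c(msg, sprintf("assays must include %s", paste(need, collapse = ", ")))
  rd <- rowData(object)
  needCols <- c("amplicon", "chrom", "pos", "ref", "alt", "group", "site")
  if (!all(needCols %in% colnames(rd)))
    msg <- c(msg, sprintf("rowData must have columns %s", paste(needCols, collapse = ", ")))
  if (length(msg) == 0L) {
    if (nrow(object) > 0L && any(rd$pos < 1L))
      msg <- c(msg, "positions must be >= 1 (1-based VCF coordinates)")
    for (a in need) {
      v <- assay(object, a)
      if (any(v < 0L, na.rm = TRUE)) msg <- c(msg, sprintf("%s has negative depths", a))
    }
    if (is.null(colnames(object)) && ncol(object) > 0L)
      msg <- c(msg, "samples must be named")
    if (anyDuplicated(colnames(object)))
      msg <- c(msg, "duplicate sample ids")
  }
  if (length(msg)) msg else TRUE
}
setValidity("VariantTable", .validVariantTable)

#' Construct a VariantTable
#'
#' @param info data.frame or DataFrame with columns `amplicon`, `chrom`,
#'   `pos`, `ref`, `alt`, `group`, `site` (one row per alternate allele).
#' @param refDepth,altDepth,siteDepth integer matrices, variants x samples,
#'   with sample ids as column names. `NA` marks a sample absent from the
#'   source file for that record.
#' @return A [VariantTable-class] object.
#' @export
VariantTable <- function(info, refDepth, altDepth, siteDepth) {
  info <- S4Vectors::DataFrame(info)
  se <- SummarizedExperiment(
    assays = list(refDepth = refDepth, altDepth = altDepth, siteDepth = siteDepth),
    rowData = info)
  new("VariantTable", se)
}

#' VafMatrix: variant allele frequencies with a missing mask
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with a single `vaf`
#' assay (variant alleles x samples) holding values in `[0, 1]`, `NA` where a
#' value is missing (site depth below threshold, coverage-excluded sample, or
#' sample absent from the source file). Row metadata as in
#' [VariantTable-class].
#'
#' @export
setClass("VafMatrix", contains = "SummarizedExperiment")

.validVafMatrix <- function(object) {
  msg <- character()
  if (!"vaf" %in% assayNames(object)) msg <- c(msg, "assay 'vaf' required")
  rd <- rowData(object)
  needCols <- c("amplicon", "chrom", "pos", "alt", "group", "site")
  if (!all(needCols %in% colnames(rd)))
    msg <- c(msg, sprintf("rowData must have columns %s", paste(needCols, collapse = ", ")))
  if (length(msg) == 0L) {
    v <- assay(object, "vaf")
    if (any(v < 0 | v > 1, na.rm = TRUE)) msg <- c(msg, "VAF values must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
}
setValidity("VafMatrix", .validVafMatrix)

#' SampleDistanceMatrix: pairwise sample distances over a locus set
#'
#' Symmetric non-negative matrix of pairwise-complete Euclidean distances
#' between samples, zero diagonal, `NA` where a pair shares no observed
#' column. Carries the locus-set label it was computed from.
#'
#' @slot values numeric matrix, samples x samples, dimnames = sample ids.
#' @slot locusSet character(1) label.
#' @export
setClass("SampleDistanceMatrix",
         representation(values = "matrix", locusSet = "character"))

.validSdm <- function(object) {
  m <- object@values
  msg <- character()
  if (nrow(m) != ncol(m)) msg <- c(msg, "matrix must be square")
  else {
    if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
      msg <- c(msg, "dimnames must be identical sample ids")
    if (any(abs(m - t(m)) > 1e-8, na.rm = TRUE)) msg <- c(msg, "matrix must be symmetric")
    if (any(diag(m) != 0, na.rm = TRUE)) msg <- c(msg, "diagonal must be zero")
    if (any(m < 0, na.rm = TRUE)) msg <- c(msg, "distances must be non-negative")
  }
  if (length(msg)) msg else TRUE
}
setValidity("SampleDistanceMatrix", .validSdm)

#' @rdname SampleDistanceMatrix-class
#' @param values,locusSet see slots.
#' @export
SampleDistanceMatrix <- function(values, locusSet = NA_character_) {
  new("SampleDistanceMatrix", values = values, locusSet = locusSet)
}

#' LinkageTree: Ward's D2 agglomeration of a sample distance matrix
#'
#' Stores the merge history in [stats::hclust] convention: `merge[i, ]` are
#' the two nodes joined at step `i` (negative = leaf index, positive = prior
#' merge), `height[i]` the merge height on the distance (not squared) scale.
#'
#' @slot merge integer matrix (n-1 x 2).
#' @slot height numeric vector (n-1), non-decreasing under Ward's D2.
#' @slot order integer leaf ordering for plotting.
#' @slot labels character leaf labels (sample ids).
#' @slot locusSet character(1) label of the locus set clustered.
#' @export
setClass("LinkageTree",
         representation(merge = "matrix", height = "numeric", order = "integer",
                        labels = "character", locusSet = "character"))

.validLinkageTree <- function(object) {
  n <- length(object@labels)
  msg <- character()
  if (nrow(object@merge) != n - 1L) msg <- c(msg, "need n-1 merges for n leaves")
  if (length(object@height) != n - 1L) msg <- c(msg, "need n-1 heights")
  if (!setequal(object@order, seq_len(n))) msg <- c(msg, "order must permute the leaves")
  if (anyDuplicated(object@labels)) msg <- c(msg, "duplicate leaf labels")
  if (length(msg)) msg else TRUE
}
setValidity("LinkageTree", .validLinkageTree)

#' ParentageResult: maternal and paternal lineage calls for a hybrid
#'
#' Maternal call is the argmin of candidate mean chloroplast distances;
#' paternal call is the argmin of candidate mean SDR distances among
#' male-called samples. Margins are runner-up mean minus winner mean.
#'
#' @slot hybrid character(1) hybrid taxon id.
#' @slot maternal,paternal character(1) winning taxon (or "undecided").
#' @slot maternalEvidence,paternalEvidence named numeric: candidate mean distances.
#' @slot maternalMargin,paternalMargin numeric(1), >= 0.
#' @slot degenerate logical(1): TRUE when both lineages select the same taxon.
#' @export
setClass("ParentageResult",
         representation(hybrid = "character", maternal = "character",
                        paternal = "character",
                        maternalEvidence = "numeric", paternalEvidence = "numeric",
                        maternalMargin = "numeric", paternalMargin = "numeric",
                        degenerate = "logical"))

.validParentage <- function(object) {
  msg <- character()
  if (object@maternalMargin < 0 || object@paternalMargin < 0)
    msg <- c(msg, "margins must be non-negative")
  if (length(msg)) msg else TRUE
}
setValidity("ParentageResult", .validParentage)
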