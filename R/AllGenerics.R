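#' Locus-set label of a distance matrix or linkage tree
#' @param x a SampleDistanceMatrix, LinkageTree or VafMatrix.
#' @return character(1).
#' @export
setGeneric("locusSet", function(x) standardGeneric("locusSet"))

#' Extract the plain distance matrix
#' @param x a SampleDistanceMatrix.
#' @return numeric matrix with sample dimnames.
#' @export
setGeneric("distanceMatrix", function(x) standardGeneric("distanceMatrix"))

#' @rdname locusSet
#' @export
setMethod("locusSet", "SampleDistanceMatrix", function(x) x@locusSet)

#' @rdname locusSet
#' @export
setMethod("locusSet", "LinkageTree", function(x) x@locusSet)

#' @rdname distanceMatrix
#' @export
setMethod("distanceMatrix", "SampleDistanceMatrix", function(x) x@values)

#' Leaf labels of a linkage tree
#' @param object a LinkageTree.
#' @param ... ignored.
#' @export
labels.LinkageTree <- function(object, ...) object@labels

#' Convert a LinkageTree to stats::hclust
#' @param x a LinkageTree.
#' @param ... ignored.
#' @return an object of class `hclust`.
#' @export
as.hclust.LinkageTree <- function(x, ...) {
  structure(list(merge = x@merge, height = x@height, order = x@order,
                 labels = x@labels, method = "ward.D2",
                 call = match.call(), dist.method = "euclidean"),
            class = "hclust")
}

setMethod("show", "SampleDistanceMatrix", function(object) {
  cat(sprintf("SampleDistanceMatrix: %d samples, locus set '%s'\n",
              nrow(object@values), object@locusSet))
  nNA <- sum(is.na(object@values[upper.tri(object@values)]))
  if (nNA > 0) cat(sprintf("  %d undefined pair(s) (no shared observed columns)\n", nNA))
  v <- object@values[upper.tri(object@values)]
  if (length(v)) cat(sprintf("  pair distances: min %.4g, median %.4g, max %.4g\n",
                             min(v, na.rm = TRUE), stats::median(v, na.rm = TRUE),
                             max(v, na.rm = TRUE)))
})

setMethod("show", "LinkageTree", function(object) {
  cat(sprintf("LinkageTree (Ward.D2): %d leaves, locus set '%s'\n",
              length(object@labels), object@locusSet))
  cat(sprintf("  merge heights: %.4g .. %.4g\n",
              min(object@height), max(object@height)))
})

setMethod("show", "ParentageResult", function(object) {
  cat(sprintf("ParentageResult for hybrid '%s'\n", object@hybrid))
  cat(sprintf("  maternal: %s (margin %.4g)\n", object@maternal, object@maternalMargin))
  for (nm in names(object@maternalEvidence))
    cat(sprintf("    chloroplast mean distance to %s: %.4g\n", nm, object@maternalEvidence[[nm]]))
  cat(sprintf("  paternal: %s (margin %.4g)\n", object@paternal, object@paternalMargin))
  for (nm in names(object@paternalEvidence))
    cat(sprintf("    male SDR mean distance to %s: %.4g\n", nm, object@paternalEvidence[[nm]]))
  if (object@degenerate)
    cat("  NOTE: both lineages select the same taxon (degenerate, non-hybrid pattern)\n")
})
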