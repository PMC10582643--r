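# Ward's D2 agglomeration of VAF distance matrices, Newick export, cluster
# cuts and consensus taxon assignment across locus sets. Bootstrap support is
# deliberately not computed: most accessions are interspecific hybrids that
# jump between parental clusters under subsampling, so distance matrices are
# exported instead.

#' Impute undefined pairwise distances
#'
#' Replaces `NA` off-diagonal distances (pairs sharing no observed column) by
#' the maximum observed distance, with a warning. Ward's method needs a
#' complete matrix; imputation affects clustering only, never the reported
#' distances.
#'
#' @param d a [SampleDistanceMatrix-class].
#' @return a complete [SampleDistanceMatrix-class].
#' @export
completeDistances <- function(d) {
  m <- distanceMatrix(d)
  if (!anyNA(m)) return(d)
  mx <- max(m, na.rm = TRUE)
  nNA <- sum(is.na(m[upper.tri(m)]))
  warning(sprintf("imputing %d undefined pairwise distance(s) with the maximum observed (%.6g) for clustering", nNA, mx))
  m[is.na(m)] <- mx
  diag(m) <- 0
  SampleDistanceMatrix(m, locusSet = locusSet(d))
}

#' Ward's D2 agglomerative clustering of a distance matrix
#'
#' Agglomerates samples by the Ward.D2 criterion applied to the supplied
#' distances: squared distances follow the Lance-Williams update
#' `d(k, i+j)^2 = ((n_i + n_k) d(k,i)^2 + (n_j + n_k) d(k,j)^2 - n_k
#' d(i,j)^2) / (n_i + n_j + n_k)`; merge heights are reported on the distance
#' (not squared) scale and are non-decreasing. Undefined pairs are imputed
#' via [completeDistances()] first.
#'
#' @param d a [SampleDistanceMatrix-class] or symmetric numeric matrix.
#' @return a [LinkageTree-class].
#' @export
wardLinkage <- function(d) {
  label <- if (is(d, "SampleDistanceMatrix")) locusSet(d) else NA_character_
  if (!is(d, "SampleDistanceMatrix")) {
    if (!is.matrix(d) || nrow(d) != ncol(d) ||
        any(abs(d - t(d)) > 1e-8, na.rm = TRUE) || any(d < 0, na.rm = TRUE))
      .err("input must be a symmetric non-negative distance matrix",
           "amplitax_invalid_parameter")
    if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("S", seq_len(nrow(d)))
    d <- SampleDistanceMatrix(d, locusSet = label)
  }
  if (nrow(distanceMatrix(d)) < 2L)
    .err("need >= 2 samples to cluster", "amplitax_invalid_parameter")
  d <- completeDistances(d)
  hc <- hclust(stats::as.dist(distanceMatrix(d)), method = "ward.D2")
  new("LinkageTree", merge = hc$merge, height = hc$height,
      order = as.integer(hc$order), labels = hc$labels,
      locusSet = locusSet(d))
}

#' Export a linkage tree as a Newick string
#'
#' Ultrametric branch lengths: the two children of a merge at height `h` hang
#' at depth `h / 2`, so the path between any two leaves through their joining
#' node equals the merge height (a two-leaf tree is `(A:h/2,B:h/2);`). The
#' string round-trips through a standard Newick parser preserving topology
#' and heights.
#'
#' @param tree a [LinkageTree-class].
#' @return character(1) Newick string.
#' @export
toNewick <- function(tree) {
  phy <- ape::as.phylo(as.hclust(tree))
  ape::write.tree(phy, digits = 12)
}

#' Write a linkage tree to a Newick file
#' @param tree a [LinkageTree-class].
#' @param path output path.
#' @export
writeNewick <- function(tree, path) {
  con <- file(path, "wb"); on.exit(close(con))
  writeLines(toNewick(tree), con, sep = "\n")
  invisible(path)
}

#' Cut a linkage tree into k clusters
#'
#' Standard cut yielding exactly `k` clusters; labels are renumbered 1..k in
#' order of first-appearing sample, so the assignment is deterministic.
#'
#' @param tree a [LinkageTree-class].
#' @param k number of clusters, `1 <= k <= n`.
#' @return named integer vector (sample -> cluster), with attribute
#'   `locusSet`.
#' @export
cutClusters <- function(tree, k) {
  n <- length(tree@labels)
  if (k < 1 || k > n) .err(sprintf("k must lie in [1, %d]", n),
                           "amplitax_invalid_parameter")
  raw <- cutree(as.hclust(tree), k = k)
  relabel <- match(raw, unique(raw))
  out <- setNames(as.integer(relabel), names(raw))
  attr(out, "locusSet") <- tree@locusSet
  out
}

# smallest k (up to cap) at which every reference taxon is the majority taxon
# of some cluster; falls back to the cap when none qualifies. The cap is
# 2T + 2: on sex-linked locus sets each taxon can split into a male and a
# female clade, so up to 2T clusters may be needed.
.purityCut <- function(tree, referenceGroups) {
  taxa <- names(referenceGroups)
  cap <- min(length(tree@labels), 2L * length(taxa) + 2L)
  for (k in seq_len(cap)) {
    cl <- cutClusters(tree, k)
    maj <- .clusterMajorities(cl, referenceGroups)
    if (all(taxa %in% maj))
      return(list(k = k, cap = cap, clusters = cl, majorities = maj))
  }
  cl <- cutClusters(tree, cap)
  list(k = cap, cap = cap, clusters = cl,
       majorities = .clusterMajorities(cl, referenceGroups))
}

# candidate taxon for one query: majority of its cluster at the purity cut;
# if tied or reference-free there, escalate the cut towards the cap until the
# candidate resolves
.candidateFor <- function(tree, referenceGroups, query, cut) {
  cand <- cut$majorities[[cut$clusters[[query]]]]
  k <- cut$k
  while (is.na(cand) && k < cut$cap) {
    k <- k + 1L
    cl <- cutClusters(tree, k)
    maj <- .clusterMajorities(cl, referenceGroups)
    cand <- maj[[cl[[query]]]]
  }
  cand
}

# majority reference taxon per cluster (NA on tie or no reference members)
.clusterMajorities <- function(clusters, referenceGroups) {
  refTaxon <- rep(NA_character_, length(clusters))
  names(refTaxon) <- names(clusters)
  for (tx in names(referenceGroups)) {
    ids <- intersect(referenceGroups[[tx]], names(clusters))
    refTaxon[ids] <- tx
  }
  ks <- sort(unique(clusters))
  vapply(ks, function(k) {
    tab <- table(refTaxon[clusters == k], useNA = "no")
    if (!length(tab)) return(NA_character_)
    top <- which(tab == max(tab))
    if (length(top) > 1L) NA_character_ else names(tab)[top]
  }, character(1))
}

#' Consensus taxon assignment across locus sets
#'
#' For each query sample and each locus set, the candidate taxon is the
#' majority reference taxon of the query's cluster at a purity-based cut (the
#' smallest k at which every reference taxon is the majority of some cluster,
#' capped at `2 * n_taxa + 2`; the cap allows for sex-linked locus sets on
#' which every taxon splits into a male and a female clade). If the query's
#' cluster has a tied or empty majority at that k, the cut is escalated
#' towards the cap until the candidate resolves. The consensus label is
#' emitted only when all
#' locus sets in which the sample is present agree; otherwise the call is
#' "ambiguous" with per-set candidates listed. Sets from which the sample is
#' missing (coverage) are skipped and noted.
#'
#' @param samples character vector of query sample ids.
#' @param trees named list of [LinkageTree-class], one per locus set
#'   (typically `all16`, `sdr`, `traditional14`).
#' @param referenceGroups named list: taxon -> character vector of confidently
#'   labeled sample ids (>= 1 each).
#' @return data.frame: `sample_id`, one `candidate_<set>` column per set,
#'   `consensus`, `supporting_sets`, `skipped_sets`.
#' @export
consensusAssign <- function(samples, trees, referenceGroups) {
  if (!length(trees) || is.null(names(trees)))
    .err("trees must be a named list of LinkageTree objects", "amplitax_invalid_parameter")
  if (!length(referenceGroups) || any(!lengths(referenceGroups)))
    .err("each reference taxon needs >= 1 labeled sample", "amplitax_invalid_parameter")
  cuts <- lapply(trees, .purityCut, referenceGroups = referenceGroups)
  out <- data.frame(sample_id = samples, stringsAsFactors = FALSE)
  cand <- matrix(NA_character_, length(samples), length(trees),
                 dimnames = list(samples, names(trees)))
  skipped <- matrix(FALSE, length(samples), length(trees),
                    dimnames = list(samples, names(trees)))
  for (s in names(trees)) {
    cl <- cuts[[s]]$clusters
    for (q in samples) {
      if (!q %in% names(cl)) { skipped[q, s] <- TRUE; next }
      cand[q, s] <- .candidateFor(trees[[s]], referenceGroups, q, cuts[[s]])
    }
  }
  for (s in names(trees)) out[[paste0("candidate_", s)]] <- cand[, s]
  out$consensus <- vapply(samples, function(q) {
    cs <- cand[q, !skipped[q, ]]
    if (!length(cs) || anyNA(cs) || length(unique(cs)) != 1L) "ambiguous"
    else unique(cs)
  }, character(1))
  out$supporting_sets <- vapply(samples, function(q) {
    cs <- cand[q, !skipped[q, ], drop = FALSE]
    paste(colnames(cand)[!skipped[q, ]][!is.na(cs) & cs == out$consensus[out$sample_id == q]],
          collapse = ",")
  }, character(1))
  out$skipped_sets <- vapply(samples, function(q)
    paste(names(trees)[skipped[q, ]], collapse = ","), character(1))
  rownames(out) <- NULL
  out
}
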