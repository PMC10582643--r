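# VAF matrices per locus set and pairwise-complete Euclidean distances.
#
# VAF for an alternate allele = alt reads / (ref reads + all alt reads at the
# site). Distances over partially missing vectors use pairwise-complete
# columns rescaled by M/m (total columns / shared observed columns), which
# reduces exactly to plain Euclidean distance on complete data.

#' Build a VAF matrix from a variant table
#'
#' `VAF = altDepth / siteDepth` per variant allele and sample; the value is
#' missing (`NA`) when the site depth is below `minSiteDepth`, when the
#' sample is coverage-excluded for the row's locus group, or when the sample
#' was absent from the source file. Rows keep the canonical
#' (group, amplicon, position, alt allele) order.
#'
#' @param table a [VariantTable-class].
#' @param minSiteDepth minimum total reads at a site for a defined VAF.
#' @param exclusions optional logical matrix from [flagLowCoverage()]
#'   (samples x locus groups).
#' @return a [VafMatrix-class].
#' @export
buildVaf <- function(table, minSiteDepth = 20, exclusions = NULL) {
  rd <- rowData(table)
  altD <- assay(table, "altDepth")
  siteD <- assay(table, "siteDepth")
  vaf <- altD / siteD                      # 0/0 -> NaN, masked below
  vaf[is.na(siteD) | siteD == 0L | siteD < minSiteDepth] <- NA_real_
  if (!is.null(exclusions)) {
    samp <- colnames(table)
    miss <- setdiff(samp, rownames(exclusions))
    if (length(miss))
      .err(sprintf("exclusions lack samples: %s", paste(miss, collapse = ", ")),
           "amplitax_config_error")
    for (g in colnames(exclusions)) {
      rows <- rd$group == g
      if (!any(rows)) next
      excl <- rownames(exclusions)[exclusions[, g]]
      vaf[rows, colnames(vaf) %in% excl] <- NA_real_
    }
  }
  ord <- order(match(rd$group, .GROUPS), rd$amplicon, rd$pos, rd$alt)
  se <- SummarizedExperiment(assays = list(vaf = vaf[ord, , drop = FALSE]),
                             rowData = rd[ord, , drop = FALSE])
  new("VafMatrix", se)
}

#' Named locus sets
#'
#' The analysis' standard locus-set compositions: `traditional14` (multicopy
#' + single-copy nuclear + chloroplast), `nuclear11` (multicopy + single-copy
#' nuclear), `chloroplast3`, `sdr`, `arr17`, `all16` (everything).
#'
#' @return named list mapping set name to locus groups.
#' @export
locusSets <- function() {
  list(traditional14 = c("MULTICOPY_NUCLEAR", "SINGLECOPY_NUCLEAR", "CHLOROPLAST"),
       nuclear11 = c("MULTICOPY_NUCLEAR", "SINGLECOPY_NUCLEAR"),
       chloroplast3 = "CHLOROPLAST",
       sdr = "SDR",
       arr17 = "ARR17",
       all16 = .GROUPS)
}

#' Restrict a VAF matrix to a locus set
#'
#' @param vaf a [VafMatrix-class].
#' @param locusSet a name from [locusSets()], a locus-group name, or a single
#'   amplicon id.
#' @return a [VafMatrix-class] restricted to the set's columns, in canonical
#'   (group, amplicon, position, alt) order; errors on unknown names or an
#'   empty result.
#' @export
subsetLoci <- function(vaf, locusSet) {
  rd <- rowData(vaf)
  sets <- locusSets()
  rows <- if (locusSet %in% names(sets)) rd$group %in% sets[[locusSet]]
  else if (locusSet %in% .GROUPS) rd$group == locusSet
  else if (locusSet %in% unique(rd$amplicon)) rd$amplicon == locusSet
  else .err(sprintf("unknown locus set '%s'", locusSet), "amplitax_invalid_parameter")
  if (!any(rows))
    .err(sprintf("locus set '%s' selects no variant columns", locusSet),
         "amplitax_empty_set")
  se <- SummarizedExperiment(
    assays = list(vaf = assay(vaf, "vaf")[rows, , drop = FALSE]),
    rowData = rd[rows, , drop = FALSE])
  new("VafMatrix", se)
}

#' Pairwise-complete Euclidean distances between samples
#'
#' For samples a, b with M total variant columns and `m_ab` columns observed
#' in both: `d(a,b) = sqrt((M / m_ab) * sum over shared columns (VAF_a -
#' VAF_b)^2)`. With no missing values this is plain Euclidean distance. Pairs
#' sharing no observed column get `NA` with a warning and are excluded (or
#' imputed) at clustering time.
#'
#' @param vaf a [VafMatrix-class].
#' @param label locus-set label stored on the result (defaults to the
#'   constituent groups pasted together).
#' @param weightByGroup scale every column by `1 / sqrt(columns in its locus
#'   group)` so each group contributes equally regardless of variant count;
#'   off by default (the default analysis concatenates columns unweighted).
#' @return a [SampleDistanceMatrix-class].
#' @export
euclideanDistances <- function(vaf, label = NULL, weightByGroup = FALSE) {
  X <- t(assay(vaf, "vaf"))                # samples x columns
  if (weightByGroup) {
    grp <- as.character(rowData(vaf)$group)
    w <- 1 / sqrt(table(grp)[grp])
    X <- sweep(X, 2, as.numeric(w), `*`)
  }
  if (nrow(X) < 2L) .err("need >= 2 samples", "amplitax_invalid_parameter")
  if (ncol(X) < 1L) .err("need >= 1 variant column", "amplitax_invalid_parameter")
  M <- ncol(X)
  W <- !is.na(X)
  A <- X; A[!W] <- 0
  Wn <- W * 1
  m <- Wn %*% t(Wn)
  C <- A^2
  ss <- C %*% t(Wn) + Wn %*% t(C) - 2 * A %*% t(A)
  ss[ss < 0] <- 0                          # guard fp round-off
  d <- sqrt((M / m) * ss)
  d[m == 0] <- NA_real_
  diag(d) <- 0
  d <- (d + t(d)) / 2                      # enforce exact symmetry
  allMissing <- rowSums(W) == 0L
  if (any(allMissing)) {
    warning(sprintf("sample(s) with no observed VAF values: %s",
                    paste(rownames(X)[allMissing], collapse = ", ")))
    d[allMissing, ] <- NA_real_
    d[, allMissing] <- NA_real_
    diag(d) <- 0
  } else if (any(is.na(d[upper.tri(d)]))) {
    warning("some sample pairs share no observed columns; distances set to NA")
  }
  if (is.null(label)) label <- paste(unique(rowData(vaf)$group), collapse = "+")
  SampleDistanceMatrix(d, locusSet = label)
}

#' Mean distance between (or within) sample groups
#'
#' Arithmetic mean of `d(a, b)` over all `a` in A and `b` in B with defined
#' distances. When A and B are the same set, averages over unordered pairs,
#' excluding the diagonal.
#'
#' @param d a [SampleDistanceMatrix-class] or plain symmetric matrix.
#' @param groupA,groupB character vectors of sample ids; disjoint and
#'   non-empty, or identical for the within-group mean.
#' @return numeric(1).
#' @export
groupMeanDistance <- function(d, groupA, groupB = groupA) {
  m <- if (is(d, "SampleDistanceMatrix")) distanceMatrix(d) else d
  if (!length(groupA) || !length(groupB))
    .err("groups must be non-empty", "amplitax_invalid_parameter")
  miss <- setdiff(c(groupA, groupB), rownames(m))
  if (length(miss))
    .err(sprintf("samples not in distance matrix: %s", paste(miss, collapse = ", ")),
         "amplitax_invalid_parameter")
  within <- setequal(groupA, groupB)
  if (!within && length(intersect(groupA, groupB)))
    .err("groups must be disjoint (or identical for the within-group mean)",
         "amplitax_invalid_parameter")
  if (within) {
    sub <- m[groupA, groupA, drop = FALSE]
    if (length(groupA) < 2L)
      .err("within-group mean needs >= 2 samples", "amplitax_invalid_parameter")
    vals <- sub[upper.tri(sub)]
  } else {
    vals <- as.vector(m[groupA, groupB, drop = FALSE])
  }
  vals <- vals[!is.na(vals)]
  if (!length(vals)) .err("no defined distances between the groups",
                          "amplitax_no_defined_pairs")
  mean(vals)
}

#' Write a distance matrix as square TSV
#'
#' Header row and column of sample ids; values with fixed 6 decimals so
#' identical runs produce byte-identical files.
#'
#' @param d a [SampleDistanceMatrix-class].
#' @param path output path.
#' @export
writeDistanceMatrix <- function(d, path) {
  m <- distanceMatrix(d)
  txt <- apply(m, 1, function(r) paste(sprintf("%.6f", r), collapse = "\t"))
  lines <- c(paste(c("sample_id", colnames(m)), collapse = "\t"),
             paste(rownames(m), txt, sep = "\t"))
  con <- file(path, "wb"); on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a distance matrix written by [writeDistanceMatrix()]
#' @param path TSV path.
#' @param locusSet label to attach.
#' @return a [SampleDistanceMatrix-class].
#' @export
readDistanceMatrix <- function(path, locusSet = NA_character_) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  SampleDistanceMatrix(m, locusSet = locusSet)
}

#' Write a VAF matrix and its missing mask as TSV
#'
#' @param vaf a [VafMatrix-class].
#' @param path output path for values; the mask (1 = missing) goes to
#'   `<path>.mask.tsv`.
#' @export
writeVafMatrix <- function(vaf, path) {
  v <- assay(vaf, "vaf")
  rd <- rowData(vaf)
  id <- paste(rd$site, rd$alt, sep = "_")
  df <- data.frame(column = id, group = rd$group,
                   as.data.frame(rd[, c("amplicon", "pos", "alt")]),
                   round(v, 6), check.names = FALSE)
  .writeTsv(df, path)
  mask <- data.frame(column = id, (is.na(v)) * 1L, check.names = FALSE)
  .writeTsv(mask, paste0(path, ".mask.tsv"))
  invisible(path)
}
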