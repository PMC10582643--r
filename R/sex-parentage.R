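# Sex genotyping from SDR/ARR17 evidence and hybrid parentage inference.
#
# In XY poplars (sections Aigeiros/Tacamahaca) the male-specific SDR portion
# carrying partial ARR17 repeats yields reads only in males, so coverage of
# the male-specific amplicons is the first evidence line; a two-way cut of
# the SDR dendrogram, voted by any samples of known sex, is the second. The
# chloroplast is maternally inherited, so the hybrid's maternal species is
# the candidate with the smallest mean chloroplast distance; the Y is
# paternal, so the paternal species is the candidate with the smallest mean
# SDR distance among male plants.

#' Infer sample sex from male-specific coverage and SDR clustering
#'
#' Evidence line 1 calls a sample male when its mean depth over the
#' male-specific amplicons is at least `presenceRatioMin` times its overall
#' mean amplicon depth, female otherwise (unknown when the sample has no
#' coverage at all). Evidence line 2, available when an SDR tree and at least
#' one labeled sex are supplied, cuts the SDR tree two ways and votes each
#' cluster by the majority labeled sex. The final call is the agreement of
#' the two lines; on disagreement the call is "unknown". Samples in a cluster
#' without labeled members fall back to line 1.
#'
#' @param cov samples x amplicons coverage matrix from [coverageByAmplicon()].
#' @param maleSpecific character vector of male-specific amplicon ids.
#' @param sdrTree optional [LinkageTree-class] built from the SDR locus set.
#' @param presenceRatioMin fraction of the sample's overall mean amplicon
#'   depth required on male-specific amplicons to call presence (default 0.1;
#'   presence at ~full depth vs a noise floor of a few reads gives a wide
#'   margin).
#' @param labeledSexes optional named character vector (sample -> "male" /
#'   "female") of known sexes guiding the cluster vote.
#' @return data.frame: `sample_id`, `call`, `ms_depth`, `presence_ratio`,
#'   `cluster_vote`.
#' @export
inferSex <- function(cov, maleSpecific, sdrTree = NULL, presenceRatioMin = 0.1,
                     labeledSexes = NULL) {
  if (!length(maleSpecific)) .err("maleSpecific must be non-empty",
                                  "amplitax_invalid_parameter")
  ms <- intersect(maleSpecific, colnames(cov))
  if (!length(ms)) .err("no male-specific amplicons found in coverage table",
                        "amplitax_config_error")
  msDepth <- rowMeans(cov[, ms, drop = FALSE])
  overall <- rowMeans(cov)
  ratio <- ifelse(overall > 0, msDepth / overall, NA_real_)
  line1 <- ifelse(is.na(ratio), "unknown",
                  ifelse(ratio >= presenceRatioMin, "male", "female"))
  vote <- rep(NA_character_, nrow(cov))
  names(vote) <- rownames(cov)
  if (!is.null(sdrTree) && length(labeledSexes)) {
    cl <- cutClusters(sdrTree, 2L)
    for (k in 1:2) {
      ids <- names(cl)[cl == k]
      lab <- labeledSexes[intersect(names(labeledSexes), ids)]
      lab <- lab[lab %in% c("male", "female")]
      if (!length(lab)) next
      tab <- table(lab)
      top <- which(tab == max(tab))
      if (length(top) == 1L) vote[intersect(ids, names(vote))] <- names(tab)[top]
    }
  }
  final <- vapply(seq_len(nrow(cov)), function(i) {
    if (is.na(vote[i])) return(line1[i])
    if (line1[i] == "unknown") return(vote[[i]])
    if (identical(line1[[i]], vote[[i]])) line1[[i]] else "unknown"
  }, character(1))
  data.frame(sample_id = rownames(cov), call = final, ms_depth = msDepth,
             presence_ratio = ratio, cluster_vote = unname(vote),
             row.names = NULL, stringsAsFactors = FALSE)
}

# argmin over candidate mean distances with a tie tolerance
.argminLineage <- function(means, tieTol = 1e-9) {
  ord <- order(means)
  winner <- names(means)[ord[1]]
  margin <- if (length(means) > 1L) means[[ord[2]]] - means[[ord[1]]] else Inf
  if (length(means) > 1L && margin <= tieTol) {
    tied <- names(means)[means - means[[ord[1]]] <= tieTol]
    list(taxon = "undecided", margin = 0,
         note = sprintf("tie between %s", paste(tied, collapse = ", ")))
  } else list(taxon = winner, margin = margin, note = NA_character_)
}

#' Infer the maternal species of a hybrid from chloroplast distances
#'
#' The chloroplast is inherited from the seed parent, so the maternal species
#' is the candidate minimizing the mean chloroplast-locus distance to the
#' hybrid's samples. Ties within `1e-9` return "undecided".
#'
#' @param chloroD [SampleDistanceMatrix-class] over the chloroplast locus set.
#' @param hybrid character vector of hybrid sample ids.
#' @param candidates named list: candidate taxon -> sample ids (>= 2 taxa).
#' @return list: `taxon`, `means` (named candidate means), `margin`, `note`.
#' @export
inferMaternal <- function(chloroD, hybrid, candidates) {
  if (length(candidates) < 2L) .err("need >= 2 candidate taxa",
                                    "amplitax_invalid_parameter")
  means <- vapply(candidates, function(ids)
    groupMeanDistance(chloroD, hybrid, ids), numeric(1))
  res <- .argminLineage(means)
  list(taxon = res$taxon, means = means, margin = res$margin, note = res$note)
}

#' Infer the paternal species of a hybrid from male-restricted SDR distances
#'
#' Sons inherit the father's Y, so among male-called samples the paternal
#' species is the candidate minimizing the mean SDR distance to the hybrid's
#' males. Mirrors the male-cluster reading of the SDR dendrogram, but uses
#' evidence-based sex calls rather than tree position.
#'
#' @param sdrD [SampleDistanceMatrix-class] over the SDR locus set.
#' @param hybrid character vector of hybrid sample ids.
#' @param candidates named list: candidate taxon -> sample ids.
#' @param sexCalls data.frame from [inferSex()] (or columns `sample_id`,
#'   `call`).
#' @return list: `taxon`, `means`, `margin`, `note`.
#' @export
inferPaternal <- function(sdrD, hybrid, candidates, sexCalls) {
  if (length(candidates) < 2L) .err("need >= 2 candidate taxa",
                                    "amplitax_invalid_parameter")
  males <- sexCalls$sample_id[sexCalls$call == "male"]
  hybM <- intersect(hybrid, males)
  if (!length(hybM))
    .err("paternal lineage unresolvable from SDR: hybrid has no male-called samples",
         "amplitax_no_male_samples")
  candM <- lapply(candidates, intersect, y = males)
  empty <- names(candM)[lengths(candM) == 0L]
  if (length(empty))
    .err(sprintf("candidate taxa without male-called samples: %s",
                 paste(empty, collapse = ", ")), "amplitax_no_male_samples")
  means <- vapply(candM, function(ids) groupMeanDistance(sdrD, hybM, ids),
                  numeric(1))
  res <- .argminLineage(means)
  list(taxon = res$taxon, means = means, margin = res$margin, note = res$note)
}

#' Infer both parental lineages of a hybrid taxon
#'
#' Combines [inferMaternal()] (chloroplast) and [inferPaternal()]
#' (male-restricted SDR) and flags the degenerate case where both lineages
#' select the same taxon (a non-hybrid pattern).
#'
#' @param hybridTaxon label for the result.
#' @param hybrid character vector of hybrid sample ids.
#' @param candidates named list: candidate taxon -> sample ids.
#' @param chloroD distance matrix over the chloroplast locus set.
#' @param sdrD distance matrix over the SDR locus set.
#' @param sexCalls data.frame from [inferSex()].
#' @return a [ParentageResult-class].
#' @export
inferParentPair <- function(hybridTaxon, hybrid, candidates, chloroD, sdrD,
                            sexCalls) {
  mat <- inferMaternal(chloroD, hybrid, candidates)
  pat <- inferPaternal(sdrD, hybrid, candidates, sexCalls)
  new("ParentageResult", hybrid = hybridTaxon,
      maternal = mat$taxon, paternal = pat$taxon,
      maternalEvidence = mat$means, paternalEvidence = pat$means,
      maternalMargin = mat$margin, paternalMargin = pat$margin,
      degenerate = identical(mat$taxon, pat$taxon) && mat$taxon != "undecided")
}

#' Write sex calls as TSV
#' @param sexCalls data.frame from [inferSex()].
#' @param path output path.
#' @export
writeSexCalls <- function(sexCalls, path) .writeTsv(sexCalls, path)

#' Write a parentage report (TSV plus human-readable block)
#'
#' @param results list of [ParentageResult-class] objects.
#' @param path TSV path; a text block goes to `<path>.txt`.
#' @export
writeParentageReport <- function(results, path) {
  rows <- lapply(results, function(r) data.frame(
    hybrid = r@hybrid, maternal = r@maternal, paternal = r@paternal,
    maternal_margin = r@maternalMargin, paternal_margin = r@paternalMargin,
    degenerate = r@degenerate,
    maternal_means = paste(sprintf("%s=%.6g", names(r@maternalEvidence),
                                   r@maternalEvidence), collapse = ";"),
    paternal_means = paste(sprintf("%s=%.6g", names(r@paternalEvidence),
                                   r@paternalEvidence), collapse = ";"),
    stringsAsFactors = FALSE))
  .writeTsv(do.call(rbind, rows), path)
  txt <- unlist(lapply(results, function(r) c(
    sprintf("Hybrid %s:", r@hybrid),
    sprintf("  maternal lineage (chloroplast mean distances): %s", r@maternal),
    sprintf("    %s: %.6g", names(r@maternalEvidence), r@maternalEvidence),
    sprintf("  paternal lineage (male SDR mean distances): %s", r@paternal),
    sprintf("    %s: %.6g", names(r@paternalEvidence), r@paternalEvidence),
    if (r@degenerate) "  NOTE: degenerate (both lineages select the same taxon)" else NULL,
    "")))
  con <- file(paste0(path, ".txt"), "wb"); on.exit(close(con))
  writeLines(txt, con, sep = "\n")
  invisible(path)
}
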