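# Reading multi-sample VCFs and panel metadata into validated tables.
# Coordinates are VCF-native: 1-based, inclusive. AD is required; every
# alternate allele becomes its own row (multiallelic decomposition).

#' Read a sample sheet
#'
#' Tab-separated columns `sample_id`, `taxon`, `sex`, `region`. Taxon labels
#' containing "?" (or empty) are flagged as doubtful; sex must be one of
#' male/female/unknown (empty treated as unknown).
#'
#' @param path TSV path.
#' @return data.frame with an added logical `doubtful` column.
#' @export
readSampleSheet <- function(path) {
  if (!file.exists(path)) .err(sprintf("sample sheet '%s' not found", path),
                               "amplitax_io_error")
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "taxon", "sex", "region")
  if (!all(need %in% colnames(df)))
    .err(sprintf("sample sheet needs columns %s", paste(need, collapse = ", ")),
         "amplitax_config_error")
  if (anyDuplicated(df$sample_id))
    .err("duplicate sample ids in sample sheet", "amplitax_config_error")
  df$sex[is.na(df$sex) | df$sex == ""] <- "unknown"
  bad <- setdiff(unique(df$sex), c("male", "female", "unknown"))
  if (length(bad))
    .err(sprintf("invalid sex values: %s", paste(bad, collapse = ", ")),
         "amplitax_config_error")
  df$doubtful <- is.na(df$taxon) | df$taxon == "" | grepl("\\?", df$taxon)
  df
}

#' Read a locus-group map
#'
#' Tab-separated columns `amplicon`, `chrom`, `group`; groups must be among
#' MULTICOPY_NUCLEAR, SINGLECOPY_NUCLEAR, CHLOROPLAST, SDR, ARR17.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
readLocusMap <- function(path) {
  if (!file.exists(path)) .err(sprintf("locus map '%s' not found", path),
                               "amplitax_io_error")
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("amplicon", "chrom", "group")
  if (!all(need %in% colnames(df)))
    .err(sprintf("locus map needs columns %s", paste(need, collapse = ", ")),
         "amplitax_config_error")
  bad <- setdiff(unique(df$group), .GROUPS)
  if (length(bad))
    .err(sprintf("unknown locus groups: %s", paste(bad, collapse = ", ")),
         "amplitax_config_error")
  if (anyDuplicated(df$amplicon))
    .err("duplicate amplicon ids in locus map", "amplitax_config_error")
  df
}

# AD extraction that copes with both the array (uniform allele count) and
# list-matrix layouts VariantAnnotation produces
.adTriple <- function(ad, i, s, nAlt) {
  v <- if (length(dim(ad)) == 3L) ad[i, s, ] else ad[[i, s]]
  v <- suppressWarnings(as.integer(v))
  if (length(v) < nAlt + 1L || all(is.na(v))) return(NULL)
  v
}

# parse one VCF into per-alt-allele records
.readOneVcf <- function(path) {
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(path)),
    error = function(e) .err(sprintf("malformed VCF '%s': %s", path,
                                     conditionMessage(e)), "amplitax_parse_error"))
  g <- geno(vcf)
  if (!"AD" %in% names(g))
    .err(sprintf("VCF '%s' lacks the AD FORMAT field", path), "amplitax_parse_error")
  ad <- g$AD
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  refA <- as.character(ref(vcf))
  altL <- alt(vcf)
  altC <- lapply(seq_along(altL), function(i) as.character(altL[[i]]))
  samples <- colnames(vcf)
  nSite <- length(rr)
  recs <- vector("list", nSite)
  for (i in seq_len(nSite)) {
    alts <- altC[[i]]
    nAlt <- length(alts)
    if (nAlt < 1L)
      .err(sprintf("VCF '%s' record %s:%d has no alternate allele",
                   path, chrom[i], pos[i]), "amplitax_parse_error")
    refD <- rep(NA_integer_, length(samples))
    altD <- matrix(NA_integer_, nAlt, length(samples))
    siteD <- rep(NA_integer_, length(samples))
    for (s in seq_along(samples)) {
      v <- .adTriple(ad, i, s, nAlt)
      if (is.null(v)) next
      refD[s] <- v[1]
      altD[, s] <- v[1 + seq_len(nAlt)]
      siteD[s] <- sum(v[seq_len(nAlt + 1L)])
    }
    recs[[i]] <- list(chrom = chrom[i], pos = pos[i], ref = refA[i], alts = alts,
                      refD = refD, altD = altD, siteD = siteD)
  }
  list(records = recs, samples = samples)
}

#' Read multi-sample VCFs into a VariantTable
#'
#' Parses one or more VCFv4.2 files (AD per-sample allelic depths required),
#' decomposes multiallelic sites into one row per alternate allele, attaches
#' locus-group labels from the map, and harmonizes samples across files: the
#' sample set is the union, with `NA` depths where a sample is absent from a
#' file. InDel alleles are retained alongside SNPs.
#'
#' @param paths character vector of VCF paths.
#' @param groupMap data.frame as from [readLocusMap()] (or the simulator's
#'   `groupMap`); every VCF contig must map to an amplicon.
#' @param sampleOrder optional character vector fixing the column order
#'   (e.g. the sample-sheet order); must contain every sample found.
#' @return a [VariantTable-class], rows ordered by (group, amplicon, pos, alt).
#' @export
readVcfs <- function(paths, groupMap, sampleOrder = NULL) {
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    .err(sprintf("VCF file(s) not found: %s", paste(missing, collapse = ", ")),
         "amplitax_io_error")
  parsed <- lapply(paths, .readOneVcf)
  samples <- unique(unlist(lapply(parsed, `[[`, "samples")))
  if (!is.null(sampleOrder)) {
    extra <- setdiff(samples, sampleOrder)
    if (length(extra))
      .err(sprintf("samples absent from sample order: %s",
                   paste(extra, collapse = ", ")), "amplitax_config_error")
    samples <- intersect(sampleOrder, samples)
  }
  chrom2amp <- setNames(groupMap$amplicon, groupMap$chrom)
  chrom2grp <- setNames(groupMap$group, groupMap$chrom)

  infos <- list(); refL <- list(); altL <- list(); siteL <- list()
  for (p in seq_along(parsed)) {
    fsamp <- parsed[[p]]$samples
    idx <- match(fsamp, samples)
    for (rec in parsed[[p]]$records) {
      if (!rec$chrom %in% names(chrom2amp))
        .err(sprintf("contig '%s' (in %s) is not in the locus-group map",
                     rec$chrom, paths[p]), "amplitax_config_error")
      nAlt <- length(rec$alts)
      for (k in seq_len(nAlt)) {
        infos[[length(infos) + 1L]] <- data.frame(
          amplicon = unname(chrom2amp[rec$chrom]), chrom = rec$chrom,
          pos = rec$pos, ref = rec$ref, alt = rec$alts[k],
          group = unname(chrom2grp[rec$chrom]),
          site = paste0(rec$chrom, ":", rec$pos), stringsAsFactors = FALSE)
        row <- function(x) { out <- rep(NA_integer_, length(samples)); out[idx] <- x; out }
        refL[[length(refL) + 1L]] <- row(rec$refD)
        altL[[length(altL) + 1L]] <- row(rec$altD[k, ])
        siteL[[length(siteL) + 1L]] <- row(rec$siteD)
      }
    }
  }
  if (!length(infos)) .err("no variant records found", "amplitax_parse_error")
  info <- do.call(rbind, infos)
  mkm <- function(l) {
    m <- do.call(rbind, l); colnames(m) <- samples; m
  }
  refD <- mkm(refL); altD <- mkm(altL); siteD <- mkm(siteL)
  ord <- order(match(info$group, .GROUPS), info$amplicon, info$pos, info$alt)
  VariantTable(info[ord, , drop = FALSE], refD[ord, , drop = FALSE],
               altD[ord, , drop = FALSE], siteD[ord, , drop = FALSE])
}

#' Mean per-site coverage by sample and amplicon
#'
#' For each sample and amplicon: total site depth summed over the amplicon's
#' sites divided by the site count (each site counted once, not per alternate
#' allele). A sample absent from an amplicon's file contributes 0.
#'
#' @param table a [VariantTable-class].
#' @return numeric matrix, samples x amplicons.
#' @export
coverageByAmplicon <- function(table) {
  if (nrow(table) == 0L) .err("empty VariantTable", "amplitax_invalid_parameter")
  rd <- rowData(table)
  siteD <- assay(table, "siteDepth")
  keep <- !duplicated(rd$site)           # one row per site
  sd1 <- siteD[keep, , drop = FALSE]
  amp1 <- rd$amplicon[keep]
  sd1[is.na(sd1)] <- 0L
  amps <- unique(rd$amplicon)
  out <- matrix(0, ncol(table), length(amps),
                dimnames = list(colnames(table), amps))
  for (a in amps) {
    rows <- amp1 == a
    out[, a] <- colSums(sd1[rows, , drop = FALSE]) / sum(rows)
  }
  out
}

#' Flag samples with low coverage per locus group
#'
#' A sample is flagged for a locus group when its mean depth over the group's
#' amplicons falls below `minMeanDepth`. Flags propagate as missing data in
#' [buildVaf()]; samples are never dropped globally.
#'
#' @param cov samples x amplicons matrix from [coverageByAmplicon()].
#' @param groupMap locus-group map (amplicon, chrom, group).
#' @param minMeanDepth reads; default 20, a conservative fraction of the
#'   ~500-read panel mean.
#' @return logical matrix, samples x locus groups (TRUE = excluded).
#' @export
flagLowCoverage <- function(cov, groupMap, minMeanDepth = 20) {
  if (minMeanDepth < 0) .err("minMeanDepth must be >= 0", "amplitax_invalid_parameter")
  groups <- intersect(.GROUPS, unique(groupMap$group))
  out <- matrix(FALSE, nrow(cov), length(groups),
                dimnames = list(rownames(cov), groups))
  for (g in groups) {
    amps <- intersect(groupMap$amplicon[groupMap$group == g], colnames(cov))
    if (!length(amps)) next
    out[, g] <- rowMeans(cov[, amps, drop = FALSE]) < minMeanDepth
  }
  out
}
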