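# Orchestration: a validated run configuration drives simulate/ingest, VAF,
# per-locus-set distances + trees + cuts, sex calls, parentage and consensus,
# with a run manifest for reproducibility.

.DEFAULT_THRESHOLDS <- list(min_site_depth = 20, min_mean_depth = 20,
                            presence_ratio_min = 0.1)

#' Read and validate a run configuration
#'
#' YAML with either a `simulate:` block (n_species, variants_per_amplicon,
#' divergence, xy_divergence, y_divergence, depth model, pedigrees — each
#' pedigree a mapping with taxon, type, mother, father, n_samples, sex_ratio)
#' or an `inputs:` block
#' (`vcfs` or `vcf_dir`, `sample_sheet`, `locus_map`); plus `locus_sets`,
#' `thresholds` (min_site_depth, min_mean_depth, presence_ratio_min),
#' optional `cluster_cuts` (set -> k), `male_specific_amplicons`, optional
#' `parentage` entries (hybrid + candidate taxa) and `consensus` block
#' (samples, reference_taxa, sets), `out_dir` and `seed`.
#'
#' @param path YAML path.
#' @return validated config list (class `RunConfig`).
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) .err(sprintf("config '%s' not found", path),
                               "amplitax_io_error")
  cfg <- yaml::read_yaml(path)
  cfg$config_path <- normalizePath(path)
  validateRunConfig(cfg)
}

#' Validate a run configuration list
#'
#' @param cfg list with the fields described in [readRunConfig()].
#' @return the completed config (defaults filled), class `RunConfig`.
#' @export
validateRunConfig <- function(cfg) {
  if (is.null(cfg$out_dir)) .err("config needs out_dir", "amplitax_config_error")
  if (is.null(cfg$seed)) cfg$seed <- 1L
  cfg$seed <- as.integer(cfg$seed)
  if (is.null(cfg$locus_sets)) cfg$locus_sets <- c("traditional14", "sdr", "all16")
  unknown <- setdiff(cfg$locus_sets, names(locusSets()))
  if (length(unknown))
    .err(sprintf("unknown locus sets: %s", paste(unknown, collapse = ", ")),
         "amplitax_config_error")
  thr <- .DEFAULT_THRESHOLDS
  thr[names(cfg$thresholds)] <- cfg$thresholds
  cfg$thresholds <- thr
  if (is.null(cfg$male_specific_amplicons))
    cfg$male_specific_amplicons <- c("SDR_malespec", "ARR17")
  if (is.null(cfg$simulate)) {
    inp <- cfg$inputs
    if (is.null(inp)) .err("config needs a simulate or inputs block",
                           "amplitax_config_error")
    if (is.null(inp$locus_map)) .err("config inputs missing locus_map",
                                     "amplitax_config_error")
    if (is.null(inp$sample_sheet)) .err("config inputs missing sample_sheet",
                                        "amplitax_config_error")
    if (is.null(inp$vcfs) && is.null(inp$vcf_dir))
      .err("config inputs missing vcfs / vcf_dir", "amplitax_config_error")
  } else {
    sim <- cfg$simulate
    if (is.null(sim$pedigrees)) .err("simulate block needs pedigrees",
                                     "amplitax_config_error")
    if (is.null(sim$n_species)) .err("simulate block needs n_species",
                                     "amplitax_config_error")
  }
  class(cfg) <- c("RunConfig", "list")
  cfg
}

.simFromConfig <- function(cfg) {
  sim <- cfg$simulate
  prof <- simulateProfiles(
    nSpecies = sim$n_species,
    variantsPerAmplicon = if (is.null(sim$variants_per_amplicon)) 20
                          else sim$variants_per_amplicon,
    divergence = if (is.null(sim$divergence)) 0.5 else sim$divergence,
    xyDivergence = if (is.null(sim$xy_divergence)) 0.8 else sim$xy_divergence,
    yDivergence = if (is.null(sim$y_divergence)) 0.1 else sim$y_divergence,
    seed = cfg$seed)
  dp <- sim$depth
  model <- depthModel(
    meanDepth = if (is.null(dp$mean_depth)) 500 else dp$mean_depth,
    dispersion = if (is.null(dp$dispersion)) 50 else dp$dispersion,
    dropoutProb = if (is.null(dp$dropout_prob)) 0.02 else dp$dropout_prob,
    noiseFloor = if (is.null(dp$noise_floor)) 2L else dp$noise_floor)
  peds <- do.call(rbind, lapply(sim$pedigrees, function(p) {
    # YAML 1.1 parses a bare `n` key as boolean FALSE; accept all spellings
    n <- p$n_samples
    if (is.null(n)) n <- p$n
    if (is.null(n)) n <- p[["FALSE"]]
    if (is.null(n))
      .err(sprintf("pedigree '%s' needs n_samples", p$taxon), "amplitax_config_error")
    data.frame(taxon = p$taxon, type = p$type, mother = p$mother,
               father = p$father, n = n,
               sex_ratio = if (is.null(p$sex_ratio)) 0.5 else p$sex_ratio,
               stringsAsFactors = FALSE)
  }))
  simulatePanel(panelConfig(prof, peds, model, seed = cfg$seed))
}

.log <- function(logLines, fmt, ...) {
  line <- sprintf("[amplitax] %s", sprintf(fmt, ...))
  message(line)
  c(logLines, line)
}

#' Run the full inference pipeline
#'
#' Stages: simulate or ingest VCFs; coverage and low-coverage flags; VAF
#' matrix; per requested locus set a VAF TSV, distance TSV, Newick tree and
#' cluster-assignment TSV; sex calls; parentage reports; consensus
#' assignments; and a run manifest (config echo, md5, package version, seed).
#' Identical configurations (including seed) produce byte-identical distance
#' TSVs.
#'
#' @param cfg a validated config from [readRunConfig()] /
#'   [validateRunConfig()], or a plain list (validated here).
#' @return invisibly, a list with the in-memory objects (`table`, `vaf`,
#'   `distances`, `trees`, `sexCalls`, `parentage`, `consensus`, `paths`).
#' @export
runPipeline <- function(cfg) {
  if (!inherits(cfg, "RunConfig")) cfg <- validateRunConfig(cfg)
  out <- cfg$out_dir
  if (!dir.exists(out) && !dir.create(out, recursive = TRUE))
    .err(sprintf("cannot create output directory '%s'", out), "amplitax_io_error")
  logLines <- character()

  if (!is.null(cfg$simulate)) {
    panel <- .simFromConfig(cfg)
    simDir <- file.path(out, "sim")
    writePanel(panel, simDir)
    vcfPaths <- file.path(simDir, paste0(unique(panel$groupMap$amplicon), ".vcf"))
    sheet <- panel$sampleSheet
    sheet$doubtful <- FALSE
    groupMap <- panel$groupMap
    logLines <- .log(logLines, "simulated panel: %d samples, %d variant alleles",
                     ncol(panel$table), nrow(panel$table))
  } else {
    inp <- cfg$inputs
    vcfPaths <- if (!is.null(inp$vcfs)) unlist(inp$vcfs)
                else list.files(inp$vcf_dir, pattern = "\\.vcf$", full.names = TRUE)
    sheet <- readSampleSheet(inp$sample_sheet)
    groupMap <- readLocusMap(inp$locus_map)
  }
  table <- readVcfs(vcfPaths, groupMap, sampleOrder = sheet$sample_id)
  logLines <- .log(logLines, "variant table: %d variant alleles x %d samples",
                   nrow(table), ncol(table))

  cov <- coverageByAmplicon(table)
  flags <- flagLowCoverage(cov, groupMap, cfg$thresholds$min_mean_depth)
  logLines <- .log(logLines, "coverage: %.1f mean reads/site; %d sample-group exclusions",
                   mean(cov), sum(flags))
  vaf <- buildVaf(table, cfg$thresholds$min_site_depth, exclusions = flags)
  logLines <- .log(logLines, "VAF matrix: %d columns, %.1f%% missing",
                   nrow(vaf), 100 * mean(is.na(assay(vaf, "vaf"))))

  refGroups <- split(sheet$sample_id[!sheet$doubtful], sheet$taxon[!sheet$doubtful])
  distances <- list(); trees <- list(); paths <- list()
  for (s in cfg$locus_sets) {
    sub <- subsetLoci(vaf, s)
    d <- suppressWarnings(euclideanDistances(sub, label = s))
    tr <- suppressWarnings(wardLinkage(d))
    k <- if (!is.null(cfg$cluster_cuts[[s]])) cfg$cluster_cuts[[s]]
         else min(length(refGroups), length(tr@labels))
    cl <- cutClusters(tr, k)
    maj <- .clusterMajorities(cl, refGroups)
    asn <- data.frame(sample_id = names(cl), locus_set = s, cluster = unname(cl),
                      candidate_taxon = maj[unname(cl)], stringsAsFactors = FALSE)
    paths[[paste0("vaf_", s)]] <- writeVafMatrix(sub, file.path(out, sprintf("vaf_%s.tsv", s)))
    paths[[paste0("dist_", s)]] <- writeDistanceMatrix(d, file.path(out, sprintf("distance_%s.tsv", s)))
    paths[[paste0("tree_", s)]] <- writeNewick(tr, file.path(out, sprintf("tree_%s.nwk", s)))
    paths[[paste0("clusters_", s)]] <- .writeTsv(asn, file.path(out, sprintf("clusters_%s.tsv", s)))
    distances[[s]] <- d; trees[[s]] <- tr
    logLines <- .log(logLines, "locus set %s: %d columns, cut k=%d", s, nrow(sub), k)
  }

  sdrTree <- trees[["sdr"]]
  if (is.null(sdrTree)) {
    sdrSub <- subsetLoci(vaf, "sdr")
    sdrTree <- suppressWarnings(wardLinkage(euclideanDistances(sdrSub, label = "sdr")))
  }
  labeled <- setNames(sheet$sex, sheet$sample_id)
  labeled <- labeled[labeled %in% c("male", "female")]
  sexCalls <- inferSex(cov, cfg$male_specific_amplicons, sdrTree,
                       cfg$thresholds$presence_ratio_min, labeled)
  paths$sex_calls <- writeSexCalls(sexCalls, file.path(out, "sex_calls.tsv"))
  logLines <- .log(logLines, "sex calls: %d male, %d female, %d unknown",
                   sum(sexCalls$call == "male"), sum(sexCalls$call == "female"),
                   sum(sexCalls$call == "unknown"))

  parentage <- list()
  if (!is.null(cfg$parentage)) {
    chloroD <- distances[["chloroplast3"]]
    if (is.null(chloroD))
      chloroD <- suppressWarnings(euclideanDistances(subsetLoci(vaf, "chloroplast3"),
                                                     label = "chloroplast3"))
    sdrD <- distances[["sdr"]]
    if (is.null(sdrD))
      sdrD <- suppressWarnings(euclideanDistances(subsetLoci(vaf, "sdr"), label = "sdr"))
    for (p in cfg$parentage) {
      cand <- refGroups[unlist(p$candidates)]
      res <- inferParentPair(p$hybrid, refGroups[[p$hybrid]], cand,
                             chloroD, sdrD, sexCalls)
      parentage[[p$hybrid]] <- res
      logLines <- .log(logLines, "parentage %s: maternal %s, paternal %s",
                       p$hybrid, res@maternal, res@paternal)
    }
    paths$parentage <- writeParentageReport(parentage, file.path(out, "parentage.tsv"))
  }

  consensus <- NULL
  if (!is.null(cfg$consensus)) {
    cs <- cfg$consensus
    sets <- if (is.null(cs$sets)) c("all16", "sdr", "traditional14") else unlist(cs$sets)
    ctrees <- trees[intersect(sets, names(trees))]
    for (s in setdiff(sets, names(ctrees)))
      ctrees[[s]] <- suppressWarnings(wardLinkage(euclideanDistances(subsetLoci(vaf, s),
                                                                     label = s)))
    refs <- refGroups[unlist(cs$reference_taxa)]
    refs <- lapply(refs, setdiff, y = unlist(cs$samples))
    consensus <- consensusAssign(unlist(cs$samples), ctrees[sets], refs)
    paths$consensus <- .writeTsv(consensus, file.path(out, "consensus.tsv"))
    logLines <- .log(logLines, "consensus: %d of %d samples assigned",
                     sum(consensus$consensus != "ambiguous"), nrow(consensus))
  }

  manifest <- list(
    package = "amplitax", version = as.character(packageVersion("amplitax")),
    r_version = as.character(getRversion()), seed = cfg$seed,
    config_md5 = if (!is.null(cfg$config_path)) unname(md5sum(cfg$config_path))
                 else NA_character_,
    locus_sets = cfg$locus_sets, thresholds = cfg$thresholds)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  cfgEcho <- unclass(cfg)
  yaml::write_yaml(cfgEcho, file.path(out, "config_used.yaml"))
  con <- file(file.path(out, "run.log"), "wb")
  writeLines(logLines, con, sep = "\n"); close(con)

  invisible(list(table = table, coverage = cov, flags = flags, vaf = vaf,
                 distances = distances, trees = trees, sexCalls = sexCalls,
                 parentage = parentage, consensus = consensus, paths = paths,
                 sampleSheet = sheet))
}
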