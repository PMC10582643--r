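# Synthetic amplicon-panel simulator: species allele-frequency profiles,
# pedigree-aware genotypes (diploid nuclear, maternal chloroplast, XY SDR),
# negative-binomial read depths, and VCF/TSV export with a ground-truth table.

.GROUPS <- c("MULTICOPY_NUCLEAR", "SINGLECOPY_NUCLEAR", "CHLOROPLAST", "SDR", "ARR17")
.GROUP_PLOIDY <- c(MULTICOPY_NUCLEAR = "diploid", SINGLECOPY_NUCLEAR = "diploid",
                   CHLOROPLAST = "haploid_maternal", SDR = "sex_linked",
                   ARR17 = "sex_linked")

.err <- function(msg, class) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Default 16-locus amplicon panel
#'
#' The panel emulated by the simulator: two multicopy nuclear loci (NTS 5S
#' rDNA, ITS), nine single-copy nuclear loci (DSH 2/5/8/12/29, 6, 15, 16,
#' X18), three chloroplast loci (trnG-psbK-psbI, rps2-rpoC2, rpoC2-rpoC1),
#' the sex-determining region (SDR) and the ARR17 gene. The SDR locus is
#' sequenced as two amplicons: a shared region present in both sexes
#' (`SDR_shared`, X/Y polymorphism) and the male-specific portion carrying
#' partial ARR17 repeats (`SDR_malespec`), which yields reads only in males,
#' as does the `ARR17` amplicon.
#'
#' @return data.frame with columns `amplicon`, `chrom`, `group`,
#'   `male_specific`.
#' @export
defaultPanel <- function() {
  amp <- c("NTS_5S", "ITS",
           "DSH2", "DSH5", "DSH8", "DSH12", "DSH29", "P6", "P15", "P16", "X18",
           "trnG_psbK_psbI", "rps2_rpoC2", "rpoC2_rpoC1",
           "SDR_shared", "SDR_malespec", "ARR17")
  grp <- c(rep("MULTICOPY_NUCLEAR", 2), rep("SINGLECOPY_NUCLEAR", 9),
           rep("CHLOROPLAST", 3), "SDR", "SDR", "ARR17")
  data.frame(amplicon = amp, chrom = amp, group = grp,
             male_specific = amp %in% c("SDR_malespec", "ARR17"),
             stringsAsFactors = FALSE)
}

#' Read-depth model for the simulator
#'
#' Per-site total depth is negative binomial with mean `meanDepth` and size
#' `dispersion` (large size approaches Poisson); alternate-allele reads are
#' binomial in the true allele dosage. Amplicons absent from a sample (the
#' male-specific ones in females) receive at most `noiseFloor` stray
#' reference-like reads. Whole amplicons drop out with probability
#' `dropoutProb`.
#'
#' @param meanDepth mean reads per site (default 500, the panel-wide average
#'   depth the analysis assumes).
#' @param dispersion negative-binomial size parameter.
#' @param dropoutProb probability an amplicon yields no reads in a sample.
#' @param noiseFloor maximum stray reads on absent amplicons (integer).
#' @return a `DepthModel` list.
#' @export
depthModel <- function(meanDepth = 500, dispersion = 50, dropoutProb = 0.02,
                       noiseFloor = 2L) {
  if (meanDepth <= 0) .err("meanDepth must be > 0", "amplitax_invalid_parameter")
  if (dispersion <= 0) .err("dispersion must be > 0", "amplitax_invalid_parameter")
  if (dropoutProb < 0 || dropoutProb > 1)
    .err("dropoutProb must be in [0, 1]", "amplitax_invalid_parameter")
  if (noiseFloor < 0 || noiseFloor != round(noiseFloor))
    .err("noiseFloor must be a non-negative integer", "amplitax_invalid_parameter")
  structure(list(meanDepth = meanDepth, dispersion = dispersion,
                 dropoutProb = dropoutProb, noiseFloor = as.integer(noiseFloor)),
            class = "DepthModel")
}

# P(two given species land on opposite sides of a uniform random nonempty
# proper subset of n species)
.pairOppositeProb <- function(n) 2^(n - 1) / (2^n - 2)

# random bipartition of n species: 0/1 vector, not all equal, oriented so
# species 1 carries the reference allele
.randomBipartition <- function(n) {
  repeat {
    b <- rbinom(n, 1L, 0.5)
    if (any(b == 0L) && any(b == 1L)) break
  }
  if (b[1] == 1L) b <- 1L - b
  b
}

#' Simulate species allele-frequency profiles for the panel
#'
#' Generates, per species and amplicon, population alternate-allele
#' frequencies. A site is interspecifically variable with probability
#' `divergence / q(n)` (capped at 1), where `q(n)` is the chance a random
#' species bipartition separates a given pair; at variable sites species are
#' fixed 0 vs 1 along the bipartition, so the expected per-pair mean absolute
#' frequency difference over all sites is `divergence` (attainable up to
#' `q(n)`, which is 1 for two species). Non-variable sites share a baseline
#' frequency across species (multicopy loci draw intermediate baselines,
#' folding paralog mixtures into the allele frequency). Chloroplast loci are
#' fixed haplotypes, distinct per species; SDR amplicons carry per-species X
#' frequencies and fixed Y haplotypes, with a fraction `xyDivergence` of
#' shared-region sites fixed between X (ref) and Y (alt) in every species.
#' Every species pair is guaranteed at least one diagnostic (fixed 0 vs 1)
#' site per amplicon, recorded in the diagnostics table.
#'
#' @param nSpecies number of species (>= 2).
#' @param variantsPerAmplicon integer, or named integer vector by amplicon.
#' @param divergence per-site expected frequency-difference scale in (0, 1].
#' @param seed integer seed; fixed seed gives identical profiles.
#' @param panel amplicon panel, see [defaultPanel()].
#' @param xyDivergence fraction of SDR shared-region sites fixed between the
#'   X and Y haplotypes in all species. Must be large relative to
#'   `divergence` for the SDR tree to split by sex before species, as
#'   observed for XY dioecious poplars (sex-first requires roughly
#'   `xyDivergence / (1 - xyDivergence) > 4 * divergence`).
#' @param yDivergence between-species differentiation of the Y haplotype
#'   (shared-region Y sites, the male-specific SDR portion and ARR17);
#'   smaller than autosomal `divergence`, reflecting the slowly diverging
#'   clonal Y lineage, yet sufficient for paternal-lineage tracing.
#' @return a `SpeciesProfiles` list: `species`, `panel`, `amplicons` (each
#'   with `positions`, `ref`, `alt`, `freq` matrix species x sites, `yhap`,
#'   `sexdiag`), `chloroHap`, `diagnostics` data.frame.
#' @export
simulateProfiles <- function(nSpecies = 2, variantsPerAmplicon = 20,
                             divergence = 0.5, seed = 1,
                             panel = defaultPanel(), xyDivergence = 0.8,
                             yDivergence = 0.1) {
  if (nSpecies < 2) .err("nSpecies must be >= 2", "amplitax_invalid_parameter")
  if (!is.numeric(divergence) || divergence <= 0 || divergence > 1)
    .err("divergence must lie in (0, 1]", "amplitax_invalid_parameter")
  if (xyDivergence < 0 || xyDivergence > 1)
    .err("xyDivergence must lie in [0, 1]", "amplitax_invalid_parameter")
  if (yDivergence <= 0 || yDivergence > 1)
    .err("yDivergence must lie in (0, 1]", "amplitax_invalid_parameter")
  species <- sprintf("sp%02d", seq_len(nSpecies))
  nv <- if (length(variantsPerAmplicon) == 1L && is.null(names(variantsPerAmplicon)))
    setNames(rep(as.integer(variantsPerAmplicon), nrow(panel)), panel$amplicon)
  else {
    miss <- setdiff(panel$amplicon, names(variantsPerAmplicon))
    if (length(miss))
      .err(sprintf("variantsPerAmplicon missing amplicons: %s",
                   paste(miss, collapse = ", ")), "amplitax_invalid_parameter")
    as.integer(variantsPerAmplicon[panel$amplicon])
  }
  nv <- setNames(as.integer(nv), panel$amplicon)
  if (any(nv < 1)) .err("variantsPerAmplicon must be >= 1", "amplitax_invalid_parameter")
  q <- .pairOppositeProb(nSpecies)
  f <- min(1, divergence / q)
  fY <- min(1, yDivergence / q)
  pairs <- utils::combn(nSpecies, 2)

  withr::with_seed(seed, {
    amplicons <- list()
    for (r in seq_len(nrow(panel))) {
      a <- panel$amplicon[r]; grp <- panel$group[r]; v <- nv[[a]]
      positions <- 10L * seq_len(v)
      isIndel <- seq_len(v) %% 8L == 0L
      ref <- rep("A", v)
      alt <- ifelse(isIndel, "AGT", "C")
      freq <- matrix(NA_real_, nSpecies, v, dimnames = list(species, NULL))
      yhap <- NULL
      sexdiag <- NULL
      ploidy <- .GROUP_PLOIDY[[grp]]
      maleSpec <- panel$male_specific[r]

      if (ploidy %in% c("diploid", "haploid_maternal")) {
        for (j in seq_len(v)) {
          if (runif(1) < f) {
            freq[, j] <- .randomBipartition(nSpecies)
          } else if (grp == "MULTICOPY_NUCLEAR") {
            freq[, j] <- runif(1)               # shared paralog-mixture baseline
          } else if (grp == "CHLOROPLAST") {
            freq[, j] <- as.numeric(runif(1) < 0.2)
          } else {
            freq[, j] <- if (runif(1) < 0.6) 0 else runif(1)
          }
        }
        # guarantee >= 1 diagnostic site per species pair on this amplicon
        for (p in seq_len(ncol(pairs))) {
          i <- pairs[1, p]; k <- pairs[2, p]
          if (!any(abs(freq[i, ] - freq[k, ]) == 1)) {
            j <- ((p - 1L) %% v) + 1L
            b <- numeric(nSpecies); b[k] <- 1
            freq[, j] <- b
          }
        }
      } else if (ploidy == "sex_linked" && !maleSpec) {
        # shared SDR region: X frequencies per species + fixed Y haplotypes
        sexdiag <- runif(v) < xyDivergence
        yhap <- matrix(0L, nSpecies, v, dimnames = list(species, NULL))
        for (j in seq_len(v)) {
          if (sexdiag[j]) {
            freq[, j] <- 0; yhap[, j] <- 1L     # X fixed ref, Y fixed alt
          } else {
            freq[, j] <- if (runif(1) < f) .randomBipartition(nSpecies)
                         else if (runif(1) < 0.6) 0 else runif(1)
            yhap[, j] <- if (runif(1) < fY) .randomBipartition(nSpecies) else 0L
          }
        }
        open <- which(!sexdiag)
        for (p in seq_len(ncol(pairs))) {
          i <- pairs[1, p]; k <- pairs[2, p]
          if (length(open) == 0L) break
          if (!any(abs(freq[i, open] - freq[k, open]) == 1)) {
            j <- open[((p - 1L) %% length(open)) + 1L]
            b <- numeric(nSpecies); b[k] <- 1
            freq[, j] <- b
          }
          if (!any(yhap[i, ] != yhap[k, ])) {
            j <- open[(p %% length(open)) + 1L]
            b <- integer(nSpecies); b[k] <- 1L
            yhap[, j] <- b
          }
        }
      } else {
        # male-specific amplicons: haploid Y content only
        yhap <- matrix(0L, nSpecies, v, dimnames = list(species, NULL))
        for (j in seq_len(v))
          if (runif(1) < fY) yhap[, j] <- .randomBipartition(nSpecies)
        for (p in seq_len(ncol(pairs))) {
          i <- pairs[1, p]; k <- pairs[2, p]
          if (!any(yhap[i, ] != yhap[k, ])) {
            j <- ((p - 1L) %% v) + 1L
            b <- integer(nSpecies); b[k] <- 1L
            yhap[, j] <- b
          }
        }
      }
      amplicons[[a]] <- list(group = grp, positions = positions, ref = ref,
                             alt = alt, freq = freq, yhap = yhap,
                             sexdiag = sexdiag, male_specific = maleSpec)
    }

    diagList <- list()
    for (a in names(amplicons)) {
      am <- amplicons[[a]]
      if (!.GROUP_PLOIDY[[am$group]] %in% c("diploid", "haploid_maternal")) next
      for (p in seq_len(ncol(pairs))) {
        i <- pairs[1, p]; k <- pairs[2, p]
        idx <- which(abs(am$freq[i, ] - am$freq[k, ]) == 1)
        if (length(idx))
          diagList[[length(diagList) + 1L]] <- data.frame(
            amplicon = a, group = am$group, index = idx,
            pos = am$positions[idx],
            species_a = species[i], species_b = species[k],
            stringsAsFactors = FALSE)
      }
    }
    diagnostics <- if (length(diagList)) do.call(rbind, diagList)
                   else data.frame(amplicon = character(), group = character(),
                                   index = integer(), pos = integer(),
                                   species_a = character(), species_b = character())

    structure(list(species = species, panel = panel, divergence = divergence,
                   xyDivergence = xyDivergence, yDivergence = yDivergence,
                   amplicons = amplicons,
                   chloroHap = setNames(seq_len(nSpecies), species),
                   diagnostics = diagnostics),
              class = "SpeciesProfiles")
  })
}

#' Describe a pedigree (a taxon's parental origin)
#'
#' @param taxon taxon id for samples of this pedigree.
#' @param type "species" (both gametes from one profile) or "F1".
#' @param mother,father species ids in the profiles; equal for type
#'   "species", distinct for "F1" (the mother contributes the chloroplast and
#'   one X; the father contributes an X to daughters and the Y to sons).
#' @return a `PedigreeSpec` list.
#' @export
pedigree <- function(taxon, type = c("species", "F1"), mother, father = mother) {
  type <- match.arg(type)
  if (type == "F1" && identical(mother, father))
    .err("F1 pedigree requires mother != father", "amplitax_invalid_parameter")
  if (type == "species" && !identical(mother, father))
    .err("species pedigree requires mother == father", "amplitax_invalid_parameter")
  structure(list(taxon = taxon, type = type, mother = mother, father = father),
            class = "PedigreeSpec")
}

#' Simulate one sample's true per-amplicon genotype
#'
#' Diploid loci draw one allele from the mother's and one from the father's
#' population frequencies; the chloroplast haplotype is copied from the
#' mother; on the shared SDR region a female carries a maternal and a
#' paternal X, a male a maternal X and the paternal Y; male-specific
#' amplicons are present (haploid paternal Y content) only in males.
#'
#' @param ped a [pedigree()] spec.
#' @param sex "male" or "female".
#' @param profiles a `SpeciesProfiles` object.
#' @param seed integer seed.
#' @return a `SampleGenotype` list: taxon, sex, mother, father, chloroHap,
#'   and per-amplicon `dosage` (true allele dosage in \[0, 1\]) and `present`.
#' @export
simulateSample <- function(ped, sex = c("female", "male"), profiles, seed = 1) {
  sex <- match.arg(sex)
  if (!ped$mother %in% profiles$species || !ped$father %in% profiles$species)
    .err(sprintf("pedigree '%s' references unknown species", ped$taxon),
         "amplitax_invalid_parameter")
  withr::with_seed(seed, {
    amps <- lapply(profiles$amplicons, function(am) {
      v <- length(am$positions)
      ploidy <- .GROUP_PLOIDY[[am$group]]
      if (ploidy == "diploid") {
        a1 <- rbinom(v, 1L, am$freq[ped$mother, ])
        a2 <- rbinom(v, 1L, am$freq[ped$father, ])
        list(dosage = (a1 + a2) / 2, present = TRUE)
      } else if (ploidy == "haploid_maternal") {
        list(dosage = am$freq[ped$mother, ], present = TRUE)
      } else if (am$male_specific) {
        if (sex == "male") list(dosage = as.numeric(am$yhap[ped$father, ]), present = TRUE)
        else list(dosage = rep(0, v), present = FALSE)
      } else {
        xm <- rbinom(v, 1L, am$freq[ped$mother, ])
        if (sex == "female") {
          xp <- rbinom(v, 1L, am$freq[ped$father, ])
          list(dosage = (xm + xp) / 2, present = TRUE)
        } else {
          list(dosage = (xm + am$yhap[ped$father, ]) / 2, present = TRUE)
        }
      }
    })
    structure(list(taxon = ped$taxon, sex = sex, mother = ped$mother,
                   father = ped$father,
                   chloroHap = unname(profiles$chloroHap[ped$mother]),
                   amplicons = amps),
              class = "SampleGenotype")
  })
}

# canonical row metadata for a profiles object: one row per variant allele,
# ordered by (group, amplicon, position); site id = chrom:pos
.panelInfo <- function(profiles) {
  panel <- profiles$panel
  ord <- order(match(panel$group, .GROUPS), panel$amplicon)
  rows <- lapply(ord, function(r) {
    a <- panel$amplicon[r]
    am <- profiles$amplicons[[a]]
    data.frame(amplicon = a, chrom = panel$chrom[r], pos = am$positions,
               ref = am$ref, alt = am$alt, group = panel$group[r],
               site = paste0(panel$chrom[r], ":", am$positions),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate read depths for one sample
#'
#' Applies the [depthModel()] to a true genotype: negative-binomial total
#' depth per site, binomial alternate reads at the true dosage, uniform stray
#' reads (at most `noiseFloor`, all reference-like) on absent amplicons, and
#' whole-amplicon dropout with probability `dropoutProb`.
#'
#' @param truth a `SampleGenotype` from [simulateSample()].
#' @param profiles the `SpeciesProfiles` the genotype was drawn from.
#' @param model a [depthModel()].
#' @param seed integer seed; identical seeds give identical tables.
#' @param sampleId sample id for the single column.
#' @return a single-sample [VariantTable-class].
#' @export
simulateDepths <- function(truth, profiles, model = depthModel(), seed = 1,
                           sampleId = "S1") {
  info <- .panelInfo(profiles)
  withr::with_seed(seed, {
    tot <- integer(0); altd <- integer(0)
    for (a in unique(info$amplicon)) {
      am <- truth$amplicons[[a]]
      v <- sum(info$amplicon == a)
      if (!am$present) {
        t_ <- pmin(as.integer(floor(runif(v, 0, model$noiseFloor + 1))),
                   model$noiseFloor)
        al <- integer(v)
      } else if (runif(1) < model$dropoutProb) {
        t_ <- integer(v); al <- integer(v)
      } else {
        t_ <- rnbinom(v, size = model$dispersion, mu = model$meanDepth)
        al <- rbinom(v, t_, am$dosage)
      }
      tot <- c(tot, t_); altd <- c(altd, al)
    }
    m <- function(x) matrix(as.integer(x), ncol = 1, dimnames = list(NULL, sampleId))
    VariantTable(info, refDepth = m(tot - altd), altDepth = m(altd),
                 siteDepth = m(tot))
  })
}

#' Configure a synthetic panel
#'
#' @param profiles a `SpeciesProfiles` object.
#' @param pedigrees data.frame with columns `taxon`, `type`, `mother`,
#'   `father`, `n` (samples) and `sex_ratio` (fraction male; male counts are
#'   rounded, sexes shuffled under the seed).
#' @param model a [depthModel()].
#' @param seed integer master seed; drives per-sample sub-seeds so identical
#'   configs give byte-identical outputs.
#' @return a `PanelConfig` list.
#' @export
panelConfig <- function(profiles, pedigrees, model = depthModel(), seed = 1) {
  need <- c("taxon", "type", "mother", "father", "n", "sex_ratio")
  if (!all(need %in% colnames(pedigrees)))
    .err(sprintf("pedigrees needs columns %s", paste(need, collapse = ", ")),
         "amplitax_invalid_parameter")
  if (anyDuplicated(pedigrees$taxon))
    .err("duplicate taxon ids would produce duplicate sample ids",
         "amplitax_invalid_parameter")
  for (r in seq_len(nrow(pedigrees)))
    pedigree(pedigrees$taxon[r], pedigrees$type[r], pedigrees$mother[r],
             pedigrees$father[r])   # validates
  if (any(pedigrees$n < 1)) .err("each taxon needs n >= 1", "amplitax_invalid_parameter")
  if (any(pedigrees$sex_ratio < 0 | pedigrees$sex_ratio > 1))
    .err("sex_ratio must lie in [0, 1]", "amplitax_invalid_parameter")
  structure(list(profiles = profiles, pedigrees = pedigrees, model = model,
                 seed = as.integer(seed)),
            class = "PanelConfig")
}

#' Simulate a full multi-sample panel
#'
#' Draws every sample's genotype and depths under the config's master seed
#' and assembles them into one [VariantTable-class] plus sample sheet, locus
#' group map and ground-truth table.
#'
#' @param config a [panelConfig()].
#' @return a `SimulatedPanel` list: `table` (VariantTable), `sampleSheet`,
#'   `groupMap`, `truth`, `diagnostics`, `profiles`, `config`.
#' @export
simulatePanel <- function(config) {
  stopifnot(inherits(config, "PanelConfig"))
  ped <- config$pedigrees
  nTot <- sum(ped$n)
  plan <- withr::with_seed(config$seed, {
    rows <- list()
    for (r in seq_len(nrow(ped))) {
      n <- ped$n[r]
      nMale <- round(ped$sex_ratio[r] * n)
      sexes <- sample(c(rep("male", nMale), rep("female", n - nMale)))
      rows[[r]] <- data.frame(
        sample_id = sprintf("%s_%02d", ped$taxon[r], seq_len(n)),
        taxon = ped$taxon[r], type = ped$type[r], mother = ped$mother[r],
        father = ped$father[r], sex = sexes, stringsAsFactors = FALSE)
    }
    plan <- do.call(rbind, rows)
    plan$geno_seed <- sample.int(.Machine$integer.max - 1L, nTot)
    plan$depth_seed <- sample.int(.Machine$integer.max - 1L, nTot)
    plan
  })
  info <- .panelInfo(config$profiles)
  nr <- nrow(info)
  mk <- function() matrix(NA_integer_, nr, nTot, dimnames = list(NULL, plan$sample_id))
  refD <- mk(); altD <- mk(); siteD <- mk()
  chl <- integer(nTot)
  for (i in seq_len(nTot)) {
    pd <- pedigree(plan$taxon[i], plan$type[i], plan$mother[i], plan$father[i])
    g <- simulateSample(pd, plan$sex[i], config$profiles, seed = plan$geno_seed[i])
    vt <- simulateDepths(g, config$profiles, config$model,
                         seed = plan$depth_seed[i], sampleId = plan$sample_id[i])
    refD[, i] <- assay(vt, "refDepth")[, 1]
    altD[, i] <- assay(vt, "altDepth")[, 1]
    siteD[, i] <- assay(vt, "siteDepth")[, 1]
    chl[i] <- g$chloroHap
  }
  table <- VariantTable(info, refD, altD, siteD)
  sampleSheet <- data.frame(sample_id = plan$sample_id, taxon = plan$taxon,
                            sex = plan$sex, region = "synthetic",
                            stringsAsFactors = FALSE)
  truth <- data.frame(sample_id = plan$sample_id, taxon = plan$taxon,
                      sex = plan$sex, mother = plan$mother, father = plan$father,
                      chloro_hap = chl, stringsAsFactors = FALSE)
  structure(list(table = table, sampleSheet = sampleSheet,
                 groupMap = config$profiles$panel[, c("amplicon", "chrom", "group")],
                 truth = truth, diagnostics = config$profiles$diagnostics,
                 profiles = config$profiles, config = config),
            class = "SimulatedPanel")
}

.fmtGt <- function(dp, ad) {
  if (dp == 0L) return(sprintf("./.:%d,%d:%d", ad[1], ad[2], dp))
  vaf <- ad[2] / dp
  gt <- if (vaf < 0.1) "0/0" else if (vaf > 0.9) "1/1" else "0/1"
  sprintf("%s:%d,%d:%d", gt, ad[1], ad[2], dp)
}

# write one VCFv4.2 file for a subset of rows of a VariantTable
.writeVcfFile <- function(table, rows, path) {
  rd <- rowData(table)[rows, , drop = FALSE]
  refD <- assay(table, "refDepth")[rows, , drop = FALSE]
  altD <- assay(table, "altDepth")[rows, , drop = FALSE]
  siteD <- assay(table, "siteDepth")[rows, , drop = FALSE]
  samples <- colnames(table)
  contigs <- unique(rd$chrom)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=amplitax-simulator",
           vapply(contigs, function(ct)
             sprintf("##contig=<ID=%s,length=%d>", ct,
                     max(rd$pos[rd$chrom == ct]) + 100L), character(1)),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  lines <- vapply(seq_along(rows), function(i) {
    cells <- vapply(seq_along(samples), function(s)
      .fmtGt(siteD[i, s], c(refD[i, s], altD[i, s])), character(1))
    paste(c(rd$chrom[i], rd$pos[i], ".", rd$ref[i], rd$alt[i], ".", ".", ".",
            "GT:AD:DP", cells), collapse = "\t")
  }, character(1))
  con <- tryCatch(file(path, "wb"),
                  error = function(e) .err(sprintf("cannot write '%s': %s",
                                                   path, conditionMessage(e)),
                                           "amplitax_io_error"))
  on.exit(close(con))
  writeLines(c(hdr, lines), con, sep = "\n")
  invisible(path)
}

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a simulated panel to disk
#'
#' Writes one VCFv4.2 file per amplicon (GT, AD, DP per sample), a
#' tab-separated sample sheet, locus-group map, ground-truth table and
#' diagnostic-site table, and optionally a merged multi-locus VCF. Identical
#' configurations (including seed) give byte-identical files.
#'
#' @param x a `SimulatedPanel` from [simulatePanel()], or a [panelConfig()]
#'   (simulated first).
#' @param outDir output directory, created if needed.
#' @param mergedVcf also write `panel_merged.vcf` containing every amplicon.
#' @return invisibly, a named list of written paths (`vcfs`, `sampleSheet`,
#'   `groupMap`, `truth`, `diagnostics`, and `mergedVcf` if requested).
#' @export
writePanel <- function(x, outDir, mergedVcf = FALSE) {
  if (inherits(x, "PanelConfig")) x <- simulatePanel(x)
  stopifnot(inherits(x, "SimulatedPanel"))
  if (!dir.exists(outDir) && !dir.create(outDir, recursive = TRUE))
    .err(sprintf("cannot create output directory '%s'", outDir), "amplitax_io_error")
  rd <- rowData(x$table)
  vcfs <- character(0)
  for (a in unique(rd$amplicon)) {
    p <- file.path(outDir, paste0(a, ".vcf"))
    .writeVcfFile(x$table, which(rd$amplicon == a), p)
    vcfs[a] <- p
  }
  paths <- list(
    vcfs = vcfs,
    sampleSheet = .writeTsv(x$sampleSheet, file.path(outDir, "sample_sheet.tsv")),
    groupMap = .writeTsv(x$groupMap, file.path(outDir, "locus_groups.tsv")),
    truth = .writeTsv(x$truth, file.path(outDir, "truth.tsv")),
    diagnostics = .writeTsv(x$diagnostics, file.path(outDir, "diagnostic_sites.tsv")))
  if (mergedVcf)
    paths$mergedVcf <- .writeVcfFile(x$table, seq_len(nrow(x$table)),
                                     file.path(outDir, "panel_merged.vcf"))
  invisible(paths)
}
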