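test_that("divergence outside (0,1] is rejected", {
  expect_error(simulateProfiles(2, 10, divergence = 0), class = "amplitax_invalid_parameter")
  expect_error(simulateProfiles(2, 10, divergence = 1.5), class = "amplitax_invalid_parameter")
  expect_error(simulateProfiles(1, 10, divergence = 0.5), class = "amplitax_invalid_parameter")
})

test_that("divergence 1 with two species makes every diploid site diagnostic, species A ref-fixed", {
  prof <- simulateProfiles(2, 10, divergence = 1.0, seed = 7)
  for (a in names(prof$amplicons)) {
    am <- prof$amplicons[[a]]
    ploidy <- c(MULTICOPY_NUCLEAR = "d", SINGLECOPY_NUCLEAR = "d", CHLOROPLAST = "d")[am$group]
    if (is.na(ploidy)) next
    expect_true(all(am$freq["sp01", ] == 0), info = a)
    expect_true(all(am$freq["sp02", ] == 1), info = a)
  }
})

test_that("realised pairwise divergence matches the requested scale", {
  prof <- simulateProfiles(3, 50, divergence = 0.5, seed = 1)
  dipAmps <- names(prof$amplicons)[vapply(prof$amplicons, function(am)
    am$group %in% c("MULTICOPY_NUCLEAR", "SINGLECOPY_NUCLEAR"), logical(1))]
  F <- do.call(cbind, lapply(prof$amplicons[dipAmps], `[[`, "freq"))
  for (p in list(c(1, 2), c(1, 3), c(2, 3))) {
    mdiff <- mean(abs(F[p[1], ] - F[p[2], ]))
    expect_gt(mdiff, 0.4); expect_lt(mdiff, 0.6)
  }
})

test_that("every species pair has a diagnostic site on every diploid/chloroplast amplicon", {
  prof <- simulateProfiles(4, 6, divergence = 0.2, seed = 3)
  dg <- prof$diagnostics
  for (a in names(prof$amplicons)) {
    grp <- prof$amplicons[[a]]$group
    if (!grp %in% c("MULTICOPY_NUCLEAR", "SINGLECOPY_NUCLEAR", "CHLOROPLAST")) next
    sub <- dg[dg$amplicon == a, ]
    pairs <- paste(sub$species_a, sub$species_b)
    expect_setequal(unique(pairs),
                    apply(utils::combn(prof$species, 2), 2, paste, collapse = " "))
  }
})

test_that("chloroplast haplotypes are distinct per species and maternally inherited", {
  prof <- simulateProfiles(3, 10, divergence = 0.3, seed = 5)
  cpAmps <- names(prof$amplicons)[vapply(prof$amplicons, function(am)
    am$group == "CHLOROPLAST", logical(1))]
  Fcp <- do.call(cbind, lapply(prof$amplicons[cpAmps], `[[`, "freq"))
  expect_false(any(duplicated(Fcp)))   # rows = species haplotype vectors
  ped <- pedigree("h", "F1", mother = "sp02", father = "sp03")
  g <- simulateSample(ped, "female", prof, seed = 11)
  expect_identical(g$chloroHap, unname(prof$chloroHap["sp02"]))
  for (a in cpAmps)
    expect_equal(g$amplicons[[a]]$dosage, unname(prof$amplicons[[a]]$freq["sp02", ]))
})

test_that("F1 dosage is exactly 0.5 at parent-diagnostic diploid sites", {
  prof <- simulateProfiles(2, 20, divergence = 0.8, seed = 2)
  ped <- pedigree("h", "F1", mother = "sp01", father = "sp02")
  g <- simulateSample(ped, "male", prof, seed = 4)
  dg <- prof$diagnostics
  dg <- dg[dg$group %in% c("MULTICOPY_NUCLEAR", "SINGLECOPY_NUCLEAR"), ]
  expect_gt(nrow(dg), 0)
  for (r in seq_len(nrow(dg)))
    expect_identical(g$amplicons[[dg$amplicon[r]]]$dosage[dg$index[r]], 0.5)
})

test_that("sex linkage: male-specific amplicons are absent in females, Y-typed in males", {
  prof <- simulateProfiles(2, 10, divergence = 0.5, seed = 9)
  ped <- pedigree("h", "F1", mother = "sp01", father = "sp02")
  f <- simulateSample(ped, "female", prof, seed = 1)
  m <- simulateSample(ped, "male", prof, seed = 1)
  for (a in c("SDR_malespec", "ARR17")) {
    expect_false(f$amplicons[[a]]$present)
    expect_true(all(f$amplicons[[a]]$dosage == 0))
    expect_true(m$amplicons[[a]]$present)
    expect_equal(m$amplicons[[a]]$dosage,
                 as.numeric(prof$amplicons[[a]]$yhap["sp02", ]))
  }
})

test_that("simulated depths recover the true dosage and respect the noise floor", {
  prof <- simulateProfiles(2, 200, divergence = 1.0, seed = 13,
                           panel = defaultPanel()[3, , drop = FALSE])  # one SC amplicon
  ped <- pedigree("h", "F1", mother = "sp01", father = "sp02")
  g <- simulateSample(ped, "female", prof, seed = 5)
  expect_true(all(g$amplicons[["DSH2"]]$dosage == 0.5))  # 200 diagnostic sites
  vt <- simulateDepths(g, prof, depthModel(meanDepth = 500, dropoutProb = 0), seed = 6)
  vaf <- SummarizedExperiment::assay(vt, "altDepth") /
    SummarizedExperiment::assay(vt, "siteDepth")
  expect_gt(mean(vaf), 0.47); expect_lt(mean(vaf), 0.53)

  gs <- simulateSample(pedigree("s", "species", "sp01"), "female", prof, seed = 5)
  vt0 <- simulateDepths(gs, prof, depthModel(noiseFloor = 0L, dropoutProb = 0), seed = 6)
  zero <- gs$amplicons[["DSH2"]]$dosage == 0
  expect_true(all(SummarizedExperiment::assay(vt0, "altDepth")[zero, ] == 0))
})

test_that("identical seeds give identical depth tables; different seeds differ", {
  prof <- simulateProfiles(2, 10, divergence = 0.5, seed = 1)
  g <- simulateSample(pedigree("s", "species", "sp01"), "male", prof, seed = 2)
  a <- simulateDepths(g, prof, seed = 3)
  b <- simulateDepths(g, prof, seed = 3)
  c <- simulateDepths(g, prof, seed = 4)
  expect_identical(SummarizedExperiment::assay(a, "siteDepth"),
                   SummarizedExperiment::assay(b, "siteDepth"))
  expect_false(identical(SummarizedExperiment::assay(a, "siteDepth"),
                         SummarizedExperiment::assay(c, "siteDepth")))
})

test_that("panel-wide maternal inheritance and sex linkage hold on a simulated panel", {
  pan <- smallPanel(seed = 21)
  expect_identical(pan$truth$chloro_hap,
                   unname(pan$profiles$chloroHap[pan$truth$mother]))
  cov <- coverageByAmplicon(pan$table)
  nf <- pan$config$model$noiseFloor
  msCov <- rowMeans(cov[, c("SDR_malespec", "ARR17")])
  expect_true(all(msCov[pan$truth$sex == "female"] <= nf))
  expect_true(all(msCov[pan$truth$sex == "male"] > nf))
})

test_that("writePanel emits re-readable files and validates duplicate taxa", {
  pan <- smallPanel(seed = 31, nPerTaxon = 2, variantsPerAmplicon = 4)
  td <- withr::local_tempdir()
  paths <- writePanel(pan, td, mergedVcf = TRUE)
  expect_length(paths$vcfs, 17)
  expect_true(all(file.exists(unlist(paths))))
  sheet <- readSampleSheet(paths$sampleSheet)
  expect_identical(sheet$sample_id, pan$sampleSheet$sample_id)
  gm <- readLocusMap(paths$groupMap)
  expect_identical(gm$amplicon, pan$groupMap$amplicon)
  # merged VCF reads back to the same table as the per-amplicon files
  tabM <- readVcfs(paths$mergedVcf, gm, sampleOrder = sheet$sample_id)
  tabP <- readVcfs(unname(paths$vcfs), gm, sampleOrder = sheet$sample_id)
  expect_equal(SummarizedExperiment::assay(tabM, "altDepth"),
               SummarizedExperiment::assay(tabP, "altDepth"))
  peds <- data.frame(taxon = c("A", "A"), type = "species", mother = "sp01",
                     father = "sp01", n = 2, sex_ratio = 0.5)
  expect_error(panelConfig(pan$profiles, peds), class = "amplitax_invalid_parameter")
})

test_that("same config gives byte-identical files, new seed changes genotypes not schema", {
  prof <- simulateProfiles(2, 4, divergence = 0.5, seed = 1)
  peds <- data.frame(taxon = c("A", "B"), type = "species",
                     mother = c("sp01", "sp02"), father = c("sp01", "sp02"),
                     n = 2, sex_ratio = 0.5)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir(); d3 <- withr::local_tempdir()
  writePanel(panelConfig(prof, peds, seed = 5), d1)
  writePanel(panelConfig(prof, peds, seed = 5), d2)
  writePanel(panelConfig(prof, peds, seed = 6), d3)
  f1 <- file.path(d1, "DSH2.vcf")
  expect_identical(unname(tools::md5sum(f1)),
                   unname(tools::md5sum(file.path(d2, "DSH2.vcf"))))
  expect_false(identical(unname(tools::md5sum(f1)),
                         unname(tools::md5sum(file.path(d3, "DSH2.vcf")))))
  h1 <- grep("^#", readLines(f1), value = TRUE)
  h3 <- grep("^#", readLines(file.path(d3, "DSH2.vcf")), value = TRUE)
  expect_identical(h1, h3)   # same schema
})
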