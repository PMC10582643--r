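makeTable <- function(ref, alt, site = NULL, group = "SINGLECOPY_NUCLEAR") {
  # one sample, rows as given; site groups rows of a multiallelic record
  n <- length(ref)
  if (is.null(site)) site <- seq_len(n)
  tot <- ave(alt, site, FUN = sum) + ref
  info <- data.frame(amplicon = "DSH2", chrom = "DSH2", pos = 10L * as.integer(site),
                     ref = "A", alt = paste0("C", seq_len(n)), group = group,
                     site = paste0("DSH2:", site))
  m <- function(x) matrix(as.integer(x), ncol = 1, dimnames = list(NULL, "S1"))
  VariantTable(info, m(ref), m(alt), m(tot))
}

test_that("VAF is alt depth over total site depth, with multiallelic sharing", {
  t1 <- makeTable(ref = 250, alt = 250)
  expect_identical(unname(SummarizedExperiment::assay(buildVaf(t1), "vaf")[1, 1]), 0.5)
  t2 <- makeTable(ref = c(100, 100), alt = c(50, 50), site = c(1, 1))
  v <- SummarizedExperiment::assay(buildVaf(t2), "vaf")
  expect_equal(unname(v[, 1]), c(0.25, 0.25))
})

test_that("sites below the depth threshold or excluded by coverage are missing", {
  t1 <- makeTable(ref = 5, alt = 5)
  expect_true(is.na(SummarizedExperiment::assay(buildVaf(t1, minSiteDepth = 20), "vaf")[1, 1]))
  expect_identical(unname(SummarizedExperiment::assay(buildVaf(t1, minSiteDepth = 10), "vaf")[1, 1]), 0.5)
  excl <- matrix(TRUE, 1, 1, dimnames = list("S1", "SINGLECOPY_NUCLEAR"))
  t2 <- makeTable(ref = 250, alt = 250)
  expect_true(is.na(SummarizedExperiment::assay(buildVaf(t2, exclusions = excl), "vaf")[1, 1]))
})

test_that("locus sets subset to the panel compositions and error when unknown/empty", {
  pan <- smallPanel(seed = 71, nPerTaxon = 2, variantsPerAmplicon = 4)
  vaf <- panelVaf(pan)
  expect_identical(nrow(subsetLoci(vaf, "all16")), nrow(vaf))
  cp <- subsetLoci(vaf, "chloroplast3")
  expect_setequal(unique(SummarizedExperiment::rowData(cp)$group), "CHLOROPLAST")
  expect_setequal(unique(SummarizedExperiment::rowData(cp)$amplicon),
                  c("trnG_psbK_psbI", "rps2_rpoC2", "rpoC2_rpoC1"))
  n11 <- subsetLoci(vaf, "nuclear11")
  expect_setequal(unique(SummarizedExperiment::rowData(n11)$group),
                  c("MULTICOPY_NUCLEAR", "SINGLECOPY_NUCLEAR"))
  t14 <- subsetLoci(vaf, "traditional14")
  expect_identical(nrow(t14), nrow(n11) + nrow(cp))
  expect_error(subsetLoci(vaf, "nonsense"), class = "amplitax_invalid_parameter")
})

test_that("worked distance examples match the closed-form values", {
  X <- rbind(a = c(0, 0.5, 1), b = c(1, 0.5, 0))
  d <- euclideanDistances(vafFromMatrix(X))
  expect_equal(distanceMatrix(d)["a", "b"], sqrt(2), tolerance = 1e-12)
  Y <- rbind(a = c(0.5, NA, 1), b = c(0.5, 0.2, 0))
  d2 <- euclideanDistances(vafFromMatrix(Y))
  expect_equal(distanceMatrix(d2)["a", "b"], sqrt(3 / 2), tolerance = 1e-12)
  Z <- rbind(a = c(0.1, 0.9), b = c(0.1, 0.9))
  expect_identical(distanceMatrix(euclideanDistances(vafFromMatrix(Z)))["a", "b"], 0)
})

test_that("distances agree with the brute-force oracle and stats::dist on complete and missing data", {
  for (seed in 1:10) {
    X <- randomVafMatrix(sample(3:12, 1), sample(2:30, 1),
                         missingFrac = ifelse(seed %% 2, 0, 0.2), seed = seed)
    d <- suppressWarnings(distanceMatrix(euclideanDistances(vafFromMatrix(X))))
    expect_equal(d, bruteEuclidean(X), tolerance = 1e-12)
    ref <- as.matrix(stats::dist(X))        # same M/m rescaling convention
    expect_equal(unname(d), unname(ref), tolerance = 1e-12)
  }
})

test_that("duplicating every column scales complete-data distances by sqrt(2)", {
  X <- randomVafMatrix(6, 9, seed = 3)
  d1 <- distanceMatrix(euclideanDistances(vafFromMatrix(X)))
  d2 <- distanceMatrix(euclideanDistances(vafFromMatrix(cbind(X, X))))
  expect_equal(d2, sqrt(2) * d1, tolerance = 1e-12)
})

test_that("group weighting equalizes locus-group contributions", {
  # two groups with 1 and 4 columns of identical per-column signal: weighted
  # distance gives both groups equal weight
  X <- rbind(a = rep(0, 5), b = rep(1, 5))
  nc <- 5L
  info <- S4Vectors::DataFrame(
    amplicon = c("trnG_psbK_psbI", rep("DSH2", 4)),
    chrom = c("trnG_psbK_psbI", rep("DSH2", 4)),
    pos = seq_len(nc) * 10L, alt = rep("C", nc), ref = rep("A", nc),
    group = c("CHLOROPLAST", rep("SINGLECOPY_NUCLEAR", 4)),
    site = paste0("s", seq_len(nc)))
  vaf <- new("VafMatrix", SummarizedExperiment::SummarizedExperiment(
    assays = list(vaf = t(X)), rowData = info))
  plain <- distanceMatrix(euclideanDistances(vaf))["a", "b"]
  expect_equal(plain, sqrt(5), tolerance = 1e-12)
  wtd <- distanceMatrix(euclideanDistances(vaf, weightByGroup = TRUE))["a", "b"]
  expect_equal(wtd, sqrt(2), tolerance = 1e-12)   # 1/1 + 4 * (1/4)
})

test_that("pairs sharing no columns are NA with a warning; all-missing samples flagged", {
  X <- rbind(a = c(0.2, NA), b = c(NA, 0.4), c = c(0.5, 0.5))
  expect_warning(d <- euclideanDistances(vafFromMatrix(X)), "no observed columns")
  expect_true(is.na(distanceMatrix(d)["a", "b"]))
  expect_false(is.na(distanceMatrix(d)["a", "c"]))
  Y <- rbind(a = c(NA_real_, NA_real_), b = c(0.1, 0.2), c = c(0.3, 0.4))
  expect_warning(dy <- euclideanDistances(vafFromMatrix(Y)), "no observed VAF")
  expect_true(all(is.na(distanceMatrix(dy)["a", c("b", "c")])))
  expect_identical(distanceMatrix(dy)["a", "a"], 0)
})

test_that("group mean distance averages defined pairs; within-group excludes the diagonal", {
  m <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  m["a", "c"] <- m["c", "a"] <- 1; m["a", "d"] <- m["d", "a"] <- 2
  m["b", "c"] <- m["c", "b"] <- 3; m["b", "d"] <- m["d", "b"] <- 4
  d <- SampleDistanceMatrix(m, "test")
  expect_identical(groupMeanDistance(d, c("a", "b"), c("c", "d")), 2.5)
  expect_identical(groupMeanDistance(d, "a", "c"), 1)
  expect_identical(groupMeanDistance(d, c("a", "b")), 0)   # within-group
  expect_error(groupMeanDistance(d, c("a", "b"), c("b", "c")),
               class = "amplitax_invalid_parameter")
  mNA <- m; mNA["a", "c"] <- mNA["c", "a"] <- NA
  dNA <- SampleDistanceMatrix(mNA, "test")
  expect_error(groupMeanDistance(dNA, "a", "c"), class = "amplitax_no_defined_pairs")
})

test_that("distance matrices round-trip through the TSV writer at 6 decimals", {
  X <- randomVafMatrix(5, 7, seed = 4)
  d <- euclideanDistances(vafFromMatrix(X), label = "t")
  td <- withr::local_tempdir()
  p <- writeDistanceMatrix(d, file.path(td, "d.tsv"))
  d2 <- readDistanceMatrix(p, "t")
  expect_equal(distanceMatrix(d2), distanceMatrix(d), tolerance = 1e-6)
})

test_that("clonal replicates sit far below between-taxon distances", {
  prof <- simulateProfiles(2, 20, divergence = 0.5, seed = 81)
  gA <- simulateSample(pedigree("A", "species", "sp01"), "female", prof, seed = 1)
  gB <- simulateSample(pedigree("B", "species", "sp02"), "female", prof, seed = 2)
  model <- depthModel(dropoutProb = 0)
  cols <- list()
  for (i in 1:3) cols[[paste0("A_cl", i)]] <- simulateDepths(gA, prof, model, seed = 100 + i, sampleId = paste0("A_cl", i))
  for (i in 1:3) cols[[paste0("B_cl", i)]] <- simulateDepths(gB, prof, model, seed = 200 + i, sampleId = paste0("B_cl", i))
  ref <- do.call(cbind, lapply(cols, SummarizedExperiment::assay, i = "refDepth"))
  alt <- do.call(cbind, lapply(cols, SummarizedExperiment::assay, i = "altDepth"))
  tot <- do.call(cbind, lapply(cols, SummarizedExperiment::assay, i = "siteDepth"))
  tab <- VariantTable(SummarizedExperiment::rowData(cols[[1]]), ref, alt, tot)
  d <- distanceMatrix(euclideanDistances(subsetLoci(buildVaf(tab), "traditional14")))
  clones <- mean(c(d["A_cl1", "A_cl2"], d["A_cl1", "A_cl3"], d["A_cl2", "A_cl3"]))
  between <- mean(d[paste0("A_cl", 1:3), paste0("B_cl", 1:3)])
  expect_lt(clones, between / 5)
})
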