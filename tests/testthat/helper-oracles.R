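# Independent oracles and small fixture builders, kept deliberately naive and
# separate from the package implementation paths they check.

# brute-force pairwise-complete Euclidean distance with M/m rescaling
bruteEuclidean <- function(X) {
  n <- nrow(X); M <- ncol(X)
  d <- matrix(0, n, n, dimnames = list(rownames(X), rownames(X)))
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b) next
    shared <- which(!is.na(X[a, ]) & !is.na(X[b, ]))
    if (!length(shared)) { d[a, b] <- NA_real_; next }
    ss <- 0
    for (j in shared) ss <- ss + (X[a, j] - X[b, j])^2
    d[a, b] <- sqrt(M / length(shared) * ss)
  }
  d
}

# from-scratch Ward.D2 agglomerator: squared-distance Lance-Williams update,
# heights reported on the distance scale
naiveWard <- function(D) {
  n <- nrow(D)
  labels <- rownames(D); if (is.null(labels)) labels <- paste0("S", seq_len(n))
  cur <- D^2
  members <- as.list(labels)
  sizes <- rep(1, n)
  heights <- numeric(n - 1); mergedSets <- vector("list", n - 1)
  for (s in seq_len(n - 1)) {
    k <- nrow(cur)
    bestVal <- Inf; bi <- bj <- NA
    for (i in seq_len(k - 1)) for (j in seq((i + 1), k))
      if (cur[i, j] < bestVal) { bestVal <- cur[i, j]; bi <- i; bj <- j }
    heights[s] <- sqrt(bestVal)
    ni <- sizes[bi]; nj <- sizes[bj]
    newRow <- vapply(seq_len(k), function(l) {
      if (l == bi || l == bj) return(0)
      nl <- sizes[l]
      ((ni + nl) * cur[bi, l] + (nj + nl) * cur[bj, l] - nl * bestVal) /
        (ni + nj + nl)
    }, numeric(1))
    newMembers <- sort(c(members[[bi]], members[[bj]]))
    keep <- setdiff(seq_len(k), c(bi, bj))
    cur <- rbind(cbind(cur[keep, keep, drop = FALSE], newRow[keep]),
                 c(newRow[keep], 0))
    members <- c(members[keep], list(newMembers))
    sizes <- c(sizes[keep], ni + nj)
    mergedSets[[s]] <- newMembers
  }
  list(heights = heights, members = mergedSets)
}

# per-merge-step member sets of a LinkageTree, for comparison with naiveWard
linkageMembers <- function(tree) {
  lab <- labels(tree); m <- tree@merge
  out <- vector("list", nrow(m))
  getm <- function(x) if (x < 0) lab[-x] else out[[x]]
  for (s in seq_len(nrow(m))) out[[s]] <- sort(c(getm(m[s, 1]), getm(m[s, 2])))
  out
}

# wrap a plain samples x columns matrix as a VafMatrix with dummy metadata
vafFromMatrix <- function(X, group = "SINGLECOPY_NUCLEAR") {
  nc <- ncol(X)
  info <- S4Vectors::DataFrame(
    amplicon = rep("DSH2", nc), chrom = rep("DSH2", nc),
    pos = seq_len(nc) * 10L, alt = rep("C", nc), ref = rep("A", nc),
    group = rep(group, nc), site = paste0("DSH2:", seq_len(nc) * 10L))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(vaf = t(X)), rowData = info)
  new("VafMatrix", se)
}

randomVafMatrix <- function(nSamples, nCols, missingFrac = 0, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(runif(nSamples * nCols), nSamples, nCols,
                dimnames = list(sprintf("S%02d", seq_len(nSamples)), NULL))
    if (missingFrac > 0)
      X[sample(length(X), round(missingFrac * length(X)))] <- NA
    X
  })
}

# distance matrix with fixed values for decision-rule tests: one hybrid
# sample plus one sample per candidate, at stated hybrid-candidate distances
decisionMatrix <- function(hybridDist, locusSet = "test") {
  ids <- c("hyb", names(hybridDist))
  m <- matrix(2.0, length(ids), length(ids), dimnames = list(ids, ids))
  diag(m) <- 0
  m["hyb", names(hybridDist)] <- hybridDist
  m[names(hybridDist), "hyb"] <- hybridDist
  SampleDistanceMatrix(m, locusSet = locusSet)
}

# small three-species panel (two parents + outgroup) with one F1 hybrid taxon
smallPanel <- function(seed = 1, nPerTaxon = 4, variantsPerAmplicon = 10,
                       divergence = 0.5, dropoutProb = 0, meanDepth = 500,
                       hybridMother = "sp01", hybridFather = "sp02",
                       noiseFloor = 2L) {
  prof <- simulateProfiles(nSpecies = 3, variantsPerAmplicon = variantsPerAmplicon,
                           divergence = divergence, seed = seed)
  peds <- data.frame(
    taxon = c("A", "B", "O", "hyb"),
    type = c("species", "species", "species",
             if (identical(hybridMother, hybridFather)) "species" else "F1"),
    mother = c("sp01", "sp02", "sp03", hybridMother),
    father = c("sp01", "sp02", "sp03", hybridFather),
    n = nPerTaxon, sex_ratio = 0.5, stringsAsFactors = FALSE)
  cfg <- panelConfig(prof, peds,
                     depthModel(meanDepth = meanDepth, dropoutProb = dropoutProb,
                                noiseFloor = noiseFloor),
                     seed = seed + 1000L)
  simulatePanel(cfg)
}

panelVaf <- function(pan, minSiteDepth = 20) {
  cov <- coverageByAmplicon(pan$table)
  flags <- flagLowCoverage(cov, pan$groupMap)
  buildVaf(pan$table, minSiteDepth, exclusions = flags)
}
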