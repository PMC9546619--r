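test_that("generateTruth is seeded-deterministic and honours fixed values", {
  cfg <- defaultTruthConfig()
  t1 <- generateTruth(cfg, seed = 11)
  t2 <- generateTruth(cfg, seed = 11)
  expect_identical(truthCopies(t1), truthCopies(t2))
  expect_identical(boundPerReceptor(t1), boundPerReceptor(t2))
  expect_equal(truthCopies(t1)[["TNFR1"]], 25000)

  # members without fixed copies are drawn from the configured range,
  # deterministically per seed
  cfg2 <- cfg
  cfg2$copiesPerCell <- cfg$copiesPerCell[
    setdiff(names(cfg$copiesPerCell), "CYLD")]
  cfg2$copiesRange <- c(1e3, 1e6)
  d1 <- generateTruth(cfg2, seed = 3)
  d2 <- generateTruth(cfg2, seed = 3)
  expect_identical(truthCopies(d1)[["CYLD"]], truthCopies(d2)[["CYLD"]])
  expect_gte(truthCopies(d1)[["CYLD"]], 1e3)
  expect_lte(truthCopies(d1)[["CYLD"]], 1e6)
  cfg2$copiesRange <- c(10, 1)
  expect_error(generateTruth(cfg2, 1), "min exceeds max")

  # receptor without a copy number is an error
  cfg3 <- cfg
  cfg3$copiesPerCell <- cfg$copiesPerCell[
    setdiff(names(cfg$copiesPerCell), "TNFR1")]
  cfg3$copiesRange <- NULL
  expect_error(generateTruth(cfg3, 1), "TNFR1")

  # non-receptor proteins are unbound at time 0, receptor bound at its
  # oligomer count, and recruitment peaks at 10 min
  b <- boundPerReceptor(t1)
  expect_true(all(b$bound[b$timepoint == 0 & b$protein_id != "TNFR1"] == 0))
  expect_true(all(b$bound[b$protein_id == "TNFR1"] == 3))
  for (p in c("RIPK1", "CYLD", "UBC")) {
    bp <- b[b$protein_id == p, ]
    expect_equal(bp$timepoint[which.max(bp$bound)], 10)
  }
})

test_that("the noiseless lysate simulator reproduces amounts exactly and censors below LOD", {
  tr <- singleProteinTruth(noiseCv = 0)
  sim <- simulateLysateQuant(tr, nReplicates = 2, peptidesPerProtein = 3,
                             timepoints = 0, cellEquivalents = 3043,
                             seed = 5)
  true_amol <- 1e5 * 3043 / avogadroConstant() * 1e18
  ratio <- sim$peptides$endogenous_intensity /
    sim$peptides$reference_intensity
  expect_equal(ratio * sim$peptides$spike_amount_amol,
               rep(true_amol, nrow(sim$peptides)))
  expect_equal(nrow(sim$peptides), 2 * 3)
  expect_true(all(sim$meta$sample_type == "lysate"))

  # below-LOD protein: rows omitted entirely
  cfg <- list(
    complexes = ComplexSet(
      ComplexDefinition("solo", c(X = 1), receptorFlag = TRUE,
                        receptorOligomer = 1L)),
    copiesPerCell = c(X = 1e5, FAINT = 1),
    timepoints = 0, noiseCv = 0, responseFactorSigma = 0, lodAmol = 0.5)
  trc <- generateTruth(cfg, 1)
  simc <- simulateLysateQuant(trc, nReplicates = 1, timepoints = 0,
                              cellEquivalents = 3043, seed = 1)
  expect_false("FAINT" %in% simc$peptides$protein_id)
  expect_true("X" %in% simc$peptides$protein_id)

  expect_error(simulateLysateQuant(tr, peptidesPerProtein = 0),
               "peptidesPerProtein")
})

test_that("simulated ratio noise has the configured CV", {
  tr <- singleProteinTruth(noiseCv = 0.2)
  sim <- simulateLysateQuant(tr, nReplicates = 1000,
                             peptidesPerProtein = 1, timepoints = 0,
                             cellEquivalents = 3043, seed = 42)
  est <- quantifyPeptideAmount(sim$peptides$endogenous_intensity,
                               sim$peptides$reference_intensity,
                               sim$peptides$spike_amount_amol)
  cv <- sd(est) / mean(est)
  expect_gt(cv, 0.18)
  expect_lt(cv, 0.22)
})

test_that("AP simulation is zero for non-receptor proteins at t = 0 and closes the loop noiselessly", {
  tr <- noiselessTruth()
  ap <- simulateApQuant(tr, nReplicates = 1, seed = 9)
  p0 <- ap$peptides[ap$peptides$sample_id == "ap_t00_r1", ]
  nonzero <- unique(p0$protein_id[p0$endogenous_intensity > 0])
  expect_equal(nonzero, "TNFR1")

  # quantify + context recovers bound-per-receptor exactly
  amounts <- suppressWarnings(quantifyProteins(ap$peptides))
  est <- apBoundPerReceptor(amounts, ap$meta, receptor = "TNFR1")
  truth <- boundPerReceptor(tr)
  m <- merge(est, truth, by = c("protein_id", "timepoint"),
             suffixes = c("_est", "_true"))
  expect_equal(m$bound_est, m$bound_true, tolerance = 1e-12)

  expect_error(simulateApQuant(tr, timepoints = c(-1, 0)), "negative")
})

test_that("BNPAGE simulation produces well-trapped -DUB and periodic +DUB profiles", {
  tr <- noiselessTruth()
  prof <- simulateBnpageProfiles(tr, nFractions = 70, period = 10,
                                 wellFractions = 3, noise = 0, seed = 2)
  minus <- profilesToMatrix(prof, "minusDUB")
  plus <- profilesToMatrix(prof, "plusDUB")
  # zero noise: all -DUB signal in the well fractions
  expect_equal(colSums(minus[1:3, ]) / colSums(minus),
               setNames(rep(1, ncol(minus)), colnames(minus)))
  # +DUB local maxima exactly at the ladder positions
  pk <- detectPeaksAndPeriodicity(normalizeProfileMax(plus[, 1]))
  expect_equal(pk$peak_indices, c(10, 20, 30))

  # seeded rerun gives identical tables
  prof2 <- simulateBnpageProfiles(tr, nFractions = 70, period = 10,
                                  wellFractions = 3, noise = 0, seed = 2)
  expect_identical(prof, prof2)

  expect_error(simulateBnpageProfiles(tr, nFractions = 20, period = 25),
               "period")
})

test_that("ground truth exports to JSON for use as an oracle", {
  tr <- singleProteinTruth(noiseCv = 0.1)
  path <- withr::local_tempfile(fileext = ".json")
  writeTruth(tr, path)
  js <- jsonlite::read_json(path)
  expect_equal(js$copies_per_cell$X, 1e5)
  expect_equal(js$noise_cv, 0.1)
  expect_equal(js$seed, 1L)
})
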