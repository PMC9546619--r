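test_that("relative stoichiometry normalises to the reference member", {
  cd <- ComplexDefinition("demo", c(A = 1, B = 1, C = 1))
  rs <- relativeStoichiometry(cd, c(A = 100, B = 50, C = 100))
  # tie at 100 between A and C: earliest member in the definition wins
  expect_equal(rs$reference_member, "A")
  expect_equal(rs$ratios, c(A = 1, B = 0.5, C = 1))

  # fixed-reference policy: BIRC2 at 0.22 of the RIPK1 anchor
  core <- ComplexDefinition("core", c(RIPK1 = 3, BIRC2 = 1),
                            referencePolicy = "fixed:RIPK1")
  rs2 <- relativeStoichiometry(core, c(RIPK1 = 300, BIRC2 = 66))
  expect_equal(rs2$ratios[["BIRC2"]], 0.22)

  # missing member -> NA ratio, reported
  rs3 <- relativeStoichiometry(cd, c(A = 100, C = 25))
  expect_true(is.na(rs3$ratios[["B"]]))
  expect_equal(rs3$missing, "B")

  # scale invariance: amounts in any common unit give the same ratios
  amt <- c(A = 37, B = 91, C = 12)
  expect_equal(relativeStoichiometry(cd, amt)$ratios,
               relativeStoichiometry(cd, 1e6 * amt)$ratios)

  expect_error(relativeStoichiometry(cd, c(A = 0, B = 0, C = 0)),
               "undefined stoichiometry")
  expect_error(
    relativeStoichiometry(cd, c(A = 1, C = 1), policy = "fixed:B"),
    "absent or zero")
})

test_that("integer stoichiometry fitting recovers known architectures", {
  # clean 1:2:2 observed as (0.5, 1, 1): core 1:1:1 with one excess
  # copy each of the last two subunits wins at zero error
  fit <- fitIntegerStoichiometry(c(HOIP = 0.5, HOIL1 = 1, SHARPIN = 1))
  top <- fit[1, ]
  expect_equal(top$fit_error, 0)
  expect_equal(unlist(top[paste0("base_", c("HOIP", "HOIL1", "SHARPIN"))],
                      use.names = FALSE), c(1, 1, 1))
  expect_equal(unlist(top[paste0("excess_",
                                 c("HOIP", "HOIL1", "SHARPIN"))],
                      use.names = FALSE), c(0, 1, 1))
  expect_equal(unlist(top[paste0("pred_", c("HOIP", "HOIL1", "SHARPIN"))],
                      use.names = FALSE), c(0.5, 1, 1))

  # exact simple ratios without excess
  fit2 <- fitIntegerStoichiometry(c(A = 1, B = 1), allowExcess = FALSE)
  expect_equal(unlist(fit2[1, c("base_A", "base_B")], use.names = FALSE),
               c(1, 1))
  expect_equal(fit2[1, "fit_error"], 0)
  fit3 <- fitIntegerStoichiometry(c(A = 1, B = 0.5, C = 0.5),
                                  allowExcess = FALSE)
  expect_equal(unlist(fit3[1, paste0("base_", c("A", "B", "C"))],
                      use.names = FALSE), c(2, 1, 1))

  # ranking: ties in error break towards fewer total copies
  expect_true(all(diff(fit$fit_error) >= 0))
  expect_error(fitIntegerStoichiometry(c(A = 1)), "at least 2")
  expect_error(fitIntegerStoichiometry(c(A = 1, B = 1), maxCopies = 0),
               "maxCopies")
})

test_that("the integer fit matches an independent brute-force oracle", {
  set.seed(202)
  for (n in 2:3) {
    for (rep in 1:6) {
      obs <- setNames(2^runif(n, -2, 0), LETTERS[seq_len(n)])
      obs <- obs / max(obs)
      got <- fitIntegerStoichiometry(obs, maxCopies = 4)[1, "fit_error"]
      expect_equal(got, bruteForceBestError(obs, 4, TRUE),
                   tolerance = 1e-12)
      got_ne <- fitIntegerStoichiometry(obs, maxCopies = 4,
                                        allowExcess = FALSE)[1, "fit_error"]
      expect_equal(got_ne, bruteForceBestError(obs, 4, FALSE),
                   tolerance = 1e-12)
    }
  }

  # round trip: every max-normalised integer vector is refit at zero error
  for (truth in list(c(3, 1), c(2, 2, 1), c(4, 2, 1), c(1, 1, 1))) {
    obs <- setNames(truth / max(truth), LETTERS[seq_along(truth)])
    expect_equal(fitIntegerStoichiometry(obs)[1, "fit_error"], 0)
  }
})

test_that("occupancy and complex-bound fractions cover the sub- and super-stoichiometric regimes", {
  expect_equal(occupancyFraction(100, 5), 0.05)
  expect_equal(occupancyFraction(100, 250), 2.5)
  expect_equal(occupancyFraction(100, 0), 0)
  expect_equal(occupancyFraction(100, 50, interactor_multiplicity = 2),
               0.25)
  expect_error(occupancyFraction(0, 5), "bait_amount")

  bf <- complexBoundFraction(100, 22)
  expect_equal(bf$fraction, 0.22)
  expect_false(bf$over_unity)
  expect_equal(complexBoundFraction(100, 100)$fraction, 1)
  expect_true(complexBoundFraction(100, 130)$over_unity)
  expect_error(complexBoundFraction(0, 5), "carrier")
})

test_that("recruitment time courses normalise to the receptor with maximum 1", {
  nt <- normalizeTimecourse(c(10, 40, 80, 60), c(10, 20, 40, 60),
                            c(0, 5, 10, 15))
  expect_equal(nt$values, c(0.5, 1, 1, 0.5))
  expect_equal(nt$timepoints, c(0, 5, 10, 15))

  # analyte proportional to receptor -> flat at 1
  expect_equal(normalizeTimecourse(c(5, 10, 20), c(50, 100, 200))$values,
               rep(1, 3))
  # invariant to rescaling the receptor series
  a <- c(3, 9, 27, 9); r <- c(1, 2, 3, 4)
  expect_equal(normalizeTimecourse(a, r)$values,
               normalizeTimecourse(a, 7 * r)$values)
  # zero amounts pass through as zero even at zero receptor
  expect_equal(normalizeTimecourse(c(0, 10), c(0, 10))$values, c(0, 1))
  expect_warning(z <- normalizeTimecourse(c(0, 0), c(1, 1)), "all-zero")
  expect_equal(z$values, c(0, 0))
  expect_error(normalizeTimecourse(c(1, 2), c(1, 0)), "receptor")
})

test_that("profile clustering groups proteins by recruitment shape", {
  tp <- c(0, 5, 10, 15)
  early <- function(s) s * c(0, 1, 0.9, 0.7)
  mid <- function(s) s * c(0, 0.4, 1, 0.8)
  late <- function(s) s * c(0, 0.1, 0.6, 1)
  profiles <- rbind(
    e1 = early(1), e2 = early(5), e3 = early(0.2),
    m1 = mid(1), m2 = mid(3),
    l1 = late(1), l2 = late(10))
  cl <- clusterProfiles(profiles, k = 3)
  expect_equal(unname(cl[c("e1", "e2", "e3")]), rep(1L, 3))
  expect_equal(unname(cl[c("m1", "m2")]), rep(2L, 2))
  expect_equal(unname(cl[c("l1", "l2")]), rep(3L, 2))

  # duplicated profiles always share a label; k = n separates the rest
  cl2 <- clusterProfiles(profiles[c("e1", "m1", "l1"), ], k = 3)
  expect_equal(length(unique(cl2)), 3)

  # zero-variance profile -> singleton class after k, with a warning
  withflat <- rbind(profiles, flat = rep(2, 4))
  expect_warning(cl3 <- clusterProfiles(withflat, k = 3),
                 "zero-variance")
  expect_equal(unname(cl3[["flat"]]), 4L)
  expect_equal(cl3[rownames(profiles)], cl)

  expect_error(clusterProfiles(profiles[1:2, ], k = 3), "fewer")
})
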