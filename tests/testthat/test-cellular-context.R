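test_that("mass, cell-equivalent and molecule conversions give the expected magnitudes", {
  # 4.1 mg from 1.8e7 cells ~ 228 pg of protein per cell
  expect_equal(proteinMassPerCell(4.1, 1.8e7), 4.1e9 / 1.8e7)
  expect_equal(proteinMassPerCell(4.1, 1.8e7), 227.8, tolerance = 1e-3)
  # 100 ug at 230 pg/cell ~ 435,000 cell equivalents
  expect_equal(cellEquivalents(100, 230), 1e8 / 230)
  expect_equal(cellEquivalents(100, 230), 434783, tolerance = 1e-5)
  # 0.7 % injected ~ 3,043 cells on column
  expect_equal(injectedCellEquivalents(434783, 0.007), 3043.5,
               tolerance = 1e-4)
  # one zeptomole is ~602 molecules
  expect_equal(amountToMolecules(1e-21), 6.02214076e23 * 1e-21)
  expect_equal(amountToMolecules(1e-21), 602.2, tolerance = 1e-3)
  expect_error(proteinMassPerCell(0, 1), "> 0")
  expect_error(injectedCellEquivalents(1000, 1.5), "injected_fraction")
})

test_that("copies per cell follow from amount, Avogadro's number and cell equivalents", {
  # direct arithmetic oracle, written independently of the implementation
  oracle <- function(amol, cells) amol * 1e-18 * 6.02214076e23 / cells
  expect_equal(copiesPerCell(126, 3043), oracle(126, 3043))
  expect_equal(copiesPerCell(126, 3043), 24937, tolerance = 1e-4)
  expect_equal(copiesPerCell(0, 3043), 0)
  expect_error(copiesPerCell(1, 0), "cell_equivalents")

  # calibrant ruler: copies scale with the amount ratio
  expect_equal(translateCopiesViaCalibrant(25000, 2, 1), 50000)
  expect_equal(translateCopiesViaCalibrant(25000, 1, 1), 25000)
  expect_equal(translateCopiesViaCalibrant(25000, 0.36, 1), 9000)
  expect_error(translateCopiesViaCalibrant(25000, 1, 0),
               "calibrant_amount")

  # ruler is consistent with the direct route when both are available
  cells <- 3043
  cal_amol <- 25000 * cells / 6.02214076e23 * 1e18
  prot_amol <- 9000 * cells / 6.02214076e23 * 1e18
  expect_equal(translateCopiesViaCalibrant(25000, prot_amol, cal_amol),
               copiesPerCell(prot_amol, cells))
})

test_that("complex counts per cell are set by the scarcest member", {
  cd <- ComplexDefinition("XY", c(X = 2, Y = 2))
  expect_equal(complexesPerCell(c(X = 200, Y = 50), cd), 25)
  expect_equal(complexesPerCell(c(X = 200, Y = 200), cd), 100)
  expect_warning(n0 <- complexesPerCell(c(X = 200), cd), "absent")
  expect_equal(n0, 0)

  # brute-force check: the count floors integer assembly
  set.seed(7)
  for (i in 1:10) {
    cp <- c(X = sample(1:500, 1), Y = sample(1:500, 1))
    n <- complexesPerCell(cp, cd)
    expect_true(all(floor(n) * members(cd) <= cp))
    expect_false(all((floor(n) + 1) * members(cd) <= cp))
  }

  # isostoichiometry requirement: one complex per receptor trimer
  cs <- ComplexDefinition("CYLD-SPATA2", c(CYLD = 2, SPATA2 = 2))
  req <- copiesRequiredForIsostoichiometry(cs, 24000)
  expect_equal(req, c(CYLD = 16000, SPATA2 = 16000))
  expect_equal(
    copiesRequiredForIsostoichiometry(cs, 24000, receptor_oligomer = 1),
    c(CYLD = 48000, SPATA2 = 48000))
  expect_error(copiesRequiredForIsostoichiometry(cs, 0), "> 0")
})

test_that("limiting components are those strictly below their requirement", {
  out <- limitingComponents(c(A = 10000, B = 5000, C = 8000),
                            c(A = 8000, B = 8000, C = 8000))
  expect_equal(out$protein_id, c("B", "C", "A"))  # most constrained first
  expect_equal(out$limiting, c(TRUE, FALSE, FALSE))  # equality suffices
  expect_true(all(is.na(out$copies_recovered)))

  # monotonicity: raising availability never makes a protein limiting
  set.seed(11)
  for (i in 1:10) {
    av <- setNames(runif(4, 100, 1000), LETTERS[1:4])
    rq <- setNames(runif(4, 100, 1000), LETTERS[1:4])
    l1 <- limitingComponents(av, rq)
    l2 <- limitingComponents(av * 2, rq)
    m <- merge(l1, l2, by = "protein_id")
    expect_true(all(m$limiting.y <= m$limiting.x))
  }
  expect_error(limitingComponents(c(A = 1), c(B = 1)), "same proteins")
})

test_that("AP-recovered copies and yields follow from the processed cell count", {
  # an amount equivalent to one copy in each of 2.4e6 cells
  amol <- 2.4e6 / 6.02214076e23 * 1e18
  rec <- recoveredCopies(amol, 2.4e6)
  expect_equal(rec$copies_recovered, 1)
  expect_null(rec$yield)
  rec2 <- recoveredCopies(amol, 2.4e6, copies_available = 10)
  expect_equal(rec2$yield, 0.1)
  expect_error(recoveredCopies(1, 0), "ap_cell_equivalents")
})

test_that("signalosome mass sums member molecules weighted by monomer mass", {
  mw <- c(R = 100, A = 50, U = 10)
  # per receptor chain: 3 copies of A, 30 of ubiquitin
  s <- signalosomeMass(c(A = 30, U = 300), receptor_amount = 10,
                       monomer_mw = mw, per = "monomer",
                       receptor_id = "R", ubiquitin_id = "U")
  expect_equal(s$molecules_per_receptor, c(R = 1, A = 3, U = 30))
  expect_equal(s$total_molecules, 34)
  # 1*100 + 3*50 + 30*10 = 550 kDa
  expect_equal(s$total_mw_mda, 0.55)
  expect_equal(s$ubiquitin_mass_fraction, 300 / 550)
  expect_true(s$ubiquitin_dominated)

  # per trimer: same bound amounts give 3x the molecules plus 3 receptor
  # chains
  st <- signalosomeMass(c(A = 30, U = 300), receptor_amount = 10,
                        monomer_mw = mw, per = "trimer",
                        receptor_id = "R", receptor_oligomer = 3,
                        ubiquitin_id = "U")
  expect_equal(st$molecules_per_receptor, c(R = 3, A = 9, U = 90))
  expect_equal(st$total_mw_mda, (3 * 100 + 9 * 50 + 90 * 10) / 1000)

  # invariant to rescaling all amounts together
  s2 <- signalosomeMass(c(A = 3000, U = 30000), receptor_amount = 1000,
                        monomer_mw = mw, per = "monomer",
                        receptor_id = "R", ubiquitin_id = "U")
  expect_equal(s2$total_mw_mda, s$total_mw_mda)

  # receptor alone: no interactors bound
  s3 <- signalosomeMass(setNames(numeric(0), character(0)), 10, mw,
                        per = "monomer", receptor_id = "R",
                        ubiquitin_id = "U")
  expect_equal(s3$total_molecules, 1)
  expect_equal(s3$ubiquitin_mass_fraction, 0)
  expect_false(s3$ubiquitin_dominated)

  expect_error(signalosomeMass(c(Z = 1), 10, mw, receptor_id = "R"),
               "missing monomer molecular weight")
  expect_error(signalosomeMass(c(A = 1), 0, mw, receptor_id = "R"),
               "receptor_amount")
})
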