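# Default study conditions: the TNF receptor signalosome complexes, the
# literature homo-oligomer assumptions (trimeric receptor, dimeric CYLD
# and TBK1), approximate monomer masses, and copy numbers in the regime
# the pipeline is designed for (receptor ~2.5e4/cell, members 1e3-1e6).

#' Default complex definitions of the TNF receptor signalosome
#'
#' The receptor core (trimeric TNFR1 with TRADD, RIPK1, TRAF2 in an
#' approximate 1:1:1 ratio per receptor chain and substoichiometric
#' BIRC2), the linear-ubiquitin ligase LUBAC (an isostoichiometric
#' HOIP:HOIL1:SHARPIN core plus one excess HOIL1/SHARPIN subunit,
#' encoded as 1:2:2), the IKK kinase complex with a duplicated NEMO
#' scaffold (2:1:1), the TAB/TAK1 complex (2:2:1), the dimeric
#' deubiquitinase module CYLD-SPATA2 (2:2) and the dimeric TBK1 kinase
#' module TANK:TBK1 (2:2).
#'
#' @return a [ComplexSet-class] with the receptor complex flagged.
#' @examples
#' defaultComplexSet()
#' @export
defaultComplexSet <- function() {
  ComplexSet(
    ComplexDefinition("receptor-core",
      c(TNFR1 = 3, TRADD = 3, RIPK1 = 3, TRAF2 = 3, BIRC2 = 1),
      receptorFlag = TRUE, receptorOligomer = 3L),
    ComplexDefinition("LUBAC", c(HOIP = 1, HOIL1 = 2, SHARPIN = 2)),
    ComplexDefinition("IKK", c(NEMO = 2, IKKA = 1, IKKB = 1)),
    ComplexDefinition("TAB-TAK1", c(TAB1 = 2, TAB2 = 2, TAK1 = 1)),
    ComplexDefinition("CYLD-SPATA2", c(CYLD = 2, SPATA2 = 2)),
    ComplexDefinition("TBK1-module", c(TANK = 2, TBK1 = 2)))
}

#' Default monomer molecular weights
#'
#' Approximate monomeric molecular weights (kDa) of the signalosome
#' members plus ubiquitin, used for signalosome mass estimates.
#'
#' @return data.frame with columns `protein_id`, `monomer_mw` (kDa).
#' @export
defaultMonomerMw <- function() {
  data.frame(
    protein_id = c("TNFR1", "TRADD", "RIPK1", "TRAF2", "BIRC2", "HOIP",
                   "HOIL1", "SHARPIN", "NEMO", "IKKA", "IKKB", "TAB1",
                   "TAB2", "TAK1", "CYLD", "SPATA2", "TANK", "TBK1",
                   "UBC"),
    monomer_mw = c(50, 34, 76, 56, 70, 120, 58, 40, 48, 85, 87, 55, 76,
                   67, 107, 59, 50, 84, 8.6),
    stringsAsFactors = FALSE)
}

#' Default ground-truth configuration
#'
#' The simulated cellular state the package's tests and worked examples
#' run on: 25,000 receptor copies per cell; member copy numbers in the
#' 1e3--1e6 range with the CYLD-SPATA2 module set below its
#' isostoichiometry requirement (the limiting components); copies bound
#' per trimeric receptor unit peaking at 10 minutes with a
#' ubiquitin-dominated total mass of about 6 MDa; saturating
#' recruitment kinetics in three timing classes (core early, kinase
#' modules intermediate, deubiquitinase/ubiquitin late); multiplicative
#' lognormal measurement noise with a 20% ratio CV and peptide-level
#' response factors.
#'
#' @param noiseCv coefficient of variation of the endogenous/reference
#'   ratio (default 0.2).
#' @param responseFactorSigma lognormal sigma of per-peptide response
#'   factors (default 0.5).
#' @param lodAmol detection limit in amol (default 0.01, zeptomole-range
#'   sensitivity).
#' @return a configuration list for [generateTruth()].
#' @export
defaultTruthConfig <- function(noiseCv = 0.2, responseFactorSigma = 0.5,
                               lodAmol = 0.01) {
  list(
    complexes = defaultComplexSet(),
    copiesPerCell = c(
      TNFR1 = 25000, TRADD = 150000, RIPK1 = 60000, TRAF2 = 120000,
      BIRC2 = 45000, HOIP = 20500, HOIL1 = 41000, SHARPIN = 60000,
      NEMO = 120000, IKKA = 65000, IKKB = 90000, TAB1 = 50000,
      TAB2 = 40000, TAK1 = 30000, CYLD = 9000, SPATA2 = 9500,
      TANK = 30000, TBK1 = 70000, UBC = 2.5e7),
    peakBound = c(
      TRADD = 3, RIPK1 = 4, TRAF2 = 3, BIRC2 = 1, HOIP = 2, HOIL1 = 2,
      SHARPIN = 2, NEMO = 4, IKKA = 2, IKKB = 2, TAB1 = 2, TAB2 = 2,
      TAK1 = 1, CYLD = 1, SPATA2 = 1, TANK = 1, TBK1 = 1, UBC = 420),
    recruitment = data.frame(
      complex_name = c("receptor-core", "LUBAC", "IKK", "TAB-TAK1",
                       "CYLD-SPATA2", "TBK1-module", "ubiquitin"),
      lag = c(0.5, 1, 1, 1, 3, 3, 3),
      rate = c(0.6, 0.35, 0.35, 0.35, 0.25, 0.25, 0.25),
      peak_time = 10,
      decay_rate = 0.04,
      stringsAsFactors = FALSE),
    timepoints = c(0, 5, 10, 15),
    noiseCv = noiseCv,
    responseFactorSigma = responseFactorSigma,
    lodAmol = lodAmol)
}
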