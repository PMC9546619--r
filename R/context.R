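# Cellular context: amounts (amol) to molecule counts and copies per
# cell, receptor-ruler calibration, complex-formation capacity,
# isostoichiometry requirements, limiting components, AP recovery and
# signalosome mass.

#' Average protein mass per cell
#'
#' @param total_mass_mg total protein mass of the preparation (mg).
#' @param cell_count number of cells it came from.
#' @return pg of protein per cell.
#' @examples
#' proteinMassPerCell(4.1, 1.8e7)  # ~228 pg
#' @export
proteinMassPerCell <- function(total_mass_mg, cell_count) {
  if (total_mass_mg <= 0 || cell_count <= 0)
    stop("total_mass_mg and cell_count must be > 0")
  total_mass_mg * 1e9 / cell_count  # mg -> pg
}

#' Cell equivalents of a protein mass
#'
#' @param protein_mass_ug protein mass taken into the workflow (ug).
#' @param mass_per_cell_pg protein content per cell (pg).
#' @return number of cells the mass corresponds to.
#' @examples
#' cellEquivalents(100, 230)  # ~435,000 cells
#' @export
cellEquivalents <- function(protein_mass_ug, mass_per_cell_pg) {
  if (protein_mass_ug <= 0 || mass_per_cell_pg <= 0)
    stop("protein_mass_ug and mass_per_cell_pg must be > 0")
  protein_mass_ug * 1e6 / mass_per_cell_pg  # ug -> pg
}

#' Cell equivalents in the injected fraction
#'
#' @param cell_equivalents cells represented by the full sample.
#' @param injected_fraction fraction injected, in (0, 1].
#' @return injected cell equivalents.
#' @examples
#' injectedCellEquivalents(434783, 0.007)  # ~3,043 cells
#' @export
injectedCellEquivalents <- function(cell_equivalents, injected_fraction) {
  if (injected_fraction <= 0 || injected_fraction > 1)
    stop("injected_fraction must be in (0, 1]")
  cell_equivalents * injected_fraction
}

#' Convert an amount in mol to molecules
#'
#' One zeptomole (1e-21 mol) corresponds to about 600 molecules.
#'
#' @param amount_mol amount in mol (>= 0).
#' @return molecule count.
#' @examples
#' amountToMolecules(1e-21)  # ~602 molecules
#' @export
amountToMolecules <- function(amount_mol) {
  if (any(amount_mol < 0)) stop("amount must be >= 0")
  amount_mol * AVOGADRO
}

#' Copies per cell from an absolute amount
#'
#' Divides the molecule count of an amount (amol) by the cell
#' equivalents represented at the spike point.
#'
#' @param amount_amol absolute amount (amol).
#' @param cell_equivalents cells represented at the spike point (> 0).
#' @return copies per cell.
#' @examples
#' copiesPerCell(126, 3043)  # ~24,900 copies per cell
#' @export
copiesPerCell <- function(amount_amol, cell_equivalents) {
  if (any(cell_equivalents <= 0)) stop("cell_equivalents must be > 0")
  amountToMolecules(amount_amol * 1e-18) / cell_equivalents
}

#' Translate amounts to copies per cell via a calibrant ruler
#'
#' Multiplies the calibrant's known copies per cell by the ratio of the
#' protein's absolute amount to the calibrant's absolute amount from
#' the same experiment.
#'
#' @param calibrant_copies_per_cell known calibrant copy number.
#' @param protein_amount protein absolute amount (any common unit).
#' @param calibrant_amount calibrant absolute amount (> 0, same unit).
#' @return copies per cell of the protein.
#' @examples
#' translateCopiesViaCalibrant(25000, 2, 1)  # 50,000
#' @export
translateCopiesViaCalibrant <- function(calibrant_copies_per_cell,
                                        protein_amount,
                                        calibrant_amount) {
  if (any(calibrant_amount <= 0)) stop("calibrant_amount must be > 0")
  calibrant_copies_per_cell * protein_amount / calibrant_amount
}

#' Complete complexes formable per cell
#'
#' Minimum over members of `copies_i / multiplicity_i`. A member absent
#' from `copies` makes the count 0, with a warning.
#'
#' @param copies named numeric copies per cell.
#' @param complexDef a [ComplexDefinition-class].
#' @return complete-complex count per cell.
#' @examples
#' cd <- ComplexDefinition("XY", c(X = 2, Y = 2))
#' complexesPerCell(c(X = 200, Y = 50), cd)  # 25
#' @export
complexesPerCell <- function(copies, complexDef) {
  stopifnot(is(complexDef, "ComplexDefinition"))
  m <- members(complexDef)
  absent <- setdiff(names(m), names(copies))
  if (length(absent)) {
    warning(sprintf("member(s) %s absent: 0 complexes can form",
                    paste(absent, collapse = ", ")))
    return(0)
  }
  min(copies[names(m)] / m)
}

#' Copies required for isostoichiometry
#'
#' The copies per cell of each member needed to supply at least one
#' complete complex per oligomeric receptor unit:
#' `multiplicity_i * receptor_copies / receptor_oligomer`.
#'
#' @param complexDef a [ComplexDefinition-class].
#' @param receptor_copies_per_cell receptor copies per cell (> 0).
#' @param receptor_oligomer receptor homo-oligomer count (default 3).
#' @return named numeric: required copies per cell per member.
#' @examples
#' cd <- ComplexDefinition("CYLD-SPATA2", c(CYLD = 2, SPATA2 = 2))
#' copiesRequiredForIsostoichiometry(cd, 24000)  # 16,000 each
#' @export
copiesRequiredForIsostoichiometry <- function(complexDef,
                                              receptor_copies_per_cell,
                                              receptor_oligomer = 3L) {
  stopifnot(is(complexDef, "ComplexDefinition"))
  if (receptor_copies_per_cell <= 0)
    stop("receptor_copies_per_cell must be > 0")
  if (receptor_oligomer < 1L) stop("receptor_oligomer must be >= 1")
  m <- members(complexDef)
  setNames(m * receptor_copies_per_cell / receptor_oligomer, names(m))
}

#' Identify limiting components
#'
#' A protein is limiting when its available copies per cell fall
#' strictly below its isostoichiometry requirement; equality means
#' exactly sufficient. Records are sorted by `available / required`
#' ascending, so the most constraining components come first.
#'
#' @param copies_available named numeric, copies per cell.
#' @param copies_required named numeric over the same protein set.
#' @param copies_recovered optional named numeric of AP-recovered
#'   copies per cell, carried into the records.
#' @return data.frame with columns `protein_id`, `copies_available`,
#'   `copies_required`, `copies_recovered`, `limiting`.
#' @examples
#' limitingComponents(c(A = 10000, B = 5000), c(A = 8000, B = 8000))
#' @export
limitingComponents <- function(copies_available, copies_required,
                               copies_recovered = NULL) {
  if (!setequal(names(copies_available), names(copies_required)))
    stop("copies_available and copies_required must cover the same proteins")
  ids <- names(copies_available)
  req <- copies_required[ids]
  rec <- if (is.null(copies_recovered)) rep(NA_real_, length(ids))
         else unname(copies_recovered[ids])
  out <- data.frame(
    protein_id = ids,
    copies_available = unname(copies_available),
    copies_required = unname(req),
    copies_recovered = rec,
    limiting = unname(copies_available < req),
    stringsAsFactors = FALSE)
  out <- out[order(out$copies_available / out$copies_required,
                   out$protein_id), ]
  rownames(out) <- NULL
  out
}

#' Copies per cell recovered from an affinity purification
#'
#' @param ap_amount_amol recovered absolute amount (amol).
#' @param ap_cell_equivalents cells processed in the AP experiment,
#'   represented at the spike point (> 0).
#' @param copies_available optional copies per cell in the lysate; when
#'   given, the recovery yield `recovered / available` is reported too.
#' @return list with `copies_recovered` and (optionally) `yield`.
#' @examples
#' recoveredCopies(2400000 / 6.02214076e23 * 1e18, 2400000)
#' @export
recoveredCopies <- function(ap_amount_amol, ap_cell_equivalents,
                            copies_available = NULL) {
  if (ap_cell_equivalents <= 0) stop("ap_cell_equivalents must be > 0")
  rec <- copiesPerCell(ap_amount_amol, ap_cell_equivalents)
  out <- list(copies_recovered = rec)
  if (!is.null(copies_available))
    out$yield <- rec / copies_available
  out
}

#' Signalosome molecule and mass estimate
#'
#' Average number of molecules of each member associated with the
#' receptor at one time point, and their summed molecular weight.
#' With `per = "trimer"` (default) molecules are counted per oligomeric
#' receptor unit (`bound_i / (receptor_amount / receptor_oligomer)`),
#' and the receptor contributes `receptor_oligomer` molecules of its
#' own mass; with `per = "monomer"` counts are per receptor chain. The
#' estimate is invariant to rescaling all amounts together. When
#' ubiquitin contributes more than half of the total mass the estimate
#' is flagged as ubiquitin-dominated.
#'
#' @param bound_amounts named numeric amounts of bound proteins
#'   (receptor excluded; any common unit).
#' @param receptor_amount receptor amount in the same unit (> 0).
#' @param monomer_mw data.frame with `protein_id`, `monomer_mw` (kDa),
#'   or a named numeric vector (kDa).
#' @param per `"trimer"` (default) or `"monomer"`.
#' @param receptor_id receptor protein identifier (for its own mass).
#' @param receptor_oligomer receptor homo-oligomer count (default 3).
#' @param ubiquitin_id identifier of ubiquitin in the inputs
#'   (default `"UBC"`).
#' @param timepoint optional time label carried through.
#' @return list with `timepoint`, `molecules_per_receptor` (named,
#'   receptor included), `total_molecules`, `total_mw_mda`,
#'   `ubiquitin_mass_fraction`, `ubiquitin_dominated`.
#' @export
signalosomeMass <- function(bound_amounts, receptor_amount, monomer_mw,
                            per = c("trimer", "monomer"),
                            receptor_id = "TNFR1",
                            receptor_oligomer = 3L,
                            ubiquitin_id = "UBC",
                            timepoint = NA_real_) {
  per <- match.arg(per)
  if (receptor_amount <= 0) stop("receptor_amount must be > 0")
  if (is.data.frame(monomer_mw))
    monomer_mw <- setNames(monomer_mw$monomer_mw, monomer_mw$protein_id)
  bound_amounts <- bound_amounts[setdiff(names(bound_amounts),
                                         receptor_id)]
  ids <- c(receptor_id, names(bound_amounts))
  nomw <- setdiff(ids, names(monomer_mw))
  if (length(nomw))
    stop("missing monomer molecular weight for: ",
         paste(nomw, collapse = ", "))
  unit <- if (per == "trimer") receptor_amount / receptor_oligomer
          else receptor_amount
  mol <- c(setNames(if (per == "trimer") receptor_oligomer else 1,
                    receptor_id),
           bound_amounts / unit)
  mass <- mol * monomer_mw[ids]
  total_mw <- sum(mass)
  ub_frac <- if (ubiquitin_id %in% ids)
    unname(mass[ubiquitin_id] / total_mw) else 0
  list(timepoint = timepoint,
       molecules_per_receptor = mol,
       total_molecules = sum(mol),
       total_mw_mda = total_mw / 1000,  # kDa -> MDa
       ubiquitin_mass_fraction = ub_frac,
       ubiquitin_dominated = ub_frac > 0.5)
}
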