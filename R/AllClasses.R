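#' Complex definition
#'
#' An S4 class describing one protein complex: its members with integer
#' multiplicities, the reference-member policy used for relative
#' stoichiometry, and whether the complex is the receptor-carrying one
#' (with its homo-oligomeric state, trimeric for the TNF receptor).
#'
#' @slot complexName single identifier string.
#' @slot members named integer vector, protein identifier to multiplicity
#'   (all at least 1).
#' @slot referencePolicy `"most_abundant"` or `"fixed:<protein_id>"`.
#' @slot receptorFlag is this the receptor complex?
#' @slot receptorOligomer homo-oligomeric state of the receptor (3 for a
#'   trimeric receptor); ignored unless `receptorFlag`.
#'
#' @exportClass ComplexDefinition
setClass("ComplexDefinition",
  representation(
    complexName = "character",
    members = "integer",
    referencePolicy = "character",
    receptorFlag = "logical",
    receptorOligomer = "integer"
  ),
  prototype(
    referencePolicy = "most_abundant",
    receptorFlag = FALSE,
    receptorOligomer = 3L
  )
)

setValidity("ComplexDefinition", function(object) {
  msg <- character()
  if (length(object@complexName) != 1L || !nzchar(object@complexName))
    msg <- c(msg, "complexName must be a single non-empty string")
  if (length(object@members) < 1L)
    msg <- c(msg, "a complex needs at least one member")
  if (is.null(names(object@members)) || any(!nzchar(names(object@members))))
    msg <- c(msg, "members must be named by protein identifier")
  if (anyDuplicated(names(object@members)))
    msg <- c(msg, "duplicated member protein identifiers")
  if (any(is.na(object@members)) || any(object@members < 1L))
    msg <- c(msg, "multiplicities must be integers >= 1")
  if (!(object@referencePolicy == "most_abundant" ||
        grepl("^fixed:.+$", object@referencePolicy)))
    msg <- c(msg, "referencePolicy must be 'most_abundant' or 'fixed:<protein_id>'")
  if (grepl("^fixed:", object@referencePolicy)) {
    fixed <- sub("^fixed:", "", object@referencePolicy)
    if (!fixed %in% names(object@members))
      msg <- c(msg, sprintf("fixed reference '%s' is not a member", fixed))
  }
  if (length(object@receptorFlag) != 1L || is.na(object@receptorFlag))
    msg <- c(msg, "receptorFlag must be TRUE or FALSE")
  if (isTRUE(object@receptorFlag) &&
      (length(object@receptorOligomer) != 1L || object@receptorOligomer < 1L))
    msg <- c(msg, "receptorOligomer must be a positive integer")
  if (length(msg)) msg else TRUE
})

#' Construct a ComplexDefinition
#'
#' @param complexName complex identifier.
#' @param members named integer (or coercible) vector of member
#'   multiplicities, e.g. `c(CYLD = 2, SPATA2 = 2)`.
#' @param referencePolicy `"most_abundant"` (default) or
#'   `"fixed:<protein_id>"`.
#' @param receptorFlag whether this complex carries the receptor.
#' @param receptorOligomer receptor homo-oligomer count (default 3,
#'   trimeric receptor).
#' @return a validated [ComplexDefinition-class] object.
#' @examples
#' ComplexDefinition("CYLD-SPATA2", c(CYLD = 2, SPATA2 = 2))
#' @export
ComplexDefinition <- function(complexName, members,
                              referencePolicy = "most_abundant",
                              receptorFlag = FALSE,
                              receptorOligomer = 3L) {
  m <- members
  if (is.null(names(m)))
    stop("members must be a named vector (protein_id = multiplicity)")
  if (any(is.na(m)) || any(m != round(m)))
    stop("multiplicities must be whole numbers")
  new("ComplexDefinition",
    complexName = as.character(complexName),
    members = setNames(as.integer(m), names(m)),
    referencePolicy = referencePolicy,
    receptorFlag = isTRUE(receptorFlag),
    receptorOligomer = as.integer(receptorOligomer))
}

#' Set of complex definitions
#'
#' A validated collection of [ComplexDefinition-class] objects. Exactly
#' one complex in a set must carry the receptor flag, and complex names
#' must be unique.
#'
#' @slot complexes list of `ComplexDefinition`.
#' @exportClass ComplexSet
setClass("ComplexSet", representation(complexes = "list"))

setValidity("ComplexSet", function(object) {
  msg <- character()
  if (!all(vapply(object@complexes, is, logical(1), "ComplexDefinition")))
    msg <- c(msg, "all elements must be ComplexDefinition objects")
  else {
    nm <- vapply(object@complexes, function(x) x@complexName, character(1))
    if (anyDuplicated(nm))
      msg <- c(msg, "duplicated complex names")
    nrec <- sum(vapply(object@complexes, function(x) x@receptorFlag, logical(1)))
    if (nrec != 1L)
      msg <- c(msg, sprintf(
        "exactly one complex must have receptorFlag = TRUE (found %d)", nrec))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ComplexSet
#'
#' @param ... `ComplexDefinition` objects, or a single list of them.
#' @return a validated [ComplexSet-class].
#' @examples
#' cs <- ComplexSet(
#'   ComplexDefinition("receptor-core", c(TNFR1 = 3, TRADD = 1),
#'                     receptorFlag = TRUE),
#'   ComplexDefinition("CYLD-SPATA2", c(CYLD = 2, SPATA2 = 2)))
#' complexNames(cs)
#' @export
ComplexSet <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1]]) &&
      !is(args[[1]], "ComplexDefinition"))
    args <- args[[1]]
  new("ComplexSet", complexes = args)
}

#' Ground-truth cellular state for simulation
#'
#' Holds everything the synthetic-data generator needs and everything the
#' downstream pipeline is expected to recover: per-protein copies per
#' cell, the complex definitions, copies bound per trimeric receptor unit
#' over the stimulation time course, and the measurement-noise model.
#'
#' @slot copiesPerCell named numeric, protein copies per cell (> 0).
#' @slot complexes a [ComplexSet-class].
#' @slot boundPerReceptor data.frame with columns `protein_id`,
#'   `timepoint` (minutes), `bound` (copies per trimeric receptor unit);
#'   zero at time 0 for every non-receptor protein.
#' @slot recruitmentParams data.frame of per-complex kinetics
#'   (`complex_name`, `lag`, `rate`, `peak_time`, `decay_rate`).
#' @slot noiseCv coefficient of variation of the endogenous/reference
#'   intensity ratio.
#' @slot responseFactorSigma lognormal sigma of per-peptide response
#'   factors (flyability); cancels in the AQUA ratio.
#' @slot lodAmol detection limit; simulated rows below it are censored.
#' @slot seed integer seed the truth was generated from.
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(
    copiesPerCell = "numeric",
    complexes = "ComplexSet",
    boundPerReceptor = "data.frame",
    recruitmentParams = "data.frame",
    noiseCv = "numeric",
    responseFactorSigma = "numeric",
    lodAmol = "numeric",
    seed = "integer"
  )
)

setValidity("GroundTruth", function(object) {
  msg <- character()
  cpc <- object@copiesPerCell
  if (is.null(names(cpc)) || any(!nzchar(names(cpc))))
    msg <- c(msg, "copiesPerCell must be named by protein identifier")
  if (any(!is.finite(cpc)) || any(cpc <= 0))
    msg <- c(msg, "copiesPerCell must be finite and > 0")
  if (object@noiseCv < 0) msg <- c(msg, "noiseCv must be >= 0")
  if (object@responseFactorSigma < 0)
    msg <- c(msg, "responseFactorSigma must be >= 0")
  if (object@lodAmol < 0) msg <- c(msg, "lodAmol must be >= 0")
  b <- object@boundPerReceptor
  need <- c("protein_id", "timepoint", "bound")
  if (!all(need %in% names(b)))
    msg <- c(msg, "boundPerReceptor needs columns protein_id, timepoint, bound")
  else {
    if (any(b$bound < 0)) msg <- c(msg, "bound values must be >= 0")
    rec <- receptorProtein(object@complexes)
    at0 <- b[b$timepoint == 0 & b$protein_id != rec, "bound"]
    if (length(at0) && any(at0 != 0))
      msg <- c(msg, "non-receptor bound copies must be 0 at timepoint 0")
  }
  if (length(msg)) msg else TRUE
})

#' Cell-level bookkeeping for copy-number calibration
#'
#' Carries the quantities that convert absolute amounts (amol) into
#' copies per cell: protein mass per cell, number of processed cells,
#' injected fraction, and the calibrant ("ruler") protein with its known
#' copy number.
#'
#' @slot massPerCellPg average protein content per cell, pg.
#' @slot cellsProcessed number of cells represented at the spike point.
#' @slot injectedFraction fraction of the processed sample injected,
#'   in (0, 1].
#' @slot calibrantProtein identifier of the ruler protein.
#' @slot calibrantCopiesPerCell known copies per cell of the calibrant.
#' @exportClass CellContext
setClass("CellContext",
  representation(
    massPerCellPg = "numeric",
    cellsProcessed = "numeric",
    injectedFraction = "numeric",
    calibrantProtein = "character",
    calibrantCopiesPerCell = "numeric"
  )
)

setValidity("CellContext", function(object) {
  msg <- character()
  for (sl in c("massPerCellPg", "cellsProcessed", "injectedFraction",
               "calibrantCopiesPerCell")) {
    v <- slot(object, sl)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("%s must be a single positive number", sl))
  }
  if (length(object@injectedFraction) == 1L &&
      is.finite(object@injectedFraction) && object@injectedFraction > 1)
    msg <- c(msg, "injectedFraction must be <= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a CellContext
#'
#' @param massPerCellPg average protein content per cell (pg).
#' @param cellsProcessed cells represented by the matrix at the spike
#'   point.
#' @param injectedFraction fraction of the sample injected, in (0, 1].
#' @param calibrantProtein ruler protein identifier.
#' @param calibrantCopiesPerCell known copies per cell of the ruler.
#' @return a validated [CellContext-class].
#' @examples
#' CellContext(230, 435000, 0.007, "TNFR1", 25000)
#' @export
CellContext <- function(massPerCellPg, cellsProcessed, injectedFraction = 1,
                        calibrantProtein, calibrantCopiesPerCell) {
  new("CellContext",
    massPerCellPg = as.numeric(massPerCellPg),
    cellsProcessed = as.numeric(cellsProcessed),
    injectedFraction = as.numeric(injectedFraction),
    calibrantProtein = as.character(calibrantProtein),
    calibrantCopiesPerCell = as.numeric(calibrantCopiesPerCell))
}
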