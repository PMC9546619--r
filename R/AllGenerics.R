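#' Accessors for complex definitions and sets
#'
#' @param object a [ComplexDefinition-class], [ComplexSet-class] or
#'   [GroundTruth-class] object, as appropriate.
#' @name accessors
NULL

#' @rdname accessors
#' @return `complexName()`: the complex identifier.
#' @export
setGeneric("complexName", function(object) standardGeneric("complexName"))

#' @rdname accessors
#' @export
setMethod("complexName", "ComplexDefinition", function(object)
  object@complexName)

#' @rdname accessors
#' @return `members()`: named integer vector of member multiplicities.
#' @export
setGeneric("members", function(object) standardGeneric("members"))

#' @rdname accessors
#' @export
setMethod("members", "ComplexDefinition", function(object) object@members)

#' @rdname accessors
#' @return `isReceptor()`: logical receptor flag.
#' @export
setGeneric("isReceptor", function(object) standardGeneric("isReceptor"))

#' @rdname accessors
#' @export
setMethod("isReceptor", "ComplexDefinition", function(object)
  object@receptorFlag)

#' @rdname accessors
#' @return `receptorOligomer()`: homo-oligomeric state of the receptor.
#' @export
setGeneric("receptorOligomer", function(object)
  standardGeneric("receptorOligomer"))

#' @rdname accessors
#' @export
setMethod("receptorOligomer", "ComplexDefinition", function(object)
  object@receptorOligomer)

#' @rdname accessors
#' @export
setMethod("receptorOligomer", "ComplexSet", function(object)
  receptorOligomer(receptorComplex(object)))

#' @rdname accessors
#' @return `referencePolicy()`: the reference-member policy string.
#' @export
setGeneric("referencePolicy", function(object)
  standardGeneric("referencePolicy"))

#' @rdname accessors
#' @export
setMethod("referencePolicy", "ComplexDefinition", function(object)
  object@referencePolicy)

#' @rdname accessors
#' @return `complexNames()`: character vector of complex names in a set.
#' @export
setGeneric("complexNames", function(object) standardGeneric("complexNames"))

#' @rdname accessors
#' @export
setMethod("complexNames", "ComplexSet", function(object)
  vapply(object@complexes, complexName, character(1)))

#' @rdname accessors
#' @return `receptorComplex()`: the receptor-flagged
#'   `ComplexDefinition` of a set.
#' @export
setGeneric("receptorComplex", function(object)
  standardGeneric("receptorComplex"))

#' @rdname accessors
#' @export
setMethod("receptorComplex", "ComplexSet", function(object) {
  hit <- vapply(object@complexes, isReceptor, logical(1))
  object@complexes[[which(hit)[1]]]
})

#' @rdname accessors
#' @return `receptorProtein()`: identifier of the receptor protein (the
#'   member of the receptor complex whose multiplicity equals the
#'   receptor oligomer count, or the first member as fallback).
#' @export
setGeneric("receptorProtein", function(object)
  standardGeneric("receptorProtein"))

#' @rdname accessors
#' @export
setMethod("receptorProtein", "ComplexSet", function(object) {
  rc <- receptorComplex(object)
  m <- members(rc)
  hit <- which(m == rc@receptorOligomer)
  names(m)[if (length(hit)) hit[1] else 1L]
})

#' @rdname accessors
#' @return `allMembers()`: sorted unique protein identifiers across a
#'   set.
#' @export
setGeneric("allMembers", function(object) standardGeneric("allMembers"))

#' @rdname accessors
#' @export
setMethod("allMembers", "ComplexSet", function(object)
  sort(unique(unlist(lapply(object@complexes, function(x)
    names(members(x)))))))

#' @param x a `ComplexSet`.
#' @param i index or complex name.
#' @rdname accessors
#' @export
setMethod("[[", "ComplexSet", function(x, i) {
  if (is.character(i)) i <- match(i, complexNames(x))
  x@complexes[[i]]
})

#' @rdname accessors
#' @export
setMethod("length", "ComplexSet", function(x) length(x@complexes))

#' Accessors for ground truth
#'
#' @param object a [GroundTruth-class].
#' @return `truthCopies()`: named per-protein copies per cell;
#'   `truthComplexes()`: the [ComplexSet-class];
#'   `boundPerReceptor()`: long data.frame of copies bound per trimeric
#'   receptor unit over time.
#' @name truth-accessors
NULL

#' @rdname truth-accessors
#' @export
setGeneric("truthCopies", function(object) standardGeneric("truthCopies"))

#' @rdname truth-accessors
#' @export
setMethod("truthCopies", "GroundTruth", function(object) object@copiesPerCell)

#' @rdname truth-accessors
#' @export
setGeneric("truthComplexes", function(object)
  standardGeneric("truthComplexes"))

#' @rdname truth-accessors
#' @export
setMethod("truthComplexes", "GroundTruth", function(object) object@complexes)

#' @rdname truth-accessors
#' @export
setGeneric("boundPerReceptor", function(object)
  standardGeneric("boundPerReceptor"))

#' @rdname truth-accessors
#' @export
setMethod("boundPerReceptor", "GroundTruth", function(object)
  object@boundPerReceptor)

setMethod("show", "ComplexDefinition", function(object) {
  cat("ComplexDefinition:", object@complexName,
      if (object@receptorFlag)
        sprintf("(receptor, oligomer %d)", object@receptorOligomer)
      else "", "\n")
  cat("  members:",
      paste(sprintf("%s x%d", names(object@members), object@members),
            collapse = ", "), "\n")
  cat("  reference policy:", object@referencePolicy, "\n")
  invisible(object)
})

setMethod("show", "ComplexSet", function(object) {
  cat(sprintf("ComplexSet with %d complex(es): %s\n",
              length(object), paste(complexNames(object), collapse = ", ")))
  cat("  receptor complex:", complexName(receptorComplex(object)),
      sprintf("(receptor protein %s)\n", receptorProtein(object)))
  invisible(object)
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf(
    "GroundTruth: %d proteins, %d complexes, seed %d\n",
    length(object@copiesPerCell), length(object@complexes), object@seed))
  cat(sprintf("  noise CV %.3g, response-factor sigma %.3g, LOD %.3g amol\n",
              object@noiseCv, object@responseFactorSigma, object@lodAmol))
  tp <- sort(unique(object@boundPerReceptor$timepoint))
  cat("  timepoints (min):", paste(tp, collapse = ", "), "\n")
  invisible(object)
})

setMethod("show", "CellContext", function(object) {
  cat(sprintf(
    "CellContext: %.4g pg/cell, %.4g cells processed, %.3g injected\n",
    object@massPerCellPg, object@cellsProcessed, object@injectedFraction))
  cat(sprintf("  ruler: %s at %.4g copies/cell\n",
              object@calibrantProtein, object@calibrantCopiesPerCell))
  invisible(object)
})
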