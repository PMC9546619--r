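# Relative and integer complex stoichiometry, occupancy, and
# recruitment time-course normalisation/clustering.

#' Relative stoichiometry of a complex
#'
#' Member amounts expressed relative to a reference member: 1.0 for the
#' reference, `amount_i / amount_reference` otherwise. The reference is
#' the most abundant member (ties broken by member order in the complex
#' definition) or a fixed member, per the complex's reference policy or
#' the `policy` override. Members absent from `amounts` get an `NA`
#' ratio and are reported in `missing`.
#'
#' @param complexDef a [ComplexDefinition-class].
#' @param amounts named numeric amounts (amol or any common scale).
#' @param policy optional override: `"most_abundant"` or
#'   `"fixed:<protein_id>"`.
#' @param timepoint optional time label carried through.
#' @param source `"aqua"` (default) or `"ibaq"`.
#' @return list with `complex_name`, `timepoint`, `reference_member`,
#'   `ratios` (named, reference = 1), `missing`, `source`.
#' @examples
#' cd <- ComplexDefinition("demo", c(A = 1, B = 1, C = 1))
#' relativeStoichiometry(cd, c(A = 100, B = 50, C = 100))
#' @export
relativeStoichiometry <- function(complexDef, amounts, policy = NULL,
                                  timepoint = NA_real_, source = "aqua") {
  stopifnot(is(complexDef, "ComplexDefinition"))
  if (is.null(policy)) policy <- referencePolicy(complexDef)
  member_ids <- names(members(complexDef))
  present <- member_ids[member_ids %in% names(amounts)]
  missing <- setdiff(member_ids, present)
  vals <- amounts[present]
  if (!length(present) || all(vals == 0))
    stop("undefined stoichiometry: all member amounts are zero or missing")
  if (policy == "most_abundant") {
    ref <- present[which.max(vals)]  # which.max: earliest tie wins
  } else {
    ref <- sub("^fixed:", "", policy)
    if (!ref %in% present || !(amounts[[ref]] > 0))
      stop(sprintf("fixed reference '%s' absent or zero", ref))
  }
  ratios <- setNames(rep(NA_real_, length(member_ids)), member_ids)
  ratios[present] <- vals / amounts[[ref]]
  list(complex_name = complexName(complexDef), timepoint = timepoint,
       reference_member = ref, ratios = ratios, missing = missing,
       source = source)
}

.gcd2 <- function(a, b) if (b == 0) a else .gcd2(b, a %% b)
.gcdv <- function(v) Reduce(.gcd2, v)

# Full candidate set: base vectors in {1..maxCopies}^n with gcd 1,
# optionally combined with one additive excess vector in
# {0..maxCopies}^n (not all zero).
.integerCandidates <- function(n, maxCopies, allowExcess) {
  B <- as.matrix(expand.grid(rep(list(seq_len(maxCopies)), n),
                             KEEP.OUT.ATTRS = FALSE))
  B <- B[apply(B, 1L, .gcdv) == 1L, , drop = FALSE]
  E0 <- matrix(0L, nrow = 1L, ncol = n)
  if (allowExcess) {
    E <- as.matrix(expand.grid(rep(list(0:maxCopies), n),
                               KEEP.OUT.ATTRS = FALSE))
    E <- E[rowSums(E) > 0, , drop = FALSE]
    E <- rbind(E0, E)
  } else E <- E0
  nb <- nrow(B); ne <- nrow(E)
  list(base = B[rep(seq_len(nb), each = ne), , drop = FALSE],
       excess = E[rep(seq_len(ne), times = nb), , drop = FALSE])
}

#' Fit the best integer stoichiometry model
#'
#' Exhaustively enumerates integer base stoichiometries (each
#' multiplicity 1..`maxCopies`, gcd-reduced) and, when `allowExcess`,
#' one additive excess vector per model (entries 0..`maxCopies`, not
#' all zero), supporting partial-complex isoforms in which excess
#' subunits ride on an isostoichiometric core. Each candidate's
#' predicted ratio vector is `(base + excess)` normalised to its
#' maximum; the fit error is the root-mean-square difference between
#' predicted and observed ratios in log2 space, so two-fold errors in
#' either direction weigh equally. Models are ranked by fit error, ties
#' broken by smaller total copy number, then lexicographically on
#' `c(base, excess)`.
#'
#' @param observed named numeric ratios (finite, > 0), typically from
#'   [relativeStoichiometry()].
#' @param maxCopies search bound per subunit (default 4; covers
#'   trimers, dimers, 2:2:1 and core-plus-excess arrangements).
#' @param allowExcess include single additive excess vectors
#'   (default TRUE).
#' @param nTop number of top-ranked models to return (default 5).
#' @return data.frame, one row per model: `base_*`, `excess_*`,
#'   `pred_*` columns per member, plus `total_copies` and `fit_error`.
#' @examples
#' fitIntegerStoichiometry(c(HOIP = 0.5, HOIL1 = 1, SHARPIN = 1))[1, ]
#' @export
fitIntegerStoichiometry <- function(observed, maxCopies = 4L,
                                    allowExcess = TRUE, nTop = 5L) {
  if (maxCopies < 1L) stop("maxCopies must be >= 1")
  obs <- observed[is.finite(observed) & observed > 0]
  if (length(obs) < 2L)
    stop("need at least 2 members with finite positive ratios")
  n <- length(obs)
  cand <- .integerCandidates(n, maxCopies, allowExcess)
  total <- cand$base + cand$excess
  pred <- total / apply(total, 1L, max)
  err <- sqrt(rowMeans((log2(pred) -
                          matrix(log2(obs), nrow(pred), n,
                                 byrow = TRUE))^2))
  ord <- do.call(order, c(list(err, rowSums(total)),
                          lapply(seq_len(n), function(j) cand$base[, j]),
                          lapply(seq_len(n), function(j)
                            cand$excess[, j])))
  take <- ord[seq_len(min(nTop, length(ord)))]
  out <- data.frame(
    cand$base[take, , drop = FALSE],
    cand$excess[take, , drop = FALSE],
    pred[take, , drop = FALSE],
    total_copies = rowSums(total)[take],
    fit_error = err[take])
  names(out) <- c(paste0("base_", names(obs)),
                  paste0("excess_", names(obs)),
                  paste0("pred_", names(obs)),
                  "total_copies", "fit_error")
  rownames(out) <- NULL
  out
}

#' Occupancy of a bait by an interactor
#'
#' Fraction of bait molecules bound by an interactor, from absolute
#' amounts in the same isolate:
#' `(interactor / multiplicity) / bait`. Values above 1 are permitted
#' (super-stoichiometric binding, e.g. ubiquitin chains).
#'
#' @param bait_amount bait amount (> 0).
#' @param interactor_amount interactor amount (>= 0).
#' @param interactor_multiplicity subunits per bound unit (default 1).
#' @return occupancy fraction.
#' @examples
#' occupancyFraction(100, 5)    # 0.05
#' occupancyFraction(100, 250)  # 2.5, super-stoichiometric
#' @export
occupancyFraction <- function(bait_amount, interactor_amount,
                              interactor_multiplicity = 1) {
  if (bait_amount <= 0) stop("bait_amount must be > 0")
  (interactor_amount / interactor_multiplicity) / bait_amount
}

#' Fraction of a carrier complex bound by a cargo complex
#'
#' `cargo_complexes / carrier_complexes` from per-cell complex counts
#' (see [complexesPerCell()]); a fraction above 1 is reported with an
#' over-unity flag rather than capped.
#'
#' @param carrier_complexes carrier complex count per cell (> 0).
#' @param cargo_complexes cargo complex count per cell (>= 0).
#' @return list with `fraction` and `over_unity`.
#' @examples
#' complexBoundFraction(100, 22)$fraction  # 0.22
#' @export
complexBoundFraction <- function(carrier_complexes, cargo_complexes) {
  if (carrier_complexes <= 0) stop("carrier complex count must be > 0")
  f <- cargo_complexes / carrier_complexes
  list(fraction = f, over_unity = f > 1)
}

#' Receptor- and maximum-normalised recruitment profile
#'
#' Divides the analyte amount by the receptor amount at each time point
#' and normalises by the maximum, yielding values in \[0, 1\] with
#' maximum 1. Invariant to rescaling of the receptor series. An all-zero
#' analyte yields a flat-zero profile with a warning.
#'
#' @param amounts analyte amounts over time.
#' @param receptor_amounts receptor amounts at the same time points.
#' @param timepoints time labels (minutes), same length.
#' @return list with `timepoints` and `values`.
#' @examples
#' normalizeTimecourse(c(10, 40, 80, 60), c(10, 20, 40, 60),
#'                     c(0, 5, 10, 15))
#' @export
normalizeTimecourse <- function(amounts, receptor_amounts,
                                timepoints = seq_along(amounts)) {
  stopifnot(length(amounts) == length(receptor_amounts),
            length(amounts) == length(timepoints))
  if (all(amounts == 0)) {
    warning("all-zero analyte profile; returning flat zeros")
    return(list(timepoints = timepoints, values = rep(0, length(amounts))))
  }
  if (any(amounts > 0 & receptor_amounts <= 0))
    stop("receptor amount must be > 0 wherever the analyte is detected")
  ratio <- ifelse(amounts == 0, 0, amounts / receptor_amounts)
  list(timepoints = timepoints, values = ratio / max(ratio))
}

#' Cluster recruitment profiles
#'
#' Agglomerative hierarchical clustering of recruitment profiles with
#' distance `1 - Pearson correlation` and average linkage, cut into `k`
#' clusters. Deterministic for a given input order; cluster labels are
#' renumbered by first appearance. Zero-variance profiles cannot enter
#' a correlation distance and are assigned singleton classes beyond `k`
#' with a warning.
#'
#' @param profiles numeric matrix, rows = proteins (named), columns =
#'   common time grid.
#' @param k number of clusters (default 3).
#' @return named integer vector of cluster labels.
#' @export
clusterProfiles <- function(profiles, k = 3L) {
  stopifnot(is.matrix(profiles))
  if (is.null(rownames(profiles)))
    rownames(profiles) <- paste0("profile", seq_len(nrow(profiles)))
  v <- apply(profiles, 1L, sd)
  flat <- v == 0
  labels <- setNames(integer(nrow(profiles)), rownames(profiles))
  ok <- which(!flat)
  if (length(ok) < k)
    stop("fewer non-degenerate profiles than clusters requested")
  if (length(ok)) {
    d <- as.dist(1 - cor(t(profiles[ok, , drop = FALSE])))
    hc <- hclust(d, method = "average")
    cl <- cutree(hc, k = k)
    # renumber by first appearance for determinism
    cl <- match(cl, unique(cl))
    labels[ok] <- cl
  }
  if (any(flat)) {
    warning(sprintf(
      "%d zero-variance profile(s) assigned singleton classes",
      sum(flat)))
    labels[which(flat)] <- k + seq_len(sum(flat))
  }
  labels
}
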