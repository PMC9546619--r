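# End-to-end orchestration: simulate -> quantify -> stoichiometry ->
# cellular context, with a deterministic report writer.

#' Estimate copies per cell from lysate quantifications
#'
#' Implements the receptor-ruler calibration: the calibrant's copies
#' per cell are estimated directly in each lysate sample by dividing
#' its molecule count by the sample's cell equivalents at the spike
#' point (averaged across samples), and every other protein is
#' translated through the calibrant ratio within the same sample, then
#' averaged across samples. Copy numbers are treated as a property of
#' the cell state, so all lysate samples (replicates and time points)
#' are pooled.
#'
#' @param amounts protein amount table from [quantifyProteins()].
#' @param meta sample metadata (see [readSampleMeta()]); only
#'   `sample_type == "lysate"` rows are used.
#' @param calibrant calibrant (ruler) protein identifier.
#' @param calibrant_copies optional known calibrant copies per cell; by
#'   default estimated from the data.
#' @return named numeric vector of copies per cell.
#' @export
estimateCopiesPerCell <- function(amounts, meta, calibrant,
                                  calibrant_copies = NULL) {
  lys <- meta[meta$sample_type == "lysate", , drop = FALSE]
  if (!nrow(lys)) stop("no lysate samples in the metadata")
  a <- amounts[amounts$sample_id %in% lys$sample_id, , drop = FALSE]
  cal <- a[a$protein_id == calibrant, , drop = FALSE]
  if (!nrow(cal)) stop("calibrant '", calibrant,
                       "' not quantified in any lysate sample")
  cells <- lys$cell_equivalents[match(cal$sample_id, lys$sample_id)]
  if (is.null(calibrant_copies))
    calibrant_copies <- mean(copiesPerCell(cal$amount, cells))
  a$cal_amount <- cal$amount[match(a$sample_id, cal$sample_id)]
  a <- a[!is.na(a$cal_amount), , drop = FALSE]
  a$copies <- translateCopiesViaCalibrant(calibrant_copies, a$amount,
                                          a$cal_amount)
  est <- vapply(split(a$copies, a$protein_id), mean, numeric(1))
  est[calibrant] <- calibrant_copies
  est
}

#' Molecules bound per receptor unit from AP quantifications
#'
#' For each affinity-purification sample, divides each protein's
#' absolute amount by the receptor amount per oligomeric unit
#' (`receptor_amount / receptor_oligomer`), then averages replicates
#' within each time point.
#'
#' @param amounts protein amount table from [quantifyProteins()].
#' @param meta sample metadata; only `affinity_purification` rows used.
#' @param receptor receptor protein identifier.
#' @param receptor_oligomer receptor homo-oligomer count (default 3).
#' @return data.frame `protein_id`, `timepoint`, `bound` (molecules per
#'   receptor unit).
#' @export
apBoundPerReceptor <- function(amounts, meta, receptor,
                               receptor_oligomer = 3L) {
  ap <- meta[meta$sample_type == "affinity_purification", , drop = FALSE]
  if (!nrow(ap)) stop("no affinity-purification samples in the metadata")
  a <- amounts[amounts$sample_id %in% ap$sample_id, , drop = FALSE]
  rec <- a[a$protein_id == receptor, , drop = FALSE]
  if (!nrow(rec)) stop("receptor '", receptor, "' not quantified")
  a$rec_amount <- rec$amount[match(a$sample_id, rec$sample_id)]
  a <- a[!is.na(a$rec_amount) & a$rec_amount > 0, , drop = FALSE]
  a$bound <- a$amount / (a$rec_amount / receptor_oligomer)
  a$timepoint <- ap$timepoint[match(a$sample_id, ap$sample_id)]
  out <- stats::aggregate(bound ~ protein_id + timepoint, data = a,
                          FUN = mean)
  out <- out[order(out$protein_id, out$timepoint), ]
  rownames(out) <- NULL
  out
}

#' Run the full quantification pipeline on simulated data
#'
#' Simulates lysate and affinity-purification peptide tables from a
#' ground truth, quantifies them, calibrates copies per cell with the
#' receptor ruler, derives per-time-point complex stoichiometries and
#' best integer models, computes the resource allocation (available vs
#' required vs recovered copies, limiting flags), per-cell complex
#' counts, and signalosome molecule/mass estimates over the time
#' course. Deterministic for a given (truth, seed).
#'
#' @param truth a [GroundTruth-class].
#' @param seed integer seed for the measurement simulation.
#' @param nReplicates replicates per time point for both designs.
#' @param peptidesPerProtein peptides per protein.
#' @param outDir optional directory; when given, all result tables plus
#'   a JSON run summary are written via [writeReport()].
#' @param monomer_mw monomer molecular weight table (default
#'   [defaultMonomerMw()]).
#' @return named list of result tables and estimates.
#' @export
runPipeline <- function(truth, seed = 1L, nReplicates = 3L,
                        peptidesPerProtein = 3L, outDir = NULL,
                        monomer_mw = defaultMonomerMw()) {
  stopifnot(is(truth, "GroundTruth"))
  cs <- truthComplexes(truth)
  rec <- receptorProtein(cs)
  oligo <- receptorOligomer(cs)

  lys <- simulateLysateQuant(truth, nReplicates = nReplicates,
                             peptidesPerProtein = peptidesPerProtein,
                             seed = seed)
  ap <- simulateApQuant(truth, nReplicates = nReplicates,
                        peptidesPerProtein = peptidesPerProtein,
                        seed = seed + 1L)
  lysAmounts <- quantifyProteins(lys$peptides)
  apAmounts <- quantifyProteins(ap$peptides)

  copies <- estimateCopiesPerCell(lysAmounts, lys$meta, calibrant = rec)
  bound <- apBoundPerReceptor(apAmounts, ap$meta, receptor = rec,
                              receptor_oligomer = oligo)

  # per-complex, per-timepoint relative stoichiometry from AP amounts
  timepoints <- sort(unique(bound$timepoint))
  stoich <- list()
  models <- list()
  for (cn in complexNames(cs)) {
    cd <- cs[[cn]]
    for (t in timepoints[timepoints > 0]) {
      bt <- bound[bound$timepoint == t, ]
      amt <- setNames(bt$bound, bt$protein_id)
      amt <- amt[names(amt) %in% names(members(cd))]
      if (length(amt) < 1L || all(amt == 0)) next
      st <- relativeStoichiometry(cd, amt, timepoint = t)
      stoich[[length(stoich) + 1L]] <- data.frame(
        complex_name = cn, timepoint = t,
        protein_id = names(st$ratios),
        ratio = unname(st$ratios),
        reference_member = st$reference_member,
        stringsAsFactors = FALSE)
    }
    # integer model from the peak time point (10 min)
    tpk <- timepoints[which.min(abs(timepoints - 10))]
    bt <- bound[bound$timepoint == tpk, ]
    amt <- setNames(bt$bound, bt$protein_id)
    amt <- amt[names(amt) %in% names(members(cd))]
    if (length(amt) >= 2L && all(amt > 0)) {
      st <- relativeStoichiometry(cd, amt, timepoint = tpk)
      top <- fitIntegerStoichiometry(st$ratios, nTop = 1L)
      models[[length(models) + 1L]] <- cbind(
        data.frame(complex_name = cn, timepoint = tpk,
                   stringsAsFactors = FALSE),
        top)
    }
  }
  stoich <- do.call(rbind, stoich)

  # allocation: requirement per member from its complex, receptor-ruled
  required <- numeric(0)
  for (cn in complexNames(cs)) {
    req <- copiesRequiredForIsostoichiometry(cs[[cn]], copies[[rec]],
                                             receptor_oligomer = oligo)
    required[names(req)] <- req
  }
  avail <- copies[names(required)]

  # recovered copies at the recruitment peak
  apMeta <- ap$meta
  cells_ap <- apMeta$cell_equivalents[1]
  tpk <- timepoints[which.min(abs(timepoints - 10))]
  apPk <- apAmounts[apAmounts$sample_id %in%
                      apMeta$sample_id[apMeta$timepoint == tpk], ]
  recAmt <- vapply(split(apPk$amount, apPk$protein_id), mean, numeric(1))
  recovered <- setNames(rep(NA_real_, length(required)), names(required))
  hit <- intersect(names(recAmt), names(recovered))
  recovered[hit] <- copiesPerCell(recAmt[hit], cells_ap)

  allocation <- limitingComponents(avail, required, recovered)

  complexCounts <- data.frame(
    complex_name = complexNames(cs),
    complexes_per_cell = vapply(complexNames(cs), function(cn)
      suppressWarnings(complexesPerCell(copies, cs[[cn]])), numeric(1)),
    stringsAsFactors = FALSE)

  mass <- do.call(rbind, lapply(timepoints[timepoints > 0], function(t) {
    bt <- bound[bound$timepoint == t & bound$protein_id != rec, ]
    # bound is already per receptor unit; feed amounts proportional to it
    est <- signalosomeMass(setNames(bt$bound, bt$protein_id),
                           receptor_amount = oligo, monomer_mw,
                           per = "trimer", receptor_id = rec,
                           receptor_oligomer = oligo, timepoint = t)
    data.frame(timepoint = t,
               total_molecules = est$total_molecules,
               total_mw_mda = est$total_mw_mda,
               ubiquitin_mass_fraction = est$ubiquitin_mass_fraction,
               stringsAsFactors = FALSE)
  }))

  results <- list(
    lysate_amounts = lysAmounts,
    ap_amounts = apAmounts,
    copies_per_cell = data.frame(protein_id = names(copies),
                                 copies_per_cell = unname(copies),
                                 stringsAsFactors = FALSE),
    bound_per_receptor = bound,
    stoichiometry = stoich,
    integer_models = if (length(models))
      do.call(rbind, lapply(models, function(m)
        m[, c("complex_name", "timepoint", "total_copies", "fit_error")]))
      else NULL,
    allocation = allocation,
    complex_counts = complexCounts,
    signalosome_mass = mass)
  results$integer_models_full <- if (length(models)) models else NULL

  if (!is.null(outDir)) {
    tables <- results[vapply(results, is.data.frame, logical(1))]
    writeReport(tables, outDir, seed = seed,
                params = list(nReplicates = nReplicates,
                              peptidesPerProtein = peptidesPerProtein,
                              calibrant = rec,
                              receptor_oligomer = oligo))
  }
  results
}
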