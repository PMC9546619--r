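# AQUA ratio quantification: the endogenous/reference intensity ratio
# times the known spike amount gives the endogenous amount; per-protein
# amounts are the average over peptide-level estimates.

#' Quantify one peptide measurement
#'
#' `amount = endogenous_intensity / reference_intensity * spike_amount`,
#' in amol. Scale-invariant: multiplying both intensities by the same
#' positive constant leaves the amount unchanged.
#'
#' @param endogenous_intensity endogenous-channel intensity (>= 0).
#' @param reference_intensity reference-channel intensity (> 0).
#' @param spike_amount_amol spiked reference amount (amol, > 0).
#' @return amount in amol.
#' @examples
#' quantifyPeptideAmount(2000, 1000, 100)  # 200 amol
#' @export
quantifyPeptideAmount <- function(endogenous_intensity,
                                  reference_intensity,
                                  spike_amount_amol) {
  if (any(reference_intensity <= 0))
    stop(sprintf(
      "quantification error: reference_intensity <= 0 (element %d)",
      which(reference_intensity <= 0)[1]))
  if (any(spike_amount_amol <= 0))
    stop(sprintf(
      "quantification error: spike_amount <= 0 (element %d)",
      which(spike_amount_amol <= 0)[1]))
  endogenous_intensity / reference_intensity * spike_amount_amol
}

#' Aggregate peptide-level amounts into a protein amount
#'
#' The protein amount is the arithmetic mean of its peptide-level
#' amounts (the average-ratio estimator); `median` is available for
#' outlier-prone peptide sets. The CV is the sample standard deviation
#' (n-1 denominator) over the mean, 0 when only one peptide was used.
#'
#' @param amounts numeric vector of peptide-level amounts (amol).
#' @param method `"mean"` (default) or `"median"`.
#' @return list with `amount`, `cv`, `n_peptides`.
#' @examples
#' aggregateProteinAmount(c(80, 100, 120))
#' @export
aggregateProteinAmount <- function(amounts, method = c("mean", "median")) {
  method <- match.arg(method)
  if (!length(amounts)) stop("no peptide-level amounts to aggregate")
  a <- if (method == "mean") mean(amounts) else stats::median(amounts)
  cv <- if (length(amounts) > 1L && a > 0) sd(amounts) / mean(amounts)
        else 0
  list(amount = a, cv = cv, n_peptides = length(amounts))
}

#' Quantify all proteins in a peptide table
#'
#' Applies the AQUA ratio to every usable row and aggregates to one
#' amount per (sample, protein). Rows with zero endogenous intensity are
#' kept (amount 0); rows with zero reference intensity are dropped with
#' a warning. Multiple charge states of the same peptide are averaged at
#' the peptide level before protein aggregation, so multiply-observed
#' peptides are not over-weighted.
#'
#' @param peptides peptide table (see [readPeptideTable()]).
#' @param method aggregation method, `"mean"` (default) or `"median"`.
#' @return data.frame with columns `sample_id`, `protein_id`, `amount`
#'   (amol), `cv`, `n_peptides`.
#' @export
quantifyProteins <- function(peptides, method = c("mean", "median")) {
  method <- match.arg(method)
  validatePeptideTable(peptides)
  drop <- peptides$reference_intensity <= 0
  if (any(drop)) {
    warning(sprintf(
      "dropping %d row(s) with zero reference intensity", sum(drop)))
    peptides <- peptides[!drop, , drop = FALSE]
  }
  if (!nrow(peptides))
    return(data.frame(sample_id = character(), protein_id = character(),
                      amount = numeric(), cv = numeric(),
                      n_peptides = integer(), stringsAsFactors = FALSE))
  peptides$.amount <- quantifyPeptideAmount(
    peptides$endogenous_intensity, peptides$reference_intensity,
    peptides$spike_amount_amol)
  # charge states -> peptide level
  pep <- stats::aggregate(
    .amount ~ sample_id + protein_id + peptide_sequence,
    data = peptides, FUN = mean)
  out <- do.call(rbind, lapply(
    split(pep, list(pep$sample_id, pep$protein_id), drop = TRUE),
    function(g) {
      agg <- aggregateProteinAmount(g$.amount, method)
      data.frame(sample_id = g$sample_id[1], protein_id = g$protein_id[1],
                 amount = agg$amount, cv = agg$cv,
                 n_peptides = agg$n_peptides, stringsAsFactors = FALSE)
    }))
  out <- out[order(out$sample_id, out$protein_id), ]
  rownames(out) <- NULL
  out
}

#' Count observable tryptic peptides
#'
#' In-silico tryptic digestion for the iBAQ denominator: cleavage
#' C-terminal to K or R except before P, no missed cleavages, counting
#' fully tryptic fragments with length in `[min_len, max_len]`.
#'
#' @param sequence amino-acid string (standard 20-letter alphabet).
#' @param min_len,max_len inclusive length window (default 7--30).
#' @return integer count of observable peptides.
#' @examples
#' countObservablePeptides("MKWVTFISLLFLFSSAYSR")  # 1
#' @export
countObservablePeptides <- function(sequence, min_len = 7L, max_len = 30L) {
  if (!nzchar(sequence)) stop("empty protein sequence")
  sequence <- toupper(sequence)
  if (grepl("[^ACDEFGHIKLMNPQRSTVWY]", sequence))
    stop("non-amino-acid character in sequence")
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  cut <- which(aa %in% c("K", "R"))
  cut <- cut[cut < n]            # terminal K/R just ends the chain
  cut <- cut[aa[cut + 1L] != "P"]  # no cleavage before proline
  starts <- c(1L, cut + 1L)
  ends <- c(cut, n)
  len <- ends - starts + 1L
  sum(len >= min_len & len <= max_len)
}

#' iBAQ abundance
#'
#' Intensity-based absolute quantification: the protein's summed peptide
#' intensity divided by its number of theoretically observable tryptic
#' peptides, giving a relative molar abundance.
#'
#' @param summed_intensity summed peptide intensity (>= 0).
#' @param observable_peptides observable tryptic peptide count (>= 1).
#' @return list with `summed_intensity`, `observable_peptides`, `ibaq`.
#' @examples
#' ibaqAbundance(1e6, 10)$ibaq  # 1e5
#' @export
ibaqAbundance <- function(summed_intensity, observable_peptides) {
  if (observable_peptides < 1L)
    stop("observable_peptides must be >= 1")
  if (summed_intensity < 0)
    stop("summed_intensity must be >= 0")
  list(summed_intensity = summed_intensity,
       observable_peptides = as.integer(observable_peptides),
       ibaq = summed_intensity / observable_peptides)
}

#' Fit dilution-series linearity
#'
#' Ordinary least squares of log10 intensity on log10 injected amount
#' over a reference-peptide dilution series (the assessment design
#' injects 0.4 to 40,000 amol in ten-fold steps). Points with zero
#' intensity are excluded and counted.
#'
#' @param amounts injected amounts (amol), strictly increasing.
#' @param intensities measured intensities (same length).
#' @return list with `slope`, `intercept`, `r_squared`, `n_used`,
#'   `n_excluded`.
#' @examples
#' fitLinearity(c(0.4, 4, 40, 400, 4000, 40000),
#'              1000 * c(0.4, 4, 40, 400, 4000, 40000))
#' @export
fitLinearity <- function(amounts, intensities) {
  stopifnot(length(amounts) == length(intensities))
  if (is.unsorted(amounts, strictly = TRUE))
    stop("amounts must be strictly increasing")
  keep <- intensities > 0
  n_excluded <- sum(!keep)
  x <- log10(amounts[keep])
  y <- log10(intensities[keep])
  if (length(x) < 3L)
    stop("insufficient data: fewer than 3 usable dilution points")
  fit <- lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r2, n_used = length(x), n_excluded = n_excluded)
}
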