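# Differential native-gel migration-profile analysis: normalisation,
# first-relative-minimum anchoring, early/late deubiquitinase shift,
# ladder periodicity, and comigration correlation.

#' Normalise a profile to its maximum
#'
#' @param profile numeric vector of per-fraction intensities (>= 0).
#' @return profile divided by its maximum (output max = 1); idempotent.
#' @examples
#' normalizeProfileMax(c(2, 4, 8))
#' @export
normalizeProfileMax <- function(profile) {
  m <- max(profile)
  if (m <= 0) stop("cannot normalise an all-zero profile")
  profile / m
}

# centred moving average; the window shrinks symmetrically at the edges
.smoothProfile <- function(x, window) {
  if (window <= 1L) return(x)
  h <- (window - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    k <- min(h, i - 1L, n - i)
    mean(x[(i - k):(i + k)])
  }, numeric(1))
}

#' Find the first relative minimum of a profile
#'
#' After centred moving-average smoothing (window shrinking at the
#' edges), returns the smallest index `i` with
#' `smoothed[i] < smoothed[i-1]` and `smoothed[i] <= smoothed[i+1]`;
#' plateaus resolve to their earliest index. Used to pick the anchor
#' fraction separating well-trapped from resolved signal.
#'
#' @param profile numeric vector (length >= 3).
#' @param smoothing_window centred window size (default 3).
#' @return 1-based fraction index of the first relative minimum.
#' @examples
#' findFirstRelativeMinimum(c(10, 7, 4, 6, 9, 3, 8),
#'                          smoothing_window = 1)  # 3
#' @export
findFirstRelativeMinimum <- function(profile, smoothing_window = 3L) {
  if (length(profile) < 3L) stop("profile too short")
  s <- .smoothProfile(profile, smoothing_window)
  n <- length(s)
  for (i in 2:(n - 1L))
    if (s[i] < s[i - 1L] && s[i] <= s[i + 1L]) return(i)
  stop("no relative minimum found (monotone profile)")
}

#' Normalise a profile to a chosen anchor fraction
#'
#' @param profile numeric vector of intensities.
#' @param fraction_index 1-based anchor fraction; its intensity must be
#'   positive.
#' @return profile divided by the anchor intensity.
#' @examples
#' normalizeProfileToFraction(c(9, 6, 3, 6, 9), 3)
#' @export
normalizeProfileToFraction <- function(profile, fraction_index) {
  stopifnot(fraction_index >= 1, fraction_index <= length(profile))
  a <- profile[fraction_index]
  if (a <= 0) stop("zero intensity at the anchor fraction")
  profile / a
}

#' Early-to-late signal shift between conditions
#'
#' For each protein present in both conditions, computes the early
#' share: the fraction of total signal in fractions
#' `1..early_cutoff`. Deubiquitinase-driven disassembly moves signal
#' out of the well, so untreated profiles should have the larger early
#' share; a paired one-sided Wilcoxon signed-rank test across proteins
#' tests `early_share(minus) > early_share(plus)`. Shares are invariant
#' to per-profile rescaling. With fewer than 5 matched proteins the
#' test is skipped (p = NA) with a warning; shares are still reported.
#'
#' @param profiles_minus,profiles_plus named lists (or matrices with
#'   proteins in columns) of per-fraction intensity vectors for the
#'   untreated and deubiquitinase-treated condition.
#' @param early_cutoff last "early" fraction (default 5).
#' @return list with `shares` (data.frame: `protein_id`,
#'   `early_share_minus`, `early_share_plus`, `difference`) and
#'   `p_value`.
#' @export
earlyLateShift <- function(profiles_minus, profiles_plus,
                           early_cutoff = 5L) {
  asList <- function(x) {
    if (is.matrix(x)) {
      out <- lapply(seq_len(ncol(x)), function(j) x[, j])
      names(out) <- colnames(x)
      out
    } else x
  }
  pm <- asList(profiles_minus)
  pp <- asList(profiles_plus)
  ids <- intersect(names(pm), names(pp))
  if (!length(ids)) stop("no matched proteins between conditions")
  share <- function(v) {
    if (early_cutoff >= length(v))
      stop("early_cutoff must be smaller than the profile length")
    tot <- sum(v)
    if (tot <= 0) return(NA_real_)
    sum(v[seq_len(early_cutoff)]) / tot
  }
  sm <- vapply(pm[ids], share, numeric(1))
  sp <- vapply(pp[ids], share, numeric(1))
  shares <- data.frame(protein_id = ids,
                       early_share_minus = unname(sm),
                       early_share_plus = unname(sp),
                       difference = unname(sm - sp),
                       stringsAsFactors = FALSE)
  usable <- stats::complete.cases(shares)
  p <- NA_real_
  if (sum(usable) < 5L) {
    warning("fewer than 5 matched proteins; shift test skipped")
  } else if (all(shares$difference[usable] == 0)) {
    p <- 1  # no shift anywhere
  } else {
    p <- suppressWarnings(wilcox.test(
      shares$early_share_minus[usable], shares$early_share_plus[usable],
      paired = TRUE, alternative = "greater"))$p.value
  }
  list(shares = shares, p_value = p)
}

# topographic prominence of a local maximum at index i: height above
# the higher of the two minima separating it from higher ground
.prominence <- function(x, i) {
  n <- length(x)
  left <- x[i]; j <- i
  while (j > 1L && x[j - 1L] <= x[i]) {
    j <- j - 1L
    left <- min(left, x[j])
  }
  if (j == 1L && x[j] <= x[i]) left <- min(x[seq_len(i)])
  right <- x[i]; j <- i
  while (j < n && x[j + 1L] <= x[i]) {
    j <- j + 1L
    right <- min(right, x[j])
  }
  if (j == n && x[j] <= x[i]) right <- min(x[i:n])
  x[i] - max(left, right)
}

#' Detect ladder peaks and their periodicity
#'
#' Finds local maxima whose topographic prominence is at least
#' `min_prominence_fraction` of the profile maximum, optionally
#' excluding the well region, and summarises the ladder: peak
#' positions, successive spacings with their mean and CV, and
#' successive peak-height ratios. An empty result is a valid outcome
#' (no qualifying peaks), not an error.
#'
#' @param profile numeric per-fraction intensity vector (typically
#'   max-normalised).
#' @param min_prominence_fraction prominence threshold as a fraction of
#'   the profile maximum (default 0.1).
#' @param exclude_well number of leading well fractions to exclude from
#'   peak calling (default 0).
#' @return list with `peak_indices`, `peak_heights`, `spacings`,
#'   `spacing_mean`, `spacing_cv`, `peak_intensity_ratios`
#'   (`spacing_*` are NA with fewer than two peaks).
#' @examples
#' x <- rowSums(sapply(c(10, 20, 30), function(c0)
#'   exp(-(seq_len(40) - c0)^2 / 2)))
#' detectPeaksAndPeriodicity(normalizeProfileMax(x))$peak_indices
#' @export
detectPeaksAndPeriodicity <- function(profile,
                                      min_prominence_fraction = 0.1,
                                      exclude_well = 0L) {
  n <- length(profile)
  if (exclude_well >= n) stop("exclude_well must be < length(profile)")
  # the threshold baseline excludes the well region too, so dominant
  # well-trapped signal cannot mask the resolved ladder
  thr <- min_prominence_fraction *
    max(profile[(exclude_well + 1L):n])
  idx <- integer(0)
  for (i in seq_len(n)) {
    if (i <= exclude_well) next
    l <- if (i > 1L) profile[i - 1L] else -Inf
    r <- if (i < n) profile[i + 1L] else -Inf
    # strict rise on the left, fall-or-end on the right: plateaus
    # report their first fraction
    if (profile[i] > l && profile[i] >= r) {
      if (.prominence(profile, i) >= thr) idx <- c(idx, i)
    }
  }
  heights <- profile[idx]
  spacings <- if (length(idx) >= 2L) diff(idx) else numeric(0)
  ratios <- if (length(idx) >= 2L) heights[-1] / heights[-length(heights)]
            else numeric(0)
  list(peak_indices = idx,
       peak_heights = heights,
       spacings = spacings,
       spacing_mean = if (length(spacings)) mean(spacings) else NA_real_,
       spacing_cv = if (length(spacings) >= 2L && mean(spacings) > 0)
         sd(spacings) / mean(spacings)
         else if (length(spacings) == 1L) 0 else NA_real_,
       peak_intensity_ratios = ratios)
}

#' Pairwise comigration correlation matrix
#'
#' Pearson correlation between migration profiles on a shared fraction
#' grid: diagonal 1, symmetric. Zero-variance profiles get `NA`
#' correlations with a warning.
#'
#' @param profiles numeric matrix, fractions in rows, proteins in
#'   columns (as from [profilesToMatrix()]).
#' @return correlation matrix.
#' @export
comigrationMatrix <- function(profiles) {
  stopifnot(is.matrix(profiles), ncol(profiles) >= 2L)
  v <- apply(profiles, 2L, sd)
  if (any(v == 0))
    warning(sprintf(
      "zero-variance profile(s): %s; correlations reported as NA",
      paste(colnames(profiles)[v == 0], collapse = ", ")))
  m <- suppressWarnings(cor(profiles))
  diag(m) <- 1
  m
}
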