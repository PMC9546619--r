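# Synthetic-data generator. Emulates the study design end to end:
# spiked-reference peptide tables for lysates and affinity purifications
# (multiplicative lognormal noise, peptide-level response factors that
# cancel in the AQUA ratio, LOD censoring), saturating recruitment
# kinetics peaking at 10 min, and native-gel profiles with well-trapped
# (-DUB) versus periodic-ladder (+DUB) structure.

.recruitScale <- function(t, lag, rate, peak_time, decay_rate) {
  s <- 1 - exp(-rate * pmax(0, t - lag))
  d <- exp(-decay_rate * pmax(0, t - peak_time))
  sp <- (1 - exp(-rate * pmax(0, peak_time - lag)))
  v <- s * d
  if (sp > 0) v / sp else v
}

#' Generate a ground-truth cellular state
#'
#' Builds a [GroundTruth-class] from a configuration (see
#' [defaultTruthConfig()]): per-protein copies per cell (fixed values
#' are taken verbatim; complex members without a fixed value are drawn
#' log-uniformly from `config$copiesRange`; the receptor, being the
#' ruler anchor, must always have a fixed value), and copies bound per
#' trimeric receptor unit over the stimulation time course, obtained by
#' scaling each protein's peak occupancy with a saturating-with-lag,
#' post-peak-decaying recruitment curve. The receptor itself is bound at
#' its oligomer count at every time point; every other protein is
#' unbound at time 0.
#'
#' @param config configuration list with elements `complexes`
#'   ([ComplexSet-class]), `copiesPerCell`, `peakBound`, `recruitment`,
#'   `timepoints`, `noiseCv`, `responseFactorSigma`, `lodAmol`, and
#'   optionally `copiesRange` (c(min, max) copies for unfixed members).
#' @param seed integer seed; the result is deterministic given
#'   (config, seed).
#' @return a validated [GroundTruth-class].
#' @examples
#' truth <- generateTruth(defaultTruthConfig(), seed = 1)
#' head(truthCopies(truth))
#' @export
generateTruth <- function(config, seed = 1L) {
  stopifnot(is.list(config))
  cs <- config$complexes
  if (is.null(cs) || !is(cs, "ComplexSet"))
    stop("config$complexes must be a ComplexSet")
  rec <- receptorProtein(cs)
  fixed <- config$copiesPerCell
  if (is.null(fixed)) fixed <- numeric(0)
  proteins <- union(allMembers(cs), names(fixed))
  if (!rec %in% names(fixed))
    stop(sprintf(
      "receptor protein '%s' has no copies-per-cell entry; the ruler anchor must be fixed, not drawn",
      rec))
  unfixed <- setdiff(proteins, names(fixed))
  cpc <- fixed[intersect(names(fixed), proteins)]
  if (length(unfixed)) {
    rng <- config$copiesRange
    if (is.null(rng)) rng <- c(1e3, 1e6)
    if (rng[1] > rng[2])
      stop("config$copiesRange: min exceeds max")
    drawn <- withr::with_seed(seed, {
      10^runif(length(unfixed), log10(rng[1]), log10(rng[2]))
    })
    cpc <- c(cpc, setNames(drawn, unfixed))
  }
  cpc <- cpc[order(names(cpc))]

  tp <- config$timepoints
  if (is.null(tp)) tp <- c(0, 5, 10, 15)
  rp <- config$recruitment
  if (is.null(rp))
    rp <- data.frame(complex_name = complexNames(cs), lag = 1, rate = 0.35,
                     peak_time = 10, decay_rate = 0.04,
                     stringsAsFactors = FALSE)

  # protein -> kinetics row: first complex containing it, otherwise the
  # 'ubiquitin' row (free-ubiquitin pool), otherwise the last row.
  proteinComplex <- function(p) {
    for (cc in cs@complexes) if (p %in% names(members(cc)))
      return(complexName(cc))
    if ("ubiquitin" %in% rp$complex_name) "ubiquitin" else
      rp$complex_name[nrow(rp)]
  }
  peak <- config$peakBound
  if (is.null(peak)) peak <- numeric(0)
  oligo <- receptorOligomer(cs)

  rows <- lapply(setdiff(names(cpc), rec), function(p) {
    pb <- if (p %in% names(peak)) unname(peak[p]) else {
      cn <- proteinComplex(p)
      mult <- if (cn %in% complexNames(cs))
        unname(members(cs[[cn]])[p]) else NA_real_
      if (is.na(mult)) 1 else mult  # profiled extras default to 1
    }
    k <- rp[match(proteinComplex(p), rp$complex_name), ]
    data.frame(protein_id = p, timepoint = tp,
               bound = pb * .recruitScale(tp, k$lag, k$rate, k$peak_time,
                                          k$decay_rate),
               stringsAsFactors = FALSE)
  })
  bound <- rbind(
    data.frame(protein_id = rec, timepoint = tp, bound = oligo,
               stringsAsFactors = FALSE),
    do.call(rbind, rows))
  bound <- bound[order(bound$protein_id, bound$timepoint), ]
  rownames(bound) <- NULL

  new("GroundTruth",
    copiesPerCell = cpc,
    complexes = cs,
    boundPerReceptor = bound,
    recruitmentParams = rp,
    noiseCv = if (is.null(config$noiseCv)) 0.2 else config$noiseCv,
    responseFactorSigma = if (is.null(config$responseFactorSigma)) 0.5
                          else config$responseFactorSigma,
    lodAmol = if (is.null(config$lodAmol)) 0.01 else config$lodAmol,
    seed = as.integer(seed))
}

# sigma per intensity channel such that the endogenous/reference ratio
# (a ratio of two iid lognormals) has coefficient of variation cv.
.channelSigma <- function(cv) sqrt(log1p(cv^2) / 2)

#' Default spike ladders
#'
#' Geometric ladders of reference-peptide spike amounts: five levels for
#' lysate samples and four for affinity-purified samples, spanning 16 to
#' 160,000 amol.
#' @return numeric vector of spike amounts (amol).
#' @export
defaultSpikeLevels <- function() 16 * 10^(0:4)

#' @rdname defaultSpikeLevels
#' @export
defaultApSpikeLevels <- function() 16 * 10^seq(0, 4, length.out = 4)

.nearestSpike <- function(amount, levels) {
  levels[pmax(1L, pmin(length(levels),
    vapply(amount, function(a) {
      if (a <= 0) 1L else which.min(abs(log(levels) - log(a)))
    }, integer(1))))]
}

# Core measurement model shared by lysate and AP simulators. amounts:
# named list sample_id -> named numeric of true amounts (amol).
.simulatePeptides <- function(amounts, peptidesPerProtein, spikeLevels,
                              noiseCv, responseFactorSigma, lodAmol,
                              seed) {
  if (peptidesPerProtein < 1L)
    stop("peptidesPerProtein must be >= 1")
  sigma <- .channelSigma(noiseCv)
  proteins <- sort(unique(unlist(lapply(amounts, names))))
  withr::with_seed(seed, {
    # one flyability factor per (protein, peptide), shared across samples
    rf <- matrix(exp(rnorm(length(proteins) * peptidesPerProtein, 0,
                           responseFactorSigma)),
                 nrow = length(proteins),
                 dimnames = list(proteins, NULL))
    perSample <- lapply(names(amounts), function(sid) {
      a <- amounts[[sid]]
      keep <- names(a)[a >= lodAmol]  # LOD censoring: row omitted
      if (!length(keep)) return(NULL)
      true <- rep(unname(a[keep]), each = peptidesPerProtein)
      prot <- rep(keep, each = peptidesPerProtein)
      pep <- rep(seq_len(peptidesPerProtein), times = length(keep))
      spike <- rep(.nearestSpike(pmax(unname(a[keep]),
                                      spikeLevels[1] * 1e-6),
                                 spikeLevels),
                   each = peptidesPerProtein)
      fly <- rf[cbind(match(prot, proteins), pep)]
      n <- length(true)
      eps <- matrix(rnorm(2L * n, 0, sigma), ncol = 2L)
      data.frame(
        sample_id = sid,
        protein_id = prot,
        peptide_sequence = sprintf("%s_pep%02d", prot, pep),
        charge = 2L,
        endogenous_intensity = fly * true * exp(eps[, 1L]),
        reference_intensity = fly * spike * exp(eps[, 2L]),
        spike_amount_amol = spike,
        stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, perSample)
    rownames(out) <- NULL
    out
  })
}

#' Simulate lysate AQUA quantification
#'
#' Emulates the lysate absolute-quantification design: for each time
#' point and replicate one lysate sample, each protein represented by
#' `peptidesPerProtein` peptides whose reference channel is spiked at
#' the ladder level nearest the endogenous amount. Intensities follow
#' `response_factor * amount * exp(eps)` with `eps ~ N(0, sigma)` and
#' sigma chosen so the endogenous/reference ratio has CV `noiseCv(truth)`;
#' the shared per-peptide response factor cancels in the ratio. True
#' amounts below the LOD are censored (row omitted). Copy numbers are a
#' property of the cell state, so true amounts do not depend on the
#' time point; the time course simply yields the study's 12 lysates
#' (3 replicates x 4 time points) for pooled estimation.
#'
#' @param truth a [GroundTruth-class].
#' @param nReplicates lysate replicates per time point (default 3).
#' @param peptidesPerProtein peptides monitored per protein (default 3).
#' @param spikeLevels spike ladder in amol (default 5 levels, 16 to
#'   160,000).
#' @param timepoints minutes (default the truth's time points).
#' @param cellEquivalents cells represented by the matrix at the spike
#'   point (default ~3,043: 0.7% injection of a 435,000-cell digest).
#' @param injectedFraction recorded injected fraction (default 0.007).
#' @param seed integer seed.
#' @return list with elements `peptides` (peptide table) and `meta`
#'   (sample metadata), both in the canonical TSV column layout.
#' @export
simulateLysateQuant <- function(truth, nReplicates = 3L,
                                peptidesPerProtein = 3L,
                                spikeLevels = defaultSpikeLevels(),
                                timepoints = NULL,
                                cellEquivalents = 435000 * 0.007,
                                injectedFraction = 0.007,
                                seed = 1L) {
  stopifnot(is(truth, "GroundTruth"))
  if (is.null(timepoints))
    timepoints <- sort(unique(boundPerReceptor(truth)$timepoint))
  amol <- truthCopies(truth) * cellEquivalents / AVOGADRO * 1e18
  amounts <- list()
  meta <- list()
  for (t in timepoints) for (r in seq_len(nReplicates)) {
    sid <- sprintf("lysate_t%02d_r%d", as.integer(t), r)
    amounts[[sid]] <- amol
    meta[[sid]] <- data.frame(
      sample_id = sid, sample_type = "lysate", timepoint = t,
      replicate = r, cell_equivalents = cellEquivalents,
      injected_fraction = injectedFraction, treatment = "",
      fraction_index = NA_integer_, stringsAsFactors = FALSE)
  }
  peptides <- .simulatePeptides(amounts, peptidesPerProtein, spikeLevels,
                                truth@noiseCv, truth@responseFactorSigma,
                                truth@lodAmol, seed)
  list(peptides = peptides, meta = do.call(rbind, meta))
}

#' Simulate affinity-purification AQUA quantification
#'
#' True affinity-purified amount of protein p at time t equals
#' `bound_per_receptor(p, t) * receptor_trimers_per_cell * cells`, with
#' receptor trimers per cell given by the truth's receptor copy number
#' divided by its oligomer count, passed through the same measurement
#' model as [simulateLysateQuant()]. At time 0 only the receptor has
#' signal.
#'
#' @inheritParams simulateLysateQuant
#' @param timepoints minutes; must include 0.
#' @param processedCells cells processed per AP sample, represented at
#'   the spike point (default 2.4e6, i.e. 2% of 1.2e8 starting cells).
#' @param nReplicates AP replicates per time point (default 3).
#' @return list with `peptides` and `meta` as in
#'   [simulateLysateQuant()].
#' @export
simulateApQuant <- function(truth, timepoints = NULL,
                            processedCells = 2.4e6,
                            injectedFraction = 1,
                            nReplicates = 3L,
                            peptidesPerProtein = 3L,
                            spikeLevels = defaultApSpikeLevels(),
                            seed = 1L) {
  stopifnot(is(truth, "GroundTruth"))
  b <- boundPerReceptor(truth)
  if (is.null(timepoints)) timepoints <- sort(unique(b$timepoint))
  if (any(timepoints < 0)) stop("negative timepoint")
  if (processedCells <= 0) stop("processedCells must be > 0")
  rec <- receptorProtein(truthComplexes(truth))
  trimers <- truthCopies(truth)[[rec]] /
    receptorOligomer(truthComplexes(truth))
  amounts <- list()
  meta <- list()
  for (t in timepoints) for (r in seq_len(nReplicates)) {
    sid <- sprintf("ap_t%02d_r%d", as.integer(t), r)
    bt <- b[b$timepoint == t, ]
    a <- setNames(bt$bound * trimers * processedCells / AVOGADRO * 1e18,
                  bt$protein_id)
    amounts[[sid]] <- a
    meta[[sid]] <- data.frame(
      sample_id = sid, sample_type = "affinity_purification",
      timepoint = t, replicate = r, cell_equivalents = processedCells,
      injected_fraction = injectedFraction, treatment = "",
      fraction_index = NA_integer_, stringsAsFactors = FALSE)
  }
  peptides <- .simulatePeptides(amounts, peptidesPerProtein, spikeLevels,
                                truth@noiseCv, truth@responseFactorSigma,
                                truth@lodAmol, seed)
  list(peptides = peptides, meta = do.call(rbind, meta))
}

#' Simulate differential BNPAGE migration profiles
#'
#' Generates per-fraction intensity profiles for every protein of the
#' truth in two conditions. Without deubiquitinase treatment
#' (`minusDUB`) the signalosome stays trapped in the gel well: all
#' specific signal falls in fractions 1..`wellFractions` (geometrically
#' decaying into the gel). After deubiquitinase treatment (`plusDUB`)
#' the signal resolves into a ladder: Gaussian peaks centred at
#' `period, 2*period, ...` with a constant successive height ratio. A
#' uniform additive noise floor (amplitude `noise`) is applied to both;
#' with `noise = 0` the profiles are exact.
#'
#' @param truth a [GroundTruth-class].
#' @param nFractions number of 1-mm gel slices (default 70; gels in
#'   this design are cut into 65--75 slices).
#' @param period ladder spacing in fractions (default 10).
#' @param wellFractions number of well fractions (default 3).
#' @param nPeaks number of ladder peaks (default 3).
#' @param peakSigma Gaussian peak width in fractions (default 1.5).
#' @param heightRatio successive peak-height ratio (default 0.7).
#' @param noise uniform noise-floor amplitude relative to the profile
#'   maximum (default 0.02).
#' @param seed integer seed.
#' @return long data.frame with columns `protein_id`, `condition`
#'   (`minusDUB`/`plusDUB`), `fraction_index`, `intensity`.
#' @export
simulateBnpageProfiles <- function(truth, nFractions = 70L, period = 10L,
                                   wellFractions = 3L, nPeaks = 3L,
                                   peakSigma = 1.5, heightRatio = 0.7,
                                   noise = 0.02, seed = 1L) {
  stopifnot(is(truth, "GroundTruth"))
  if (period >= nFractions)
    stop("period must be smaller than the number of fractions")
  if (wellFractions < 1L || wellFractions >= nFractions)
    stop("wellFractions must be in [1, nFractions)")
  proteins <- names(truthCopies(truth))
  fr <- seq_len(nFractions)
  centers <- period * seq_len(nPeaks)
  centers <- centers[centers <= nFractions]
  withr::with_seed(seed, {
    rows <- list()
    for (p in proteins) {
      scale <- 1 + runif(1)  # per-protein overall signal scale
      minus <- numeric(nFractions)
      minus[seq_len(wellFractions)] <-
        scale * 0.6^(seq_len(wellFractions) - 1)
      plus <- numeric(nFractions)
      for (k in seq_along(centers))
        plus <- plus + scale * heightRatio^(k - 1) *
          exp(-((fr - centers[k])^2) / (2 * peakSigma^2))
      if (noise > 0) {
        minus <- minus + runif(nFractions, 0, noise * max(minus))
        plus <- plus + runif(nFractions, 0, noise * max(plus))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = p,
        condition = rep(c("minusDUB", "plusDUB"), each = nFractions),
        fraction_index = rep(fr, 2L),
        intensity = c(minus, plus),
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out[order(out$protein_id, out$condition, out$fraction_index), ]
  })
}

#' Export a ground truth as JSON
#'
#' Writes the simulated cellular state (copies per cell, bound copies
#' over time, noise parameters, seed) as JSON so downstream checks can
#' use it as an oracle.
#'
#' @param truth a [GroundTruth-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTruth <- function(truth, path) {
  stopifnot(is(truth, "GroundTruth"))
  jsonlite::write_json(list(
    copies_per_cell = as.list(truthCopies(truth)),
    bound_per_receptor = boundPerReceptor(truth),
    recruitment = truth@recruitmentParams,
    noise_cv = truth@noiseCv,
    response_factor_sigma = truth@responseFactorSigma,
    lod_amol = truth@lodAmol,
    seed = truth@seed), path, auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(path)
}
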