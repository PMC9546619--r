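# Shared fixtures: small complex sets and truths built in code.

toyComplexSet <- function() {
  ComplexSet(
    ComplexDefinition("receptor-core", c(TNFR1 = 3, TRADD = 1),
                      receptorFlag = TRUE, receptorOligomer = 3L),
    ComplexDefinition("CYLD-SPATA2", c(CYLD = 2, SPATA2 = 2)))
}

# one-protein truth for measurement-noise checks: the receptor is its
# own (monomeric) complex
singleProteinTruth <- function(noiseCv, copies = 1e5, seed = 1) {
  cfg <- list(
    complexes = ComplexSet(
      ComplexDefinition("solo", c(X = 1), receptorFlag = TRUE,
                        receptorOligomer = 1L)),
    copiesPerCell = c(X = copies),
    timepoints = 0,
    noiseCv = noiseCv, responseFactorSigma = 0.5, lodAmol = 0)
  generateTruth(cfg, seed = seed)
}

noiselessTruth <- function(seed = 1) {
  generateTruth(defaultTruthConfig(noiseCv = 0, responseFactorSigma = 0,
                                   lodAmol = 0), seed = seed)
}

# independent brute-force enumeration of integer stoichiometry models,
# written as plain nested loops (oracle for fitIntegerStoichiometry)
bruteForceBestError <- function(obs, maxCopies = 4L, allowExcess = TRUE) {
  n <- length(obs)
  gcdAll <- function(v) {
    g <- v[1]
    for (x in v[-1]) {
      a <- g; b <- x
      while (b != 0) { t <- b; b <- a %% b; a <- t }
      g <- a
    }
    g
  }
  best <- Inf
  bases <- expand.grid(rep(list(seq_len(maxCopies)), n))
  excesses <- if (allowExcess)
    expand.grid(rep(list(0:maxCopies), n)) else
    as.data.frame(matrix(0L, 1, n))
  for (i in seq_len(nrow(bases))) {
    b <- as.numeric(bases[i, ])
    if (gcdAll(b) != 1) next
    for (j in seq_len(nrow(excesses))) {
      e <- as.numeric(excesses[j, ])
      tot <- b + e  # the all-zero excess row is the no-excess model
      pred <- tot / max(tot)
      err <- sqrt(mean((log2(pred) - log2(obs))^2))
      if (err < best) best <- err
    }
  }
  best
}
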