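---
title: "Methods: from spiked peptide ratios to cellular context"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from spiked peptide ratios to cellular context}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contextomics)
```

This vignette documents the quantitative model behind `contextomics`,
the parameter choices, what the synthetic-data generator does and does
not capture, and the numerical decisions made along the way. It states
no empirical results beyond what the package's tests and
`scripts/acceptance.R` compute.

## 1. Absolute quantification from spiked references

A stable-isotope-labeled reference peptide of known amount is spiked
into each sample. For one peptide,

$$\mathrm{amount} = \frac{I_\mathrm{endogenous}}{I_\mathrm{reference}}
  \times \mathrm{spike\ (amol)}.$$

Systematic peptide-level effects (ionisation efficiency, recovery —
"flyability") multiply both channels and cancel in the ratio; that is
the method's central virtue and the reason `quantifyProteins()` works
at the ratio level. Charge states of one peptide are averaged first,
then peptides are averaged per protein (`mean` by default, `median`
available); the reported CV uses the sample standard deviation
(`n - 1`). A zero endogenous intensity is a valid measurement (amount
0); a zero reference intensity destroys the ratio and the row is
dropped with a warning.

iBAQ (`ibaqAbundance()`) divides a protein's summed intensity by its
count of observable tryptic peptides: fully tryptic cleavage (after K
or R, not before P), zero missed cleavages, length 7–30 residues
(`countObservablePeptides()`). Dilution linearity
(`fitLinearity()`) is assessed by ordinary least squares in
log10–log10 space, excluding zero intensities, because spike ladders
are geometric and relative (fold) error is the natural scale.

## 2. Integer stoichiometry

`relativeStoichiometry()` expresses member amounts relative to the
most abundant member (or a fixed reference). `fitIntegerStoichiometry()`
then searches integer explanations exhaustively:

* base vectors in $\{1..m\}^n$ reduced to gcd 1 (a stoichiometry is a
  ratio, so $2{:}2$ is $1{:}1$);
* optionally one additive excess vector in $\{0..m\}^n$, representing
  a mixture in which extra copies of some subunits ride on an
  isostoichiometric core (how a $1{:}1{:}1$ ligase core carrying one
  extra copy of two subunits yields observed $0.5{:}1{:}1$);
* predictions are $(\mathrm{base}+\mathrm{excess})$ normalised to
  their maximum; the fit error is root-mean-square in log2 space, so
  two-fold deviations up and down weigh equally;
* ranking: fit error, then total copy number (parsimony), then
  lexicographic order of `c(base, excess)` — a complete, deterministic
  tie-break, which matters because distinct (base, excess) pairs can
  predict identical ratio vectors.

The default bound `maxCopies = 4` covers trimers, dimers, 2:2:1
arrangements and core-plus-excess mixtures while keeping the search
space exactly enumerable; raising it grows the space as
$m^n (m{+}1)^n$. The acceptance suite verifies self-consistency over
the *entire* default space for 2- and 3-member complexes: every
distinct predicted ratio vector refits at zero error.

## 3. Cellular context

Conversions are elementary but load-bearing:

* protein mass per cell = total protein mass / cell count
  (`proteinMassPerCell()`), e.g. 4.1 mg from 1.8×10⁷ cells ≈ 228 pg;
* cell equivalents = processed protein mass / per-cell mass
  (`cellEquivalents()`), scaled by the injected fraction
  (`injectedCellEquivalents()`);
* copies per cell = amount × Avogadro / cell equivalents
  (`copiesPerCell()`); one zeptomole ≈ 602 molecules.

**Receptor ruler.** Absolute amounts are calibrated to copies per cell
through a receptor of independently known (or directly computable)
copy number: `translateCopiesViaCalibrant()` multiplies the calibrant's
copies by the within-sample amount ratio. `estimateCopiesPerCell()`
pools *all* lysate samples — replicates and stimulation time points —
because copy number is a property of the cell state, not of the
stimulation time; pooling 3 replicates × 4 time points gives 12
per-sample estimates per protein and is what makes the 10 %-accuracy
recovery target statistically reachable at CV 0.2 (3 samples alone
would not suffice; this is a design property, not a tuning knob).

**Allocation.** `copiesRequiredForIsostoichiometry()` asks how many
copies per cell of each member are needed to supply one complete
complex per oligomeric receptor unit
($\mathrm{mult}_i \times \mathrm{receptor}/3$ for a trimer).
`limitingComponents()` flags members strictly below their requirement
(equality is "exactly sufficient") and sorts by available/required so
the tightest constraint comes first. `complexesPerCell()` is the
minimum over members of copies/multiplicity.

**Signalosome mass.** `signalosomeMass()` converts bound amounts into
molecules per receptor unit and sums monomer masses. The default
accounting unit is the receptor *trimer* (`per = "trimer"`), since the
ligand-bound receptor is trimeric and "molecules per signalosome" is
the quantity of interest; `per = "monomer"` divides by single chains.
Ubiquitin contributing more than half the mass sets a
`ubiquitin_dominated` flag, because in that regime the assembly's size
is a statement about its scaffold, not its subunit count.

## 4. Native-gel migration profiles

Profiles (intensity per gel fraction) are compared after
normalisation: to the maximum, to a fixed anchor fraction, or to the
first relative minimum (`findFirstRelativeMinimum()`), which separates
well-trapped from resolved signal. The minimum search smooths with a
centred moving average (window 3, shrinking at the edges) so a
single-fraction glitch does not create a spurious anchor; plateaus
resolve to their earliest fraction for determinism.

The deubiquitinase shift test (`earlyLateShift()`) reduces each
profile to its *early share* — the fraction of total signal in
fractions 1..cutoff (default 5) — which is invariant to per-profile
scaling, and applies a paired one-sided Wilcoxon signed-rank test
(untreated > treated) across proteins. A nonparametric paired test is
used because per-protein shares are bounded, non-normal, and profiles
are paired by protein across conditions. Fewer than 5 matched proteins
cannot give a meaningful rank test, so the p-value is NA with a
warning rather than a fragile number.

`detectPeaksAndPeriodicity()` calls local maxima whose *topographic
prominence* (height above the higher of the two flanking minima that
separate a peak from higher ground) reaches 10 % of the profile
maximum — prominence, unlike raw height, ignores shoulders on the
flank of a larger peak. When leading well fractions are excluded, the
threshold baseline excludes them too, so dominant well-trapped signal
cannot mask the resolved ladder. Ladder structure is summarised as
peak spacings (mean, CV) and successive height ratios;
`comigrationMatrix()` gives pairwise Pearson correlations on the
shared fraction grid.

## 5. The synthetic-data generator

The generator is a first-class deliverable and mirrors the real study
design rather than an abstract benchmark:

* **Cell state** (`generateTruth()`): per-protein copies per cell
  (fixed values verbatim; unfixed members drawn log-uniformly; the
  receptor, as ruler anchor, must be fixed), and copies bound per
  receptor trimer over a time course. Recruitment follows a
  saturating-with-lag curve with post-peak decay,
  $b(t) \propto (1-e^{-r\,(t-\ell)_+})\,e^{-d\,(t-t_p)_+}$, scaled so
  the configured peak occupancy is reached at the peak time (10 min).
  Module-specific lags order core before kinases before the
  deubiquitinase module and ubiquitin accumulation. Non-receptor
  proteins are unbound at t = 0.
* **Measurement model** (`simulateLysateQuant()`,
  `simulateApQuant()`): intensity = flyability × amount ×
  $e^\varepsilon$ per channel, with one lognormal flyability factor
  per (protein, peptide) shared across samples — so it cancels in the
  ratio, as in reality — and channel noise
  $\sigma = \sqrt{\log(1+\mathrm{CV}^2)/2}$ chosen so the *ratio* has
  exactly the configured CV (the ratio of two iid lognormals is
  lognormal with doubled variance). Reference spikes snap to the
  nearest geometric ladder level. True amounts below the LOD are
  censored by omitting the row, reproducing missingness, not zeros.
* **Gel profiles** (`simulateBnpageProfiles()`): untreated profiles
  are well-trapped (geometric decay over the well fractions); treated
  profiles are a Gaussian ladder at multiples of the period with a
  constant height ratio; both get a uniform noise floor. With
  `noise = 0` all structure is exact, which the tests exploit.

**Realism and limits.** The generator captures ratio-level noise,
flyability cancellation, LOD censoring, recruitment order and
ubiquitin dominance. It does not model peptide-level interference,
chromatographic drift, partial digestion, isotopic impurity of the
spikes, shared peptides between proteins, or fraction-to-fraction gel
smearing; profile periodicity is idealised as exact. Conclusions about
those effects cannot be drawn from it.

Default parameters (`defaultTruthConfig()`) are chosen a priori to
represent the studied regime — a receptor at 25,000 copies per cell, a
scarce deubiquitinase module, ubiquitin bound at hundreds of copies
per trimer — and are fixed study conditions, not tuned quantities.

## 6. Determinism and numerical choices

All simulation randomness flows through `withr::with_seed()`, so
generators are pure functions of (configuration, seed) and leave the
session RNG untouched. `runPipeline()` with an output directory writes
plain TSV tables plus a JSON summary recording the seed and an MD5
hash of the configuration; identical inputs reproduce byte-identical
files, which the test suite checks with file hashes. Exact comparisons
in tests use exact equality only where the arithmetic is exact
(noiseless closures hold to floating-point round-off); noisy estimates
are tested against pre-stated statistical bands. Log-space is used
wherever quantities are ratios by nature (fit errors, linearity,
spike-level snapping, copy-number draws).

## 7. Limitations

* The integer search is exhaustive and therefore exponential in
  members; for complexes beyond ~5 members at `maxCopies = 4` it
  becomes slow, and a single additive excess vector cannot represent
  arbitrary isoform mixtures.
* The receptor ruler propagates any bias in the calibrant's copy
  number multiplicatively into every protein.
* Isostoichiometry requirements assume one complete complex per
  receptor unit and ignore subcellular compartmentalisation and
  turnover.
* The shift test detects a direction of redistribution, not its
  mechanism; comigration correlation does not by itself establish
  physical association.
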