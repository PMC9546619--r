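# contextomics

Interaction proteomics usually answers *who binds whom*. This package
answers the follow-up questions that place an interactome in its
cellular context: **how much** of each subunit is in a complex (absolute
stoichiometry), **how many** copies of each component the cell owns
(copies per cell), **which component runs out first** when a receptor
signal recruits the whole machinery (limiting components), **how heavy**
the resulting assembly is (signalosome mass), and **how it falls apart**
when its ubiquitin scaffold is removed (differential native-gel
migration).

The concrete system modelled throughout is the TNF receptor signaling
complex (TNF-RSC): a TNFR1 trimer that, on stimulation, recruits a core
(TRADD, RIPK1, TRAF2, BIRC2), the ubiquitin ligase LUBAC (HOIP, HOIL-1,
SHARPIN), kinase modules (NEMO/IKKα/IKKβ, TAB/TAK1, TANK/TBK1), the
deubiquitinase module CYLD–SPATA2, and a large amount of ubiquitin.

## What the package does

1. **Absolute quantification** — spiked-reference (AQUA) peptide
   tables in, absolute protein amounts out: the endogenous/reference
   intensity ratio times the spike amount gives amol per peptide;
   peptides are averaged per protein with a CV. iBAQ abundances and
   dilution-linearity fits are included, along with an in-silico
   tryptic digest for observable-peptide counting.
2. **Stoichiometry** — relative member ratios against a reference
   subunit, plus an exhaustive search over integer stoichiometry
   models (bounded subunit multiplicities with an optional additive
   "excess subunit" vector) ranked by log-space fit error.
3. **Cellular context** — copies per cell from absolute amounts via
   Avogadro's number and the cell equivalents on the column, or via a
   receptor-ruler calibrant; complex-formation capacity; copies
   required for isostoichiometry with the receptor; limiting
   components; AP-recovered copies; signalosome molecule counts and
   megadalton mass over the stimulation time course.
4. **Native-gel migration (BNPAGE)** — profile normalisation
   (maximum, fixed anchor, or first-relative-minimum anchor), ladder
   peak detection with topographic prominence and periodicity
   statistics, a paired one-sided early/late shift test for
   deubiquitinase-driven disassembly, and comigration correlation.
5. **Synthetic data** — a first-class, seeded generator that emulates
   the whole study design (lysate and affinity-purification AQUA
   tables with lognormal noise and LOD censoring, recruitment
   kinetics, well-trapped vs ladder-resolved gel profiles), so every
   stage is testable without raw mass-spectrometry data.

## Worked example

```r
library(contextomics)

# a synthetic cellular state with the default complex map
truth <- generateTruth(defaultTruthConfig(), seed = 42)

# simulate -> quantify -> calibrate -> contextualise
res <- runPipeline(truth, seed = 43)

copies <- setNames(res$copies_per_cell$copies_per_cell,
                   res$copies_per_cell$protein_id)
round(copies[c("TNFR1", "HOIP", "HOIL1", "SHARPIN", "CYLD", "SPATA2")])
#>   TNFR1    HOIP   HOIL1 SHARPIN    CYLD  SPATA2
#>   25024   20625   43088   58966    9550    9874
```

The receptor ruler recovers ~25,000 TNFR1 copies per cell from noisy
peptide ratios (truth: 25,000), and the deubiquitinase module is the
scarce part of the machinery:

```r
subset(res$allocation, limiting)
#>   protein_id copies_available copies_required copies_recovered limiting
#> 1       CYLD         9550.477        16682.87         7838.679     TRUE
#> 2     SPATA2         9874.134        16682.87         7715.732     TRUE
```

Every other member is present in excess of the one-complex-per-trimer
requirement; CYLD and SPATA2 fall short of it, so full signalosome
equipment cannot be reached — consistent with only a fraction of LUBAC
carrying the CYLD–SPATA2 module:

```r
cc <- setNames(res$complex_counts$complexes_per_cell,
               res$complex_counts$complex_name)
complexBoundFraction(cc[["LUBAC"]], cc[["CYLD-SPATA2"]])$fraction
#> [1] 0.2315216
```

The assembly the receptor nucleates is megadalton-scale and dominated
by ubiquitin at the 10-minute recruitment peak:

```r
res$signalosome_mass
#>   timepoint total_molecules total_mw_mda ubiquitin_mass_fraction
#> 1         5        219.4907     3.470817               0.4718949
#> 2        10        461.8179     5.991602               0.6109841
#> 3        15        390.6084     5.024548               0.6176323
```

Integer stoichiometry: an observed 0.5 : 1 : 1 ratio for LUBAC is
explained at zero error by a 1:1:1 core carrying one excess copy each
of HOIL-1 and SHARPIN, i.e. HOIP:HOIL-1:SHARPIN = 1:2:2:

```r
fitIntegerStoichiometry(c(HOIP = 0.5, HOIL1 = 1, SHARPIN = 1))[1, ]
#>   base_HOIP base_HOIL1 base_SHARPIN excess_HOIP excess_HOIL1 excess_SHARPIN
#> 1         1          1            1           0            1              1
#>   pred_HOIP pred_HOIL1 pred_SHARPIN total_copies fit_error
#> 1       0.5          1            1            5         0
```

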