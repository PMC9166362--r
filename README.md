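# FCplus

Division-cycle timing of midcell protein recruitment in rod-shaped
bacteria, from snapshot immunofluorescence.

## What it does, and for whom

A steadily growing bacterial culture, fixed and imaged once, contains
cells at every stage of the division cycle. For microbiologists who
quantify when a protein arrives at the division site — divisome
assembly order, premature or delayed constriction in deletion mutants
— this package turns per-cell measurement tables (length, diameter,
background-subtracted axial fluorescence profile) into timing
estimates and comparable curves, without live imaging.

The pipeline rests on two statistics:

* **Cell-division-cycle age from length rank.** In balanced
  exponential growth the age density is `f(a) = 2^(1−a) ln 2` on
  `[0, 1)`. With cells sorted ascending by length and 0-based rank
  `r` among `n` cells,

  ```
  age = ln(1 − 0.5 · r/(n−1)) / ln(0.5)
  ```

* **FCPlus, the midcell fluorescence surplus.** Each axial profile is
  split at the central 0.8 µm window; fluorescence integrals inside
  and outside are divided by the corresponding sphero-cylinder
  volumes and

  ```
  FCPlus = (C_mid − C_rest) · V_mid
  ```

  A volume-uniform signal gives exactly 0; a midcell ring gives up to
  the whole cellular fluorescence.

Binned in 5% age classes with 95% confidence intervals, the FCPlus
curve yields the arrival time `t0` (first persistent positive
surplus) and `t1/2` (first crossing of half the curve maximum);
a Welch t-test compares these across replicates between strains.
Curves can be min-max normalized and averaged across replicates,
converted to molecule numbers via a copy-number calibration (133
molecules per average cell by default), and whole populations can be
rendered as length-sorted demographs. A steady-state population
simulator with a known recruitment model (`simulatePopulation()`)
provides ground truth for every statistic.

## Worked example

```r
library(FCplus)

law <- GrowthLaw(birthLength = 2.0, diameter = 0.9)
wt  <- RecruitmentModel(t0True = 0.33, riseWidth = 0.2)

pop <- simulatePopulation(3000, law, wt, seed = 1, strain = "WT")
pop
#> CellPopulation with 3000 cells
#>   strain: WT  replicate: r1  condition: simulated
#>   pixel pitch: 15.28 px/um
#>   length: 2.00-4.00 um (median 2.63)
#>   constricting: 453 (15.1%)
#>   simulated: ground-truth sidecar attached

estimateTiming(pop, protein = "FtsZ")
#>  protein strain replicate_id        t0    t_half  fc_max n_cells
#>     FtsZ     WT           r1 0.3304013 0.4890693 113.498    3000
```

The estimated onset (0.330) recovers the simulated ground truth
(0.33) to a fraction of one 5% age bin; `t1/2` sits on the rising
flank, and `fc_max` is the plateau of the binned surplus in
fluorescence units. Converting the curve to molecules at midcell with
the default calibration:

```r
fc    <- fcplus(pop)
curve <- binByAge(fc$fcplus, assignAges(fc$length_um)$age)
mol   <- as.data.frame(moleculesAtMidcell(curve, mean(fc$total_F)))
tail(mol, 3)
#>  bin_center   mean   ci   n
#>       0.875 105.40 1.80 113
#>       0.925 109.41 2.05 110
#>       0.975 113.86 2.51 106
```

about 110 molecules sit at the division site late in the cycle.
Comparing against a prematurely assembling mutant (true onset 0.25,
i.e. 8% of the cycle earlier) over six 1000-cell replicates per
strain:

```r
mut <- RecruitmentModel(t0True = 0.25, riseWidth = 0.2)
wtReps <- do.call(rbind, lapply(1:6, function(i)
  estimateTiming(simulatePopulation(1000, law, wt, seed = i))))
mutReps <- do.call(rbind, lapply(1:6, function(i)
  estimateTiming(simulatePopulation(1000, law, mut, seed = 100 + i))))
compareStrains(wtReps, mutReps, statistic = "t0")
#>  statistic_name mean_difference mean_difference_pct     p_value
#>              t0      0.09050947            9.050947 4.06551e-10
#>  n_parental n_mutant significance
#>           6        6          ***
```

The 8%-of-cycle shift is recovered (9.1% estimated) and strongly
significant.

A command-line wrapper with `simulate`, `analyze`, `timing`,
`compare` and `demograph` subcommands lives at
`inst/scripts/fcplus`; every run writes a `manifest.yaml` with the
configuration echo, input checksums and record counts.

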