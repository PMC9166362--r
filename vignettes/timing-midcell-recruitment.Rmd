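---
title: "Timing midcell protein recruitment from steady-state snapshots"
author: "FCplus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Timing midcell protein recruitment from steady-state snapshots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(FCplus)
```

## The problem

Rod-shaped bacteria such as *Escherichia coli* divide by assembling a
multiprotein machine, the divisome, at midcell. Live imaging of the
assembly is slow and perturbative; the alternative used throughout
this package is a *snapshot* experiment: fix a steadily growing
culture, immunolabel one protein, image thousands of cells once, and
exploit the fact that a steady-state population contains every stage
of the division cycle simultaneously. Two ideas make that
quantitative:

1. **Length rank encodes cycle age.** In balanced exponential growth
   the age distribution is time-invariant, with density
   $f(a) = 2^{\,1-a}\ln 2$ on $[0,1)$ — newborns are twice as frequent
   as dividing cells. Because length increases monotonically with age,
   a cell's 0-based rank $r$ among $n$ cells sorted by length maps to
   its age by inverting the CDF $F(a) = 2(1 - 2^{-a})$:
   $$a = \frac{\ln\!\left(1 - \tfrac{1}{2}\,r/(n-1)\right)}{\ln(1/2)}.$$
   `assignAges()` implements exactly this; `sampleAges()` draws from
   the same distribution for simulation.

2. **The midcell surplus isolates division-site signal.** The axial
   fluorescence profile of each cell is split at the central 0.8 µm
   (the division-site window at the package's default pixel pitch of
   15.28 px/µm). Integrated fluorescence inside ($F_{mid}$) and
   outside ($F_{rest}$) the window is converted to concentrations
   using the sphero-cylinder geometry — the window is a pure
   cylindrical slab of volume $V_{mid} = \pi r^2 w$, the remainder is
   the rest of $\pi r^2 (L - 2r) + \tfrac{4}{3}\pi r^3$ — and the
   surplus is
   $$\mathrm{FCPlus} = (C_{mid} - C_{rest})\, V_{mid}.$$
   A protein spread uniformly through the cell volume gives exactly 0
   regardless of expression level; signal concentrated in a midcell
   ring gives up to the whole cellular fluorescence. This
   concentration-based contrast is what distinguishes genuine
   recruitment from the trivial fact that bigger cells hold more
   protein.

Binning per-cell FCPlus into 5% age classes (Student-t 95% confidence
half-widths per bin) produces the recruitment curve of the protein,
from which two timing landmarks are read: `t0`, the age at which the
curve first turns (and stays) positive, and `t1/2`, the age at which
it first reaches half of its maximum. The maximum itself is avoided
as a landmark because the curve usually plateaus before declining
late in the cycle, making the argmax ill-conditioned; the half-maximum
crossing sits on the steep part of the curve and is stable.

## The synthetic-data generator

Every downstream statistic is validated on populations from
`simulatePopulation()`, which has a fully known ground truth:

* **Ages** from the steady-state distribution above.
* **Lengths** from a `GrowthLaw`: exponential
  ($\ell_0\, 2^a$, default) or linear ($\ell_0 (1+a)$); both double
  the birth length over a cycle, as steady state requires. Defaults —
  birth length 2.0 µm, diameter 0.9 µm — describe slowly growing
  minimal-medium cells, for which the midcell window plus a full
  hemispherical cap always fits inside even the shortest cell.
* **Recruitment** from a `RecruitmentModel`: the fraction of a cell's
  molecules at midcell is 0 before the onset age `t0True`, rises
  (linearly, or by a smoothstep) to `plateauFraction` over
  `riseWidth`, stays at the plateau, and optionally declines to zero
  after `declineAge`. The defaults (onset 0.25, rise 0.2, plateau
  0.6) reproduce the qualitative shape of measured early-divisome
  curves.
* **Expression** per cell: expected total molecules either
  proportional to cell volume (`"volume"`, the default — envelope
  proteins accumulate roughly with size) or age-constant
  (`"constant"`). The proportionality is scaled so the *population
  mean* equals `meanMolecules` (default 133, a published
  ribosome-profiling copy number for the endopeptidase this analysis
  was developed around, which also anchors `moleculesAtMidcell()`).
* **Profiles**: the diffuse (non-recruited) fraction is distributed
  over the axial samples proportionally to the local cross-sectional
  volume of the sphero-cylinder, computed in closed form per
  pixel-wide slab with the outermost slabs pinned to the poles. This
  makes a non-recruiting cell *exactly* volume-uniform, so its FCPlus
  is zero to machine precision — the null model is exact, not
  approximate. The recruited fraction is a Gaussian ring of axial
  s.d. `ringSigma` (default 0.1 µm, a diffraction-limited ring) at
  the cell midpoint, renormalized over the cell so noiseless profiles
  conserve total fluorescence to $10^{-6}$ relative.
* **Noise**: per-cell multiplicative lognormal noise of coefficient
  of variation `noiseCv` (default 0.1) models expression and labeling
  variability; optional per-sample Poisson counting noise
  (`countingNoise`, `photonGain`) models shot noise. Both are seeded;
  a fixed seed reproduces populations bit-identically.

What the simulator deliberately does **not** model: off-center or
asymmetric rings, cell bending, polar artifacts, segmentation errors,
background-estimation residuals, the camera point-spread function,
and departure from ideal steady state. Passing the validation suite
therefore demonstrates correctness of the *statistics* under the
stated population model, not robustness to every imaging pathology of
real data.

## Numerical choices

* **Window integration.** 0.8 µm is 12.224 px at the default pitch,
  so the window edges cut through pixels; edge samples are weighted
  by their linear overlap with the window. For any profile that is
  locally constant across the edge pixels this weighting is exact.
* **Volume geometry.** The cell is a cylinder with hemispherical
  caps. The midcell window is treated as a purely cylindrical slab,
  which requires `length > midcellWidth + diameter`; shorter cells
  are excluded from FCPlus and counted in a message. The geometry is
  a convention — the measurement pipeline this package mirrors
  computes volumes without stating the solid — and both per-volume
  (`concentrationPerVolume()`) and per-circumference
  (`midcellDensityPerCircumference()`) normalizations are exposed.
* **Rank ties.** Equal lengths keep their input order (stable sort)
  and each tied cell its own integer rank: rank averaging would break
  the monotonicity of age in rank. The printed denominator $n-1$
  gives the longest cell age exactly 1, which the last (closed) age
  bin keeps.
* **Onset detection.** `estimateT0()` declares onset where the binned
  mean exceeds `tolRel` × (curve maximum) for `persistence`
  consecutive occupied bins, then interpolates the crossing linearly
  between the bracketing bin centers. A strict sign rule
  (`tolRel = 0`) is available but has unbounded sensitivity: the bin
  just below the true onset picks up a systematically positive mean
  of order 0.1% of the maximum purely from length-rank age scatter
  (cells barely past onset ranked one bin early), so the default
  detection floor is 1% of the maximum — far below any meaningful
  surplus, and scale-invariant, so multiplying a curve by a positive
  constant never changes the estimate.
* **Missing bins** propagate as missing (never zero); timing
  estimates interpolate across interior gaps with a warning.
* **Empty-bin CIs.** Singleton bins get half-width 0, empty bins NA.
* **Degenerate inputs** fail loudly: constant curves cannot be
  min-max normalized, flat profiles cannot be aligned, curves that
  never rise raise a `noOnsetError` rather than returning a number.

## Strain comparison

`estimateTiming()` reduces one replicate (one immunolabeled
population) to `(t0, t1/2, fc_max, n_cells)`;
`compareStrains()` applies a two-sided unpaired Welch t-test across
replicates, reporting the parental-minus-mutant difference both as an
age fraction and in percent of the division cycle. Welch rather than
pooled-variance, because replicate counts and variances routinely
differ between strains. No multiple-testing correction is applied
across proteins or statistics: comparisons are reported per protein,
per statistic, as in the experimental practice this mirrors.

## Validation problem sizes

The packaged test-suite checks, chosen to give each stochastic check
clear resolution at desk scale: closed-form age checks at $10^5$ to
$10^6$ draws; onset/half-maximum recovery on 20 populations of 5000
cells (onset 0.25, rise 0.2, 10% noise; both landmarks required
within one 5% bin in at least 18 of 20); an 8%-of-cycle onset shift
between two strains with 6 replicates of 1000 cells each and
replicate-level jitter of 2% of the cycle, detected with the Welch
test at p < 0.01 and an estimated shift within [0.05, 0.11] in at
least 90 of 100 meta-repeats; and a never-recruiting null whose
binned curve stays within its 95% CI of zero in at least 90% of
occupied bins. `scripts/acceptance.R` recomputes all of these from
scratch against the installed package.

## A worked example

```{r example, eval = FALSE}
library(FCplus)

## simulate a wild-type-like replicate and a premature-assembly mutant
law <- GrowthLaw(birthLength = 2.0, diameter = 0.9)
wt  <- RecruitmentModel(t0True = 0.33, riseWidth = 0.2)
mut <- RecruitmentModel(t0True = 0.25, riseWidth = 0.2)

popWt <- simulatePopulation(3000, law, wt, seed = 1, strain = "WT")
timingWt <- estimateTiming(popWt, protein = "FtsZ")

## per-cell statistics and the binned curve
fc <- fcplus(popWt)
ages <- assignAges(fc$length_um)$age
curve <- binByAge(fc$fcplus, ages)
normalized <- minmaxNormalize(curve)

## demograph of the same population
demo <- buildDemograph(popWt, normalizePerCell = TRUE)
writeDemograph(demo, "wt_demograph.png")

## replicate-level comparison
wtReps <- do.call(rbind, lapply(1:6, function(i)
  estimateTiming(simulatePopulation(1000, law, wt, seed = i),
                 protein = "FtsZ")))
mutReps <- do.call(rbind, lapply(1:6, function(i)
  estimateTiming(simulatePopulation(1000, law, mut, seed = 100 + i),
                 protein = "FtsZ")))
compareStrains(wtReps, mutReps, statistic = "t0")
```

## Known limitations

* The rank-to-age transformation assumes an ideal steady state;
  cultures that fail to reach one (e.g. strains with irregular DNA
  replication) violate the age density and bias all timing estimates.
  The simulator is always ideal, so it cannot quantify that bias.
* t0 inherits a systematic underestimate of up to one bin width from
  binning plus interpolation (the crossing is bracketed by bin
  centers). The bias is shared between strains compared under the
  same binning, so differences are unbiased to first order.
* FCPlus assumes the division site sits at the profile midpoint;
  markedly asymmetric division would smear the ring across the
  window edge.
* The molecule conversion is linear in an external copy-number
  calibration and shares all of that calibration's uncertainty.
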