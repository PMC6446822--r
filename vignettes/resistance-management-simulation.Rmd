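---
title: "Simulating Bt resistance management with self-limiting insect releases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating Bt resistance management with self-limiting insect releases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(whackamole)
```

## The system being modelled

`whackamole` is a forward-in-time, discrete-generation simulator of caged
metapopulations of the diamondback moth (*Plutella xylostella*, DBM)
evolving resistance to the *Bacillus thuringiensis* toxin Cry1Ac under the
high-dose/refuge strategy, while homozygous self-limiting (fsRIDL)
transgenic males are mass-released into the cages. It tracks two unlinked
autosomal loci:

* a biallelic **resistance locus** with alleles R (resistant) and
  S (susceptible). At the diagnostic toxin dose, resistance is
  near-recessive: only RR larvae survive toxin diet (heterozygote survival
  `h` is configurable and defaults to 0);
* the insertion site of a **dominant, tetracycline-repressible,
  female-specific lethal construct**, alleles L (insertion present) and
  w (wild type). Off tetracycline, any female carrying at least one L copy
  dies at the larval stage; males are unaffected. Released males are
  homozygous at both loci: genotype LLSS.

Releases manage resistance through two coupled channels: released males
pre-empt matings that would otherwise produce viable daughters
(suppression), and the S alleles they carry introgress into the population
through their surviving sons (dilution of R). Because L-carrying females
die and L males transmit the construct to only half their offspring, the
construct is *self-limiting*: its frequency decays once releases stop.

## Cage life cycle and event order

Each generation of each cage executes, in order:

1. **Refuge assignment.** Either a constant refuge fraction
   (homogeneous selection) or a fresh uniform random permutation of a set
   of refuge sizes across the cages (heterogeneous selection).
2. **Random mating and egg laying.** Every female takes a single mate
   drawn with probability proportional to male counts (monandry); her egg
   number is Poisson; egg genotypes follow the Mendelian cross
   distribution at two freely recombining loci; egg sex is Bernoulli(1/2).
3. **Bioassay sampling.** A fixed fraction (10%) of eggs is removed,
   pooled across the replicate's cages, before any toxin exposure. A fixed
   number of the sampled larvae (100 or 150 depending on the experiment)
   are scored at the diagnostic dose; with `h = 0` the survivor proportion
   estimates the RR egg fraction.
4. **Egg placement and diet split.** At most `eggs_placed_max` of the
   remaining eggs are placed onto diet (a uniform without-replacement
   subsample if more were laid); each placed egg goes to refuge diet with
   probability equal to the refuge fraction, otherwise to toxin diet.
5. **Viability selection and pupation.** Each egg survives with its
   genotype's diet-specific probability; off tetracycline, surviving
   L-carrying females are removed before the pupal census; each diet
   compartment is then truncated to its carrying capacity
   (`capacity * diet fraction`) by uniform without-replacement subsampling.
6. **Census.** Pupae per diet, allele frequencies, release bookkeeping and
   the bioassay outcome are recorded; the toxin-survivor count feeds the
   whack-a-mole targeting rule.
7. **Dispersal.** A fixed fraction (10%) of each cage's pupae is drawn
   without replacement and split as evenly as possible among the other
   cages, simultaneously for all cages, conserving every genotype's
   network count exactly.
8. **Release.** If the next generation is inside the release window,
   LLSS males are added: `base_ratio` (4) per local wild male everywhere,
   or `base_ratio * whack_multiplier` (12) per local wild male into the
   single cage that had the most toxin survivors (ties broken uniformly;
   a random cage if all counts are zero, since the protocol always
   deployed its budget). Released males join the mating pool only — they
   are never dispersed and die with the rest of the adults.

Releases begin at generation 1 because the whack-a-mole rule needs
generation-0 survivor counts before it can target. With equal local male
counts the two release modes deploy identical totals (3 cages x 4:1 =
1 cage x 12:1), which is what makes their comparison a comparison of
*spatial allocation* rather than of budget.

## Parameters, defaults, and why

| parameter | default | rationale |
|---|---|---|
| `founder_pupae` | 200/cage | founding census of each cage |
| `founder_r_freq` | 0.075 | founder R frequency; genotypes at Hardy-Weinberg |
| `bioassay_fraction` | 0.10 | egg fraction sampled before the diet split |
| `dispersal_fraction` | 0.10 | pre-mating pupal exchange |
| refuge fraction | 0.10 (exp. 1); 0.12 or {0.05, 0.10, 0.20} (exp. 2) | homogeneous and mean-matched heterogeneous selection |
| `toxin_survival` | (0, h, 1), h = 0 | high-dose, near-recessive resistance |
| `refuge_survival` | 0.8 | egg-to-pupa survival on clean diet |
| `fitness_cost_r` | 0 | costs of resistance are minor and unquantified |
| `eggs_per_female` | 150 | realistic DBM lifetime fecundity (see below) |
| `eggs_placed_max` | 2500/cage | bounded egg placement on bounded diet (see below) |
| `capacity_refuge`, `capacity_toxin` | 2000/unit diet | pupal carrying capacity per unit of diet fraction |
| `base_ratio`, `whack_multiplier` | 4, 3 | the 4:1 and 12:1 release ratios |

Two demographic choices deserve explanation, because the cage experiments
report no egg counts and the design was genuinely open.

**Fecundity.** With the 10% bioassay removal, a 10% refuge, monandry and
an everywhere release at 4:1, the female line replaces itself only if
`0.2 x fecundity x 0.09 x refuge_survival x 0.5 >= 1`, i.e.
`fecundity x survival >= 111`. A mean fecundity of 30 would therefore
drive every release cage extinct within two to three generations, which
is not what release cages do — they persist under suppression. The
default of 150 eggs per female is a realistic DBM lifetime fecundity and
places the everywhere-release female line at about 1.08x per generation
(persistence at suppressed density) while control cages grow rapidly to
carrying capacity.

**Bounded egg placement.** Cage populations were limited by the quantity
of diet, so the number of eggs reaching diet each generation is bounded,
not proportional to total fecundity. Without this bound, every egg laid
would compete on diet, and at realistic fecundities the toxin compartment
(90% of diet) would yield so many RR survivors from the 7.5% founder
frequency that resistance would approach fixation in a single generation —
selection intensity would be set by fecundity rather than by the cage.
The default cap of 2500 eggs per cage is chosen to be self-consistent
with the pupal capacities: 2500 x 10% refuge x 0.8 survival = 200, the
refuge compartment capacity and the founder scale, and
2500 x 90% x 0.8 = 1800, the toxin compartment capacity at a 10% refuge.
A fully susceptible cage therefore equilibrates near 200 pupae, and
realized carrying capacity rises toward 2000 as phenotypic resistance
gives access to the toxin compartment — the density pattern the cage
system shows.

## The deterministic oracle

`deterministic_generation()` is the infinite-population, expected-value
transcription of the identical event order: random-mating offspring
distribution, bioassay removal, diet allocation, diet survival,
female-lethality, proportional capacity truncation, and release as a
male-frequency injection `(m + rho * e_LLSS) / (1 + rho)`. It models a
single panmictic cage; it exists to verify the stochastic engine and to
explore expected dynamics (`run_oracle()`, `cmd_sweep()`), not to
replicate spatial stochasticity.

Two of its consequences anchor the test suite:

* with a fully resistant cohort and equal survival on both diets, the
  expected toxin-survivor-in-cage proportion equals `1 - refuge_fraction`
  exactly: 0.9 at a 10% refuge, 0.88 at 12%;
* after releases cease, the L frequency declines monotonically through
  the male line toward loss.

The oracle-versus-simulator agreement test runs 20 seeded single-cage
simulations at 50,000 founders for 6 generations under each release mode
and requires every per-generation mean genotype frequency to lie within
4 Monte-Carlo standard errors of the oracle, plus an absolute floor of
1e-3. The floor is a discretization allowance, not slack in the model:
at this population size some frequency components are near-deterministic
(across-run standard errors around 1e-6), while integer rounding of
release counts and capacities contributes offsets of order 1e-4 that no
number of replicate runs averages away. Measured worst-case absolute
disagreement is about 7e-4.

## The statistics layer

The analysis functions mirror the standard cage-experiment readouts
without re-implementing mixed-model machinery:

* `fit_quadratic_trend()` — ordinary least squares of `asin(sqrt(p))`
  (the variance-stabilizing transform for binomial proportions) on
  generation and generation squared; fewer than three points fall back to
  a flagged linear fit.
* `lag1_autocorrelation()` — the circular lag-1 sample autocorrelation of
  the centered, detrended series. This estimator is used because its null
  expectation for exchangeable data is exactly `-1/(n-1)` (the classical
  small-sample benchmark; -1/3 for the four-generation series produced
  here), so an observed negative lag-1 autocorrelation can be judged
  against a known finite-sample baseline. The detrending unit is the
  subpopulation.
* `permutation_treatment_test()` — treatment contrasts on replicate-level
  summaries by random relabeling, with the add-one p-value estimator
  (exactly uniform on its support under the null) or exhaustive
  enumeration for two small groups. Binomial GLMMs with replicate random
  effects are deliberately out of scope; the tidy trajectory tables are
  designed so users can fit them externally.

## What the synthetic experiments do and do not emulate

`run_experiment1()` and `run_experiment2()` reproduce the *design* of the
two selection experiments — founder numbers and frequency, refuge
regimes, release strategies and ratios, dispersal, bioassay sizes,
generation counts, and the release-budget standardization — with all
randomness driven by a single master seed through a fixed seed-splitting
scheme (any replicate is reproducible in isolation).

They do not emulate: overlapping generations or within-generation timing
(the two egg collections per generation are collapsed into one laying
event, which has no genetic consequence in a discrete-generation model);
polyandry (monandry is assumed; allele-frequency expectations under
random mating are unchanged); larval competition between genotypes on a
diet; maternal effects; variation in male competitiveness (released and
wild males compete equally); or any fitness cost of the construct in
males beyond female lethality. Passing tests therefore validate the
model's internal consistency and its qualitative agreement with the cage
system's headline behaviour — they do not certify quantitative agreement
with any particular wet trajectory, whose inferential statistics are
properties of the real data.

## Numerical choices

* **Rounding.** Dispersal and release counts use R's round-half-to-even;
  an odd dispersal batch assigns its residual pupa to a receiver chosen
  by fair coin. Both are unbiased in expectation.
* **Without-replacement sampling** (egg placement caps, capacity
  truncation, dispersal draws, bioassay draws) is multivariate
  hypergeometric via sequential `rhyper`, conserving counts exactly and
  preserving proportions in expectation.
* **Degenerate inputs.** A cage with no females or no males lays nothing
  and is flagged; network extinction truncates the trajectory with
  explicit flagged records; an empty cage's toxin-survivor proportion is
  `NA` (not 0) so trend fits drop it explicitly; an empty bioassay sample
  returns `(0, 0)` flagged; an undersized sample is drawn with
  replacement and flagged.
* **Whack targeting** uses pre-dispersal toxin-survivor counts (cages
  are scored per cage before pupae are pooled and shared), while release
  numbers are computed against post-dispersal local male counts (releases
  are timed to the emergence of the local males). With all counts zero
  the budget still goes to a random cage by default
  (`release_when_empty = FALSE` skips instead). A persistent fixed-source
  variant is available via `fixed_target`.
* **Problem sizes in the test suite.** The oracle comparison uses 20 runs
  of a 50,000-founder cage over 6 generations per release mode; the
  treatment-ordering check uses 200 replicate metapopulations per
  treatment at first-experiment defaults; calibration uses 1000 null
  permutation tests (499 relabelings each) and 10,000 white-noise
  autocorrelation draws.

## A worked oracle example

```{r oracle}
cfg <- experiment_config(strategy = release_strategy("everywhere",
                                                     base_ratio = 4))
run_oracle(cfg)[, c("generation", "release_ratio", "freq_R", "freq_L",
                    "toxin_survivor_prop")]
```

Under the everywhere release the expected R frequency is pinned near its
starting value while the construct frequency is held high by continued
releases; setting `release_stop_generation` shows the self-limiting decay.

## Known limitations

* The oracle is panmictic; it cannot verify spatial aspects of the
  whack-a-mole policy (those are exercised by the stochastic tests).
* Density regulation is hard truncation; smoother forms (Beverton-Holt)
  would change transient population sizes, though not allele-frequency
  expectations.
* The release budget is assumed unlimited at the stated ratios;
  production constraints are not modelled.
* Whether the 12:1 whack ratio should be computed against the target's
  local males (as here, following the release-timing description) or
  against a third of the network's males is ambiguous when cage sizes
  differ; totals are exactly standardized only in the equal-size case.
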