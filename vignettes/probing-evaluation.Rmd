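---
title: "Evaluating RNA chemical probing data against reference structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating RNA chemical probing data against reference structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(probeval)
```

## The problem

Chemical probing reagents such as dimethyl sulfate (DMS) and SHAPE
acylating compounds react preferentially with flexible, solvent-exposed
nucleotides, which are mostly the ones not locked into base pairs. Two
sequencing readouts dominate: reverse-transcription **stop** profiling
(SEQ), where the polymerase terminates at a modified base, and
**mutational** profiling (MaP), where modified bases are read through but
miscoded. Either way the experiment yields, per transcript position, a
read depth and an event count, and the per-position event *rate* is used
as a reactivity score.

`probeval` evaluates such data against reference secondary structure
(dot-bracket notation), ensemble pairing probabilities and
solvent-accessible surface area (SASA), and ships a generative simulator
with a known ground-truth structure so that every evaluation statistic
can be validated end to end against closed-form expectations.

## Reactivity model

Rates are raw event fractions:

* mutation rate = mutated reads / reads covering the position,
* stop rate = stops recorded at the position / reads informative there.

One definitional point deserves emphasis. For stop profiling, the only
denominator that yields a meaningful per-position rate is the number of
reads *informative* at the position — reads whose cDNA covers or
terminates there. Defining the denominator as the stop count itself
would make every rate identically 1, so `stop_rate()` uses the
informative-read convention throughout, and the simulator's depth output
is defined the same way.

Background adjustment subtracts the probe-free (minus channel) rate from
the probe-treated rate. Negative differences are **kept by default**
(`clamp = FALSE`): ROC and top-x% statistics consume only the rank order
of reactivities, and clamping collapses ranks among positions whose
background exceeds their signal. Clamping is available for export to
tools that require non-negative reactivities.

Filters, all of which flip `valid` rather than dropping rows:

* coverage: a position is kept only when depth **strictly exceeds**
  `min_depth` (default 500) — depth 501 is in, depth 500 is out;
* probe chemistry: DMS methylates N1(A)/N3(C), so DMS profiles are
  restricted to A and C; SHAPE probes the 2'-hydroxyl of all four bases;
* mRNA inclusion: a transcript qualifies when at least 50 positions pass
  the coverage filter.

Positions with zero depth carry a `NaN` sentinel and an invalid flag, so
they can never leak into downstream rank statistics.

## Structure concordance

`roc_auc()` treats **unpaired** bases (dots) as the positive class and
reactivity as the score. Many toolkits score the opposite direction;
this convention is stated on every result object. Tied scores across
classes receive half credit, making the trapezoidal AUC identical to the
Mann-Whitney statistic; the test suite verifies this equivalence against
a brute-force pairwise oracle at 1e-12 on hundreds of randomized
instances.

`top_fraction_unpaired()` ranks the valid positions of one molecule by
reactivity (per-molecule, not pooled across molecules), selects the top
`ceiling(x/100 * n_valid)` and reports the unpaired fraction. Ties are
broken by ascending position, so results are exactly reproducible. At
`x = 100` the statistic reduces to the unpaired fraction of the valid
set.

Rate histograms use half-open bins `[a, b)` with a `1e-12` edge nudge so
a value lying exactly on an edge lands in the bin starting there;
negative (background-adjusted) values pool into an underflow bin and
values at or above the range maximum into an overflow bin. The
class-conditional overlap coefficient is the binwise minimum of the two
class densities, 1 for identical and 0 for disjoint distributions.

## Ensemble pairing probabilities

`marginal_pairing_probability()` sums each row of a base-pair
probability matrix: the probability that base *i* pairs with anything.
Imported matrices are accepted as sparse `(i, j, p)` TSV; marginals may
exceed 1 by at most `1e-6` (import tolerance), anything larger is an
inconsistency error, values inside the band are clipped.

Because full partition-function ensembles are outside this package's
scope, validation uses a **toy ensemble**: `enumerate_structures()`
generates every pseudoknot-free structure of a short RNA (canonical +
wobble pairs, hairpin span at least 3, length capped at 30 against
combinatorial blowup), and `ensemble_bpp()` weights each structure by
`w^(#pairs)`. This is the minimal model sufficient to test
marginalisation and discordance flagging; it deliberately does not
emulate the Turner energy model, so its probabilities should never be
interpreted thermodynamically. Two independent algorithms — explicit
recursive enumeration (C++) and a Nussinov-style counting recurrence
(pure R, memoised) — are compared exhaustively over every 4-letter
sequence up to length 10 and on random sequences up to length 14.

`flag_discordant()` applies the joint rule "ensemble says almost
certainly paired (marginal at or above 0.995, inclusive) while the
probing data put the base in the top 10% of reactivity", the signature
of reference-structure/ensemble disagreements worth manual review.

```{r}
marginal_pairing_probability(ensemble_bpp("GAAAC", pair_weight = 1))
```

## Solvent accessibility

`shrake_rupley()` places a deterministic golden-spiral lattice (default
960 points, no RNG) on each atom's solvent-expanded sphere and counts
points strictly inside no neighbouring expanded sphere. Numerical
choices:

* probe radius defaults to 3 Å — roughly the bulk of a probing reagent
  rather than a 1.4 Å water molecule;
* van der Waals radii C 1.70, N 1.55, O 1.52, P 1.80 Å, overridable via
  `radii` (atoms with unknown elements require an explicit entry);
* the interior test is strict with a `1e-9` relative epsilon, so exactly
  coincident spheres do not occlude each other;
* coordinates are first mapped to a canonical principal-axes frame
  (centroid origin, third-moment sign fixing, right-handed), which makes
  the quadrature exactly invariant under rigid rotation and translation
  of the input — a fixed global lattice alone is only invariant to about
  one part in the number of test points.

*Relative* accessibility divides a residue's in-context area by the same
residue's area recomputed in isolation; the choice is recorded here
because reference tools report absolute values and no standard
normalisation exists for RNA. Users preferring fixed per-nucleotide
maxima can divide `absolute_sasa` themselves. Residues missing from the
coordinate model are simply absent and are excluded from correlations.
Numbering shifts between coordinate models and reference sequences are
handled by an explicit integer `offset` (profile position = residue
index + offset); no automatic alignment is attempted.

## The simulator

`simulate_experiment()` draws from an explicit generative model. Each of
`n_molecules` molecules is modified independently at position *i* with
probability `m[i]`, set per class (`p_mod_unpaired`, `p_mod_paired`) or
per position (`p_mod_by_position`). Single-hit kinetics — roughly one
modification per ~200 nucleotides — is implemented as a proportional
rescaling of `m` to a target expected modifications per molecule, not as
hard truncation; in stop mode the detection censoring below already
limits what is observable.

* **SEQ**: reverse transcription initiates at the 3' end and terminates
  at the first modified base or spontaneous stop (rate
  `natural_stop_rate` per position) it encounters. Only the 3'-most
  modification of a molecule is therefore detectable, which reproduces
  the 5' detection bias of real stop profiles, and depth decays towards
  the 5' end. The stop is recorded at the modified base
  (`stop_offset = 0`, the default, matching the evaluation convention
  that reactivity indexes the modified base) or one position 3' of it
  (`stop_offset = 1`, provided because protocols differ).
* **MaP**: every molecule is read full length; each modification is
  recorded with `mutation_detect_prob` and sequencing errors add
  spurious mutations at `seq_error_rate` per read.

The minus channel repeats the process with all `m[i] = 0`. The ground
truth (`truth`) counts all modifications, detected or censored. All
randomness flows from one integer seed; outputs are identical across
runs and platforms given the seed. `expected_rate_profile()` gives the
closed-form expectation (for SEQ with offset 0 it reduces to the
combined per-position stop probability), and the test suite requires the
empirical rates to sit within 3 binomial standard errors at 99% of
positions.

### Benchmark scenarios and the choice of their parameters

The scenarios fix the study conditions; they are not tuning knobs.
All use a deterministic 200-nt stem-loop structure with 48% unpaired
bases, inside the 38-50% range of rRNA reference structures.

* `"overlap"` (MaP, 1e5 molecules): per-position modification
  probabilities follow quadratic grids, unpaired 0.005-0.10 and paired
  0.001-0.05, plus a 0.001 sequencing-error floor. The grids give the
  two classes broadly overlapping rate distributions — as in real data,
  where overlap is biological rather than sampling noise — while keeping
  roughly 99% of bases below a rate of 0.1 and most near zero, matching
  the strongly zero-inflated histograms of transcriptome-scale
  experiments. Resulting AUCs (~0.7) sit in the range reported for real
  rRNA evaluations.
* `"separable"` (MaP): disjoint class rates 0.20 vs 0.002 with no
  noise; downstream AUC and top-10% unpaired fraction are 1 by
  construction, which pins the evaluation conventions.
* `"background-heavy"` (SEQ, single-hit target of one modification per
  molecule, spontaneous stop rate 0.005): both channels carry
  independent stop noise, the setting in which subtracting the minus
  channel *adds* variance to the reactivity ranks. Across seeded
  replicates the plus-only AUC beats the background-subtracted AUC in
  nearly every replicate — the qualitative finding that dropping
  background data can improve pairedness prediction in stop profiling.

Problem sizes used throughout the tests and the acceptance script
(L = 200, 1e5 molecules, enumeration exhaustive to length 10) were
chosen as the smallest scales at which the binomial standard errors are
far below the effect sizes being checked.

### What the simulator does not model

Read-level artefacts (PCR duplication, fragmentation, random priming,
quality decay), sequence-context reactivity bias, structural dynamics
(the reference structure is static), correlated modifications, and
ligation biases are all absent. Passing simulator-based tests therefore
demonstrates that the evaluation machinery is correct under the stated
generative model — it does not certify accuracy on any particular real
library preparation.

## Degenerate inputs

Single-class label sets (all valid bases paired or all unpaired) make
AUC undefined: `roc_auc()` raises a typed error and
`pipeline_evaluate()` converts it into a `NULL` metric with a reason
string. Empty valid sets, sub-3-point correlation subsets and
zero-variance correlates are likewise typed errors, reported as `NA`
rows with reasons by `pipeline_sasa()`.

## Known limitations

* Reactivity normalisation schemes (2-8% winsorising etc.) are out of
  scope; the package works with raw rates.
* The toy ensemble cannot stand in for a thermodynamic partition
  function on long RNAs; imported matrices are the intended route there.
* Dot-bracket layers beyond `()` are treated uniformly as "paired";
  annotation formats that encode non-canonical pairs differently are
  the user's responsibility to convert.
* The SASA module does not reproduce any specific reference
  implementation's radii or dot densities; values are internally
  consistent rather than tool-identical.
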