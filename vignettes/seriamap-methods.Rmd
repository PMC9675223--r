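---
title: "Order-robust linkage mapping by seriation and bin placement: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Order-robust linkage mapping by seriation and bin placement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seriamap)
```

## The mapping problem this package addresses

With dense genotyping, the number of available markers in a biparental
cross vastly exceeds what the population's crossovers can order: ordering
information scales with population size, not marker count. Forcing every
marker into one ordered map therefore produces orders that are not
statistically supported. `seriamap` takes the *bin-mapping* view instead:

1. **Scaffold** — a sparse, highly robust ordered backbone is grown by
   seriation from seed marker pairs: at each step the most strongly linked
   candidate is appended at a map end, and is kept only if the map with the
   candidate at the end beats every alternative placement by a LOD gap.
2. **Framework** — the scaffold is densified with as many markers as
   possible while every marker's position stays supported at the chosen
   order-robustness LOD threshold (default 3.0): a candidate is inserted at
   its maximum-likelihood interval and retained only if that interval beats
   the best alternative interval by the threshold.
3. **Total map** — every remaining polymorphic marker is *placed* into the
   bin (interval between adjacent framework markers) that maximizes the
   multipoint likelihood, with an ML position inside the bin. Placement
   gives every marker a precise estimated position without claiming
   statistical support for the order of close placed markers, and leaves
   the framework's structure and length untouched.

The framework/placed distinction is the central contract: framework order
is defended by a likelihood gap; placed order within a bin is not.

## Genetic models

Supported populations: backcross (BC), doubled haploids (DH), F2
intercross, recombinant inbred lines (RIL, finite or fixed selfing
generations), intermated RILs (IRIL, extra generations of random mating
between the F2 and selfing), and outbred full-sib families (CP) from two
heterozygous parents.

Multipoint computations use a hidden Markov chain along each individual's
ordered loci:

* BC/DH: 2 hidden states (which parental gamete allele was transmitted),
  transition probability `r` per interval.
* F2: 4 states, the ordered pair of the two independent meioses; the
  transition matrix is the Kronecker square of the 2-state matrix.
* CP: 4 states, the transmitted homolog of each parent; the offspring
  genotype implied by a state depends on the marker's parental genotypes
  *and its linkage phase* (which parental allele sits on which homolog).
  Phases are inferred on the fly: when a marker is added to a chain, its
  (at most four, often two) structurally distinct phase configurations are
  each scored at the marker's ML attachment and the argmax is fixed.
  Pseudo-testcross markers (heterozygous in one parent) carry linkage
  information for that parent's meioses only; a female-testcross ×
  male-testcross pair is correctly treated as uninformative.
* RIL/IRIL: 2 fixed-line states. The transition parameter is the observed
  recombinant-line fraction `R(r)`, computed exactly by iterating the
  two-locus genotype distribution through the generation scheme (selfing
  recursion; intermating multiplies the gamete-pool disequilibrium by
  `1 - r` per generation). For selfing to fixation this reproduces the
  classic `R = 2r/(1+2r)`. Residual heterozygous calls are handled in the
  emission with the expected residual heterozygosity `0.5^g` after `g`
  selfing generations. This 2-state design is an approximation — an exact
  multigeneration multilocus model would be far heavier than the problem
  warrants — and the package's `expected_joint_freqs()` keeps the exact
  chain for validation.

Missing observations emit 1 in every state, which marginalizes them — this
is how missing data are imputed in all multipoint calculations. Dominant F2
codes (`C` = not-A, `D` = not-B) contribute through the states they are
compatible with rather than being dropped.

Interval distances are fitted by Baum–Welch EM (expected transition counts
in the E step; the M step divides by the number of informative meioses per
interval). The log-likelihood is non-decreasing by construction; the
stopping rule is a log10-likelihood gain below `1e-6` or 100 iterations.
Two-point estimates use the same hidden-state structure on observed
2-locus class counts (EM initialized at `r = 0.25`, co-typed individuals
only, LOD against `r = 0.5`); for RIL the likelihood is maximized on the
observed-`R` scale and transformed back to `r`.

## Mapping function

Distances are reported through Haldane's function, `d = -50 ln(1 - 2r)`.
This choice is deliberate: the bundled simulator draws crossovers as a
Poisson process without interference, for which Haldane is exact, so
simulation benchmarks measure the pipeline rather than a mapping-function
mismatch. Kosambi's function is available for reporting
(`kosambi_r_to_d()`), not for internal likelihoods.

## Error handling

Genotyping errors inflate maps: every isolated miscall looks like a double
crossover. Three mechanisms limit this:

* **Error emission model.** During construction the HMM emits a wrong code
  with rate `eps` (default 0.01), which stops single miscalls from
  dominating ordering decisions.
* **Posterior detection.** After fitting, a call whose observed class has
  posterior compatibility below `error_threshold` (default 0.01) is
  flagged and *masked to missing* — never rewritten to the imputed value.
  The threshold must sit above the posterior plateau that the error model
  itself assigns to a fully contradicted call (about `eps/4` at a 1 cM
  spacing); a lower threshold would never fire.
* **Singleton rule.** A call disagreeing with both immediate flanking
  calls, when those flanks agree and lie within `singleton_window` (10 cM),
  is flagged. A missing flank shields the call, and terminal markers are
  never flagged. The rule compares raw codes, so the pipeline applies it
  to populations with a shared code alphabet (BC/DH/F2/RIL); for CP data,
  whose observed classes are marker-specific allele pairs, the posterior
  method covers the same signature.

Distances reported in the final maps are re-estimated on the masked data
with a small residual error rate `eps_final` (default `1e-4`). Using the
construction value there would bias distances downward, because an `eps`
of 0.01 absorbs genuine crossovers — markers that are individually less
informative (CP pseudo-testcrosses especially) lose several percent of map
length. Setting `error_correction = FALSE` disables the detectors *and*
sets the emission rate to zero; the error-handling machinery is one
switch, which is what makes corrected/uncorrected comparisons meaningful.

**Twins.** Markers with identical segregation on at least
`twin_min_overlap` co-typed individuals (identical up to class relabelling
for CP) are grouped before ordering; the representative with the fewest
missing calls is mapped and the others re-attach at its position in the
total map. Twins also serve as a redundancy-based signal of low error
probability, and a twin pair is never used as a seed.

## Seeds and linkage groups

Without an anchor map, preliminary linkage groups are the connected
components of the 2-point graph at `group_lod` (default 6), and one seed
pair is drawn per component; with a physical/anchor map
(`read_physical_map()`), at least one pair is drawn per declared
chromosome. A seed pair must be linked at `seed_lod` (default 10), have
low missing rates, not be twins, and have `r` inside
`[seed_rmin, seed_rmax] = [0.05, 0.25]`. The lower bound matters: at high
marker density the strongest-LOD pairs are adjacent ones, and a ~1 cM seed
interval carries too few recombinants to orient nearby candidates (the
left-end versus right-end likelihoods tie), stalling seriation. The upper
bound keeps the scaffold steps within reliably estimated linkage. The pair
is drawn at random among the top qualifying pairs under the run seed, so
reruns are reproducible.

Scaffolds that turn out to tile the same chromosome (shared markers, or
any cross-chain pair linked at `group_lod`) are merged by union
densification: the larger chain keeps its order and the other chain's
markers are re-inserted one at a time through the same robustness gate.

## The robustness statistic

The ideal criterion — the LOD between the best order and *any* other order
— is unaffordable (`m!/2` orders). The package uses the standard
single-marker neighborhood instead: for each marker, the accepted map is
compared with the best map obtained by moving that marker to any other
interval of its group (the scan also covers positions beyond both ends) or
flipping it with a neighbor. `verify_order_robustness()` reports the
per-marker gaps and the minimum; `exact = TRUE` additionally refits every
alternative by full EM and is intended for small groups, where it matches
factorial enumeration whenever the best alternative order is a single move
or flip — which is the typical failure mode. During densification the
alternatives are evaluated conditional on the current fitted distances
(each insertion point optimizes only the candidate's own attachment), a
standard approximation that keeps a pass over all candidates linear in map
size.

Numerically, the insertion scan caches the forward and backward passes of
the current chain, evaluates every slot coarsely (interior slots at the
interval midpoint, preserving the interval's total distance; exterior
slots on a log-spaced distance grid) and refines the top eight slots by
golden-section search. Interior insertions preserve the receiving
interval's summed distance, so densification does not drift the map length
between the periodic full EM refits (every `refit_every = 25` acceptances
and at the end).

## The simulator

`simulate_pop()` generates the designs used throughout the tests: markers
at `0, s, 2s, …, L` (both chromosome ends included) on chromosomes of
given cM lengths; crossover counts per gamete `~ Poisson(L/100)` with
uniform positions and no interference; population construction per crossing
scheme (for IRIL, a finite population of the requested size is randomly
intermated; for RIL, single-seed descent with `self_gens = Inf` simulated
as 20 generations, residual heterozygosity `~1e-6`). CP parental phases
are randomized per marker and recorded, and marker informativeness classes
are drawn from `cp_class_probs` (default: equal quarters of female
testcross `ab×aa`, male testcross `aa×ab`, `ab×ab`, `ab×cd`). Errors
resample the observed code uniformly among the other valid codes, at a
uniform rate or per-marker Gamma-distributed rates (shape → ∞ recovers
the uniform model; small shapes give L-shaped rate distributions); missing
data are independent, and the two masks are disjoint by construction.

What the simulator does **not** emulate: crossover interference,
segregation distortion, sex-specific recombination, linked error
processes (e.g. allele-specific dropout), and non-random missingness.
Passing benchmarks on these simulations therefore demonstrates the
correctness of the inference machinery under its own model assumptions,
not robustness to every pathology of real data.

`evaluate_map()` matches computed groups to reference chromosomes by
shared-marker majority and reports orientation-free Spearman rank
correlations, the summed length ratio (against the full reference length,
and against the reference span actually covered), and the inclusion rate
(mapped / polymorphic markers).

## Problem sizes and reproducibility

The package's benchmark design is two chromosomes of 100 and 200 cM at 1
marker/cM with 200 individuals — 302 markers, the scale at which the
framework/total distinction is meaningful while a full automatic run
completes in about a minute per population on a single core. The test
suite exercises the same machinery at a range of smaller sizes. Every
random choice in `auto_map()` descends from one run seed fanned out to
per-stage child seeds, so a rerun with the same input and seed reproduces
the map files bitwise.

## Known limitations

* CP maps are sex-averaged; sex-specific recombination fractions are not
  fitted.
* Bins are frozen at placement: placed markers never update framework
  distances, and a marker whose ML attachment lies beyond a terminal
  framework marker is clamped to the terminal position (its bin records
  the exterior attachment). This keeps framework coordinates invariant
  under placement, at the cost of compressing genuinely distal placed
  markers onto the map end when the framework stops short of a chromosome
  tip.
* The robustness statistic is a single-move neighborhood, not an
  all-orders guarantee; the framework threshold should be read in that
  light.
* Placement has, by construction, no order guarantee: on simulated CP
  data with the default informativeness mix, a small fraction of
  pseudo-testcross markers land one bin away from their true interval
  (total-map rank correlations of ~0.9999 where framework maps are
  exactly colinear). Fully informative marker sets do not show this.
* Genotype likelihood input (as opposed to called genotypes) is not
  supported.
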