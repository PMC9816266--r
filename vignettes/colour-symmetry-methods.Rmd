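---
title: "Colour symmetry, holographic goodness, and the simulated 2IFC observer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Colour symmetry, holographic goodness, and the simulated 2IFC observer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirrorcue)
```

## The scientific problem

Mirror (bilateral) symmetry detection is a classic probe of mid-level
perceptual organization: observers discriminate a pattern whose elements
are partially mirrored about a vertical axis from a fully random foil.
When element *colour* is correlated with the symmetry signal — all
symmetric elements share one colour ("segregated") — detection improves,
and attending to that colour improves it further; when colour is
anti-correlated ("antisymmetric": each mirror pair mismatched in colour
across the axis), attending to one colour can push detection to chance.
`mirrorcue` implements the full computational side of such a study: the
constrained stimulus generators (figural wedge patterns and classical
random-dot patterns), the holographic goodness score that quantifies each
stimulus, a parametric observer that performs the two-interval
forced-choice (2IFC) task, the blocked experiment designs, and the
binomial mixed-model analysis of single-trial accuracy.

No human data are shipped or required: the observer model is a synthetic
stand-in whose role is to make the entire pipeline testable end to end.
Nothing about it should be read as a mechanistic claim about human vision
beyond the qualitative structure it is built to reproduce.

## The holographic goodness score W = E/N

The holographic model of regularity quantifies the perceptual goodness of
a partly symmetric pattern as

$$W = E / N,$$

where $E$ is the evidence for regularity — the number of mirror-symmetric
element pairs — and $N$ the total number of elements. A perfectly
symmetric pattern has $W = 0.5$ (every element in a pair), a fully random
pattern $W = 0$. The constructed stimuli sit in between:

```{r}
g24 <- wedge_geometry(24, 0.5)
p2 <- generate_wedge_pattern(g24, condition_label("segregated", 2), "red",
                             seed = 1)
score_symmetry(p2)                       # W = 0.25: 50% position symmetry
p3 <- generate_wedge_pattern(g24, condition_label("nonsegregated", 3),
                             seed = 1)
round(score_symmetry(p3)$W, 2)           # 0.17: 33% position symmetry
score_symmetry(subset_elements(p2, role = "signal"))  # W = 0.5
```

`score_symmetry()` computes $E$ as a *maximum bipartite matching* between
left- and right-hemifield elements, with an edge wherever the mirror
image of one element falls within the matching tolerance of the other.
Matching is colour-blind: $W$ measures position symmetry only. We use
maximum matching rather than greedy nearest-neighbour pairing so that the
score is well defined, order-independent, and provably equal to the
brute-force optimum (the test suite enumerates all matchings on small
patterns). Elements exactly on the axis (excluded by construction) would
be self-pairs and are defined as non-matchable.

The default tolerance is half a wedge width for wedge patterns and one
blob diameter for dot patterns — deliberately identical to the
anti-accidental-symmetry margin used during generation, so that generated
foils score exactly $W = 0$ and generated symmetric patterns score
exactly their nominal $E$.

## Stimulus construction

All geometry is stored in degrees of visual angle (polar angle for wedge
positions); pixels appear only in `render_pattern()`. Angles run
clockwise from 12 o'clock and the symmetry axis is the vertical, so
reflection is $\theta \mapsto (360 - \theta) \bmod 360$ for wedges and
$(x, y) \mapsto (-x, y)$ for dots. The angular origin itself is a free
convention; only the axis matters perceptually (the experiment reinforces
it with an elongated fixation cross).

Two geometries follow the original designs: Experiment 1 uses 24 or 36
wedges covering 50% of a 13.79°-diameter circle with a 3.10° blank
centre; Experiment 2 uses 16 wedges at 20% coverage of a 14.74° circle,
and 96 Gaussian blobs (0.41° diameter, profile SD = diameter/5) over an
11° × 11° field. The blank-centre size of the Experiment 2 wedge pattern
is not separately specified in the source design; we reuse the 3.10°
value, which exists for visual comfort and does not interact with any
scored quantity.

Placement is rejection sampling under explicit, testable constraints:

* signal elements are sampled in one hemifield and mirrored exactly, so
  mirror pairs are exact by construction; signal wedge centres keep a
  margin of one full wedge width from the axis so mirrored partners are
  never adjacent across it;
* no two wedges' angular extents overlap (equivalently, centres are at
  least one wedge width apart); blob centres are at least one blob
  diameter apart, and no blob straddles the axis;
* a proposed noise element is rejected whenever its mirrored position
  falls within the matching tolerance of any other element — this is the
  operational meaning of "noise has 0% position symmetry";
* budgets: 10,000 proposals per element, then up to 100 restarts of the
  whole pattern, then an error naming the constraint that failed.
  Feasibility is comfortable at the design densities, so restarts are
  rare and failures diagnosable.

Colour assignment is solved at the whole-pattern level. Every colour
appears in exactly $N/k$ elements ($k$ = number of colours), and every
colour appears equally often in the two hemifields; for the colour-grouped
arrangements (which exist only for two colours) each hemifield is instead
single-coloured. For three-colour patterns whose signal count is not a
multiple of the colour count (e.g. 8 signal elements over 3 colours), the
pair colouring is made as equal as possible and the noise colour counts
are solved so that the whole-pattern totals and the hemifield balance
hold exactly — the 33%-per-colour property is a pattern-level constraint,
not a per-role one. Three-colour antisymmetric pairs draw their two
colours from the three unordered colour pairs, balanced across the
pattern.

The two-colour signal count is $N/2$; the three-colour signal count is
the largest even number not exceeding $N/3$ (8 of 24, 12 of 36), which
reproduces the printed $W$ values above.

Condition predicates (`condition_predicate()`) re-derive the arrangement
from positions and colours alone and are pairwise exclusive across the
six *structural* classes. The random-segregated condition is
deliberately not a seventh structural class: a random-segregated pattern
is a segregated pattern whose signal colour was drawn per trial, so the
two are indistinguishable from a single stimulus. The generators are
therefore cross-validated as a 6 × 6 diagonal acceptance matrix, with the
random-segregated *sampling policy* validated distributionally (its
signal colour is approximately uniform over seeds).

## The synthetic observer

The observer is a noisy-W comparator with feature-based colour attention:

1. every element position is jittered by independent zero-mean Gaussian
   noise with SD `sigma_pos` (degrees of polar angle for wedges, degrees
   of visual angle for dots);
2. on cued trials, with probability
   `attention_filter * cue_utilization`, all elements not of the cued
   colour are dropped before matching — except for colour-grouped
   patterns, where the hemifield-pure layout makes the cue transparently
   neutral and no filtering occurs;
3. the internal evidence is the holographic $W$ of the jittered (possibly
   filtered) pattern; the interval with larger $W$ is chosen, exact ties
   split at random; with probability `lapse_rate` the response is random.

The attentional state is drawn once per trial and applied to both
intervals — attention is a property of the trial, not of a stimulus
interval.

This minimal model reproduces the qualitative signature of the task:

* a segregation benefit (filtering a segregated pattern leaves pure
  signal, $W = 0.5$, while the filtered foil stays near 0);
* a pronounced cueing benefit only for colour-segregated symmetry, and a
  pronounced cueing cost only for nongrouped antisymmetric patterns
  (whose attended-colour subset carries no symmetry: noiseless filtered
  detection is exactly at chance);
* no cueing effect for colour-grouped patterns.

Two honest limitations, both documented in the tests: the hard filter
halves the number of pooled elements, so the *nonsegregated* condition
shows a small density-dependent cueing side effect (a cost at 16 wedges
or 96 dots, a benefit at 24 wedges) rather than exactly zero — the tests
assert that it stays strictly smaller than the real benefit and cost.
And under positional noise, wedge foils accrue slightly more accidental
same-colour correspondences than filtered antisymmetric targets (the
anti-accidental margin of half a wedge width is smaller than the full
wedge-width spacing that protects mirror slots in symmetric patterns), so
noisy cued antisymmetric accuracy sits just *below* chance (~0.45 at the
preset noise) instead of exactly at it; dot patterns are immune because
their two margins coincide at one blob diameter.

Age is a configuration preset, not a claim: `observer_preset()` gives
older observers 1.6× the positional noise of younger ones for both
stimulus types, full cue utilization for wedges, and minimal cue
utilization (0.15) for dots. That reproduces the qualitative
dissociation of interest — older observers overcome their wedge deficit
through colour cueing but fail to benefit from cueing on dots. The
younger wedge noise SD (2.5° of polar angle; 0.33° of visual angle for
dots) was chosen once to put uncued 16-wedge segregated accuracy in the
realistic ~0.8 range, between ceiling and chance.

## Experiment designs

`build_design(1)` crosses {24, 36} wedges × {2, 3} colours into four
stimulus blocks, each with 120 main trials (40 per condition:
segregated, nonsegregated, antisymmetric), run first uncued and then
cued, block order randomized per participant. `build_design(2)` blocks
by stimulus type (wedges, dots; order counterbalanced across
participants) with 250 main trials per block (50 per condition:
segregated, random segregated, nonsegregated, antisymmetric,
colour-grouped antisymmetric), uncued before cued. Colour-grouped
antisymmetric trials are paired with colour-grouped random foils; all
other conditions use plain random foils. Each block begins with 16
practice trials, repeated while accuracy fails to exceed 60%; practice
trials are generated and simulated but flagged and excluded from every
analysis. Timing fields (700 ms fixation, 700 ms ISI, 500/1000 ms
stimulus; 0.55° × 5.52° fixation cross) are metadata carried for design
export — nothing is presented in real time.

Cue-validity accounting of the cued Experiment 2 design classifies the
segregated condition and (in expectation) half of the random-segregated
trials as valid — 30% of trials — the colour-grouped antisymmetric
condition as neutral (20%), and the rest as invalid (50%):

```{r}
cue_validity_breakdown(build_design(2, seed = 1))
```

Participant exclusion applies the strict-below rule: overall accuracy
below the 55% threshold excludes; exactly 55% is retained.

## The analysis pipeline

`fit_glmm_backward()` fits the full factorial binomial GLMM on
single-trial accuracy (logit link) with per-participant random effects.
The random structure starts from the requested specification —
`"maximal"` tries slopes for all fixed main effects and simplifies on
non-convergence or singularity down to a random intercept; the default
is the random intercept, appropriate at simulation scale. Fixed terms
are then backward-eliminated: at each step every term not contained in a
retained higher-order term is tested by a likelihood-ratio chi-squared
test against the current model, and the term with the largest
non-significant p (at the retention threshold `alpha = 0.05`, the
conventional value) is removed; the full test history is returned as a
ledger. Effect sizes are standardized odds ratios with the anchors
1.68 / 3.47 / 6.71 (≈ Cohen's d of 0.2 / 0.5 / 0.8), banded by the
nearest anchor on the log scale.

`posthoc_contrasts()` computes estimated marginal means on the
linear-predictor scale for the cells of a retained interaction (equal
weights over the other factors), all pairwise contrasts, and Wald z
statistics. The multiplicity adjustment simulates the null distribution
of the maximum absolute z from the estimated contrast correlation
matrix (100,000 seeded draws by default) — a parametric analogue of
multivariate-t adjustment; exact multivariate-t quadrature is out of
scope, and a Bonferroni fallback is provided. The Monte-Carlo estimate
uses the (1 + count)/(draws + 1) form, so adjusted p-values have a
resolution floor of 1/(draws + 1); they are also clamped to be at least
the unadjusted p. An independent cross-check against `emmeans` cell
means and z statistics runs in the test suite.

## Numerical and design choices

* **Determinism.** Every generator takes an explicit seed and restores
  the caller's RNG state; per-trial seeds are derived by counter from the
  participant seed, so simulated records are reproducible and
  order-independent, and the CLI pipeline is byte-reproducible under a
  fixed seed.
* **Ties.** Exact W ties in the 2IFC decision are split uniformly at
  random from the trial's RNG stream.
* **Degenerate inputs.** Empty patterns, axis-straddling elements,
  impossible condition/colour combinations, sub-threshold participant
  counts and rank-deficient contrast sets all raise errors naming the
  violated constraint.
* **Problem sizes in the test suite.** The suite validates the
  condition-predicate matrix over 1002 generated patterns, observer
  monotonicity at 5,000 trials per noise level, noise recovery at 5
  levels × 2,000 trials, and the GLMM operating characteristics at 20
  participants × 200 trials/cell with 40 null and 20 effect replicates —
  sizes chosen to keep Monte-Carlo error far below the asserted margins
  while the whole suite stays desk-scale. Observer Monte-Carlo
  experiments cycle moderate pools of pre-generated patterns rather than
  generating a fresh pattern per trial; accuracy estimates average over
  both pattern and encoding noise either way.

## What passing tests do and do not show

The synthetic observer emulates the *structure* of the behavioural data
— accuracy that is graded by colour-symmetry condition, modulated by
attention with the correct signs, and degraded by age-like noise — so a
green suite demonstrates that the stimulus arithmetic, designs and
statistical machinery are correct and that the qualitative behavioural
signature is attainable within this pipeline. It does not reproduce
human accuracy levels (e.g. the published group means), does not model
orientation information in wedges separately from position (angular
jitter already differentiates wedge difficulty), and carries no claim
about the mechanism of human feature-based attention.
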