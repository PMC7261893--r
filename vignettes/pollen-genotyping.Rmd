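---
title: "Methods: crossover and distortion analysis from single-pollen genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: crossover and distortion analysis from single-pollen genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollenscan)
```

## The data and the model

The unit of observation is a haploid gamete (a flow-sorted,
whole-genome-amplified pollen nucleus) scored at a panel of mapped SSR and
SNP markers, each heterozygous in the focal parent. Because the parent's
two haplotypes are known (phased), every successful allele call identifies
which parental haplotype the gamete inherited at that locus: code `P1` or
`P2`. A failed amplification is `MISSING`; an allele carried by both
haplotypes is `AMBIGUOUS` (the marker is uninformative for that gamete);
an allele matching neither haplotype is `OFF_LADDER` (typically a sizing
artifact or contamination) and is kept visible rather than silently
dropped. All three non-informative codes are treated identically by the
downstream crossover analysis; the chain of informative markers is what
carries signal.

Along one chromosome, the sequence of origin codes of a single gamete is a
direct readout of meiosis: every change of origin between consecutive
informative markers is (at least) one crossover. The model is
intentionally minimal — no interference, each observation interval scored
as 0/1 switch — because a pair of flanking markers can only reveal the
*parity* of the crossover count between them. An even number of
crossovers inside one interval is invisible; reported counts are
therefore lower bounds, and the per-gamete count can never exceed
(number of informative markers − 1).

### Quality control

A gamete is retained when its fraction of positive calls over the full
marker panel is at least `threshold` (default 0.65, the conventional cut
for WGA single-nucleus panels of this size; at 12–30 markers it demands
8/12 or 20/30 successes). The denominator is always the full panel, so a
locus that failed in many gametes still counts as attempted. Two overall
rates are reported: retention (gametes kept / gametes assayed) and the
positive-call rate of whatever matrix is passed in. Published accounting
of this kind typically quotes the positive-call rate *of the retained
gametes*, so the pipeline applies `qc_filter()` twice — once to the full
population, once to the retained subset.

### Crossover counting and the CO ratio

`detect_switches()` walks consecutive informative markers; missing pairs
are omitted by merging: the observation simply spans the skipped loci.
Per-arm counts need a centromere position (in cM) per linkage group —
an external input, though for the packaged panels it is derivable from
the published distance-to-centromere column. Assignment rules, chosen
where the data cannot adjudicate and applied deterministically:

- a switch interval entirely on one side of the centromere belongs to
  that arm;
- a centromere-spanning interval goes to the arm holding the larger cM
  share of the interval; an exact tie goes to arm 1 (the short-position
  side). With markers a few cM apart this affects at most the rare switch
  bracketing the centromere.

The per-interval recombination frequency is `co_ratio = n_co /
n_informative` per elementary (adjacent-marker) interval. Merged
observations raise a bookkeeping question the field leaves open: with
`denominator = "spanning"` (default) an observation contributes to every
elementary interval it covers, and its switch (if any) is assigned to the
genetically longest covered interval (leftmost on ties), which preserves
the identity "sum of interval n_co = total detected switches";
`"adjacent"` restricts to flank-exact observations. Intervals with no
informative observation report `NaN`, never 0 — absence of data is not
absence of recombination.

### The distortion scan

Transmitted-allele counts come from `allele_counts()`. Haploid calls
count directly. Diploid progeny calls are decomposed by brute force over
the two parent-assignments; the count is taken only when exactly one
focal-parent allele is consistent (e.g. focal 155/162 × other 162/168
observing "162/168" forces focal → 162, since 168 is not a focal allele).
Calls where both decompositions are valid are excluded and reported as
ambiguous — on panels chosen for unequivocal parental differentiation
this set is empty.

Each marker is tested with the uncorrected two-category chi-square
against 1:1, `(A1 − A2)² / (A1 + A2)`, df = 1. No continuity correction
is applied and no multiplicity adjustment is made by default; both match
how such scans are conventionally reported (an `adjust` argument exposes
`p.adjust` methods for users who want them). The distortion rate is the
flagged fraction of tested markers. `sd_regions()` calls a
segregation-distortion region as a maximal run of ≥ `min_run` (default 2)
consecutive distorted markers on one linkage group — hitchhiking around a
selected locus is expected to flag neighbours together, and a minimum run
of 2 keeps isolated single-marker flips (which at alpha = 0.05 occur by
chance in ~1 marker per 20) out of region calls.

`compare_populations()` contrasts two scans on one panel: markers
distorted in both populations indicate selection already acting in the
gamete pool (gametic), markers distorted only in the progeny indicate
selection at fertilization or later (gametophytic incompatibility,
zygotic viability).

### Diversity

`simple_matching()` implements the simple-matching dissimilarity at
ploidy 1 — one minus the fraction of matching calls over jointly scored
loci, with pairwise deletion of missing data (L is pair-specific; the
software the field commonly uses does not document its missing-data rule,
so ours is stated here prominently). Neighbor joining is delegated to
`ape::nj()` (classic Saitou–Nei); the "weighted" variant falls back to
classic with a warning rather than approximating a likelihood-weighted
method badly. Negative NJ branch lengths are clamped to zero with the
deficit pushed to the adjacent branches, preserving path lengths through
the node; Newick output carries 6-decimal branch lengths.

## The simulator

`simulate_gametes()` draws each chromosome's origin chain marker by
marker: the first origin is fair (1/2), and adjacent markers switch with
probability given by the mapping function of the interval. Under Haldane
the per-interval crossover *count* is drawn Poisson(d/100) and the origin
switches on odd counts — the Poisson process from which the Haldane
function derives — so the recorded truth contains multi-crossover
intervals and the detected switch pattern should equal the parity of the
truth. Kosambi has no equivalent count process, so there a single
Bernoulli(r) switch is one crossover. Selection and noise:

- **gametic selection**: a transmission probability t per selected locus,
  applied by rejection sampling on the realized allele; linked loci
  hitchhike through the map rather than being modelled directly;
- **zygotic selection**: `simulate_progeny()` pairs male and female
  gametes and thins zygotes by a survival probability per genotype class
  at selected loci — the male pool itself is untouched, which is exactly
  the gametic/zygotic contrast the analysis is meant to detect;
- **dropout**: i.i.d. per call at a single rate (defaults used in
  validation: 0.05–0.12, the range seen in WGA single-nucleus panels).
  Real WGA failure is partly locus-specific and includes allele-specific
  dropout; neither is modelled, so simulated missingness is more benign
  than real missingness.

The simulator emulates sample sizes like the motivating study (34–54
gametes, 12–30 markers over 9 linkage groups, up to ~12% dropout,
near-complete zygotic exclusion of one allele class). What passing tests
on simulated data show is that the *estimators* are correct under the
stated model — they do not validate the no-interference assumption, the
uniformity of dropout, or allele-calling accuracy on real
electropherograms.

Determinism: every stochastic function takes a single integer seed;
derived substreams use a fixed documented offset rule
(`seed + 1000003·k mod (2³¹ − 1)`), and the caller's RNG state is always
restored.

## Numerical and degenerate-input choices

- Map ties (equal cM) are ordered stably by locus id; co-located markers
  get recombination fraction 0 and always share an origin.
- Allele labels are opaque text: SSR fragment sizes are never coerced to
  numbers, so "204" and "A" live in one representation.
- A gamete with < 2 informative markers on a chromosome is excluded from
  that chromosome's summaries with a logged reason (the panel-wide QC is
  separate; no per-chromosome threshold beyond feasibility is imposed).
- `chi_square_1to1(0, 0)` is an error, not 0; empty scans report a `NaN`
  distortion rate and render as "no markers tested".
- Rejection sampling aborts with an explicit error after a bounded number
  of batches when selection constraints are infeasible (e.g. t = 1 and
  t = 0 at fully linked loci); zygotic thinning that kills every zygote
  errors rather than returning an empty population.

## Validation problem sizes

The test suite checks calibration and recovery at sizes chosen to make
Monte-Carlo bounds tight while staying fast: type-I error of the scan
over 2000 no-selection populations of 48 gametes at 11.3% dropout (the
mixture of attempted-call counts makes the discrete test's exact size
average ≈ 0.050, so a 95% CI around the Monte-Carlo rate is expected to
cover 0.05 — at a single fixed n the uncorrected chi-square's exact size
oscillates between ≈ 0.040 and 0.059 with parity); recombination-fraction
recovery from 5000 complete gametes (3-binomial-SD bound per interval);
selection power at t = 0.9, n = 86 against the exact binomial and its
noncentral chi-square approximation; NJ path-length recovery on additive
matrices to 1e−9.

## Known limitations

- No crossover-interference model (gamma/counting) and no chromatid
  interference; the tail of the per-arm count distribution is therefore a
  qualitative, not quantitative, surface.
- Parental phase is an explicit input, never inferred from the gamete
  population.
- The weighted NJ variant is a documented fallback to classic.
- Distortion tests are marginal per marker; no joint model of linked
  selection, and no estimation of selection coefficients.
- With tied (zero) dissimilarities, NJ join order — hence topology among
  identical profiles — depends on input order; tree comparisons should
  treat such clades as unresolved.
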