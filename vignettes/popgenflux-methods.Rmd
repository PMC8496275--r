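---
title: "PopGenFlux: methods, models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PopGenFlux: methods, models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PopGenFlux)
```

PopGenFlux implements the polymorphism-and-divergence analysis chain for a
codon-structured gene region sampled in one or more populations with one or
two outgroup sequences. This vignette records the statistical models, the
parameters that matter, the numerical conventions, and the design decisions
that were genuinely open — in enough detail that a reader can judge what a
passing test suite does and does not establish.

## Coordinates, site classes and effective lengths

All internal coordinates are 0-based half-open; printed reports render
1-based inclusive. The codon frame is built by walking the concatenated
exon columns in annotation order, honouring the first exon's phase and
requiring phases to chain consistently across splice sites; codons
truncated at region boundaries are flagged and skipped by codon-level
analyses.

A variable exon column is *synonymous* when every codon variant observed at
that column encodes the same amino acid, holding the other two positions at
their observed context, and *nonsynonymous* when all variants encode
distinct amino acids. Three situations are excluded and logged rather than
guessed at: codons segregating at more than one position (no pathway
averaging), columns whose variants mix synonymous and nonsynonymous
effects, and codons containing an observed stop. Codons with an alignment
gap in any analyzed row are excluded whole — the conservative reading when
indels have already been curated to codon multiples — while an `N`
drops only the affected row for that codon.

Per-site rates need a denominator. Synonymous and nonsynonymous effective
lengths are Nei–Gojobori fractional site counts (each codon position
contributes the fraction of its three possible point mutations that are
synonymous; mutations creating stops count as nonsynonymous, which keeps
the two classes summing to exactly 3 per codon), averaged over the analyzed
rows and summed over codons after exclusions. Equal-weight counting, with
no transition/transversion bias, matches the convention of the standard
desktop tools this pipeline mirrors. Intron effective length is the count
of intact intron columns. Sites with missing data in the population sample
are dropped listwise for S, π and the frequency spectrum (complete
deletion).

## Summary statistics

* Watterson's θ_W = S / (a_n · L) with a_n = Σ_{i<n} 1/i.
* π is the mean pairwise difference over all C(n,2) pairs; per-class π
  divides the class's pairwise total by the class's effective length
  (invariant columns contribute zero differences, so restricting the sweep
  to variable columns is exact).
* Tajima's D uses the 1989 variance constants and is undefined at S = 0
  (returned as `NA` with a reason, never silently zero).
* Fay & Wu's H = θ_π − θ_H is computed from the polarized spectrum and
  reported **unnormalized**, the scale on which values of magnitude several
  units arise for a ~1.5 kb region; polarization requires all outgroup
  bases at the column to agree and to match one of the two ingroup alleles,
  otherwise the variant is excluded from polarized statistics.
* Divergence is uncorrected (no multiple-hit correction). Between-species
  synonymous/nonsynonymous divergence is computed codon-wise: one-step
  codon differences are classified by effect, codons differing at two or
  three positions are excluded, and numerators are divided by
  pair-averaged fractional site counts before averaging over the
  between-species sequence pairs. This keeps fixed differences at
  ingroup-invariant codons in the numerator, which a column-class-based
  denominator would miss.

## The coalescent null and empirical p-values

Neutrality tests on D and H use simulated null distributions rather than
asymptotic ones. The simulator is an exact backward-in-time ancestral
recombination graph in the Hudson tradition, written in C++ for speed: with
k lineages, any pair coalesces at rate 1/λ(t) per pair (time in units of
2N₀ generations, λ the relative population size), a lineage spanning
breakable material of width w recombines at rate (R/2)·w, and infinite-sites
mutations arrive at rate (θ/2) per unit of ancestral material per unit
time, attached to the descendant set of the segment they hit. Material that
reaches its marginal MRCA stops being tracked. An exact ARG — not an SMC
approximation — is the right tool here: the target regions are ~1.5 kb with
R of order 10², well inside exact-simulation range.

Demography is piecewise-exponential: within an epoch starting at t_j with
size s_j and growth g_j, λ(t) = s_j·exp(−g_j(t−t_j)). Three constructors
cover the supported scenarios: `equilibriumModel()`, `growthModel(alpha)`
(population grown toward the present, so the backward hazard inflates as
e^{αt}), and `bottleneckModel()` (three constant-size epochs). Waiting
times under time-varying rates are drawn by analytic inversion of the
integrated hazard, epoch by epoch; the final epoch must have non-negative
growth so coalescence is guaranteed. For X-linked loci the population
recombination parameter is R = 3N_e·r·L (three X copies per breeding pair)
rather than 4N_e·r·L; with N_e = 10⁶, r = 3.34×10⁻⁸/bp and L = 1500 the
formula gives R = 150.3. (Published analyses of such regions sometimes
quote a rounded R ≈ 152 for the same inputs; the package reports the
formula value.)

Growth and bottleneck parameter values are study inputs, typically cited
from demographic-inference literature; the package deliberately ships no
default values for them. Priors are independent uniforms over named
parameters (e.g. `theta_per_site` bounds of 0.006–0.009 per site are the
kind of range used for African *D. melanogaster* samples); one RNG stream
drives all draws and every draw is logged per replicate.

Empirical p-values count **inclusively**: the proportion of null values ≤
the observed statistic for the lower tail (negative statistics) or ≥ for
the upper tail. A zero count is reported as "< 1/N" rather than 0. The
default of 10,000 replicates makes "< 0.0001" the smallest reportable
value; replicate count is a config field. Replicates where a statistic is
undefined (S = 0) are skipped and recorded, with the defined replicates as
the denominator; a resampling policy is available by flag. Bonferroni
adjustment uses a per-test cutoff of α_family/k with **strict** inequality:
a p-value exactly at the cutoff does not reject. The default family level
of 0.025 corresponds to running two one-tailed tests per sample at an
overall 0.05.

## McDonald–Kreitman machinery

Sites are classified by the original manual construction: a site is
*polymorphic* when any species in the designated polymorphism set
segregates more than one nucleotide in its sample, and *fixed divergent*
when all alleles of one species differ from all alleles of the others. A
site that is both counts as polymorphic only — under the divergence
definition a truly fixed difference cannot coexist with shared variation,
so polymorphism must take precedence. The combined-polymorphism variant
simply lists two sister species in the polymorphism set; with one of them
reduced to a single sequence it collapses to the single-species table
(a tested reduction property).

The 2×2 test is the two-tailed Fisher exact test under the
point-probability rule (the sum of probabilities of all tables with the
observed margins no more probable than the observed one), which is what
`stats::fisher.test` computes; the suite verifies it cell-for-cell against
a brute-force hypergeometric enumeration across margins up to 60. A zero
margin yields p = 1.

The low-frequency filter removes polymorphic variants below a frequency
threshold (0.15 by convention) from the polymorphism cells only —
fixed-divergent cells are untouched by construction. Frequency is measured
on the derived allele when the variant polarizes; unpolarizable variants
under derived mode are excluded and logged rather than guessed. At
threshold 0 the filter is the identity. Removing two 10%-frequency
synonymous singletons from a (19, 0 | 19, 7) table gives (17, 0 | 19, 7)
and a Fisher p of 0.031.

## The CF test

The CF test asks whether fixed synonymous substitutions on a lineage are
biased toward preferred codons relative to opportunity. Fixations are
assigned by unpolarized two-outgroup parsimony: the focal species must be
fixed for one codon state with both outgroups sharing the alternative
state; disagreeing or unfixed outgroups, segregating focal samples, and
codons differing at more than one position are logged unassigned. "Sites"
are current-state opportunity counts on the focal consensus — a currently
preferred codon is one opportunity for an unpreferred change and vice
versa — the only reading under which the unpreferred-site count dwarfs the
preferred-site count in a preferred-codon-rich gene, as observed. Met and
Trp codons contribute to neither.

The default test on (substitutions) × (sites) is the Pearson chi-square
without continuity correction. This was a genuinely open choice: published
CF tables are sometimes footnoted as Fisher exact, yet the uncorrected
chi-square reconstructs the printed p-values of such tables far more
closely than any Fisher variant (e.g. (1, 3 | 154, 31) gives χ² ≈ 9.0,
p ≈ 0.0027), so chi-square is the default and Fisher remains available by
flag. Direction of departure is reported in the table style ("Preferred
codons favored" / "No preference"), with a zero margin short-circuiting to
p = 1 and no preference.

Codon preference is config data, not code. The bundled table
(`inst/extdata/dmel_preference.tsv`) assigns one preferred (major) codon
per amino-acid family for *D. melanogaster* in the major-codon-usage
tradition, with Met and Trp not applicable; analyses record the species tag
of the table they used. Because published CF site counts depend on the
exact preference set, which such papers rarely print, site counts are
reproduced structurally rather than asserted numerically against any
particular publication.

## Substitution mapping

Amino-acid substitutions are mapped by Fitch parsimony — the minimal
assumption-free reconstruction for descriptive substitution tallies —
rather than by model-based ancestral reconstruction. State sets are built
tip-to-root (intersection where non-empty, else union, one penalty per
union); branch placement follows one deterministic minimal resolution
root-to-tip: a node inherits its parent's state whenever allowed, else
takes the alphabetically first member of its set, which places changes as
deep as the minimum allows; placements with more than one candidate are
flagged ambiguous. Codons with a gap in any taxon are excluded
symmetrically from counts and region totals. Region boundaries (N-terminal
/ RNA-binding / C-terminal) are configuration with 1-based-inclusive codon
intervals; the heterogeneity test is the uncorrected 2×2 Pearson chi-square
of substituted-vs-not against region.

Parsimony counts are a lower bound on true event counts. The tests
demonstrate equality only at *homoplasy-free* codons — all states in the
codon's true history distinct and no branch hit twice (a branch hit twice
hides the intermediate state from every tip) — and verify the bound
everywhere else; on real data with saturated codons the mapped counts
understate the truth by construction.

## Synthetic data: what it emulates and what it does not

`makePopulationAlignment` threads exact coalescent haplotypes onto an
ancestral codon-structured sequence: each simulated variant draws a site
class from a requested mix and lands on an unused column where such a
change is possible (rejection sampling against the enumerated opportunity
pool; quota exhaustion is an error, never silent degradation). Outgroups
are emitted from the ancestral state, optionally with extra fixed
differences. `evolveOnTree` runs a Poisson codon-substitution process along
branches with separate synonymous and nonsynonymous rates and a tunable
preference bias for synonymous moves. `makeMKFixture` plants exact MK cell
counts, one codon per event. Every generator is seed-deterministic and logs
every event exactly once; replaying a truth log onto the ancestor
reproduces the emitted sequences, and this is tested.

The generators emulate the *structure* of real data — codon frame, site
classes, frequency spectra, lineage-specific fixation — not its chemistry:
there is no mutation-spectrum bias, no CpG or context dependence, no
selection during the coalescent, no indel process, and outgroup divergence
is planted rather than evolved. Passing tests therefore certify the
counting and testing machinery, not robustness to alignment error or to
violations of the infinite-sites assumption.

## Numerical conventions and problem sizes

Degenerate inputs have defined behaviour throughout: S = 0 makes Tajima's D
`NA`-with-reason and the singleton fraction undefined; zero-margin
contingency tables give p = 1; an empty opportunity pool or an infeasible
fixture request is an error. Fisher/enumeration agreement is asserted to
1e−9; chi-square/closed-form identities to 1e−10; analytic identities
(θ_π-from-SFS vs pairwise π, site-count conservation) to 1e−12.

Monte-Carlo checks use fixed seeds and ±3 standard-error bands: simulator
moment calibration at 2,000 replicates (n = 10, θ = 10, L = 1500);
p-value uniformity with a 1,000-replicate null and 200 test observations
(Kolmogorov–Smirnov distance below 0.1 — note the 5% critical value at 200
points is 0.096, so this band is tight by design); growth-skew and
recombination-variance checks at 400–800 replicates; the CF type-I
calibration over 1,000 simulated tables; Fisher-vs-enumeration over 400
random margin configurations up to 60 plus the standard reference tables;
and Fitch-vs-truth over 1,000 tree-evolved codons. These sizes are the
package's own choice of a good precision/runtime balance for routine
testing; all are config-adjustable upward.

## Known limitations

* No normalized H (or Zeng's E), haplotype statistics or sliding windows.
* No α-of-adaptive-substitutions estimators on top of the MK tables.
* The CF test has no mutation-bias correction; preference tables are
  single-preferred-codon-per-family by default.
* Fitch mapping reports one deterministic minimal resolution; the full set
  of equally parsimonious placements is only flagged, not enumerated.
* The simulator has no gene conversion and no selection; it serves
  p-values, not posterior inference.
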