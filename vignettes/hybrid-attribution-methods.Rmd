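---
title: "Attributing wild duck hybrids: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributing wild duck hybrids: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duckhybrids)
```

`duckhybrids` turns a field study's analysis chain — hunter-solicited hybrid
duck specimens, ddRAD genotypes, mtDNA barcodes, continental abundance maps
— into a reusable, fully testable pipeline. This vignette explains each
model, its assumptions, the tunable parameters, and the design decisions
taken where the underlying procedure left genuine freedom. Nothing here
states an empirical result beyond what the package's own tests and
acceptance script compute.

## 1. The scientific question

Waterfowl hybridize more than any other bird family, yet individual hybrids
are rare (`harvest_rate()` on the bundled multi-season harvest totals gives
just under 2 per 10,000 parentals). Three behavioural mechanisms could
generate them: interspecific forced copulations, sexual mis-imprinting of
fostered chicks, and scarcity of conspecific mates. Distinguishing them
requires knowing, for each F1 hybrid, *which species was the father*. The
pipeline therefore (i) verifies that a specimen is an F1 from genome-wide
ancestry, (ii) reads the mother species from maternally inherited mtDNA,
(iii) infers the father as the other member of the nuclear parent pair, and
(iv) tests whether fathers are predicted by phallus-length asymmetry (the
standard proxy for a species' propensity to force copulations), by mass
asymmetry, and whether hybrid-pair frequencies track breeding-range
abundance overlap.

## 2. Genotype scoring and filtering

Read counts per candidate haplotype at a locus are scored by
`call_genotype()`:

* homozygous when the top haplotype exceeds **93%** of reads (strict `>`);
* heterozygous when a second haplotype exceeds **29%** (strict `>`), or
  reaches **20%** (inclusive `>=`) *and* that haplotype is seen in other
  individuals — the two conditions are alternatives, so an allele at
  exactly 29% with population support qualifies via the 20% rule;
* flagged otherwise, when more than two haplotypes are credible (share ≥
  20%), or when fewer than **5** reads are present. A flagged genotype
  keeps its majority allele and scores the second allele missing, so it
  counts as genotyped-with-one-allele; *missingness* below always means
  fully missing slots.

The inclusive 20% boundary follows the wording of the protocol the rule
derives from ("as few as 20% of reads"); all other thresholds are strict as
stated. "Consistent with a haplotype" is operationalised as an exact
haplotype-key match on count fractions — alignment-level read/haplotype
consistency is upstream of this package.

`filter_matrix()` implements two lab presets whose rules and *order* differ
(the order matters and is tested):

* **wsu**: drop loci with more than 20% missing or more than 5% flagged
  genotypes; then drop individuals genotyped at fewer than 75% of the
  retained loci.
* **cornell**: keep a single SNP per RAD locus (the first position per
  locus identifier — the upstream export does not specify a choice, and
  first-position is reproducible); keep loci present in at least 80% of
  individuals; drop individuals with more than 25% of loci missing;
  re-apply the presence filter to the survivors (the "re-export" pass);
  finally drop Z-linked sites, identified purely by the chromosome label in
  the locus metadata.

Both presets are idempotent, every removal is reported with a reason, and
survivor sets are verified against brute-force re-implementations of the
rules on random matrices.

## 3. Supervised ancestry

Reference allele frequencies per species are plain tallies
(`estimate_allele_freqs()`), with missing genotypes excluded from the
denominator and frequencies clamped to `[1e-4, 1 - 1e-4]`. The clamp avoids
infinite log-likelihood terms when a panel is fixed for one allele; its
magnitude is far below the sampling noise of an 8–12 bird reference panel
and does not move any estimate materially.

For a query with dosages `g_l ∈ {0, 1, 2}` the ancestry vector `q` (length
K, on the simplex) maximises

```
L(q) = Σ_l [ g_l log(p_l) + (2 − g_l) log(1 − p_l) ],   p_l = Σ_k q_k f_kl
```

via the EM update

```
q_k ← q_k / (2 L') · [ Σ_l f_kl g_l / p_l + Σ_l (1 − f_kl)(2 − g_l)/(1 − p_l) ]
```

over the L' non-missing loci. Because the likelihood is concave in `q` for
fixed frequencies, a single deterministic run from the uniform start
`q = 1/K` suffices — no restarts. Convergence is declared when the
log-likelihood improves by less than `tol = 1e-6` (units of log-likelihood)
within `max_iter = 2000` iterations; monotonicity is asserted at every
step. Near the simplex boundary (nearly pure individuals) EM drains the
minor components geometrically and can exhaust `max_iter`; the best iterate
is returned with a warning, and in practice the maximum assignment is far
inside its classification band by then. The two-species case is verified
against a dense grid search (step 0.001) to within 0.005.

Hybrid classes follow the maximum assignment probability `max_k q_k`:

| class | band | pedigree expectation |
|---|---|---|
| F1 | ≤ 0.64 | 0.50 |
| F2 backcross | (0.64, 0.875] | 0.75 |
| later backcross | (0.875, 0.95) | 0.875 |
| parental | ≥ 0.95 | 1.00 |

The 0.64 F1 bound is the study's published rule (the empirical maximum-
assignment distribution is bimodal with modes near 0.50 and 0.75). The
upper bounds are our choice, taken from pedigree expectations: 0.875 is the
midpoint-free natural cap for an F2 backcross (expected 0.75) before the
later-backcross expectation (0.875), and 0.95 separates later backcrosses
from parentals while absorbing panel sampling noise. Z-linked loci are
assumed removed upstream (the cornell preset does this); ancestry treats
all loci as autosomal diploid. The package exposes the reference-panel
composition as data, since supervised runs with different panel sizes are a
known degree of freedom.

## 4. Maternal assignment

Published analyses embedded each hybrid's haplotype in a tree
(Neighbor-Joining under HKY distances, or SVDquartets with bootstrap) and
read the dam from the clade it fell in. For species-diagnostic markers the
decision boundary of that procedure is the nearest reference species, so
`assign_maternal()` uses the mean uncorrected p-distance
(`p_distance()`: mismatches over comparable sites, N/gap sites excluded) to
each species' references and assigns the argmin. This is exactly testable
and invariant to reference order and duplication. A distance-model
correction (K80/TN93 via `ape::dist.dna()`) is available but not the
default — at barcode-scale divergences the correction cannot reorder
species whose distances differ by more than the margin below.

"Unambiguous" clade membership becomes a margin rule: the second-best
species must be at least `min_margin = 0.01` substitutions/site further
than the best. The default is an order of magnitude above the
within-species haplotype diversity the simulator produces (≤ 2 sites on a
600 bp marker ≈ 0.003); a smaller margin raises an explicit ambiguity
error, never a guess. Mixed marker panels (e.g. control region and COI) are
aligned separately and must agree (`assign_maternal_markers()`), else the
specimen is ambiguous. `infer_sire()` returns the non-maternal member of
the nuclear parent pair and raises an inconsistency error when the mtDNA
mother is not in that pair — such specimens are flagged for manual
resolution by exclusion, mirroring how a sire can be inferred when direct
reference material is lacking.

## 5. The encounter null model

The null hypothesis is that hybrid combinations form in proportion to how
often the two species meet on the breeding grounds. `compute_pair_weights()`
summarises, for every unordered species pair, the log-transformed
abundances over *cells of sympatry* — cells where both species' abundances
exceed zero. Three per-cell combiners are provided because the source
description ("summed abundances between all possible species pairs") is
ambiguous:

* `product_log` (default): `Σ_cells ln(1 + a_i) · ln(1 + a_j)` — both
  species must be present and the product rewards joint abundance;
* `sum_log`: `Σ_cells [ln(1 + a_i) + ln(1 + a_j)]`;
* `min_log`: `Σ_cells min(ln(1 + a_i), ln(1 + a_j))`.

The choice is a config switch so it is auditable; `log(1 + x)` (natural
log) keeps zero-abundance cells well-defined. Sympatry has no buffer or
adjacency — a cell either holds both species or it does not.

`simulate_expected()` draws `n_draws = 127` hybrids i.i.d. from the
categorical distribution proportional to the weights, `n_reps = 1000`
times, and reports each pair's mean and sample standard deviation
(denominator `n − 1`; with 1000 replicates the difference from `n` is
immaterial but must be fixed for determinism). `method = "exact"` provides
the multinomial closed form (`μ = np`, `σ = √(np(1−p))`, population form),
which the tests verify against exhaustive enumeration of the multinomial to
1e-9 and which the resampler converges to.

`standardized_effects()` computes `SES = (O − μ)/σ` and classifies pairs
outside ±1.645 (the two-sided 90% interval) as over- or under-represented.
Degenerate spreads are handled explicitly: `σ = 0` leaves SES undefined —
the pair is `within` if `O = μ`, `over` (with a zero-weight flag) if
hybrids were observed despite zero overlap, and `no_expectation` otherwise.
SES is invariant under uniform rescaling of the weights. Because counts are
discrete, the nominal 10% outside-rate is approximate; the acceptance suite
checks calibration within ±0.05 over 500 null replicates. Pairs with
`O = 0` that were expected to be common are visible in the report as large
negative SES; both the SES and the zero-observed state are reported rather
than collapsing them into one call.

## 6. Behavioural statistics

`binomial_tail()` computes exact tails by summation (`stats::pbinom`);
the default is one-sided in the direction "the longer-phallus species
sires", because the reproducible published values (18/22 → 0.002, 10/11 →
0.006, 11/13 → 0.011) are exactly the one-sided tails. Two-sided doubles
the smaller tail. `fisher_exact_2x2()` enumerates `stats::dhyper` over the
feasible range and uses the minimum-likelihood two-sided convention, which
reproduces the published 0.09 on the reduced complementarity table. Two
published values are *not* reproduced by any exact convention and are
flagged as discrepancies rather than matched: the 14-of-16 entry printed as
0.006 (exact one-sided 0.0021, two-sided 0.0042) and the full
complementarity table printed as 0.001 (minimum-likelihood two-sided
≈ 4.7×10⁻⁴). The tests assert the exact values and that they differ from
the printed ones.

`summarize_sire_tests()` groups parental pairs into large versus small
phallus asymmetry at a configurable 40 mm threshold ("about 40 mm or
more"). The bundled published table carries its printed sectioning in a
`section` column — the printed large-asymmetry section includes a 39 mm
pair, which a strict threshold would misplace — and an explicit section
column takes precedence over the threshold. Mass complementarity
(`build_complementarity()`) contrasts the sire species' *male* mass with
the dam species' *female* mass, the biologically relevant comparison for
whether larger females can resist forced copulations. Winter phallus means
missing for a species are estimated from summer means by the log-log
regression (`predict_winter_phallus()`, coefficients 0.7836/0.3195 treated
as base-10 — the published plot says only "log-log", and predictions are
labelled as estimated). The flock-association test is the one-sided exact
binomial on the larger of the mother/father association counts.

## 7. The synthetic-data generator

The generator's defaults are the study conditions, not tuning knobs:

| parameter | default | emulates |
|---|---|---|
| `n_species` | 8 | the eight-species reference panel |
| `n_ref_per_species` | 10 | 8–12 reference birds per species |
| `n_loci` | 2000 | a post-filter ddRAD SNP panel |
| `fst` | 0.3 | divergence among duck genera at ddRAD SNPs |
| `grid_side`, `range_radius` | 30, 10 | broadly overlapping breeding ranges |
| abundance lognormal | meanlog 1, sdlog 1 | right-skewed cell abundances |
| `mtdna_length`, `mtdna_divergence` | 650 bp, 0.05 | barcode-scale species-diagnostic markers |

Abundances are lognormal inside a *hard circular footprint* — real
abundance surfaces are continuous, but a hard footprint makes sympatry
unambiguous for testing. Allele frequencies follow the Balding–Nichols
model: per locus an ancestral frequency `p ~ U(0.05, 0.95)`, species
frequencies `Beta(p(1−F)/F, (1−p)(1−F)/F)` with variance `F·p(1−p)`
(verified against these moments at 10,000 loci). Hybrid genotypes follow
the pedigree with unlinked loci: an F1 takes one allele from each species;
backcross gametes mix lineages independently per locus, giving expected
recurrent-parent ancestry 0.75 (F2 backcross) and 0.875 (later backcross).
mtDNA mutations are placed uniformly with no rate heterogeneity — enough
for a distance classifier, not for model-based phylogenetics — with at most
one private mutation per reference or hybrid haplotype. All randomness
derives from a single seed through deterministic per-component substreams
(`substream_seed()`), so any stage can be regenerated independently and a
fixed seed gives byte-identical output.

What the simulants do *not* model — and hence what passing tests cannot
show about real data: spatial autocorrelation and migratory geometry of
real ranges, linkage and variable coverage in ddRAD data, reference
panels contaminated by undetected backcrosses, mtDNA heteroplasmy or
numts, and hunter ascertainment bias in which hybrids get recognised and
submitted.

## 8. Problem sizes and numerical choices

The test suite and acceptance script use the study-scale conditions where
the claim depends on them (2,000 loci, `fst = 0.3`, 10 references/species,
50 F1 replicates; 127 draws × 1000 replicates; 500 calibration replicates;
100 mtDNA hybrids at 600 bp) and deliberately small instances where only
correctness of the rules is at stake (oracle matrices of ~10×15, 5×5
grids, enumerable multinomials with ≤ 3 categories and ≤ 5 draws).
Tolerances: EM `tol = 1e-6`, frequency clamp `1e-4`, maternal margin
`0.01` subs/site, enumeration agreement `1e-9`, oracle equality `1e-12`.
Ties are deterministic everywhere: haplotypes by count then name, parent
pairs by ancestry then species name, nearest species by distance then
name.

## 9. Known limitations

* The encounter null is only as good as the abundance surfaces and the
  sympatry definition; at coarse grids the product-log combiner compresses
  genuine differences in overlap.
* The F1/backcross bands assume clean reference panels; introgressed
  references bias `q` toward the contaminating species.
* Maternal assignment assumes species-diagnostic mtDNA; recently diverged
  species pairs that share haplotypes (the reason mallard-like monochromes
  are excluded from such studies) will return ambiguity errors rather than
  assignments.
* The behavioural tests treat each F1 as independent; clutch-mates in a
  sample would overstate significance.
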