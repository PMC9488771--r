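# duckhybrids

Hybrids are rarer in wild ducks than folklore suggests — about 2 per 10,000
hunter-shot birds — yet waterfowl still hybridize more than any other avian
family, and the behaviour that generates those hybrids has been contested
for decades. `duckhybrids` implements, as a tested and reusable R pipeline,
the computational analysis used to attribute wild F1 hybrid ducks to their
parental species, mothers, and likely siring mechanism (interspecific forced
copulation versus mis-imprinting versus scarcity of conspecific mates):

* **Genotype QC** (`call_genotype()`, `filter_matrix()`) — ddRAD read-count
  genotype scoring (homozygous when >93% of reads support one haplotype,
  heterozygous when >29% support a second, or ≥20% with population support;
  <5 reads flagged) and two locus/individual filtering presets
  (`"wsu"`, `"cornell"`) with their exact rule ordering.
* **Supervised ancestry** (`estimate_allele_freqs()`,
  `supervised_admixture()`, `call_hybrid_class()`) — EM estimation of
  ancestry fractions `q` against fixed parental allele frequencies,
  maximising `Σ_l [g_l log p_l + (2−g_l) log(1−p_l)]` with
  `p_l = Σ_k q_k f_kl` on the simplex. The maximum assignment probability
  `max_k q_k` classifies hybrids: ≤ 0.64 → F1, ≤ 0.875 → F2 backcross,
  < 0.95 → later backcross, else parental.
* **Maternal ID** (`p_distance()`, `assign_maternal()`, `infer_sire()`) —
  mtDNA nearest-reference assignment of each hybrid's dam with an explicit
  ambiguity margin; the sire is the other member of the nuclear parent pair.
* **Encounter null model** (`compute_pair_weights()`,
  `simulate_expected()`, `standardized_effects()`) — expected hybrid-pair
  frequencies from breeding-season abundance overlap: pair weights combine
  log abundances over cells of sympatry, 127 hybrids are resampled 1000
  times from the weight vector, and standardized effect sizes
  `SES = (O − μ)/σ` outside ±1.645 mark combinations over- or
  under-represented relative to the 90% null interval.
* **Behavioural statistics** (`binomial_tail()`, `fisher_exact_2x2()`,
  `summarize_sire_tests()`, `build_complementarity()`, `harvest_rate()`,
  `predict_winter_phallus()`, `association_test()`) — exact one-sided
  binomial tests of whether the longer-phallus species sires F1s, Fisher
  tests of phallus/mass complementarity, the harvest rate, and the log-log
  winter-phallus regression (`y = 0.7836x + 0.3195` on the log10 scale).
* **Synthetic data** (`sim_config()`, `gen_*()`) — a generator for every
  input the pipeline consumes: overlapping circular range footprints with
  lognormal cell abundances, Balding–Nichols parental allele frequencies,
  pedigree-faithful F1/backcross genotypes, species-diagnostic mtDNA, and
  abundance-weighted hybrid samples, all with truth labels, so the whole
  analysis is testable without field data.

`run_pipeline()` composes the stages end to end, and
`inst/cli/duckhybrids.R` is a thin command-line front end
(`simulate`, `qc`, `ancestry`, `maternal`, `null-model`, `stats`, `run`).

## Worked example

```r
library(duckhybrids)

# Siring asymmetries: does the longer-phallus species sire the F1s?
res <- summarize_sire_tests(siring_asymmetry_table())
res$pooled
#>   group n_f1 sire_longer sire_shorter   binomial_p percent_longer
#> 1 large   59          45           14 3.265315e-05       76.27119
#> 2 small   21           8           13 9.053764e-01       38.09524

fisher_exact_2x2(complementarity_tables()$reduced)
#> [1] 0.0926458

tot <- harvest_survey_totals()
harvest_rate(tot$hybrids, tot$parentals)
#> [1] 1.91162

# End-to-end synthetic run with truth-label recovery
rep <- run_pipeline(sim_config(n_species = 4, n_loci = 600,
                               n_ref_per_species = 6, seed = 101),
                    n_hybrids = 40)
rep
#> duckhybrids pipeline report
#>   species: 4 | loci simulated: 600 | retained: 600
#>   hybrids: 40 simulated, 40 analysed, 0 flagged, 33 called F1
#>   recovery: F1 recall 1.000 | pair accuracy 1.000 | dam accuracy 1.000
#>   null model: 0 pairs over, 0 under, 6 combinations
```

Where asymmetries are large (≥ ~40 mm), 45 of 59 F1s (76%) were sired by
the longer-phallus species (exact one-sided p ≈ 3×10⁻⁵) — the signature of
interspecific forced copulation. When the asymmetry is small the signal
vanishes (8 of 21). The synthetic run shows the full pipeline recovering
simulated F1s, parent pairs, and dams from genotypes and mtDNA alone.

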