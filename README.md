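# jaycline

Geographic cline analysis of a mito-nuclear avian hybrid zone.

## The problem

When two long-diverged bird lineages meet again — as the coastal and
interior lineages of western scrub-jays do in a narrow belt east of the
Sierra Nevada — Haldane's rule predicts asymmetric introgression: hybrid
females (the heterogametic sex in birds) suffer reduced fertility, so
maternally inherited mtDNA should cross the contact zone less readily than
biparentally inherited nuclear markers. Along a one-dimensional transect
this appears as a **narrower geographic cline** in mtDNA haplotype
frequency than in nuclear admixture proportions.

`jaycline` implements the full analysis chain needed to test that
prediction, with every stage reproducible on synthetic data of known truth:

* **Synthetic contact zones** — transect sites, multiallelic microsatellite
  genotypes from two parental pools with controllable divergence,
  marker-specific mtDNA and nuclear clines, ancestry-linked phenotypes,
  diagnostic sequences; one seed drives everything.
* **mtDNA typing** — an in-silico analogue of a diagnostic restriction
  digest (`digest()`): two bands ⇒ coastal, one band ⇒ interior.
* **Genotype QC** — exact-conditional Hardy–Weinberg tests (Monte-Carlo
  and enumeration routes), G-statistic linkage-disequilibrium permutation
  tests, joint Bonferroni correction, locus retention rules.
* **Admixture** — a Gibbs sampler for the standard Bayesian admixture
  model yielding per-individual Q-scores, with label alignment and the
  successive K = 2 splitting strategy.
* **Cline fitting** — the sigmoid-with-exponential-tails cline family

  `f(x) = 1 / (1 + exp(-4 (x - c) / w))`,

  with tails `f(c-δ)·exp(θ(x-c+δ))`, `θ = (4τ/w)/(1+exp(-4δ/w))`, scaled
  into `[p_min, p_max]`; 15 models (3 scaling sets × 5 tail
  configurations) plus a null model, fitted by Metropolis–Hastings with a
  pilot-tuned proposal covariance, ranked by AICc, with
  two-log-likelihood support intervals and the reciprocal-CI significance
  rule for cross-dataset comparison.
* **Contact dating** — neutral diffusion, `w = 2.51 σ √t`, with both the
  literal solution and the variant that reproduces published year ranges.
* **Phenotype association** — correlation-matrix PCA and trait-on-Q
  regressions at nested spatial extents.

## Worked example

```r
library(jaycline)

cfg <- pipeline_config(seed = 5, out_dir = "runs",
                       fit_args = list(tuning_iters = 4000,
                                       chain_iters = 16000, n_chains = 2))
res <- run_pipeline(cfg)
print(res)
```

```
hybrid-zone pipeline report (seed 5, config 994cb63ba2024190f5f72fa10079a17b)
stages: simulate, type_mtdna, qc, admixture, cline_mt, cline_q, compare, dating, phenotype
mtDNA cline [set1_none]: width 176.302 (131.321 - 239.013) km, center 318.063 (294.358 - 342.284) km
nuclear cline [set1_none]: width 381.702 (292.257 - 522.587) km, center 302.391 (265.698 - 339.963) km
width comparison: mtDNA narrower than nuclear; reciprocal 2-LL non-overlap: significantly different
contact date mtDNA (formula): 197.346 - 2192.74 generations (~200 - 2200)
contact date nuclear (formula): 2569.55 - 92504 generations (~2600 - 93000); overlap: FALSE
QC: 13 loci retained, 0 dropped, 0 borderline
```

Reading it: the zone was simulated with a true mtDNA width of 131 km and a
true nuclear width of 331 km, both centered at 300 km. The pipeline typed
every individual's mtDNA from its sequence, inferred Q-scores from 13
microsatellite loci, fitted all 16 cline models to each marker class (the
plain unscaled sigmoid, `set1_none`, won both), and found the mtDNA cline
significantly narrower than the nuclear cline by the reciprocal
two-log-likelihood rule — the simulated Haldane's-rule signature,
recovered. Both true widths fall inside their support intervals. The
contact-date ranges use female dispersal (1.5–5 km) for mtDNA and the
male–female average (0.5–3 km) for nuclear markers and do not overlap.

The `analysis/` directory holds the same workflow as numbered scripts
(`01_simulate.R` … `07_phenotype.R`) writing their tables under
`results/`.

## Documentation

The methods vignette (`vignettes/hybrid-zone-clines.Rmd`) describes the
models, priors, numerical choices, generator assumptions and known
limitations in detail.
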