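---
title: "Geographic clines across a mito-nuclear hybrid zone: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geographic clines across a mito-nuclear hybrid zone: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`jaycline` analyses secondary contact between two divergent bird lineages —
think of the coastal and interior scrub-jay lineages that meet east of the
Sierra Nevada — along a one-dimensional transect. Because female birds are
the heterogametic sex, Haldane's rule predicts that maternally inherited
mtDNA should introgress less than biparentally inherited nuclear markers,
which appears as a *narrower* geographic cline for mtDNA haplotype
frequencies than for nuclear ancestry. The package provides every stage of
that test on data with known truth: a synthetic contact-zone generator, an
in-silico restriction-typing assay, genotype quality control, Bayesian
admixture (Q-score) inference, cline fitting with model selection, neutral
diffusion contact dating, and phenotype–ancestry regression.

## The cline model family

The expected frequency of the interior class at transect position $x$ is a
scaled sigmoid with optional exponential tails. The central shape is

$$f(x) = \frac{1}{1 + e^{-4 (x - c)/w}},$$

where $c$ is the **center** (the position where the unscaled cline crosses
one half) and $w$ the **width**, defined as the inverse of the maximum
slope. Left of $x = c - \delta_L$ the sigmoid hands over to an exponential
tail

$$f(x) = f(c-\delta_L)\, e^{\theta_L (x - c + \delta_L)}, \qquad
  \theta_L = \frac{4 \tau_L / w}{1 + e^{-4\delta_L/w}},$$

and symmetrically on the right. $\delta$ is the distance from the center at
which the tail takes over and $\tau \in [0,1]$ the ratio of the tail slope
to the sigmoid slope at the junction; the curve is continuous always and
continuously differentiable exactly when $\tau = 1$ (both properties are
tested). The observed frequency is $p(x) = p_{\min} + (p_{\max} -
p_{\min}) f(x)$.

Fifteen models arise from three scaling sets (set 1: $p_{\min}=0,
p_{\max}=1$; set 2: fixed at the observed extremes; set 3: free) crossed
with five tail configurations (none, left, right, mirrored, both), plus a
null model of no clinal transition whose single parameter has the
closed-form maximum-likelihood solution $\hat p = \sum k / \sum n$. Tails
are applied to the unscaled shape and scaling wraps the composite; the
alternative composition order (scale, then tails) is not distinguishable
from the data fitted here and was fixed once as a package convention.

Site data enter through a binomial likelihood: for mtDNA, $k$ interior
haplotypes of $n$ sampled; for nuclear data the site-mean Q-score is
converted to effective successes $k = \mathrm{round}(n \bar q)$ so that both
marker classes run through identical machinery (a Gaussian alternative
using the site variance of Q is available behind `cline_loglik()`'s
`q_likelihood` flag for sensitivity analysis). Expected frequencies
are clamped to $[10^{-9}, 1-10^{-9}]$ so structural zeros cannot produce
infinite deviance against mismatched observations.

## Fitting, model selection, and uncertainty

Each model is fitted by random-walk Metropolis sampling with flat priors on
box bounds derived from the transect: $c$ within half a span of the sampled
range, $w \in (0, 2\,\mathrm{span}]$, $\delta \in [0, \mathrm{span}]$,
$\tau, p_{\min}, p_{\max} \in [0,1]$ with $p_{\min} \le p_{\max}$ enforced
by rejection. A pilot run with independent proposals estimates the proposal
covariance, which is scaled by $2.38^2/d$ for the main phase of three
chains from overdispersed random starts. Inference pools the post-burn-in
draws; convergence is gated by split-$\hat R < 1.05$ and effective sample
size $> 200$ per parameter (a warning, not an error — exactly the judgment
call a trace plot supports). Desk-scale defaults are 10,000 pilot
iterations and 3 chains of 50,000 with 20% burn-in, which reproduce a
13-site transect fit in about a second; production-scale settings are plain
arguments.

The reported maximum likelihood is the best sampled draw refined by a
deterministic Nelder–Mead pass. The refinement matters for model
*selection*: without it, AICc differences between structurally identical
models (set 1 and set 2 coincide whenever the observed frequencies span 0
to 1) are pure sampler noise, and ranking becomes a coin flip. Ranked
tables treat AICc differences below 0.01 as ties, resolved toward the
earlier model set and simpler tail structure; additionally, when a simpler
model sits within 2 AICc units of the raw winner it is reported as the
parsimony-preferred model. AICc uses the number of *sites* as the sample
size — the likelihood has one binomial term per locality — with the usual
$-2\ell + 2k + 2k(k+1)/(n-k-1)$ form.

Parameter uncertainty is summarised by two-log-likelihood support
intervals: the range of a parameter over all pooled draws whose
log-likelihood is within 2 units of the maximum, an approximate 95%
interval under a quadratic likelihood (the Gaussian closed form
$\hat\theta \pm 2s$ is a test case). Two datasets differ significantly in a
parameter only under the *reciprocal* rule: each point estimate must fall
outside the other dataset's interval.

## Neutral-diffusion contact dating

With root-mean-square parent–offspring dispersal $\sigma$, a neutral cline
widens as $w = 2.51\,\sigma\sqrt{t}$. The package solves this for $t$ two
ways. The `formula` variant is the literal inversion $t = (w/2.51\sigma)^2$
and is the default for new analyses. The `paper_match` variant computes
$t = (w/\sigma)^2$; it exists because the year ranges printed in the source
analyses for widths of 131 and 331 km (roughly 690–7,600 and
12,000–440,000) are reproduced exactly, to two significant figures, by the
latter expression and not by the former — the two differ by the constant
$2.51^2 = 6.3001$, suspiciously close to a plausible generation time in
years, but the printed text does not say which interpretation was meant.
Both are exposed and the reproduction harness uses `paper_match`; units are
generations, conventionally read as years.

## The admixture model

Q-scores come from the standard Bayesian admixture model for multiallelic
genotypes: each allele copy carries a latent cluster of origin; per-cluster
allele frequencies have independent Dirichlet($\lambda$) priors
($\lambda = 1$); each individual's ancestry vector has a symmetric
Dirichlet($\alpha$) prior with $\alpha = 1$ fixed — deliberately simpler
than samplers that update $\alpha$ or correlate frequencies across
clusters. The correlated-frequency prior was left out because the quantity
every downstream stage consumes is the Q-score, and the independent model
is exactly specified and can be checked against closed-form oracles
(fully private alleles make maximum-likelihood assignment exact; F1
hybrids must sit at even ancestry by symmetry). The Gibbs sweep is compiled
code; desk-scale defaults are 5,000 burn-in plus 20,000 kept sweeps, with
the original production scale (100,000 + 500,000) available by
configuration.

Cluster labels are arbitrary, so multi-run comparisons go through
`align_labels()`, which permutes columns to minimise the summed absolute
difference to the first run. The recursive `successive_split()` strategy
runs K = 2 repeatedly: a node splits when at least half its individuals
have max-Q ≥ 0.8, the strongly assigned individuals partition by majority
ancestry, and admixed individuals are set aside rather than forced into a
child; nodes stop below 4 individuals. The stopping thresholds are
documented stand-ins for a judgment the original workflow made by
inspection ("no further clustering found").

One caveat worth stating: permuting the input order of individuals leaves
the posterior unchanged in distribution but not draw-for-draw, because all
latent updates consume one random stream; tests therefore check order
invariance at the level of posterior summaries, not bits.

## Genotype quality control

Hardy–Weinberg testing is exact-conditional: given the observed allele
pool, random mating makes every re-pairing of the $2n$ copies equally
likely, and the heterozygote count — ordered toward *deficit*, the
signature of null alleles and inbreeding-like artifacts — is the statistic.
The Monte-Carlo route (default 9,999 re-pairings, seed required) reports
$p = (1 + \#\{h_{perm} \le h_{obs}\})/(1 + B)$; for biallelic loci an
enumeration route evaluates the exact conditional (Levene) distribution
with no sampling error, and the two routes are tested against a
brute-force enumeration of every re-pairing at small $n$.

Because the statistic is discrete, the test is *conservative*: its
rejection rate under the null sits below the nominal level by about half
the probability mass of one lattice atom, which at field-typical sample
sizes (20–100 diploids) means roughly 0.03 at $\alpha = 0.05$. p-values
are super-uniform, never anti-conservative — the safe direction for
locus screening. The nominal level is approached only as information
grows; the package's calibration check therefore runs the enumeration
route at 10,000 diploids per biallelic locus, where the size reaches
0.045–0.05.

The Bonferroni family is *all* population-by-locus tests jointly (the
family choice is switchable); `flag_loci()` drops loci whose significant
failures occur in more than 5 populations — the threshold separating
"many" from "some" populations is a configuration default, since no
numeric rule was published — and reports borderline loci for sensitivity
reruns. Linkage disequilibrium between loci is a permutation test on the
G-statistic of the two-locus genotype contingency table, permuting one
locus across individuals; the G-statistic's many distinct values make this
test nearly exact despite discreteness. The QC report runs it *within*
populations and combines per-population p-values by Fisher's method,
because pooling individuals across a hybrid zone detects admixture LD —
ancestry correlation among unlinked loci, which is real and expected —
rather than the physical linkage the locus-retention decision cares
about.

## The synthetic contact zone

The generator imposes the study conditions directly rather than simulating
the evolutionary mechanisms that produce them — no forward-time dynamics,
no explicit hybrid-fertility selection, no sex-biased dispersal mechanics.
Marker-specific cline widths are inputs: by default a mtDNA cline of width
131 km and a nuclear cline of width 331 km, both centered at 300 km on a
600 km transect of 13 sites, with per-site sample sizes drawn uniformly
from 1–28 (the range of a realistic jay transect) unless fixed.

For an individual at position $x$: true ancestry is
$q \sim \mathrm{Beta}(m\nu, (1-m)\nu)$ with mean $m$ given by the nuclear
cline and concentration $\nu = 10$ — bounded in $[0,1]$, mean on the cline,
and with the within-site ancestry spread a real hybrid zone shows; no
empirical estimate of that spread was available, so $\nu$ is a free choice
exposed in the configuration, and $\nu = \infty$ (ancestry exactly equal to
the cline mean) supports oracle tests. Each of the two allele copies per
locus comes from the interior parental pool with probability $q$, else the
coastal pool. Parental pools are built per locus from a Dirichlet(1)
base vector by reallocating mass $d$ to disjoint halves of the allele set,
which makes the total-variation distance between the pools *exactly* the
configured divergence ($d = 1$ gives fully private alleles); the default
$d = 0.9$ represents strongly diverged lineages. The mtDNA class is a
Bernoulli draw from the mtDNA cline, phenotypes are linear in $q$ plus
Gaussian noise (plumage scores rounded into the ordinal 1–6 scale), and
one integer seed drives everything.

Sequences for the typing assay are generated so that coastal individuals
carry exactly one occurrence of the recognition motif across both strands
and interior individuals none. The motif defaults to `GCAATG` — the
recognition sequence of the BsrDI enzyme the assay emulates — but it is a
configurable default, not a biological claim about the real amplicon; the
published assay names only the enzyme.

What passing tests on this generator do **not** show: robustness to
null alleles and allele-size homoplasy in real microsatellites, to
spatially aggregated sampling, to cline-shape misfit (the generator draws
from the same sigmoid family the fitter assumes), or to admixture-model
misspecification such as correlated parental frequencies. Those belong to
analyses of real data.

Phenotype spatial extents mirror the nested design of the original
specimen series (everything ⊃ transect ⊃ core): the generator flags
individuals within 250 km of the nuclear center as "transect" and within
100 km as "core". Default effect sizes give the three plumage scores a
slope of −4 across the full ancestry range against a residual SD of 0.8,
and the six morphometric traits a slope of zero — so plumage tracks the
genome and morphology is environmental noise, the qualitative pattern the
regression stage is meant to detect inside the core zone.

## Numerical choices and problem sizes

* Proposal covariance: pilot second-half sample covariance, jittered by
  $10^{-8}\,(\mathrm{range})^2$ on the diagonal, scaled by $2.38^2/d$.
* Likelihood clamp $10^{-9}$; continuity at tail junctions verified to
  $10^{-12}$; C¹ at $\tau = 1$ checked by finite differences at $10^{-6}$
  relative tolerance.
* Transect projection uses the haversine great circle with Earth radius
  6371.0088 km; 1° of latitude is 111.19 km.
* Degenerate inputs have defined behaviour rather than errors where a
  convention exists: monomorphic loci give $p = 1$ with a flag, empty
  sites are excluded with a warning, ambiguous digest calls are excluded
  with a count.
* Test and reproduction problem sizes were chosen to exercise the
  statistics at desk scale: 13-site transects with 20 individuals per
  site for cline recovery (50 replicates), 20 model-selection replicates,
  10 end-to-end mito-nuclear runs, 5,000 null loci for the HWE
  calibration, and reduced MCMC settings (pilot 3,000–4,000; 2 chains of
  12,000–16,000) wherever a full production run would add nothing but
  wall-clock time. The vignette's and tests' statements about recovery
  rates are computed by the test suite itself, not quoted from elsewhere.

## Known limitations

* The q-mean binomial likelihood treats site-mean ancestry as $n$ binary
  trials; it inherits the right mean–variance scaling only approximately,
  which is why the Gaussian alternative exists.
* Two-log-likelihood intervals are read off sampled draws; with poorly
  mixing tail parameters the interval can under-cover until chains are
  lengthened (the ESS/R-hat gate warns).
* The admixture sampler fixes $\alpha$; strongly unbalanced admixture
  proportions would be better served by updating it.
* Ordinal plumage scores are regressed as numeric, exactly as the
  Table-1-style analysis implies; an ordinal-logit treatment is out of
  scope for v1.
* The in-silico digest counts non-overlapping motif occurrences and treats
  forward and reverse-complement hits at different positions as distinct
  sites; physically overlapping sites on opposite strands (possible for
  some motifs, not for BsrDI's) would be counted twice.
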