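---
title: "Methods: genomic divergence across geographic mosaics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genomic divergence across geographic mosaics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

divscape analyses genomic divergence among populations arranged in a
geographic mosaic: sets of demes on two host plants, some pairs in
direct contact ("adjacent"), most separated by kilometres of unsuitable
habitat, sequenced at very low per-individual coverage.  This vignette
is the package's methods record: the models, their assumptions, the
tunable parameters and their defaults, what the simulator emulates and
what it does not, and the numerical choices that an analyst would
otherwise have to reverse-engineer from the code.

## 1. The data layer

The observed data are per-individual, per-locus read counts at
biallelic SNPs: a total depth and a non-reference depth
(`read_count_matrix`).  Missing genotypes are represented as zero
coverage, not as a sentinel value: the Bayesian model below conditions
on reads, so "no reads" and "few reads" are the same situation in
different degrees.  VCF input uses the per-sample `AD`/`DP` fields;
multiallelic records are skipped (or rejected) because every model in
the package is written for two alleles.  Coordinates may be planar
kilometres or lon/lat degrees (haversine); at study extents of tens of
kilometres the choice is immaterial, but it must be explicit.
Adjacency is a categorical field observation supplied as a pair list —
it is never inferred from a distance threshold.

## 2. Allele frequencies with genotype uncertainty

At ~0.77x per-individual coverage most genotypes are not directly
observable, so genotypes and population allele frequencies are joint
parameters.  For individual $k$ with $n_k$ reads of which $a_k$ are
non-reference, the genotype likelihood is

$$L(g) = \mathrm{Binom}(a_k \mid n_k, e_g), \qquad
  e_0 = \epsilon,\; e_1 = \tfrac12,\; e_2 = 1 - \epsilon,$$

with sequencing error $\epsilon$ fixed (default 0.005; estimating it is
out of scope).  The prior links individuals through Hardy–Weinberg
proportions at the population frequency $p$, with $p \sim
\mathrm{Beta}(1,1)$.  A Gibbs sampler alternates genotype draws and the
conjugate Beta update $p \mid g \sim \mathrm{Beta}(1 + \sum g_k,\,
1 + 2N - \sum g_k)$; populations and loci are conditionally independent
and the implementation vectorizes across both.  Genotype posteriors are
Rao–Blackwellized averages of the conditional genotype probabilities
over retained iterations.  Defaults are 20,000 iterations thinned to
every fourth sample; burn-in (2,000) is a package default.  The
pipeline's scaled-down desk setting (2,000/500/thin 4) is documented in
the run log it writes.

Two consequences worth knowing: a locus with *no* reads in a population
returns the prior (posterior mean 0.5), and an uncovered individual
among covered ones gets the HWE proportions at the posterior frequency
— exactly at the posterior draws, approximately at the posterior mean
(the difference is Jensen's inequality; it is visible only when the
frequency itself is nearly unconstrained).

With 20 diploids the data contain at most 40 chromosomes of information
about $p$, so the posterior mean cannot beat binomial sampling noise of
$\sqrt{p(1-p)/40} \approx 0.07$; accuracy claims tighter than that are
not achievable at this design, while interval *calibration* (90%
credible intervals covering ~90% of the time) is, and is what the test
suite checks.

## 3. The pairwise hierarchical F-model

Differentiation between two populations is modelled per locus by the
F-model: population frequencies are Beta-distributed around an
ancestral frequency $\pi_i$,

$$p_{ij} \sim \mathrm{Beta}\!\big(\pi_i \tfrac{1-F_i}{F_i},\,
  (1-\pi_i)\tfrac{1-F_i}{F_i}\big), \qquad j \in \{1, 2\},$$

which has the defining moment $\mathrm{Var}(p_{ij}) = F_i\,
\pi_i(1-\pi_i)$.  The locus-specific $\alpha_i = \mathrm{logit}(F_i)$
is pooled across the genome through $\alpha_i \sim \mathcal{N}(\mu,
1/\tau)$ with diffuse hyperpriors $\mu \sim \mathcal{N}(0, 10)$, $\tau
\sim \mathrm{Gamma}(0.01, 0.01)$, and $\pi_i \sim \mathrm{U}(0,1)$.
Integrating the Beta over $p_{ij}$ gives a beta-binomial likelihood for
the population allele counts, so the sampler never represents $p_{ij}$
explicitly.

*Data interface.*  The default input is expected allele counts
$\mathrm{round}(\sum_k E[g_k])$ out of $2N$ chromosomes, taken from the
genotype posterior (`pair_allele_counts()`); a second mode pools raw
read counts per population (`pair_read_counts()`), treating reads as
draws of allele copies.  The two-stage coupling (frequency model, then
F-model) is an explicit approximation; a single joint chain would
propagate slightly more uncertainty.

*Sampling.*  Metropolis-within-Gibbs: vectorized random-walk updates of
$\alpha$ and $\mathrm{logit}(\pi)$ (per-locus proposal scales adapt
toward ~30% acceptance during burn-in and are frozen afterwards),
conjugate draws of $\mu$ and $\tau$, plus one joint rescale move of
$(\alpha - \mu, \tau)$ per iteration.  The rescale move matters: the
posterior has the classic hierarchical funnel geometry in which the
spread of $\alpha$ and $\tau$ move together, and without it $\tau$
mixes an order of magnitude more slowly.  $\alpha$ is initialized at
per-locus moment estimates of $F_{ST}$ so its spread is realistic from
the first iteration.

*Exclusions.*  Loci monomorphic in both populations carry no
information about $F_{ST}$ (it is undefined there) and are excluded
with a logged count.  This conditioning slightly tilts the likelihood
when many loci are near fixation; at the default study design the
effect is small compared with posterior spread.

*Outliers.*  The genome-wide distribution of $\alpha$ is the posterior
predictive $\int \mathcal{N}(\mu, 1/\tau)\, d\Pi(\mu, \tau)$,
approximated by drawing $K = 10$ values of $\alpha^\ast$ per retained
hyperparameter draw.  A locus is an outlier when its posterior median
$\alpha_i$ falls outside the $(1-q, q)$ quantiles of that pooled sample
(default $q = 0.95$, both tails flagged); the headline count is the
high tail.  Because the hierarchy shrinks locus estimates toward
$\mu$, the realized null flag rate sits well below the nominal $2(1-q)$
— that is a feature of the empirical-Bayes construction, verified by
simulation in the test suite.

*Shape summaries.*  Mean, variance, skewness $g_1 = m_3/m_2^{3/2}$ and
kurtosis of the per-locus $F_{ST}$ point estimates use central moments
with denominator $n$.  Kurtosis is reported both raw ($m_4/m_2^2$) and
as excess (raw − 3), labelled as such, since either convention is
common in genome-scan summaries.

## 4. Burrows' composite disequilibrium

For unphased dosages at two loci, $\hat\Delta = \frac{1}{2n}\sum_k
g_{Ak} g_{Bk} - 2\hat p_A \hat p_B$ — the genotype-based composite of
within- and between-locus disequilibrium that assumes neither phase nor
Hardy–Weinberg equilibrium.  It is a plain moment estimator (no
$n/(n-1)$ correction) computed per population, from posterior modal
genotypes (ties broken toward the heterozygote).  Its attainable
magnitude shrinks with minor-allele frequency, so surveys report both
signed and absolute means, stratified by whether the two loci share a
contig.  Exhaustive pair sets are quadratic; the survey subsamples a
seed-deterministic set of pairs (default 10^5) instead.

## 5. ABC model choice for gene flow

For each population pair two demographic models are compared under
rejection ABC with equal priors: (i) divergence without gene flow and
(ii) divergence with gene flow, in an isolation-with-migration
parameterization (divergence time $t$ in units of $2N$ generations,
migration as $4N_e m$, per-locus diversity shaped by $\theta$).

*Simulator.*  Each locus starts at an ancestral frequency from
$\mathrm{Beta}(\theta, \theta)$ (truncated to (0.01, 0.99)); the two
daughter frequencies then experience per-generation symmetric migration
$m = 4N_e m/(4 N_{sim})$ and binomial drift on a scaled grid of
$N_{sim}$ diploids for $t \cdot 2 N_{sim}$ generations, and $n$
chromosomes are sampled per population.  $N_{sim} = 50$ by default:
the diffusion scaling (time in $2N$ units, migration as $4Nm$) is
preserved while keeping a 10,000-row reference table affordable; the
grid coarseness adds drift-discretization noise that is small relative
to the rejection tolerance.  The inner loop is compiled (Rcpp) and uses
R's RNG, so runs are seed-reproducible.

*Summary statistics.*  Mean and SD of per-locus Hudson-type $F_{ST}$
(the mean as a ratio of averages, unbiased around zero divergence),
expected heterozygosity per population, the fraction of loci fixed for
alternative alleles, and the fraction polymorphic in exactly one
population.  Statistics are standardized by the reference pool's median
absolute deviation (falling back to the SD when the MAD degenerates,
e.g. for a mostly-zero fixation fraction), and the nearest
`tolerance_fraction` of simulations by Euclidean distance is accepted.

*Priors.*  $t \sim \mathrm{U}(0.05, 4)$, $\theta \sim \mathrm{U}(0.2,
2)$, and under the with-flow model $\log_{10}(4N_e m) \sim
\mathrm{U}(0, 2)$.  The lower bound of one migrant gene copy per
generation is a modelling decision, not a numerical convenience:
migration rates far below that are demographically indistinguishable
from isolation on the timescales modelled, and a with-flow prior that
piles mass on effectively-zero migration makes the model comparison
unanswerable by construction — the zero-flow posterior probability can
then never exceed ~0.7 no matter how informative the data.  With the
boundary at $4N_e m = 1$, "divergence with gene flow" means flow at a
level that shapes divergence, and the comparison is decidable.

*Reuse.*  The reference table depends only on the priors, never on the
observation, so one table serves many pairs (and many replicate
analyses); the per-pair cost is a distance computation.

*A caution on connected landscapes.*  The two-population model knows
nothing about stepping-stones.  On a connected mosaic, pairs beyond the
direct-migration cutoff still exchange genes through intermediate
demes, and the ABC correctly reports that effective flow; expecting
"zero gene flow" calls there is a misreading of the model.  Recently
separated pairs are similarly confounded with long-diverged pairs under
equilibrium migration.  What is robust on the default mosaic — and what
the acceptance suite asserts — is the direction: the zero-flow
posterior probability rises with distance and the migration estimate
falls.  The magnitude claim (probability above 0.9 under true
isolation) is tested where it is identifiable: on deeply diverged,
genuinely isolated pairs.

*Reported migration estimate.*  The per-pair `mig_estimate` in the
master table is model-averaged: the accepted-draw median of $4N_e m$
under the with-flow model times the with-flow posterior probability, so
it falls to zero as the zero-flow model takes over.

## 6. Matrix tests, ordination, clines, behavioural indices

*Mantel and partial Mantel.*  Pearson correlation of lower triangles;
the null permutes rows and columns of one matrix simultaneously.
P-values use $(1 + \#\{r^\ast \text{ at least as extreme}\})/(1 +
n_{perm})$, two-sided on $|r|$ by default with one-sided options (the
study's predictions are signed), so the discrete floor is
$1/(n_{perm}+1)$.  For $n \le 7$ an exact mode enumerates all $n!$
permutations.  The partial variant correlates residuals of both
matrices on the covariate triangle and permutes the residual structure
of one of them; when a triangle is numerically fully explained by the
covariate the partial correlation is 0 by convention.  Competing
permutation schemes exist for the partial test; residual permutation is
the package's declared choice.

*Genotype PCA.*  Principal components of the individuals × (loci ×
genotype-states) posterior-probability matrix, centred but not scaled
(the inputs are probabilities on a common scale).  Both a two-state
variant (P(het), P(hom alt) — two of the three states determine the
third) and a three-state variant are provided.  Components are made
sign-deterministic by forcing each component's largest-magnitude
loading positive.

*Clines.*  Per locus, ordinary least squares of population allele
frequencies on three standardized covariates (two climate axes and
longitude), with per-coefficient t-tests and partial residuals for
plotting.  Covariates are z-scored before fitting, so slopes are per
standard deviation of covariate.  Constant frequencies return zero
slopes with p = 1; rank-deficient designs are refused with the
collinear columns named.

*Behavioural indices.*  Sexual isolation is $1 - (\%\text{between} /
\%\text{within})$ mating, unclamped (negative values are meaningful).
Morph divergence is the signed percentage-point difference in striped
morph frequency between hosts.  Group comparisons use Student's
pooled-variance t-test by default (two groups of three population pairs
give d.f. = 4), with Welch available.

## 7. The landscape generator

The simulator provides ground truth with the statistical structure the
analysis assumes — it is the package's test bed, not a model of any
real genome.

Forward Wright–Fisher on allele frequencies, one locus at a time (free
recombination; the LD survey on its output should and does find mean
$\Delta \approx 0$).  Each generation: migration with the
distance-decaying kernel $m(d) = m_0 e^{-d/\delta}$ truncated to
exactly zero beyond a cutoff, then class-specific selection, then
binomial drift with $2N$ draws; sampled genotypes are
$\mathrm{Binom}(2, p)$.

Defaults emulate the target study design in structure, scaled down in
magnitude: 8 populations up to ~25 km apart with two contact zones,
alternating host classes, 20 individuals per deme, 2,000 loci,
0.77x per-individual coverage (per-population coverage per locus is
then ~15x, which is what makes population-level inference possible),
$N = 100$, 60 generations, $m_0 = 0.12$, $\delta = 3$ km, cutoff 12 km.
These values were chosen once so that the generated mosaic reproduces
the qualitative field pattern the methods are built for: adjacent-pair
mean $F_{ST}$ ~0.02 against separated-pair ~0.12, and gene flow
negligible beyond 10–15 km.

Locus classes and their rationale:

* **neutral** (94%) — drift and migration only.  The genome must be
  overwhelmingly neutral for outlier calling to make sense; with a
  large selected fraction the genome-wide hyperdistribution simply
  stretches to cover it and nothing is an outlier.
* **host_selected** (2%) — pushed up on one host and down on the other
  by $s_{host}\, p(1-p)$ ($s_{host} = 0.2$).  Between different-host
  pairs these diverge at any distance; within contact zones the push is
  mostly overwhelmed by migration, which is exactly the "subtle host
  effect" regime the analysis should detect.
* **adjacency_specific** (2%) — each contact zone maintains its *own*
  subset, pushed in opposite directions in the two members of that
  adjacent pair ($s_{adj} = 0.7$).  Divergence maintained against
  contact-zone gene flow requires selection stronger than the migration
  rate, hence the strong coefficient and the stronger effect-multiplier
  range below.  Zone-specific subsets are what restrict the resulting
  outliers to adjacent pairs; a shared set would also differentiate
  members of different contact zones from each other.
* **climate_clinal** (2%) — pulled by $s_{cl}\, z_{clim}\, p(1-p)$
  along the first climate axis ($s_{cl} = 0.12$), producing allele
  frequency clines and an outlier count that grows with distance.

Every selected locus draws an effect-size multiplier from
$\mathrm{U}(0.25, 1)$ ($\mathrm{U}(0.6, 1)$ for adjacency loci): loci
under selection of graded strength are what make the *number* of
detectable outliers respond smoothly to the selective contrast, rather
than switching between all and none.

Default covariates derive deterministically from the coordinates: the
first climate axis follows the main spatial gradient, the second adds
deterministic micro-relief variation so that the three cline covariates
are never collinear; real covariates are supplied as a table.

What the generator does not emulate: linkage and recombination maps (no
LD decay with physical distance — only a contig map for stratified
surveys), restriction-site dropout or PCR duplicates in the read model
(depth is plain Poisson), mutation after the ancestral draw, selfing or
population-size change, and any explicit behavioural mechanism of
reinforcement (adjacency loci are a phenomenological push, because the
targeted pattern — outliers restricted to contact-zone pairs — is
pattern-level).  Passing tests therefore show the inference stack
recovers truth under its own assumptions at realistic information
levels; they do not validate those assumptions for any particular
empirical dataset.

## 8. Pipeline, determinism, problem sizes

`run_pipeline()` executes simulate → freqs → divergence/ld/abc →
mantel/clines with per-stage seeds derived by hashing the global seed
with the stage name, so disabling one stage never shifts another's
random stream; reruns are bit-identical.  Outputs are tab-separated
with `#`-prefixed headers, stamped with a configuration hash; the run
log records every defaulted parameter actually used.  Figures
(`report_run()`): log–log outliers vs distance with adjacency coded,
per-pair logit-$F_{ST}$ histograms with the genome-wide predictive
density and its 95th-quantile line, and gene flow vs distance.

Desk-scale problem sizes used by the test-suite and the acceptance
script — the package's own choices for routine validation, all
overridable: 500–600 loci, 20 individuals per deme, allele-frequency
chains of 1,200–3,000 iterations, F-model chains of 2,000–4,000
iterations, ABC reference tables of 6,000–10,000 simulations at 500
loci.  At these sizes a full 28-pair analysis runs in a few minutes on
one core; the production-scale settings (20,000-iteration chains,
10^5 LD pairs) scale linearly.

## 9. Known limitations

* The frequency model and the F-model are run as two stages; the
  point-mass handoff (rounded expected counts) discards some genotype
  uncertainty relative to one joint chain.
* $\tau$ (the precision of logit-$F_{ST}$ across loci) is weakly
  identified from two populations of ~40 chromosomes; its posterior is
  broad and right-skewed.  Genome-level summaries ($\mu$) and outlier
  calls are robust to this; per-locus $F_{ST}$ intervals inherit it.
* The ABC compares exactly two demographic models per pair;
  stepping-stone connectivity, asymmetric migration and size changes
  are outside both.
* Burrows' $\Delta$ is computed from modal genotypes; at very low
  coverage the modal call is itself uncertain, which inflates
  within-population disequilibrium slightly.  (Whether to use posterior
  dosages instead is an open choice; the modal convention is declared.)
* Permutation p-values are sampled (except the exact small-$n$ Mantel
  mode) and carry the usual $1/(n_{perm}+1)$ floor.
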