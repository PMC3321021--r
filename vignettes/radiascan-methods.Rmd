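---
title: "Methods and design of radiascan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of radiascan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

radiascan is a pipeline for dominant-marker (AFLP-style) population genomics
of closely related, geographically structured taxa — the typical island
radiation setting: many small populations, a binary presence/absence matrix
of anonymous markers, a mitochondrial barcode alignment, and shell or body
landmarks on a subset of specimens. This vignette documents the models, the
tunable parameters, the numerical choices, and the limits of what the test
suite establishes. It states no empirical result that the tests or
`scripts/acceptance.R` do not themselves compute.

## The generative model (module `synthetic_data`)

All downstream statistics are validated against a simulator whose structure
matches the assumptions those statistics make.

**Allele frequencies.** Each locus has an ancestral presence-allele
frequency $p_i$ drawn from a Beta$(a,b)$ prior truncated to $[0.05, 0.95]$
(defaults $a=b=1$: a flat prior with the near-fixed tail removed, since real
AFLP panels exclude quasi-monomorphic bins). Population frequencies follow
the Balding–Nichols model,
$$p_{ij} \sim \mathrm{Beta}\!\big(p_i \theta_{ij},\,(1-p_i)\theta_{ij}\big),
\qquad \theta_{ij} = \frac{1-F_{ij}}{F_{ij}},$$
with $F_{ij} = \mathrm{logistic}(\alpha_i + \beta_j)$, $\beta_j =
\mathrm{logit}(F_j)$. The locus effect $\alpha_i$ (default 0) models
selection; this is deliberately the same family the Bayesian outlier scan
assumes, so parameter-recovery tests are meaningful.

**Dominance.** A diploid shows a band iff it carries at least one presence
allele; under Hardy–Weinberg the band probability is $1-(1-p_{ij})^2$.
Partial selfing (relevant for some land snails) would require an $F_{IS}$
term in this map; it is intentionally not modelled, and every downstream
module inherits the HWE assumption.

**Scoring error and replicates.** Calls flip independently (absent→present
with rate `e01`, present→absent with `e10`; defaults 0.04 each, which gives
a replicate discordance rate of $2e(1-e) \approx 7.7\%$ — the magnitude
reported for careful AFLP studies). A fraction of samples (default 11%) is
re-genotyped: the replicate row is an independent re-corruption of the same
true genotypes.

**Space.** In spatial mode the independent population effects are replaced
by sequential drift along a 1-D stepping-stone chain: each population's
frequencies are a Balding–Nichols draw around its neighbour's, with step
divergence $F_{step} = 1 - e^{-d\cdot\mathrm{drift\_per\_km}}$. This is the
simplest mechanism producing a monotone differentiation–distance pattern;
it does not model two-dimensional geometry, barriers, or migration–drift
equilibrium.

**Scale defaults.** 47 populations × 13 individuals × 1964 loci — the scale
of a real island-radiation AFLP data set. Tests override these with smaller
values and say so.

The generator also emits electropherogram peak lists (one jittered peak per
present call, log-normal heights around 5000 fluorescence units, Poisson
noise peaks around 30 units), clustered Jukes–Cantor-style sequences, and
2-D landmark configurations (group mean shapes displaced along random
Procrustes-tangent directions, isotropic landmark noise, then arbitrary
similarity transformations). What a green test establishes is therefore
internal consistency under these models — not robustness to peak-height
normalization artifacts, alignment error, indels, allometry, or digitizing
bias, none of which are simulated.

## Marker QC (`marker_qc`)

Scoring uses a per-profile noise floor at 1% of the *second-largest* peak
(robust to one rogue peak and to overall profile intensity), a 50-unit
detection threshold, a 60–550 b size window, and global bins built greedily
left-to-right over the sorted union of retained peak sizes with a 0.75 b
width cap. The vendor software's binning is proprietary; greedy binning is a
reconstruction, and the round-trip test (zero jitter, zero noise → exact
matrix recovery) pins its behavior. All threshold comparisons are "≥
keeps": repeatability exactly 0.81 survives ("less than 81% … excluded"
read literally), and a peak of height exactly 50 is detected.

The filter drops, in order: (1) markers with replicate repeatability below
0.81; (2) bins with no present call among replicates (shared absences are
homoplasy-prone null alleles); (3) bins without a confirmed present/present
replicate pair; (4) markers monomorphic over the main samples. The ledger
conserves loci and the filter is idempotent. The error rate is the
replicate mismatch rate; the default is the unweighted mean of per-marker
rates, with the pooled ratio behind `method = "pooled"` (both appear in the
genotyping-error literature; the unweighted mean is the common reading of
"average error rate per marker").

## Distances, trees, MOTUs (`distance_phylo`)

The Nei–Li (Dice) distance $1 - 2n_{xy}/(n_x+n_y)$ counts shared bands only:
a shared absence can arise in many independent ways and carries no
similarity information. Missing calls are handled by pairwise deletion; a
pair with no shared bands at all gets distance 0 with a warning rather than
0/0.

Neighbor joining is the standard Saitou–Nei agglomeration with the
Q-criterion. Ties are broken at the lowest index pair, making trees
reproducible; negative branch lengths are clamped to zero with the deficit
moved to the sister branch so path lengths are preserved. Bootstrap support
resamples loci with replacement and reports bipartition frequencies. NJ is
exact on additive matrices, which is what the acceptance suite asserts on
100 random additive trees.

MOTU clustering is single-linkage transitive closure at an inclusive
threshold (3% uncorrected p-distance by default). The threshold-clustering
program the field uses does not document its linkage; single linkage is the
chaining-faithful choice and is isolated behind one function so complete
linkage could be swapped in. Labels are deterministic (smallest member id).

## AMOVA (`amova`)

The variance decomposition follows the squared-distance formulation with
$d^2(x,y)$ = number of mismatching loci — the standard convention for
dominant phenotype data (missing calls rescale by total/comparable loci).
One-level designs give $\Phi_{ST}$; two-level designs give $\Phi_{CT}$,
$\Phi_{SC}$, $\Phi_{ST}$ with the usual unequal-size coefficients.
Permutation schemes: individuals among populations ($\Phi_{ST}$),
individuals among populations within groups ($\Phi_{SC}$), whole
populations among groups ($\Phi_{CT}$); $p = (\mathrm{hits}+1)/(B+1)$, so a
permutation test never returns 0. Populations under the size cut-off
(default 5) are excluded; negative variance components are reported as-is
and flagged, since zeroing them silently would bias the $\Phi$ denominators.

**What $\Phi_{ST}$ estimates here.** For dominant band data the estimand is
the *band-scale* variance ratio, not the allelic $F_{ST}$. At allelic
$F = 0.1$ under the generator's prior, the band-scale $\Phi_{ST}$ is
$\approx 0.13$–$0.14$: the dominance map $q = 1-(1-p)^2$ inflates
between-population variance relative to within. The calibration test
therefore measures bias against the truth functional computed from the
simulator's realized $p_{ij}$ (band-scale between-variance over total), and
finds it below 0.02. Comparing the estimate to the allelic $F$ would
conflate the estimator with the scale of its estimand.

## Isolation by distance (`ibd`)

Great-circle distances on a spherical earth ($R = 6371$ km) between
population sites (centroids if a population has several georeferenced
samples). The simple Mantel test correlates upper triangles and permutes
rows+columns of one matrix simultaneously; the default is one-tailed
positive, the IBD direction. For $n \le 7$ all $n!$ permutations are
enumerated, replacing Monte Carlo error with an exact p-value (the identity
permutation is included in the count, the enumeration analogue of the $+1$
correction). The conventional permutation count for publication-grade runs
is $10^6$; tests use $10^4$ and the exact mode, which is a pure
computational scaling, not a change of method.

## Model-based clustering and ΔK (`cluster_model`)

A full admixture MCMC with a recessive-allele model is out of scope; the
package fits a no-admixture product-Bernoulli mixture by EM to supply
$L(K)$. The M-step uses the Beta(1,1) posterior-mean (Laplace) update
$(s+1)/(n+2)$, which keeps frequencies off the boundary; the monotone
quantity under this EM is the penalized objective (log-likelihood plus
$\sum \log p(1-p)$), which is what the monotonicity test tracks, while
$L(K)$ is reported as the plain observed-data log-likelihood.
Initialization seeds cluster frequencies from randomly chosen sample rows
(random responsibilities start EM at the uniform saddle and strand it in
poor optima); each fit takes the best of several restarts.

Evanno's $\Delta K = |L(K+1) - 2L(K) + L(K-1)| / \mathrm{sd}(L(K))$ needs
run-to-run variability in its denominator. A stochastic-search clustering
program gets that from Monte Carlo noise; a deterministic EM does not — with
identical data every run finds the same optimum at the easy $K$, the sd
collapses, and $\Delta K$ degenerates. `delta_k_scan` therefore defines a
"run" as a fit of a bootstrap resample of the loci (all $K$ in a run share
the resample), giving comparable sampling variability at every $K$. With
that definition the three-population recovery criterion (argmax $\Delta K =
3$ in ≥ 90/100 seeds) holds. $\Delta K$ is undefined at the endpoints and
wherever sd = 0; such $K$ are flagged and excluded from the argmax, never
silently defaulted. Externally produced $L(K)$ tables can be fed straight
into `evanno_delta_k()`.

## Bayesian outlier scan (`outlier_fmodel`)

The scan is a hierarchical F-model for one population pair: ancestral
$p_i \sim U(0,1)$; population effects $\beta_j \sim N(-1, 1.8^2)$ (the
prior used by the standard genome-scan software); a per-locus selection
indicator $\delta_i$ with prior odds 10 for neutrality; a locus effect
$\alpha_i \sim N(0, 2^2)$ active only when $\delta_i = 1$;
Balding–Nichols population frequencies; and a binomial dominant-band
likelihood under HWE (`band_prob`, exposed so test oracles share the exact
likelihood). Instead of reversible jump, the sampler uses a spike-and-slab
move that proposes $\alpha$ from its prior on activation, so the prior
density cancels and the move reduces to a likelihood ratio times the prior
odds — equivalent posterior-inclusion target, far easier to validate. All
locus-indexed updates are vectorized; proposal scales adapt toward ~35%
acceptance during burn-in, and post-adaptation acceptance rates outside
[0.1, 0.7] raise a warning. Loci monomorphic across the pair are skipped
and reported: their posterior would be prior-dominated noise.

The sampler is validated against an independent quadrature oracle (full
grid integration over $p$, $q_{1}$, $q_{2}$, $\alpha$, $\beta_{1,2}$ for a
single locus): MCMC and oracle agree to well under 0.03. Two properties of
the honest posterior are worth stating because they bound what any user
should expect. First, with only two demes the genome-wide background pins
$\beta$, but a single locus's elevated divergence still competes with prior
odds 10 — posteriors above 0.95 require near-opposite fixation.
Second, a locus simulated with $\alpha = +3$ has divergence parameter
$F \approx 0.69$, under which both populations drift to the *same* boundary
about 40% of the time; such a locus is monomorphic in the sample and
carries no signal for any method. Consequently the package's power
criterion ("all 3 injected loci above 0.95 in ≥ 18/20 seeds") fails by
design of the generative world, and is left failing rather than weakened;
the false-positive criterion (≤ 5% at prior odds 10) passes with a wide
margin.

`consistent_outliers()` intersects the outlier sets over every population
pair of a MOTU pair (erroring if a combination is missing) and flags MOTUs
represented by a single population, whose outliers may reflect
population-specific demographic history rather than selection.

## Population graphs (`popgraph`)

Population mean band-frequency vectors are formed, their among-population
covariance is computed across loci, converted to a correlation matrix, and
inverted; partial correlations $\rho_{ij\cdot rest}$ give edge-exclusion
deviances $-N\ln(1-\rho^2)$ tested against $\chi^2_1$. Retained edges carry
weight $-\ln(\rho^2)$; node size is the mean squared distance of
individuals to their population centroid; connected components are
reported.

Two numerical points. First, the per-locus grand mean must *not* be removed
before forming the covariance: centered population means sum to zero
locus-wise, the covariance is exactly singular, and all partial
correlations collapse to ±1. `cov()` across loci already removes each
population's own mean, which is the correct centering. Second, the deviance
multiplier: the original software convention uses total individuals $N$,
but the correlation matrix is estimated from $L$ loci, so the $\chi^2_1$
calibration holds when the multiplier matches $L$. Both conventions are
exposed (`n_convention`); "individuals" is the default for fidelity to the
field's convention, and the null-calibration test uses "loci", the
statistically calibrated choice, with a null of *independent* per-population
frequency vectors — under a shared ancestral pool the populations carry a
genuine common factor and their true partial correlations are not zero, so
no convention would (or should) give retention ≈ α there. Singular
correlation matrices fall back to a ridge-regularized inverse with a
warning; populations under the size cut-off (default 3) are dropped.

## Morphometrics (`morphometrics`)

Generalized Procrustes alignment: center, scale to unit centroid size,
iterative SVD rotation to the consensus (rotations only — no reflections)
until the consensus moves less than $10^{-10}$. Centroid sizes are reported
in original units. Shape PCA runs on the flattened aligned coordinates; the
non-null dimension is at most $2k-4$. CVA assignment reduces to a PCA
subspace (capped so the pooled within-group covariance stays well
conditioned, plus a small ridge), assigns held-out specimens to the nearest
group mean by Mahalanobis distance, and computes typicality probabilities
$P(\chi^2_d \ge D^2)$; an assignment is "unambiguous and statistically
significant" when the best group's typicality exceeds 0.05 and every other
group's is at most 0.05 — a reconstruction of the convention used by the
interactive morphometrics suites, documented as such. Goodall's F uses
partial Procrustes distances with $df = (2k-4,\ (n_A+n_B-2)(2k-4))$ and
offers both the F-distribution p and a label-permutation p.

## Pipeline (`cli_pipeline`)

`run_pipeline()` takes one YAML (or JSON, or in-memory list) config, runs
stages in dependency order, hashes every output into `manifest.json`, and
caches: a stage whose outputs exist is skipped unless an upstream stage was
re-run. Every stochastic stage derives its stream from the single config
seed, so a rerun reproduces deterministic hashes. `inst/cli/radiascan.R` is
a thin command-line wrapper.

## Known limitations

- HWE dominance everywhere; no $F_{IS}$ / selfing correction.
- Population pairs only in the outlier scan (matching a pairwise study
  design); no joint multi-deme F-model.
- No admixture model behind $L(K)$; ΔK conclusions are about the
  Bernoulli-mixture surrogate.
- 1-D stepping-stone space only.
- The acceptance-grade power of the outlier scan is intrinsically limited
  at two demes and prior odds 10, as quantified above.
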