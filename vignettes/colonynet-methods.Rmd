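---
title: "Methods: social network position as the hub of worker physiology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: social network position as the hub of worker physiology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`colonynet` implements an end-to-end analysis of how an ant worker's position
in the colony social network relates to its behavior, physical environment,
age, brain gene expression and gut microbiota. This vignette explains the
models and procedures, the tunable parameters and their defaults, what the
synthetic colony generator does and does not emulate, and the numerical
choices made where the design was genuinely open.

## Social maturity from soft community detection

Carpenter-ant colonies contain two overlapping social communities: one of
workers that tend the queen and brood (nurses) and one of workers that leave
the nest to forage. A worker's position between these communities — its
*social maturity* — is a number in $[0, 1]$.

`facetnet_decompose()` factorizes the colony's weighted interaction matrix
$W$ (internally normalized to total sum 1) as

$$W \approx X \Lambda X^\top,$$

where the $k$ columns of $X \ge 0$ each sum to 1 and the community weights
$\Lambda = \mathrm{diag}(\lambda)$ sum to 1, by minimizing the generalized
Kullback–Leibler divergence $D(W \,\|\, X \Lambda X^\top)$ with multiplicative
updates. The soft membership of worker $i$ in community $c$ is
$M_{ic} \propto x_{ic} \lambda_c$, with rows summing to 1. With $k = 2$
(fixed throughout, as appropriate for nurse/forager colonies),
`orient_social_maturity()` labels as "forager" the community whose membership
correlates best with the fraction of time spent in the foraging arena, and
social maturity is the forager-community membership. The orientation makes
the output invariant to the arbitrary column order of the factorization; an
exact correlation tie is broken toward the community whose top-decile members
forage most, and logged.

Numerical choices: updates are sequential ($X$ then $\lambda$), each
non-increasing in the objective, and the objective trace is exported so tests
can assert monotonicity at every iteration. A guard of $10^{-12}$ inside
ratios avoids division by zero; it is a numerical guard, not model content.
Defaults `n_restarts = 10`, `tol = 1e-9`, `max_iter = 2000` converge well on
colony-sized ($n \approx 100$) problems. Workers with zero network strength
cannot be placed and receive uniform membership $1/k$, flagged as isolated
(normally they are removed earlier by the detection filter).

**Accuracy at sparse degree.** On the direct two-community generator
(`simulate_interaction_network()`, $w_{ij} \sim \mathrm{Poisson}(\lambda
[m_i m_j + (1 - m_i)(1 - m_j) + \varepsilon])$) with $n = 100$ and mean
weighted degree 20, recovery of the latent $m$ by the factorization sits at
the information limit: the test suite compares it against a direct
constrained maximum-likelihood fit of the generating model and finds the two
essentially indistinguishable. At that degree an appreciable share of random
draws yields Pearson $r$ just below 0.9 for *any* estimator, so recovery
summaries should be read as distributions, not thresholds. Denser networks
(real deployments record days of video) recover correspondingly better.

## Interaction inference from tag detections

`detect_interactions()` models each ant's head as a disk of radius
`head_radius` centred `head_offset` ahead of the tag along the body axis, and
its body as a disk at the tag centre. Defaults scale from a 10 mm body
length: head offset 0.4 L, head radius 0.2 L, body radius 0.35 L — the
published analyses annotate per-ant region shapes, but no geometry is
published, so these are declared package defaults. Two workers are in
contact in a frame when their head disks intersect (`mode = "head_head"`), or
additionally when either head intersects the other's body
(`mode = "head_or_body"`, which roughly triples pairwise counts on synthetic
colonies and serves as a false-positive sensitivity analysis).

An *interaction* is a maximal run of contact frames; runs separated by at
most `gap_bridge` non-contact frames are merged (default 0 — no bridging —
because the bout-merging rule used upstream of published counts is not
stated). `weighting = "frames"` counts contact frames instead of bouts. The
two conventions differ in one subtle way: widening the contact definition can
*merge* two bouts into one, so only frame weighting is guaranteed to be
entrywise monotone in the contact definition; bout counts on synthetic
colonies agree with the monotone bound for >99% of pairs and correlate with
frame counts almost perfectly.

## Space use, detection filtering, behaviors

`spatial_fidelity()` bins detections into an equilateral grid of flat-top
hexagons whose internal (across-flats) diameter defaults to the mean body
length, anchored at the origin. Points map to cells by axial-coordinate cube
rounding with the standard largest-residual correction, which assigns each
point to its nearest cell centre (tests verify this against an exhaustive
nearest-centre search; exact cell-edge ties are resolved by the rounding rule
and checked for distance-optimality).

`filter_low_detection()` drops workers detected in fewer frames than the
colony mean minus `k_sd` (default 2) sample standard deviations, computed
within colony. `foraging_fraction()` is arena frames over detected frames,
using half-open point-in-rectangle zone tests (`assign_zone()`).
`normalize_behaviors()` rescales each behavior to $[0, 1]$ within colony;
constant columns map to 0 rather than NaN so PCA input stays finite.

## Layers, dimension reduction and the R² network

Five layers share the same workers: social (interaction counts), behavior,
expression, microbiota and physical environment (pairwise Euclidean profile
distances). `upper_quartile_edges()` keeps pairs strictly above the 75th
percentile of off-diagonal weights (strictly below the 25th percentile for
distance layers, since distance is a dissimilarity); percentiles use linear
interpolation of order statistics (R type 7). `build_multiplex()` assembles
the edge sets plus identity interlayer couplings.

Per-layer scores: social maturity for the social layer; PCA scores for the
others (`reduce_layer()`), sign-oriented to correlate nonnegatively with
foraging. PCA preprocessing is declared per layer: behavior uses the
within-colony normalized profiles; expression is size-factor normalized,
$\log_2(x + 1)$, gene-centred; microbiota uses relative abundances after
excluding the obligate endosymbiont (*Blochmannia*-like, present in every
worker and dominating the community — workers left with all-zero profiles are
retained and flagged so layer worker sets stay aligned); physical uses
row-proportion hexagon occupancy. For the correlation analysis PCAs are per
colony; for prediction, pooled — following the published convention for
behavior, generalized to all layers.

Expression needs one extra step: the leading PC of brain expression is
typically dominated by RNA-extraction batches. `select_expression_pc()`
reports, per component, the $R^2$ against batch (one-way fit) and the best
$R^2$ against the biological variables, and recommends the smallest component
whose biological $R^2$ exceeds its batch $R^2$ (PC1 with a warning if none
qualifies; a single batch counts as batch $R^2 = 0$).

`interlayer_r2_network()` computes, within each colony, squared Pearson
correlations between the six per-worker variables (five layer scores plus
age), averages the colony matrices, and reports each variable's strength
(sum of incident edge weights); the maximum-strength variable is the *hub*.
Constant variables yield 0 entries with a warning.

`random_intercept_fit()` relates two scores with a colony random intercept
(maximum likelihood via lme4). Because no $R^2$ definition is published for
this regression, the package defines it as the squared correlation between
the fixed-effect fitted values and the response (marginal-style) and says so
in its output; $t$ is the Wald statistic of the slope.

## Differential expression engine

`nb_wald_test()` fits, per gene, a log-link negative-binomial regression
with `offset(log sf)`, colony indicators, an optional control covariate and
the covariate of interest, holding the gene's dispersion fixed, and tests the
covariate coefficient with a Wald z-test; `bh_adjust()` applies
Benjamini–Hochberg step-up correction across genes, and genes are called at
adjusted $p < 0.05$. Genes with fewer than 100 reads across all samples are
removed first (`filter_low_count_genes()`). Covariates are continuous, used
as-is.

This is a deliberately simplified engine relative to full empirical-Bayes
frameworks: size factors are median-of-ratios (`size_factors()`, rescaled to
geometric mean 1, with a $\ge$ 90%-nonzero fallback reference set);
dispersions are per-gene method-of-moments estimates on normalized counts,
floored at $10^{-8}$ and shrunk on the log scale (weight 0.5) toward a
non-increasing mean–dispersion trend fitted by isotonic regression
(`estimate_dispersions()`); there is no independent filtering and no
fold-change shrinkage. The simplifications are calibration-testable: under a
simulated global null the raw-$p$ rejection rate at 0.05 stays near nominal
and the BH-significant fraction stays at or below 0.05, and planted
fold changes are recovered without material bias. The suite also
cross-checks coefficients and calls against an independent reference
implementation on a small fixture. Non-convergent genes are flagged and
conservatively assigned $p = 1$.

`de_accounting()` reproduces the controlled-DE bookkeeping: for each
variable, the number of DE genes alone, and the percentage of those that
remain DE when controlling for each other variable. "Remain" is implemented
as the intersection of the uncontrolled set with the controlled-model set;
because the alternative reading (controlled significance regardless of
uncontrolled status) is also defensible, the controlled-set sizes are
emitted alongside. Controlling a variable for itself is blocked by a
collinearity guard and reported as missing, and percentages are also given
as fractions of all tested genes.

## Prediction from brain expression

`iterate_prediction()` follows the published protocol: features are the
genes differentially expressed by the target (all samples, colony +
target model, BH $< 0.05$); at each of 100 seeded iterations workers are
split in half (stratified by colony, which the published protocol does not
state but which keeps colony terms estimable), a linear
$\varepsilon$-insensitive support-vector regression (cost 1,
$\varepsilon$ = 0.1) is trained on z-scored log-normalized features using
training-half statistics, and the squared Pearson correlation between
predicted and observed values on the held-out half is recorded. Selecting
features on all samples leaks information across the split; the protocol is
reproduced verbatim for fidelity, and `strict_cv = TRUE` re-selects features
inside each training half for leakage-free estimates.
`compare_r2_distributions()` compares two variables' per-iteration $R^2$
distributions with Welch's t-test.

## The synthetic colony generator

`simulate_colony()` generates the study conditions the analysis assumes: 4
colonies of 100 known-age workers, a latent maturity $m \sim
\mathrm{Beta}(0.5, 0.5)$ (the simplest two-parameter bimodal family,
matching the U-shaped score distributions of real colonies), age as a linear
— hence rank-preserving — transform of a noisy copy of $m$ calibrated to
$r(\mathrm{age}, m) = 0.7$ (the strength implied by published
maturity–age regressions), and six behaviors whose logistic rates depend on
$m$ plus a shared per-worker "personality" deviation, so the behavior
profile is informative but imperfect; foraging noise is calibrated to
$r(\mathrm{foraging}, m) \approx 0.75$, the moderate coupling real colonies
show.

Expression counts are negative-binomial, $\mathrm{mean} = s_w q_g
2^{\beta_g m_w + B_{g,\mathrm{batch}(w)}}$, with 200 of 2000 genes
responding at one $\log_2$ unit per unit maturity (balanced up/down so depth
normalization stays unconfounded), dispersion 0.3, and a rank-1 gene-specific
batch structure that dominates the leading expression PC the way extraction
batches do in practice; genes respond to a noisy copy of $m$ (sd 0.2,
individual biological variation). The 2000-gene scale is a desk-scale
choice — real brain transcriptomes are an order of magnitude larger — sized
so the full accounting and prediction analyses run in minutes. The
microbiota is Dirichlet-multinomial over 79 ASVs with one obligate
endosymbiont at a mean share of 0.8 exactly by construction, and 8 minor
taxa whose weights scale as $e^{2.5 (m - 0.5)}$ against a noisy copy of $m$
(sd 0.35) — emulating taxa present in foragers but rare in nurses, and the
overall weakness of microbiota as a correlate.

Trajectories are Ornstein–Uhlenbeck walks in the two-chamber geometry
(nest and arena 170 × 123 mm, 19 mm tube). Each worker's arena occupancy
follows a two-state Markov chain with stationary probability equal to its
foraging tendency. Inside the nest, workers track one of two aggregation
sites (brood pile vs pre-foraging area) interpolated by maturity; the sites'
separation axis rotates slowly around the nest centre, so same-community
workers stay near each other (sharply assortative head-overlap contacts)
while each worker's time-averaged occupancy map is nearly centred — the
social network deliberately carries more membership information than the
marginal spatial distribution, as it does in real colonies where interaction
partners are chosen, not just collided with. A 10% per-frame miss rate
leaves `present = FALSE` detections. The default 1000 frames per colony is a
desk-scale choice; the package's own tests run at this size.

Not emulated: queens and brood as agents, tag id-swaps, colony demography
over time, raw video, and real amplicon processing. Passing tests on this
generator therefore certify the pipeline's logic and calibration — recovery
of planted structure, controlled-DE asymmetry, hub identification — not the
effect sizes of any real colony.

## Problem sizes and runtime

The test suite exercises: soft-community oracles at 6–20 nodes, recovery at
$n = 100$ over 10 seeds, DE calibration at 2000 genes × 100–200 workers with
20 permutations, controlled-DE asymmetry and prediction ranking over 10
replicate datasets (400 workers, ~2000 genes each), and the full pipeline
hub analysis over 10 master seeds. These sizes were chosen so the whole
suite completes in well under half an hour on a single core.

## Known limitations

- Bout merging across detection gaps is configurable but defaults to none;
  real tracking systems lose tags for stretches, and the right `gap_bridge`
  depends on the frame rate.
- The NB engine's plug-in dispersions make Wald tests mildly anticonservative
  at small $n$; the calibration tests bound this at the sizes used.
- The mixed-model $R^2$ is one of several possible definitions; compare only
  like with like.
- Feature selection on all samples (the published protocol) inflates
  prediction $R^2$; use `strict_cv = TRUE` when absolute accuracy matters.
- At sparse network degree the maturity score's accuracy is information
  limited (see above), a property of the data, not the estimator.
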