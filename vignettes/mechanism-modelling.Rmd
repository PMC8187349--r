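---
title: "Modelling drug mechanism of action on signed protein networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling drug mechanism of action on signed protein networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moanet)
```

## The modelling problem

A disease phenotype such as heart failure with preserved ejection fraction
can be characterised molecularly by a set of protein *effectors*, each
pathologically active (`v = +1`) or inactive (`v = -1`), grouped into named
*pathophysiological motifs* (oxidative stress, systemic inflammation,
myocardial extracellular-matrix remodelling, and so on). A drug such as an
SGLT2 inhibitor is characterised by its direct protein *targets*, each with
a modulation sign. The question `moanet` answers in silico is: if the drug
clamps its targets, how does the perturbation travel through the signed
protein-interaction network, which effectors does it push to the sign
*opposite* their pathological one, and through which intermediate cascade?

The package works entirely on user-supplied (or synthetically generated)
signed networks and profiles; it does no database retrieval and no
identifier mapping. Protein names are opaque case-sensitive strings.

## Signal propagation model

A *solution model* assigns every edge `i -> j` a weight `w_ij` whose sign is
fixed by the curated interaction type (activation `+1`, inhibition `-1`)
and whose magnitude lies in `(0, 1]`. Given clamp values on the drug
targets, node states follow the damped synchronous update

$$s_j \leftarrow (1-\lambda)\, s_j + \lambda \tanh\!\Big(\sum_{i \to j} w_{ij} s_i + b_j\Big),$$

starting from the all-zero state, with clamped nodes held fixed at every
iteration. The saturating `tanh` keeps every state inside `[-1, 1]`, so a
state is directly interpretable as a signed activity level. Iteration stops
when the largest per-node change drops below `tau` (default `1e-6`) or
after `max_iter` (default 200) sweeps; on feed-forward (acyclic) networks
the fixed point equals a one-pass topological evaluation, which the test
suite checks against an independent oracle. Cyclic networks with gain may
fail to converge; such runs are returned with `converged = FALSE` and their
last damped state, and downstream scoring treats them as valid but
flaggable. Damping `lambda = 0.5` is the default because it stabilises
feedback loops without changing fixed points.

Two modelling choices deserve emphasis because the underlying methodology
literature leaves them open. First, drug targets are *clamped* at their
modulation sign for the whole simulation rather than merely initialised;
this is recorded here as this package's convention, not asserted as the
original systems' behaviour. Second, the initial state is all-zero --- no
prior pathway activity --- so disease semantics live entirely in the
pathological signs `v`, matching the reversal framing of the intensity
statistic below.

## Training against expression-derived restrictions

A *restriction set* lists proteins with required output signs, typically
the up/down directions of genes differentially expressed between patient
and control cohorts. A model's *accuracy* is the fraction of restrictions
whose simulated sign under the drug matches the required sign; states with
`|y| < eps` (default `1e-3`) count as unsatisfied, because a silent node
achieves no direction. The same `eps` dead-band is shared with the
intensity statistic for consistency.

Weight magnitudes are fitted by simulated annealing: single-weight
proposals rescale one magnitude by `exp(U(-0.5, 0.5))` (clipped to
`(0, 1]`, signs never touched), accepted by the Metropolis rule on the
objective `1 - accuracy`, cooling geometrically from `T0 = 1` by factor
`gamma = 0.95` with 50 proposals per temperature down to `1e-3`. These
defaults are sized for desk-scale networks of up to a few hundred nodes;
the best-ever model is tracked, so the reported objective trace is
monotone. Because a single fit is underdetermined --- many weight
assignments satisfy the same sign restrictions --- the package trains an
*ensemble* of independent fits with per-run seeds derived from one global
seed, and reports the mean and dispersion of accuracy. All solutions are
kept; no "plausibility" cut is applied, since any admission threshold
would be arbitrary, but a minimum-accuracy filter can be applied by the
caller on the tidied ensemble.

## Intensity of response

With `v_i` the pathological sign of effector `i` and `y_i` its simulated
activity under the drug, the number of effectors achieving the expected
(opposite) signal is

$$\#\mathrm{Eff} = \sum_{i=1}^{n} \delta\!\left(\frac{v_i}{|v_i|} + \frac{y_i}{|y_i|}\right),$$

with `delta(0) = 1` and zero otherwise: the delta fires exactly when the
unit signs cancel. The printed form divides by `|y_i|`, which is undefined
at zero; the package completes it conservatively by counting effectors
with `|y_i| < eps` as *not* achieving the signal. Intensity is reported as
`100 * #Eff / n` overall and per motif, and ensemble results average the
percentage over solutions. Per-target contributions are computed by
ablating the drug to a single target and re-simulating every solution ---
an in-silico answer to "which target carries the effect". The analogous
benchmarking table evaluates several drug profiles on the same disease
model; by default one ensemble is trained per drug against the shared
restriction set, because accuracy is defined relative to a drug's clamps
and a single ensemble would be ill-defined across drugs with different
targets. Callers holding cached ensembles can supply a factory function
instead.

One caution: published tables of this kind are produced by proprietary
supervised systems on curated inputs. This package reports the mechanistic
reversal intensity and, separately, a network-proximity percentile; it
does not claim to reproduce any published table values, whose inputs are
not available.

## Network proximity score

The proximity of two protein sets is the mean, over set A, of the shortest
undirected path length to the nearest member of set B. Unreachable pairs
are scored as network diameter plus one, so disconnection is penalised
finitely. Significance is assessed against a degree-preserving null:
nodes are relabelled within `log2`-degree bins (1000 draws by default,
seeded), and the score is the percentage of null draws at least as distant
as the observed value, so 100 means maximally close. With zero null draws
the raw distance is returned with an undefined score.

## Mechanism-of-action subnetwork

"Most probable mechanism" is operationalised as ensemble agreement. An
edge is *supported* by a solution when its weight magnitude is at least
`w_min` (default 0.1) and it lies on some directed target-to-effector path
whose edges are all active in that solution; support is the fraction of
supporting solutions. For each target--effector pair the package
enumerates simple paths up to 8 hops (a cap that bounds enumeration),
scores each path by the product of its edge supports, keeps the `k_paths`
best (default 3; ties broken by shorter path, then lexicographic node
order), and prunes edges below `min_support` (default 0.5). Raising
`min_support` can only shrink the subnetwork. Retained nodes are tagged
target / intermediate / effector, and exports are offered as SIF with a
TSV attribute sidecar (lossless round trip), GraphML and DOT. Edges whose
sign disagrees across solutions cannot occur here --- signs are fixed by
the network --- but the support statistic quantifies how consistently an
edge participates in the mechanism.

## Expression-derived restrictions

The differential-expression protocol mirrors standard two-cohort array
analysis: per gene, both cohorts are screened with the Lilliefors
normality test at `alpha = 0.05`; if both pass, a two-sided Welch t-test
is used, otherwise the Wilcoxon rank-sum test. Raw p-values are corrected
by Benjamini--Hochberg across all genes and significance is called at
FDR < 0.05. The normality screen is stated in the source protocol for
group sizes strictly between 4 and 20; this package also applies it at
`n >= 20` (the test's critical values extend there) and routes `n <= 4`
directly to Wilcoxon, where normality cannot be usefully assessed. Welch's
variant is the default because equal variances are never guaranteed;
direction is the sign of the case-minus-control mean difference, with no
fold-change threshold since the protocol imposes none. Values are tested
as given and are assumed to be on a roughly symmetric (e.g. log) scale;
the package does not transform them. Genes constant in both cohorts get
p = 1 with a warning. Significant genes become restriction entries with
provenance `derived-from-expression`.

## Clinical bioflag deltas

The clinical readout is the percent *delta change* of an analyte's cohort
mean between baseline and follow-up, rounded half-away-from-zero to the
integer percent. The delta of means is the primary quantity --- it is what
published mean +/- SD pairs allow one to recompute exactly --- and the mean
of per-patient percent changes is carried as a secondary column. Patients
missing either timepoint are excluded pairwise per analyte with a reported
count; out-of-range measurements are flagged against the declared assay
range but never silently dropped. SEM is SD/sqrt(n); for a singleton
cohort the summary SD is reported as 0 rather than undefined. No paired
test is computed because per-patient source data are generally
unavailable at this level of reporting.

## The synthetic study generator

Because curated disease profiles and patient-level data are not
redistributable, every pipeline stage is exercised on synthetic scenarios
with known ground truth:

* **Network** (`sim_network`): preferential-attachment growth, 50 nodes,
  mean out-degree 2, 30% inhibitory edges by default. Edges point from
  older to newer nodes, so the graph is acyclic, hub-out-degree nodes
  emerge early (natural drug targets) and late nodes are sinks (natural
  effectors); every node is reachable from the source layer.
* **Scenario** (`sim_scenario`): a planted true model with weight
  magnitudes uniform on [0.2, 1] (comfortably above the `eps` dead-band),
  3 inhibited targets picked among the highest-out-degree nodes, 10
  effectors among reachable low-out-degree nodes with decisive planted
  activity (|y| >= 0.05), 5 motifs assigned uniformly at random (no motif
  structure is claimed), pathological signs set so the planted drug
  reverses exactly a fraction rho = 0.6 of effectors, and restrictions
  equal to the planted drug-on signs of all decisive non-target nodes with
  a 5% sign-flip noise rate.
* **Expression** (`sim_expression`): 500 Gaussian genes, 10% truly
  shifted by 2 within-group SDs, cohorts of 10 vs 10 --- a size and effect
  regime typical of the public array cohorts this emulates.
* **Bioflags** (`sim_bioflags`): 20 paired patients by default (a small
  prospective cohort), baselines lognormal around each assay's geometric
  midrange with multiplicative CV 0.3 (matching the dispersion of
  published mean +/- SD pairs), follow-up equal to baseline times
  `(1 + decline/100)` times mean-one lognormal noise, with planted
  declines of -14%, -6% and -17% for the three default analytes.

What passing tests on these scenarios show is that the machinery is
correct and well calibrated *under its own generative assumptions*:
exact recovery of planted reversal fractions, restriction-consistent
training, controlled false discovery, unbiased delta recovery. What they
do not show is performance on real interactomes, whose topology is richer
than preferential attachment, whose expression data are correlated across
genes and batches, and whose motif structure is biologically curated
rather than random.

## Problem sizes and determinism

The test suite and the acceptance script run ensembles of 20--25 solutions
on 50-node scenarios, 10--20 seeded replicates for ranking and null-control
checks, and 1000 null draws for proximity --- sizes chosen so the full
pipeline demonstrates its statistical behaviour in minutes on one core
while leaving every property measurable. Production analyses simply raise
`n_models` (a published-analysis-scale ensemble of 250 is the natural
setting) and the null-draw count. Every stochastic entry point takes an
explicit seed and derives per-run seeds deterministically from it;
regenerating any bundle or ensemble with the same seed is byte-identical,
which the suite asserts.

## Known limitations

* The transfer function, clamping convention and annealing proposal are
  reasoned defaults for sign-interpretable continuous propagation, not a
  reconstruction of any proprietary system.
* Accuracy counts restriction signs only; it carries no likelihood, so
  ensemble "support" is agreement, not posterior probability.
* Genetic-algorithm and dimensionality-reduction samplers mentioned in the
  surrounding literature are out of scope; simulated annealing is the one
  implemented sampler.
* The proximity null preserves degree only within log2 bins; very sparse
  degree classes make the null conservative.
* Published efficacy tables for specific drugs rest on unavailable curated
  inputs and are therefore out of reach of any reimplementation; all
  quantitative claims here are about synthetic scenarios with known truth.
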