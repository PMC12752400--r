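---
title: "Methods: cross-cohort knowledge distillation for SNP-based risk prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-cohort knowledge distillation for SNP-based risk prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`gwaskd` studies a concrete failure mode of genotype-based risk models:
a classifier trained on one case/control cohort degrades on another cohort
whose allele frequencies and effect architecture differ. The package
implements the full mitigation pipeline — cross-cohort feature selection, a
Wide-Deep neural teacher, knowledge distillation into a compact student,
teacher-feature reuse by tree ensembles, and Shapley-value attribution —
together with a synthetic multi-cohort generator so that every stage is
testable without access to restricted human genotype data. This vignette
records the modelling choices, their defaults, and their limits.

## The synthetic multi-cohort generator

`simulate_cohorts()` draws, for SNP $j$, a base minor-allele frequency
$f_j \sim U(a, b)$ (default $a = 0.05$, $b = 0.5$) shared by all cohorts,
then perturbs it per cohort $c$ by $\delta_{cj} \sim N(0, \sigma^2)$ and
clips to $[0.01, 0.99]$. Dosages are $g_{ij} \sim \mathrm{Binomial}(2,
f_{cj})$, independent across SNPs — deliberately free of linkage
disequilibrium (see *Limitations*). The disease liability is

$$\ell_i = \sum_{j \in \mathcal{C}} m_{cj}\,\beta_j\, g_{ij}
          + \sum_{(a,b,\gamma)} \gamma\, g_{ia} g_{ib} + c_0,$$

with $\mathcal{C}$ the causal set, $\beta_j$ per-allele log-odds effects,
$m_{cj}$ an optional cohort-by-SNP effect multiplier, and dosage-product
interaction terms for the configured epistatic pairs. The multiplier matrix
is how shared versus cohort-private causal architecture is planted: a zero
entry silences that SNP's effect in that cohort, mimicking effects that are
real in one study population and absent in another.

Labels follow a logistic liability model rather than a hard threshold, so
penetrance is probabilistic as in real case/control data. The intercept
$c_0$ is solved by bisection so that the *expected* case fraction matches
the request to $10^{-6}$. Because a raw Bernoulli draw would still miss the
requested count by $O(\sqrt n)$, the draw is conditioned onto the total:
with $u_i \sim U(0,1)$, the $m = \mathrm{round}(\pi n)$ samples with the
largest $\sigma(\ell_i) - u_i$ become cases. This is the Bernoulli draw
with only its most marginal outcomes flipped, and it guarantees realised
case counts within one sample of the request — which downstream stratified
splitting and balancing tests rely on. Missing genotypes are masked
uniformly at the configured rate. Everything is bit-reproducible from the
seed.

Default cohort sizes (1462, 534, 1386, 240, 1310) and case fractions
(0.57–0.70) mirror the magnitudes of typical clinical Alzheimer's
genotyping cohorts; the default 2000-SNP panel is a desk-scale stand-in
for a post-QC array. The default frequency-shift scale
$\sigma = 0.05$ is a package choice: published cohorts are not
characterised precisely enough to calibrate it, so transfer experiments
treat $\sigma$ as an explicit knob (0.1 in the bundled fixtures).

**What the generator does not emulate:** linkage disequilibrium and haplotype
block structure, ancestry admixture and principal-component stratification,
genotyping-platform batch effects, imputation-quality heterogeneity, and
X-chromosome dosage rules. Passing tests therefore demonstrate that the
pipeline behaves correctly under controlled frequency and effect shift —
not that it overcomes every source of real-world cohort divergence.

## Feature selection

Three per-SNP scores are provided, all invariant to sample order:

- `association_test()` — the additive (Cochran–Armitage) trend test on the
  2×3 genotype table, the standard single-variant GWAS scan. The variance
  of the score statistic is the exact multivariate-hypergeometric one
  (denominator $N-1$); base R's `prop.trend.test` uses the $N$ convention,
  and the test suite pins down the known $N/(N-1)$ ratio between the two.
  Zero-variance SNPs get $p = 1$.
- `f_score()` — the one-way ANOVA F statistic, between-class over
  within-class variance of dosage. This is the *feature-selection* F-score,
  not the F1 classification metric. Perfectly separating SNPs (zero within,
  nonzero between variance) would be infinite; they are mapped to the
  maximum finite score plus one so ranking remains well defined.
- `mutual_information()` — the plug-in discrete MI (nats) between the
  3-level dosage and the label. Dosages are ordinal with three levels, so
  no continuous-MI estimator is warranted; real-valued imputed dosages are
  binned to the nearest genotype class.

`select_common_top()` operationalises "consistently top-ranked in every
cohort": intersect the per-cohort top-$m$ lists, rank survivors by mean
per-cohort dense rank, keep the best $k$ with lexicographic rsID
tie-breaks. The literature describing this style of selection reports only
the endpoint (a 75-SNP panel), not $m$ or the aggregation rule, so both are
explicit arguments; an intersection smaller than $k$ is returned in full
with a flagged shortfall rather than padded.

## The Wide-Deep model

The wide path is $y_\text{wide} = w^\top [x, \phi(x)] + b$ with $\phi(x)$
the dosage products of configured SNP pairs; by default the pairs are all
$\binom{10}{2} = 45$ combinations of the ten top-F-score SNPs
(`top_fscore_pairs()`), bounding the width while pairing signal-bearing
variants. The deep path embeds each scalar dosage as a learned affine
token $x_j E_j + B_j \in \mathbb{R}^d$ (one SNP = one token), optionally
applies multi-head scaled dot-product self-attention
$\mathrm{softmax}(QK^\top/\sqrt{d_k})V$ with concatenated heads projected
by $W_O$, average-pools over tokens, and applies dense layers. The fused
affine map over $[a^{(L)}, y_\text{wide}]$ produces one logit $z$; the
class-logit pair is fixed as $(0, z)$ so that the temperature-1 softmax
equals $\sigma(z)$ exactly — the identity that couples the sigmoid output
convention to the class-softmax used in distillation, and one the test
suite asserts.

Defaults: teacher embed 16, 4 heads ($d_k = 4$), hidden 128–64; student
embed 8, 1 head, one 32-wide hidden layer (`build_student()` verifies the
student is *strictly* smaller in parameter count at construction).
Weights are Glorot-uniform, biases zero, all from the seed. The default
activation is GELU: in repeated small-network fits the last ReLU hidden
layer occasionally died entirely (all-zero activations for every input),
which silently destroys feature extraction; GELU's smooth tail removes that
failure mode at equal accuracy, and ReLU remains available.

Training is minibatch Adam (default rate 0.01, batch 64) with early
stopping on validation loss (patience 10) and best-weight restoration. The
entire backward pass — including attention, the token embeddings and the
cross-product wide path — is analytic and is verified against central
finite differences to $10^{-6}$ in the test suite; that check is the
load-bearing guarantee for everything trained downstream.

`extract_features()` defaults to the `"fused"` penultimate representation
$[a^{(L)}, y_\text{wide}]$. The deep activations alone discard the wide
path's share of the learned signal — empirically a large share on additive
genetic architectures — so handing downstream classifiers anything less
than the full pre-logit vector handicaps them for no reason. Named layers
(`pooled`, `hidden1`…) remain selectable.

## Knowledge distillation

`train_student()` minimises
$\alpha\, L_\text{CE} + (1-\alpha)\, L_\text{distill}$, where
$L_\text{CE}$ is hard-label cross-entropy of the student's temperature-1
distribution and $L_\text{distill}$ is the cross-entropy of the student's
temperature-$T$ distribution under the teacher's temperature-$T$
distribution. No $T^2$ gradient-rescaling factor is applied to the
distillation term: the stated objective is implemented as written, and
users accustomed to the classic rescaling should fold it into $\alpha$.
The student trains on the *target* cohort's training partition with
teacher logits computed in inference mode — the reading consistent with
evaluating a source-trained teacher against a target-adapted student;
same-cohort distillation is simply a matter of passing the same cohort.

$\alpha$ is tuned on validation macro-F1 (the tie-break prefers the
smaller $\alpha$, i.e. more distillation). Inside `run_scenario()` a
distillation config carrying a grid triggers 5-fold cross-validated
selection on the target training partition; the bundled fixtures use the
coarse grid $\{0.2, 0.8\}$ spanning the hard-label-dominant and
distillation-dominant regimes at tractable cost. Temperature defaults to
4; neither value is claimed to be optimal for any particular dataset.

## Preprocessing and evaluation protocol

Class balancing is the two-stage scheme: oversample the minority with
replacement up to $\rho \times$ the majority count (default $\rho = 0.8$,
a package choice — the two stages are standard but no ratio is canonical),
then undersample the majority to match. Every output row is a copy of an
input row, and originals are never dropped from the minority. Balancing
applies to training partitions only by default; `balance_eval` reproduces
balanced-evaluation variants. Mean imputation fits its per-SNP means on
the training partition and applies them to the test partition — a
statistical-hygiene choice, not a published protocol.
The nearest-neighbour imputer measures Euclidean distance over mutually
observed SNPs rescaled to the full dimension, so pairs sharing few SNPs
are not spuriously close.

`run_scenario()` executes one of the four transfer shapes end to end:
pool sources, 80/20 stratified split, impute, balance, train the teacher
(early-stopped on the source test split), split the target, distil the
student on the target training partition, extract fused teacher features,
fit `rf`/`dt`/`gb`/`xgboost` on source-train features, and evaluate all
six models on the held-out target test split. Whether published
cross-cohort metrics are computed on a held-out target split or the full
target cohort is ambiguous in the surrounding literature; the default here
is the held-out split (no overlap with anything fitted), with
`eval_full_target` for the other reading. A leakage audit accumulates the
sample identifiers of every fitting input — including imputation
statistics and balancing — and asserts the target test identifiers are
absent; `run_scenario()` fails rather than return silently leaky results.

Metrics: accuracy at threshold 0.5, macro-averaged precision/recall/F1
(on balanced test sets macro averaging makes accuracy, precision, recall
and F1 nearly coincide, matching how such results are usually tabulated),
specificity TN/(TN+FP), and AUC by the rank statistic with half credit for
ties. Every scalar metric is recomputable from the stored confusion
matrix, which the tests verify. `gb` and `xgboost` are both gradient
boosted trees with deliberately different hyperparameters (depth 3 / rate
0.1 versus depth 6 / rate 0.3), single-threaded for determinism.

## Shapley attribution

`attribute_student()` implements permutation-sampling Shapley values with
antithetic pairs: per drawn background row and permutation, features are
switched from background to explained values one at a time, marginal
probability changes are accredited, and the reversed permutation is
evaluated alongside. Local accuracy — attributions plus the mean sampled
background prediction equal $f(x)$ — holds *exactly* by telescoping, so a
null player (a SNP the network provably ignores) receives exactly zero.
Attribution explains the probability output, not the logit, because the
quantity of interest is impact on the model's output. The per-row random
draws are seeded from the row's content rather than its position, making
summaries invariant to the order of the explain set. A KernelSHAP-style
weighted-regression estimator (`method = "kernel"`) is provided as an
alternative, with the local-accuracy constraint eliminated exactly in the
solve. Estimator choice can reorder near-tied SNPs; ranks are comparable
only within one estimator. The default background is 100 seeded samples
from the target training split.

`cross_cohort_presence()` aggregates per-cohort top-$k$ lists into a
presence table (which cohorts rank each SNP top-$k$, and its best rank) —
the transferability view of attribution.

## Study conditions used by the bundled tests and acceptance script

Problem sizes were fixed once, as the package's desk-scale study design:

- *Cross-cohort recovery*: 5 cohorts × 2000 samples, 2000 SNPs, 10 shared
  causal SNPs at $\beta = 1$, shift 0.05; top-50 intersection, panel of 10.
- *Distillation transfer*: 2 cohorts × 600 samples, 75 SNPs, shift 0.1,
  12 causal SNPs of which 6 shared, 3 source-private, 3 target-private
  ($\beta = 1$); small networks (embed 4, 1 head, hidden 16–8), 15 epochs,
  $\alpha \in \{0.2, 0.8\}$. The private-effect architecture is what makes
  naive transfer genuinely lossy; with fully shared effects a source model
  transfers almost unimpaired and there is nothing for distillation to fix.
- *Feature transfer*: teacher trained on a 1500-sample source with dense
  polygenic signal (20 causal at $\beta = 0.5$) plus ten dosage-product
  interactions ($\gamma = 0.5$) over 200 SNPs; trees then fit on only 150
  labelled target samples, raw versus teacher features. Scarce downstream
  labels are where representation transfer earns its keep — with abundant
  labels, forests on raw dosages are already excellent tabular learners and
  learned features add little. Attention is disabled in this fixture; the
  mechanism under test is feature extraction, and the attention-free path
  is fully vectorised.
- The null-signal calibration uses $\beta = 0$ throughout and expects
  held-out AUC near 0.5 — the no-leakage canary.

## Numerical choices

Softmax uses max-subtraction; logarithms in the losses are clamped at
$10^{-12}$; the intercept bisection runs to $10^{-6}$ on the expected case
fraction; shifted allele frequencies are clipped to $[0.01, 0.99]$; dense
ranks (1 = best) break ties lexicographically by rsID wherever a
deterministic order is needed. All sub-seeds are derived from the master
seed and stay below $2^{31}$.

## Limitations

Simulated cohorts lack LD, ancestry structure and platform artefacts, so
results here bound what the pipeline can do under idealised shift only.
The networks are intentionally small; no claim is made that they are
competitive with tuned gradient boosting on raw tabular genotypes — the
package's own transfer experiments reproduce the usual finding that tree
ensembles dominate on modest tabular data unless label scarcity or domain
shift favours transferred representations. Shapley estimates are Monte
Carlo: with the default permutation budget, near-tied SNPs can swap ranks
between seeds even though local accuracy is exact.
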