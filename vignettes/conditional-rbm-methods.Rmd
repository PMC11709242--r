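---
title: "Methods: a conditional RBM for diet and exercise recommendation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a conditional RBM for diet and exercise recommendation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietrbm)
```

## The problem

Diabetic patients benefit from diet plans that match both their food
preferences and their nutritional needs. `dietrbm` implements a two-stage
system: a conventional ensemble classifier screens pathology reports for
diabetes, and a collaborative-filtering model predicts which foods a
screened-positive patient would rate highly, which is then intersected with
the patient's nutrient deficits, a price window, and an activity plan.

The preference model is an energy-based latent-variable model chosen for
sparse binary rating data: a restricted Boltzmann machine whose hidden
layer receives two additional *conditioning* inputs summarising the
social context of each item.

## Model

Four layers: visible ratings $V \in \{0,1\}^{n}$ over food items, hidden
features $H \in \{0,1\}^{F}$, and two context layers of the same length as
$V$ — similarity $S$ and popularity $P$. The joint energy is

$$E(V,S,P,H) = -\sum_i b_i V_i - \sum_i c_i S_i - \sum_i d_i P_i
              - \sum_j a_j H_j - \sum_{ij} V_i R_{ij} H_j
              - \sum_{ij} S_i \mathit{Sw}_{ij} H_j
              - \sum_{ij} P_i \mathit{Tw}_{ij} H_j,$$

with $\Pr(\text{config}) = e^{-E}/Z$ and $Z$ the sum of $e^{-E}$ over all
joint configurations. Because the graph is bipartite between $H$ and
$(V,S,P)$, all conditionals factorize into per-unit sigmoids; these are the
identities `exact_distribution()` verifies by enumeration for every model
with at most 16 total units, and they are the package's central
correctness property (checked to $10^{-10}$ against the enumerated
conditionals, with normalization to $10^{-12}$).

### Context scores

* $S(u,i)$ — the fraction of user $u$'s *neighbourhood* that rated item
  $i$ positively. The neighbourhood is defined as the other members of
  $u$'s training group: group co-membership is the model's only grouping
  construct, so it is the natural (and only self-consistent) choice of
  neighbour set. Singleton groups yield an all-zero similarity row.
* $P(i)$ — the positive-rating fraction of item $i$ over the whole
  training split, scaled by $1/r_{\max}$. For binary ratings
  $r_{\max} = 1$. The reference set is all training users; a per-user
  reference would make "popularity" redundant with similarity.

Both scores live in $[0,1]$ and enter the hidden pre-activation as clamped,
real-valued inputs. They are *conditioned on, not modelled*: during
training and prediction the chain never resamples them. Their
reconstruction conditionals (sigmoids with biases $c$, $d$) exist in the
code because the exact enumeration oracle and the unclamped Gibbs sampler
need the full joint model; they are exercised by the sampler-validity
tests, not by training.

### Training

Contrastive divergence with $k$ Gibbs steps (default $k=1$). For one data
case: clamp $V$ (observed items only), $S$, $P$; take hidden
*probabilities* for the data statistic and a hidden *sample* to start the
chain; alternate sampled visible reconstructions (masked to the case's
observed items) with hidden updates; the update is

$$\Delta R_{ij} = \varepsilon\left(\langle V_i H_j\rangle_{\text{data}}
  - \langle V_i H_j\rangle_{k}\right)$$

and analogously for $\mathit{Sw}$, $\mathit{Tw}$ (where the clamped
context multiplies the difference of hidden statistics) and the $a$, $b$
biases. Items unobserved in a case contribute to no delta, and the clamped
context biases receive zero deltas. At $k=50$, averaged over 1,000 chains,
the update direction sign-matches the exact conditional log-likelihood
gradient on ≥ 95 % of coordinates (tested on an enumerable model).

**Update granularity.** An epoch is a sequential pass of *per-case*
updates: each user contributes one CD update, applied immediately at the
full learning rate. The alternative — accumulating a whole group's
statistics into one averaged update per epoch — was measured during
development to be far too coarse: it yields exactly one effective
$\varepsilon$-step per epoch, and at $\varepsilon = 0.05$ within 200
epochs the model never leaves its initialization regime (held-out RMSE
stuck near 0.45 on the benchmark below). Per-case updates also make the
expected step size independent of group size, which is the practical point
of gradient/group-size normalization: no group dominates because it is
large, because no update is ever a group sum.

**Grouping.** Users who rated overlapping item sets are grouped greedily:
seed with the unassigned user holding the most ratings, absorb users whose
rated-item Jaccard overlap with the group's item union is at least
`min_overlap` (default 0.2, a permissive threshold under 30 % observation
density), single deterministic pass, smallest-index tie-breaks. Each group
trains only the weight-matrix rows of its own item subset against a shared
global store, sequentially per epoch, so later groups see earlier groups'
updates; items rated by nobody keep their initial parameters. The grouping
principle (shared tasted items) is fixed; the specific greedy pass is this
package's choice, made for determinism and $O(\text{users} \times
\text{groups})$ cost.

### Prediction and evaluation

Prediction is a mean-field pass (no sampling): hidden probabilities
$\bar H$ from the user's observed ratings and context, then
$P(V_q=1) = \sigma(b_q + \sum_j \bar H_j R_{qj})$. Note the visible bias
$b_q$ appears here; the parameter store is unified so that the rating
weight matrix and biases used in the energy, the conditionals and the
prediction rule are one set of arrays.

Reported model error is held-out RMSE: per-user, 20 % of observed entries
are masked from training (every user keeps at least one training entry)
and $\sqrt{\tfrac1N \sum (Y_i - \hat Y_i)^2}$ is computed on the masked
entries. Held-out rather than training RMSE is the defensible reading of
"testing" error for a recommender. The trainer records both per epoch
(`curves.csv`) and tracks the held-out optimum (`best_params`,
`best_epoch`), which is what "trained to convergence" reports.

## Tunable parameters

| Parameter | Default | Units / range | Rationale |
|---|---|---|---|
| `hidden_units` | 100 | 1–200 | capacity window within which the model is operated; 100 is the headline configuration |
| `learning_rate` | 0.05 | per-update step | 0.05 with an informative start (log-odds visible biases or a pretrained checkpoint); 0.01 for cold starts and the ablated model |
| `epochs` | 50 | passes | learning curves are read at epoch 50; up to 200 for convergence runs |
| `cd_k` | 1 | Gibbs steps | CD-1 is the standard estimator; larger k only sharpens the gradient approximation |
| `activation` | sigmoid | — | sigmoid everywhere probabilities are needed; `relu` optionally rectifies hidden pre-activations for data statistics and prediction, never for sampling |
| `min_overlap` | 0.2 | Jaccard | permissive grouping under sparse observation |
| `test_fraction` | 0.2 | per-user | conventional 80/20 holdout |

Initialization: weights $\mathcal N(0, 0.01^2)$; hidden biases 0; visible
biases at the log-odds of each item's observed rating mean clipped to
$\pm 4$ (items with no observations get 0). The log-odds start makes the
epoch-0 model predict marginal popularity, a standard RBM trick that
removes the burden of learning item base rates.

## The synthetic benchmark

No public deposit of the original rating study exists, so the package
ships generators that plant the structure the model assumes:

* `generate_ratings()` — users in `n_groups` groups; each group has a
  Bernoulli(0.5) binary item-preference prototype; an observed rating is
  the prototype XOR Bernoulli(`flip_noise`); the observation mask is
  i.i.d. Bernoulli(`obs_density`). Defaults (500 users, 200 items, 5
  groups, density 0.3, noise 0.05) scale the original study's shape down
  to a size where the full acceptance suite runs in about two minutes on
  one CPU; the planted structure is recoverable (k-means on raw rating
  rows reaches adjusted Rand > 0.9), so the benchmark has learnable
  signal, and the 5 % flip noise puts the Bayes-optimal held-out RMSE at
  $\sqrt{0.05 \times 0.95} \approx 0.218$ — a known floor to read results
  against.
* `generate_food_tables()` — log-uniform prices, log-normal nutrient
  amounts, each nutrient present in ≥ 10 % of foods; with six nutrients
  the six classic compositional elements (Potassium, Calcium, Fiber,
  Protein, Fat, Iron) are used as names.
* `generate_patients()` — two multivariate-normal classes on 7
  unit-variance pathology features, means `separation` SDs apart on each
  feature, class ratio 1:2 diabetic:non-diabetic.

What the benchmark does *not* emulate: real marginal distributions of
foods and ratings, correlated observation masks (people rate what they
eat), graded rating scales, covariate shift between cohorts, and any
clinical validity of the feature–nutrient relationship. Passing the
synthetic benchmarks demonstrates that the machinery learns the structure
it assumes, not that the recommendations are clinically sound.

One consequence worth stating: because the generator's observation mask is
independent of group membership, rated-item *sets* carry no group signal,
and Jaccard grouping typically finds one dominant group plus outliers. The
planted structure lives in rating *values* and is learned by the RBM
itself; the similarity layer in this regime is close to a popularity
signal. A mask correlated with preferences would make the grouping stage
informative as well; the code supports it, the generator deliberately does
not conflate the two.

## Recommendation rules

* Deficit: reference daily intake for the patient's sex and age band
  (bands $[\text{min}, \text{max})$, non-overlapping per sex) minus
  estimated current intake (0 without a diary), floored at 0. The shipped
  reference table is **synthetic and non-clinical** (round numbers of
  plausible magnitude); any real deployment must supply its own
  `rda.yaml`-style table.
* Filters: price inside `[lo, hi]`; the food must contain at least one
  positive-deficit nutrient.
* Bins: `round(100 * p)` mapped to 100 / 90–99 / 80–89 / 70–79; below 70
  the food is dropped. Rounding (rather than truncation) is used so that
  "90 to 99 percent" reads as the nearest-percent band; R's round-half-even
  resolves exact .5 boundaries deterministically.
* Ordering: probability descending; ties re-ordered by the one-hot
  preference flags (price flags order by price, rating flags by the
  supplied popularity score); final tie-break food id ascending. The
  display list caps the 100 % bin at ten items.
* Exercise: greedy kcal fill, highest kcal/min first, ≤ 60 min per
  activity, minutes rounded up, shortfall flagged when every activity is
  capped. The mechanism is deliberately simple plumbing — no source
  specifies one — and the catalog is a convenience fixture.
* Empty candidate sets return structured drop counts
  (`price_filter`, `no_deficit_coverage`, `below_70`), never an error: in
  a pipeline, "nothing clears the filters" is a reportable outcome.

## Degenerate inputs and numerical choices

* `exact_distribution()` refuses models above 16 total units rather than
  silently truncating; energies are max-shifted before exponentiation.
* `sigmoid()` saturates without under/overflow warnings; probabilities
  used in log-odds are clipped to $[10^{-6}, 1-10^{-6}]$.
* Single-class truth makes precision/recall/specificity `NA` with a
  warning, never a silent 0. Single-class *training* cohorts are an error.
* Classification ties at probability 0.5 label diabetic: a screening
  stage prefers sensitivity over specificity.
* Duplicate rating rows resolve last-write-wins with a warning; users
  with zero observations are rejected at construction.
* All stochastic components (generators, initialization, chains, splits,
  classifier fits) are driven by explicit integer seeds; two runs with
  the same configuration produce byte-identical artifacts, which the
  pipeline tests assert.

## Known limitations

* The intake side of the deficit computation defaults to zero — without a
  food diary the "deficit" is simply the reference intake.
* Patients and rating users are distinct identifier spaces; the pipeline
  links them round-robin, which is explicitly synthetic plumbing.
* The similarity/popularity layers are clamped conditioning inputs; the
  model does not learn to *generate* context, and the context biases
  $c, d$ are only identified by the enumeration oracle, not by training.
* No momentum, weight decay, minibatch schedules or persistent CD; the
  trainer is deliberately the plain algorithm.
* Screening wraps established classifier implementations; only the
  vote-averaging rule is bespoke. No hyperparameter search is performed.
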