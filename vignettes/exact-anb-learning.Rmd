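---
title: "Exact learning of augmented naive Bayes classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact learning of augmented naive Bayes classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anbc)
```

## The model

A discrete Bayesian network classifier is a DAG $G$ over variables
$X_0, X_1, \dots, X_n$ (the class $X_0$ with $r_0$ states plus $n$ features)
together with conditional probability tables
$\theta_{ijk} = P(X_i = k \mid \mathrm{Pa}_i = j)$. The joint factorizes as
$P(X_0,\dots,X_n) = \prod_i P(X_i \mid \mathrm{Pa}_i)$, and classification
proceeds by the posterior
$$
\hat c \;=\; \arg\max_c \;
\theta_{0 j(c) }\prod_{i : X_i \in \mathrm{ch}(X_0)} \theta_{i j_i(c) x_i},
$$
so only the Markov blanket of $X_0$ (parents, children, co-parents) ever
influences the decision. `class_posterior()` implements exactly this product,
accumulated in log space and normalized by log-sum-exp so that long products
over many children cannot underflow.

Structures are scored by the BDeu marginal likelihood with equivalent sample
size $N'$ (`ess`, default 1.0, the weakest standard prior so that the data
dominate). The log local score of a child with $q$ parent configurations and
$r$ states is
$$
\sum_{j=1}^{q}\left[\ln\Gamma\!\left(\tfrac{N'}{q}\right)
 - \ln\Gamma\!\left(\tfrac{N'}{q} + N_j\right)\right]
 + \sum_{j=1}^{q}\sum_{k=1}^{r}\left[
   \ln\Gamma\!\left(\tfrac{N'}{rq} + N_{jk}\right)
 - \ln\Gamma\!\left(\tfrac{N'}{rq}\right)\right],
$$
which is decomposable over families and identical for Markov-equivalent
DAGs (a BDe score). Everything stays in natural logs end to end; ratios such
as the Bayes factor are only exponentiated for display.

## Exact search

`learn_exact()` finds a globally optimal DAG by dynamic programming over
variable subsets, exploiting the fact that every DAG has a sink. Three tables
are built bottom-up over subsets in increasing cardinality: all local scores,
the best admissible parent set within every available pool ("best parents"),
and the best sink of every subset via
$$
\mathrm{score}(Z) = \max_{s \in Z}\;
\Big[\mathrm{Score}_s\big(g_s^*(Z \setminus \{s\})\big)
 + \mathrm{score}(Z \setminus \{s\})\Big].
$$
In `gbn` mode the subsets range over all variables. In `anb` mode the class
is pinned as a parentless root adjacent to every feature, so only feature
subsets are enumerated and every stored candidate parent set implicitly
contains $X_0$; the class's own local score is a constant dropped during the
search and added back for reporting. The instrumented phase counts
(`dp_work_counts()`) show the constrained search does strictly less work
than the unconstrained one on the same variables — one table entry per
(feature, subset-of-other-features) instead of per (variable,
subset-of-other-variables).

Ties are resolved deterministically, and deliberately in the direction of
parsimony: among equal-scoring parent candidates the smaller set wins, then
the lower bit-set encoding; among equal-scoring sinks the lowest variable
index. A maximum-parent option is intentionally absent in exact mode — any
such cap would void the optimality guarantee. Parent pools with more than
$10^7$ joint configurations are rejected outright, and the search itself is
capped at 25 total variables (tables are $O(n2^n)$).

The test oracle, `brute_force_optimum()`, shares no recurrence with the DP:
for up to four searched variables it enumerates every parent-set combination
literally and filters by acyclicity; at five it enumerates all topological
orders crossed with all predecessor subsets, which also visits every DAG.

## Why constrain to ANB

When the class acquires many parents in an exactly learned general network,
its conditional distribution is estimated from the few rows that fall in
each parent configuration and classification degrades on small samples. The
ANB space forbids class parents while remaining expressive enough to contain
a complete graph, hence at least one I-map of any positive distribution.
Under three assumptions — the true distribution is faithful to some DAG, all
features lie in the class's Markov blanket, and blanket members are adjacent
to the class — the BDeu-optimal ANB is asymptotically
*classification-equivalent* to the true structure: its class posterior
converges to the truth. The evaluation module probes both regimes: the
bundled `cancer_like_synthetic.bif` (a 5-node network with the classic
lung-cancer topology, class mid-graph) satisfies the assumptions, while
`asia_like_synthetic.bif` (the 8-node chest-clinic shape) violates them —
its class has non-blanket ancestors and a co-parent not adjacent to it. Both
fixtures are synthetic stand-ins: the topologies are the well-known
benchmark shapes, but the CPT values are this package's own.

## Feature selection

`bf_pc_select()` removes a feature $X_i$ when the zero-order Bayes factor
$$
\mathrm{BF}(X_0, X_i) =
\frac{\exp \mathrm{Score}(\mathrm{CFT}(X_0, \emptyset))}
     {\exp \mathrm{Score}(\mathrm{CFT}(X_0, \{X_i\}))}
$$
exceeds a threshold $\delta$ (evidence for marginal independence from the
class). Only zero-order tests are run — exactly $n$ of them — because
low-order tests are the most reliable and missing a relevant variable harms
accuracy more than keeping an irrelevant one. Kept sets are nested in
$\delta$: raising it removes less. `tune_hyperparameters()` picks
$(N', \delta)$ from the grids $\{1, 2, 5\} \times \{3, 20, 150\}$ by
two-fold cross-validation of the whole pipeline (select, exact ANB search,
EAP fit), with ties resolved toward the smaller $N'$ and then the smaller
$\delta$ — the weaker prior and the more inclusive selection. The same $N'$
drives both the Bayes factor and the structure score within a grid point;
the EAP parameter prior stays at its own default (below) regardless, since
parameter smoothing and structure scoring play different roles. When every
feature is removed, `fit_fsanb()` degenerates to the class marginal and
predicts by prior — the only total behavior once the selected blanket is
empty. Tuning inside each training fold (nesting) is the default in
`cross_validate_accuracy(method = "fsanb")`.

## Parameter estimation and its prior

`fit_eap()` uses the posterior-mean estimator
$\hat\theta_{ijk} = (N'_{ijk} + N_{ijk}) / (N'_{ij} + N_j)$ with
$N'_{ijk} = \mathrm{ess}/(r_i q_{\mathrm{Pa}_i})$ and `ess = 1` by default,
i.e. the hyperparameters $1/(r_i q_{\mathrm{Pa}_i})$. This choice is
score-coherent: each estimate is a one-step Dirichlet-multinomial posterior
predictive, so the fitted joint equals a ratio of BDeu marginal likelihoods
and Markov-equivalent ANB structures yield *identical* class posteriors at
any finite sample size — a property the suite checks exhaustively over all
543 feature sub-DAGs on four binary features. Unseen parent configurations
fall back to the uniform prior-only estimate; no extra smoothing is
invented.

## Evaluation protocol

`asymptotic_eval()` mirrors the standard recovery experiment: sample
$N$ rows, learn the ANB exactly, then report (a) the structural Hamming
distance to `reference_optimal_anb()` and (b) the class-posterior
Kullback–Leibler divergence to the *true structure fitted by EAP on the same
sample*, weighted by the generative network's exact feature marginal. Three
deliberate readings are baked in:

* **SHD on CPDAGs.** Both structures are converted to their equivalence-class
  patterns (Chickering's label-edges algorithm) and node pairs whose status
  (absent / undirected / directed either way) differs are counted, so
  score-equivalent relabelings of the same class cost nothing. A raw-DAG
  variant is exposed via `shd(..., on = "dag")`.
* **Expected-count reference.** The population-optimal ANB is computed by
  running the same exact search on fractional expected counts
  $N_{\mathrm{ref}} \cdot P(\text{config})$ ($N_{\mathrm{ref}} = 10^6$; the
  log-Gamma score accepts real counts), which removes sampling noise from
  the oracle.
* **KLD against the fitted true structure.** Comparing against the true
  structure with parameters fitted on the same sample is the only reading
  under which the divergence can hit exactly zero at finite $N$ — which it
  does the moment the learned structure becomes classification-equivalent to
  the truth, the effect the protocol is designed to exhibit.

## The synthetic generator

`random_discrete_network()` emulates benchmark-style ground truth: a random
DAG with a parent bound, CPT rows drawn from a symmetric Dirichlet(0.5)
whose U-shaped density produces the decisive probabilities benchmark
networks have, every entry floored at 0.05 (strict positivity, so no branch
of the state space starves), and a faithfulness margin: each parent must
shift its child's distribution by at least 0.2 in total variation between
two configurations differing only in that parent, with redraws until the
margin holds. Without the margin a raw Dirichlet draw can place an edge
whose dependence is numerically nil — a DAG the distribution is not
detectably faithful to — and no finite-sample method could or should recover
it. With `anb_like = TRUE` the class is a parentless root adjacent to every
feature, so the recovery assumptions hold by construction.

What the generator does *not* emulate: real tabular data with continuous
measurements, missing-value mechanisms, label noise, or unfaithful
near-cancellations. Passing the synthetic batteries therefore demonstrates
correctness of the algorithms under the stated assumptions, not performance
on any particular applied corpus.

## Preprocessing conventions

`load_dataset()` follows the common benchmark protocol: rows containing the
missing marker `"?"` are deleted first; designated continuous columns are
binarized at the whole-column sample median (computed before any
cross-validation split), with ties at the median going to the low bin;
remaining columns are categorical with states sorted lexicographically.
Constant columns are rejected rather than silently carried as
cardinality-1 variables. State indices are 1-based throughout, and parent
configurations are enumerated in a fixed mixed-radix order with the last
parent varying fastest — the single convention shared by frequency tables,
CPT rows, and BIF output.

## Numerical choices and degenerate inputs

All scoring is double-precision log-Gamma arithmetic; an all-zero table
scores exactly 0, and an empty dataset gives score 0 for every structure
and the uniform EAP fit. Posteriors normalize by log-sum-exp. Prediction
ties break to the lowest class index. The exact KLD enumerates feature
configurations and refuses spaces above $2^{20}$. Seeds control every
random element (sampling, network generation, fold splits) through a
scoped RNG helper that restores the caller's RNG state.

## Problem sizes used in the bundled checks

The test suite and the acceptance script run entirely on data generated in
code: exactness batteries of 120–400 search problems on 2–5 variables at
$N \in \{10, 50, 200\}$; recovery batteries of 20 networks on 4–6 variables
at $N = 10^5$; selection operating characteristics over 50–100 replicates at
$N = 10^4$; and 10-fold cross-validation at $N = 600$. These sizes keep a
full run in tens of seconds while leaving each property enough resolution to
fail loudly if an implementation detail drifts.

## Known limitations

* The exact search is exponential in the variable count by design; beyond
  roughly 20–25 variables, memory for the $O(n2^n)$ tables, not time, is
  the binding constraint. Feature selection is the intended remedy.
* Prediction-time missing values are supported only outside the Markov
  blanket of the class.
* Only BDeu among the BDe family is implemented (no informative prior
  network), and only multinomial CPTs (no trees or noisy-OR gates).
* The BIF reader covers the bnlearn-compatible subset the package writes:
  `network`, `variable`, `probability` blocks with `table` or
  per-configuration rows.
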