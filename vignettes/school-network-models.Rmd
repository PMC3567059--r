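---
title: "Modelling classroom-confined friendship and enmity networks"
author: "schoolnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling classroom-confined friendship and enmity networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(schoolnet)
```

## The problem

Social ties among elementary-school students have a distinctive
topology. Friendship networks are *spatially confined*: a student's
friends sit overwhelmingly in their own classroom, so the adjacency
matrix is nearly block-diagonal, the degree distribution is close to
Poisson, and the clustering index is far higher than an Erdős–Rényi
(ER) graph of equal density would give. Enmity ("non-affective")
networks are also classroom-confined but sparse and disconnected, with
many isolated students and a small number of students disliked by many:
a heavy, power-law-like degree tail that no growth model with a
guaranteed minimum degree (e.g. Barabási–Albert, BA) can produce.

schoolnet implements generative models for both topologies, the nine
standard network measurements used to characterise them, the classic
ER / Watts–Strogatz (WS) / BA reference models with their closed-form
degree laws, the statistical machinery used to validate distributional
claims, and the survey-ingestion rules that turn sociometric nomination
tables into symmetric relationship matrices.

## The friendship model (SFN)

The School Friendship Network model has four parameters: the number of
students $N$, the number of classrooms $m$, the target mean number of
friends per student $\langle k\rangle$, and a shortcut probability $p$.

1. Classrooms get balanced sizes $a \in \{\lfloor N/m\rfloor,
   \lceil N/m\rceil\}$ (`classroom_sizes()`).
2. Friendships inside a classroom form as an ER block. The ER identity
   $\langle k\rangle = q\,(a-1)$ fixes the within-block link
   probability $q = \langle k\rangle/(a-1)$, which — because ER
   clustering equals density — is also the expected clustering $C_T$ of
   a union of such isolated blocks (`intra_group_probability()`,
   `expected_block_clustering()`).
3. *Sense of belonging*: group-dynamics theory distinguishes small,
   affectively bonded primary groups from large, institutionally imposed
   secondary groups, with primary groups nesting inside secondary ones.
   A large classroom therefore does not behave as one uniform block. If
   $C_T = \langle k\rangle/(a-1)$ falls below a threshold $u$, the
   classroom is split into $s$ primary sub-groups — the smallest $s$
   with $\langle k\rangle/(a/s - 1) \ge u$, capped so that
   $a/s \ge \langle k\rangle + 1$ keeps the block probability below 1
   (`subgroup_count()`); each sub-group is built by the same rule,
   recursively, with a depth cap (default 3) guaranteeing termination.
   When a classroom is subdivided, a within-classroom shortcut pass
   knits its sub-groups together.
4. *Shortcuts*: each link is, independently with probability $p$,
   deleted and replaced by a link between two uniformly chosen,
   distinct, currently unlinked nodes (`add_shortcuts()`). A final pass
   over the whole school graph links the classrooms. Rewiring conserves
   the node and link counts exactly, so $E[\text{size}] = N \langle
   k\rangle / 2$ for every $p$.

The model interpolates between isolated binomial blocks ($p = 0$) and a
single ER-like graph with a Poisson degree law ($p = 1$); at
intermediate $p$ it keeps a Poisson-consistent degree distribution
*and* high clustering, which is what the ER and WS baselines each fail
to deliver (ER: clustering collapses to density; WS: the degree law
concentrates at the lattice degree $K$, leaving no room for introverts
and extroverts).

### Default parameters and the fitted shortcut probability

The packaged school presets (`school_parameters()`) are the three
studied schools: $(N, m, \langle k\rangle)$ = (108, 7, 9.315),
(226, 9, 8.717) and (419, 12, 7.518); the first school's split
classroom is counted as two groups. The sub-grouping threshold defaults
to $u = 0.25$, chosen against the observed clustering range of the
three schools (0.226–0.292): classrooms of ~16 students
($C_T \approx 0.62$) stay whole while classrooms of ~35 students
($C_T \approx 0.22$) split into two primary groups. Both $u$ and the
sub-group rule are arguments, so alternative subdivision rules can be
swapped in.

The shortcut probability has no closed-form link to the data and is the
model's one free parameter. `fit_shortcut_probability()` fits it by
simulation: mean clustering is a monotonically decreasing function of
$p$ (each rewiring pass dilutes within-block triangles roughly like
$(1-p)^3$), so a coarse grid of simulated means can be
inverse-interpolated at the observed clustering index. Fitted against
the three schools' observed clustering (0.292, 0.248, 0.226) this gives
$p \approx 0.27$, $0.13$ and $0.15$ (40 replicates per grid point),
the values stored in `school_parameters()$p_fitted`.

```{r sfn-example}
pars <- sfn_params(N = 108, m = 7, k_avg = 9.315, p = 0.27)
rep1 <- run_batch("sfn", pars, replicates = 50, seed = 1)
rep1
```

## The enmity model (SEN)

The School Enmity Network model shares the $(N, m, \langle k\rangle,
p)$ parameterisation but replaces the ER block with sequential
preferential attachment over a *fixed* node set: each classroom of size
$a$ receives $l = \mathrm{round}(a\langle k\rangle/2)$ links
(`links_per_classroom()`), each joining an endpoint drawn with
probability $k_i/\sum_j k_j$ (uniformly while all degrees are zero) to
a uniformly drawn distinct endpoint, resampling self-loops and
duplicates (`build_classroom_enmity()`). Because nodes are never
"added", students that are never picked stay isolated — matching the
data and explaining why BA (minimum degree $m$, always connected)
cannot. The shortcut step rewires each link with probability $p$ into a
whole-school link whose first endpoint is again chosen preferentially,
mixing preferential attachment (the power-law body) with randomness
(an exponential cutoff), i.e. the degree family
$p(k) \propto k^{-\alpha} e^{-k/\kappa}$
(`powerlaw_cutoff_pdf()`).

The zero-degree start of each block makes the strict
degree-proportional rule undefined for the first link; the package
falls back to a uniform pick, with a shifted `degree + 1` variant
available via `sen_params(..., attachment = "shifted")`.

Enmity-side survey aggregates are not publicly re-derivable, so SEN
validation runs at reference conditions representative of the largest
school: $N = 419$, $m = 12$, $\langle k\rangle = 1.5$, $p = 0.1$.

```{r sen-example}
g <- generate_sen(sen_params(419, 12, 1.5, 0.1), seed = 1)
sum(igraph::degree(g) == 0)     # isolated students
max(igraph::degree(g))          # the most-disliked student
```

## Measurements and conventions

`measure_graph()` reports order, size, mean degree, diameter, density,
clustering, geodesic, betweenness and closeness, averaging node-level
definitions over the whole network. Degenerate and disconnected cases
follow explicit conventions:

* local clustering of degree-0/1 nodes is 0 (enmity graphs are full of
  them; this keeps the average defined);
* on disconnected graphs, diameter and betweenness come from the
  principal (largest) component — ties broken towards the component
  holding the smallest node index — betweenness normalized by
  $(n-1)(n-2)/2$ on that component;
* closeness uses the Wasserman–Faust component-scaled form
  $\frac{n_c - 1}{\sum d}\cdot\frac{n_c - 1}{N-1}$ (0 for isolates),
  and the geodesic is then estimated as the reciprocal of the mean
  closeness. The published measurement conventions do not pin down the
  disconnected-graph closeness; this choice is bounded, component-aware
  and keeps the reciprocal-geodesic estimate computable, and it is
  isolated in one code path should a different convention be needed;
* an edgeless graph reports diameter, geodesic, betweenness and
  closeness of 0.

Ensemble tables report the mean over replicates of each replicate's
integer diameter, which is why batch diameters are non-integer.

## Statistical validation toolkit

* `poisson_gof()` — Karl–Pearson $\chi^2$ against Poisson($\hat\lambda$)
  with $\hat\lambda$ the MLE (sample mean); expected counts pooled from
  both tails until each tail bin reaches 5 (Cochran's rule), dof =
  bins − 2. Under the null its type-I rate is calibrated (tested at
  2000 simulations).
* `fit_power_law()` — Clauset-style discrete power-law tail fit:
  discrete MLE for $\alpha$ via the Hurwitz zeta likelihood, $k_{min}$
  chosen to minimise the KS distance, p-value by semiparametric
  bootstrap (default 2500 replicates; $p \ge 0.1$ read as consistency).
  Zero degrees are excluded from tail fitting but retained in
  two-sample comparisons.
* `potential_regression()` — OLS of $\log p(k)$ on $\log k$ for
  $p(k) = C k^{-\gamma}$, $k \ge 1$; suggestive only, the KS fit is the
  real test.
* `ks_two_sample()` — two-sample KS with asymptotic p-value, for
  model-vs-reference degree comparisons (`compare_to_reference()`).

Numerical choices: the Hurwitz zeta is computed as Riemann zeta minus a
partial sum (`pracma::zeta`); the power-law sampler inverts an explicit
CDF table extended to cover the largest uniform draw; the WS degree law
truncates its binomial–Poisson convolution at the exact finite support
of the binomial term; the cutoff law normalises by chunked summation
with a $10^{-12}$ relative tail tolerance.

## Survey ingestion

`build_matrices()` turns a roster and a nomination table into symmetric
friendship/enmity/kinship matrices. Kinship first
(`infer_kinship()`): a sibling tie needs one sibling nomination plus
*both* surnames matching; a cousin tie needs one cousin nomination plus
at least one shared surname; the relations are closed to a fixpoint
(sibling symmetric + transitive, cousin symmetric, cousin-of-sibling is
cousin) because young children often omit kin ties; siblingship wins
when both would hold. Friendship and enmity are *bilateral* (both
students must nominate each other), and kinship ties count as
friendships. Surname matching is exact after case-folding and
trimming. A pair that is simultaneously bilateral friend and bilateral
enemy is kept in both matrices and reported as a conflict.

`synthetic_roster()` generates survey data with this structure —
surnames from a fixed pool, balanced classrooms, planted
sibling/cousin pairs, classroom-concentrated friend/enemy nominations
with a tunable reciprocation probability — so the pipeline is testable
without confidential survey data. What it does *not* emulate: real
surname frequency skew, grade-adjacent mixing, sex assortativity, or
nomination-count limits of a questionnaire; pipeline tests on it
therefore establish rule-engine correctness, not demographic realism.

## Problem sizes and what the checks show

Validation batches use 200 replicates for measurement tables (matching
the order of magnitude behind the published ensemble means), 40-trial
pass-rate checks for KS consistency, and bootstraps of 100–250 for
power-law p-values inside the test suite (the 2500 default remains for
interactive use). At these sizes the SFN batches reproduce the
published model measurements to within Monte-Carlo and calibration
error, e.g. School1: size ≈ 502–503, clustering ≈ 0.29, geodesic ≈
2.53–2.55.

One distributional caveat is a finding, not a defect: SEN degrees
pooled over many replicates *fail* a pure power-law tail test, because
classroom size bounds the maximum within-block degree and the true
generated law has an exponential cutoff — precisely the
power-law-with-cutoff family argued to describe the observed data. At
single-school sample size ($n = 419$) the KS test cannot resolve the
cutoff and the Clauset fit is consistent with a power law in most
replicates, which is the scale at which the original comparison was
made.

## Known limitations

* The shortcut probability is fitted by simulation, not derived; a
  theoretical link between $p$ and the data remains open.
* The sub-grouping rule is a threshold heuristic; alternative closed
  forms can be substituted through the `u` argument and
  `subgroup_count()`.
* Graphs are simple and undirected; weighted, directed or temporal
  ties, and signed-graph analyses combining friendship and enmity, are
  out of scope.
* Empirical survey matrices cannot be re-derived here (the underlying
  questionnaires are confidential); the ingestion pipeline is validated
  on synthetic rosters with planted ground truth instead.
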