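---
title: "Inferring domain-disease associations on a quadripartite network"
author: "dominfer maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring domain-disease associations on a quadripartite network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dominfer)
```

# The problem

Protein domains are portable functional units: when a gene is implicated
in a disease, often only one of the domains of its product carries the
causal lesion. Direct evidence for domain-disease associations is scarce,
but three relations are abundant: which domains each protein contains
(e.g. Pfam), which genes are associated with which diseases (e.g.
OMIM-style catalogues), and how phenotypically similar diseases are to
one another. `dominfer` infers domain-disease associations from exactly
these three inputs.

Because any single disease typically has very few known genes, diseases
are first grouped into **modules** of phenotypically similar diseases;
modules may overlap, since one disease can belong to several clinical
families. A gene (protein) is then *associated with a module* when it is
associated with at least one of the module's diseases. The inference
problem lives on the resulting quadripartite graph

domains — proteins — (observed associations) — modules — diseases,

held by the `AssociationNetwork` class.

# Module detection

`buildDiseaseNetwork()` links two diseases when their similarity is
**strictly above** a threshold (default 0.5; the boundary value gives no
edge, and this convention is tested). `detectModules()` then grows
potentially overlapping clusters greedily: seeds are taken in descending
weighted-degree order, and each cluster repeatedly applies the single
vertex addition or removal that most increases the cohesiveness

$$f(S) = \frac{w_{in}(S)}{w_{in}(S) + w_{bound}(S) + p\,|S|},$$

with node penalty $p = 2$ by default. Clusters whose overlap score
$|A \cap B|^2 / (|A||B|)$ exceeds 0.8 are merged. Finally modules must
contain at least 5 diseases and pass a one-sided Mann–Whitney rank test
(members' internal versus boundary weights) at $p \le 0.05$. For a fully
detached module the rank test degenerates and the exact probability that
all internal weights exceed all external ones under random interleaving,
$1/\binom{2n}{n}$, is used instead. The procedure is deterministic for a
fixed graph; edge weights are used by default, and `weighted = FALSE` gives
the unweighted variant — both are common in cohesiveness clustering.
Users reproducing an externally published module catalogue should supply
it directly as a `diseaseModule` table; the detector here is an
independent implementation, not a wrapper around any existing tool.

# Candidate extraction

For a query disease the seven-step scheme collects: its modules and all
their diseases; modules sharing at least one disease with those (one hop
only — a single sharing step, deliberately not a transitive closure); the
diseases of these modules; all proteins observed associated with the
collected modules; their domains; all proteins sharing any of those
domains; and finally all domains of those proteins — the **candidate
domains**. The query disease itself counts when deciding whether two
modules share a disease.

For each candidate pair $(D_m, T_n)$ the witness sets are global:
$N_{mn}$ is every (protein, module) pair with $D_m \in P$ and
$T_n \in M$, and $A_{mn} \subseteq N_{mn}$ the observed-associated
subset. Every candidate has $N_{mn} \neq \emptyset$ by construction;
$A_{mn}$ may be empty. `buildCandidateIndex()` materialises the union of
candidate pairs, the **evaluation universe** (every (protein, module)
pair containing at least one candidate pair, with the observation
indicator $O_{ij}$), and their sparse containment incidence; all
model-based scorers run off this one structure. Universe pairs without
an observed association are the $O_{ij} = 0$ "negative" rows — the
Cartesian complement within the universe, which keeps the likelihood
product finite and well-defined.

# The five scorers

**Association.** $\mathrm{Score} = |A_{mn}| / |N_{mn}|$, zero when no
witness is associated. Fully determined by counting.

**MLE (EM).** The generative assumption is a noisy-OR: a protein
associates with a module iff at least one contained domain associates
with at least one member disease, so
$\Pr(\psi_{ij}=1) = 1 - \prod_{(m,n) \in (i,j)} (1 - \lambda_{mn})$,
and observations flip with rates $fp = \Pr(O=1 \mid \psi=0)$,
$fn = \Pr(O=0 \mid \psi=1)$. The EM update is the classic
domain-interaction form: the E-step computes
$e_{mn}^{ij} = \lambda_{mn} \Pr(O_{ij} \mid \phi_{mn}=1) / \Pr(O_{ij})$
for each containing pair, the M-step averages over the $|N_{mn}|$
containing pairs. Initialisation is $1/|D^{(n)}|$ (equal probability
over a disease's candidates), capped at $1/2$ because a disease with a
single candidate would otherwise start exactly on the absorbing boundary
fixed point $\lambda = 1$. $\lambda$ is clipped to
$[10^{-12}, 1-10^{-12}]$; convergence is a relative log-likelihood
change below $10^{-6}$ (500 iterations default, both configurable). The
trace is monotone up to $10^{-9}$ and this is enforced by the class
validity. The default operating point $fp = 0, fn = 0.9$ is the
operating point a grid search over both rates favours for this family
of models; the large $fn$ reflects that absence of a recorded association is weak evidence.

**DPEA.** With noise ignored ($fp = fn = 0$), the exclusion score of a
pair is the summed log-ratio, over observed-associated pairs containing
it, of $\Pr(O_{ij}=1)$ under the unrestricted fit versus a full EM refit
with $\lambda_{mn}$ pinned to zero. The sum is restricted to pairs
containing $(m,n)$; terms for other pairs would not cancel exactly (the
refit perturbs the rest of $\lambda$ too) but carry no exclusion signal,
and the restriction is the standard exclusion-analysis convention.
Three numerical decisions matter and are documented here because each
alternative was tried and failed:

* the restricted run restarts from the uniform initialisation — warm
  starting from the unrestricted estimate leaves saturated rows
  saturated and collapses every score to zero;
* an unexplained associated pair gives a vanishing denominator; the
  score is capped (default 50 on the log scale) and flagged;
* both runs stop at a finite tolerance, so pairs whose true score is
  zero (full compensation) come back as $\pm 10^{-4}$-scale residuals
  with arbitrary sign. Scores below `snapTol` (default $1000 \times$
  the EM tolerance) are reported as exact zeros; tiny spurious
  *negative* values would otherwise rank below genuine zeros and
  corrupt rank-based evaluation. `snapTol = 0` disables the floor.

**Bayesian.** Priors $fp \sim U[u_p, v_p]$, $fn \sim U[u_n, v_n]$,
$\lambda_{mn} \sim \mathrm{Beta}(\alpha, \beta)$ (defaults $0, 1, 2, 2$;
`flatLambda = TRUE` gives $U[0,1]$). The posterior is explored by a
Gibbs sweep over every $\lambda_{mn}$, then $fp$, then $fn$, each drawn
by shrinkage slice sampling on its bounded support. Slice sampling is
derivative-free and exact without log-concavity assumptions — the
full conditionals are log-concave only under restrictions that can
fail, so a sampler that does not rely on it is the robust choice. The
score is the posterior mean of $\lambda_{mn}$. A degenerate prior
interval (`up == vp`) pins the rate, which is how "fixed $fp$/$fn$"
analyses are expressed. The model has a label-switching twin mode at
$fp > 1 - fn$ (observations interpreted as anti-correlated with truth);
on weak data single-site updates can wander into it and not return, so
the chain starts at the 10% quantile of the $fp$ prior, inside the
identifiable regime. Chain defaults (2000 retained draws, 500 burn-in)
are stated choices, not reconstructions; determinism is guaranteed given
`seed`. On desk-scale fixtures the posterior under free noise priors is
genuinely diffuse — the likelihood cannot pin $fp$ and $fn$ with a few
dozen rows — so posterior means hover near the prior mean with small
data-driven tilts; this is a property of the model, not the sampler,
and it is why the MLE-agreement checks use pinned noise rates.

**PE.** Over the set $\Delta$ of candidate pairs contained in at least
one observed-associated (protein, module) pair, minimise
$\sum x_{mn}$ subject to $\sum_{(m,n) \in (i,j)} x_{mn} \ge 1$ for every
observed-associated pair, $x \ge 0$. Vertices of this covering
polyhedron automatically satisfy $x \le 1$. No LP solver ships with the
supported R stack, so the package carries a dense two-phase primal
simplex (Bland's rule on entering and leaving variables: deterministic,
cycle-free). Alternative optima are real (symmetric constraint groups);
they are resolved only by the solver's deterministic pivoting and, when
$r < 1$, by averaging over constraint subsamples. With reliability
$r < 1$ each constraint enters with probability $r$ and the LP-score is
the mean of $x_{mn}$ over `nRuns` solves (default 1000; $r = 1$
collapses to a single solve). The randomisation p-value rewires the
protein-module edges uniformly (compositions and edge count preserved)
and counts permuted LP-scores $\ge$ the observed one; each permuted
network is scored by one full-constraint solve — the cheaper,
deterministic choice, against which the observed LP-score is compared
like for like at the default $r = 1$.
Edges rewired outside the candidate universe share no variables with
indexed pairs and are dropped exactly. The pw-score is
$\min(p, (1-r)^{w})$ with $w = |A_{mn}|$; at $r = 1$ any witnessed pair
has pw-score 0. For ranking, a pair failing the pw threshold is demoted
below passing pairs of equal LP-score by an infinitesimal tie-break
(half the smallest LP gap) — PE yields two numbers, so a single ranking
needs a combination rule, and this tie-break is the package's declared
choice.

# Evaluation

All labelled pairs are pooled and ranked by descending score with
average ranks on ties; sensitivity, specificity and precision follow the
threshold sweep, AUC is the trapezoid area (equal to the normalised
Mann–Whitney U under average ranks — cross-checked in the tests),
top-$k$ accuracy is the fraction of positive pairs whose domain ranks in
the top $k$ (default 10) of its disease's candidate list, and the mean
rank ratio averages rank over list length. Positives that were never
scored (not candidates) are excluded from the AUC but count as failures
in accuracy and with ratio 1 in the mean rank ratio, with logged counts.
A uniform random ranking of a 72-candidate list has expected top-10
accuracy $10/72 \approx 0.139$ and mean rank ratio $\approx 0.5$; both
identities are verified analytically and by simulation in the test
suite. `robustnessSweep()` re-scores and re-evaluates over a parameter
grid (noise rates for the MLE, $r$ and the pw threshold for PE, prior
settings for the Bayesian scorer).

# The synthetic world

`simulateNetwork()` generates the quadripartite world the model assumes:
protein compositions and module sizes are truncated-geometric
(right-skewed — most proteins carry 1–2 domains, modules hold at most 10
diseases), truth $\phi_{mn}$ is Bernoulli over all domain × disease
cells, $\psi$ follows by the exact OR rule, observations flip with
$(fp_{obs}, fn_{obs})$, and similarities are emitted with within-module
pairs uniform on (threshold + δ, 1) and all others on (0, threshold − δ)
with δ = 0.05, so module detection at the default threshold can
rediscover the planted modules unambiguously. Defaults — 60 domains, 80
proteins, 60 diseases, 12 modules, plant rate 0.05, $fp_{obs} = 0.01$,
$fn_{obs} = 0.1$ — describe a small but realistically sparse benchmark:
the mild false-negative rate mirrors incomplete curation, the near-zero
false-positive rate mirrors the high precision of curated links. What a
green test on this world establishes is internal consistency — the
scorers recover planted truth under the model's own assumptions at desk
scale. It does not establish performance on real catalogues, whose
similarity profiles are not block-structured, whose degree distributions
are heavier-tailed, and whose "noise" is model mismatch rather than
independent flips. Notably, the exclusion analysis (DPEA) assumes
noise-free observations, and independent false-negative flips are
adversarial for it: a single unobserved containing row forces a true
pair's $\hat\lambda$ to zero. Its margin over chance on the synthetic
default is therefore modest by design of the world, not by accident.

`makeWorkedFixture()` is a hand-built miniature of the
module-specificity phenomenon: one disease in a single module, another
shared between two, dedicated proteins per "linked" domain, a bridge
protein pulling "unlinked" domains into the candidate set, and two extra
observation-free modules that keep the universe sparse. By construction
the unlinked domains get Association and LP scores of exactly zero for
the single-module disease, and the linked domains score at least as high
for the single-module disease as for the two-module one under all five
methods.

# Numerical and design notes

* Identifiers are opaque strings throughout; duplicate edges
  deduplicate with a warning; dangling references error only under
  `strict = TRUE`.
* The gene-to-protein mapping is treated as one-to-one; gene and protein
  identifiers are synonymous.
* Probability clipping: $\Pr(O)$ is clipped to
  $[10^{-300}, 1 - 10^{-16}]$ inside likelihoods so degenerate
  configurations report very negative finite log-likelihoods rather
  than `-Inf`.
* `simulateNetwork()` regenerates (new sub-seed) when a sampled world
  has no observed association, up to `maxRetry`, then returns the empty
  world with a warning — a null configuration (`piTrue = 0, fpObs = 0`)
  is representable, not an error.
* The per-run seeds are ordinary R seeds; the Rcpp samplers draw from
  R's RNG, so `set.seed()` reproduces entire analyses including the
  compiled paths.

# Limitations

Module detection is a faithful-but-independent reimplementation of the
greedy cohesiveness procedure; on real data its catalogue will differ
from any published one, which is why a precomputed module table is the
supported path for exact reproduction. The DPEA refit loop is quadratic
in practice (one EM per nonzero candidate); at desk scale this is under
a minute, but genome-scale use would want the component-wise
decomposition of the incidence structure. The Bayesian sampler is
single-chain; multimodality beyond the documented label-switching pair
is not monitored.
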