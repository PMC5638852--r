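---
title: "Reconstructing adaptive landscapes for body mass on phylogenies with fossils"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing adaptive landscapes for body mass on phylogenies with fossils}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`oulandscape` models a continuous trait — natural-log body mass in kg
throughout — as an Ornstein–Uhlenbeck (OU) process on a time-calibrated
phylogeny:

$$ dX(t) = \alpha\,[\theta - X(t)]\,dt + \sigma\,dB(t) $$

The deterministic part pulls the trait toward a *primary adaptive optimum*
$\theta$ at rate $\alpha$ (units 1/Ma); $\sigma\,dB(t)$ is white noise of
intensity $\sigma^2$ (trait²/Ma) summarising unmeasured selective factors
and drift. A **selective regime** is a set of branches sharing one optimum;
an assignment of every branch to a regime is a **painting**. A regime may
occupy non-adjacent branches, which is how convergence is expressed. The
rate of adaptation is reported as the phylogenetic half-life
$t_{1/2} = \ln 2 / \alpha$, the expected time for a maladapted lineage to
cover half the distance to its optimum; $t_{1/2} = \infty$ ($\alpha = 0$)
is Brownian motion (BM), the no-adaptation reference model.

Under a painting with optima $\theta$, tip values are jointly Gaussian.
With root-to-tip time $T_i$ and MRCA depth $t_a$ measured from the root,

$$ \mathrm{E}[X_i] = \sum_r W_{ir}(\alpha)\,\theta_r, \qquad
   \mathrm{Cov}(X_i, X_j) = \frac{\sigma^2}{2\alpha}
   e^{-\alpha (T_i + T_j - 2 t_a)} \left(1 - e^{-2\alpha t_a}\right), $$

where $W_{ir}$ integrates $\alpha e^{-\alpha(T_i - t)}$ over the parts of
the root-to-tip path painted $r$. These expressions hold on
non-ultrametric trees, so fossil tips (which end above the present) enter
the likelihood exactly like extant ones — they are what anchors optima deep
in time. The residual root weight $e^{-\alpha T_i}$ is assigned to the root
regime's optimum: the root state equals the root optimum and is not a free
parameter. This convention follows the software lineage this method comes
from and keeps parameter counts comparable across paintings.

### Log scale

All analysis is on natural-log kg. Mass spans 0.05–126 kg across the taxa
of interest; additive Gaussian noise on raw kg would put positive
probability on negative masses and make $\sigma^2$ scale with mass.
Reported optima are back-transformed with `exp()`.

## Fitting

`fit_ou()` profiles the likelihood over $\alpha$: at fixed $\alpha$, the
optima $\hat\theta$ are generalized least squares with the weight matrix as
design, and $\hat\sigma^2$ is the closed-form ML (1/n) residual variance —
ML rather than REML, so that AICc is computed on the actual maximized
likelihood. The profile is evaluated on a 64-point log-spaced grid over
$\alpha \in [10^{-6}, 10^{3}]$ per Ma (half-lives from ~7·10⁵ Ma down to
~7·10⁻⁴ Ma, beyond any biological case here) and refined by bounded scalar
optimization in $\log \alpha$ to tolerance 1e-8. An $\hat\alpha$ at either
bound is recorded as a flat-likelihood warning in the fit's `notes`.

Parameter counts: BM has k = 2 ($\sigma^2$, root state); an OU model with
p regimes has k = p + 2 ($\alpha$, $\sigma^2$, p optima; no separate root
state under the root convention). Models are compared by
$\mathrm{AICc} = -2\ell + 2k + 2k(k+1)/(n-k-1)$.

### Numerical choices

* $\hat\sigma^2$ is floored at 1e-12 inside the likelihood. Identical (or
  numerically collinear) trait values otherwise make the profiled
  likelihood follow the log of pure rounding noise, and stepwise
  comparisons between equally degenerate models become arbitrary. 1e-12
  log-kg² is far below any biological signal; fits at the floor are
  flagged `degenerate`.
* Cholesky factorization of the covariance is attempted directly, then
  once more with a 1e-10 relative jitter; failure raises an error
  reporting the condition number.
* Unidentifiable optima (a regime whose weights vanish numerically at very
  small $\alpha$) are handled by pivoted least squares and reported as 0
  with a rank-deficiency note.

## The stepwise regime search

`surface_search()` reconstructs the painting from the data. The **forward
phase** starts from a single peak (OU1). Each step tries a new regime on
every edge that is not already a shift origin — the new regime claims the
edge and all descendants not claimed by a more recent shift — and accepts
the candidate with the lowest AICc if it strictly improves on the
incumbent (any improvement counts; there is no minimum-improvement
cutoff). Shifts may sit on terminal edges, so single-species regimes are
allowed. The **backward phase** then tries every pairwise merge of regime
labels, accepting the best strictly-improving merge until none remains.
Surviving regimes whose edges are not contiguous were reached by more than
one origin and are reported as **convergent**. By construction the final
AICc ≤ forward AICc ≤ OU1 AICc.

Determinism: candidate ties within 1e-6 AICc are broken by the smallest
postorder edge index (shifts) or the lexicographically first label pair
(merges); when a merge involves the root regime, the root label survives.
One structural tie deserves mention: a shift on a root-child edge is
likelihood-equivalent to the complementary shift on its sister, because
the root regime influences tips only through the root weight
$e^{-\alpha T}$, which is negligible at the rates estimated here. The
tie-break resolves such pairs deterministically, but "the" shift edge is
genuinely ill-defined in that configuration, and simulation harnesses
avoid planting truth shifts there.

Performance: candidates are ranked on a coarser 24-point $\alpha$ grid
(tree decompositions are cached and shared across candidates); the winner
is refit on the full grid with refinement before the acceptance test, so
accepted AICc values are always fully optimized. `search_control()`
exposes the ranking grid and optional `max_steps`/`max_merges` caps.
Truncating the forward phase can only leave the search at a higher AICc,
so capped searches are conservative in model comparisons; the analysis
scripts cap at 20–25 shifts to bound runtime on 87-tip data.

### Known limitation: overfitting of the forward scan

With a short half-life relative to tree depth (here ~1 Ma on a 70-Ma
tree), tips are nearly independent draws from their regimes' stationary
distributions, and the forward step is effectively a scan over ~2n clade
contrasts accepting whenever the best one clears a ~2.3-unit AICc
penalty. Under a true single-peak model, the maximum of that many
contrasts clears the bar almost always, so the search reliably accepts
spurious shifts and typically reports more regimes than the generating
landscape (the backward merge phase recovers some, not all, of the
inflation). `false_shift_harness()` measures this directly and the
calibration script reports it; this behaviour is a property of stepwise
AICc shift selection itself — it motivated later penalized-selection
methods — not of this implementation, whose likelihoods are verified
against dense multivariate-normal oracles to 1e-8. Consequences for use:
the *location* of strong shifts and the dominance of the searched model
over fixed alternatives are reliable (see the harnesses), while the raw
regime count is upward-biased and optima of single-species regimes should
not be over-interpreted.

## Fixed hypotheses

Alternatives are expressed purely as paintings; optima are always
estimated, never pinned to literature values. `build_anc_pan_painting()`
encodes the chimpanzee-sized hominoid-ancestor hypothesis by editing a
reference painting (normally the search result): the chimpanzee regime —
identified as the regime of the *Pan* pendant edges — is extended over the
hominoid backbone and rootward across the stem while the lineages peeled
off are stem apes, and the hylobatid stem-plus-crown receives a derived
dwarf regime. Regimes outside the edited region are kept from the
reference painting; which non-hominoid regimes the published alternative
retained is only visible in a figure's coloring, so keeping the searched
painting there is an interpretation, made once and used everywhere.

## The synthetic dataset

Nothing in the published analysis's extant data can be redistributed, so
`make_paper_like_dataset()` builds a dataset with the same *structure* and
uses it as the package's study conditions:

* An extant backbone of 57 species: hand-calibrated hominoid nodes
  (hylobatids 19.5 Ma, *Pongo* 16.5, *Gorilla* 10, *Pan*–*Homo* 8, a
  4-species hylobatid crown at 8) and a *Papio* cherry, joined at
  calibrated backbone nodes (root 70 Ma, anthropoids 43, catarrhines 31,
  platyrrhines 25) to seeded pure-birth radiations for strepsirrhines,
  New World monkeys, atelids and Old World monkeys. Pure birth is the
  simplest stationary topology model; no realism is claimed for the
  radiations.
* 21 hominoid/hominin fossils grafted at their published first-appearance
  dates with 1-Ma ghost lineages (the default), following the published
  verbal placements; deviations from 1 Ma are confined to keeping the
  *Proconsul* and *Ekembo* genus pairs monophyletic on the stem and to
  placing *H. floresiensis* with the habiline grade rather than 1 Ma
  before its very late first appearance. Nine non-hominoid fossil
  primates carry synthetic first-appearance dates in the right
  stratigraphic order; their exact ages and placements are not printed in
  the embedded table and do not affect the hominoid analyses.
* The generating landscape mirrors the published regime table: root
  regime at 1.36 kg; a broad 6.95-kg regime entered on the catarrhine
  stem and convergently by atelids; a 17.65-kg terrestrial-baboon regime;
  and hominid-clade regimes at 29.68, 45.23, 59.85, 94.96 and 126.16 kg
  with the published convergences (e.g. *Pr. africanus* with *Pan*,
  *Pr. major* with *Gorilla*, *E. nyanzae* and *D. fontani* with the
  *Pongo*/*H. erectus*/human regime).
* $\alpha = \ln 2 / 0.88$ (the published complete-set half-life) and
  stationary SD 0.35 log-kg, chosen once so that species cluster around
  their optima with the spread seen in the published species-vs-optima
  figure; traits are drawn from the exact OU transition density in
  preorder, one seeded RNG stream per call.
* Per-species metadata (sample sizes from the embedded table, seeded
  dimorphism factors for female masses, single-individual fossil averages
  doubling as female values, the two dual-estimate early hominins carrying
  the printed small/large ratio) drive the dataset variants:
  `well_sampled` (drops poorly sampled or unreliably attributed hominins
  and all non-hominin fossils; N = 63 from 87), `extant_only` (N = 57),
  `small_estimates`, `no_eurasian_apes`, `females_only`.

What passing tests on this generator do and do not show: they validate the
estimator, the search and the pipeline under a landscape of the published
shape — they cannot validate the published biological conclusions, which
depend on the real masses, the real consensus topology, and an unrecorded
random pruning of extant taxa. Published AICc and half-life values are
therefore treated as worked-example arithmetic (their printed deltas are
reconstructed exactly) and as qualitative anchors (the search dominates
BM, OU1 and the chimpanzee-ancestor hypothesis on synthetic data, as it
did in the published comparison), not as numerical targets.

## Tree handling

Trees are `ape` `phylo` objects with branch lengths in Ma. Ages are always
derived from branch lengths — the present is set by the deepest tip and the
root age is never read from the input. `graft_fossil()` splits the
attachment edge at `tip age + ghost` and verifies the attachment age lies
strictly inside the edge; grafting preserves all pre-existing patristic
distances. `prune_similar_sisters()` applies the sister-redundancy rule
(drop the second member of a cherry whose lighter member exceeds 80% of
the heavier's mass) in one deterministic post-order pass over the cherries
of the input tree, with protected taxa never dropped; "second" is the
later tip in stored child order, a determinism choice where the rule's
source leaves the order unstated. `reduce_to_n()` reproduces the final
random thinning as seeded uniform sampling of unprotected tips —
reproducible per seed, since the original random step is unrecorded.

## Problem sizes used by the checks

The simulation harnesses run at 128 tips × 50 replicates (recovery),
128 × 30–50 (shift detection, forward capped at 3 steps — the planted
shift is by far the strongest signal and is found at step 1 when found at
all), 64 × 30 (false-shift rate), and 87-tip datasets over 20 seeds with
the forward phase capped at 25 shifts (dominance). These sizes are the
package's chosen study conditions for its own validation and are stated
here so results are interpreted at the scale they were computed.
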