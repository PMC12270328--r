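---
title: "A coarse-grained consumer-resource model of serial-dilution communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coarse-grained consumer-resource model of serial-dilution communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serialcrm)
```

## The model

Serial-dilution (batch) culture exposes a microbial community to
boom-and-bust cycles: at the start of each passage the culture is diluted by
a factor $D$ into fresh medium, the strains grow until the resources are
exhausted, and the cycle repeats. `serialcrm` implements a deliberately
coarse-grained consumer-resource model of this protocol for communities with
tens of strains and tens-to-hundreds of resources.

The state is the vector of strain biomasses $N_\alpha$ at the end of each
cycle, with all yields rescaled to 1 so that resource concentrations $R_i$
are measured in biomass units. Mass conservation over one cycle reads

$$
N_\alpha(k) - \frac{N_\alpha(k-1)}{D}
 = \sum_i R_i^{\mathrm{tot}}
   \frac{c_{\alpha i}\, W_\alpha}{\sum_\gamma c_{\gamma i}\, W_\gamma},
$$

where $c_{\alpha i} \in [0,1]$ is the fraction of resource $i$ a unit of
biomass of strain $\alpha$ consumes in monoculture (measured by
metabolomics before/after batch growth), and each resource is split among
its consumers in proportion to consumption flux times the *time-weighted
average* abundance

$$
W_\alpha = N_\alpha(k-1)^{1-f}\, N_\alpha(k)^{f}.
$$

The single **time fraction** $f \in [0,1]$ stands in for all within-cycle
timing detail (resource depletion order, exponential growth): $f \to 1$
means resources deplete near the end of the cycle, so the end-of-cycle
abundance dominates the sharing weights. Explicit depletion times, Monod
kinetics and diauxie are deliberately outside the model's resolution.

Cross-feeding enters as a linear inflation of the effective concentration,

$$
R_i^{\mathrm{tot}} = R_i \Bigl(1 + \sum_\gamma p_{\gamma i} N_\gamma(k)\Bigr),
$$

with per-biomass production fluxes $p_{\gamma i} = p'_{\gamma i} /
N_\gamma^{\mathrm{alone}}$, where $p'_{\gamma i}$ is the monoculture
fold-excess and $N_\gamma^{\mathrm{alone}}$ the monoculture biomass. The
latter is itself fixed by mass conservation,
$N_\gamma^{\mathrm{alone}} = \sum_i R_i\,[c_{\gamma i} > 0]$.

### Solving one passage

The balance is implicit in $N(k)$ (both $W$ and the cross-feeding multiplier
depend on it). `passage_update()` solves it by successive substitution
starting from $N(k) := N(k-1)$. The substitution error contracts
geometrically at a rate close to $f$, so roughly $\log(\varepsilon)/\log(f)$
sweeps give accuracy $\varepsilon$; the default cap of 400 sweeps reaches
machine precision at $f = 0.9$, the loop exits early once the iterate is
stationary (relative step $< 10^{-14}$), and a post-hoc residual check warns
above $10^{-6}$. Two guards matter:

* a resource with no surviving consumer has an undefined sharing fraction
  and contributes no growth;
* the linear cross-feeding term has no finite fixed point when
  $\sum_i R_i\, p_{\gamma i}$ exceeds unit gain for some producer — the
  update detects divergence, warns, and returns the last finite iterate
  flagged non-converged. Strongly amplified media can cross this threshold,
  which is why the greedy optimizer (below) scores divergent candidates as
  infinitely bad rather than crashing.

The dilution carry-over $N(k-1)/D$ is negligible at $D = 15{,}000$ but kept
for exact bookkeeping; `omit_dilution_carryover = TRUE` drops it for
sensitivity checks.

### Steady state

Communities under strong dilution empirically reach steady state within
about three passages, and `steady_state(mode = "passage3")` adopts exactly
that convention. A `mode = "converge"` loop (stop when
$\max |\Delta \log_{10} N| <$ `tol`) is also provided, but note a structural
caveat: when more strains compete than there are resources, losing strains
decline geometrically forever; they never satisfy a convergence test on
their log-abundance, so converge mode runs to its passage cap and the
passage-3 convention is the default everywhere in the perturbation
experiments.

## Coarse-graining metabolites

With fewer abundance observations than metabolites the inference is
underdetermined, so metabolites are clustered by who eats them. The
consumption matrix is binarized at a threshold (default 0.3, selectable by
maximizing the Spearman correlation between strain degree and steady-state
abundance across candidate thresholds; ties go to the smallest threshold).
Metabolites above the threshold for more than `min_consumers` (default 5)
strains are clustered by Ward-linkage agglomerative clustering on Euclidean
distances between binary columns, cut into `n_clusters` groups (default 10 —
the dendrogram cut is a free parameter, exposed rather than hidden);
metabolites with 1–5 consumers become singleton clusters; metabolites nobody
consumes are dropped. Cluster fluxes are geometric means in the appropriate
log domain: $\tilde c = -\overline{\log(1 - c_j)}$, back-transformed as
$1 - e^{-\tilde c}$, and $\tilde p = \overline{\log(1 + p'_j)}$,
back-transformed as $e^{\tilde p} - 1$. Consumption fluxes are capped at
$1 - 10^{-9}$ so a fully consumed metabolite does not send
$\log(1 - c)$ to $-\infty$; the bias is negligible. Duplicate metabolite
names (the same compound measured by different analytical methods) are kept
distinct with numeric suffixes.

## Inference

Given abundances at two consecutive passages, the balance above is *linear*
in $R$: `build_nnls_system()` assembles one equation per strain and
replicate (sharing weights and cross-feeding multipliers computed from each
replicate's own observed abundances; replicates matched by index), and
`solve_nnls()` minimizes $\lVert A R - b \rVert_2$ subject to $R \ge 0$
(Lawson–Hanson). Fitted concentrations below $10^{-8}$ are reported as
exact zeros. Rows are uniformly weighted.

Because $P$ depends on $N^{\mathrm{alone}}$, which depends on $R$,
`infer_resources()` alternates the NNLS solve with the mass-conservation
update of $N^{\mathrm{alone}}$ (initialized at $1/n_S$), up to 100 rounds
with early exit when $N^{\mathrm{alone}}$ is stationary; without production
fluxes the loop decouples and finishes in one round. A strain consuming no
non-zero-concentration resource gets its monoculture biomass floored at
$10^{-12}$ with a warning.

The time fraction is estimated by grid search (`estimate_time_fraction()`):
refit $R$ at each $f$ on the training passage pair, predict from the
averaged inoculum to the target passage, and score the Pearson correlation
between $\log_{10}$ predictions and $\log_{10}$ observations (replicates
combined by geometric mean on the log scale; zero values excluded pairwise,
which is documented behaviour wherever logs are taken in this package).
The default grid is 0.05 steps over $[0.3, 1]$; ties break toward the larger
$f$. Predictions inside the scan use 2000 substitution sweeps because the
contraction rate degrades as the grid approaches $f = 1$.

## In-silico perturbation experiments

**Leave-one-out.** Each strain is removed from the inoculum in turn and the
passage-3 steady state recomputed; responses are
$\Delta \log_{10} N$ with abundances floored at $10^{-15}$ to keep
extinctions finite. Edges with more than a 10-fold change enter a directed
interaction network — competitive if the target *increased* on removal,
cooperative if it decreased — weighted by $|\Delta \log_{10} N|$, with
per-sign weighted degrees on the nodes. Competition (shared consumed
resources among those present in the medium) and cross-feeding (consumed
resources produced by the partner) scores, both normalized by the perturbed
strain's consumed set, can be compared between edge classes with a
two-sided Mann–Whitney test (exact for small tie-free groups, otherwise the
tie-corrected normal approximation).

**Single-resource amplification.** Each resource with non-zero fitted
concentration is multiplied by 100 and the steady-state response recorded
strain by strain. A strain moved at least 10-fold by fewer than 3 resources
is flagged *non-responsive*; the 10-fold response threshold is our choice
(made for consistency with the network edge threshold — the underlying
screen does not dictate one) and is echoed in the output provenance.
Resources with zero fitted concentration are excluded from the screen
(amplifying zero is a no-op) but re-enter the greedy optimizer below at a
nominal $10^{-8}$.

**Greedy media equalization.** To push the community toward equal strain
abundances, the optimizer repeatedly changes one resource concentration at
a time. Per step, a fair coin toss per resource fixes the direction that
resource would move this step: heads multiplies by 10; tails pulls back
toward the base medium in log space,
$\log_{10} R^{\mathrm{next}} = \log_{10} R^{\mathrm{base}} + 0.6\,
(\log_{10} R^{\mathrm{cur}} - \log_{10} R^{\mathrm{base}})$ — so
concentrations never fall below the base medium (you can supplement an
undefined rich medium, not subtract from it; a hard floor enforces the
bound exactly). Every single-resource candidate is evaluated by the
passage-3 steady state from the inoculum and the objective
$\sqrt{\mathrm{mean}\,(\log_{10} N_\alpha - \log_{10} N_{\mathrm{eq}})^2}$
with $N_{\mathrm{eq}} = \sum N_\alpha / n$ (equalization preserves the
resource-determined total biomass; the target had to be fixed somewhere and
the arithmetic mean is the choice consistent with that conservation). The
best strictly improving candidate is accepted, ties toward the lowest
resource index. Because directions are re-randomized each step, one
improvement-free step does not prove a local optimum; a run ends after
`patience` (default 10) consecutive improvement-free steps or 500 total
steps. Non-responsive strains are excluded from the community before
optimizing. The stochastic search is repeated `n_runs` (default 10) times
and the final concentration profiles averaged geometrically, matching the
log-scale on which they live.

## The synthetic-data generator

`synthetic_scenario()` + `simulate_experiment()` produce serial-dilution
datasets with the statistical structure the inference assumes: sparse
consumption fluxes with magnitudes on $(0.3, 1)$ (so the default
binarization threshold is meaningful), sparse production fold-excesses
drawn log-normal around 1% — small relative to bolus concentrations, as
byproduct excesses in rich media are, which also keeps the cross-feeding
feedback subcritical under 100-fold amplification — a true concentration
vector, an inoculum, exact forward dynamics, and multiplicative log-normal
replicate noise of standard deviation $\sigma$ on the $\log_{10}$ scale
(default 0.3, comparable to biological replicate scatter in rich-medium
experiments; $\sigma = 0$ gives identical replicates). Every strain is
guaranteed to consume at least one resource and every resource to have at
least one consumer (rejection sampling).

Defaults follow the experimental protocol the model targets: $D = 15{,}000$,
$f = 0.9$, 3 biological replicates, 3 passages, fitting on the passage 1→2
pair. The default community is 30 strains × 20 resources, which keeps the
three-replicate NNLS system comfortably overdetermined; the perturbation
and equalization demonstrations instead use 20 strains × 30 clusters,
mirroring the strains-to-clusters ratio of a mature gut community, because
with fewer resources than strains competitive exclusion empties niches and
equalization is structurally impossible.

What the generator does **not** emulate: compositional (relative-abundance)
distortion unless `normalize = TRUE` is requested, LC-MS measurement error
in the fluxes themselves, batch-to-batch media variation, and lag/diauxie
effects. Passing tests on synthetic data therefore demonstrate correctness
of the machinery under the model's own assumptions, not predictive accuracy
on any real community.

## Numerical choices, in one place

* Fixed-point sweeps: cap 400 (`passage_update`), early exit at relative
  step $10^{-14}$, residual warning above $10^{-6}$; 2000 sweeps inside the
  $f$ grid scan; 150 inside greedy candidate evaluations (objective
  differences dwarf the residual there).
* Steady state: passage-3 convention for all perturbation experiments;
  converge mode available with `tol` on $\max|\Delta\log_{10} N|$.
* Floors: $10^{-15}$ before logs of abundances, $10^{-12}$ for monoculture
  biomasses of non-consumers, $10^{-8}$ for "absent" resources entering the
  greedy search and for reporting fitted concentrations as zero.
* Zeros are excluded pairwise in every log-scale comparison.
* Ties: smallest threshold in threshold selection, largest $f$ in the grid
  scan, lowest resource index in greedy acceptance; clustering uses the
  deterministic input column order.
* Sizes in the shipped verification runs (tests and `scripts/acceptance.R`)
  are 100 random instances for conservation laws, 20 for the oracle
  comparison, 30×20 communities for recovery, and a 20×30 community with 10
  greedy runs for equalization.

## Known limitations

The model inherits every coarse-graining of its derivation: one global $f$,
linear cross-feeding with end-of-cycle producer biomass, equal yields,
complete resource depletion each cycle. The NNLS fit is unregularized, so
collinear consumption profiles trade concentration between clusters freely
(only the fitted *sums* along collinear directions are well determined).
Cross-feeding inference assumes production fluxes are measured, not
inferred. And the greedy optimizer is a local search: different runs end in
different local optima, which is precisely why it is run repeatedly and
averaged.
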