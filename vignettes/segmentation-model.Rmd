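---
title: "The voxseg segmentation model: sampling cell boundaries on a voxel lattice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The voxseg segmentation model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxseg)
```

## The problem

Imaging-based spatial transcriptomics platforms (10x Xenium, Vizgen
MERSCOPE, NanoString CosMx) report individual RNA transcripts with
micrometre-scale coordinates but no cell membership.  Assigning transcripts
to cells — cell segmentation — is the step every downstream analysis rests
on, and errors at this step manifest as phantom co-expression between
neighboring cell types.  voxseg treats segmentation as posterior inference:
cell boundaries are latent variables in a generative model of where
transcripts land, and a Markov chain Monte Carlo sampler simulates
boundaries that explain the observed transcripts.

## The model

Space is discretized into a lattice of voxels; each voxel carries a state
$\sigma_i \in \{\varnothing, 1, \dots, n\}$ — unassigned, or owned by one of
$n$ cells.  The number of cells is fixed by an initial nuclear
segmentation, supplied as per-transcript nuclear labels: voxels holding
nuclear transcripts seed the cells, and a prior with retention probability
$p_\text{nuc} = 0.8$ penalizes moving a nuclear transcript to any other
assignment (the remaining mass is spread flatly over alternatives, so the
ratio between two non-matching assignments is 1 and only matched/unmatched
transitions contribute).

Transcript positions follow an inhomogeneous Poisson point process whose
intensity for gene $g$ at a point inside cell $c$ is
$\tau_g^{bg} + \tau_{gc}$, and $\tau_g^{bg}$ alone in unassigned space.
Writing $\nu_c$ for the volume of cell $c$, the log-likelihood is

$$
\sum_{g}\sum_{c} -\nu_c(\tau^{bg}_g + \tau_{gc})
\;-\; \sum_g \tau^{bg}_g \,\nu_\varnothing
\;+\; \sum_{j=1}^{M} \log\!\big(\tau^{bg}_{g_j} + \tau_{g_j \sigma(i(s_j))}\big) .
$$

The middle term — background exposure of unassigned space — makes the
background rate identifiable; a convenient consequence is that the total
background exposure is $\tau^{bg}_g \cdot V_\text{tot}$, a constant in
$\sigma$, so boundary-flip likelihood deltas reduce to the flipped cells'
rate column sums plus the point terms of transcripts in the flipped voxel.

Cell rates are governed by a hierarchical Gamma mixture with $k$
components (interpretable as broad cell types):
$\tau_{gc} \sim \text{Gamma}(\alpha_{g z_c}, \beta_{g z_c})$,
$z_c \sim \text{Categorical}(\pi)$, with Gamma priors on the shapes, a
Normal prior on $\phi_{gt} = -\log \beta_{gt}$, and a shared hyper-rate $h$
controlling overall dispersion.  Marginally the per-cell counts are
negative binomial,
$X_{gc} \sim \text{NB}(\alpha_{g z_c},\, \nu_c / (\nu_c + \beta_{g z_c}))$,
which is what makes the Gibbs updates below conjugate.  Cell volumes get a
per-component log-normal model so that systematically large and small cell
types are captured.

Finally, RNA demonstrably leaks from cells.  Each transcript therefore has
a latent true position $s_i$ tied to its observed position $s_i'$ by a
Normal-mixture diffusion prior
$\rho\, N(s_i', \sigma_a^2 I) + (1-\rho)\, N(s_i', \sigma_b^2 I)$ with
$\rho = 0.2$, $\sigma_a = 4\,\mu m$, $\sigma_b = 0.5\,\mu m$: most
transcripts sit essentially where observed, a fifth may have drifted
several micrometres.  Latent positions are resampled by a random-walk
Metropolis step whose acceptance ratio multiplies the mixture prior ratio
by the point-term ratio of the voxels involved.  For flat (single-layer)
data the mixture densities are two-dimensional; using the 3-d normalization
on a z-slice would silently re-weight the two components.

## Sampling boundaries with detailed balance

Boundary proposals follow the cellular-Potts recipe: maintain the pool of
ordered von Neumann voxel pairs $(i, j)$ with $\sigma_i \ne \sigma_j$, draw
one uniformly, and propose writing $\sigma_i$ into $j$ — or, with
probability $0.05$, the unassigned state (a "bubble" proposal, which makes
the popping and reforming of inter-cell vacuoles mutually reversible).
Because this is posterior sampling rather than energy minimization
(temperature fixed at 1), the acceptance probability must weight the
posterior ratio by the proposal-density ratio $q(\sigma|\sigma') /
q(\sigma'|\sigma)$.  That ratio is computed exactly: the probability of
proposing a given new state at voxel $j$ sums the copy branches over
neighbors already carrying that state and, for bubbles, the bubble branch
over all mismatched edges into $j$, normalized by the pool size — before
the flip for the forward move, after it for the reverse.  A move whose
reverse has zero probability (for instance filling the last voxel of an
isolated vacuole strictly inside a cell, which leaves no mismatched edge
targeting that voxel) is rejected outright, which is exactly what
reversibility demands.

Three guards are applied before any probability is computed:

* **Annihilation prohibition** — a cell reduced to one voxel cannot lose
  it; cells can never be reborn, so their death is irreversible.
* **Local connectivity** — a flip may not change the number of
  Moore-connected components of either affected cell within the Moore
  neighborhood of the target voxel (the articulation-point test).  This is
  the sufficient condition for detailed balance in connectivity-preserving
  lattice samplers; the test includes the target voxel itself in the
  neighborhood subgraph.  The unassigned state is exempt, which is what
  bubble proposals compensate for.
* **Perimeter bound** — on every z-layer, a cell's perceived perimeter must
  stay within $b \cdot 2\sqrt{\pi \cdot \text{area}}$ of the equal-area
  disk circumference, $b = 1.3$.  The perceived perimeter is the in-plane
  Moore mismatch tally scaled by a constant $\xi$ that is calibrated once
  by rasterizing disks of radius 10–100 voxels and regressing the true
  circumference on the tally ($\xi \approx 0.324$; the tally is
  proportional to smoothed boundary length, but the proportionality
  constant is geometry that must be measured).  One refinement proved
  necessary: a rough boundary's mismatch tally is not exactly
  scale-invariant, so immediately after a resolution doubling a cell can
  sit a few percent over the bound, and a strict reject-if-violating rule
  then freezes it there forever (every one-voxel repair still violates).
  The engine therefore rejects a move only if the resulting excess is
  positive *and* not smaller than the current excess — identical behavior
  anywhere inside the valid set, which stays closed, while letting cells
  relax back under the bound after refinement.

Two structural facts about this chain are worth knowing.  First, a voxel
can only be proposed if a mismatched edge targets it, so the outermost
voxel of a cell pressed against the lattice boundary (whose only neighbor
is its own cell) is frozen — on a $6 \times 1$ toy this pins one cell to
each end, and the package's detailed-balance audit enumerates exactly that
reachable class.  Second, in one dimension interior voxels are never
proposal targets, so the articulation guard only becomes load-bearing in
two dimensions; the audit exercises it on a $3\times3$ toy whose reachable
state class is enumerated with independently re-implemented move rules.

Sampling proceeds on a coarse-to-fine schedule: $4\,\mu m$ voxels in a
single z-layer, then $2\,\mu m$, then $1\,\mu m$ (with z-layers 1, 2, 4 for
3-d data; flat data keeps one layer, and only the in-plane axes are
subdivided since there is no z extent to split).  Resolution doubling
copies each voxel's state into its children, leaving every cell's region
and volume unchanged.  Each stage runs 200 boundary sweeps by default (one
sweep = as many proposals as there are pool edges), interleaved with one
Gibbs parameter sweep per boundary sweep and a repositioning sweep every 5
boundary sweeps.

A checkerboard schedule (bins subdivided into four sub-quadrants, cycled
phase by phase) restricts same-phase proposals to well-separated targets so
that batches could be evaluated concurrently; the engine tracks per-phase
eligible edges and counts same-cell conflicts, warning when the bin size is
too small for the cells.  Batches are executed sequentially on one CPU —
the contract that matters is distributional equivalence to sequential
evaluation, which conflict-freedom guarantees; thread- or GPU-level
execution is out of scope.

## Parameter inference

With boundaries fixed, all parameters have conjugate Gibbs updates:

* $z_c$: categorical over components, weighting $\pi_t$ by the NB marginal
  of the cell's count vector (and optionally the volume model).
* $\tau_{gc} \sim \text{Gamma}(\alpha + X_{gc},\, \beta + \nu_c)$;
  $\tau^{bg}_g \sim \text{Gamma}(e_0^{bg} + X^{bg}_g,\, f_0^{bg} +
  V_\text{tot})$ — the background is exposed over the whole lattice.
* $\alpha_{gt}$: Chinese-restaurant-table augmentation
  $\ell_{gc} \sim \text{CRT}(X_{gc}, \alpha)$ gives
  $\alpha_{gt} \sim \text{Gamma}(e_0 + \sum \ell,\; h - \sum \log
  \beta/(\nu_c + \beta))$, then
  $h \sim \text{Gamma}(e_0 + mk,\, f_0 + \sum \alpha)$.
* $\phi_{gt} = -\log\beta_{gt}$: Polya-Gamma augmentation
  $\omega_{gc} \sim \text{PG}(X_{gc} + \alpha,\, \log\nu_c + \phi)$ gives a
  Normal update with precision $\gamma + \sum\omega$ and mean
  $\text{var}^* \sum[(X_{gc} - \alpha)/2 - \omega_{gc}\log\nu_c]$ — the
  canonical PG form for the NB likelihood with $r \equiv \alpha$.
* Volume model: Normal–Gamma conjugate updates on log-volumes per
  component (the scale parameter is treated as a precision, which keeps the
  Gamma prior conjugate); $\pi \sim \text{Dirichlet}(1 + \text{occupancy})$.

No Polya-Gamma sampler is available as an R dependency, so the package
ships its own: a truncated sum-of-Gammas representation
($\text{PG}(b, c) = \tfrac{1}{2\pi^2}\sum_k \text{Gamma}(b,1) /
[(k - \tfrac12)^2 + c^2/4\pi^2]$, 200 terms) with a deterministic
correction equal to the dropped tail's mean, switching to a moment-matched
Normal for $b \ge 30$ where the distribution is effectively Gaussian.  The
truncation bias in the mean is below $2\times10^{-4}$ at $b = 1$, an order
of magnitude under the Monte-Carlo noise of the package's own moment
checks.  Both samplers are verified against closed forms: the CRT mean
$r(\psi(r+n) - \psi(r))$ and the PG mean $\tfrac{b}{2c}\tanh(c/2)$.

Hyperparameter defaults ($e_0 = f_0 = e_0^{bg} = f_0^{bg} = \gamma =
\alpha_0 = \beta_0 = 1$, $\mu_0 = \log 200\,\mu m^3$, $\sigma_0 = 1$,
$k = 10$) are weakly informative implementation choices, all exposed in
`prior_config()`; at realistic transcript counts the posterior is
insensitive to them.  $\pi$ is resampled by default
(Dirichlet–multinomial conjugacy) with a switch to hold it uniform.

## Evaluation metrics

**Spurious co-expression.**  Nuclear segmentation is an easier problem, so
gene pairs whose conditional co-expression
$C_{ij} = |P_i \cap P_j| / |P_j|$ (with $P_i$ the set of cells expressing
gene $i$) inflates at least 1.5-fold under deliberately crude nuclear
expansion are labeled spurious; a method is then scored by its
co-expression on those pairs relative to nuclear segmentation.  Ratios are
computed directionally, matching the defining formula.  To stop the metric
being gamed by under-assignment or cell-count inflation, counts are first
down-sampled: cells with at least 50 transcripts are redrawn
$\text{Multinomial}(50, \text{observed proportions})$, so every cell
contributes exactly 50 transcripts.  Pairs with zero nuclear co-expression
after down-sampling are excluded from ratios and reported separately.

**Random-walk proximity.**  On the Delaunay triangulation of cell
centroids (x/y only — the data are quasi-3-d; degenerate point sets are
perturbed by a deterministic $10^{-9}$ jitter), cells of a chosen type are
made absorbing and the expected hitting time solves the sparse system
$(I - Q)\,t = 1$.  Transient cells with no path to absorption are flagged
infinite.  To remove the influence of local composition, each cell is
first sent on a $k$-step random walk (defaults $k = 10$, 100 repeats) and
$t$ at the endpoint is averaged as a background.  The background walk
moves over non-absorbing cells only.  The alternative — letting walks
terminate on absorbing cells with remaining hitting time 0 — looks natural
but is ruled out by the identity
$t(X_0) = E[\min(T, k)] + E[t(X_k);\, T > k]$: that background is *always*
smaller than $t$, so every relative score would exceed 1 and the measure
could never read "as expected under random organization".  Walking over
transient cells instead matches the intended reading — reposition the cell
among its non-tumor neighbors, then ask how close to tumor it is — and
yields scores near 1 for well-mixed labels and below 1 for genuinely
tumor-adjacent types.  The terminate variant remains available as an
option.

## The synthetic generator

`generate_tissue()` draws tissue from (a superset of) the model's own
assumptions: Poisson-disk cell centers, per-cell areas log-normal around a
mean radius of $8\,\mu m$, cell regions rasterized at $1\,\mu m$ from the
radius-clipped Voronoi partition (compact, convex-ish shapes that satisfy
the perimeter bound by construction), component-structured Gamma rates (3
components with 10 marker genes each; marker and background mean rates 0.1
and 0.005 transcripts$/\mu m^3$, giving roughly 220 transcripts per cell —
typical of a targeted panel), uniform-within-cell Poisson placement,
uniform background noise at $5\times10^{-3}$ transcripts$/\mu m^3$
(about 2% of transcripts), and the Normal-mixture diffusion above.
Nuclear labels are given to transcripts generated inside the central disk
holding 35% of each cell's area, emulating a nuclear segmentation input
rather than perfect supervision.

What the generator deliberately omits: optical crowding, probe-efficiency
differences between genes, platform-specific noise signatures,
subcellular RNA localization, and irregular (non-convex) cell shapes.
Passing the end-to-end recovery checks therefore demonstrates that the
inference machinery is correct and well-calibrated under the model's own
assumptions — not that segmentation of real tissue reaches the same
accuracy.

## Problem sizes and numerical choices in the test suite

The shipped checks run at deliberately modest scale, chosen to exercise
every code path while keeping the suite fast: the detailed-balance audits
use $10^6$–$2\times10^6$ proposals against exhaustively enumerated
posteriors (total-variation threshold 0.02, with negative controls showing
the proposal-ratio and articulation safeguards are load-bearing);
augmentation moments use $2\times10^5$ draws per grid point against
closed forms (3 Monte-Carlo SE); Gibbs recovery uses 500 cells, 5 genes, 3
components with boundaries fixed to truth (rate correlation > 0.95,
component agreement > 0.9, shape/scale errors within 20%); and the
end-to-end run segments the default 50-cell tissue with diffusion and
background on, requiring at least 85% of non-background transcripts
assigned to their true cells and a predicted/true cell-count ratio within
[0.9, 1.2].  Incremental likelihood deltas are required to match full
recomputation within $10^{-8}$; cached tallies must equal from-scratch
recounts exactly; down-sampled totals must equal 50 exactly.

Other numerical conventions: 0-based voxel indices with half-open
$[\text{lo}, \text{hi})$ intervals (upper-face points map to the last
voxel); nuclear-initialization ties broken by Moore-neighborhood support
and then smaller label id, with only the largest connected component of a
label retained; all randomness flows through R's RNG, so a seed makes the
whole pipeline — including the C++ engine — bit-reproducible; the final
segmentation is the chain's last state rather than a posterior average,
matching how a single reported segmentation is used downstream.

## Limitations

The number of cells is fixed by the nuclear input: missed nuclei cannot be
discovered, and spurious nuclei are only emptied down to the
one-voxel/ten-transcript floor, not removed.  Boundary uncertainty is
available in principle from the chain but only the final state is
exported.  The diffusion parameters are fixed rather than inferred —
jointly fitting them is unstable, as everything can be explained as wide
diffusion.  Hexagonal or anisotropic in-plane lattices are unsupported,
and the expression model assumes within-cell spatial uniformity of each
gene, which subcellular localization violates in ways that mostly average
out at segmentation scale.
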