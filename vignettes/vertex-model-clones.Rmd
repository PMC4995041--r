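---
title: "Patterned bond tension and clone shape in a growing epithelium"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patterned bond tension and clone shape in a growing epithelium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiclone)
```

## The model

`epiclone` describes the apical junction network of an epithelium as a
planar tiling of polygonal cells. A mechanical state is a set of vertex
positions; balanced configurations are local minima of the work function

$$
E \;=\; \frac{K}{2}\sum_\alpha \left(A_\alpha - A^{(0)}\right)^2
\;+\; \sum_{\langle ij\rangle} \Lambda_{ij}\,\ell_{ij}
\;+\; \frac{\Gamma}{2}\sum_\alpha L_\alpha^2 ,
$$

where $A_\alpha$ and $L_\alpha$ are the area and perimeter of cell
$\alpha$, $\ell_{ij}$ the length of the junction (cell bond) between
vertices $i$ and $j$, $K$ the area elastic modulus, $\Lambda_{ij}$ the bond
line tension, and $\Gamma$ the perimeter elasticity. Internally the model is
nondimensionalized with $K = A^{(0)} = 1$, so lengths are measured in units
of $\sqrt{A^{(0)}}$ and the mechanics is fully specified by two
dimensionless numbers, $\bar\Lambda = \Lambda/(K (A^{(0)})^{3/2})$ and
$\bar\Gamma = \Gamma/(K A^{(0)})$.

The defaults are $\bar\Lambda_0 = 0.12$ and $\bar\Gamma = 0.04$. These are
the canonical parameters of the vertex-model framework this package builds
on, for which the stress-free ground state is a regular hexagonal packing;
the source work does not prescribe values, so this choice is exposed in
`model_parameters()` rather than hard-wired. At these values the stationary
hexagon edge length is about $0.471\sqrt{A^{(0)}}$
(`stationary_edge_length()`), and cells in the bulk are correspondingly
smaller than their preferred area — tension compresses them.

## Clones and patterned tension

A clone is the marked progeny of a single founder cell. Tension patterning
follows two dimensionless ratios: $\alpha = \bar\Lambda_C/\bar\Lambda_0$
rescales bonds whose both neighbouring cells are clone members, and
$\lambda = 2\bar\Lambda_B/(\bar\Lambda_0 + \bar\Lambda_C)$ rescales the
clone-border bonds (exactly one clone neighbour). The reference case is
$\alpha = \lambda = 1$; case I varies $\lambda$, case II varies $\alpha$,
case III combines $\lambda = 2$ with $\alpha = 0.5$. The pattern activates
only once the clone exceeds 8 cells; below that all bonds carry
$\bar\Lambda_0$. Two margin conventions were genuinely open and are decided
here: border tension $\bar\Lambda_B$ applies only to interior clone/non-clone
interfaces, and a margin bond (one adjacent cell) carries $\bar\Lambda_C$
when that cell is a clone member, $\bar\Lambda_0$ otherwise.

## Growth protocol

Growth starts from a 4 × 4 patch of 16 regular hexagons with the clone
founded in the central cell — a deterministic founder reduces ensemble
variance and the central position minimizes margin artefacts. Each step
picks one cell uniformly at random and divides it in a direction drawn
uniformly from $[0,\pi)$: the cell's preferred area is doubled, the network
relaxed, the cell split by the straight line through its area centroid, both
daughters revert to preferred area 1 and inherit the clone and compartment
labels, and the network is relaxed again. The generation counter is
$G = \log_2(\text{cells}/16)$, so "five generations" means 512 cells; this
is the unique definition consistent with a 16-cell initial patch at
$G = 0$. Because division is uniform, the clone *fraction* is a
martingale: at $G = 4$ (256 cells) the expected clone size is
$256/16 = 16$ regardless of mechanics, which the test suite uses as a
self-calibrating check of the growth bookkeeping.

A division line that would cross the boundary closer than 2 % of a bond's
length to an existing vertex, or whose two crossing points would lie closer
than $0.1\sqrt{A^{(0)}}$, is rejected and the angle nudged deterministically
(golden-angle increments, bounded retries): sliver daughters destabilize the
subsequent relaxation without changing the statistics of interest.

## Relaxation and junction remodeling

Balanced states are found by L-BFGS with a backtracking (Armijo) line
search, implemented in compiled code; the energy never increases, and a step
that would invert a polygon (non-positive shoelace area) is rejected by the
line search, which implements degenerate-step halving at negligible cost.
Convergence is declared when the largest per-vertex force norm falls below
`grad_tol` (default $10^{-6}$ for `relax()`; growth uses $10^{-4}$, set in
`growth_config()`, since division-scale forces are of order $10^{-1}$ and
the shape statistics are insensitive below that). Note that with energies of
order 10 in double precision the achievable force residual bottoms out
around $10^{-8}$–$10^{-10}$ depending on system size.

Topological moves fire during the descent, between minimization chunks:

* **T1 (neighbour exchange).** A bond shorter than $0.05\sqrt{A^{(0)}}$
  joining two 3-valent vertices flips its adjacency and is re-created
  perpendicular at length $0.1\sqrt{A^{(0)}}$ (shorter fallbacks if the
  default would invert a crowded neighbour). Interior bonds flip between
  their two cells; margin bonds flip against the outer face, pulling one
  vertex into the tissue. The shortest eligible bond is processed first.
* **Margin collapse.** A short margin bond with a 2-valent endpoint merges
  its endpoints (the merged vertex stays at most 3-valent).
* **T2 (cell extinction).** A cell is extruded — collapsed to a single
  vertex — when its area falls below $0.01 A^{(0)}$; a triangle is also
  extruded when one of its bonds falls below the T1 trigger, since
  triangles cannot flip. Mutually degenerate cells (adjacent collapsing
  triangles that would block each other's removal) are extruded together as
  a cluster. This is what eliminates clone cells when clone-bulk tension is
  high (case II, $\alpha = 2$).
* **Rosette formation.** Extrusion can leave a vertex with four or more
  bonds, where the 3-valent T1 move is undefined; a short interior bond
  pinned by such a vertex collapses into a single multi-fold vertex, the
  way crowded junctions resolve into rosettes in epithelia. If a dividing
  cell is itself extruded during the pre-division relaxation, that division
  is abandoned.

In the rare event that no feasible move unjams a shrinking bond the
realization aborts with a diagnostic; `run_ensemble()` records such
realizations as failures and excludes them from means rather than silently
retrying.

## The shape statistics

**Boundary roughness** $w(L)$ quantifies how far a compartment boundary
deviates from a straight line at scale $L$. The boundary is the ordered path
of bonds whose adjacent cells carry different compartment labels; $h(x)$ is
its orthogonal distance from the axis through the path's end points.
Windows of axis length $L$ slide along the path, one per boundary vertex
(windows truncated by the path ends are dropped); within a window the
deviation $(h - \bar h)^2$ is averaged over the vertices inside, and $w(L)$
is the square root of the across-window mean, normalized by the tissue's
mean bond length $\bar\ell$. The root is taken so the statistic has units of
length and can be normalized by $\bar\ell$; the mean-square form is
retrievable as $w^2$.

**Clonal roughness** measures the excess contour length of a clone border.
For all border-vertex pairs whose straight distance falls in the bin
$[(L-\tfrac12)\bar\ell,\,(L+\tfrac12)\bar\ell)$, the contour length $s$ of
the *shorter* arc between them is collected, and the statistic at $L$ is
$(\bar s - \bar d)/\bar\ell$. The shorter-arc convention is the only one for
which the circle limit stays finite at all $L$; bins are centred on integer
multiples of $\bar\ell$ and pairs are enumerated exhaustively. The statistic
is only defined when the clone border is a single simple loop; fragmented
clones are reported as unmeasurable, never as zero. For segmented inputs the
normalization $\bar\ell$ is always computed from the whole tissue, not from
the boundary itself. Clones of at most 40 cells are excluded by the analysis
filter (`filter_clones()`), matching the size cutoff used for segmented
tissue.

## The ablation assay

`ablate_bond()` sets one bond's line tension to zero — the junction remains
in the network, so the area and perimeter terms are untouched and the force
imbalance created on each freed vertex is exactly the severed tension
$\Lambda$. `relax_overdamped()` integrates $\dot x = F/\mu$ (forward Euler,
friction $\mu = 1$ per vertex, `dt` $= 10^{-3}$) and records the distance
$d(t)$ between the freed vertices. At $t \to 0^+$ this gives
$\dot d(0^+) = 2\Lambda/\mu$, so the initial recession velocity `v0`
(estimated from the first integration interval) is a direct, linear readout
of bond tension; the estimator's sensitivity to `dt` is below 0.5 % at the
default step. The stored trace is normalized by $\bar\ell$, while `v0` is
reported as the slope of the absolute distance so that the
$2\Lambda/\mu$ law holds exactly; ratio readouts between bond classes are
unaffected by this choice. On a tissue grown with $\lambda = 2$, severing
clone-border bonds yields twice the initial velocity of bulk bonds — the
in-silico analogue of the two-fold experimental readout — which the
acceptance checks verify to within 5 %.

Destroying the bond's perimeter contribution as well would confound the
readout with $\bar\Gamma$; that mode is deliberately not implemented.
Active resealing after ablation (retraction of the cut) is out of scope.

## Synthetic fixtures and what they do (and do not) show

`make_interface_fixture()` emulates a segmented two-compartment tissue: a
brick-offset lattice (combinatorially hexagonal — every interior vertex is
3-valent — with all bonds of length 1) whose compartment labels follow a
lateral random-walk interface with per-column steps
$\mathcal N(0, \sigma^2)$ rounded to cell rows. The brick geometry is
chosen deliberately: on a true honeycomb no edge path is collinear, so a
straight interface with $w(L) = 0$ exactly — the natural null case for the
estimator — is only realizable on a lattice with collinear edge runs. Large
steps can strand a cell touching its compartment only at a corner; such
cells are relabeled so both compartments stay edge-connected and the
interface remains one open path. `make_clone_fixture()` labels disc- or
star-shaped clones on a regular hexagonal lattice, with the region scaled to
hit the requested clone size exactly.

Fixtures are *not* mechanically relaxed, on purpose: experimental
segmentations are not energy minima, and the statistics must not assume
relaxed geometry. Ground truth comes from `ground_truth_roughness()`: zero
for straight interfaces, a Monte-Carlo average over the raw height process
for random-walk interfaces, and the arc–chord closed form
$s = 2R\,\mathrm{asin}(L/2R)$ for the circle equivalent to a disc clone.
The continuum closed form is a *lower bound* for the lattice disc: a border
that follows hexagon edges is a staircase whose detour factor is at most
$2/\sqrt3$ per unit straight distance, and the tests bound the excess
accordingly rather than pretending the discretisation error vanishes.
Passing these checks shows the estimators recover known shapes from
segmentation-like input; it does not validate the upstream image
segmentation, which is outside this package.

## Problem sizes and determinism

The heavy ensemble checks are scaled to desk hardware: the neutral-growth
(martingale) check uses at least 200 realizations at $G = 4$ (256 cells),
and the tension-case comparison uses 10 realizations per condition at
$G = 5$ with size-matched roughness at $N = 30$ cells; `scripts/acceptance.R`
reports the same quantities at comparable sizes. All randomness flows
through R's generator: realization $i$ of an ensemble uses
`base_seed + i`, so every snapshot, CSV and figure table is bit-reproducible
from the seed, and every command-line run writes a manifest with the
resolved configuration and package version.

## Known limitations

* Open (free) tissue margin only; no periodic boundaries, external pressure,
  curved geometry, motility or active fluctuations.
* Overdamped relaxation is the only dynamics; there is no viscoelastic
  rheology beyond it, and no resealing after ablation.
* Division rates are uniform across cells; there is no mechanical feedback
  on proliferation and no cell-cycle model.
* Under strong clone-bulk tension ($\alpha = 2$) cell elimination and clone
  fragmentation compete: a clone that is eroded quickly ends as a *single*
  patch of one to few cells, which a strict component count scores as
  coherent even though no coherent clone ever formed. The fragmentation
  *fraction* at fixed ensemble size is therefore a noisy readout of this
  phenotype (probability near one half at the default parameters); the
  reduction in clone cell number is the robust one.
* The 7-cell rosette border on a hexagonal lattice has 18 bonds (three outer
  edges per petal); shape statistics at $L \lesssim 2\bar\ell$ are dominated
  by such lattice-scale geometry and should be read accordingly.
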