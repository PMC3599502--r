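---
title: "Exact structure alignment under the RMSD: models, algorithms, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact structure alignment under the RMSD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmsdalign)
```

# The model

A structure is an ordered sequence of 3D points — the Cα trace, one point
per residue. An alignment between traces $P = (p_1,\dots,p_n)$ and
$Q = (q_1,\dots,q_m)$ is a partial bijection $f$; it is *sequential* when it
preserves residue order on both sides. Its quality is the RMSD after
optimal rigid superposition of the mapped pairs,

$$\mathrm{RMSD} = \min_T \sqrt{\tfrac{1}{\ell}\sum_i \lVert T(q_{j(i)}) - p_i\rVert^2},$$

minimized over proper rigid motions $T$ (rotation with determinant $+1$
plus translation; reflections are excluded, as is standard for molecular
superposition). The package convention is fixed once: **transforms always
map Q-side points onto P**, and the tests assert it.

Two dual problems are solved throughout:

* **LCP**: maximize the alignment size $\ell$ subject to
  $\mathrm{RMSD} \le \theta$;
* **MAD**: minimize the RMSD subject to $|f| = \ell$ exactly.

Both are hard in general. Each module below removes one source of
hardness — fixing the transform, fixing the correspondence, or
discretizing the transform space via integrality — and solves the residual
problem exactly.

# Fixed superposition: dynamic program and min-cost flow

With the transform $T$ known, pair costs
$d_{ij} = \lVert T(q_j) - p_i \rVert^2$ are constants. The sequential case
fills the three-index table $M[i,j;k]$ — the minimum total cost of $k$
order-preserving matches within the prefixes of length $i$ and $j$ — by

$$M[i,j;k] = \min\big(M[i{-}1,j{-}1;k{-}1] + d_{ij},\; M[i,j{-}1;k],\; M[i{-}1,j;k]\big),$$

in $O(nmk)$ time. One printed form of this recurrence uses "max" over the
three branches; since $M$ is defined as a minimum cost, that cannot be
meant literally, and the implementation uses min — the brute-force
equivalence tests would fail instantly otherwise. LCP reads off the
largest $k$ with $M[n,m;k] \le k\theta^2$; MAD reads $M[n,m;\ell]$.
Traceback tie-breaking is deterministic: the diagonal (match) move is
preferred, then the $j$-skip, then the $i$-skip.

The non-sequential case is a min-cost bipartite matching, solved by
successive shortest-path augmentation (Bellman–Ford on the residual graph;
all edge costs are nonnegative, so no negative cycles arise). Each
augmentation step yields the optimal matching *of its own size*, so a
single run answers both the MAD query at $\ell$ and the LCP sweep over all
$k$. The solver is implemented in the package: no pre-installed R package
provides min-cost flow, and the desk-scale graphs here (tens of nodes) do
not justify one.

On integer inputs with an exact (e.g. identity or lattice) transform, all
costs are exact integers in doubles and the threshold test
$M \le k\theta^2$ uses a $10^{-12}$ relative epsilon — effectively exact.

# Known correspondence: the translation-space arrangement

In model superposition the residue correspondence $F$ ($l$ pairs) is given
and only the subset and the transform are free. Under pure translations
the residual of pair $i$ depends only on the displacement
$w_i = q'_i - p'_i$: pairs $i$ and $j$ swap their residual order exactly on
the perpendicular bisector plane of $w_i$ and $w_j$ in displacement space.
The $\binom{l}{2}$ planes (one per pair of pairs; equal displacements yield
no plane and are recorded as permanently tied) partition translation space
into cells, and within a cell the residual *ordering* of all $l$ pairs is
constant. The optimal $\ell$-subset is therefore always the first $\ell$
pairs of some cell's ordering, its optimal translation is minus the mean of
its displacements, and scanning all cells is exact — the tests verify
equality with subset brute force on every random instance tried.

Note the plane count: separating every pair of pairs requires
$\binom{l}{2}$ planes, although a linear count is sometimes quoted; at desk
scale the difference is irrelevant and only the complexity bound changes.

**Cell enumeration.** Exact arrangement construction is avoided. Witness
points are generated from all plane triples (vertices), plane pairs (edge
points at three stations along each intersection line), and single planes
(both sides), each perturbed into the adjacent cells by solving for a
displacement with prescribed signed distances to the incident planes — the
step is half the distance to the nearest non-incident plane, so no other
plane is crossed. Far-field points on a large enclosing sphere cover
unbounded cells of near-parallel families. Witnesses are deduplicated by
sign vector. For $k$ planes in general position this realizes exactly the
$1 + k + \binom{k}{2} + \binom{k}{3}$ cells of the counting formula (tested
up to $k = 6$), and the brute-force equivalence tests enforce coverage on
the instances that matter. Residual ties within a cell are broken by pair
index. The incremental $O(1)$-per-neighbor ordering update exists in
theory; each cell is instead sorted independently — same results, simpler,
and after vectorization (rank computation by batched pairwise comparisons,
subset scoring by running sums) a full solve at $l = 6$ takes ~7 ms.

**Full rigid motions.** The exact treatment of rotations leads to sign
conditions of degree-six polynomial systems in nine variables, which is out
of scope here. `mad_given_mapping_rigid_sampled` substitutes a uniform ZYZ
Euler-angle grid: for each grid rotation the exact translation solver
runs, and the best result is returned **labelled heuristic**
(`exact = FALSE`). Its RMSD is an upper bound on the true rigid optimum,
within 10% of subset-brute-force-plus-Kabsch at a 15° grid on the tested
instances, and converging as the grid refines. It is plumbing for
experimentation, not a claim.

# RMSD bounds for integer coordinates

Three bounds calibrate and terminate the other algorithms. Two of them are
garbled by typesetting in their printed statements and were reconstructed
from their proofs; the reconstructions are guarded by enumeration tests.

* **Pairwise-distance lower bound.** Rigid motions preserve intra-structure
  distances, so for any permutation $\Pi$ of the $\ell$ mapped pairs,
  pairing index $\Pi(i)$ with $\Pi(i + \lfloor\ell/2\rfloor)$,
  $$\sqrt{\tfrac{1}{2\ell}\sum_i \lvert d^P_i - d^Q_i \rvert^2} \le \mathrm{RMSD},$$
  with equality in the two-point case ($\mathrm{RMSD} = |d^P - d^Q|/2$).
* **Resolution gap.** With integer coordinates bounded by $c_{\max}$,
  squared distances are integers at most $12c_{\max}^2$, so two unequal
  distances differ by at least
  $\sqrt{12c_{\max}^2} - \sqrt{12c_{\max}^2 - 1}$, and the smallest
  possible nonzero RMSD is
  $$\mathrm{gap}(c_{\max}, \ell) = \frac{\sqrt{12c_{\max}^2} - \sqrt{12c_{\max}^2-1}}{\sqrt{2\ell}}.$$
  Exhaustive enumeration of all two-point integer instances at
  $c_{\max} = 1$ reproduces this value exactly.
* **Upper bound.** All coordinates in $[-c_{\max}, c_{\max}]^3$ give
  $\mathrm{RMSD} \le \sqrt{48}\,c_{\max} = 4\sqrt3\,c_{\max}$
  (equivalently $\ell\,\mathrm{RMSD}^2 \le 48\,\ell\,c_{\max}^2$), checked
  on $10^4$ randomized instances.

# MAD from an LCP solver: binary search

On integral inputs, MAD reduces to $O(\log \ell c_{\max})$ LCP decisions:
bisect the threshold on $[0, \ell c_{\max}]$, shrink the upper end when the
LCP solution has size $\ge \ell$, and stop when the interval is narrower
than the resolution gap. The printed upper start $\ell c_{\max}$ is kept as
the default for fidelity; `upper_start = "lemma6"` switches to the tighter
$4\sqrt3\,c_{\max}$, which matters for $\ell \ge 7$. One deliberate
addition: the solver is called once at the upper end before bisecting, so
"the most recent feasible solution" is always defined (and instances whose
optimum exceeds the printed interval fail loudly instead of looping). The
bisection count excludes this seed call and never exceeds
`iteration_budget(c_max, ell)` $= \lceil \log_2(\ell c_{\max}/\mathrm{gap})\rceil$
(e.g. 13 at $\ell = 4$, $c_{\max} = 10$).

**The termination assumption, probed.** The argument that the search may
stop rests on distinct achievable RMSD values being spaced at least one gap
apart. The package's empirical probe (see `test-bounds.R`) shows this is
*stronger than what holds*: consecutive distinct two-point RMSD values of
the form $(\sqrt a - \sqrt b)/2$ can lie far closer together than the gap,
even though every nonzero value individually clears the gap. The spacing
property is therefore not relied on for correctness claims; instead the
reduction is certified directly against the brute-force MAD oracle (50/50
random tiny instances exact, within budget). Should an instance family ever
defeat the interval criterion, the oracle cross-check is the test that
would catch it. Solutions larger than $\ell$ are re-reported at exactly
$\ell$ by dropping the largest-residual pairs and re-superposing — a
presentation choice validated by the same oracle equality. The reduction
refuses non-integral inputs, where termination is not guaranteed.

# The exact lattice enumeration

For integral coordinates the optimal MAD transform is determined by
lattice quantities: the centering translations $t_P, t_Q$ are centroids of
$\ell$ integer points — coordinates $I/\ell$ with
$|I| \le \ell c_{\max}$ — and each entry of the $3{\times}3$ correlation
matrix of the centered subsets is $I/\ell^2$ with
$|I| \le 4\ell^3 c_{\max}^2$. Enumerating all lattice points, deriving each
rotation by SVD (with determinant sign correction; unrealizable matrices
are processed harmlessly), mapping $q \mapsto R(q - t_Q) + t_P$, and
solving the fixed-transform problem at each yields the exact optimum in
pseudo-polynomial time.

The full lattice is astronomically large even for toys (the matrix lattice
alone is $(8\ell^3 c_{\max}^2 + 1)^9$ points), so `lattice_spec` carries
explicit numerator sub-ranges, enforces an enumeration budget, and every
result reports the scanned fraction; only full ranges set `exact = TRUE`.
Correctness of the *full* algorithm is instead established by two tested
properties: **membership** — the brute-force-optimal transform's
translations and matrix entries lie on their lattices within bounds,
verified in exact integer arithmetic on 100% of random tiny instances — and
**conditional exactness** — restricting the enumeration to the
oracle-optimal lattice point reproduces the oracle optimum. Together with
the fixed-transform DP's own exactness these imply the full loop would find
the optimum. A single-translation mode ($q \mapsto Rq - t$) mirrors the
compact printed form of the algorithm; it is kept optional because the
composed optimal translation $t_P - R\,t_Q$ need not itself lie on the
$\{I/\ell\}$ lattice, and any observed discrepancy between the modes would
be worth logging.

# Synthetic data: the stated world

`generate_chain` emulates a Cα trace as a random walk with steps of fixed
length `bond = 3.8` (the natural cap on consecutive Cα distances) in
uniform random directions, anchored at the origin, optionally confined to a
ball of radius $O(n^{1/3})$ (`globular = TRUE`, the compact-structure
regime where $c_{\max}$ grows slowly). Coordinates are rounded to integers
after scaling: `scale = 1` (default) keeps $c_{\max}$ small so oracles and
lattices stay tiny for algorithm tests; `scale = 1000` mirrors PDB
three-decimal precision. Rounding moves points by at most $\sqrt3/2$, so
integral chains obey the cap with a $\sqrt3$ slack, which the validator
admits for integral sequences.

`plant_common_fragment` embeds a rigidly moved copy of a fragment between
decoy random-walk flanks, with optional isotropic Gaussian noise, and
returns the ground-truth mapping and transform. On integral chains the
default motion is a *lattice* rigid motion — a proper signed-permutation
rotation plus integer translation — chosen so that a noiseless plant stays
exactly congruent after rounding and is recoverable at $\theta = 0$; a
generic rotation (`lattice_transform = FALSE`) leaves a rounding residual
of roughly $0.5/\mathrm{scale}$ per coordinate, which is itself a realistic
regime but makes exact recovery the wrong test. Noisy plants are not
flagged `protein_mode`, since unbounded noise can stretch a consecutive
distance past the cap.

What the generator does **not** emulate: backbone dihedral statistics,
excluded volume, secondary structure, or any sequence signal. A green test
therefore establishes algorithmic correctness on integer protein-*scaled*
geometry, not biological realism; conclusions about real structures need
real coordinates (via `read_pdb_ca` + `scale_to_integral`).

# Numerical choices

* Rotation validity: orthogonality and $\det = +1$ within $10^{-9}$
  (max-abs); transforms assembled from SVD output use a relaxed $10^{-6}$
  gate to absorb accumulated round-off.
* Degenerate SVD (collinear/planar subsets): any minimizing proper
  rotation is accepted; only the RMSD value is asserted. The determinant
  correction flips the smallest singular direction, so reflections never
  leak through (tested on reflected planar sets).
* Threshold comparisons: exact `<=` semantics with $10^{-12}$ relative
  epsilon on DP/flow costs; $10^{-7}$ absolute tolerance where a Kabsch
  RMSD of an exactly congruent set must count as zero ($\theta = 0$
  queries).
* Ties: DP traceback prefers match, then $j$-skip, then $i$-skip; cell
  orderings break residual ties by pair index — all outputs deterministic.
* Randomness: every generator takes a seed and restores the caller's RNG
  state; rotation sampling is quaternion-uniform on SO(3).

# Known limitations

* The exact sign-condition algorithm for rigid-motion model superposition
  is not implemented (out of scope); the grid heuristic that stands in is
  labelled and bounded but not exact.
* The full lattice enumeration is exact *in principle* but can only be run
  on restricted ranges; exactness at scale is certified compositionally
  (membership + conditional exactness + DP correctness), not by running
  the full loop.
* The brute-force oracles are exponential and refuse instances beyond a
  configurable budget; they exist for verification, not use.
* All-atom superposition, weighted RMSD, gap penalties, and local
  alignment variants are out of scope.
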