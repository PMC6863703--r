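---
title: "Enumerating and matching hydrogen-bond-connected active sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enumerating and matching hydrogen-bond-connected active sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbnetforge)
```

## The problem

Classical computational enzyme design specifies how each catalytic side chain
should interact with the reaction transition state, then searches protein
scaffolds for backbones that can host those side chains. What that
formulation cannot express is connectivity *between* the catalytic side
chains themselves — yet highly active natural and laboratory-evolved enzymes
typically show an extensive hydrogen-bond network linking their catalytic
residues, which preorganizes the site and enables concerted chemistry such as
proton shuffling.

`hbnetforge` works from the opposite direction. The user writes down a purely
two-dimensional "wiring diagram" of an active site: which functional groups
(hydroxyl, phenol, carboxylate, carboxamide, imidazole, guanidinium, primary
amine) the site contains, which ligand sites each group hydrogen-bonds or
covalently bonds to, and which groups bond to each other. The package then

1. **enumerates** all 3D placements of each functional group that realize its
   specified ligand interaction, deduplicated on a coordinate grid;
2. **filters** pairs of placements on every group–group edge and **assembles**
   complete, clash-free networks in which one placement per group satisfies
   every specified interaction simultaneously;
3. **realizes** each placement as full side chains (inverse rotamers) with
   backbone anchor frames;
4. **clusters** networks on the coordinates of their central functional
   groups; and
5. **matches** networks into scaffold backbones with a rigid-body
   transform-hashing search, reporting how often the full specified
   connectivity survives placement.

## The placement model

A hydrogen-bonded pose of a rigid functional-group template has six degrees
of freedom relative to the ligand site. We parameterize them as: the
donor-heavy–acceptor-heavy distance $d$; the donor angle $\theta$
(D–H$\cdots$A); the acceptor angle $\psi$ (base–A$\cdots$H); a torsion about
the acceptor-base axis; a torsion about the H-bond axis; and a spin of the
group about its own interacting bond. Hydrogen-bond acceptance uses window
criteria

$$d_{\min} \le d \le d_{\max},\qquad \theta \ge \theta_{\min},\qquad
\psi \ge \psi_{\min}$$

with defaults $2.6\!-\!3.2$ Å, $120^\circ$, $90^\circ$ — common
structural-biology practice; hydrogen-bond detection thresholds are not a
settled constant in this field, so all four are configuration options. Ranking uses a
deliberately simple continuous score, $-w\,f(d)\,f(\theta)$, a product of
linear ramps peaking at the ideal geometry ($2.8$ Å, $180^\circ$) and
vanishing on the window boundary; only the *ordering* of networks matters
downstream, so the simplest continuous choice is used. Window comparisons
carry a $10^{-6}$ numerical tolerance so poses sampled exactly on a boundary
survive rigid-motion round-trips.

### Grid deduplication and the sampling scheme

Placements are deduplicated on the grid cell of the group's interacting heavy
atom (the contact atom), computed in the ligand's local frame with a
half-away-from-zero rounding rule, at a user-specified spacing (default
$g = 0.2$ Å). Of the six degrees of freedom, three determine the contact
atom's *position* and three only rotate the group about it; which three are
positional depends on the bond direction. The default scheme samples the
positional triple densely (distance every $0.1$ Å, angles every
$4$–$5^\circ$, torsions every $5^\circ$) so that the accessible shell of
contact-atom cells is near-saturated at $g = 0.2$ Å, and subsamples the
orientational degrees of freedom coarsely (3 angle and 6 torsion values,
spins every $60^\circ$), keeping only the best-scoring pose per cell. Under
these defaults one hydrogen-bond interaction yields on the order of
$10^3$–$10^4$ unique placements at $g = 0.2$ Å (about $3\,600$ for a hydroxyl
donating to the toy ketone's carbonyl), and halving the positional step sizes
changes the count by well under a factor of two — the count is controlled by
the grid, not by the sampling density, which is the intended "complete
enumeration at a resolution set by the grid spacing" behaviour.

Because grid keys are integers computed in the ligand's canonical local frame
(defined by its first three non-collinear atoms, with coordinates rounded to
$10^{-9}$ Å), every downstream count is exactly — bit-for-bit — invariant
under a global rigid motion of the inputs.

Covalent attachments (e.g. a nucleophilic lysine forming a carbinolamine)
have one degree of freedom: the torsion about the framing bond of the
attachment site, sampled every $30^\circ$ by default, with the bond built at
$1.5$ Å and the ideal tetrahedral angle, and the amine's remaining
substituents staggered. A tetrahedral attachment carbon leaves little free
volume, so only a few torsions typically survive the clash filter — that is
chemistry, not a failure of sampling.

A steric pre-filter discards placements whose heavy atoms come within
$2.7$ Å of a ligand heavy atom (the interacting pair, and the 1–3 neighbours
of a covalent attachment, exempt). Whether the original method applied any
steric filter between functional groups is not stated; ours is on by default
and can be disabled (`clash_threshold = 0`) to recover pure connectivity
enumeration.

## Network assembly

For every group–group edge, all placement pairs are queried for the specified
hydrogen bond (spatial bucketing internally; the result equals an all-pairs
scan, which the test suite verifies against an $O(n^2)$ oracle), and
placements with no partner are discarded. Networks are then assembled by
backtracking over groups in spec order, candidate placements in
best-score-first order; a group participating in several edges must satisfy
all of them with a single placement. Hydrogen-bonded partner atoms are exempt
from the inter-group clash check. Output is sorted by total score and capped
(default $2 \times 10^6$, comfortably above the largest published network
count) with a warning on truncation.

## Inverse rotamers and the product rule

A side chain is grown backward from its fixed functional group with ideal
bond lengths and angles, sampling every rotatable bond at staggered values
$\{-60^\circ, 60^\circ, 180^\circ\}$ by default, and completing the backbone
with ideal N–CA–C geometry. All sampled torsions — including the final
backbone-placing one — use the same staggered set, keeping the per-bond
product rule exact; no rotamer-library statistics or off-rotamer relaxation
are used because the method needs anchor frames, not an energy model. The
total number of full side-chain realizations of a network is the product over
groups of per-group realization counts, and the suite checks this against
direct enumeration.

## Clustering and matching

Networks are clustered by seeded k-means on the concatenated coordinates of
each group's central (contact) atom in the ligand frame. $k$ interpolates
between two regimes: $k = N$ treats every network independently during
matching, $k = 1$ pools all side-chain conformations into one calculation.
The default target of 250 clusters follows the published balance between
completeness and run time; requested clusters that come out empty reduce the
returned $k'$.

The matcher places networks into scaffold backbones by transform hashing: for
each designable position and each inverse rotamer, the rotamer's backbone
frame is superposed onto the residue (least squares), the implied ligand pose
is derived, and the pose is quantized into a 6-D bin — translation bins
(default $1$ Å) plus quantized canonical-sign quaternion cells (default
$10^\circ$). A match is a bin holding entries for every group at pairwise
distinct positions. Each combination (bounded by a per-bin cap) is rebuilt in
full coordinates in the ligand frame implied by the first group's entry,
clash-checked against the scaffold backbone, and evaluated for completeness:
a match is *complete* iff every specified edge, ligand and group–group,
passes the hydrogen-bond criteria (covalent edges by a $1.2$–$1.8$ Å bond
window). Results are deduplicated on (scaffold, ligand bin, position set);
the representative kept is the combination realizing the most specified
interactions, so a placement is judged by its best rotamer combination.

Four modes cover the standard comparison of matching strategies: `residue`
regenerates each
group's rotamers from its ligand interaction alone (the classical baseline —
most of its matches are partial networks, since residues are treated
independently); `pooled` mixes all networks' rotamers in one calculation;
`clustered` runs one pooled calculation per cluster; `per_network` uses a
single network's rotamers, which by construction can only produce
fully-connected sites. The completion report prints, for each simulation, the
incomplete and complete match counts and the completion rate defined as the
ratio of the two columns (with the rate relative to the total also shown,
since published tables are ambiguous on this point; the column-ratio
convention reproduces all three published percentages: 0.013%, 1.18%,
3.23%).

## Fixtures and what the tests do (and do not) show

Everything is testable without downloads. `make_toy_ligand()` builds three
minimal annotated ligands (a vicinal diol; a ketone + phosphate; a
carbinolamine-like tetrahedral intermediate with a covalent attachment
point); `make_toy_spec()` provides matching wiring diagrams, including a
four-group quartet in the style of an evolved retro-aldolase (covalent
lysine + three polar groups, every group in direct ligand contact).
`make_helix_scaffold()` builds ideal α-helices ($\phi=-57^\circ$,
$\psi=-47^\circ$), and `plant_network_scaffold()` grows short helical
segments outward from each realization's exact backbone frame, producing
scaffolds guaranteed to host a given network — the basis of the
planted-recovery tests, in which the matcher must rediscover the planted
network as a complete match in per-network, clustered ($k=N$) and pooled
modes.

These fixtures emulate the *geometry* of the problem — realistic bond
lengths, angles, steric crowding, covalent attachment — but not the scale or
heterogeneity of real inputs: quantum-chemistry transition-state models,
crystal-structure scaffolds with non-ideal backbone geometry, and
thousand-scaffold libraries. Passing tests therefore demonstrate algorithmic
correctness (oracle equivalence, by-construction completeness, exact
invariances), not that any particular published match count is reproduced;
those counts depend on input sets that are not redistributable at this
scale.

## Numerical choices

* Deterministic everywhere: candidate orderings are lexicographic, ties break
  on stable indices, k-means is seeded (default 2019), and all stochastic
  steps record their seed. Identical inputs give byte-identical outputs.
* Degenerate torsion references (a $180^\circ$ angle upstream of a dihedral)
  are replaced by a deterministic perpendicular; collinear point triples are
  a hard error in the exported `superpose_frames()`, while the matcher uses
  least-squares superposition since real backbone triangles are only
  approximately congruent.
* Problem sizes in the test suite are chosen for desk-scale completeness
  checking: toy pipelines run at $g = 0.4$ Å with a reduced scheme
  (hundreds of placements per group, ~200 networks), while the density and
  convergence checks run one interaction at the full default scheme and
  $g = 0.2$ Å. The acceptance script uses the same sizes.

## Known limitations

* No water-mediated bridges; a bridging-water network member cannot be
  expressed in the wiring diagram.
* Groups are enumerated only from ligand-anchored interactions, so every
  group needs at least one ligand edge (as in the published direct-contact
  criterion); second-shell residues interacting only with other side chains
  are out of reach of the current enumeration.
* The hydrogen-bond score is a geometric ramp, not an energy; rankings should
  not be over-interpreted.
* Scaffold positions are treated as pure backbone geometry (no sequence
  design, no rotamer-library weighting), as in classical geometric matching.
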