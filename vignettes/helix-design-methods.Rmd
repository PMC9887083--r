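---
title: "Generative design of full-atom alpha-helices: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generative design of full-atom alpha-helices: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(helixforge)
```

## The design problem

Alpha-helices mediate a large share of protein-protein recognition, and short
helical peptides that reproduce the *hotspot* residues of a natural partner —
the few side chains contributing most of the binding energy — are attractive
leads. D-peptides (mirror-image amino acids) are especially attractive because
they resist proteolysis, but almost no D-helix structures exist to learn from.
helixforge addresses both problems with a single generative model: it learns
the distribution of natural L-helices, designs new helices whose residues
match a set of hotspot conformations, and converts any design into its exact
D-enantiomer by reflection.

## Representation: angles, not coordinates

A helix of fixed length $L$ (default 14) is encoded as an $L \times 42$
feature map:

* 20 sequence channels — a one-hot row per residue over the alphabetical
  one-letter alphabet (`A, C, D, …, Y`). The alphabet order matters only for
  argmax ties, which resolve to the lowest index.
* 22 angle channels — each of 11 angles per residue (phi, psi, omega; the
  main-chain bond angles C(i−1)–N–CA, N–CA–C, CA–C–N(i+1); chi1–chi5) as a
  $(\sin\theta, \cos\theta)$ pair.

The trigonometric pair removes the $\pm\pi$ wrap a network would otherwise
have to learn across; decoding is `atan2(sin, cos)`, which is invariant to
positive rescaling of the pair, so generated pairs need not lie on the unit
circle. A pair of norm below 0.1 decodes as *masked* (undefined angle), the
same convention used to encode terminal angles and unused chi slots, which
are written as exact $(0, 0)$. A raw $\theta/\pi$ encoding (31 channels) is
retained behind `angle_encoding = "raw"` for ablation.

Bond lengths are deliberately absent: reconstruction re-idealizes them
(N–CA 1.458, CA–C 1.525, C–N 1.329, C=O 1.231, CA–CB 1.521 Å) and places
side-chain heavy atoms from a fixed topology table, so a structure is fully
specified by its angles up to rigid motion. One convention deserves note: the
last residue's psi is defined through its carbonyl oxygen
($\psi_L = \angle(N, CA, C, O) - \pi$), so the measure/reconstruct round trip
is exact at both termini; phi(1), omega(L) and the two terminal tau angles
remain masked. Degenerate (collinear) dihedrals measure as masked values,
never NaN.

Chirality: `reconstruct()` always builds L-structures (the CB improper
dihedral N–CA–C–CB is negative); `mirror_transform()` reflects through the
xy-plane, an exact isometry and involution that negates every dihedral and
flips the chirality flag. All D-mode functionality is built on this one
primitive.

## The generative model

The generator maps a standard-normal latent vector (desk default 64
dimensions) through a linear projection to $C \times L$ (64 channels),
four residual ConvBlocks (1-D convolution, kernel 3, same padding, ReLU),
and a per-position linear head to the 42 channels. Angle pairs pass through a
radial cap $g \mapsto g / \max(\lVert g\rVert, 1)$: encoded real pairs sit on
the unit circle and masked ones at the origin, so the cap matches the data
range like tanh would, but without per-channel saturation — a property the
latent-space search relies on, because saturated tanh units make the search
gradient vanish. Sequence channels are unconstrained logits (argmax-invariant).

The critic mirrors the generator (ConvBlocks, then a linear read-out to one
scalar) and is built exclusively from linear maps and ReLU, hence piecewise
linear in its input. Training minimizes the Wasserstein objective
$E[D(\text{fake})] - E[D(\text{real})]$ with a gradient penalty
$\lambda\, E[\max(0, \lVert\nabla_{\hat x} D\rVert - 1)^2]$ on uniform
real/fake interpolates ($\lambda = 10$; the one-sided form penalizes only
gradients above one, matching the constraint it enforces; the two-sided
textbook variant is a config switch). Because the critic is piecewise linear,
the penalty's weight-gradient is computed exactly by a tangent
(forward-over-reverse) pass with the ReLU masks held constant — the same
almost-everywhere-exact double backward a general autodiff system performs
for ReLU networks. Both networks use Adam with $\beta_1 = 0$,
$\beta_2 = 0.9$, five critic steps per generator step.

Two configurations ship: the full defaults (latent 128, lr $10^{-4}$) and
`desk_config()` (latent 64, channels 64, batch 64, lr $10^{-3}$) sized for
laptop corpora; with only a few hundred generator updates in a 30-epoch desk
run, the larger step size is the appropriate Adam regime. All tests and the
shipped analyses use the desk scale.

Training logs, per epoch, the critic's Wasserstein estimate and the fraction
of a *fixed* probe of 500 latent vectors whose decoded structures pass the
surrogate quality gate (below); the probe is drawn once, so the curve is
comparable across epochs, and epoch 0 is the untrained model. A non-finite
loss aborts training and returns the last finite epoch's checkpoint.

## Synthetic corpus: what it emulates and what it does not

The package trains and tests against a synthetic idealized corpus
(`make_synthetic_corpus()`): sequences from a helix-propensity-weighted
distribution (A/L/E/K enriched, proline excluded from interior positions),
backbone torsions at the canonical $(-57°, -47°, 180°)$ plus independent
Gaussian noise of 7°, ideal main-chain bond angles, and chi angles drawn from
the three canonical rotamer wells (gauche−/trans/gauche+, weights
0.5/0.35/0.15) with 10° noise. Everything is reproducible from a seed.

This emulates the *marginal* statistics of helical windows well enough to
exercise every operation, but not real data's couplings: no sequence-
conformation correlation, no rotamer-environment coordination (so roughly a
quarter of synthetic records carry one or two side-chain contacts below the
2.5 Å clash cutoff), no length heterogeneity, no experimental noise. Passing
tests therefore demonstrate the machinery — encoding, training dynamics,
search, reconstruction — not performance on PDB-scale data, and the package
makes no claim of reproducing published success rates that depend on a
corpus of millions of real helices.

`extract_helices()` provides the real-data path: maximal runs of residues
whose defined (phi, psi) fall in the alpha-R box with unbroken chain
continuity, emitted as stride-1 windows and deduplicated at $10^{-3}$ rad.
Dihedral-run detection was chosen over DSSP to avoid an external tool; a
DSSP-based extractor can be plugged in behind the same interface. The
train/test split filter retains a test record only if its position-wise
identity to *every* train record is at most 42.8% — at $L = 14$ that means at
most 5 shared positions, since $6/14 = 42.86\%$ already exceeds the
threshold — and exact duplicates are never test material at any threshold.

## Quality assessment

`surrogate_quality()` is an internal physical-plausibility gate:
$\text{score} = 10\,n_\text{clash} + 50\,(1 - f_\text{helical}) +
100\,n_\text{break}$, pass below 100. Clashes are inter-residue heavy-atom
pairs under 2.5 Å excluding the bonded/1-3 pairs across the peptide bond;
$f_\text{helical}$ counts residues in either the alpha-R *or* alpha-L
Ramachandran box (so the gate is exactly mirror-symmetric, as are the
distance-based terms); breaks are C–N distances outside [1.2, 1.5] Å. The
weights make the noise-free ideal helix score 0 and random coordinates fail
by orders of magnitude. An external physics-based scorer can be attached via
`rosetta_hook()` (one PDB per structure, total score parsed from the last
line; the 100 REU "reasonable" bin is applied to its output); the hook is
never a test dependency and degrades to NA with a message when absent.

The Ramachandran boxes are rectangles chosen mirror-symmetric so L/D tests
are exact: alpha-R is $\phi \in (-100°, -30°)$, $\psi \in (-80°, -5°)$;
alpha-L its point reflection; beta is $\phi \in (-180°, -45°)$ with
$\psi \in (45°, 180°] \cup (-180°, -150°)$.

## Constrained latent-space search

A hotspot specification is an ordered list of residues (identity, reference
heavy-atom coordinates, register spacings). `enumerate_assignments()` places
the pattern at every offset that preserves the spacings exactly — for a span
$s$ there are $L - s$ placements; preserving register keeps the hotspots on
the same helical face. The search optimizes, per restart and assignment, the
loss

$$\mathcal{L}(z) = \sum_j \text{CE}\big(\text{softmax}(\text{seq}_{a_j}),
t_j\big) + w \cdot \frac{1}{|A|}\sum_{j,q}
\big\lVert \hat u_{a_j,q} - u^{*}_{j,q} \big\rVert^2$$

where $\hat u$ is the *normalized* generated (sin, cos) pair and $u^*$ the
target's encoded pair ($w = 1$ by default). Two numerical choices matter and
are deliberate:

* The angle deviation is measured between pair *directions*, because the
  decoder reads only direction; the raw-channel MSE has its minimum away
  from any latent whose output pairs are not unit-norm and measurably drags
  the optimum off the correct geometry.
* The cross-entropy is *hinged* by default: its gradient is dropped at a
  position once the target residue holds the softmax argmax with probability
  above 0.6. Identity is a constraint with an entropy floor of roughly 2.5
  nat per position; left active, that floor dominates the combined loss and
  distorts the recovered conformation by tens of degrees. `ce_mode = "plain"`
  restores the textbook term.

Optimization is Adam on $z$ (lr 0.05, 200 steps by default), with $z$
re-projected to a ball of radius $3\sqrt{d}$ to stay in-distribution; every
(restart, assignment) pair starts from its own standard-normal draw, and all
trajectories are optimized jointly as one batched pass (the per-candidate
losses are independent, so this is exactly independent optimization,
vectorized). Above 64 enumerated assignments only the 16 best by initial
loss are pursued. Candidates are then decoded, reconstructed, mirrored in
D-mode, checked for exact residue identity at the assigned positions, scored
by the true partial-alignment RMSD — Kabsch superposition (SVD with
determinant correction, so a reflection is never returned) over the matched
residues' backbone N/CA/C/O plus all side-chain heavy atoms
(`atom_mode = "backbone"` restricts to the backbone) — and ranked by RMSD
with identity failures flagged unmatched and ranked last. Match bins follow
the convention of the underlying benchmark: below 1.5 Å "matched", 1.5–2.5 Å
"intermediate" for L-designs (1.5–2.0 Å for D).

D-mode never retro-inverts: the specification is mirrored, the search runs
entirely in the L frame against the mirrored target, and the decoded helix
is mirrored afterwards — equivalent by isometry, and the design keeps the
original peptide's N→C orientation.

## Long targets: fragment, search, join

Targets longer than $L$ are designed through an overlapping-fragment plan
(explicit ranges honored verbatim; otherwise equal-coverage windows with
overlap ≥ 2). Each fragment is searched with the assignment register-locked
to the hotspots' in-fragment positions, so the generated window maps 1:1
onto the fragment range — the property the joiner needs. The best candidate
per fragment is placed into the target frame by its hotspot superposition,
optional point mutations rebuild single side chains from the topology table
(reusing shared chi angles), and fragments are stitched at the midpoint of
each overlap — termini are the least reliable part of generated helices, so
the midpoint minimizes their influence. The stitch point is additionally
constrained so that every hotspot residue is contributed by the fragment
whose search optimized it (in the GLP-1 plan this moves the first cut from
16 to 12). Junction geometry is idealized by
re-measuring the stitched chain's internal coordinates and rebuilding with
ideal bond lengths (then superposing back onto the stitched backbone), so
the output always satisfies chain continuity; if the shared backbone of two
fragments disagrees by more than 2 Å RMSD the join refuses and reports the
value rather than emitting a broken chain.

The shipped GLP-1 example uses the native GLP-1(7–36) sequence
(`synthetic_glp1_helix()`, an ideal-helix stand-in for the receptor-bound
conformation, labelled synthetic) with the three-fragment plan 7–20 / 12–25 /
23–36 and hotspots {7, 9, 12} / {13, 15, 19} / {28, 29, 32}
(`glp1_plan()`, also as `inst/extdata/glp1_plan.yaml`; plan files are YAML).

## Problem sizes and determinism

The shipped analyses use desk-scale sizes chosen as a realistic laptop
workload: 2 000-record corpora, 30-epoch training runs, searches of 8
restarts × 200 steps, and 20-case search benchmarks. Every stochastic
operation takes an explicit seed and restores the caller's RNG state;
seed-fixed training, sampling and search are bitwise reproducible, and the
fixed-probe latents are constant across epochs by construction.

## Known limitations

* Idealized geometry: no bond-length/angle relaxation, approximate aromatic
  ring closure, proline's ring closure not enforced.
* No hydrogens, non-standard residues, cyclic peptides, or energy
  minimization; the surrogate gate is a plausibility filter, not an energy
  function.
* Whether omega should be generated or pinned near 180° is data-dependent;
  it is generated by default (it is part of the encoding) and noise-free
  corpora can fix it.
* The desk-scale model demonstrates the method; published success rates on
  PDB-scale corpora are out of reach of a synthetic corpus by design.
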