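---
title: "Restraint-guided folding in torsion space: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Restraint-guided folding in torsion space: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Deep learning restraint predictors emit, for every residue pair of a
protein, probability histograms over binned inter-residue geometry:
C&beta;&ndash;C&beta; and C&alpha;&ndash;C&alpha; distances (38 bins: one
below 2 &Aring;, 36 bins of 0.5 &Aring; over [2, 20), one at &ge; 20
&Aring;), contact probabilities, and three inter-residue orientation
angles binned at 15&deg; with an extra *no-interaction* bin flagging
pairs farther than 20 &Aring;.  When such restraints are abundant and
accurate they smooth the folding energy landscape to the point where a
local, gradient-based search suffices: no fragment assembly, no Monte
Carlo.  `torsionfold` implements that folding engine &mdash; the
conversion of binned histograms into a continuously differentiable
potential, a composite energy with generic physical terms, and L-BFGS
minimization over the backbone torsion angles &mdash; together with a
synthetic restraint generator so the entire pipeline can be exercised,
and its statistical behaviour measured, without any trained network.

## Reduced representation and geometry

A conformation is parameterized entirely by the backbone torsions
$(\phi_i, \psi_i)$; bond lengths and angles are fixed at ideal values
(Engh&ndash;Huber-style constants: N&ndash;C&alpha; 1.458 &Aring;,
C&alpha;&ndash;C 1.525 &Aring;, C&ndash;N 1.329 &Aring;, C=O 1.231
&Aring;, N&ndash;H 1.010 &Aring;; angles N&ndash;C&alpha;&ndash;C
111.2&deg;, C&alpha;&ndash;C&ndash;N 116.2&deg;,
C&ndash;N&ndash;C&alpha; 121.7&deg;), with the peptide bond $\omega$
held at 180&deg;.  Each residue carries seven sites: N, amide H,
C&alpha;, C&beta;, a side-chain center (SC), C and carbonyl O.  C&beta;
sits at the ideal tetrahedral position (the improper dihedral
C&ndash;N&ndash;C&alpha;&ndash;C&beta; = &minus;122.55&deg; fixes the
L-configuration); SC lies on the C&alpha;&rarr;C&beta; axis at a
residue-specific distance (a shipped coarse table standing in for true
side-chain centroids, whose exact definition full side-chain geometry
would require); glycine aliases C&beta; and SC to C&alpha;, and every
consumer of "C&beta;" uses C&alpha; for glycine, matching the field's
contact convention.  Coordinates are built by sequential
internal-to-Cartesian (NeRF) placement; the first residue fixes the
frame (N at the origin, C&alpha; on +x, C in the xy-plane), so there are
no rigid-body degrees of freedom and the optimization vector is exactly
the $2L-2$ defined torsions.  The torsion convention is IUPAC (cis =
0&deg;), verified in the tests against two independent dihedral
formulations and `bio3d`.

## From histograms to a differentiable potential

Restraint predictors emit only binned probabilities; an energy is
obtained per pair and channel as a negative log-ratio against a
reference bin,
$$E_b = -\log\frac{p_b + \varepsilon}{p_{\mathrm{ref}} + \varepsilon},
\qquad \varepsilon = 10^{-4},$$
with the &ge; 20 &Aring; bin as reference for distances and the
no-interaction bin for orientations.  $\varepsilon$ guards
$\log 0$ and caps the well depth at
$-\log\varepsilon \approx 9.2$ for a fully confident bin.  The per-bin
energies are interpolated with cubic splines over knots at the bin
centers so that L-BFGS sees a $C^1$ energy:

* distance channels: natural cubic splines on the 38 knots
  (1.75&ndash;20.25 &Aring;); below the first knot the potential
  continues linearly with a repulsive slope of at least 10 energy units
  per &Aring;; beyond the last knot the terminal slope eases out
  quadratically to zero within 1.75 &Aring; (flat past 22 &Aring;), so
  unrestrained pairs feel no force at long range and the extension stays
  $C^1$;
* dihedral channels ($\Omega$, $\theta$): periodic uniform cubic
  B-splines on the 24 angular knots, so value and derivative match at
  &plusmn;180&deg; exactly;
* the planar channel ($\varphi$): a natural cubic spline on its 12 knots
  over [0&deg;, 180&deg;].

Orientation angles follow the trRosetta-style conventions on the reduced
sites: $\Omega_{ij}$ = dihedral
C&alpha;$_i$&ndash;C&beta;$_i$&ndash;C&beta;$_j$&ndash;C&alpha;$_j$
(symmetric), $\theta_{ij}$ = dihedral
N$_i$&ndash;C&alpha;$_i$&ndash;C&beta;$_i$&ndash;C&beta;$_j$ and
$\varphi_{ij}$ = planar angle
C&alpha;$_i$&ndash;C&beta;$_i$&ndash;C&beta;$_j$ (both directed).
Glycine pairs carry no orientation terms.  Contacts do not use bins:
each selected pair contributes a smooth flat-bottom well of depth equal
to the contact probability, constant up to the first-well width $d_b$
(default 8 &Aring;, the contact-definition distance, configurable) and
switched to zero with a cubic smoothstep over the next 1 &Aring;.

**Selection.**  The default policy keeps distance pairs whose confidence
&mdash; the summed probability of all sub-20-&Aring; bins &mdash;
exceeds 0.55; orientation pairs with no-interaction probability below
0.5; contact pairs with probability above 0.5.  A `top_nl` policy keeps
the $\lfloor nL \rfloor$ most confident pairs of a sequence-separation
class (ties broken lexicographically), which is how the restraint-budget
experiments below are run.  Pairs with $|i-j| \le 1$ are never used.

## The composite energy

$$E = \sum_{c \in \text{7 channels}} \sum_{r \in \{s,m,l\}} w_{c,r}
E_{c,r} + w_{hb} E_{hb} + w_{vdw} E_{vdw} + w_{tor} E_{tor}$$

Restraint terms are split by sequence separation into short
($1 < |i-j| \le 11$), medium ($11 < |i-j| \le 23$) and long
($|i-j| > 23$) classes, giving $7 \times 3 + 3 = 24$ weights.  The three
generic terms use simple smooth forms (every gate is a cubic smoothstep,
keeping the total $C^1$):

* $E_{vdw}$: a soft quadratic overlap penalty
  $\sum (r_{\mathrm{clash}} - d)^2$ over non-bonded site pairs with
  $r_{\mathrm{clash}} = 0.85\,(R_a + R_b)$, excluding pairs within two
  covalent bonds; unified pseudo-atom radii (C/C&alpha;/C&beta; 1.70, N
  1.55, O 1.52 &Aring;, SC residue-specific, polar H excluded);
* $E_{hb}$: backbone N&ndash;H&hellip;O=C wells contributing up to
  &minus;1 per bond when the H&hellip;O distance lies in [1.5, 2.6]
  &Aring; (switch-in 1.2&ndash;1.5, switch-out 2.6&ndash;3.0) and the
  N&ndash;H&hellip;O angle exceeds 120&deg; (full weight beyond
  150&deg;), donors and acceptors at least two residues apart;
* $E_{tor}$: a statistical backbone-torsion surface: coarse
  15&deg;&times;15&deg; log-probability grids (separate general /
  glycine / proline tables, generated from smooth basin mixtures over
  the known Ramachandran regions and shipped as code), interpolated by a
  periodic bicubic B-spline so both the value and the
  $(\phi, \psi)$-gradient are analytic.

These forms are the package's own design: the published description
names the terms but not their functional forms, so simple,
community-standard smooth stand-ins are used and are parameterized so
they can be swapped without touching the optimizer.

**Gradients.**  Every term's Cartesian derivative is chained through the
torsion-axis rule: for atom $a$ downstream of the rotating bond $b$,
$\partial x_a / \partial \chi_b = \hat u_b \times (x_a - p_b)$.  With
the atom order N, H, C&alpha;, C&beta;, SC, C, O per residue, the set of
atoms moved by any torsion is a suffix of the atom list, so all $2L-2$
derivatives are accumulated from per-atom forces in one reverse pass
(suffix sums of $g_a$ and $x_a \times g_a$).  Glycine C&beta;/SC forces
are redirected to C&alpha;.  The acceptance suite verifies the full
analytic gradient against central finite differences at $10^{-4}$
relative accuracy with every term active.

**Weights.**  The shipped defaults (distances 2&ndash;4, orientations
0.5&ndash;1.5, contacts 0.5&ndash;1, $E_{hb}$ 0.5, $E_{vdw}$ 1,
$E_{tor}$ 0.3, long range weighted above short) are author-set values,
chosen so the restraint channels dominate the landscape while the
generic terms resolve local geometry, and validated on the synthetic
recovery suite.  `optimize_weights()` implements the full
coordinate-descent training protocol &mdash; every weight swept
one-at-a-time over [0, 25] at step 0.25, three refinement passes at step
0.1, and a final &plusmn;2 perturbation pass at step 0.02, accepting
only improvements &mdash; for re-deriving weights against any training
fixture set (`make_fold_objective()`); the protocol itself is verified
on toy objectives with known optima.  Running it at full scale on
folding objectives is a compute-day-sized job and is deliberately not
part of the default build.

## Optimization

L-BFGS with history $m = 256$ (curvature pairs with
$y^\top s \le 10^{-12}$ discarded), Armijo backtracking line search
($\alpha_0 = 1$, halving, $c_1 = 10^{-4}$, at most 30 backtracks), up to
10 rounds of at most 2000 steps.  A round ends when $|\Delta E| <
10^{-6}$ for 5 consecutive accepted steps, when
$\|\nabla E\|_\infty < 10^{-6}$, or when the line search fails.  The
first round starts from the configured initialization; each later round
restarts from a fresh seeded draw (seed + round &minus; 1) with a
cleared history, and the returned model is the lowest-energy
conformation seen across all accepted steps of all rounds.  This restart
schedule is a deliberate design choice: restarting from the *current*
point cannot escape a converged local minimum (observed directly on
helix fixtures during development), whereas the seeded multi-start
reading of the round schedule is equally consistent with selecting "the
lowest-energy model produced during the simulations" and makes the
reported model robust.  Torsions are kept in $(-\pi, \pi]$ by wrapping
after each step; curvature pairs use the unwrapped step $\alpha d$, and
the energy is periodic, so the history stays consistent.

Initialization stands in for a learned torsion predictor: `random`
draws each residue uniformly from the two allowed Ramachandran basins,
`ss_guess` draws around helix/strand means given an H/E/C string,
`extended` is $(-120, 120)$, and `provided` passes torsions through
verbatim.  All randomness flows from the single configuration seed.

## The synthetic generator

`make_toy_protein()` builds ideal-torsion natives &mdash; helix
$(-57, -47)$, &beta;-hairpin (strands $(-120, 120)$ with a fixed
4-residue turn), two-helix bundle, and a mixed helix + hairpin topology
&mdash; with sequences drawn from structure-appropriate residue pools.
The turn/loop torsions are fixed constants calibrated once, by
minimizing cross-element C&alpha;-distance deviations (5 &Aring; for
strand pairing, 9.5 &Aring; for helix packing) plus the package's own
steric penalty &mdash; and, for the hairpin, rewarding backbone hydrogen
bonds &mdash; so the toy folds are compact, clash-free and, for the
hairpin, genuinely &beta;-ladder-bonded; a length-20 hairpin forms over
a dozen cross-strand C&beta; contacts under the 8 &Aring; definition.

`restraints_from_structure()` emulates a predictor's output from any
native: distance histograms are Gaussians of width $\sigma$ (default
0.5 &Aring;) around the true distance, discretized exactly via normal
CDF differences (mass beyond 20 &Aring; collected in the last bin);
orientation histograms are wrapped (dihedrals) or reflected (planar)
Gaussians of width $\sigma_{\mathrm{angle}}$ (default 15&deg;); contact
probabilities are $\Phi((8 - d)/\sigma)$.  A fraction $\eta$ of covered
pairs is replaced by uniform histograms (uninformative noise) and a
fraction $1 - \kappa$ carries the no-interaction pattern (coverage
loss); both draws are seeded.  Pair replacement rather than bias was
chosen as the noise model so that selection policies and error metrics
are exercised independently of histogram shape.

What this emulates &mdash; and what it does not: real predictor output
is unimodal-ish per pair but has correlated errors across pairs,
secondary modes, and confidence that varies with alignment depth; the
generator's errors are independent across pairs and its histograms are
exactly Gaussian.  Passing the recovery experiments therefore
demonstrates that the folding engine faithfully inverts
restraint maps of stated sharpness &mdash; it does not certify accuracy
on any real predictor's output.

## Evaluation metrics

TM-score is computed sequence-dependently (fixed correspondence) with
$d_0 = 1.24\,(L-15)^{1/3} - 1.8$ floored at 0.5 &Aring;, maximized over
superpositions from seed fragments of lengths $L$, $L/2$, $L/4$ at every
offset, each refined by iterating Kabsch superposition on the residues
within $\max(d_0, 4.5)$ &Aring; to a fixed point (at least 4 residues
kept); the exhaustive-seed oracle in the tests reproduces it to
$10^{-6}$, and it never falls below the single global-superposition
bound.  RMSD uses the standard SVD Kabsch solution with reflection
correction.  `distance_mae()` reports the mean absolute error between
argmax-bin-center predicted distances and model C&beta; distances over
the top $nL$ most confident pairs of a separation class;
`contact_precision()` the fraction of top predicted contacts with native
C&beta; distance below 8 &Aring;; `clash_count()` the number of
non-bonded site pairs closer than 0.6 of their summed radii &mdash; a
reduced-representation analogue of full-atom clash scores, not
numerically comparable to them.

## Numerical choices and degenerate inputs

Histogram validation tolerates $10^{-5}$ in normalization and $10^{-6}$
in symmetry.  Spline fitting requires at least 4 knots.  Dihedral
gradients return zero at colinear degeneracies (measured dihedrals raise
an error instead); planar-angle gradients clamp $\sin\theta$ at
$10^{-8}$.  `top_nl` selection beyond the available pairs keeps all of
them.  A flat landscape (no restraints, zero weights) converges
immediately and returns the initial conformation.  Ties in the
lowest-energy model keep the earliest conformation.

## Problem sizes of the shipped experiments

The fold-recovery suite is 10 fixtures of lengths 30&ndash;60 across all
four fold types at $\sigma = 0.5$ &Aring;, $\eta = 0$, $\kappa = 1$,
folded with the default 10&times;2000 schedule.  The restraint-budget
ladder ($n \in \{1, 5, 10, 20, \text{all}\}$, C&beta;-distance channel
only) uses the same default schedule and implements its levels as one
nested `top_nl` family &mdash; the final level is the keep-everything
clamp &mdash; so successive selections are strict supersets, matching
the selection-monotonicity invariant.  The orientation-synergy
comparison (8 hairpins of lengths 20&ndash;48, with and without the
three orientation channels) runs at 5 rounds &times; 1000 steps, the
package's chosen problem size for that trend-level experiment.  Even
with nested selections, adjacent near-saturated ladder levels solve
slightly different optimization problems and the folds are local
minimizations, so the monotonicity checks allow a 0.02 TM cushion
between successive means/medians.

## Known limitations

Single chains only; ideal covalent geometry (no bond/angle relaxation);
side chains reduced to a collinear center; the generic terms are simple
stand-ins, not a calibrated force field; TM-score assumes equal lengths
(no alignment search); the synthetic generator does not emulate MSA
depth, co-evolutionary error correlation, or predictor calibration
curves.  Folding quality on real predictor output depends on weights
trained against that predictor, which is what `optimize_weights()` is
for.
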