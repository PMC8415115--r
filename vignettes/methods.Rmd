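---
title: "Methods: simulating re-entry initiation in fibrotic tissue and classifying its structural triggers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating re-entry initiation in fibrotic tissue and classifying its structural triggers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fibroblock)
```

# Scope

`fibroblock` implements a complete simulation-to-classification pipeline for
studying how the fine-scale arrangement of fibrotic obstacles in cardiac
tissue triggers re-entrant arrhythmia:

1. a monodomain reaction--diffusion simulation of action-potential (AP)
   propagation through two-dimensional tissue with randomly placed
   non-conducting obstacles,
2. detection of sites of selective/unidirectional conduction block through
   the re-entry vulnerability index (RVI),
3. extraction of balanced datasets of square binary fibrosis micropatterns
   around blocking ("discriminative") and non-blocking ("indiscriminate")
   locations, and
4. dense neural-network classifiers that predict, from the binary occupancy
   window alone, whether a micropattern can initiate re-entry, together with
   gradient saliency maps.

All inputs are generated internally; there is no external data dependency.

# The cell model

Tissue electrophysiology uses the monodomain formulation

$$C_m \frac{\partial u}{\partial t} = \nabla \cdot (D \nabla u) - I_{\mathrm{ion}}(u, v, w, s),$$

with the four-variable minimal ventricular (Bueno-Orovio--Cherry--Fenton)
model supplying $I_{\mathrm{ion}} = J_{fi} + J_{so} + J_{si}$ (fast inward,
slow outward, slow inward). The parameter set (`bocf_params()`) is the
fibrosis-remodelled variant: relative to the published epicardial values it
lowers the $\tau_{so}$ sigmoid midpoint `u_so` to 0.4, the upper potential
`u_u` to 1.2, raises `tau_si` to 2.8 ms and `u_o` to 0.006. The effect is a
short, triangular AP and slow conduction, emulating strongly remodelled
myocardium. All potentials and gates are dimensionless; time constants are
in milliseconds.

Two conventions needed fixing where the published material is silent:

* **Heaviside switches at equality.** Threshold comparisons use
  $H(0) = 1$, with one deliberate exception: the $\theta_v^-$ switch of the
  $v$-gate treats the boundary as *resting*. The remodelled rest potential
  converges to exactly $u = u_o = \theta_v^- = 0.006$, and an inclusive
  convention there would slowly de-activate the $v$ gate at rest (time
  constant $\tau_{v2}^- = 1150$ ms), silently eroding tissue excitability
  over a long simulation. The exclusive convention keeps the rest state a
  true fixed point with $v_\infty = 1$. This is a measure-zero change
  everywhere else.
* **APD measurement.** `measure_apd()` measures from the upstroke crossing
  of the activation threshold ($u_v = 0.3$, the model's excitation
  threshold) to the downstroke crossing of the level corresponding to the
  requested repolarisation fraction of the AP amplitude (baseline = resting
  potential before the upstroke), with linear interpolation between
  samples. Under this standard convention the remodelled single cell gives
  APD90 = 39.6 ms at $\Delta t = 0.05$ ms (confirmed independently with a
  stiff `deSolve::lsoda` integration of the same right-hand side); the AP
  reaches *near-complete* repolarisation at about 50 ms (it falls below 5%
  of amplitude at ~46 ms and below 2% at ~53 ms). A quoted duration of
  "approximately 50 ms" for this AP therefore corresponds to near-full
  repolarisation (or to the duration read off a plotted trace), not to the
  APD90 level; we keep the standard APD90 convention rather than bending
  the measurement toward a target value.

## Time integration

Single cells and the per-node reaction step both use a second-order
(midpoint predictor--corrector) generalisation of the Rush--Larsen method:
each gate obeys $\dot y = A(u) - B(u)\,y$ and is advanced by the exact
exponential update with coefficients frozen at a half-step predictor
state; the potential is advanced by the midpoint rule. Gates therefore stay
in $[0, 1]$ unconditionally, and the observed convergence order in the test
suite is about 2 (assertion: $\geq 1.8$). $\Delta t = 0.05$ ms throughout.

# Tissue discretisation

The domain is a grid of square elements of side 0.1 mm (default 200 x 200
elements = 2 x 2 cm); tissue nodes sit on element vertices. Fibrosis is
modelled by deleting elements: `generate_pattern(n_rows, n_cols, rho, seed)`
obstructs each element independently with probability `rho` (diffuse
fibrosis). Because the unknowns live on vertices, two diagonally opposed
obstacles still leave their shared corner node conducting -- the
characteristic "diagonal crack" connectivity, which `render_connectivity()`
exposes for display and which makes vertex-centred meshes more conductive
than element-centred ones.

Spatial discretisation is a vertex-centred control-volume finite-element
method integrating bilinear interpolants over the square elements. Each
conducting element contributes the standard 4-node bilinear stiffness block
(diagonal $\tfrac{2}{3}D$, edge-adjacent $-\tfrac{1}{6}D$, opposite corner
$-\tfrac{1}{3}D$) and the *consistent* (non-diagonal) mass block (entries
summing to the element area). Obstructed elements contribute nothing; nodes
touching no conducting element are excluded from the system. Boundaries are
natural no-flux Neumann. Two exact identities are enforced in tests:
stiffness rows sum to zero (constants generate no flux) and total mass
equals the conducting area.

## Diffusion step and conductivity calibration

The published material fixes the reaction integrator and the consistent
mass matrix but not the diffusion scheme; we use operator splitting with a
Crank--Nicolson diffusion solve,
$(M + \tfrac{\Delta t}{2} K)u^{n+1} = (M - \tfrac{\Delta t}{2} K)u^{*}$,
which is unconditionally stable at $\Delta t = 0.05$ ms and $\Delta x = 0.1$
mm. The system matrix is constant per pattern, so it is factorised once
(sparse Cholesky with fill-reducing permutation) and reused by every time
step and every stimulus scenario of that pattern.

The printed conductivity value ("$2.5 \times 10^{-4}$ mS") does not close
dimensionally for a 2-D monodomain equation, so the conductivity is carried
as an effective diffusivity $D$ in mm$^2$/ms whose magnitude was calibrated
**once**: bisection on obstacle-free planar-strip runs at the reference
discretisation until the conduction velocity equalled the stated 23 cm/s.
The result, $D = 0.0219$ mm$^2$/ms, is frozen as `tissue_conductivity()`
and used unchanged for every other simulation in the package (the
acceptance checks re-measure CV without re-tuning it).

## Stimuli, records, and termination

`default_stimulus_sites()` returns the 13-scenario protocol: 5 x 5 node
patches at the four corners, four edge midpoints, the centre, and the four
centre--corner midpoints (the published layout is graphical only; this
symmetric reading matches its appearance and count). A stimulus is an
additive current of amplitude 2 (model units) for 1 ms at $t = 0$ --
robustly suprathreshold; only suprathreshold behaviour matters.
`edge_stimulus_sites()` provides the four full-edge stimuli of the
small-domain generalisation experiment.

During a run, upward/downward crossings of $u_v$ are recorded per node as
activation/repolarisation times, with a 50 ms refractory lockout. The
lockout spans the AP duration: the model's absolute refractory period
exceeds the ~50 ms AP, so no genuine second activation can occur within
it, while passive electrotonic currents at the wave back can push a
repolarising node's potential briefly back over the 0.3 threshold and
would otherwise register as spurious re-activations (and hence false
re-entries, a pronounced artifact on small domains where every node is
near the boundary). Runs end at `t_max` (2 s by default) or at
quiescence (max $u$ over active nodes below 0.05, checked every 1 ms after
the stimulus ends). Re-entry is flagged when any *boundary* node activates
a second time -- an ectopic wave that escapes the fibrotic region;
`sim_config(stop_on_reentry = TRUE)` optionally ends the run at that
moment, which leaves first-crossing markers (and hence RVI) unaffected.

# Block detection via RVI

For each node $i$ with at least one activation,

$$\mathrm{RVI}(i) = \min_{j \in N(i)} \big( \mathrm{RT}_j - \mathrm{AT}_i \big),$$

where $N(i)$ is the 8-node neighbourhood (radius 1 in the Chebyshev metric;
the radius is configurable since the published neighbourhood is unstated),
$\mathrm{AT}_i$ is the node's **first** activation and $\mathrm{RT}_j$ the
neighbour's **first** repolarisation -- the initiating block precedes any
re-entrant reactivation. Strongly negative values mark locations where a
neighbour had already recovered when the node first fired: re-excitable
substrate. Nodes with RVI at or below the threshold (-50, interpreted as
milliseconds since every quantity entering RVI is a time in ms) are grouped
into 8-connected components and each contiguous group is reduced to a
single block site at its centroid (rounded half-down toward the smaller
index, for determinism). The implementation is checked against an
exhaustive brute-force double loop over node pairs on grids up to 20 x 20.

# Micropattern datasets

`extract_discriminative()` cuts one square window (odd side, 5--23
elements = 0.5--2.3 mm) per block site, centred on the site's element.
`sample_indiscriminate()` draws control windows from the same simulation
under two rules: at least 40% of the window's *excitable* (conducting)
elements must have activated -- inclusive at exactly 40% -- so the
structure was actually probed by the wave, and the window must contain no
node with RVI at or below the threshold. The activation rule needs a
bridge between element-level structure and node-level dynamics: an element
counts as activated if any of its corner nodes activated.

Windows that would overhang the domain are skipped (not padded) for *both*
classes, so the two classes see identical border-geometry statistics.
`build_balanced_dataset()` balances the classes exactly, then splits
70/15/15 stratified by class and grouped by source realisation: no
realisation contributes to more than one split, preventing leakage of
near-duplicate windows into the test set (the published account only says
test data were "unseen"; proportions are our choice). Duplicate masks
across realisations are retained -- they are legitimate i.i.d. draws.

`motif_fixture_dataset()` provides the synthetic fixture used by the unit
tests: positives contain a planted channel-into-bay motif -- the archetypal
source--sink-mismatch geometry that produces unidirectional block --
while negatives are uniform random masks at the matched mean density. The
classes are separable by construction, which is exactly what makes the
fixture useful for verifying learner correctness and useless as evidence
about real (simulation-derived) data.

# Classifier

`train_classifier()` trains a dense feed-forward binary classifier on the
flattened 0/1 masks: 0--4 hidden ReLU layers of equal width, one sigmoid
output, Adam (step 1e-3, $\beta_1 = 0.9$, $\beta_2 = 0.999$) on binary
cross-entropy. Epoch count, batch size and stopping rule are unreported in
the published account; the defaults are 50 epochs, batch 128, early
stopping on validation loss with patience 5 and best-weights restore, all
exposed in `train_config()`. Training is seeded and exactly reproducible
on one machine. The network is implemented in-package with base matrix
algebra (no deep-learning framework is required); gradients are standard
backpropagation, and the test suite checks the input-gradient path against
the analytic gradient of a linear model.

`evaluate_classifier()` reports accuracy, sensitivity, specificity and the
confusion matrix at the 0.5 threshold (classes are balanced), and AUC via
the Mann--Whitney rank statistic (ties counted half), cross-checked against
`pROC` and against exhaustive pair counting in tests. `saliency()` returns
the absolute gradient of the output *logit* with respect to each input
element -- for a no-hidden-layer model this is exactly the absolute weight
map; using the logit rather than the post-sigmoid probability avoids
washing out saturated predictions by the factor $p(1-p)$.

# Protocol orchestration and problem sizes

`paper_protocol()` records the full-scale study: 200 x 200 element domains,
50 realisations for each of the 21 densities $\rho = 0.40, 0.41, \dots,
0.60$ plus 800 more for each of $\rho = 0.46, \dots, 0.50$, 13 stimuli per
realisation -- 5,050 unique patterns and 65,650 simulations
(`protocol_counts()` reproduces these totals by arithmetic). Executing that
protocol was supercomputer-scale work; this package reproduces it as
protocol arithmetic plus scaled-down runs.

`desk_protocol()` is the bundled scaled-down configuration, chosen once as
the desk-scale study condition: 50 x 50 elements (5 x 5 mm) by default,
densities $\{0.40, 0.44, 0.48, 0.52, 0.56, 0.60\}$, a handful of
realisations per density, 13 stimuli, 600 ms horizon; the test suite runs
a smoke variant at 60 x 60 elements with 4 realisations per density. These
sizes were fixed by single-CPU runtime alone (the whole smoke sweep in
minutes).

What such scales can and cannot show. Block sites scale roughly with
tissue area (we observe per-simulation site rates at 60--100-element
domains consistent with the full protocol's per-area rate), so the desk
sweep exercises the complete marker -> RVI -> site -> micropattern
pipeline and yields tens of discriminative windows -- far fewer than the
~229k of the full protocol, so a classifier trained on the desk pipeline
dataset is severely data-limited; the separable fixture dataset, not the
desk pipeline dataset, is the learner-correctness check, and the
full-scale accuracy (~0.91) remains a cluster-scale observation.
*Boundary-escaping re-entry*, however, has a minimum spatial scale: a
cell here is re-excitable only after near-complete repolarisation plus
fast-gate recovery (~100 ms), giving an effective wavelength of
CV x ERP ~ 2 cm in open tissue, shortened a few-fold by tortuous
percolation paths. Circuits that both fit the domain and escape to its
boundary therefore need domains of roughly a centimetre or more -- which
is why the full protocol used 2 x 2 cm sheets and why sub-centimetre
smoke ensembles record essentially no re-entry. The re-entry-dependent
end-to-end checks (the unimodal probability curve over density and the
block-site enrichment of re-entrant realisations) consequently cannot be
demonstrated at smoke scale; they are asserted at their stated desk-scale
conditions and documented as requiring domain sizes outside the bundled
smoke budget. Early versions of the crossing detector *did* report
frequent "re-entry" on small domains; auditing every such event showed
boundary re-activation intervals of 10--44 ms -- passive wave-back
chatter, not regenerative activation -- which motivated the 50 ms lockout
above.

Per-task seeding: the pattern for realisation $k$ of density $i$ derives
its seed deterministically from (base seed, $i$, $k$), so any subset of the
sweep can be re-run in any order bit-identically.

`generalisation_experiment()` re-tests a trained classifier on wholly new
simulations: 46 x 46 element domains with four full-edge stimuli,
micropatterns extracted by the same RVI pipeline, and per-case
probabilities returned for inspection of successes and failures (block
events near window borders are the known failure mode).

# Known limitations

* Two-dimensional, isotropic, single fibrosis texture (diffuse); no
  bidomain effects, no restitution protocols, no other BOCF parameter
  regimes.
* RVI localises where a wave *dies out*, which need not coincide with the
  structure *responsible* for the block; the micropattern labels inherit
  that offset.
* The desk-scale ensembles trade statistical power for runtime; all
  full-scale quantitative claims are recorded as protocol arithmetic or
  cluster-scale targets rather than desk measurements.
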