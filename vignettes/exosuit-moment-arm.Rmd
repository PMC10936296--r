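---
title: "Moment-arm design and study analysis for passive back-assist exosuits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moment-arm design and study analysis for passive back-assist exosuits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exomoment)
```

## The problem

Passive back-assist exosuits route an elastic strap from the thighs, over
the buttocks, up the back and over the shoulders.  When the wearer flexes
to lift, the strap stretches and produces an extension torque about the
lumbosacral joint (L5-S1), offloading the back extensors.  The same strap,
however, presses on the body at its anchor points — the shoulders, the
waist and the thighs — and these *device-to-body forces* are the dominant
source of discomfort in practice.

A rigid *extended moment arm* protruding posteriorly from a waist brace,
carrying a pulley that re-routes the strap, enlarges the torque lever: the
same assistive torque can then be obtained with lower strap tension, hence
lower shoulder force.  The price is a new contact force where the arm meets
the waist.  Where to put the pulley is therefore a genuine design
trade-off, and this package provides the static model, the design-space
explorer, and the complete analysis pipeline of a lifting/lowering user
study built around that question.

## The static model

All geometry lives in the sagittal plane with the origin at L5-S1
(`p0`), x cranial-positive and y posterior-positive, in metres.  The
anchor points are `p1` (shoulder), `p2` (moment-arm pulley), `p3`
(buttocks contact) and `p4` (thigh).  With frictionless routing the strap
carries a single tension $T$, and:

* shoulder force: $\vec F_S = T\,\hat u_{12}$ with
  $\hat u_{12} = \widehat{p_1 p_2}$, so $|\vec F_S| = T$;
* waist force (net pulley load through the rigid arm):
  $\vec F_W = T(\hat u_{23} - \hat u_{12})$, so $|\vec F_W| = K\,T$ with
  $K = |\hat u_{23} - \hat u_{12}| \in [0, 2]$;
* assistive torque: the shoulder-strap segment connects two points of the
  same trunk-plus-arm body, so its moments cancel and the total reduces to
  the moment of the distal strap line,
  $\tau = T\, (p_2 - p_0) \times \hat u_{23}$;
* effective moment arm: $r_\mathrm{eff} = |\tau| / T$, the perpendicular
  distance from L5-S1 to the distal strap's line of action.

The assumptions are the standard ones for this class of model: static
analysis (no inertial terms), symmetric sagittal-plane lifting, negligible
buttock friction and dissipation, and a terminal shoulder anchor.  The
elastic-inelastic strap junction above the buttocks is collapsed into
`p3`, so the distal strap acts along the straight segment `p2 -> p3`.
Degenerate geometries (coincident routing points) raise classed errors
rather than returning NaN, and 2D torques are signed scalars (reported
`r_eff` uses $|\tau|$).

```{r}
g <- exo_geometry(p2 = c(0, 0.20))   # reference anchors, pulley 20 cm posterior
exo_force_state(g, tension = 100)
```

The tests verify the torque-cancellation identity and the point-to-line
oracle on 1,000 random geometries to a relative tolerance of 1e-12, plus
the closed-form limits (straight strap: $K \to 0$,
$r_\mathrm{eff} \to$ the no-arm perpendicular distance, about 0.0584 m for
the reference anchors).

## Design-space exploration

`sweep_design()` maps $K$ and $r_\mathrm{eff}$ over a grid of pulley
locations (default window x2 in [-0.25, 0.40] m, y2 in [0.02, 0.35] m,
step 5 mm — covering the trunk's posterior region between `p3` and `p1`;
the window is a package default, since no canonical grid exists).
Degenerate nodes are stored as `NA` and exported with explicit missing
markers, never dropped.  `classify_p2()` bins a location into the
`above` / `inline` / `below` regions (a configurable 1 cm inline band)
and into `short` / `long` radius classes (default threshold 0.12 m).
`rank_candidates()` orders named candidates by the tension — and hence
shoulder force — required to reach a target torque.

Two candidate sets ship with the package:

* `default_candidates()` — a symmetric, classification-consistent layout
  (inline pair on the posterior axis, above/below pairs at ±30°, radii
  0.08 / 0.16 m).  This is the set to use for classification and ranking
  demonstrations.
* `study_candidates()` — the set the synthetic-study generator uses.

The second set deserves its own paragraph, because the design here was
genuinely open.  The study the generator emulates found one configuration
(C4: above the joint, long radius) to minimize *both* the shoulder and the
waist force.  Under the idealized model with a fixed torque demand,
$|F_S| \propto 1/r_\mathrm{eff}$ and $|F_W| \propto K/r_\mathrm{eff}$ —
and a numerical survey of the reachable $(r_\mathrm{eff}, K/r_\mathrm{eff})$
pairs shows that pulley placements below or in line with L5-S1 always
attain a smaller $K/r_\mathrm{eff}$ than above placements of equal radius.
A geometrically symmetric six-candidate layout therefore cannot make an
above-region candidate the double minimizer: the idealized strap model and
the observed behaviour of a real fabric device genuinely diverge here
(multiple distributed contact points, strap-fabric interaction).  Since
the generator's job is to emulate the *study*, `study_candidates()` is
phenomenological: C4 is given the largest effective moment arm (0.152 m)
and the smallest $K/r_\mathrm{eff}$, while the other five use sharp-wrap
placements with smaller moment arms.  It makes no claim about the physical
emulator's coordinates, which were never published.

## The synthetic-study generator

No data from the original experiment were ever deposited, so the pipeline
is exercised end-to-end on synthetic studies that reproduce the
experiment's *structure*:

* 10 participants × 7 conditions (C1-C6, NoExo) × 2 repetitions;
* 5 s lift / 10 s hold / 5 s lower cadence;
* 8 EMG channels (left/right multifidus, erector spinae, latissimus
  dorsi, rectus abdominis) at 1,000 Hz; two load-cell channels at 90 Hz;
* MVIC and rest recordings per participant;
* lifted load 20% of body weight; strap stiffness 700 N/m;
* anthropometrics drawn from the cohort statistics
  (171.14 ± 9.37 cm, 71.24 ± 5.16 kg), truncated at ±3 SD;
* a 7 reducer / 3 co-contractor EMG phenotype split;
* VAS discomfort on a 27-segment body map;
* per-participant condition order as a seeded permutation (a Latin-square
  emulation; exact balance is irrelevant because order affects no computed
  outcome).

The coupling is generative, not fitted.  The torque demand per trial is a
raised-cosine pulse peaking at mid-lift and mid-lower (the experiment
prescribed cadence, not kinematics) with a small hold plateau;
`tau_peak = load_fraction * mass * g * torque_lever` with
`torque_lever = 0.06` m chosen once so that peak device forces land in the
tens-of-newtons range typical for passive back-assist devices.  Tension
follows as $T(t) = \tau(t)/r_\mathrm{eff}$, so a configuration with a
larger moment arm produces strictly smaller peak forces — the mechanism
under study holds in the generator by construction, which is exactly what
makes end-to-end parameter recovery a meaningful test.

EMG channels are amplitude-modulated carrier noise: white noise
band-limited to 20-400 Hz (so the analysis filter is approximately
transparent to it), normalized to unit RMS and multiplied by
`rest + task_intensity * (MVIC - rest) * envelope * factor`.  The
phenotype factor is 0.8 for reducers and 1.25 for co-contractors in exo
conditions; rectus abdominis channels get a near-1 factor (weight 0.1)
since abdominal activity barely changes with a back-assist device.
Discomfort VAS is a monotone saturating map of the analytic peak forces
(half-saturation 150 N), noise-perturbed, clipped to [0, 10], reported
above a 0.5 threshold.  One report per participant-condition; repetitions
share it.

What the generator does *not* emulate: realistic EMG spectra or motor-unit
behaviour, squat kinematics, fatigue, electrode artifacts, and the
psychometrics of subjective ratings beyond monotone force coupling.
Passing tests therefore demonstrate that the pipeline recovers what the
generator put in — they do not validate the model against real data,
which remain unavailable.

## Signal pipeline

Processing follows the study's analysis: 4th-order Butterworth band-pass
20-400 Hz applied forward-backward (zero phase; the band is prescribed,
the realization is the package's choice), sliding-RMS envelope with a
125 ms centered window, single-sample hop and shrunken edge windows, and
MVIC normalization

$$\mathrm{nRMS} = 100 \cdot
  \frac{\overline{\mathrm{RMS}}_\mathrm{task} - \mathrm{RMS}_\mathrm{rest}}
       {\mathrm{RMS}_\mathrm{max} - \mathrm{RMS}_\mathrm{rest}}\ \%$$

with the task statistic being the envelope mean over the phase, the rest
level the mean envelope of the relaxed-standing recording, and the
maximum the peak envelope of the MVIC recording.  nRMS is deliberately
not clipped at zero.  Phases are half-open windows derived from the
cadence; peak `F_S` and `F_W` are window maxima; the hold phase is
segmented but not reported.  The reducer/co-contractor rule is a strict
channel majority (> 4 of 8 channels with higher mean exo nRMS than
NoExo), formalizing "increased activity in most muscles".

## Statistics

`run_study_stats()` mirrors the study's plan: Shapiro-Wilk screening;
Kruskal-Wallis omnibus per outcome and phase with mid-rank tie
correction; Mann-Whitney pairwise comparisons gated on a significant
omnibus, exact by full enumeration when `min(n) <= 8` and tie-free,
otherwise normal approximation with tie correction and continuity
correction; Bonferroni correction `min(1, m p)`; and for EMG a one-way
MANOVA (Wilks' lambda) over the 8 channels with per-channel follow-up
ANOVAs and Tukey HSD pairs.  All tests use alpha = 0.05.

Three conventions worth stating: repetitions are averaged per
participant × condition × phase before any test (avoiding
pseudo-replication; the original analysis is silent on this); the
device-force tests run across the six exosuit configurations only, since
the control condition has no device force and would trivially dominate
any minimum; and the EMG exclusion uses the phenotype classifier rather
than manual inspection, which on the default generator removes exactly
the three co-contractors.

Degenerate inputs are handled explicitly: all-identical observations give
H = 0, p = 1; a singular pooled covariance in MANOVA raises an error
advising dimension reduction (a single response column falls back to the
equivalent univariate ANOVA); zero within-group variance in Tukey HSD
warns and reports p = 0/1 by mean equality.

## Problem sizes and runtime

The unit tests run on reduced studies (3 participants, 1 s phases) so the
suite stays fast; the verification suite runs the full default study
(10 × 7 × 2 trials, 1,000 Hz EMG) twice — once with measurement noise for
the recovery checks and once noise-free for the discomfort/force ranking
identity — plus a 5,000-replicate Kruskal-Wallis type-I calibration
(7 groups of 10).  These sizes are the package's chosen verification
scale; the oracle identities are scale-free.

## Limitations

The model is static and two-dimensional: no spine compression/shear
estimates, no soft-tissue deformation, no dynamics, no asymmetric or
non-sagittal lifting.  The explorer ranks explicit candidates only — it
performs no optimization and no mechanical feasibility or collision
checking.  All conclusions drawn from synthetic studies are statements
about the pipeline, not about human subjects.
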