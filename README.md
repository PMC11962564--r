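# scapulometry

Reliability analysis of manual 3D scapular landmark digitization and its
impact on measured scapular orientation.

## The problem

Scapular orientation in standing posture can be estimated by registering
a CT-derived scapula surface model to a few palpable anatomical
landmarks. The weakest link is the manual placement of those landmarks —
the ISB triplet of acromial angle (AA), inferior angle (IA) and trigonum
spinae (TS) — on the surface model. Before such landmarks can support
surgical planning (e.g. reverse total shoulder arthroplasty), their
intraobserver repeatability and interobserver reproducibility must be
quantified, both for the landmark coordinates themselves and for the
resulting 3D scapular orientation.

scapulometry is an R package for running exactly this kind of study: it
takes repeated digitizations of AA/IA/TS in a balanced
scapulae × observers × measures design and produces a per-parameter
reliability report. It is aimed at motion-analysis and orthopaedic
research groups running landmark-reliability or digitization-protocol
studies.

## What it computes

For each scapula, landmarks are averaged across all observers and
measures; the **average scapula coordinate system** is built from the
mean triplet per ISB rules (Z along AA→TS pointing medially, X the plane
normal pointing anteriorly, Y = Z × X, origin at AA), and every
digitization is re-expressed in it — making coordinates comparable
regardless of the imaging pose. A thorax reference frame is anchored at a
published resting scapulothoracic posture (41.1° protraction, 5.4° medial
rotation, 13.5° anterior tilt) and each digitization's own scapula frame
is decomposed against it with the mobile-axis **YXZ Euler sequence**
(e1 retraction/protraction, e2 lateral/medial rotation, e3
internal/external rotation).

The twelve resulting parameter series (9 coordinates in mm, 3 angles in
degrees) feed a crossed random-effects analysis,
`y[s,o,m] = mu + a[s] + b[o] + c[m] + e`, estimated by the closed-form
balanced-ANOVA method with zero-truncation:

    sigma2_total = sigma2_scapula + sigma2_observer + sigma2_measure + sigma2_residual
    ICC_intra    = (sigma2_total - (sigma2_measure  + sigma2_residual)) / sigma2_total
    ICC_inter    = (sigma2_total - (sigma2_observer + sigma2_residual)) / sigma2_total
    SEM          = sqrt(sigma2_total * (1 - ICC)),  95% CI half-width = 1.96 * SEM

plus mean absolute deviation summaries, ICC classification (poor <0.50,
moderate 0.50–0.75, good 0.75–0.90, excellent ≥0.90) and the effect-size
conversion `d = (1 - ICC) / (1 + (k - 1) * ICC)`.

The package also ships deterministic implementations of the landmark
positioning strategies (first >45° turning angle along the lateral
acromion edge for AA; most distal point of the medial edge for IA), file
I/O for plain landmark CSV, 3D Slicer `.fcsv` fiducials (RAS→LPS
conversion) and STL meshes, a blinded randomized work-list generator, and
a fully synthetic study generator with known ground truth.

## A worked example

```r
library(scapulometry)

# a synthetic 20-scapula study with known noise structure
cfg <- generator_config(n_scapulae = 20, seed = 42)
sim <- simulate_landmark_study(cfg)
run <- run_pipeline(sim$dataset)
format_reliability(run$reliability)
```

```
# A tibble: 12 × 12
   parameter unit  mad_mean mad_sd mad_ci_low mad_ci_high icc_intra sem_intra icc_inter sem_inter icc_intra_class icc_inter_class
 1 AA_X      mm         0.6    0.5        0.5         0.7      0.11       0.8      0.11       0.8 poor            poor
 2 AA_Y      mm         0.7    0.6        0.7         0.8      0.26       0.9      0.21       0.9 poor            poor
 3 AA_Z      mm         0.6    0.5        0.6         0.7      0.19       0.8      0.03       0.9 poor            poor
 4 IA_X      mm         0.7    0.5        0.6         0.7      0.09       0.8      0.03       0.9 poor            poor
 5 IA_Y      mm         0.6    0.5        0.6         0.7      0.9        0.9      0.91       0.9 excellent       excellent
 6 IA_Z      mm         0.7    0.5        0.7         0.8      0.98       0.8      0.97       1   excellent       excellent
 7 TS_X      mm         0.7    0.5        0.6         0.8      0.31       0.8      0.09       0.9 poor            poor
 8 TS_Y      mm         0.7    0.5        0.6         0.7      0.23       0.8      0.11       0.9 poor            poor
 9 TS_Z      mm         0.6    0.5        0.5         0.7      0.92       0.8      0.91       0.8 excellent       excellent
10 e1        deg        0.6    0.4        0.5         0.6      0.2        0.7      0.19       0.7 poor            poor
11 e2        deg        0.6    0.5        0.6         0.7      0.31       0.8      0.18       0.8 poor            poor
12 e3        deg        0.4    0.3        0.4         0.5      0.22       0.5      0.03       0.6 poor            poor
```

Reading it: dispersion is uniformly small (MAD ≤ 0.7 mm / 0.6°, every
SEM ≤ 1 mm / 0.8°) — the digitizations agree closely in absolute terms.
ICCs split into two regimes, and the split is structural: AA is the
origin of the average scapula frame and TS is pinned to its Z axis, so
those coordinates (and the angles, which are relative to each scapula's
own frame) retain little between-scapula variance, driving the
variance-ratio ICC down even at low noise. Coordinates that keep their
between-scapula variance (IA_Y, IA_Z, TS_Z) show excellent ICC. Low ICC
with low SEM means a parameter with little between-subject spread in
this frame, not an unreliable measurement.

`autoplot(run$reliability)` draws the ICC/SEM summary,
`plot_orientation_deviation(run$orientations)` the angular dispersion;
`tidy()`/`glance()` give broom-style access. `write_run(run, dir)` writes
coordinate, orientation and reliability reports with provenance headers.
A thin CLI over the same functions is installed at
`system.file("scripts", "scapulometry.R", package = "scapulometry")` with
`simulate`, `randomize`, `run` and `report` subcommands.

The methods vignette (`vignettes/landmark-reliability.Rmd`) documents the
frame conventions, the estimator, the generator's noise model and its
limits, and all numerical tolerances.

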