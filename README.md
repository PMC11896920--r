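# cinemotility

Quantification and characterisation of small intestinal motility from
dynamic (cine) 3D MRI, using centerline-aware motion estimation.

## The problem

Cine-MRI of the abdomen records one 3D volume per second during a
breath-hold, with a preparation drink rendering the small-bowel lumen
bright. Clinically useful motility read-outs have to be distilled from that
moving picture: how vigorously is luminal content moving, and is the motion
coordinated peristalsis (and in which direction along the segment) or
uncoordinated mixing? The confounders are severe — breathing and cardiac
motion, activity of neighbouring bowel loops, and the fact that the
intestine is a curved, drifting tube.

`cinemotility` implements the full analysis chain for a user-supplied
intestinal segment centerline:

1. **Registration** — bidirectional deformable registration between
   consecutive frames inside a 40 mm tube around the centerline, with two
   jointly-trained sinusoidal coordinate networks (implicit neural
   representations) under an objective combining normalized
   cross-correlation, a symmetric Jacobian-determinant penalty and a
   cycle-consistency penalty (networks, analytic gradients, Adam and the
   one-cycle schedule are implemented in plain R; no deep-learning
   framework is required). An `oracle_backend()` accepts any analytic
   displacement field in place of the trained networks.
2. **Common-mode suppression** — at each centerline point, the mean motion
   over a 30 mm disc is subtracted from the mean over a 0.5 mm disc
   (both orthogonal to the local tangent), cancelling motion shared with
   the surroundings.
3. **Centerline propagation** — every frame is registered directly to the
   reference frame; sampled displacements are smoothed 8 mm along the
   segment and 3 s across time.
4. **Velocity extraction** — the suppressed local displacement is projected
   onto the local unit tangent: a signed velocity in mm/s, assembled into a
   space–time velocity map (arc-length × frame interval).
5. **Metrics and classification** — the *mean velocity* v̄ (net
   directionality; opposing motions cancel) and *mean absolute velocity*
   |v| (magnitude of motility) feed two linear 1-D threshold classifiers:
   motile vs non-motile on |v|, then backward / bidirectional / forward on
   v̄, fitted and evaluated with subject-grouped 5-fold cross-validation.

A seeded 4D phantom generator (`generate_phantom()`, `preset_phantom()`)
provides bright tubular segments with exactly known intraluminal flow,
breathing-like translation and noise, so the whole chain is validated
against analytic ground truth.

## A worked example

```r
library(cinemotility)

ph  <- generate_phantom(preset_phantom("motile_forward", seed = 1,
                                       grid_shape = c(48, 48, 10),
                                       n_frames = 4, lumen_radius = 5))
map <- compute_velocity_map(ph$frames, ph$centerline,
                            backend = "oracle", truth = ph$truth)
aggregate_metrics(map)
#> # A tibble: 1 x 3
#>   mean_velocity mean_absolute_velocity n_samples
#>           <dbl>                  <dbl>     <int>
#> 1          1.85                   1.85       141
```

The phantom prescribes a sustained intraluminal flow of +2 mm/s. The
recovered mean velocity of 1.85 mm/s is positive (forward along the
centerline) and equals the mean absolute velocity, as it must for perfectly
coordinated motion; the ~7% shortfall from 2 mm/s is the expected dilution
of the suppression step (the 30 mm outer disc itself contains a small part
of the luminal flow, which is subtracted). A breathing-only phantom
(`preset_phantom("non_motile", ...)`) yields a mean absolute velocity of
~1e-15 mm/s: uniform translations cancel exactly in the differential
sampling.

`autoplot(map)` draws the space–time velocity heatmap with begin/middle/end
summary arrows; `synthetic_segment_table()` builds a 40-segment labelled
cohort, and

```r
cv <- cross_validate_classification(synthetic_segment_table(10, seed = 1),
                                    k = 5, seed = 2)
glance(cv)
#>   accuracy kappa auc_motility auc_peristalsis  n
#> 1        1     1            1               1 40
```

A thin command-line front end (`inst/cli/cinemotility.R`) exposes
`phantom`, `analyze`, `classify` and `evaluate` subcommands over the same
functions.

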