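---
title: "Modelling and optimizing stereo-EEG recording sensitivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and optimizing stereo-EEG recording sensitivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Stereo-EEG (sEEG) localizes the epileptogenic zone by implanting multi-contact
depth electrodes and recording interictal and ictal activity. Conventional
trajectory planning optimizes safety and grey-matter contact but is agnostic to
the *spatial recording sensitivity* of the resulting configuration: which
cortical territory actually produces discernible signals at the implanted
contacts. `seegrs` models that sensitivity explicitly and uses it to drive
electrode placement.

The chain of models is:

1. **Forward model.** Each cortical surface element carries a current dipole at
   its centroid, oriented along the outward normal. The analytic forward model
   is the current-dipole potential in an infinite homogeneous conductor,
   $V(\mathbf r) = \mathbf p \cdot (\mathbf r - \mathbf r_0) / (4\pi\sigma
   |\mathbf r-\mathbf r_0|^3)$, with $\sigma = 0.33$ S/m (standard grey-matter
   conductivity) and the reference at infinity. Columns over all sources form
   the lead field in V/(A·m). Patient-specific finite-element lead fields can
   be substituted through the JSON lead-field container (`read_lead_field()`),
   which is the intended route when tissue heterogeneity and anisotropy
   matter; the analytic model exists so that every downstream stage is exactly
   testable at desk scale.
2. **Extended sources.** Interictal spikes are generated by centimetres-scale
   patches of synchronous cortex, not point dipoles. A patch is grown around
   every element by accreting whole rings of edge-adjacent triangles until the
   target area is reached (6, 10 or 20 cm²). Its column in the patch lead
   field is the area-weighted sum of member dipole columns scaled by the
   dipole moment density (0.16, 0.465 or 0.77 nA·m/mm²), reported in µV. The
   3 × 3 grid of areas and densities brackets the physiological uncertainty;
   10 cm² at 0.465 nA·m/mm² is the default pair used in all headline analyses.
3. **Discernibility and the RS metric.** A spike is discernible when it clears
   the background noise; thresholds of 200, 500 and 1000 µV span "4 SD above
   typical noise" to "clinically obvious". A patch is *recordable by an
   electrode* when at least two of its 16 contacts see $|V|$ at or above the
   threshold (source localization needs multiplicity); the comparison is
   inclusive. The recording sensitivity of a configuration for a region of
   interest (ROI) is the percentage of ROI patches recordable by at least one
   electrode, $RS = 100\,P_{rec}/P_{total}$, and the optimization cost is the
   complement $C = P_{total} - P_{rec}$.
4. **Safe candidate trajectories.** Entries are sampled on a scalp cap,
   insertion directions within 10° of the inward scalp normal, and depths on
   the 3.5 mm contact-pitch lattice with total length under 10 cm, so
   electrodes sharing a line share contact points. Candidates are discarded
   when their 128-point shaft passes within 1.5 mm of the sulci surface, 4 mm
   of the inner skull (beyond the insertion region) or 4 mm of the midline
   plane; pairs closer than 4 mm are marked as collisions.
5. **Next-best search.** Electrodes are added greedily: at each step the
   non-colliding candidate with the largest decrease in unrecordable-patch
   count at the priority threshold wins; ties fall through the secondary and
   tertiary thresholds and finally a seeded random draw. The search stops at
   31 electrodes or when no candidate improves the priority cost. Because the
   search is prefix-greedy, the optimized configuration of any size X is the
   first X electrodes.

## The synthetic head

All stages are exercised on a parametric synthetic head so that no clinical
imaging is needed:

* Scalp and inner skull are subdivided icospheres (default radii 92 and
  87 mm).
* The cortex is an icosphere (default base radius 70 mm, subdivision 4 → 5120
  elements) radially modulated by
  $A\,\sin(f\theta)\cos(f\phi)$ with amplitude $A = 8$ mm and integer
  frequency $f = 6$: outward lobes act as gyri, inward troughs as sulci.
* The midline is the explicit plane $x = 0$ and the entry cap a 50° cap about
  $+x$, mimicking a lateral implantation field that must respect the midline.

These defaults keep the geometry anatomically scaled (head ~18 cm across,
cortex area ~600 cm², sulcal depth ~1.6 cm) while remaining star-shaped and
exactly analysable. What the generator does *not* emulate: true gyral
geometry (thin, deep, branching sulci), the CSF/skull/skin conductivity
profile, tissue anisotropy, and per-patient variability. Tests passing on
this geometry therefore validate the *algorithms* (metrics, filters, search)
and the unit bookkeeping — not clinical effect sizes, which require imaging
and FEM lead fields.

The trace simulator generates Gaussian background noise of configurable SD
per channel plus biphasic triangular spikes (60 ms wide; only the peak
amplitude enters any statistic) with a spike-free mask, supporting the noise
threshold (4 × spike-free SD, which brackets 99.99% of Gaussian samples) and
the spike-amplitude summaries (per-spike maxima after common average
referencing; mean and 25th-percentile maxima).

## Numerical and design choices

* **Units.** Millimetres internally everywhere; patch areas in cm² and patch
  voltages in µV at the interface. The assembled patch column is
  V/(A·m) × mm² × nA·m/mm², i.e. nV, converted with a single 10⁻³ factor.
* **Thresholding** uses $|V| \ge thr$: spikes are detected by magnitude
  regardless of polarity, and the boundary case counts.
* **Distance bins** for the recording radius are half-open, left-closed,
  0.25 cm wide; the radius is the right edge of the farthest bin whose
  across-contact median RS reaches the 20% floor. Empty bins are flagged,
  never interpolated. Percentiles use linear interpolation between order
  statistics.
* **Patch growth** admits whole adjacency rings, so the final area overshoots
  the target by less than one ring; membership is density-independent, and
  one patch is grown per cortical element (patch count equals element count).
  Patch extent is the mean Euclidean distance from the area-weighted member
  centroid to boundary vertices, in cm; Euclidean rather than geodesic
  because it is compared against Euclidean source–contact distances.
* **Sulci derivation.** The cortex is smoothed 100 times with umbrella
  (Laplacian) smoothing at weight 0.5. Plain umbrella smoothing shrinks a
  closed surface systematically — after 100 iterations the hull would sit
  inside the folds entirely — so the hull is rescaled about its centroid to
  preserve the mean vertex radius, mirroring the shrink-compensated smoothing
  filters used by mesh-processing tools. An element is sulcal when its
  centroid, pushed 2.5 mm along the outward normal, still lies inside the
  hull (generalized winding number > 0.75). The 2.5 mm depth clearance
  absorbs facet depression and residual smoothing anisotropy, so a convex
  cortex yields an empty sulci surface and a folded one yields exactly the
  inward-trough bases.
* **Skull clearance near the entry.** The skull filter necessarily fails where the
  electrode crosses the skull, so shaft points within 10 mm of the entry are
  exempt; 10 mm is configurable (`skull_skip`).
* **Shaft sampling.** The 128-point shaft representation specified for
  collision testing is reused for all clearance filters. Collision pruning
  uses the exact segment–segment distance as a lower bound, so the pruned
  result equals the brute-force all-pairs computation bit for bit.
* **Tie-breaking** in the greedy search compares exact integer patch counts
  (no floating-point ties), then draws from a seeded generator recorded in
  the configuration. Colliding candidates are masked permanently once a
  conflicting electrode is chosen.
* **Contacts are single points** at contact centres; electrode bodies are not
  meshed. Contact lattices are deduplicated per line (trajectories on one
  line share 15 of 16 contacts between consecutive depths), which shrinks the
  lead field several-fold.
* **Sampled recording locations** (for radius estimation) are drawn
  area-weighted from an equal-area two-hemisphere partition of the cortex (35
  regions per hemisphere by default, 3 points each = 105 per hemisphere) and
  offset 1 mm inward so they never coincide with a dipole.
* **Pipeline order.** `run_pipeline()` runs synth → trajectories → leadfield →
  patches → optimize → report: the analytic model evaluates potentials at
  contact positions, so trajectories must exist before the lead field.
  Stages are skipped when their outputs are present, making runs resumable;
  a manifest records package version, seeds, parameters and a configuration
  hash.

## Problem sizes used in the test suite

The full-scale synthetic study used by the acceptance-level checks runs a
subdivision-4 cortex (5120 patch sources), ~3400 raw candidates thinned to
~1700 valid trajectories on 240 lines (~4100 unique contacts), the default
10 cm²/0.465 nA·m/mm² source, and a 45° cap ROI of ~750 elements. These sizes
were chosen so the whole study builds in about a minute on one CPU while
keeping every structural property of the full-scale problem (shared contact
lattices, collision density near 10%, thousands of patches). The optimizer is
validated against exhaustive enumeration on instances small enough to
enumerate (≤ 12 candidates, ≤ 3 electrodes) and against 100 seeded random
valid configurations at full scale.

## Behaviour worth knowing about

* A uniform dipole layer of density $p_s$ produces at most about
  $p_s/(2\sigma)$ near its surface — ~704 µV at 0.465 nA·m/mm². On the gently
  curved synthetic cortex at subdivision 4, two contacts 3.5 mm apart
  therefore never both clear 1000 µV, and RS at the 1000 µV threshold is 0
  throughout the full-scale synthetic study (coarser meshes have larger
  facets whose near-field can exceed 1 mV, so small demonstration runs may
  show nonzero RS there). This is a genuine property of the geometry, not a defect:
  real cortical folding wraps patches around contacts and lifts the local
  solid angle, which is how 1000 µV signals arise clinically. The stronger
  grid sources (e.g. 0.77 nA·m/mm²) do clear 1000 µV.
* The greedy search is not globally optimal (the covering problem has no
  optimal substructure); on every enumerable instance in the suite its gap to
  the exhaustive optimum was 0, but the tests only assert that it is never
  better and report the gap.
* Transfer of a configuration between heads is rigid (rotation + translation,
  validated to determinant +1); transferred electrodes within 2.5 mm of the
  target's sulci mark the configuration invalid, but all electrodes are kept
  in the transferred RS to measure the best case, and the comparison is made
  at the smallest electrode count reaching 75% RS in the matched case.

## Limitations

The infinite homogeneous conductor has no skull or scalp: absolute voltages
near the skull are overestimated relative to a layered head, so absolute
thresholds map onto different effective distances than in a FEM model — the
import path exists precisely for that. The synthetic folding is periodic and
shallow compared with real sulci; safety filtering against real vasculature
requires angiography, which is out of scope. The equivalent-point-dipole
surrogate used for the headline recording radius collapses the extended patch
to its total moment, which is exact on-axis in the far field and increasingly
conservative inside one patch radius.
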