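---
title: "Methods: segregation statistics and PPC reduction in mesomix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segregation statistics and PPC reduction in mesomix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesomix)
```

This vignette records how the package's two analysis tracks are defined —
the structural statistics computed on particle configurations, and the
pressure-perturbation-calorimetry (PPC) reduction — together with every
numerical choice that was genuinely open and the reasoning behind it.

## The segregation statistic

A mixture configuration is a set of molecules labelled water or alcohol in
a periodic orthorhombic box. The box is divided into `n_boxes` equal cells
(default 1000, a 10×10×10 grid). A water molecule occupies the single cell
containing its oxygen; an alcohol occupies every distinct cell containing
at least one of its three carbons, so a molecule straddling a cell face is
present in up to three cells. Cells are half-open, `[0, L/n)` per axis,
over wrapped coordinates, so each atom maps to exactly one cell and
boundaries are never double-counted.

Accumulating cell counts over an ensemble of configurations gives the
occupancy distribution `N(x)`: the fraction of (cell, configuration) pairs
holding exactly `x` alcohols. The non-ideality statistic is the Euclidean
distance between the simulated distribution and that of a matched random
null,

$$\mathrm{non\text{-}ideality} = \sqrt{\sum_x \left[N_s(x) - N_R(x)\right]^2},$$

summed over the union of observed occupancies with absent entries as zero.
The null ensemble consists of independent configurations with molecule
positions uniform in the same box at the same composition — steric overlap
is deliberately permitted, because the statistic depends only on cell
membership, not on physically realistic packing. When the simulation side
is atomistic the null is built atomistic too (rigid ideal-geometry
molecules, orientations uniform on SO(3) via quaternion sampling), so the
orientation-sensitive carbon rule acts identically on both sides of the
difference.

Choices that were open:

* **Which species enters the statistic.** The distribution compared is the
  *alcohol* occupancy; water occupancy is computed and available through
  `build_distribution(..., "water")` but excluded from the statistic. A
  joint (water, alcohol) histogram would mix two strongly anti-correlated
  marginals and has no extra discriminating power for alcohol clustering,
  so only the two marginals are exposed.
* **Ensemble sizes.** Defaults are 2500 configurations on both sides. At
  the reference scale (3000 molecules, 1000 cells) this puts the
  sampling-noise floor of the statistic — the value obtained when both
  ensembles are random — around 10⁻⁴, two orders of magnitude below the
  weakest segregation signal the statistic is asked to resolve (~0.06).
  The acceptance suite verifies the floor is below 0.01.
* **Scaled-down systems.** `auto_partition()` chooses
  `n_boxes = round(n_molecules / 3)`, preserving the reference setting's
  mean occupancy of 3 molecules per cell so values remain comparable
  across system sizes. Unit tests run at 300 molecules / 100 cells for
  speed; the acceptance suite runs the full 3000 / 1000 / 2500 setting.

## Hydrogen-bond detection and classification

A hydrogen bond is a donor O–H ··· acceptor O contact satisfying two
geometric tests: the angle at the hydrogen within 150°–210°, and the
hydrogen-to-acceptor-oxygen distance strictly below 2.5 Å. A geometric
angle cannot exceed 180°, and the band is symmetric about linearity, so it
is applied by folding: an angle `a` passes if `a` or `360° − a` lies in the
band — with the defaults, simply `a ≥ 150°`. Distances and the angle's
acceptor arm use the minimum-image convention; covalent O–H assignment
comes from the molecular template, never from distance inference, which
avoids misassignment at close contacts in overlap-permitted synthetic
configurations.

Each alcohol is then classified: `PP` if it has any bond (as donor or
acceptor) to another alcohol, else `PW` if it has any bond to a water,
else `none`. The PP > PW precedence makes the classes mutually exclusive
and exhaustive, so per-frame percentages sum to exactly 100. The packaged
reference table of bond-class percentages has rows summing slightly below
100, so its (unpublished) classification rule differed in some detail;
comparisons against it should use the printed values with tolerance rather
than expect the residual to be reproduced. Trajectory summaries are means
of per-frame percentages over a trailing window (default 1000 ps, or all
frames if shorter). Water–water bonds are detected but not summarised, as
the classification is alcohol-centric.

The detector is validated two ways: nine hand-built toy geometries whose
bond counts are forced by construction (including a pair bonded only
through the periodic image, and near-threshold cases at 149°/151° and
2.49 Å/2.51 Å), and exact set-equality against an independent brute-force
all-pairs enumeration on 100 random dense configurations of up to 60
molecules.

## Synthetic data: what it does and does not emulate

The generators provide *planted ground truth*, not liquid-state physics:

* `gen_random_mixture()` — uniform positions (the null model itself);
  atomistic mode adds rigid minimal templates: water as O + two H
  (0.96 Å, 104.5°), alcohol as a central carbon, two further carbons
  (1.53 Å, tetrahedral), hydroxyl O (1.43 Å) and H (0.96 Å).
* `gen_clustered_mixture()` — a chosen fraction of the alcohols placed as
  wrapped Gaussian displacements (sd `cluster_sigma`, default 2 Å) around
  uniform cluster centres. Clustered fraction 0 reduces draw-for-draw to
  the random generator, giving a continuous dial from ideal mixing to a
  single tight cluster.
* `gen_thermogram()` — a temperature ramp (0.1 °C/min) carrying one
  pressurization pulse per 600 s interval with the matching
  depressurization half an interval later, so up-pulses arrive at every
  1 °C and events alternate up/down starting up. Each pulse deposits a
  spike (rectangular, Gaussian or exponential-decay) whose integrated area
  equals the requested heat before noise; depressurization mirrors the
  sign. A half-interval lead-in precedes the first pulse so it has a
  pre-event baseline window.

When no box is given, the cubic box edge is derived from the 25 °C molar
volumes of water (18.07 cm³/mol) and 2-propanol (76.92 cm³/mol), i.e. the
volume a liquid-density simulation box of that composition would have.
Molecule counts from mole percentages use round-half-up, which is
deterministic and maps 3000 × 2.5 % to exactly 75.

Because random and clustered configurations carry no attractive
interactions, their hydrogen-bond counts are far below those of an
equilibrated liquid; passing bond-classification tests on them validates
the *geometry and logic* of the detector, not the thermodynamics of real
mixtures. Equally, reproducing the published bond-class percentages and
non-ideality values for real 2-propanol/water systems requires equilibrated
molecular-dynamics trajectories, which are outside the scope of this
package; the statistic itself is validated by its closed-form binomial
limit, its sampling-noise floor, and its strictly monotone response to the
planted clustering dial (exceeding 0.4 at full single-cluster segregation,
the magnitude of the strongest published values).

All generators are pure functions of their specification and seed
(RNG state is isolated with `withr::with_seed`), so every pipeline output
is reproducible byte for byte.

## PPC reduction

Spike integration (`integrate_pulse`) estimates the baseline by linear
interpolation between the medians of a pre-event window and a window just
before the next event (60 s each by default; constant and natural-spline
alternatives exist). The integration segment runs from the event start to
the start of the post-baseline window — that window is by construction at
baseline and may already carry the leading tail of the next spike. Within
the segment, the spike has "returned to baseline" at the first sample whose
excess stays within twice the noise sd of zero for 10 consecutive seconds
at or after the spike extremum; the noise sd is estimated from the
detrended pre-window, with a floor of 10⁻⁶ µW so the criterion remains
well-defined for noise-free synthetic input. A spike still away from
baseline at the cap is integrated to the cap and flagged unreliable rather
than silently accepted. Integration is trapezoidal; the rectangular
synthetic spike is aligned to the sample grid (`(t₀, t₀ + duration]`) so
the closure `reduce(gen(areas))` is exact for it, and within 0.005 % for
the smooth shapes.

`reduce_thermogram` assigns each event the sample temperature at its start
and by default trims the series to the usable 9–61 °C range. Up- and
down-pulses are kept separate; gradients default to the up-pulse
(pressurization) series.

`window_gradient` fits `ΔQ/Δp` against temperature by ordinary least
squares over a window (defaults 9–35 °C and 35–61 °C). A single-predictor
partial-least-squares fit with one component is equivalent to OLS up to
scaling, so OLS is used outright and a single slope per window is
reported. Fits with R² below 0.8 are flagged low-confidence, not dropped;
an exactly constant series is given R² = 1 (zero residual, zero slope)
rather than NaN. Slopes are reported natively in µJ·bar⁻¹·K⁻¹. The
packaged reference table prints its gradients in mJ·bar⁻¹·K⁻¹, a label
hard to reconcile dimensionally with its own heats; those columns are
therefore shipped verbatim as data and never used as regression targets,
and the package applies no hidden unit conversion.

`delta_delta_q` subtracts the straight line between the 0 and 100 mol%
endpoints; it is identically zero on any affine-in-composition series and
at the endpoints themselves, which is the invariant the tests assert.

## Expansivity equations

The two heat models and the heat-capacity identities are implemented as
forward evaluations plus linear inversions, with temperature in kelvin and
pressure converted bar → Pa internally (heats cross the interface in µJ):

* `ΔQ = T Δp (α₀ − ᾱ) V_part g_s`, invertible for ᾱ; valid at low solute
  concentration where the apparent volume approximates the
  infinite-dilution partial specific volume.
* `ΔQ = T Δp x_s [(n+1) V_b α_b − n V̄_h ᾱ_h − V_s α_s] + A′`, invertible
  for any one of ᾱ_h, n or A′. A′ is treated purely as a free offset.
  Solving for n fails cleanly when the bulk and hydration terms cancel
  (`V_b α_b = V̄_h ᾱ_h`), where the model carries no information about n.
  The model describes isolated solutes with discrete hydration layers and
  is not applicable once solutes form extended networks — the package
  therefore never fits it to the packaged mixture-series table.
* `[δC̄p,part/δp]_T = −T ∂²V_part/∂T²`, evaluated analytically from
  polynomial coefficients of V(T); the equivalent form
  `−T ∂(V_part ᾱ)/∂T` is available for tabulated data via central finite
  differences (≥ 3 points). The analytic form is negative wherever V(T)
  is strictly convex, which the tests assert on the formula itself.

Forward–inverse round trips close to 10⁻¹⁰ relative or better; the
polynomial form agrees with a well-conditioned central-difference oracle
to 10⁻⁸ relative (difference step chosen near the truncation/round-off
optimum for the magnitudes involved).

## File formats and degenerate inputs

XYZ (with `box=Lx,Ly,Lz` comment metadata), formatted DL_POLY HISTORY
(read-only, coordinates retained, velocities/forces skipped) and thermogram
CSV are read by the package; PDB atom records go through bio3d with the
CRYST1 cell handled directly. Molecules are recognised by greedy,
order-insensitive template matching over contiguous atom blocks; an
unmatchable block is an error naming the offending line, as is a truncated
HISTORY frame (naming the last complete frame) or a non-monotone thermogram
time axis (naming the first offending row). Only orthorhombic cells are
accepted anywhere — the equal-cell partition presumes them — and triclinic
input is an error, never a silent conversion. Configurations may be
point-mode (reference points only) for segregation-only work; hydrogen-bond
operations reject them explicitly. Mixed periodic flags are rejected by the
consumers that need an unambiguous wrapping rule.

## Problem sizes and limitations

The test suite validates unit behaviour at reduced scale (hundreds of
molecules, hundreds of ensemble configurations) and the acceptance checks
at the reference scale: 3000 molecules, 1000 cells, 2500-configuration
ensembles, and full 7–62 °C pulse schedules; the complete run takes about a
minute on one CPU. Known limitations: no triclinic or binary HISTORY
support; no bond-lifetime or cluster-percolation analysis; the hydration
model is not fitted to experimental series (by design, see above); and
synthetic configurations validate algorithmic correctness, not
forcefield-level realism.
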