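# mesomix

Analysis of mesoscopic structure in binary alcohol/water mixtures, and
reduction of pressure perturbation calorimetry (PPC) data.

Aqueous mixtures of small amphiphilic alcohols such as 2-propanol are not
homogeneous at the nanometre scale: above a few mole percent the alcohol
molecules hydrogen-bond to each other and segregate into transient clusters
and extended networks. Two complementary views of that structure are
implemented here for people analysing particle configurations from molecular
simulation and thermograms from PPC instruments:

* **Structural side** (simulation configurations): a geometric hydrogen-bond
  detector with full periodic-boundary handling, alcohol-centric bond
  classification (alcohol–alcohol *P–P*, alcohol–water *P–W*, unbonded), and
  a mesoscale **segregation statistic**. The box is divided into *n* equal
  cells (1000 by default), the distribution *N(x)* of cells containing *x*
  alcohol molecules is accumulated over an ensemble of configurations, and
  compared against the same distribution for an ensemble of randomly mixed
  configurations of identical composition and volume:

      non-ideality = sqrt( sum_x [ N_s(x) − N_R(x) ]² )

  Zero means statistically random mixing; larger values mean segregation.

* **Calorimetric side** (PPC thermograms): baseline-corrected integration of
  the thermal spikes caused by ±Δp pressure pulses into a pressurization-heat
  series ΔQ(T); window gradients of ΔQ/Δp versus T (the pressure derivative
  of the average heat capacity, [δC̄p/δp]_T); the deviation ΔΔQ of ΔQ from
  linear mixing between the pure-water and pure-alcohol endpoints; and the
  thermodynamic models connecting ΔQ to expansivities —
  ΔQ = TΔp(α₀ − ᾱ)V_part·g_s, the discrete hydration-layer model
  ΔQ = TΔp·x_s[(n+1)V_bα_b − n·V̄_h·ᾱ_h − V_s·α_s] + A′, and the identities
  [δC̄p,part/δp]_T = −T·∂²V_part/∂T² = −T·∂(V_part·ᾱ)/∂T.

A synthetic-data module generates randomly mixed and deliberately clustered
configurations, hand-built hydrogen-bond geometries, and thermograms with
planted pulse areas, so every analysis stage is testable against known ground
truth without running a simulation engine or an instrument. Readers are
included for XYZ (extended comment-line box), PDB (CRYST1 orthorhombic),
DL_POLY HISTORY (formatted, read-only) and thermogram CSV files.

## Worked example

```r
library(mesomix)

## segregation: 300-molecule 25 mol% mixture, half the alcohols planted in
## one Gaussian cluster, against a matched random null
sp   <- mixture_spec(300, 25, seed = 1)
traj <- gen_mixture_trajectory(sp, n_frames = 200,
                               cluster = cluster_spec(1, 2, 0.5))
trajectory_non_ideality(traj, seed = 2)
#> non_ideality (alcohol occupancy): 0.1934

## hydrogen-bond classes of a dense random atomistic configuration
cfg <- gen_random_mixture(mixture_spec(60, 30, box = simulation_box(12),
                                       seed = 3), atomistic = TRUE)
summarize_trajectory(trajectory(list(cfg)))
#> hbond_summary over 1 frame(s), 18 alcohol molecules
#>   P-P 0.00%  P-W 22.22%  no bonds 77.78%

## PPC closure: planted heats -1000 + 40·T µJ at ±4 bar give a slope of
## exactly 10 µJ/(bar K)
spec <- thermogram_spec(function(T) -1000 + 40 * T, t_start_C = 7,
                        t_end_C = 37, spike_model = "gauss")
dq <- reduce_thermogram(gen_thermogram(spec))
window_gradient(dq, window = c(9, 35))
#> gradient over 9-35 C: 10.000 uJ/(bar K) (R^2 = 1.000, n = 27)

## deviation from linear mixing, from the packaged reference table
dd <- delta_delta_q(load_fixture("table1")[, c("mole_percent", "dq_uJ")])
dd[dd$mole_percent %in% c(0, 20, 100), ]
#>    mole_percent  dq_uJ   ddq_uJ
#> 1             0     70      0.0
#> 14           20 -21630 -15924.4
#> 18          100 -28808      0.0
```

The non-ideality of 0.19 sits between the random-mixing floor (< 0.01 for
matched 2500-configuration ensembles) and the fully segregated regime
(> 0.4 for a single tight cluster), as expected for half-planted clustering.

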