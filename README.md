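# gvbleb — giant-vacuole formation by inverse blebbing

Schlemm's-canal endothelial cells drain aqueous humour from the eye. Under a
basal-to-apical pressure drop Δp they form **giant vacuoles (GVs)**: large
fluid-filled invaginations of the basal membrane that bulge *into* the cell
body — inverse blebs, with polarity opposite to ordinary cellular blebs.
`gvbleb` implements a coarse-grained mechanical model of this process for
biophysicists and mechanobiologists who want to explore how pressure,
cortical contractility and membrane reservoirs set GV size, growth and
collapse kinetics, and competition between neighbouring vacuoles.

## The model

The vacuole is a spherical cap of radius *r* and opening angle *θ* pinned at
a basal pore of half-width *a* (*r* sin *θ* = *a*, π/2 ≤ *θ* ≤ π), inflating
inside a hemispherical cell of radius *R*. Its radius obeys an overdamped
Rayleigh–Plesset balance at the cell–bleb interface,

    dr/dt = r/(4μ) · [Δp − P − 2Σ/r],

with μ an effective cytoplasmic viscosity, Σ the bleb surface tension, and
the intracellular pressure slaved to the Laplace law of the cell,
P = 2σ/R. There is no leakage, so the cell swells by exactly the cap
volume: R³ = R₀³ + Σᵢ 2rᵢ³(2 + cos θᵢ) sin⁴(θᵢ/2).

Tensions follow a **two-regime law** keyed on relative area strain. While
the strain of the membrane patch feeding the bleb stays below the reservoir
threshold ε\*, area increase is buffered (caveolae, wrinkles, microvilli,
exocytosis) at the constant cortical plateau σ₀ = σ_m + σ_c, which the
rebuilt contractile shell approaches exponentially on the actin-turnover
time τ_c. Once the reservoir is exhausted (patch area S > S\* =
πd²(1 + ε\*)) the taut membrane stiffens instantaneously:
Σ̄ = σ₀ + K_m[e^((S−S\*)/S\*) − 1].

Steady states solve Δp = 2Σ̄(r)/r + 2σ̄(r)/R. The cortex branch
(Σ̄ = σ₀, small *r*) is unstable and sets the threshold nucleation radius;
the membrane branch (large *r*) is stable and is the observed GV. The two
meet in a saddle-node at the nucleation threshold pressure
Δp\* ≃ 2σ₀(R + r)/(Rr); above Δp† ≈ 2σ₀/a + 2σ₀/R₀ only the membrane
branch survives. Vacuoles nucleated within a tension-equilibration distance
*d* of each other share one membrane patch and compete for it — an
Ostwald-ripening coarsening in which the larger vacuole wins.

## Worked example

```r
library(gvbleb)
p <- gv_params()                 # reference cell: R0 = 10, d = 10, eps* = 0.5

gv_equilibria(mmHg_to_pN_um2(7), p)
#> Steady-state configurations (2 found)
#>  delta_p delta_p_mmHg      r     R Sigma sigma   branch stable  volume
#>    933.3            7 0.9735 10.01   414   414   cortex  FALSE   3.862
#>    933.3            7 3.5985 10.30  1535   414 membrane   TRUE 195.186
```

At the physiological 7 mmHg the model is bistable: nuclei smaller than the
unstable cortex-branch radius (~1 μm) deflate, larger ones grow to the
~3.6 μm stable GV. Growth and collapse kinetics:

```r
traj <- gv_simulate(p, gv_protocol(delta_p_mmHg = 30, t_max = 300))
time_to_steady(traj)             # 1.92 min to reach the 3.89-um steady GV
coll <- gv_collapse(p)           # prepare at 30 mmHg, then remove the pressure
attr(coll, "collapse_time_min")  # 5.72 min to deflate back to r = a
```

Collapse is slower than growth because deflation is driven by tension alone.
Thresholds and coarsening:

```r
pN_um2_to_mmHg(nucleation_pressure(p))   # 2.36 mmHg  (saddle-node, Delta-p*)
pN_um2_to_mmHg(bistability_pressure(p))  # 25.46 mmHg (Delta-p-dagger)

tr <- gv_simulate_multi(p, gv_protocol(delta_p_mmHg = 7, t_max = 3600),
                        r0 = c(1.1238, 1.1241))   # shared patch
coarsening_summary(tr)
#> $survivors: 1   $winner: 2   $symmetry_breaking_time_min: 13.3
```

Two near-identical vacuoles sharing a patch grow together until the shared
reservoir runs out, then the marginally larger one takes all the stretchable
membrane and the smaller collapses — only one GV per patch matures.

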