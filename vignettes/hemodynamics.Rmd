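---
title: "A closed-loop lumped-parameter model of neonatal hypertension hemodynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A closed-loop lumped-parameter model of neonatal hypertension hemodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`cvloop` implements a closed-loop zero-dimensional (0D) model of the human
circulation in the four-chamber Windkessel tradition.  The circulation is a
single conserved volume of blood moving through fourteen dynamical
variables:

* **four chamber volumes** — left/right ventricle and atrium
  (`V_lv, V_la, V_rv, V_ra`, ml);
* **six compartment pressures** — systemic aortic sinus, systemic artery,
  systemic vein, and their pulmonary analogues
  (`P_sas, P_sat, P_svn, P_pas, P_pat, P_pvn`, mmHg);
* **four inertance-branch flows** (`Q_sas, Q_sat, Q_pas, Q_pat`, ml/s).

Each heart chamber obeys the time-varying elastance law

\[ P_{ch}(t) = E_{ch}(t)\,\big(V_{ch} - V_{ch,0}\big), \qquad
   E_{ch}(t) = E_{min} + (E_{max}-E_{min})\,e(t), \]

where the ventricular activation \(e(t)\) rises as a half-cosine on
\([0, T_{s1})\), falls on \([T_{s1}, T_{s2})\) and is zero for the rest of
the cycle; the atrial activation is a full-cosine bump of width
\(T_{pww}\) starting at \(T_{pwb}\) (wrapping across the cycle end).  The
peak of the activation maps the elastance to exactly \(E_{max}\).

The four valves are unidirectional square-root orifices,
\(Q = C_Q \sqrt{\Delta P}\) for a positive gradient and zero otherwise —
continuous at zero gradient, so the right-hand side needs no event
detection.  Each Windkessel compartment contributes
\(\dot P = (Q_{in}-Q_{out})/C\), and each inertance branch
\(\dot Q = (\Delta P - R\,Q)/L\).  Summing chamber volume rates and
compliance-weighted pressure rates gives identically zero: the loop is
closed and total stressed volume

\[ V_{tot} = \sum_{ch} V_{ch} + \sum_i C_i P_i \]

is an exact invariant of the equations (`total_volume()`), which the test
suite uses as a conservation oracle.

The default parameter set (`cv_params()`) is the published reference set of
the Shi four-chamber model as distributed through the CellML repository:
left-ventricular elastance 0.1–2.5 mmHg/ml, right 0.1–1.15, atria
0.15–0.25; valve coefficients 350/400/400/350 ml s⁻¹ mmHg⁻½; systemic
chain R = 0.003/0.05/0.5/0.52/0.075 mmHg·s/ml with C = 0.08/1.6/20.5
ml/mmHg; pulmonary analogues an order of magnitude less resistive.  All
units are mmHg, ml, s; there is no internal unit conversion.  The set
ships as a flat `name = value # unit` text file
(`inst/extdata/default_params.txt`) that round-trips losslessly.

## Initial conditions and the conserved volume

Because the loop conserves \(V_{tot}\) exactly, the initial state decides
the circulating volume, and through it every operating pressure.  A state
with literally all variables at zero holds \(V_{tot}=0\) and can never
pressurize the aorta.  The package therefore defines the protocol's
starting point as the model's *distributed reference state*
(`cv_init_state(kind = "nominal")`): filled ventricles (500 ml each),
small atrial volumes (20 ml each) and systemic arterial compartments
primed at 100 mmHg — a total stressed volume of about 1.2 l.  With that
state the baseline model settles to a systolic/diastolic aortic pressure
of about 121/83 mmHg, a systemic venous pressure near 15 mmHg, and a
left-ventricular volume excursion of roughly 53–134 ml.

What *is* independent of the initial conditions is the steady oscillation
reached from any initial **distribution** of the same total volume: the
acceptance suite redistributes 100 ml between the ventricles and swaps
50 ml of arterial storage into the veins, and requires last-window metrics
to agree within 0.5%.  `kind = "nil"` (a truly empty circulation) is kept
for degeneracy checks: with constant elastances and zero unstressed
volumes it is an exact fixed point and every waveform stays identically
zero.

## The steady-oscillation protocol

`cv_simulate()` integrates 1000 s from the reference state, discards the
wash-in, and returns the final 20 s sampled at 1 ms (at least 500 samples
per cycle down to a 0.5 s period; systolic maxima resolved well below
0.1 mmHg).  Integration uses `deSolve::lsoda` — adaptive and
stiff-capable — with relative and absolute tolerances of 1e-8 and a
maximum step of T/100 so valve switching is never stepped over.  The first
980 s are integrated without dense output.

Steadiness is not an exception but a measurement: `check_steady()`
compares the last two full cycles per waveform, normalizing the sup-norm
cycle difference by the final cycle's range (floor 1e-9 for flat
signals), and declares steady oscillation below a residual of 1e-3.  The
baseline run settles near 1e-5.  Two built-in cross-checks pin the
integrator: an analytic two-element Windkessel driven by a pulse train
(`windkessel_oracle()`, matched to < 1e-6 relative error) and the
dual-route comparison of the compiled C right-hand side against the
reference R implementation (`use_compiled = FALSE`).

The choices that the protocol leaves open were fixed as follows and are
deliberately conservative:

* **Steadiness criterion** — cycle-to-cycle sup-norm residual < 1e-3 on
  all waveforms; the slowest tested condition (25-fold arteriolar
  resistance, venous redistribution time constant of roughly 250 s) still
  settles below it within the 1000-s protocol.
* **Pacing-period changes rescale the activation timings
  proportionally** (`set_period()`), keeping systole a fixed fraction of
  the cycle.  The alternative — absolute 1-s-cycle timings — violates the
  timing invariants (\(T_{s2} < T\), \(T_{pwb} < T\)) at the 0.5 s period
  used in the fast-pacing experiments; it was tested anyway (with the
  atrial onset wrapped into the shorter cycle) and gave no better
  agreement with the fast-pacing benchmark values.

## Hypertension scenarios and sweeps

Disease conditions are multiplicative parameter perturbations
(`cv_scenario()`), applied functionally (`apply_scenario()` never mutates
the baseline; application commutes and composes).  Two named scenarios are
built in:

| scenario | arteriolar resistance | aortic compliance | LV max. elastance |
|----------|----------------------|-------------------|-------------------|
| `scenario_h1()` (literature-motivated) | × 1.5 | × 0.47 | × 2 |
| `scenario_h2()` (exaggerated)          | × 25  | × 0.25 | × 10 |

Only `E_lv,max` is scaled for hypertrophy — the diastolic elastance is
untouched — and the named scenarios scale `R_sar` and `C_sat` by default.
Because the model does not functionally distinguish the arteriole from
the capillary bed, `resistance_target = "R_scp"` retargets the factor, and
`stiffness_targets` can extend the compliance factor to the venous
compliances.  The *panel* experiments that explore one mechanism at a
time use the broader targets, matching the clinical-condition
definitions these mechanisms encode: peripheral-resistance experiments
scale `R_sar` and `R_scp` together (the model does not functionally
separate the two), and stiffness experiments reduce all three
large-vessel compliances (`C_sat`, `C_svn`, `C_pvn`).  With those
definitions a moderate resistance rise lowers vena-cava flow by about
10% and the severe one by more than 80% — the hemodynamic signature of
oliguric renal microvascular disease.

`sweep_1d()` and `grid_2d()` drive the full protocol per grid cell,
record each cell's steadiness residual, continue past per-cell failures,
and return tidy tables.

## Dynamic local sensitivity analysis

`dynamic_sensitivity()` implements the parameter-scaled local index

\[ S_{ij}(t) = p_j \frac{\partial V_i}{\partial p_j}, \]

by central finite differences: two full steady protocols at
\(p_j(1 \pm h)\), aligned by simulation time (both runs share the pacing),
differenced over the last cycle.  The default step is \(h = 1\%\); the
central scheme is second-order, and the test suite requires the cycle-mean
index to move by less than 2% when the step is halved, bracketing a
plateau over \(h \in \{0.5\%, 1\%, 2\%\}\).  The kernel itself
(`sensitivity_kernel()`) is exact for responses linear or quadratic in the
parameter, which the suite pins against closed forms.  Sensitivity to the
pacing period is deliberately unsupported: the two runs would drift out of
phase and the pointwise difference would measure phase slip, not
sensitivity.  Indices are evaluated in a *context* — baseline, `h1` or
`h2` — so that treatment priorities can be compared between operating
points (`compare_contexts()` ranks parameters by cycle-mean |S|).  The
package reports sensitivities with respect to the compliance parameter
itself; stiffness is its reciprocal, so the negative systolic
pressure–compliance sensitivity (a stiffer aorta raises the systolic
peak, while diastole runs higher with more storage) reads as a positive
pressure–stiffness sensitivity.

## Clinical series post-processing

The clinical module is deliberately small: a daily systolic
blood-pressure series (`bp_series()`, CSV schema `day,systolic_mmHg`) is
smoothed with a centered running mean (`running_mean()`).  The window is
5 days by default — the smoothing scale is a presentation choice, so it is
a parameter — and the edges use a shrinking window: no padding, no dropped
days, so the first and last day keep values.  `hypertension_flags()`
compares the *smoothed* series against a healthy reference (default
100 mmHg) with strict inequality, and summarizes the excursion (peak,
peak day, percent rise from the first observation).  Aortic diameter
tables (`diameter_table()`, four canonical ascending-aorta sites) reduce
to per-site percent changes between two exams (`diameter_changes()`);
swapping the exams maps a change of \(x\%\) to \(100(1/(1+x/100)-1)\%\),
which the suite checks as an antisymmetry property.

## Synthetic data

`gen_bp_series()` emulates the clinical course — a linear rise from
90 mmHg on day 1 to about 115 mmHg on day 15, then an exponential
relaxation toward baseline, with Gaussian observation noise (sd 3 mmHg
by default) — purely as a function of its seed.  It reproduces the
*shape* of a treated hypertensive course, not patient physiology: no
day-to-day autocorrelation, no measurement dropout, no treatment-phase
covariates.  Tests that pass on it therefore validate the smoothing and
flagging arithmetic, not clinical inference.  `gen_parameter_ensemble()`
draws log-uniform multiplier ensembles (mirroring the multiplicative
scenario language) for robustness studies, validating every draw against
the parameter invariants.  The shipped diameter table
(`inst/extdata/synthetic_aortic_diameters.csv`) is likewise synthetic:
constructed from the day-1 anchor and the reported month-5 percent
changes, so the worked example reproduces those changes by computation
rather than by quotation.

## Numerical choices, problem sizes, limitations

* Tolerances: rtol = atol = 1e-8; cross-checked at 1e-6 vs 1e-9
  (systolic aortic pressure agrees within 0.5%) and under max-step
  halving (metrics move < 0.1%).
* The analysis window reduction uses max/min over the whole 20-s window;
  at steady oscillation this coincides with per-cycle statistics.  Stroke
  work integrates the last full PV loop by the shoelace rule (rotation
  invariant; elliptical loops recovered to 0.5% at 1 ms sampling).
* Unit tests run shortened protocols (30–200 s) where only structure is
  under test; every reported physiological quantity in the acceptance
  suite uses the full 1000-s protocol.
* The model has no baroreflex or autoregulation, no valve dynamics or
  regurgitation, no respiratory coupling, and no growth/remodeling; it is
  a phenomenological pressure–flow skeleton.  Configurations of this
  model circulating in the literature differ slightly in the pulmonary
  branch, so absolute pulmonary pressures (44.5 mmHg systolic at the
  baseline here) are configuration-dependent and should be read
  qualitatively; the systemic operating point and every perturbation
  *direction* are robust to those differences.
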