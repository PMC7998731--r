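---
title: "Methods: from in-vitro assays to a whole-body rat PBPK model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from in-vitro assays to a whole-body rat PBPK model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratpbpk)
```

`ratpbpk` implements the complete preclinical pharmacokinetic
characterization of a small-molecule drug candidate in the rat, organized
the way such a study is actually run: in-vitro assays (permeability,
binding, metabolic stability, CYP inhibition), in-vivo noncompartmental
analysis and excretion mass balance, tissue partitioning, and finally a
whole-body physiologically based (PBPK) model that ties the pieces
together. The shipped example parameterization is supinoxin (RX-5902), a
monoprotic acid (MW 441.465 g/mol, logP 2.7, pKa 1.5) that is highly
plasma-protein bound (fu = 0.0363) and eliminated essentially entirely by
hepatic phase-I metabolism.

This vignette documents the models, the numerical choices, and the design
decisions where more than one defensible option existed. Every number shown
is computed by the code at build time; nothing is asserted here that the
test suite does not also compute.

## Noncompartmental analysis

AUC uses the linear trapezoidal rule over adjacent quantifiable samples.
Below-limit-of-quantification points are excluded outright — never imputed
at LOQ/2 — because exclusion is conservative and requires no assumption
about the censoring mechanism.

**First moment (AUMC).** We integrate the first moment of the
piecewise-linear concentration curve exactly per segment,
$\int t\,C(t)\,dt$ with $C$ linear, rather than applying the trapezoid to
the $t\cdot C$ ordinates. The two agree on dense grids, but the ordinate
trapezoid collapses to zero on a segment whose endpoints both have
$t\,C = 0$ (e.g. a profile falling linearly to zero from $t=0$), which is
clearly wrong; the exact segment integral gives the correct 4/3 for
$C = [2, 0]$ at $t = [0, 2]$.

**Terminal slope.** `fit_lambda_z()` implements the usual best-fit rule:
ordinary least squares on log concentration over every candidate set of the
last $k \ge 3$ points strictly after Tmax, keeping the set with the highest
adjusted $R^2$; sets within $10^{-4}$ are tied and the tie goes to the
larger set. The half-life is reported as $0.693/\lambda_z$ (the convention
of the field's reporting software, kept literal so the identity
$T_{1/2}\lambda_z = 0.693$ holds exactly). AUC and AUMC are extended to
infinity with the *observed* last concentration.

**No back-extrapolation by default.** For an intravenous bolus the first
trapezoid starts at the first sample (here 0.083 h); the area between zero
and the first sample is deliberately not reconstructed. This biases AUC
slightly low (about 0.7 % on a dense profile of the example compound, more
on sparse designs) and is documented rather than hidden; a log-linear
back-extrapolation of C(0) from the first two samples is available via
`back_extrapolate = TRUE`, and the parameter-recovery tests use it.

**A note on the linear trapezoid and sparse designs.** On the study's own
eight-point sampling design the final interval (10 to 24 h) spans nearly
five terminal half-lives; the linear trapezoid overestimates the area of an
exponential segment that wide by enough to bias AUC upward by roughly 7 %
for a compound with a 2 h half-life, irrespective of implementation. The
parameter-recovery properties are therefore measured on a rich 17-point
design where the discretization error is negligible and only estimator bias
remains. Users analysing sparse designs should read reported clearances
with the corresponding quadrature bias in mind (this is a property of the
stated method, shared by any software applying it).

**Mean-of-ratios versus ratio-of-means.** Per-animal parameters are
computed per profile and then averaged; mean-profile computations are used
only for destructively sampled tissue data (`sparse_tissue_auc()`, which
averages concentrations per time point first). Dividing group-mean dose by
group-mean AUC does not reproduce a published mean of per-animal clearances
— at the 5 mg/kg level the two differ by about 6 % — so the package never
silently mixes the two conventions.

## In-vitro assays and IVIVE

**Permeability.** $P_{app} = (dQ/dt)/(A\,C_0)$, with $dQ/dt$ the
least-squares slope (free intercept) of the cumulative transported amount.
Because each withdrawn receiver aliquot is replaced with blank buffer, the
measured concentrations are corrected by serial-dilution bookkeeping before
the slope is taken:
$Q_i = C_i V_r + \sum_{j<i} C_j v_s$. The sink condition (cumulative
transport below 10 % of the donor amount) is checked and warned about, not
enforced: at the example compound's permeability (~18.5 × 10⁻⁶ cm/s) about
30 % of a 0.5 mL donor crosses in 120 min, so the warning fires on
realistic inputs by design.

**Protein binding.** The unbound fraction is the buffer/matrix
concentration ratio of an equilibrium-dialysis time course, averaged over
the equilibrated tail. Equilibrium is declared at the first sample whose
ratio changed by less than 5 % (relative) from its predecessor — the
tolerance is a package choice; the source data show the ratio constant
beyond 18 h. A trajectory that never meets the tolerance (including the
degenerate rate-zero case, where the ratio is stuck at zero) is returned as
a flagged failure carrying the full trajectory rather than a number.

**Metabolic stability and scaling.** The depletion rate constant is the
negative log-linear slope of percent remaining versus time; slopes
indistinguishable from zero (≥ −10⁻¹²) are reported as metabolic stability
rather than as tiny clearances. Intrinsic clearance scales as
$CL_{int} = A_{protein}\,k_e/(f_{u,mic}\,C_{protein})$ with the rat
scaling factor $A_{protein}$ = 1790 mg microsomal protein per kg body
weight; omitting the microsomal-binding correction (fu,mic = 0.623 for the
example compound) understates CLint by a factor of 1.6.

**Well-stirred liver.**
$CL_h = Q\,CL_{int}f_u\,/\,(Q + CL_{int}f_u/R)$, implemented literally in
the form where only the denominator term carries the blood/plasma ratio
$R$; at $R = 1$ (assumed for the example compound) this is the textbook
blood-referenced form. The hepatic blood flow of 14.5 mL/min for a 250 g
rat is converted to 3480 mL/h/kg by `flow_per_kg()` — computed, never
hard-coded. The chain 17.1 min depletion half-life → CLint 14.0 L/h/kg →
CLh 443 mL/h/kg is reproduced by the test suite at three significant
figures.

**IC50 and interaction indices.** The inhibition model is
$100\,c^h/(c^h + IC_{50}^h)$ with the Hill slope fixed at 1 by default (a
single-parameter screening fit; `hill = "fitted"` co-estimates it). Two
numerical choices matter:

* *Weighting.* Fluorescent CYP assays measure the remaining activity, so
  the measurement error scales with activity, not with inhibition. The fit
  weights residuals by $1/(1 - \mathrm{inh}/100)^2$ (floored at 0.02):
  strongly inhibited wells are treated as the precise observations they
  are. Unweighted fitting on the inhibition scale roughly doubles the
  median IC50 recovery error under the package's noise model.
* *Censoring.* If no tested concentration reaches 50 % inhibition the IC50
  is not extrapolated; the result is reported as a lower bound at the
  highest tested concentration, matching how screening panels report weak
  inhibitors.

The drug–drug-interaction screen computes $C_{max,u}/K_i$ (threshold 0.02)
and $I_{gut}/K_i$ (threshold 10) with $I_{gut}$ = dose/250 mL in molar
units and $K_i$ taken equal to the IC50 — a deliberately conservative
screening convention. Note that the stated gut-index definition yields
values in the thousands for a high oral dose of a mid-MW compound; the
index is reported as defined, with its flag.

## Excretion mass balance

Interval amounts are concentration × volume for urine (with any cage-rinse
residue added to the final interval) and directly extracted amounts for
feces. Totals give $A_e$ and $f_e = A_e/\mathrm{dose}$; matrix clearances
are $f_e \cdot \mathrm{dose}_{/kg}/AUC$, referenced to AUClast of the
matched systemic study (the convention that reproduces the published fecal
clearance of 135 mL/h/kg from $f_e$ = 16.5 % and AUClast = 6.09 µg·h/mL).
Combined recovery above the dose triggers a supra-dose warning rather than
an error — it happens in real studies. Because animal body weights are
needed to turn mg/kg doses into µg amounts and are often unpublished, the
dose in µg is an explicit input.

## Tissue partitioning and the volume of distribution

Measured partition coefficients are AUC ratios,
$K_p = AUC_{tissue}/AUC_{plasma}$, from mean profiles of destructively
sampled cohorts. The steady-state distribution volume is reconstructed as
$V_d = \sum K_{p,T} V_T$ plus the plasma volume (the plasma row enters
with $K_p = 1$ at 31.2 mL/kg). The shipped observed table carries both the
rounded published products and the raw $K_p$/volume columns; the two sums
differ only in the fourth significant figure, and `vss_from_kp()` exposes
both (`products = "computed"` is the default; `"tabulated"` reproduces the
published total exactly).

For tissues without measured data (skin, bone) partition coefficients are
predicted mechanistically from tissue composition in the Rodgers–Rowland
framework for neutrals, monoprotic acids, and weak bases:

$$K_{pu} = f_{EW} + \frac{X_{IW}}{Y_P} f_{IW}
  + \frac{P f_{NL} + (0.3P + 0.7) f_{NP}}{Y_P}
  + \Big(\frac{1}{f_u} - 1 - \frac{P f_{NL,p} + (0.3P+0.7) f_{NP,p}}{Y_P}\Big) AR_T$$

with $P = 10^{\log P}$ (vegetable-oil-corrected for adipose,
$\log P_{vo:w} = 1.115 \log P - 1.35$), Henderson–Hasselbalch ionization
terms $X$/$Y$ at intracellular pH 7.0 and plasma pH 7.4, and $AR_T$ the
tissue/plasma albumin ratio; $K_p = K_{pu} f_u$. For a pKa 1.5 acid the
ionization terms make intracellular water partitioning small and the
albumin term dominant: the example compound predicts skin ≈ 0.29 and
bone ≈ 0.11. Strong bases (pKa > 7) belong to the acidic-phospholipid
binding class, which needs blood-cell partitioning data this package does
not model; they are refused with an explicit error rather than predicted
wrongly. The rat composition constants ship as a citable CSV
(`rat_tissue_composition.csv`, after Rodgers & Rowland, J Pharm Sci 2006).

## The whole-body PBPK model

Fifteen compartments: venous and arterial blood, lung in series between
them, and twelve perfused tissues in parallel (brain, heart, kidneys,
muscle, adipose, skin, bone, testes, spleen, gut, liver, rest-of-body).
All tissues are flow-limited: venous outflow leaves at $C_T R/K_{p,T}$.
Gut and spleen drain to the liver (portal flow), which also receives the
hepatic artery; total hepatic inflow is 3480 mL/h/kg, matching the IVIVE
flow by construction. The physiology table (volumes from the standard rat
compilations, flows as cardiac-output fractions summing exactly to the
296 mL/min/kg cardiac output) ships as `rat_physiology.csv`; a rest-of-body
compartment with $K_p = 1$ closes the volume (38.4 mL/kg) and flow
(1085 mL/h/kg) balances. Blood is split 36 mL/kg venous / 18 mL/kg
arterial out of the 54 mL/kg rat total.

**Elimination** is entirely hepatic (urinary recovery of the example
compound is ≤ 0.03 % of dose): the unbound intrinsic clearance is
back-calculated from the observed in-vivo clearance by inverting the
well-stirred relation, $CL_{int}f_u = Q_h CL_{iv}/(Q_h - CL_{iv}/R)$,
which makes the simulated intravenous plasma clearance reproduce the input
$CL_{iv}$ exactly in the AUC sense (verified to 0.005 % on a graded grid).
A clearance implying hepatic extraction ≥ 1 is rejected as infeasible.
The ~16 % fecal recovery after intravenous dosing is not mechanistically
modelled; it is lumped into the total clearance, mirroring the source
model.

**Absorption** replaces a proprietary mechanistic dissolution/absorption
model with a declared two-parameter surrogate: first-order input into the
liver with $f_a F_g = F_{obs}/F_h$ (so the simulated bioavailability
equals the observed one) and $k_a$ calibrated by bisection over
[0.1, 10]/h so the simulated Tmax matches the observed 0.75 h (giving
$k_a \approx 1.6$/h). The observed F and Tmax fully determine the
surrogate, which is the point: the absorption model contributes no free
parameters beyond what was measured.

**Numerics.** `deSolve::lsoda` with rtol 1e-8 and atol 1e-10 µg/mL.
Mass balance (dose = eliminated + in-body + unabsorbed + lumen) closes to
below 1e-14 of dose at every output time on the default grids; the test
suite enforces 1e-6. The system is linear in dose (verified to 1e-6
relative). One caution for users computing AUC from an intravenous bolus
simulation: the initial venous spike mixes away on a ~7 s time scale, so a
uniform 0.02 h grid overestimates its trapezoid area by ~1 µg·h/mL —
use a refined early grid (the tests use 0.2 ms steps to 0.25 h).

**What the model reproduces.** Simulating the 5 mg/kg oral dose on a
0–24 h grid gives a plasma AUC(0–24h) of about 3.77 µg·h/mL against the
observed 3.48 µg·h/mL — a 1.08-fold error, well inside the conventional
2-fold acceptance band. Terminal tissue/plasma ratios approach the input
$K_p$ only in the fast-perfusion regime (for slowly perfused, high-$K_p$
adipose the exact flow-limited terminal ratio is
$K_p Q/(Q - \lambda_z V K_p) \approx 1.2 K_p$); the AUC-ratio route
recovers the input $K_p$ within 3 % for every non-eliminating tissue,
while the liver's AUC ratio is shifted below its $K_p$ by the factor
$Q_h/(Q_h + CL_{int}f_u)$ — the intrahepatic extraction gradient, a real
feature of eliminating organs that also affects measured liver $K_p$
values.

## The synthetic-data module

Every pipeline input can be generated from known truth:
mono-exponential or first-order-absorption disposition (or a full PBPK
specification, which delegates to the simulator), first-order microsomal
depletion, linear sink-condition transwell accumulation with the
sampling-replacement dilution applied (so the analysis must undo it),
exponential approach-to-equilibrium dialysis, interval excretion records
spread by a fixed 0.2/h first-order profile and normalized so noise-free
totals equal $f_e \cdot$ dose exactly, and Hill-equation inhibition
curves.

Residual error is multiplicative lognormal with median 1 (σ is the log-sd;
default 0.15 for concentrations), the natural choice for positive,
right-skewed concentration data. For inhibition curves the noise is placed
on the measured activity ratio — the quantity the plate reader actually
records — and each curve point is the mean of three replicate wells,
matching the usual plate design; highly inhibited wells are therefore
precise in inhibition units, as in the real assay. The RNG is R's
Mersenne-Twister with inversion normals, seeded per call and restored
afterwards, so fixtures are portable and generators never perturb the
caller's random stream.

What the generators deliberately do **not** emulate: inter-individual
variability (all subjects share one truth; residuals are i.i.d.),
below-LOQ censoring, absorption-phase nonlinearity, enterohepatic
recirculation, and assay drift. Passing recovery tests therefore
demonstrate estimator correctness under the declared error model, not
robustness to real-data pathologies.

## Problem sizes used by the test suite

Parameter-recovery properties use 200 replicate profiles (noncompartmental
recovery, σ = 0.15) and 500 replicate curves (IC50, σ = 0.1 per well);
PBPK properties run single simulations on grids of 500–2000 points with a
refined early segment for intravenous AUC. These sizes put Monte-Carlo
error well below the 5 % assertion bands while keeping the default suite
around ten seconds.

## Known limitations

* Flow-limited tissues only; no permeability-limited sub-models, so the
  framework is inappropriate for large polar molecules or transporter
  substrates with tissue-uptake barriers.
* The partition predictor covers the extracellular-protein binding classes
  (neutrals, acids, weak bases) only.
* The first-order absorption surrogate cannot represent
  dissolution-limited or regional absorption; it is calibrated to F and
  Tmax and nothing else.
* Clearances back-calculated through the well-stirred model inherit its
  assumptions (instant intrahepatic mixing, unbound-drug-only
  elimination).
* No human scaling: physiology, scaling factors, and defaults are rat.
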