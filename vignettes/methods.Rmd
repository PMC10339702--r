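---
title: "Methods: a linked HCQ/DHCQ whole-body PBPK model with blood-partitioning variability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a linked HCQ/DHCQ whole-body PBPK model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model structure

`hcqpbpk` implements a whole-body, perfusion-limited PBPK model for
hydroxychloroquine (HCQ) linked to its primary metabolite
desethylhydroxychloroquine (DHCQ). Twelve tissues (adipose, bone, brain,
gut, heart, kidney, liver, lung, muscle, pancreas, skin, spleen) plus
arterial and venous blood are connected by blood flows; gut, pancreas and
spleen drain through the portal vein into the liver. Oral doses enter a
first-order depot (rate constant `ka`, fraction absorbed `fa`) that
absorbs into the portal inflow; i.v. doses run as constant-rate infusions
into venous blood. Labeled doses are sulfate-salt amounts and are
converted to base with the salt factor 0.775 (so the 400 mg labeled i.v.
preset delivers 310 mg base).

Each organ obeys a flow-limited balance on blood-referenced
concentrations,

$$ V_i \frac{dC_i}{dt} = Q_i\left(C_{art} - \frac{C_i}{K_{p,i}/\mathrm{B/P}}\right), $$

where $K_{p,i}$ is the plasma-referenced tissue-to-plasma partition
coefficient and B/P the subject's blood-to-plasma concentration ratio.
Hepatic elimination acts on the unbound liver outflow concentration
through pathway intrinsic clearances (well-stirred liver); renal
elimination acts on arterial blood. All three CYP pathways (CYP2C8,
CYP3A4, CYP2D6) form DHCQ in the liver with the molecular-weight
correction 307.8/335.9; DHCQ inherits the parent's B/P (the two molecules
share ionizable groups, similar pKa and logP) and is cleared renally
(2.9 L/h, blood-referenced; a flag reinterprets it as plasma-referenced)
plus by a whole-organ hepatic metabolic clearance.

Non-goals, by design: no permeability-limited or lysosomal-trapping
submodels, no Vmax/Km enzyme kinetics, no DCQ/BDCQ metabolites, no
azithromycin interaction.

## Tissue partitioning and its calibration from B/P

$K_p$ values are predicted from tissue composition in the
Rodgers–Rowland style for a moderate-to-strong diprotic base. With the
ionized:neutral ratio $X(\mathrm{pH}) = 10^{pK_{a1}-\mathrm{pH}} +
10^{pK_{a1}+pK_{a2}-2\mathrm{pH}}$ and $P = 10^{\log P}$:

$$ K_p = f_{EW} + f_u\left[\frac{1+X_{iw}}{1+X_p}f_{IW}
   + K_{a,AP}\,[AP]\,\frac{X_{iw}}{1+X_p}
   + \frac{P f_{NL} + (0.3P+0.7) f_{NP}}{1+X_p}\right]. $$

Two conventions are worth stating because the published equation family
admits variants:

- **Extracellular water is treated as plasma-equivalent** (the $f_{EW}$
  term partitions 1:1 against whole plasma). This makes the prediction
  exactly 1 for a hypothetical tissue whose composition equals plasma —
  a symmetry the test suite asserts — at the cost of ignoring the small
  difference between plasma and interstitial protein binding.
- **The acidic-phospholipid association constant $K_{a,AP}$ is not a
  fitted constant**: it is solved per subject from that subject's B/P via
  the implied blood-cell partition
  $K_{BC} = (\mathrm{B/P} - (1-Hct))/Hct$ and the blood-cell composition
  row. B/P below $1-Hct$ is rejected (no positive cell partition exists).
  This ties the whole tissue distribution to the one measurable quantity
  that varies most across subjects.

Predicted values are multiplied by the global $K_p$ scalar 2.2 (applied
to both compounds) and then the shipped adipose (800) and muscle (900)
overrides replace the scaled predictions. The overrides were produced by
the package's own estimation surface (`kp_adipose`, `kp_muscle` in
`fit_spec()`), tuned once so the default subject's single-dose i.v.
terminal half-life falls in the reported 30–40-day window and the
plasma-referenced Vss in the reported 25,000–94,000 L range; with them the
defaults give 34.5 days and ~45,500 L. By default $K_p$ is recomputed from
each subject's sampled B/P (internal consistency between distribution and
blood partitioning); `options$freeze_bp_kp` freezes prediction at
B/P = 7.

## Clearances and their reference frame

All input clearances are blood-referenced. Total HCQ blood clearance
defaults to 5.8 L/h (the scale of the single-dose i.v. study the
distribution is calibrated against) and is split by
$f_{m,CYP2C8}=0.37$, $f_{m,CYP3A4}=0.17$, $f_{m,CYP2D6}=0.19$,
$f_e=0.27$. Pathway intrinsic clearances are back-calculated through the
well-stirred relation $CL_h = Q_h f_{u,b} CL_{int}/(Q_h + f_{u,b}
CL_{int})$ at the reference subject (B/P 7), so the default subject
reproduces the total by construction; a subject's hepatic clearance then
responds to its own B/P through $f_{u,b} = f_{u,p}/\mathrm{B/P}$ and to
its CYP expression multipliers, which scale the pathway intrinsic
clearances. Renal clearance scales with the renal multiplier. Flows and
clearances scale with body weight as $W^{0.75}$, volumes as $W$.

The DHCQ whole-organ metabolic clearance is the one quantity the source
analysis estimated rather than reported. The default, 8.5 L/h, was
calibrated once: it is the value at which the default subject's
DHCQ/HCQ blood AUC$_{0-672}$ ratio on the treatment regimen matches the
published healthy-population ratio (29,872/173,388 ≈ 0.17). A
steady-state back-of-envelope (formation fraction × parent clearance /
ratio) suggests ~20 L/h, but over a 672-h window far from steady state
that argument overestimates; the windowed calibration is the one the
simulations actually use. The DHCQ metabolic clearance is deliberately
*not* scaled by the CYP multipliers — the isoform contributions to DHCQ
elimination are unknown — so the COVID-19 effect on DHCQ flows entirely
through reduced formation.

## Numerical propagation

The full system (33 states: depot, 2 × 14 organ/blood compartments, four
cumulative elimination routes) is linear and time-invariant between dose
events. Instead of a stiff ODE integrator, the package propagates the
state exactly with matrix exponentials: within each inter-event segment
with constant infusion rate $b$, $x(t+h) = e^{Ah}x(t)$ (or the augmented
$(n{+}1)$ form when $b \ne 0$), with $e^{Ah}$ cached per step length.
Oral doses are bolus additions to the depot at event times. This is
exact to machine precision, so the 0.1% mass-balance contract (delivered
base dose = compartment contents + cumulative eliminations, metabolite
mass converted at the parent/metabolite weight ratio) is asserted on
*every* simulation rather than sampled; residuals are ~1e-11. The output
grid is 1 h by default (configurable), and grid values at dose times are
pre-dose (troughs). The fast-flow, unit-$K_p$ limit collapses the model
to one compartment and is tested against the closed form
$C = D/V\,e^{-CL\,t/V}$.

## Populations

Each virtual subject draws, in fixed order: body weight (log-normal,
median 78 kg — the clinical substudies' median of 173 lb — CV 25%), a B/P
from the cohort's frequency table, three CYP expression multipliers
(log-normal with means from the population spec) and a renal multiplier
(log-normal, mean 1). The fixed order guarantees that two specs differing
only in pathway means produce identical draws for the unchanged pathways
under a common seed — asserted for CYP2D6, whose activity is unchanged in
mild COVID-19.

The default B/P table is discrete levels 1–12 with uniform weights. The
range is as reported (1–12 covers 90% of single-dose i.v. observations);
the true frequency histogram is not published, so uniform is a documented
stand-in and user tables are used verbatim. The mild-COVID-19 spec
multiplies the CYP2C8 mean by 0.40 and the CYP3A4 mean by 0.70 (60%/30%
mean-expression reductions), shifting means only, never CVs. The CVs
themselves (CYP2C8 45%, CYP3A4 45%, CYP2D6 60%, renal 30%) are invented
defaults chosen once so that population exposure CVs land at the
published magnitude (SD ≈ 60–70% of the mean); most of that variability
in *blood* exposure comes from the B/P table, which is the central
mechanistic claim of the analysis.

The analytic consequence of the expression reductions is
`expected_exposure_change()`: percent of clearance removed
$= 100\sum_p f_{m,p} r_p = 100(0.37 \cdot 0.6 + 0.17 \cdot 0.3) = 27.3\%$
(reported as ~28%), with reciprocal AUC ratio 1.38 at steady state. The
simulated AUC$_{0-672}$ ratio is smaller (~1.1): over a 10-day regimen
with a 34-day half-life little of the dose has been cleared, so windowed
exposure is insensitive to clearance — which is exactly why the virtual
trials need thousands of subjects per arm to detect the parent effect.

## Virtual trials and the t-test convention

Exposure metrics are AUC$_{0-672h}$ (linear trapezoid on the output grid;
the window is fixed at 0–672 h from first dose even though dosing stops
at day 10) and C$_{max}$ (grid maximum), computed on *blood*
concentrations to match the DBS matrix. Trials pool per-subject metrics
over individuals (never over trial means).

The arm comparison is an equal-variance two-sample t-test computed from
the pooled means and SDs with `n_effective` = participants *per trial*
per arm and df = 2·n_effective − 2. This convention was adopted because
it exactly reproduces the published table of virtual-trial p-values
(e.g. pooled HCQ AUC 162,982 (102,687) vs 182,044 (111,827) at
n_effective = 500 gives t = 2.81, p = 0.005; DHCQ Cmax 77 (51) vs 57 (34)
at 30 gives p = 0.079); the alternative reading (n = total pooled
subjects) does not. Two consequences are documented rather than hidden:
under the null the convention is conservative when n_trials > 1 (the
means use 10× more subjects than the SE assumes), so the type-I
calibration property is asserted in the single-trial regime where the
test is exact; and with no multiplicity adjustment (none is applied),
significance at α = 0.05 two-sided. `power_scan()` seeds each design
independently via the documented affine seed splitter, so extending the
grid never perturbs earlier cells.

## Model qualification

The prediction band is the 5th–95th rank percentile of the simulated
population cross-section at each matched time, with the ordinal rank
$n = \mathrm{round}(P/100 \times N)$ (half-up, clamped) — no
interpolation. The field labels this the "95% prediction interval"
although its nominal coverage is 90%; the label/coverage mismatch is
preserved deliberately, and the coverage property (WPI → 0.90 for
observations drawn from the simulation itself) is what the tests assert.
Observations match the nearest grid time within 0.5 h on
time-since-first-dose; unmatched or censored records are excluded and
counted. For AFE/AAFE the predicted partner is the geometric mean of the
positive simulated cross-section — the source analysis does not state its
pairing, and the geometric mean is the standard central-tendency choice
on log scale.

## Estimation

`fit_parameter()` is a bounded deterministic scalar search
(`stats::optimize`, Brent; relative tolerance 1e-4) over one of
`dhcq_metabolic_clearance`, `kp_adipose`, `kp_muscle`, minimizing the sum
of squared natural-log concentration differences (robust across the
3-order-of-magnitude concentration range) or AAFE.
`sensitivity_scan()` tabulates objective, AFE and AAFE over a grid,
mirroring the metric-guided tuning workflow. The i.v. calibration dataset
is digitized from literature and not redistributable, so no dataset is
bundled: estimation tests run on synthetic data produced by the simulator
itself (parameter recovery is within 2% noise-free and within 15% in
median under 20% proportional noise), and `read_observations()` accepts
user-digitized tables.

## Synthetic DBS cohorts

`generate_dbs_dataset()` emulates the two clinical substudies. Per
participant: a subject is sampled from the population, the regimen is
thinned by per-dose adherence (default 0.9 for synthetic cohorts — the
substudies were remote and self-reported — and 1.0 in virtual trial
arms), blood concentrations are simulated, 1–5 (sars_neg) or 3–5
(sars_pos) sampling times are drawn uniformly over days 1–28, reported
times get additive Gaussian noise (SD 1 h, truncated positive),
concentrations get proportional log-normal residual error (CV 20%, a
typical DBS assay magnitude; not stated in the source), and records are
flagged against the 1–2000 ng/mL assay range without altering values.
The sars_pos sampling range is 3–5 rather than 1–5 because that cohort's
published totals (123 HCQ records from 34 participants, 3.6 each) are
unreachable in expectation under uniform 1–5; this is the one place the
generator departs from the stated 1–5, and it is configurable.

Exact record-count matching (94 participants with 226/197 quantifiable
HCQ/DHCQ records for sars_neg; 34 with 123/115 for sars_pos) is by
construction: whole-cohort sampling is redrawn (bounded retries) until
quantifiable counts reach the targets, then surplus quantifiable records
are trimmed deterministically from the participants holding the most,
latest times first. The targets count quantifiable records, not
participants × samples. A generated cohort is a deterministic function of
its seed.

What a green test on synthetic data does *not* establish: the generator
shares the simulator's model, so evaluation against it checks
self-consistency (band coverage, fold-error identities), not clinical
adequacy. The published clinical fit metrics (WPI improving 0.56 → 0.80
with B/P variability, the final AFE/AAFE values) require the
participant-level DBS data, which are not public; they are intentionally
out of reach of this package's test suite.

## Reproducibility plumbing

One global seed is split into per-stage, per-subject streams with the
affine map `(seed + stage_hash + 1000003·k) mod 2147483629`, so adding
subjects or stages never perturbs earlier draws and every stream stays
below 2^31. Configs are strict JSON (unknown keys rejected; YAML is not
supported because no YAML parser is a dependency). `run_pipeline()`
writes delimited tables plus a summary JSON and reruns byte-identically
under the same config and seed.

## Known limitations

- Compound parameters not printed in the source (absorption, total
  clearance, final $K_p$ values) are calibrated stand-ins living in
  editable TSVs under `inst/extdata/`; pKa 8.3/9.7, logP 3.85,
  fu 0.5, ka 0.5 h⁻¹ (median blood tmax 3–4 h), fa 0.75.
- Instantaneous blood/plasma partitioning (blood = plasma × B/P at every
  instant) is assumed, as in the source analysis.
- The PEP regimen follows the Methods wording (400 mg daily × 3 then
  200 mg daily × 11); the figure-caption variant is not used. The 310 mg
  i.v. dose is treated as base (= 400 mg salt), configurably.
- The windowed DHCQ calibration (8.5 L/h) limits extrapolation beyond
  short-term dosing, mirroring the source's own caveat about its
  optimized metabolite clearance.
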