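---
title: "Methods: PBK modelling and reverse dosimetry for aloe-emodin and rhein"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PBK modelling and reverse dosimetry for aloe-emodin and rhein}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aepbk)
```

## The problem

Aloe-emodin, a hydroxyanthraquinone in *Aloe vera*, rhubarb and related
botanicals, shows concentration-dependent hepatotoxicity,
nephrotoxicity, ROS generation and Nrf2 activation in human cell assays;
so does rhein, the metabolite it is converted to in the liver. Whether
dietary or medicinal intakes could reach internal concentrations in the
range of those in-vitro effect concentrations is a kinetics question.
This package implements the standard new-approach-methodology answer:
a physiologically based kinetic (PBK) model translates external doses
into internal concentrations, and reverse dosimetry inverts that map to
re-express each in-vitro concentration–response curve as a predicted
in-vivo dose–response curve, from which benchmark-dose points of
departure are derived and compared with estimated daily intakes.

## Model structure

The PBK model describes two compounds over the compartments GI tract,
liver, kidney, fat, richly perfused tissue, slowly perfused tissue and
blood. All tissues are flow-limited:

$$\frac{dA_T}{dt} = Q_T\left(C_{blood} - \frac{C_T}{P_T}\right)$$

with $P_T$ the tissue:blood partition coefficient (tissue:plasma
divided by the blood-to-plasma ratio, BPR). Amounts are in µmol,
volumes in L, so concentrations are in µM and Michaelis constants can
be used unchanged.

**Absorption.** An oral dose enters an absorbable gut-lumen pool of size
$F_a \cdot \mathrm{dose}$, transferred to the liver at first-order rate
$k_a$; the remaining $(1-F_a)\cdot\mathrm{dose}$ is booked as unabsorbed.
Where the bioavailability cut is applied is not dictated by the
absorption equations themselves; applying $F_a$ at the lumen (rather
than, say, at the portal transfer) keeps the absorbed fraction exact at
any simulation length and is the choice made here. $k_a = 2 P_{eff}/R$
and $F_a = 1 - e^{-k_a T_{si}}$ with intestinal radius $R$ (0.18 cm rat,
1 cm human) and small-intestinal transit time $T_{si}$ (1.47 h rat,
3.32 h human). The permeability correlation from the Caco-2 apparent
permeability is configuration with a calibrated default intercept
because its published coefficients and the units of the input value are
ambiguous; the shipped parameter sets simply pin $k_a$/$F_a$ to 0.21
h⁻¹/0.26 (rat) and 0.14 h⁻¹/0.36 (human), so the PBK model does not
depend on that correlation. An alternative rat pair fitted to reported
oral profiles ($k_a = 4$ h⁻¹, $F_a = 0.022$) is available via
`compound_defaults("rat", absorption = "fitted")` but is not the default.

**Metabolism.** All hepatic: one saturable conversion of aloe-emodin to
rhein and three parallel saturable glucuronidation pathways (AEG1–3),
each $v = V_{max}^{scaled} C_{VL}/(K_m + C_{VL})$, plus a linear
intrinsic clearance for rhein (0.264 L/h rat; 0 human — the reported
hepatocyte value). The substrate concentration is the
venous-equilibrated liver concentration $C_{VL} = C_{liver}/P_{liver}$,
the usual convention for flow-limited PBK models (the source model code
is not reproduced, so this is stated as an assumption). In-vitro
$K_m$ is taken as in-vivo $K_m$; $V_{max}$ scales as

$$V_{max}^{scaled}\ [\mu mol/h] = V_{max}^{unscaled}\ [nmol/min/mg]
  \times \mathrm{protein}\ [mg/g\ liver] \times M_{liver}\ [g]
  \times 60/1000$$

with 46/40 mg microsomal and 165/120.7 mg S9 protein per g liver
(rat/human), and hepatocyte clearance analogously with 135,000·10⁶
cells/kg liver. Liver masses are fixed at 8.5 g and 1560 g: these are
back-derived from the scaled/unscaled maximal-rate ratios of the
kinetics tables and reproduce every scaled value at its printed
precision (three significant figures), which is verified by tests.

**Excretion.** Biliary: first-order loss of the parent from the liver at
$k_b$, interpreted as 1 h⁻¹ (the source states the constant without
units; a first-order rate in h⁻¹ is the only reading compatible with
the model structure). Bile is terminal — no enterohepatic
recirculation, so the second blood-concentration peak seen in some oral
datasets is out of scope by design. Renal: glomerular filtration of the
unbound plasma concentration, $GFR_{tot} \cdot f_{up} \cdot
C_{blood}/BPR$, drawn from the kidney compartment against the arterial
blood concentration; $GFR$ is 5.2 (rat) and 1.8 (human) mL/min/kg bw.

**Physiology.** Standard reference values for a 0.25 kg rat and a 60 kg
human (fractional volumes and flows, cardiac output $15\,BW^{0.74}$
L/h), with liver volume fractions chosen to match the back-derived
liver masses. **Partition coefficients are placeholders**: the original
tissue:plasma predictions (Rodgers–Rowland) are in supplementary
material not reproduced here, so plausible values for acidic,
moderately lipophilic compounds are shipped and documented as such.
Consequently absolute concentration predictions (and absolute in-vivo
BMDs) carry that uncertainty, while every ratio, scaling and structural
property does not. The configuration isolates these values so measured
ones can be dropped in verbatim.

## QIVIVE

The dose metric is the maximum unbound organ-venous blood concentration
in aloe-emodin equivalents:

$$C_{eq} = \frac{C_{parent}}{BPR_{parent}} f_{up,parent} \cdot 1 +
           \frac{C_{met}}{BPR_{met}} f_{up,met} \cdot RPF_{met}$$

with $RPF = BMCL_{10}^{AE}/BMCL_{10}^{rhein}$ per endpoint. The
blood→plasma→unbound chain (÷BPR, ×f_up) is reconstructed from the
symbol definitions of the source equations, which are published only as
images. BPRs: 0.55 (aloe-emodin, 1 − hematocrit), 0.95/0.96 (rhein,
rat/human); unbound plasma fractions 0.092 and 0.91. On the in-vitro
side each nominal concentration is corrected to its unbound value with
the albumin-binding model

$$f_u = \frac{1}{1 + \frac{C_{alb,vitro}}{C_{alb,plasma}}
  \left(\frac{1}{f_{up}} - 1\right)}$$

(0.23 g/L fetal bovine albumin per % FBS; plasma albumin 42.5 g/L),
giving 0.79 at 5% and 0.65 at 10% FBS for aloe-emodin. The same formula
is applied to rhein with its own $f_{up}$ — the source defines it only
for the parent, so this extension is an assumption. Endpoint→organ
mapping: hepatotoxicity, ROS and Nrf2 in liver; nephrotoxicity (and the
kidney variants of ROS/Nrf2) in kidney.

Reverse dosimetry inverts the monotone dose→$C_{eq,max}$ map by
bracketing plus bisection to a 0.1% concentration tolerance.
Concentrations not reachable below the dose cap (default 10,000 mg/kg)
are censored, never extrapolated.

One endpoint detail: the potency table prints a rhein RPF of 1.2 for
hepatotoxicity while the printed BMCL₁₀ pair gives 7.3/6.3 = 1.16; the
published value was evidently computed from unrounded bounds. The
package recomputes RPFs from the table it ships (giving 1.16) rather
than storing the published rounding.

## Benchmark-dose analysis

Continuous Hill and exponential families,
$y = a(1 + (c-1)\frac{x^d}{b^d + x^d})$ and
$y = a(c - (c-1)e^{-(x/b)^d})$, fitted by maximum likelihood under
normal residuals; both constant-variance (default) and constant-CV
(sd ∝ mean, matching multiplicative assay noise) variance models are
available. The benchmark response is a 10% change relative to the
*fitted background* ($f(BMD) = a(1 \mp 0.1)$), solved in closed form.
This is a deliberately simplified, documented procedure — the full
PROAST/EFSA model-averaging machinery is not replicated, so exact
agreement with published absolute BMDL values is not claimed; the
published ratios are reproduced.

Confidence bounds are 90% two-sided (the BMDL/BMDU convention, stated
here as an assumption) from a parametric bootstrap: data are
regenerated from the fitted curve using the *unbiased* residual sd
(n − 4 degrees of freedom) with its chi-square uncertainty drawn per
replicate, refitted (warm-started from the original optimum), and the
BMD distribution is turned into bounds by the **basic bootstrap on the
log-dose scale** — the 5th/95th quantiles reflected about the point
estimate, $BMDL = BMD^2/q_{95}$, $BMDU = BMD^2/q_{5}$. Plain percentile
bounds inherit the skewness-driven bias of the BMD estimator and
measured only ~80–84% coverage at nominal 90% in this package's
simulation study; the log-basic construction measured 89% over 200
synthetic curves, which the acceptance suite re-verifies against the
85% floor. Failed refits are dropped; above 20% failures the bounds
widen to the reflected extremes with a warning. Noise-free data give a
zero-width interval; a flat curve is rejected as unidentifiable; a
fitted curve that never reaches the benchmark response yields `NA` with
an out-of-range warning.

## Synthetic data: the stated world

Generators produce the three dataset shapes consumed by the pipeline,
each with explicit ground truth and an explicit seed (no global RNG
state):

* Michaelis–Menten velocities over the incubation design 0.5–100 µM,
  triplicate, at the published parameter values;
* first-order depletion over 0–120 min at the published intrinsic
  clearance (k = 0.00192 min⁻¹ at 0.5·10⁶ cells/mL), with a no-cells
  control series;
* four-parameter sigmoidal concentration–response curves over the
  published exposure designs, decreasing (viability) or increasing
  (ROS, Nrf2), with the analytic benchmark concentration attached.

Noise is multiplicative lognormal with a stated CV and unit mean
(assay-like heteroscedasticity; the sources state no noise model), with
additive normal available. Replicates default to 3 — the incubations
are described as triplicate and the figure-only cytotoxicity data do
not state a count. A green test on synthetic data establishes that the
estimators and the pipeline recover a known truth under this noise
model; it does not establish that real assay noise is lognormal, that
the placeholder partition coefficients are right, or that the cell
models represent in-vivo sensitivity.

## Numerical choices

* Integrator: adaptive embedded Dormand–Prince 5(4) in C++, rtol 1e-8,
  atol 1e-10, hmax 0.1 h (exposed). The system is only mildly stiff
  (fastest tissue time constants ~10⁻² h), well within explicit-method
  territory; agreement with an independent fixed-step RK4 and with the
  one-compartment closed form is tested to <0.5%.
* Cmax is read from a dense output grid (default 1201 points over the
  window); grid refinement changes it by <0.1% (tested), and a maximum
  attained at the window edge is flagged.
* Michaelis–Menten fitting: untransformed least squares via `nls`
  (port, positivity bounds), all replicates, uniform weights — no
  Lineweaver–Burk linearisation. A Km beyond 10× the tested range is
  flagged as extrapolated. Depletion fitting: log-linear OLS on
  strictly positive concentrations, dropped values logged; a
  non-depleting series yields zero clearance with a flag rather than a
  negative rate.
* Dose–response fitting: two Nelder–Mead starts plus BFGS polish on
  log-scale parameters, with the fold-change kept on the correct side
  of 1 by a direction-specific transform; non-convergence falls back to
  the other family with a warning.
* Reverse dosimetry: geometric pre-bracketing then bisection; 0.1%
  relative concentration tolerance.
* Seeds are explicit everywhere (generator specs, bootstrap, pipeline
  config); RNG state is restored after each seeded operation, so
  library calls never disturb a caller's random stream.

## Limitations

Single-dose scenarios only; no enterohepatic recirculation, dermal
route, or repeated dosing; no population variability in kinetic
parameters (a Monte-Carlo layer over Vmax/Km would be the natural
extension); no mixture effects with co-occurring hydroxyanthraquinones;
partition coefficients are placeholders pending measured values; BMD
confidence bounds are single-model bootstrap, not model-averaged. The
human model inherits the rat model's structural validation because no
human in-vivo kinetic data are available.
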