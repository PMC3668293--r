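---
title: "insox: model structure, conventions and protocols"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{insox: model structure, conventions and protocols}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`insox` is a deterministic kinetic model of insulin signalling in a rodent
adipocyte, coupled on one side to reactive oxygen species (ROS) production,
transport and detoxification, and on the other to FOXO1-mediated
transcriptional feedback on the insulin receptor (InR) and the antioxidant
SOD2. This vignette documents the model's structure, the unit and rate-law
conventions, the choices made where the published parameter tables are
ambiguous, the numerical protocols the scenario functions use, and the known
limitations of the reconstruction.

## State representation and units

All amounts are *particle numbers per cell* and time is in minutes. Five
species — cytoplasmic and extracellular ROS, cytoplasmic SOD2, PIP2 and PIP3
— use a scaled representation in which one model particle stands for 1000
real molecules; the scale enters only when converting to concentrations
(`particles_to_concentration()`), never in the rate laws. Compartment
volumes (extracellular 8.3e-12 l, cell surface 6.4e-14 l, cytoplasm
1.65e-11 l, nucleus 5e-13 l, DNA-bound 1e-13 l) are likewise used only for
particle/molar conversion and SBML export; cross-compartment transport acts
directly on particle numbers with the printed rate constants.

Two species are *boundary* species whose values are set by dosing schedules
and never changed by reactions: insulin (`Ins`, 5e5 particles = 100 nM in
the extracellular volume) and `extracellular_ROS` (5e4 model particles =
10 uM). `schedule()` events replace their values at stated times;
integration restarts cleanly at each event.

## Rate-law families

Six rate-law families cover the network (`rate_law()`):
mass action (first/second order), catalytic second order
(k x enzyme x substrate, the enzyme a non-consumed modifier),
offset mass action, Michaelis-Menten, linear transcription
(k_basal + k_stim x activator) and enzyme-driven synthesis (k x enzyme).

The offset law implements Akt and PKC activation by PIP3:
flux = k x [kinase] x max(0, PIP3 - pip3_basal) with pip3_basal = 200,
so activation is exactly zero at or below the basal PIP3 level. The clip at
zero is deliberate: the law's purpose is a dead zone, not a reversible
linear term. Michaelis-Menten laws (Km = 100 particles, i.e. deeply
saturated at physiological IRS1 levels) describe the stress-kinase serine
phosphorylation of IRS1, which therefore proceeds at a rate set by active
JNK/IKK rather than by IRS1 abundance.

Second-order constants are interpreted per particle per minute, acting
directly on particle numbers. One documented exception: the IRS1 tyrosine
phosphorylation constant k7 = 5.8 is normalized by the total receptor pool
(1e5), giving an effective per-receptor constant of 5.8e-5. The lineage
this pathway derives from expresses receptor catalysis as a function of the
*fraction* of activated receptors; the per-particle reading of 5.8 would
tyrosine-phosphorylate the entire IRS1 pool within seconds at any insulin
dose, while the normalized reading reproduces the intended peak PI3K-complex
occupancy. Other constants whose table notes say they were already
"corrected for mol number" (e.g. the internalized-receptor dephosphorylation
k6 = 4.61e-6, which times 1e5 PTP1B gives the lineage value 0.461/min) are
used as printed.

## Module structure

`build_module()` constructs five signalling sub-networks; `merge_modules()`
concatenates them, resolving duplicate species declarations by keeping the
first (so shared pools such as PTP1B or PP2A are declared once).

* **receptor** — insulin binding/unbinding (R1), fast receptor
  autophosphorylation (R2, 2500/min), second-site binding (R3),
  PTP1B-catalysed surface dephosphorylation (R4), internalization and
  recycling of free (R5) and phosphorylated (R6/R7) receptors, and
  PTP1B-catalysed dephosphorylation of internalized receptors (R10/R11).
  The printed initial surface:cytoplasm receptor ratio (9e4:1e4) equals the
  R5 equilibrium ratio kminus4/k4 = 9, corroborating this mapping of the
  internalization cycle.
* **irs** — the four IRS1 phospho-states (IRS1, IRS1_TyrP, IRS1_PolySerP,
  IRS1_TyrP_PolySerP), tyrosine phosphorylation by activated receptors,
  serine phosphorylation by active PKC (mass action) and by JNK/IKK
  (Michaelis-Menten; applied to both tyrosine states, mirroring the PKC
  pair), PI3K-complex formation with IRS1_TyrP, and turnover: zero-order
  synthesis (260/min) with first-order degradation at 1e-3/min for the base
  forms and 10x that for both serine-phosphorylated forms.
* **akt** — PIP2/PIP3 interconversion (basal + PI3K-complex-catalysed
  forward; basal + PTEN-catalysed reverse), offset-law activation of Akt
  and PKC, AS160 activation by Akt, and GLUT4 translocation (basal +
  AS160-catalysed to the surface, first-order return). AS160 saturates at
  low Akt activity, which caps GLUT4 translocation below full surface
  localization while uptake saturates at much lower insulin than PI3K.
* **phosphatases** — reversible ROS-driven oxidation of PTP1B and PTEN with
  GSH-mediated re-reduction; the NOX cycle (insulin-activated, spontaneous
  deactivation at 0.25/min, slow 1e-3/min returns to the inactive state);
  ROS production by active NOX (450/min each) and by the constant
  mitochondrial source (180/min x Mt = 9000 particles/min); ROS removal by
  SOD2 (0.12 per SOD2 per min); symmetric transmembrane ROS exchange at
  4.8/min; and the glutathione redox couple. The two printed NOX return
  steps carry no named second reactant and are implemented as first-order
  1e-3/min transitions (deactivated -> inactive and active -> inactive).
* **jnk** — ROS-driven activation of JNK and IKK, deactivation by DUSP, and
  the redox cycle of DUSP itself (oxidized by ROS, re-reduced by GSH). IKK's
  activation constant is 5x smaller than JNK's, so IKK engages at higher
  oxidant levels.

Catalysts left unnamed in the tables are assigned to the model's generic
Ser/Thr phosphatase PP2A (IRS1 serine dephosphorylation, AS160
deactivation); the resulting effective rates (1.4/min and 0.5/min) are
physiological, and PP2A is already the FOXO phosphatase.

## The FOXO module

FOXO1 carries four binary marks — Pa (Akt site), Pd (IKK site), Pe (JNK
site), pUb (ubiquitin) — in three compartments (cytoplasm, nucleus,
DNA-bound): 48 species, generated by rule (`enumerate_foxo_species()`,
`generate_foxo_reactions()`) rather than written by hand. Transport rates
are modified multiplicatively by the marks present (e.g. cytoplasm->nucleus
base 0.182/min, x0.1 with Pa, x0.5 with Pd, x10 with Pe), so a doubly
marked molecule composes both factors. Phosphorylation is second order in
the *dynamic* amount of active kinase (basal constant 5e-5 x kinase-specific
factor 6/3/2 for Akt/IKK/JNK); dephosphorylation is PP2A-catalysed at
1e-6 per PP2A. Where a printed first-order summary rate disagrees with the
second-order constant times the printed enzyme number (the synthesis row,
and the kinase rows' parenthesized enzyme counts), the second-order
convention with the dynamic enzyme amount is used throughout; it is the
only reading that couples FOXO to the state of the signalling layer.

Design choices on points the tables leave open: kinases act on cytoplasmic
and nuclear FOXO but not on the DNA-bound pool (which exchanges with the
nucleus on a faster timescale); ubiquitination (SCF/MDM2, base 1e-3/min,
x3 with Pa, x22 with Pd) and proteasomal degradation (0.1/min) are
restricted to the cytoplasm; pUb does not alter transport; synthesis (E2F1
x 0.0055) produces only the unmodified cytoplasmic species; and all 16
DNA-bound states drive transcription equally — Pa already penalizes DNA
binding through its transport factor, and double-counting it in the
readout would apply the penalty twice. The constant enzyme pools SCF/MDM2
(1000), proteasome (1000) and E2F1 (300) are fixed species.

## Transcription and translation

Each target gene (InR, SOD2) is a linear chain: nuclear mRNA synthesized at
k_basalt + k_foxot x F (F = total DNA-bound FOXO), exported at k_exp,
degraded in the cytoplasm at k_mdeg, translated at k_transl per mRNA into
the same protein pool the signalling network uses (surface InR; cytoplasmic
SOD2), with protein turnover k_pdeg. The steady-state fold change between
FOXO states, (k_basalt + k_foxot x F)/k_basalt, is independent of the four
downstream constants — the package's tests verify this both in closed form
and against long-time integration. mRNA species start at zero (no printed
initial values) and equilibrate within tens of minutes, far faster than the
multi-hour protein turnover.

A structural consequence worth stating plainly: with the printed
transcription constants, the steady-state InR pool is
k_transl (k_basalt + k_foxot F)/(k_mdeg k_pdeg) = 500 + 24 F particles,
orders of magnitude below the printed initial receptor count of 1e5 for
any attainable F. The initial amounts therefore describe a cell whose
receptor pool is *not* in equilibrium with the transcription module, and
fully equilibrated states have ~20x fewer receptors than the initial one.
The short-term scenario protocols below are defined against the printed
initial state for exactly this reason.

## Numerical methods

`assemble_ode()` compiles the network into a vectorized right-hand side
plus an analytic Jacobian (assembled per rate-law family and consistent
with the zero-clipping of fluxes), and `simulate_model()` integrates with
deSolve's `lsoda` at rtol 1e-8 / atol 1e-6 particles. The system is stiff
by construction — cytoplasmic ROS relaxes in ~0.01 s while protein
turnover takes hours to days — and the analytic Jacobian is what makes
day-scale runs take seconds. Amounts are clipped at zero inside the flux
evaluation so solver undershoot (bounded by atol) cannot generate negative
fluxes; trajectories stay above -1e-3 particles in all tested scenarios.
Halving the tolerances changes the reported readouts by well under 0.1%.
Boundary events are handled by the solver's event mechanism; integrating
across an event is verified to equal splitting the run at it.

## Scenario protocols and problem sizes

* **Insulin steps and dose-response curves** start from the printed initial
  amounts, settle 15 min at zero insulin and zero external oxidant, then
  apply the stimulus; readouts are active *fractions* of each conserved
  pool, with cell-surface GLUT4 fraction serving as the glucose-uptake
  proxy throughout. Dose-response sweeps read out at 30 min per level.
* **ROS-subsystem quantities** (basal cytoplasmic ROS, the NOX/Mt
  production ratio, the internal-vs-external tolerance threshold) are
  measured on the signalling-only model (`build_full_model(foxo = FALSE,
  transcription = FALSE)`), which holds SOD2 and the other printed amounts
  at their table values; with transcription enabled, zero-insulin FOXO
  activity drives SOD2 far above its table value and the quantities
  describe a different cell state.
* **Long-run scenarios** (fasting, oxidant preconditioning, 16-h oxidant
  dose bars) start from a fed baseline produced by the two-stage recipe
  `equilibrate_standard()`: five days of piecewise-constant diurnal insulin
  (three meal peaks to 1.2 nM over a 0.2 nM fasting baseline per 1440-min
  day; the meal profile is a documented stand-in with stepped decay over
  150 min) followed by two days at constant 0.2 nM. The
  insulin-by-oxidant interaction is read at 240 min, when the
  stress-kinase-driven IRS1 serine phosphorylation and accelerated
  turnover — the mechanism that makes insulin+oxidant weaker than insulin
  alone — has developed; at 60 min the phosphatase-oxidation boost still
  dominates.

All published-value comparisons are computed fresh by
`tests/testthat/test-acceptance.R` and `scripts/acceptance.R`; typical
sizes are a 99-species/252-reaction network integrated over 60 min to 20000
min, a 61-point external-oxidant sweep, and 4-8 preconditioning
trajectories.

## What the defaults reproduce, and what they do not

With everything taken as printed, the package reproduces: the basal and
maximal surface-GLUT4 fractions (0.082 and 0.48 against the targets 0.1 and
0.6, inside +/-20%), AS160 saturation near 1 nM insulin, the NOX/Mt ROS
production ratio (~4.5x vs ~5x), the ROS lifetime (0.012 s vs ~0.01 s),
majority PTP1B oxidation at the insulin-stimulated ROS peak (~58%), the
rise-then-fall IRS1-TyrP timecourse, the right-shift of the GLUT4
dose-response when NOX is removed, the insulin/oxidant localization control
of FOXO, the fold-change invariance, the post-fast sensitization of the
dose-response, stable diurnal cycles (SOD2 peak drift ~0.6%/day after the
transient), and the weaker-than-insulin-alone effect of combined
insulin+oxidant at 240 min.

Several printed target values are *not* reproduced by the printed rate
constants, and the package deliberately leaves them unmet rather than
adjusting constants: the PIP3 fraction window (the printed basal/stimulated
targets 0.003/0.03 imply a 10x forward-rate ratio, while the printed
k9_basal = 0.13145, k9 = 0.055 per complex particle and PTEN-dominated
reverse rate give ~9e-4 basal — which matches the printed Akt offset of
200 particles — and ~0.09 stimulated); in consequence the 2-min Akt
activation lands near 30% rather than 10%, and the peak PI3K-complex
fraction near 0.025 rather than 0.05. On the ROS side, the printed
mitochondrial source (180/min x 50) with the printed SOD2 sink yields
0.18 nM basal cytoplasmic ROS rather than the stated 1 nM, and
correspondingly an external-tolerance threshold of ~400x rather than
~1000x the 1 nM reference (a 1 nM basal would place the threshold at
~2000x, so the printed source, not the transport or sink, is the odd one
out). The 48-h fasting InR upregulation overshoots (~3.8x vs ~2x): at zero
insulin the DNA-bound FOXO pool grows several-fold, driven by the
transport table's strong nuclear bias for unphosphorylated FOXO. And the oxidant
preconditioning experiment shows no bifurcation at zero insulin — all
phase-1 stress levels converge to a common high-SOD2 state, because with
the printed factors IKK-mediated FOXO degradation never outpaces
JNK-driven nuclear accumulation. Each of these is asserted at its stated
tolerance in the acceptance tests and reported by `scripts/acceptance.R`,
so the gaps are measured, not hidden.

## Known limitations

The model is a deliberately reduced description: one generic ROS species
and one generic antioxidant; no mitochondrial ROS response to glucose
uptake (the mitochondrial source is constant); no stochastic transcription,
so cell-to-cell variability is out of reach; no mTOR/AMPK/ERK cross-talk;
and FOXO's own synthesis is not under FOXO feedback. The diurnal insulin
profile is a stepped stand-in for a physiological meal response. Passing
tests on this model demonstrate internal consistency with the printed
parameter tables and the qualitative behaviours above — not quantitative
agreement with any particular wet-lab measurement.
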