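---
title: "Methods: kinetic modeling of renal glucose metabolism under proteomics constraints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinetic modeling of renal glucose metabolism under proteomics constraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoren)
```

## The scientific question

2,3-bisphosphoglycerate mutase (BPGM) runs the Rapoport–Luebering shunt: it
diverts 1,3-bisphosphoglycerate to 2,3-bisphosphoglycerate (2,3-BPG),
bypassing the ATP-yielding phosphoglycerate-kinase step. Outside erythrocytes
— in kidney tubular cells in particular — 2,3-BPG cannot act on hemoglobin;
the working hypothesis implemented here is that it acts *inside* the producing
cell as an inhibitor of glycolytic enzymes (hexokinase and phosphoglycerate
mutase). Deleting Bpgm should then lower 2,3-BPG, release the inhibition and
elevate glycolysis: more glucose consumed, more lactate released.

`glycoren` turns that hypothesis into a testable computation: a kinetic ODE
model of glucose metabolism whose maximal enzyme activities are constrained,
sample by sample, by measured protein abundances, and whose output is the
steady-state glucose and lactate exchange flux of control versus knockout
ensembles.

## Model structure and assumptions

The network covers glycolysis, gluconeogenesis and the polyol pathway in the
style of whole-pathway hepatocyte kinetic models. Its 21 dynamic metabolites
are fixed by design (DHAP, Fru, Fru1P, Fru6P, Fru16P2, Fru26P2, GAP, Glc,
Glc6P, Lac, Mal, OA, P, PEP, 1,3-BPG, 2,3-BPG, 2PG, 3PG, PP, Pyr, Sorb); the
reaction inventory around them — GLUT, HK, G6Pase, GPI, PFK1, FBPase1, the
PFK2/FBPase2 bifunctional pair (modeled as two irreversible reactions sharing
one gene mapping), ALDO, TPI, GAPDH, PGK, BPGM, 2,3-BPG phosphatase, PGAM,
ENO, PK, LDH, lactate export, PC, PEPCK, a malate/OA shuttle, aldose
reductase, sorbitol dehydrogenase, fructose uptake, KHK, and a lumped
aldolase-B/triokinase step — was chosen so that every listed metabolite is
both produced and consumed.

Assumptions worth stating explicitly:

- **Clamped cofactors.** NAD/NADH, ADP/ATP and NADP/NADPH are held at fixed
  cytosolic concentrations: the model predicts carbon fluxes, not energy or
  redox state. A consequence is that phosphoryl groups are not conserved (see
  *Numerical choices* below).
- **Open system.** Glucose, lactate, fructose and phosphate cross the
  boundary through facilitated carriers; CO2 enters/leaves through the
  carboxylation reactions. Lactate export drains to a fixed external
  concentration (1 mM) so a nonzero steady export flux exists. Sign
  convention, used everywhere: exchange flux positive = uptake for glucose
  (and fructose, phosphate), positive = release for lactate.
- **First-order ODEs, deterministic kinetics**, concentrations in mM, fluxes
  in mM·min⁻¹ referenced to cell water volume.
- **Carbon bookkeeping** tracks the glucose-derived skeleton: nucleotides and
  phosphate carry zero tracked carbons, CO2 carries one. Every reaction is
  validated carbon-balanced at build time, and the net boundary carbon flux
  vanishes at any converged steady state (an acceptance criterion).

### Rate laws

Four forms cover the network (all proportional to their Vmax, which is what
makes abundance scaling meaningful): irreversible and reversible
Michaelis–Menten with a convenience-kinetics binding denominator, elementary
mass action, and a symmetric facilitated carrier. Reverse maximal rates
follow from the Haldane relation when an equilibrium constant is supplied, so
reversible rates vanish *exactly* at their mass-action equilibrium ratio;
when both `vmax_reverse` and `keq` are given the file is validated (1e-6
relative) rather than silently renormalized.

Effector couplings are modifier terms: competitive inhibitors add
`(I/Ki)^h` to the binding denominator (preserving the equilibrium point of
reversible laws), allosteric inhibitors multiply the rate by
`1/(1+(I/Ki)^h)`, and activators use nonessential activation
`(basal+(A/Ka)^h)/(1+(A/Ka)^h)` with a basal activity fraction of 0.1
(PFK1 ← Fru-2,6-P2, PK ← Fru-1,6-P2).

### The 2,3-BPG couplings

2,3-BPG acts as a competitive inhibitor of hexokinase (Ki 0.02 mM) and of
PGAM (Ki 0.2 mM). Both couplings are individually toggleable
(`build_reference_model(couplings = list(bpg_hk = ..., bpg_pgam = ...))`)
and ON by default. The PGAM coupling deserves a note: the biochemical
literature is ambiguous about whether 2,3-BPG activates (as a catalytic
primer) or inhibits PGAM; this package deliberately models it as an
inhibitor, consistent with the intracellular-brake reading it implements, and
exposes the toggle so the opposite assumption costs one flag. A sensitivity
test in the suite verifies that with both couplings disabled, a hard BPGM
knockout changes glycolysis only through the shunt's small direct carbon
bypass — the mechanism lives in the couplings, not in the carbon
stoichiometry.

The 2,3-BPG phosphatase is mapped to an independent gene (Minpp1), not to
Bpgm. BPGM is in reality trifunctional (it carries a phosphatase activity
itself), but mapping the drain to the same gene as the synthesis would make
both scale identically under knockout and leave steady 2,3-BPG unchanged —
the knockout would have no effect by construction. An independent drain is
the minimal structure under which reduced Bpgm abundance lowers 2,3-BPG.

## Parameter provenance

The study this package reimplements keeps its rate laws and constants in
supplementary material that is not part of the package inputs; constants here
are therefore **package-curated, literature-plausible values** stored in
`inst/extdata/reference_model.json` (structured text, one explicit unit per
constant; files without units are rejected, because transcribing kinetic
tables is exactly where silent unit errors happen). Equilibrium constants are
standard (e.g. GPI 0.3, TPI 0.045, PGK 3200, LDH 2.2e4); Km values are
typical for the mammalian enzymes; Vmax values were set so that the control
model runs at a physiologically sensible working point (≈0.9 mM·min⁻¹ glucose
uptake at 5 mM external glucose, lactate:glucose ≈ 2, 2,3-BPG in the low-mM
range, a ≈1 % shunt flux). They are *inputs* to every analysis, not fitted
quantities, and nothing downstream assumes more than their qualitative
regime.

Two parameterization choices were forced by well-posedness rather than
biochemistry and are worth knowing about:

- **Phosphate transport is fast** (Vmax 50 mM·min⁻¹). With clamped ATP, every
  glycolytic triose permanently consumes one free phosphate at GAPDH (the
  acyl phosphate leaves the tracked pool through PGK into the clamped ATP).
  If phosphate import can rate-limit, sampled models with high hexokinase and
  low transporter abundance lose their steady state entirely — hexose
  phosphates accumulate without bound. Fast Pi exchange (cellular phosphate
  homeostasis) removes that artifact.
- **A small constant pyrophosphate source** (biosynthetic turnover of clamped
  ATP) plus inorganic pyrophosphatase give the PP pool a producer and a
  consumer; both are carbon-free plumbing.

## Steady states and the glucose sweep

No stiff-solver dependency is assumed: steady states are found by
pseudo-transient continuation — adaptive backward-Euler steps solved by a
chord-Newton iteration with a finite-difference Jacobian, step size growing
geometrically on success and shrinking on rejection — followed by a damped
Newton polish of `S v(x) = 0` to near machine precision (typical final
residuals 1e-13). Convergence is declared when
`max|dx/dt| < 1e-9 · max(1, max|x|)`; if model time exceeds 1e6 min first,
the result is flagged non-converged, never silently truncated. Negative
excursions beyond 1e-10 reject a step (no projection onto the positive
orthant: silent projection masks model errors). A fixed-step explicit RK4
integrator serves as the independent oracle on non-stiff toy models; solver
agreement is an acceptance criterion.

The glucose sweep clamps external glucose at each value of a strictly
increasing grid (default 2–12 mM in 0.5 mM steps — the physiological plasma
range; the default is a package choice, not a recovered axis), warm-starting
each point from the previous converged state. Non-converged points are
flagged in the curve and excluded pairwise from downstream group statistics,
with logged counts.

## Proteomics scaling

`vmax_sample = vmax_mean_control · E_sample / E_mean_control`, with three
declared conventions where the upstream study is silent:

- **Isozymes sum.** A reaction's abundance is the *sum* of its mapped genes'
  intensities (isozymes catalyzing the same step add to total activity).
- **Unmeasured enzymes keep factor 1** (the sample behaves like the control
  mean), recorded as provenance `"default_unmeasured"`; a measured reaction
  whose control-mean abundance is zero is demoted the same way with a warning
  — division by zero is never performed.
- **No cross-sample renormalization**: intensities are used as given;
  normalization belongs to upstream proteomics processing.

Gene symbols are matched case-insensitively (mouse *Bpgm* vs human *BPGM*),
with a logged message when case folding triggers. The default gene map is
derived from the reference model's annotations and is itself a package
declaration, not a recovered fact. Scaling multiplies forward and explicit
reverse Vmax together, so equilibrium constants are preserved; instantiation
is non-destructive. The knockout is normally represented by the *measured*
Bpgm intensities; `hard_ko()` additionally forces the BPGM factor to exactly
zero for in silico deletion, the only situation in which a zero factor is
legal.

## The synthetic-data generator

`generate_proteomics()` emulates exactly the statistical structure the
scaling stage consumes: per-gene baseline intensities, a group-structured
fold change (Bpgm default 0.05 — an inducible knockout with residual signal,
not a hard zero), and multiplicative lognormal noise (Gaussian on logs,
default SD 0.25, a typical DIA between-replicate spread), seeded and
deterministic. Default group size is six per condition, mirroring the modeled
study design. Baselines are order-of-magnitude placeholders (integer-valued,
spread over 2e5–2e7), chosen so that zero-noise fold-change recovery is a
bitwise ratio identity.

What the generator does *not* emulate: peptide-level missingness, batch
effects, shared-peptide ambiguity, or correlated enzyme co-regulation. A
green end-to-end test therefore establishes that the pipeline's *mechanics*
(aggregation, ratio, instantiation, simulation, summary) are correct and that
the knockout direction is robust to independent multiplicative noise — it
does not validate the model against real kidney proteomes.

## Numerical choices, degenerate inputs, determinism

- Steady-state tolerance 1e-9 (relative to state magnitude), polish target
  1e-13; homogeneity and carbon-balance acceptance checks run at 1e-6
  relative.
- An all-Vmax-zero model is trivially steady at its initial state (time 0).
- Single-sample groups report SD as `NA`, never 0; SD uses the n−1
  denominator throughout.
- All randomness flows through one integer seed; the RNG state of the calling
  session is restored after generation. Repeated seeded runs produce
  bit-identical output files (CLI logs carry no timestamps, and config echoes
  store path basenames, for exactly this reason).
- The CLI echoes every tunable that affects numbers into `config.json`
  alongside the outputs.

## Known limitations

- Kinetic constants are curated defaults, not the source study's supplement;
  quantitative flux values should be read as model-relative, not tissue
  measurements. Only directions and ratios are used in acceptance.
- Energy and redox state are clamped, so the model cannot report ATP cost or
  NADPH budget effects (the polyol pathway's NADPH drain is stoichiometric
  only).
- One steady state per condition is computed; bifurcation structure and
  sustained glycolytic oscillations are out of scope (a non-converged flag is
  the only symptom the solver will report).
- The in vitro (fibroblast) variant of the comparison is expressible by
  editing the model file (e.g. zeroing gluconeogenic Vmax) but no separate
  fibroblast parameterization ships with the package.

## Session info

```{r}
sessionInfo()
```
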