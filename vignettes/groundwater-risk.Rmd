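---
title: "Trace-element occurrence and drinking-water risk in monitored groundwater"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trace-element occurrence and drinking-water risk in monitored groundwater}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwtrace)
```

## The problem

Shallow dug wells are the dominant drinking-water source in many fast-growing
cities. Where the aquifer sits in weathered crystalline basement rock,
metalloids — arsenic, antimony — and selenium can reach groundwater from both
geogenic weathering and surface contamination, and their concentrations swing
strongly with season: low precipitation concentrates the groundwater, so dry
seasons show both more frequent detection and higher magnitudes. `gwtrace`
packages the complete analysis of such a campaign: 35 wells stratified over
four land-use areas (24 residential, 5 commercial, 4 industrial, 2
agricultural), each sampled monthly three times per wet and per dry season for
arsenic, antimony and selenium, and shipped with the package as per-well
summary tables (`load_study_fixture()`).

Non-detects in this design are recorded as zero and **included** in every
mean. That convention is not innocuous — it biases means downward relative to
½-LOD substitution — but it is the arithmetic the packaged tables follow, and
all published quantities reproduce only under it. The per-well overall mean is
the unweighted mean of the two seasonal means, which equals the mean of all
six monthly values under the balanced design.

## The risk cascade

For each land-use area and cohort the package computes the standard
non-carcinogenic ingestion cascade:

$$\mathrm{ADD} = \frac{DW \cdot C}{BW}, \qquad
  \mathrm{HQ} = \frac{\mathrm{ADD}}{\mathrm{RfD}}, \qquad
  \mathrm{HI} = \sum_{\text{analytes}} \mathrm{HQ},$$

where $C$ is the area mean of per-well overall means (µg/L, converted once to
mg/L at the risk-module boundary), $DW$ the daily water intake (2.0 L adults,
1.0 L children), $BW$ the body weight (50 kg adults, 20 kg children), and RfD
the chronic oral reference dose (As 0.0003, Sb 0.0004, Se 0.005 mg/kg/day).
Exposure-duration and averaging-time factors present in fuller exposure
models are deliberately absent: the cascade is the simple intake form, and
HQ and HI are therefore exactly linear in concentration. Two consequences are
useful invariants: doubling every concentration doubles every HI, and the
child/adult HQ ratio is $(1/20)/(2/50) = 1.25$ for every analyte and area.

```{r risk}
rt <- risk_table(load_study_fixture())
unique(rt[, c("area", "cohort", "HI")])
```

`risk_table(c_signif = 3)` additionally reproduces the rounding regime of the
published campaign table, which rounds $C$ to three significant figures
(half-up) before the cascade; the default keeps full precision. Both flags
`hq_gt1` and `hq_gt2` are reported without interpretation: HQ > 1 is the
conventional screening threshold, and HQ is not a probability of harm.

## Exceedance, detection and seasonal comparison

Exceedance counts *wells* whose summary mean passes a guideline limit; with 35
wells the published fractions (74.3%, 11.4%, 17%) are exact well counts
(26/35, 4/35, 6/35), which is why the well — not the individual sample — is
the counting unit. The comparison is strict (`>`) by default; an `inclusive`
option exists because one dry-season selenium claim counts a well sitting
exactly at the 40 µg/L limit.

The seasonal comparison is a **paired** two-sided t-test on per-well
(dry − wet) differences. Pairing is our design choice — the same wells are
measured in both seasons — and with differences this systematic it is the
conservative one to disclose. The degenerate case (zero spread, nonzero mean
difference) reports the limiting p-value 0 with a warning rather than
failing. One-way ANOVA across land-use areas uses the classical
decomposition with `SS_between + SS_within = SS_total` checked to 1e-9.

## Ordination

`prevalence_order()` ranks analytes by total mass across wells (ties broken
alphabetically and flagged); on the fixture it yields antimony > selenium >
arsenic, and the correspondence-analysis column masses agree.
`ca_ordination()` implements the SVD of the standardized Pearson-residual
matrix directly — principal coordinates, total inertia $= \chi^2/n$, and the
transition formulas are part of its contract and are tested against an
independent canonical-correlation decomposition. `pca_ordination()` wraps
`stats::prcomp`; the input matrix is the 35 wells × 3 analytes of overall
means, standardized to the correlation matrix, which was an open choice: the
source analysis does not state its matrix orientation or scaling, so the
printed explained-variance fractions (46.6%/32.1%) are reported but never
asserted. (With these defaults they do in fact reproduce to ~0.1%.)
Component signs follow a fixed convention — first nonzero loading positive —
so results are stable across LAPACK builds.

```{r pca}
pca_ordination(wells_matrix(load_study_fixture()))$explained_fraction
```

## The synthetic campaign generator

`generate_campaign()` draws each well × season × month × analyte record from
a zero-inflated lognormal: detection is Bernoulli with an analyte- and
season-specific probability, detected magnitudes are lognormal with
season-specific log geometric mean and SD times a positive area multiplier,
and non-detects are recorded as zero. The distribution family is our choice —
the source states none — motivated by the data's character: non-negative,
right-skewed, many non-detects, and a dry-season shift carried both by the
detection probability and the magnitude.

Defaults are calibrated once from the packaged fixture
(`calibrate_sim_config()`): detection probability = fraction of wells with a
nonzero seasonal mean (arsenic 0 wet / 6/35 dry; antimony 7/35 wet / 1 dry;
selenium 1 in both), log-GM/log-GSD = mean/SD of the log of detected seasonal
means (dry-season antimony GM ≈ 47 µg/L), area multipliers 1, and the study's
own well counts. These are the study conditions the simulator emulates, not
tuning knobs. What the generator does **not** emulate: within-well random
effects (monthly values share one variance component), spatial
autocorrelation between wells, and detection-limit censoring of the magnitude
distribution — so passing recovery tests show the estimators work under the
model, not that real campaigns satisfy it.

Because the cascade is linear, the expected HI under a configuration has the
closed form built from the lognormal mean
$p \cdot e^{\mu + \sigma^2/2} \cdot m$ per season (`expected_hi()`), which the
simulated pipeline is checked against. Recovery tests run at roughly 10,000
well-months (1,680 wells × 6 monthly samples, ~60,000 records), a size chosen
to make the binomial standard error of a detection probability about 0.005 —
small enough that a ±0.02 recovery band is a real test; it completes in
seconds. All randomness flows through a single mandatory seed
(`withr::with_seed`), making campaigns byte-reproducible.

## Numerical choices and edge cases

- Unit conversion µg/L → mg/L happens exactly once, at the risk boundary.
- `signif` rounding for the published-table regime uses half-up with a 1e-8
  tie shift, because the printed values round decimal ties upward
  (0.02705 → 0.0271) while binary doubles sit just under the tie.
- Zero-variance inputs are explicit errors (`gw_degenerate_error`) for
  correlation and ANOVA, never silent NaNs; the all-zero CA matrix and
  unknown labels are validation errors with the offending name in the
  message.
- The fixture loader re-verifies structural integrity (35 wells, area counts
  24/5/4/2, `min ≤ mean ≤ max`) on every load.

## Known limitations

The packaged tables are summary statistics, not raw monthly values, so
per-well SDs cannot be re-derived and are carried as data. One transcribed
value (GW32 dry-season selenium) required normalizing an obvious misplaced
decimal; `inst/extdata/PROVENANCE.md` documents the evidence. The exceedance
and risk machinery assumes the well is the observational unit and the design
is balanced; unbalanced campaigns are summarized per scope but the
overall-equals-mean-of-seasons identity then no longer holds exactly.
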