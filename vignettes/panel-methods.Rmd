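---
title: "Methods: quantification, tolerance ranges and dysbiosis scoring"
author: "qpcrpanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantification, tolerance ranges and dysbiosis scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpcrpanel)
```

# The assay model

The package implements the computational side of a stool microbial qPCR
panel: fifteen markers spanning the major gut phyla, groups and genera (from
*Akkermansia muciniphila* to the pan-bacterial Eubacteria target), each
measured in duplicate against a per-marker standard curve.

## From threshold cycle to copies per gram

A qPCR standard curve is linear on the decade scale,
$Ct = m \log_{10}(\text{copies}) + b$ with slope $m < 0$ (about $-3.32$ at
100% amplification efficiency). Inverting it and scaling by the extraction
volumetrics gives the absolute abundance in gene copies per gram of stool:

$$A \;=\; \frac{(V_e / V_c)\; 10^{(Ct - b)/m}}{P \cdot C_g}$$

where $V_e$ is the DNA elution volume (µL), $V_c$ the volume loaded into the
PCR (µL), $P$ the stool portion weight (g, 0.040 by default) and $C_g$ the
number of 16S/18S rRNA gene copies per genome of the target. Dividing by
$C_g$ converts gene copies into organism equivalents; the per-marker values
are stored as literals in `default_panel()` (group-level markers carry the
average over their member species).

Replicates are averaged on the Ct scale before conversion. Two policies are
deliberate choices rather than assay facts:

* **No amplification is censoring, not Ct 40.** An empty Ct cell becomes a
  "below detection" flag. Imputing the cycle ceiling would fabricate an
  abundance exactly at the detection limit and bias every downstream mean.
* **Discordant duplicates** (range above one cycle) still contribute their
  mean, but the sample carries a QC flag, so review is possible without
  discarding data.

## Relative abundance

Water content of stool varies, so equal stool weights do not carry equal
microbial DNA. Each marker is therefore normalized to the total bacterial
load: `relative_log = log10(A_marker / A_EUB)`. The base is log10 — the
natural scale of the standard curve and the scale on which the clinical
thresholds below are one unit apart. Figure-style group contrasts
(`group_log_ratio()`) instead use the natural log, matching the convention
that a log-ratio of 0.05 is a 5.1% geometric-mean difference; the two scales
are kept in separately named functions so they cannot be mixed silently.

# The reference model: tolerance ranges

`fit_tolerance_ranges()` is the modelling core. On a healthy reference
cohort it computes, per marker, the mean and sample standard deviation
(n − 1 denominator) of the relative log abundance — for EUB, of the log10
absolute load, since EUB/EUB is identically one. Limits are then placed on
the clinically adverse side:

| class | borderline | beyond |
|---|---|---|
| beneficial, total | mean − SD | mean − SD − 1 |
| harmful | mean + SD | mean + SD + 1 |
| bidirectional | both | one unit outside each |

The "one unit" is one log10 decade, consistent with the dysbiosis category
thresholds (0.66 and −0.34) differing by exactly one. A value exactly on a
limit takes the less severe status — a deliberate, conservative tie-break.

Two design points were genuinely open:

* **Direction of the SD offset.** Placing the borderline limit *above* the
  mean of a beneficial marker would flag a large share of the very cohort
  the range was fitted on; limits therefore sit on the deficit side for
  beneficial markers and the excess side for harmful ones. The `direction`
  argument overrides this per marker for sensitivity analyses.
* **Below-detection classification.** A beneficial organism that fails to
  amplify is a deficit signal (`beyond`); an undetectable harmful organism
  is unremarkable (`normal`); an undetectable bidirectional marker is
  treated as a deficit.

By construction, a one-sided marker classifies a fraction
$\Phi(1) \approx 0.841$ of i.i.d. normal healthy values as `normal`; the
test suite checks this at $n = 10{,}000$ per marker.

# Clinical indices

* **FIR/BAC balance**: $\log_{10} A_{FIR} - \log_{10} A_{BAC}$. Positive
  means Bacillota (Firmicutes) predominance, negative Bacteroidota; exactly
  zero is labelled `balanced`. No tolerance range is attached — the balance
  reflects diet more than pathology.
* **Dysbiosis index**: $\log_{10} A_{FAE} - \log_{10} A_{ECO}$, the
  *F. prausnitzii* / *E. coli* contrast (anti- vs pro-inflammatory).
  Categories: `healthy` above 0.66, `severe` below −0.34, `mild` in between
  (boundaries inclusive in `mild`).

The operand order is chosen so that FAE-rich (healthy) samples score high,
which is the only orientation compatible with "healthy above 0.66"; the
`orientation` argument flips the sign for anyone wishing the literal
subtraction the index's verbal definition suggests. Both indices depend only
on abundance *ratios* within a sample, so they are exactly invariant to
$V_e$, $V_c$ and $P$ — a property tested to $10^{-12}$.

Thresholds are configuration (`dysbiosis_thresholds()`), not constants: they
derive from an external reference cohort whose raw data are not public, and
a laboratory recalibrating them should not need to patch code. A sanity
check warns whenever the supplied pair does not span one decade.

# What the simulator emulates — and what it does not

`simulate_cohort()` draws per-sample marker values from independent normals
on the log10 relative scale, an EUB load from a log-normal, metadata from
configurable category frequencies, and group-level effects as additive log10
shifts. `simulate_plate()` inverts the calibration equation to produce
duplicate Ct values with optional Gaussian noise, censoring anything past
cycle 40.

Default parameters were fixed once, before any testing, as values a
microbiologist would call typical for a healthy adult cohort measured with a
broad-group panel:

* baseline log10 relative abundances from −0.30 (Bacillota) down to −6.0
  (*C. albicans*), with SDs of 0.25–0.45 decades;
* total load $10^{11}$ copies/g (SD 0.35 decades);
* 70.13% female, age and BMI bin frequencies and IBS subtype frequencies
  matching the published cohort composition;
* group effects oriented by the reported associations: more
  *A. muciniphila* in women, less *A. muciniphila* and *M. smithii* with
  diarrheal IBS, more with constipation;
* dysbiosis scenarios re-centre the FAE−ECO contrast at 1.7 (healthy), 0.16
  (mild) and −1.2 (severe), with mixing weights 0.85/0.11/0.04 echoing the
  109/17/5 split reported clinically. A sample's *intended* category is
  always derived from its realized generating index, never from the
  scenario label, so threshold-adjacent draws are never forced into a
  category they do not occupy.

The simulator is deliberately simple: markers are compositionally
*uncoupled* (EUB is drawn as an independent denominator), amplification
kinetics, inhibitors and plate spatial effects are absent, and noise is
Gaussian on the Ct scale. Passing tests therefore demonstrate correctness of
the arithmetic and the classification logic under the stated statistical
model — not robustness to real-world artefacts such as inhibition or
compositional closure.

# Numerical choices and problem sizes

* All randomness flows from one integer seed through a fixed stream-split
  (`seed * 97 + stream * 1009 mod 2^31 − 1`), so adding a pipeline stage
  never perturbs earlier draws and runs are byte-reproducible.
* Serialized numbers carry 12 significant digits; range JSON round-trips
  bit-stably at that precision.
* The validation suite uses 50 samples for the noise-free round trip
  (recovered to within $10^{-6}$ relative, observed ~$10^{-15}$), 500
  reference subjects for range recovery (means within ±0.05 decades, SDs
  within ±10%), 10,000 draws per marker for the coverage property, and
  1,000 samples at Ct noise SD 0.25 for end-to-end category concordance
  (≥ 90% required on samples at least 0.3 from a threshold; in practice
  the noise propagates to only ~0.075 SD on the index, so concordance is
  essentially perfect). These sizes give comfortable statistical resolution
  for each property while keeping the whole suite fast.

# Known limitations

* Standard curves are inputs; the package does not fit them from dilution
  series, nor does it model plate effects or melting-curve QC.
* The published tolerance limits themselves cannot be reproduced: the
  underlying healthy-cohort raw data are not available. The package
  reproduces the *procedure* and validates it on synthetic cohorts with
  known truth.
* Cohort-level inferential statistics (MANOVA, ANOVA, logistic regression,
  imputation, power) are out of scope; standard R tooling applies directly
  to the `relative_log` matrix the pipeline produces.
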