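---
title: "From spot intensities to protein states: the secmapr workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From spot intensities to protein states: the secmapr workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secmapr)
```

## The measurement being modeled

SEC-MAP couples size-exclusion chromatography (SEC) with multiplex antibody
microarray detection. A native cell lysate is fractionated on an SEC column
(large species elute first), the 24 collected aliquots are pooled into a
small number of merged molecular-weight (MW) fractions, and each pooled
fraction is incubated on its own antibody subarray. After biotin labeling of
the lysate, bound protein is read out through a streptavidin fluorophore, so
each spot reports how much of one antibody's target eluted in one MW window
under one protein extraction protocol.

Because a protein's *monomer* MW is known, the elution pattern is
informative about its assembly state: signal at the theoretical MW fraction
means the protein runs alone; signal above it (larger apparent MW, smaller
fraction id) indicates participation in a complex; signal below it indicates
degradation/hydrolysis. `secmapr` implements this whole desk side —
spot-level normalization, the SEC model with its state rules, and the
integration of the resulting detections with LC-MS/MS (label-free
quantification, LFQ) and RNA-seq (FPKM) tables — together with a forward
simulator that provides recoverable ground truth for every stage.

## Spot-level normalization

Raw inputs are GenePix-style spot medians $\tilde\delta$. Three corrections
are applied per subarray, in this order:

1. **Background subtraction.** The antibody-free MasterMix (MM) spots of the
   subarray form the background population; with $k$ their median and
   $\sigma_k$ their standard deviation,
   $$\tau_i = (\tilde\delta_i - k) - 2\sigma_k.$$
   The background legend calls $2\sigma_k$ a *variance*, but the term is
   used additively with intensities; we therefore interpret it as twice the
   SD, which is the only dimensionally consistent reading. Negative $\tau$
   values are retained through the next steps (they are informative for QC)
   and floored at zero only in the final signal matrix.
2. **MasterMix correction.** Antibodies printed from the same MM lot share
   its assay background:
   $$S_i = \tau_i - (\tilde\delta_{MM}^{max} + 0.05\,\tilde\delta_{MM}^{max}),$$
   with $\tilde\delta_{MM}^{max}$ the maximum MM spot median of the lot.
   Because $k$ and $2\sigma_k$ are themselves estimated from the MM spots,
   the pipeline applies this correction to the MM spots' *background
   corrected* medians; using raw MM medians would subtract the optical
   background twice. A negative MM maximum is treated as zero, which keeps
   $S \le \tau$.
3. **Biotin normalization.** $S$ is divided by the subarray's biotin
   positive-control reference (the median biotin-control intensity carried
   through the same two corrections). A non-positive reference is a QC
   failure: the subarray is excluded and logged, rather than silently
   producing sign-flipped signals.

A protein is **detected** when strictly more than 50% of its spotted
antibodies display a positive replicate-median normalized signal. The
threshold is applied at the antibody level (not the spot level) and the
inequality is strict, so 1 of 2 antibodies is *not* enough while 2 of 3 is.
The per-protein, per-fraction signal is the median over antibodies of the
replicate-median normalized signal — medians at both levels, so a single bad
spot or one unspecific antibody cannot move the value.

Whether normalization operates per subarray or per slide is an open choice;
`secmapr` normalizes per subarray, because each pooled fraction is incubated
on its own subarray and the backgrounds are therefore subarray-specific.

## The SEC model

**Calibration.** MW calibration is an ordinary least-squares fit of
$\log_{10}(\mathrm{MW})$ on elution position — the standard SEC working
curve; the slope must be negative. The bundled standard mix (Ferritin
440 kDa, aldolase 158 kDa, conalbumin 75 kDa, ovalbumin 43 kDa,
ribonuclease A 13.7 kDa) ships with nominal example positions; measured
positions should be supplied for a real column run. Predictions outside the
calibrated MW range are clamped to the terminal fractions with a warning.

**Fraction schemes.** The default scheme pools the 24 collected fractions in
consecutive triples into 8 merged fractions covering 166–473, 121–142,
74–103, 54–63, 33–46, 24–28, 17–21 and 11–15 kDa; a coarser 5-range scheme
(142–437 … 11–24 kDa) is bundled as an alternative. Pooling sums member
fractions, so total signal is conserved exactly. The printed MW ranges leave
small gaps (e.g. 63–74 kDa); an MW falling in a gap is assigned to the range
whose nearest boundary is closest, with ties going to the larger-MW
fraction.

**Peaks and states.** A merged fraction is a *peak* when its signal reaches
at least half of the profile maximum and is a local maximum or plateau. The
0.5 relative threshold is deliberately permissive: it lets a 50/50
monomer–complex split show both peaks while suppressing pooling spillover.
Peaks are then compared with the theoretical fraction: peaks above it
(smaller id) contribute *complexed*, below it *hydrolyzed*, at it *monomer*.
Multi-peak profiles produce the compound states `monomer+complexed`,
`monomer+hydrolyzed`, `complexed+hydrolyzed` and `mixed`; these compound
labels are this package's extension of the single-state rule, since
graphical presentations of such profiles do not need to name them. An empty
peak set yields `not_detected`.

Two proteins are **co-complex candidates** when they share a complexed peak
fraction within the same protocol channel. These are candidates, not
assertions: unrelated complexes of similar size pool into the same merged
fraction, so candidate pairs include size coincidences by construction.

## Multi-omics integration

Datasets are merged per protein id. When a protein maps to several gene
ids, the gene with the highest FPKM is selected (ties break to the
lexicographically smallest id and are flagged). A protein is **fully
observed** when peptide count $\ge 1$, FPKM $\ge 1$ *or* QAS $\ge 1$. QAS —
the quantified array signal — is implemented as the protein's maximum
biotin-normalized SEC-MAP signal across fractions and protocols, so the
unit threshold reads "at least biotin-control-level signal".

Overlap statistics are query-normalized: $100 \cdot |A \cap B| / |A|$ with
$A$ the first-named set, reported in both orientations plus Jaccard. When a
pair involves SEC-MAP, both sets are restricted to the antibody-panel
universe first — a 162-protein panel cannot meaningfully "miss" proteins it
never probed.

Subcellular localization categories are the 15 non-empty subsets of
{Cyt, Mem, Org, Nuc}, labeled in the canonical positive-selection order
(`Nuc`, `Cyt`, `Mem`, `Org`, `Nuc-Org`, …, `Nuc-Org-Cyt-Mem`).

The LFQ/FPKM population groups are defined by rank-based fences because the
source visualization names the groups without stating thresholds: quartile
fences on each log axis define *low*/*high*; `high-LFQ/low-FPKM` and
`high-LFQ/high-FPKM` are the corner populations, `low-LFQ/progressive-FPKM`
is low LFQ with FPKM above its median, everything else is the average
population, and points whose standardized residual from a Huber robust
regression of log LFQ on log FPKM exceeds 3 are outliers. Five distinct
groups result (the source list names "average population" twice, which we
read as a typo). The grouping is purely rank/robust-fit based, hence
seedless and permutation-invariant.

## What the simulator emulates — and what it does not

The generator's defaults are the study conditions used throughout the
package's validation: 162 panel proteins targeted by 205 antibodies (the
main text's count; the abstract's 206 differs by one and the panel size is
a config parameter), 10 multi-protein complexes, 5 replicate spots per
antibody per subarray, one subarray per (protocol × merged fraction)
incubation, nine extraction protocols modeled as per-compartment extraction
efficiencies with a biotin-labeling penalty for the urea buffers (#2, #3),
and compartment-resolved channels for #7–#9.

Elution peaks are Gaussians with SD 0.6 collected fractions, discretized by
integration over fraction boundaries and renormalized so each protein's
total signal is exactly abundance × extraction × labeling efficiency. Spot
noise is multiplicative lognormal (CV 0.2 by default, unit mean);
background is additive Gaussian truncated at zero. Default intensity scales
(background 200 ± 20, MasterMix level 500, biotin control 30000, abundance
median 2 × 10⁴ a.u.) keep the signal-to-background-noise ratio far above 5,
as in a usable array scan.

Three generator constraints make the ground truth *recoverable by
construction*, which the end-to-end identity tests rely on:

- complex members are restricted to theoretical fractions ≥ 3 and the
  complex MW is clamped into the top range, so a complexed species always
  pools at least two merged fractions above its members;
- the degraded-species MW is drawn from [11 kDa, min(0.5 × MW, top of the
  range two fractions below)], so hydrolysis products are always resolvable
  from the monomer after pooling;
- species shares are 1 or 0.5, so every true species clears the 0.5
  relative peak threshold under zero noise.

When no fitted calibration is passed, the simulator places peaks with a
scheme-consistent piecewise log-linear MW→position map confined to the
central window of each pooling group. This guarantees that pooled peak
positions agree with `assign_theoretical_fraction()` for every MW — a
single global log-linear line cannot guarantee that against the printed,
unevenly spaced MW ranges, and without the guarantee a "100% recovery"
test would conflate discretization artifacts with real defects. A fitted
`mw_calibration` can be supplied to study exactly those artifacts.

The simulator does **not** model raw images, chromatogram shapes, epitope
masking by biotinylation, antibody cross-reactivity, or isoform-specific
binding (phospho/isoform antibodies carry an affinity factor but bind the
same target pool). Passing the recovery tests therefore shows the
*inference rules* are implemented correctly, not that real arrays reach
this accuracy: real data add exactly the failure modes listed above.

The LFQ/FPKM simulator draws log FPKM as a correlated companion of
standardized log abundance (target correlation 0.6 by default, 0.9 in the
correlation-recovery checks), Poisson peptide counts with abundance-scaled
rates, and forces small shares of zero peptide counts (5%) and zero FPKM
(3%) so the fully-observed logic is exercised; 10% of proteins receive a
second gene id with strictly lower FPKM.

## Numerical choices and degenerate inputs

- Background estimation needs ≥ 3 MM-only spots per subarray; fewer is an
  error naming the subarray, not a silent default.
- Replicate and antibody aggregation use `median()`; with an even number of
  values R's convention (mean of the two central values) applies.
- Merged-profile ties: plateaus count as peaks, so two exactly equal
  adjacent fractions both report.
- An all-zero profile yields no peaks and `not_detected`, never a division
  by zero (the relative threshold is only applied when the maximum is
  positive).
- FPKM selection ties are deterministic (smallest gene id) and flagged in
  the merged table.
- Problem sizes in the test-suite: the exhaustive state-rule check covers
  all 2⁸ × 8 = 2048 peak-set/theoretical combinations; conservation runs
  1000 random profiles; recovery runs the full 162-protein panel noiseless
  once and 20 seeds at CV 0.2; correlation recovery uses 2000 proteins.

## Known limitations

- The state rule compares *merged* fractions, so complexes smaller than
  about one merged fraction above the monomer are indistinguishable from
  monomers; this is a resolution limit of the pooling design, not of the
  implementation.
- Co-complex candidate pairs are size coincidences until orthogonally
  validated; the package deliberately reports them as candidates.
- The overlap percentages depend on the stated denominator convention;
  both orientations and Jaccard are always reported so no single convention
  is hidden in a headline number.
- Protocol efficiency values are plausible-scale modeling constants for the
  simulator, not measured properties of the published buffers.
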