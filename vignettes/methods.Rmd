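---
title: "Methods: AP-MS complex calling and allele-specific ChIP-seq analysis"
author: "hmrtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: AP-MS complex calling and allele-specific ChIP-seq analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmrtools)
```

# Scope

`hmrtools` implements the two quantitative arms by which a multi-subunit
chromatin complex — the Drosophila HMR complex, with subunits HMR, LHR, NLP,
BOH1, BOH2 and HP1a — is defined from reciprocal AP-MS experiments, and by
which the allele-specific loss of heterochromatin-proximal chromatin binding
of a mutant allele (`Hmr-dC`) is tested in ChIP-seq. Both arms are paired
with a synthetic-data generator with known ground truth, so every stage can
be validated end to end without any external download.

# The AP-MS enrichment model

Input is a MaxQuant-style `proteinGroups` table of per-sample iBAQ
intensities plus a sample sheet assigning samples to bait IP series and
pooled controls. The preprocessing chain is:

1. **Filtering.** Rows flagged `Reverse` (decoys), `Potential contaminant`
   or `Only identified by site` are removed.
2. **log2 transform.** Zero intensities are non-detections, carried as
   missing, never as measured zeros.
3. **Left-censored imputation.** Label-free missingness concentrates below
   the detection limit (missing-not-at-random). Missing cells of sample $s$
   are drawn from $\mathcal N(m_s - \text{shift}\cdot sd_s,\;
   (\text{scale}\cdot sd_s)^2)$ with the standard manual setting
   shift = 1.8, scale = 0.3, where $m_s, sd_s$ are the observed mean and SD
   of that sample column. The draw is seeded and logged. Proteins missing in
   *every* sample are dropped first (imputing them from column statistics
   alone is formally possible but meaningless); a count is reported.
4. **Median normalization.** Each column is shifted additively to the grand
   median of the pre-normalization column medians. Imputation precedes
   normalization because the imputation statistics are per-sample
   properties of the raw column; centering to the grand median (rather than
   zero) keeps values on the interpretable log2-iBAQ scale. Bait
   normalization (below) replaces median normalization where profiles are
   expressed relative to the bait.

Per protein $g$, a one-way group-means model is fitted by OLS over all
experiment groups (each bait series one group, all pooled controls one
group), giving residual variance $s_g^2$ on $d_g = n - k$ df. Variances are
moderated with the standard empirical-Bayes scheme: the prior
$(d_0, s_0^2)$ is estimated by matching the first two moments of
$\log s_g^2$ through digamma/trigamma inversion, and

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},\qquad
t_g = \frac{\log_2\text{FC}_g}{\sqrt{\tilde s_g^2\,(1/n_\text{IP} +
1/n_\text{CTRL})}}$$

on $d_0 + d_g$ df (capped at the ensemble's summed residual df). The
implementation is authored here and is verified in the test suite against
limma's `squeezeVar`/`eBayes` to $10^{-9}$; with $d_0 = 0$ it reduces
exactly to the ordinary two-sample $t$. BH adjustment is applied within each
contrast across all retained proteins — the universe a volcano plot of that
contrast displays — not jointly across contrasts. Raw p-values drive
differential-plot inclusion; adjusted p-values drive the interactor gate.

## Interactor sets, consensus complex, differential interactomes

Per bait, interactors are gated at log2FC > 2.5 and adjusted p < 0.05 (both
strict). Gated sets are partitioned UpSet-style into exclusive
intersections; the **consensus complex** is the full-intersection cell over
all six reciprocal IPs. Because a genuine subunit can narrowly miss one
gate, a *near-miss table* (present in $k-1$ of $k$ sets, missing bait named)
is reported alongside — HP1a-like borderline subunits surface there instead
of silently vanishing.

Bait-normalized profiles subtract the bait protein's own log2FC, making
profiles comparable between conditions with different bait expression; the
per-protein change between conditions is the offset from the diagonal in
the two-condition scatter, summarized as mean ± SEM over replicate IPs
(replicate enrichment = replicate IP minus the mean of all controls; SEM is
undefined at $n = 1$ and reported as `NA`). The differential gate includes a
protein when raw p < 0.05 versus control in at least one condition and
labels it differential when the between-condition log2 difference clears
1.5 log2 units. The printed convention "log2FC(alt/ref) < 1.5" is
internally inconsistent with "equal enrichment is not differential" (a zero
difference satisfies it), so the package applies the threshold as a
magnitude gate, two-sided by default with signed variants exposed.

# The ChIP-seq model

Inputs are per-replicate peak calls (BED) and binned coverage tracks
(bedGraph, depth/input-normalized upstream), plus an HP1a reference track.

* **Consensus peaks.** Candidate regions are the merged (≥ 1 bp overlap)
  union of all replicate peaks; a region is kept when at least
  `ceiling(0.5 · n)` replicates have an overlapping peak (5 of 10 in the
  reference design, pooled across both genotypes). The centering anchor of
  a high-confidence region is taken as the merged-region midpoint.
  Presence means ≥ 1 bp overlap; the threshold and the overlap rule are
  exposed as parameters.
* **Matrices.** 4 kb windows centered on peak midpoints, averaged into
  10 bp bins (400 columns), then z-scored by the *global* matrix mean and
  SD. Windows are snapped to the track grid; out-of-bounds windows are
  dropped with a log message.
* **HP1a-proximal class.** Peaks ranked by mean HP1a signal over the 4 kb
  window; the top `floor(0.10 · n)` are HP1a-proximal. Ties break by
  genomic order, so labels are deterministic; ranking is invariant to
  global z-scoring of the HP1a track, so raw versus z-scored input does not
  change labels.
* **Central-window statistic.** Mean z-score of the central 200 bp
  (20 bins) per peak per replicate. The Gaussian peak shape of the
  simulator makes this differ from the 4 kb mean, which is what the window
  logic is for.
* **Mixed model.** `z_central ~ genotype * class + (1 | sample)`, REML,
  Satterthwaite df (main-effects-only variant available: the design
  description names the fixed effects without stating an interaction, so
  both are implemented; the interaction term is the direct test of
  "proximal-only loss"). Fitting is done with `lme4`/`lmerTest` — the
  canonical implementation of this model — behind the package's interface;
  tests cross-check fixed effects against an independent `nlme` fit and
  the OLS limit at zero sample variance. Note that global z-scoring of
  per-sample matrices already removes most per-sample offsets, so
  $\sigma^2_\text{sample}$ is typically near zero on simulated data; the
  random intercept still guards against residual per-replicate shifts in
  real data.
* **Chromosome-wide profiles.** Replicate-mean track, 50 kb bins, global
  z-score.
* **Chromosome-4 fraction.** Per replicate, the percentage of peaks on
  chr4; genotype effect tested by OLS `pct ~ genotype`. A zero-residual
  degenerate fit (identical percentages) reports p = 1 at slope 0.

# What the synthetic generator emulates

**AP-MS** (`apms_sim_config()` defaults = the study conditions): six bait
series with the reference replicate counts (HMR 8, LHR 4, NLP 3, BOH1 4,
BOH2 5, HP1a 4) against 8 pooled controls; a shared 1000-protein log-normal
background (baseline log2-iBAQ $\mathcal N(25, 2^2)$, replicate noise SD
0.5); a planted six-member core enriched $+5$ log2 units in every bait IP
and ten bait-specific interactors per bait at $+4$; logistic
intensity-dependent dropout (midpoint 21, slope 1.5), i.e. left-censored
MNAR by construction, which is exactly the regime the shifted-Gaussian
imputation presumes. One seed drives a single generator stream.

**ChIP** (`chip_sim_config()` defaults): a scaled-down 11.5 Mb
six-chromosome genome with a 0.5 Mb chr4; 1000 non-overlapping peaks
(100 proximal, 60% of proximal on the heterochromatic chr4); Gaussian
coverage bumps (SD 200 bp) with summit amplitudes wt = 3/3 and
dC = 1/3 (proximal/nonproximal) over $\mathcal N(0, 1)$ background plus a
per-sample intercept (SD 0.3); HP1a amplitudes 10 vs 1; five replicates per
genotype; per-replicate peak-call dropout 0.1 everywhere except 0.6 for
dC-proximal. The dC configuration encodes "binding lost specifically at
HP1a-proximal sites", the synthetic analog of the biological claim, and
also produces the chr4 peak-fraction depletion.

**What the simulations do not capture:** peptide-level quantification
artifacts, correlated contaminant structure, batch effects, real genome
annotation, read-level noise, fragment-size effects and peak-shape
asymmetry. Passing the planted-recovery tests therefore demonstrates the
*statistical machinery* is correct and calibrated, not that real data meet
the generators' assumptions. One deliberate emergent feature: because
proximal peaks cluster on chr4, some "nonproximal" peaks fall within 4 kb of
an HP1a bump and are legitimately classified proximal by the definition,
which caps planted-label agreement near 0.95 — proximity is a property of
position, not of the planted amplitude class.

# Numerical choices and degenerate inputs

* All RNG flows through explicit seeds via an internal `with_seed()` that
  restores the caller's RNG state; same seed ⇒ bit-identical output.
* Trigamma inversion uses Newton iteration on the decreasing convex
  branch; non-positive excess dispersion falls back to $d_0 = \infty$ with
  the prior variance set to the mean observed variance.
* Zero global SD (constant matrix) is an error for z-scoring; a constant
  HP1a track still yields deterministic tie-broken labels.
* bedGraph binning is length-weighted and conserves total signal mass;
  trailing partial bins are normalized by the nominal bin width so the
  conservation identity holds exactly.
* 0-based half-open (BED) and 1-based inclusive (printed coordinates)
  conventions are separate explicit functions, never inferred; the worked
  example X:10,481,572–10,491,109 → 9538 bp is pinned in the tests.
* Intensity columns are located by exact prefix match (default `"iBAQ "`);
  absent flag columns default to `FALSE` with a logged message.

# Problem sizes used in validation

The test suite and the acceptance script run the generators at their
default scales: 20 seeds for consensus-complex recovery, 50 seeds for the
ChIP interaction and chr4 tests, one 5000-protein null AP-MS calibration,
500 null mixed-model fits, and 10,000 imputed cells for the imputation
moment check — sizes at which every Monte-Carlo bound used has comfortable
binomial precision while the whole suite stays desk-scale.

# Known limitations

* The pipeline consumes peak calls and normalized coverages; it does not
  align reads, call per-replicate peaks or compute iBAQ.
* The run orchestrator's ChIP stage operates on simulated inputs or
  in-memory objects; file-based ChIP runs go through the exported stage
  functions directly.
* BH within-contrast adjustment means a protein's adjusted p is not
  comparable across baits.
* Satterthwaite p-values are approximate for small replicate numbers; the
  normal-approximation fallback is exposed but anticonservative.
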