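---
title: "panelscope: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{panelscope: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelscope)
```

panelscope implements the computational core of a targeted hybrid-capture
gene panel for inherited retinal dystrophies (IRDs): an 82-gene panel data
model, a read-depth copy-number-loss caller normalized against a reference
pool, allele-frequency-based zygosity assignment, the ACMG/AMP five-tier
evidence-combination engine, panel QC metrics, and the
diagnostic-accuracy statistics used in analytical validation. A seeded
synthetic-data layer produces panel-shaped depth profiles and VCFs so that
every stage runs — and is tested — without any external data.

## The panel model

Target regions are BED intervals (0-based half-open) annotated with a gene
symbol and a free-text label (typically an exon number). For copy-number
analysis the regions are tiled left-to-right into consecutive 50-bp bins.
Two conventions are deliberate:

* **Terminal partial bins are kept and flagged**, not dropped or merged.
  Small exons would otherwise lose bases: a 90-bp exon would lose 40 of
  them. Downstream statistics weight bins by width, so a 3-bp remainder
  cannot dominate an event summary.
* **BED is read in the standard 0-based half-open dialect**; human-readable
  outputs convert to 1-based inclusive. The dialect of the original assay's
  BED is not documented, so the standard one is used.

The bundled fixture carries the real 82 gene symbols of the clinical panel
(including the deep-intronic *CEP290* intron 26/27 target, represented as an
ordinary region). Its genomic coordinates are synthetic: true capture
coordinates are not public. Exon structures that the validation analyses
depend on are pinned — *PDE6B* exons 2 and 3 span 153 and 90 bp, *PRPF31*
has 14 exons, and the X-linked genes (*RPGR*, *RP2*, *CHM*, *RS1*, *NYX*,
*CACNA1F*) sit on chrX.

## Copy-number-loss calling

For a test sample and each reference-pool member, per-bin mean depth is
divided by the sample's panel-wide **median** depth (library-size
normalization; the median is robust to the loss event itself). The sample's
normalized depth is then divided per bin by the pool's median normalized
depth, giving the fold depth $f_b$ with expectation 1 in copy-neutral bins,
0.5 under a heterozygous loss and 0 under a homozygous loss. The log2 ratio
of an event is $\log_2 \tilde f$, where $\tilde f$ is the width-weighted
median fold over the event's bins, so $-1$ corresponds to a one-copy loss.

"Significantly lower than the pool" is operationalized as a per-bin z-score
against the pool members' own fold distribution:
$z_b = (f_b - \bar f_b)/\max(s_b, s_{\min})$. A bin is a loss candidate when
$z_b < -z_{thr}$ **and** $f_b < c$; maximal runs of at least
`min_consecutive_bins` candidate bins (consecutive in panel order, never
crossing a chromosome) become events. Defaults and rationale:

| parameter | default | why |
|---|---|---|
| `z_threshold` | 3 | nominal per-bin false-candidate rate ~0.1%; three consecutive such bins under the null are vanishingly rare |
| `fold_ceiling` | 0.75 | halfway between neutral (1.0) and a het loss (0.5); excludes marginal dips that are statistically but not biologically significant |
| `min_consecutive_bins` | 3 | 3 x 50 bp = the assay's stated 150-bp calling resolution. The assay description also says "more than three consecutive bins", which would imply 4 (200 bp); the printed resolution wins, and the parameter is configurable for the other reading |
| `sd_floor` | 0.05 | a pool quieter than 5% CV per bin (including the degenerate noise-free pools used in resolution checks) should not make trivial dips significant; 5% is the low end of realistic per-bin capture variability |

The copy-number estimate is $2\tilde f$ on autosomes, rounded to the nearest
integer with exact halves rounded **down** — a loss caller should not round
a borderline loss up to copy-neutral.

**Male X handling.** Against a mixed-sex pool, a male sample's X bins sit
near fold 0.5 without any deletion. Every profile (sample and pool members
alike) is therefore recentered on sex chromosomes by its own per-chromosome
median fold, putting hemizygous and diploid X baselines both at 1. On the
recentered scale the copy-number estimate for male non-pseudoautosomal X
events uses ploidy 1, so a complete hemizygous deletion reports copy
number 0. A whole-chromosome X loss would be invisible to this recentering;
exon-scale events — the assay's scope — are unaffected.

Degenerate inputs: a pool bin with zero median depth is flagged
uninformative and excluded from calling (it can split a run); a sample with
zero median depth is an error; a zero event fold reports copy number 0 with
a `-Inf` log2-ratio sentinel.

## Zygosity from allele frequency

Variant sites must clear a total depth of 20x (inclusive; failures are
carried into reports as QC-failed sites, never dropped). The VAF is then
thresholded: below 0.20 the call is ambiguous and flagged; in [0.20, 0.80)
heterozygous; at or above 0.80 homozygous, or hemizygous on the
non-pseudoautosomal X/Y of a male sample. The 0.20/0.80 thresholds are
midpoints comfortably separating the empirically observed heterozygote
(40.6–55.3%) and homozygote (92.6–100%) ranges of validated germline panel
data — every value in those ranges is more than 0.05 from a threshold. The
product's true thresholds are not published; these are configurable. A
sample of unknown sex degrades would-be hemizygous calls to homozygous with
a `sex_unknown` flag rather than guessing sex from depth.

## ACMG/AMP evidence combination

Evidence codes are an **input**: which criteria fire for a variant depends
on curated databases and is out of scope. The combination engine implements
the published combining rules over code counts at five strengths
(stand-alone, very strong, strong, moderate, supporting), with the
pathogenic and benign sides evaluated independently; a match on both sides
forces Uncertain significance, as does no match. Strength-modified codes
(e.g. `PS1_moderate`) count in their modified slot by default — the
now-common extension of the original table — and `modified_strengths =
FALSE` restores strict default-strength counting. The test suite proves the
engine identical to an independently transcribed truth-table oracle on all
evidence subsets of size ≤ 3 and thousands of seeded larger subsets.

## QC metrics

Q20/Q30 are fractions of base calls at or above Phred 20/30; GC content
excludes N from the denominator. The GC context of a variant is the GC
percent of a 200-base window: "200 bases surrounding" is ambiguous (200
total vs 200 per side), resolved as 200 **total** with the extra base of an
even window going 3'. Coverage breadth at 20x matches the assay's variant
calling depth gate. GC-bin depth summaries use bins (low, high] with a
closed first bin and an explicit overflow bucket, so counts always
partition the input.

## Validation statistics

PPA = TP/(TP+FN) and NPA = TN/(TN+FP) with exact two-sided equal-tailed
Clopper–Pearson intervals (beta-quantile closed form; at x = n the lower
bound is $(\alpha/2)^{1/n}$, which for 43/43 concordant calls gives 91.8%
and for 4,281/4,281 bases gives 99.9%). Undefined ratios (zero denominator)
are reported as not-applicable, never coerced to a number. The replicate
design is the full factorial 2 operators x 3 lots x 3 days x 8 replicates =
144; repeatability is agreement within one operator-lot-day cell,
reproducibility over all cells. Detection rates for interference/stability
analyses use the control-detected set as denominator (the comparison the
validation defines), with condition-only variants reported separately as
gained. Display rounding is one decimal on percentages; internal values are
full precision.

## The synthetic-data generator: what it emulates, and what not

Per-base depth is negative binomial around
`mean_depth x gc_response(GC) x bin_noise x ploidy`:

* **GC response** — Gaussian-shaped multiplier peaked at 50% GC (width
  0.12, floor 0.2), a qualitative match to the unimodal GC-bias of hybrid
  capture. The per-bin GC track is itself synthetic (a bounded random walk
  in 28–68%, seeded independently of the simulation seed so all samples
  share one "genome").
* **Bin noise** — lognormal (sdlog 0.07) per-bin capture efficiency,
  giving pool per-bin fold CVs in the 5–10% range typical of capture data;
  the per-base negative binomial (size 60) adds sequencing noise. Neither
  value is published for the real assay; they are stated choices, not fits.
* **Ploidy** — 0.5x under heterozygous deletions, 0x homozygous, 0.5x
  baseline on male non-PAR X.
* **Allele depths** — Binomial(depth, p) with p = 0.5 (het) and
  p = 1 − 0.005 (hom/hemi); the 0.005 base-error keeps simulated homozygote
  VAFs inside the observed 92.6–100% band instead of identically 1. Mean
  depth defaults to 500x, matching the assay's observed on-target depths.

The generator does **not** emulate: read-level artifacts (mapping,
duplicates, strand bias), indel-realignment noise, the repetitive-sequence
dropout of regions like *RPGR* ORF15 beyond the GC response, sub-bin
breakpoint placement, or inter-bin correlated waviness. A green test on
synthetic data therefore establishes that the *algorithms* behave as
specified under the stated statistical model — not that the assay performs
identically on patient material. The five-deletion validation analog maps
the published exon ranges (*RP1L1* 3–4, *PDE6B* 2–3, *EYS* 6–8, *PRPF31*
1–14 and 2–3) onto the fixture panel because true breakpoints are not
published; spans in base pairs differ from the real 3.9–93.2 kb events,
while the exon-count structure and heterozygous copy state are preserved.

## Known limitations

* Median library normalization assumes losses affect a minority of panel
  bins; a sample deleted over half its panel would mis-normalize.
* The caller targets losses only (as validated); gains are out of scope.
* Evidence-code generation, annotation databases and HGVS nomenclature are
  out of scope; two heterozygous pathogenic variants in one gene are
  reported side by side but not phased.
* The reporting-pipeline failure mode observed in the original validation
  (an event computed as a loss but omitted from the final report) is not
  modelled; panelscope always reports what it calls, and the per-bin audit
  track exists precisely so such discrepancies can be inspected.
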