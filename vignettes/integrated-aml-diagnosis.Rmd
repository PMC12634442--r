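---
title: "Evidence integration for pediatric AML diagnosis from combined WGS and WTS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidence integration for pediatric AML diagnosis from combined WGS and WTS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amlintegrate)
```

## The problem

Pediatric acute myeloid leukemia (AML) is classified molecularly: the
defining lesion of most cases is a gene fusion, a driver mutation, or a
myelodysplasia-related (AML-MR) cytogenetic pattern. Conventional
diagnostics split this work across G-banded karyotyping, FISH, and targeted
NGS panels, each with blind spots — banded karyotyping cannot see cryptic
fusions such as *NUP98::NSD1*, and panels cannot see novel fusion partners
or genome-wide copy-number structure. An integrated whole-genome plus
whole-transcriptome (iWGS-WTS) workup sees all lesion classes from one
sample, but it needs explicit evidence-integration rules: when do two
platforms' observations corroborate a finding, when does the transcriptome
rescue a sub-threshold genomic call, and when does expression evidence
refute a DNA-predicted mechanism?

This package implements those rules as a tested pipeline: per-case evidence
containers, reportability rules, a tiered classification engine, platform
concordance statistics, and a seedable multi-platform cohort simulator so
that every stage is testable without any controlled-access patient data.

## Evidence model

A case is a `case_profile`: clinical context (disease setting, Down
syndrome status, marrow blast percentage as a tumor-content proxy) plus
evidence tables — small variants with per-platform VAFs, structural events
(breakpoint pairs with gene/exon annotation), intragenic tandem duplication
(ITD) evidence, copy-number/cnLOH segments, an optional parsed karyotype,
and an optional expression profile. Three conventions matter throughout:

* **VAFs are fractions** in $[0,1]$ internally; percentages appear only at
  I/O boundaries. This avoids mixed-unit bugs between platforms.
* **Coordinates are 1-based inclusive** for variants and segments; BEDPE
  input is converted from 0-based half-open on read, matching the VCF/SEG
  versus BEDPE standards.
* **"Insufficient coverage" is not zero.** A platform entry with value `NA`
  means the assay looked and could not measure; an absent entry means the
  assay never looked; `0` means a confident negative. The ITD and rescue
  rules depend on this distinction.

## Reportability rules

**Small variants.** A somatic P/LP variant is reportable when its WGS VAF
is at least `wgs_vaf_min` (default 0.05). A sub-threshold variant is
rescued only when it is an annotated AML driver *and* its WTS VAF strictly
exceeds `wts_rescue_vaf` (default 0.25): high mutant-allele abundance in
RNA shows the subclone is transcriptionally active. The rescue is strict
(`> 0.25`, not `>=`) and never fires from WES or panel evidence — a literal
reading of the clinical criterion. Reportability is monotone in WGS VAF by
construction.

**CNV scale classes.** Gains and losses partition into focal (`< 5` Mb)
and large-scale (`>= 5` Mb); copy-neutral LOH is reported only at
`>= 10` Mb. Focal events under 50 kb are flagged for intragenic review —
that size range holds recurrent exon-truncating deletions (e.g. *CBL*
exons 8/9) and *KMT2A* partial tandem duplications.

**ITD evidence combination.** The combiner is a total function over the
4x4 grid of evidence strengths (strong / weak / none / insufficient
coverage) on WGS and WTS. Strong WGS evidence is sufficient alone, because
WTS may simply lack junction coverage. WTS-strong with weak-or-no WGS
evidence is *borderline* — real, but requiring orthogonal (PCR fragment)
confirmation. Weak/weak is also borderline rather than dismissed: such
events have been validated by PCR, and a borderline status is what triggers
that confirmation. Only no-evidence combinations are not reportable by
sequencing.

**KMT2A-PTD.** A partial tandem duplication is called when a sub-50 kb
intragenic gain co-occurs with an in-frame chimeric junction joining exon 7
or 8 upstream of exon 2, 3, or 4 — the transcript signature of the
duplication. A qualifying gain without junction support is emitted
borderline (mirroring the ITD philosophy) rather than suppressed.

**SV mechanism.** In-frame exon-junction fusions produce fusion oncogenes,
always, regardless of window geometry. A breakpoint that falls *outside* an
oncogene's coding span but within `enhancer_window_bp` of it (default
500 kb per side) marks an enhancer-hijack candidate: the rearrangement
juxtaposes foreign regulatory sequence without producing a chimeric
protein. The window default was chosen to cover the observed clinical
breakpoint geometry (a few kb to ~300 kb from the target gene) with
headroom; it is configurable. When several surveilled oncogenes' windows
overlap a breakpoint — the HOXA cluster genes sit within a few tens of kb
of each other — the *nearest* gene is taken as the candidate target, which
is both deterministic and the biologically sensible default.

## Expression integration

Enhancer hijacking leaves no chimeric transcript; its only WTS footprint is
ectopic overexpression of the intact target. `overexpression_call()`
computes a z-score of the case's abundance on the $\log(1+x)$ scale against
a reference of cases *not* rearranged at that gene (rearranged cases are
excluded so they cannot contaminate the null). The default call threshold
is $z \ge 2$; the clinical literature shows clear separation in its plots
but states no numeric rule, so the threshold is an explicit, configurable
operationalization. A candidate is **confirmed** when its target is
overexpressed and **refuted** otherwise; refuted candidates can never be
defining lesions. A candidate with no expression data stays *unevaluated*
and remains eligible — the DNA evidence stands until the transcriptome
contradicts it.

Allele-specific expression compares a variant's DNA and RNA VAFs: a skew of
at least 0.30 in either direction calls mutant- or wildtype-allele-specific
expression. The threshold was set so that the canonical clinical example
(DNA 35%, RNA 97%, read as exclusive mutant-allele expression) is decisively
on the mutant side while balanced biallelic expression (50/50 ± noise) is
not; the rule is antisymmetric under swapping the two VAFs.

## Classification

`classify_case()` assigns exactly one category by the first matching tier:

1. Down syndrome with a reportable pathogenic *GATA1* variant (DS-AML);
2. a WHO AML-defining fusion, including a non-refuted enhancer hijack of a
   WHO-listed gene (e.g. *MECOM*);
3. a WHO AML-defining mutation — *NPM1*, *CEBPA*, or biallelic *TP53*
   (two P/LP hits counted among variants, 17p loss, and cnLOH over *TP53*);
4. a proposed class-defining lesion;
5. AML-MR evidence — an AML-MR cytogenetic pattern (5q-, -7/7q-, 11q-,
   12p-, 17p-, i(17q)), a complex karyotype (>= 3 clonal abnormalities, the
   standard convention), or an AML-MR gene mutation — **in the absence of
   any other known or potential driver**;
6. any remaining reportable in-frame fusion (rare/novel);
7. otherwise NOS, with a null defining lesion.

One deliberate design choice: the AML-MR tier yields not only to tiers 1–4
but also to a rare/novel fusion. AML-MR is defined by the *absence* of any
other known or potential genetic driver, and the clinical practice this
package models classifies a complex-karyotype case carrying a rare in-frame
fusion by the fusion, not the karyotype. Consequently the "demotion"
invariant orders AML-MR *below* rare/novel fusions: removing a case's
defining fusion may legitimately re-expose AML-MR evidence.

Within a tier, candidate fusions are considered alphabetically by 5'
partner, making multi-fusion cases (both *CBFB::MYH11* and a *CNTRL::KIT*)
resolve reproducibly. Non-defining reportable lesions are recorded as
secondary drivers. WGS losses are mapped to arm-level AML-MR patterns using
approximate centromere coordinates — band-level precision is unnecessary
because the karyotype side of the comparison is itself only band-resolved.

Rule *content* (pattern lists for each tier) ships as an editable JSON file
(`inst/extdata/classification_rules.json`), not code: adopting a new
diagnostic marker is a data update. Tier membership of proposed versus
rare/novel patterns is intentionally editable; the shipped file places the
named examples (*CBFA2T3::GLIS2*, *MYB::GATA1*, *CDK6::HOXA13*, ...) in the
proposed tier and lets rare fusions fall through to tier 6.

**Phased reporting.** WHO/proposed driver fusions, driver mutations, and
large-scale CNVs belong to the rapid tumor report (day 7); rare or novel
fusions and cooperating somatic variants to the integrated report (day 14);
germline findings to the paired tumor-normal report (day 21).

## Concordance statistics

Variant sets match on the exact normalized key (case, chromosome, position,
ref, alt); indels are reduced to minimal representation, with optional
left-alignment against local reference context, because complex indels
written in different raw forms are the dominant cause of spurious
cross-platform discordance. VAF concordance is a Pearson correlation plus
ordinary least-squares slope. Detection tables follow the clinical
convention that `total` counts truth events (`both + missed`); events seen
only by the comparator platform are listed separately, never folded into
the total. Percentages are rounded to the nearest integer, except the
headline diagnostic yield, reported to one decimal — both matching
clinical reporting practice.

## The synthetic cohort

The simulator exists so every stage is testable at cohort scale without the
controlled-access patient data. Its defaults are the study conditions, set
once:

* ~150 cases with subtype weights equal to the published cohort breakdown
  (86:26:21:5:6:4:5 over 153 cases);
* per-fusion multiplicities and cytogenetic cryptic-miss probabilities
  equal to the published per-fusion detection table (e.g. *NUP98::NSD1*
  missed 100% of the time, *RUNX1::RUNX1T1* 0%);
* *MECOM*-r generated as an enhancer-hijack rearrangement with breakpoints
  3.8–300 kb upstream of the gene and a +4-standard-deviation log-scale
  shift of *MECOM* expression, so the default $z \ge 2$ call separates
  cleanly, as the clinical plots do;
* observed VAFs drawn by binomial read sampling at depth 60 (the clinical
  assay averages ~60x genome coverage), which reproduces in spirit the
  WES/WGS discordance at the 5% boundary;
* cytogenetics sees CNVs only at >= 9 Mb (400-band resolution) and clone
  fractions >= 0.35; WGS loses large-scale CNVs when clone fraction times
  purity falls below 0.35, reproducing the reported dilution behaviour
  (reliable at 40% purity, degraded below);
* cooperating-lesion rates: FLT3-ITD in ~12% of cases (18/153 clinically),
  a cooperating driver SNV in ~50%, an incidental large-scale CNV in ~25% —
  round values consistent with the reported cohort-wide burden of
  additional P/LP findings.

What the simulator does **not** emulate: sequence-level reads, breakpoint
microhomology, clonal phylogenies, global gene-expression programs beyond
the surveilled oncogene panel, and inter-gene expression correlation.
Passing simulation tests therefore demonstrates that the *rules* behave as
specified under the assumed noise model, not that the noise model captures
every property of real sequencing data.

## Numerical and degenerate-input choices

* Threshold comparisons follow the stated inequalities exactly: focal is
  strictly `< 5` Mb, the WTS rescue strictly `> 0.25`, cnLOH large-scale at
  `>= 10` Mb. Boundary tests pin each one.
* `overexpression_call()` refuses an empty reference or a zero-variance
  reference (with guidance to enlarge it) rather than returning an
  unstable z-score.
* `vaf_concordance()` requires >= 3 pairs and non-constant coordinates.
* Validation (`validate_case_profile()`) returns violations as data rather
  than raising, so cohorts can be linted wholesale; readers, by contrast,
  reject malformed coordinates outright rather than silently coercing.
* The ISCN parser covers an explicit grammar subset (modal number, sex
  chromosomes, +N/-N, del/add/t/i, markers, idem/sl clones, metaphase
  counts); anything else becomes an `other` lesion with a warning, because
  clinical strings are heterogeneous and the downstream comparison needs
  only lesion classes. The canonical renderer `iscn_string()` inverts the
  parser on that subset.
* `observe_with_platform()` can reseed per call or draw from the current
  RNG stream; cohort-scale experiments should seed once and stream, which
  avoids structured artifacts from consecutive integer seeds.

## Problem sizes

The shipped tests run the simulator at 30–2000 cases (about 800 cases /
~580 fusion events for the miss-rate recovery check, chosen to hold at
least 500 events), and the analysis scripts use 150 cases for the worked
cohort and 600 for concordance estimation. All are desk-scale: the full
suite completes in under a minute on one CPU.

## Known limitations

* P/LP pathogenicity and driver status are input annotations; the package
  does not curate variants.
* *CEBPA* matching does not model bZIP-domain location; any reportable
  *CEBPA* P/LP variant satisfies the WHO-mutation pattern.
* Arm-level mapping of WGS losses uses approximate centromere positions on
  five chromosomes; losses on other chromosomes never match AML-MR
  patterns.
* The ISCN subset excludes derivative-chromosome and ider/dic notation;
  such lesions surface as `other` and do not enter AML-MR matching.
* Enhancer-hijack candidates without expression data stay eligible as
  defining lesions; sites wanting the conservative behaviour can refute by
  policy before classification.
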