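---
title: "Methods: evaluating Infinium-style methylation array designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evaluating Infinium-style methylation array designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, conventions and design decisions behind
`epicqc`. It states no empirical result that the test suite or the
acceptance script does not itself compute.

## Probe geometry

All internal coordinates are 0-based half-open; conversion to 1-based
happens only at I/O boundaries (manifest `mapinfo`, VCF `POS`). A probe
assays the CpG whose C sits at `target_pos` on the plus strand and occupies
a 50-base genomic footprint:

* **Type I** — two bead sequences (unmethylated/methylated allele); the
  probe 3′ terminus lies on the target C and the labelled ddNTP is
  incorporated one base upstream of the CpG on the hybridised strand, so
  the SBE base sits immediately outside the footprint. The probe body is
  the footprint minus the target CpG dinucleotide: 48 bp.
* **Type II** — one bead sequence; the target C itself is the extension
  locus (`sbe_pos == target_pos` on the plus strand) and the body is the
  footprint minus that single base: 49 bp.

Minus-strand designs are the exact mirror image
(footprint `[p − 48, p + 2)`). Footprints of both chemistries and both
strands always contain the target CpG; the test suite verifies the stored
geometry against a hybridisation oracle (exhaustive perfect-match alignment
of each probe sequence to the converted genomes).

## In-silico bisulphite genomes and the sequence convention

Bisulphite conversion reads unmethylated C as T; CpG-methylated C is
protected. Probe alignment therefore uses four genome variants, all stored
in plus coordinates:

| variant | rule |
|---|---|
| plus / unmethylated | every C → T |
| plus / CpG-methylated | C → T except the C of a CpG |
| minus / unmethylated | every G → A (C→T on the reverse complement) |
| minus / CpG-methylated | G → A except the G of a CpG |

`N` passes through and never matches. Stored probe sequences are 50 bases
over `{A, C, G, T, R}` with a fixed orientation convention: a plus-strand
design reads off the minus genomes in the forward orientation, a
minus-strand design reads off the plus genomes in the reverse-complement
orientation. Under this convention the degenerate `R` base — the read-out
of a CpG whose methylation state the probe must tolerate — always means
"A or G" (unmethylated or protected purine), matching the Type II
chemistry. Type I allele sequences assume one methylation state throughout
and contain no `R`. The reverse-complement of `R` is `Y`, which matches C
or T; the scanner applies both orientations to every genome variant.

## Cross-reactivity scan

BLAT-style search is replaced by a deterministic exact-k-mer seed +
ungapped extension scanner (C++). With non-overlapping seeds of length
`k` the scan finds every window with at most `floor(50/k) − 1` mismatches
(pigeonhole); the default `k = 12` gives four seeds and hence guaranteed
completeness at the ≥ 47/50 homology threshold used for calling. Windows
down to the reporting floor (default 40) are reported best-effort.
Degenerate seed positions are expanded exactly (at most 2^r variants,
capped at 4096). Scoring is matched-base counting only; gapped homology is
out of scope. A brute-force all-window scanner with identical scoring is
exposed as an independent oracle, and the acceptance suite checks
hit-for-hit equivalence of the two code paths on 20 simulated genomes.

Calling decisions:

* Both Type I allele sequences are scanned; the probe is flagged if either
  has an off-target hit at the threshold (conservative choice where the
  upstream protocol is ambiguous).
* A hit counts as *target* if it overlaps the annotated footprint by at
  least one base in the design orientation; everything else is off-target.
  This prevents staggered self-hits from flagging a probe.
* `tie` marks probes whose best off-target homology is attained in more
  than one genome variant. Note a planted duplication hit by a Type II
  probe is a tie by construction: its `R` bases match both methylation
  variants of the same locus equally.

## Variant classification

Variants are read with `VariantAnnotation`; the minor allele frequency of
a record folds over alternate alleles as `max_alt(min(AF, 1 − AF))`, and
the default filter keeps MAF > 0.05. Each overlapping (probe, variant)
pair is emitted once with the highest-precedence zone it touches:

`TARGET_CPG > SBE > PROBE_BODY`

* `TARGET_CPG` spans both bases of the CpG dinucleotide — a variant on
  either allele disrupts the assayed site.
* `SBE` is reachable only for Type I probes: the Type II extension locus
  is the target C, which the target zone already covers.
* INDELs are classified by any overlapping base, so a deletion spanning
  body and target lands deterministically in `TARGET_CPG`.

Variant coordinates are plus-strand (as in VCF); probe zones are kept in
plus coordinates, so no strand mapping is needed at intersection time.

## Annotation and coverage

Derived tracks follow the standard definitions: promoters are TSS ± 2 kb
(every transcript TSS, not one per gene); gene bodies are transcripts
± 2 kb minus promoters; intergenic is the complement — the three contexts
partition the genome. Island shores are the 2 kb island flanks minus any
island overlap. Out-of-bounds regions are clipped with a warning.

A region counts as covered by a probe when the probe's assayed CpG
position falls inside it (point overlap, not footprint overlap): coverage
figures count assayed loci per region, and the same point rule applies to
genomic CpGs, keeping the two coverage series comparable. Coverage is
stratified at ≥ 1 / ≥ 2 / ≥ 3 overlaps. The specific/common DHS split uses
the median occurrence across cell types; regions exactly at the median go
to the common set (deterministic, documented tie rule).

## Methylation statistics

* **Background**: the scanner software's background normalisation is
  approximated by subtracting a configurable percentile (default: median)
  of the negative-control intensities per channel and sample, flooring at
  zero.
* **Detection p**: distribution-free empirical rank of `M + U` among the
  control totals, floored at `1/(n_controls + 1)`; a probe dimmer than
  every control gets p = 1.
* **β/M**: `β = M/(M + U + 100)` (strictly < 1 for finite signal);
  `M = log2(β/(1 − β))` with β clamped to [0.01, 0.99], so the transform
  is exactly invertible on the clamp interval and extremes cannot produce
  infinities.
* **DMP calling**: probes must pass detection p < 0.01 in all samples.
  Per-probe two-group OLS on M-values; residual variances are shrunk
  towards a scaled inverse-chi-square prior fitted by method of moments on
  the log-variance scale (digamma/trigamma moment matching, Newton-solved
  trigamma inverse). The moderated t gains the prior degrees of freedom;
  with prior df = 0 it is exactly the ordinary t (tested), with prior
  df = ∞ a z-like statistic. DMP = `p < 0.001` and `|Δβ| > 0.1`; the
  absolute value matters because effects in both directions are real.
* **Cross-platform confirmation** relaxes only the p cutoff (default
  0.01) but keeps the Δβ criterion, so a "confirmed at relaxed threshold"
  probe still shows a material effect on the second platform.

The acceptance suite checks the caller's type-I error at p < 0.001 over
10^5 simulated null probes (band 0.0005–0.0015) and its power at a planted
Δβ = 0.3 (n = 3 + 3, σ_M = 0.1) against a closed-form noncentral-t oracle.

## Region methylation at distal DHSs

Eligible regions contain ≥ 3 genomic CpGs. WGBS region methylation is the
pooled ratio Σ methylated / Σ total over the region's CpGs — equal to the
coverage-weighted mean of per-CpG ratios (an algebraic identity the tests
assert). "50× coverage" is interpreted as ≥ 50 pooled observations per
region, since the pooled ratio uses all reads overlapping the region; the
mean-coverage-per-CpG interpretation is available behind
`coverage_rule = "mean_per_cpg"`. Array region methylation is the
unweighted mean of detection-passing probe βs; ≥ 1 passing probe makes the
region informative. Status cuts: low β ≤ 0.3, high β > 0.6.

Concordance is computed over regions informative on **both** platforms
(the flagged alternative — all common regions — would mix informativeness
with agreement). Platform difference is |β_WGBS − β_array| on the β scale,
so "< 20% difference" means 0.20. Large disagreements (low on one
platform, high on the other) are typed with tau = 0.2:

* `PROBE_POSITIONING` — the array agrees with the WGBS β at the probe's
  own CpG (|array − own| < tau) but not with the region mean: the probe
  faithfully assays an unrepresentative CpG.
* `TECHNICAL_ARTIFACT` — the array disagrees with its own CpG too.
* Regions whose probe CpG lacks 10× WGBS coverage stay unclassified.

Because a flagged disagreement implies |array − region| > 0.3, the typing
rule is exhaustive at tau = 0.2.

## The synthetic world

The generator emits every input with exact ground truth. Defaults state
the emulated conditions:

| parameter | default | why |
|---|---|---|
| genome | 100 kb over 2 chromosomes | desk-scale; every CpG planted deliberately |
| island CpG rate | 0.08 /bp | ~1 CpG per 12 bp, island-like density |
| background CpG rate | 0.01 /bp | genome-wide CpG depletion (~1%) |
| duplication identity | 47/50 | the calling threshold, so boundary behaviour is testable |
| samples | 3 vs 3 | the matched-fibroblast two-group design |
| Δβ at planted DMPs | 0.3 on 5% of probes | clearly above the 0.1 call threshold |
| σ_M | 0.15 | typical between-replicate M-value spread |
| WGBS coverage | Poisson(20) | ~20× mean coverage |
| negative controls | 200 | enough for a detection floor of ~0.005 |
| signal | T ~ round(logN(log 8000, 0.25)), channels binomial in β, + Gamma(4, 50) background | bright probes far above background |

Determinism: every generator derives its own RNG substream from the master
seed via a stable label hash, so adding a generator never perturbs another;
outputs are byte-identical for a fixed seed.

Construction details that make ground truth exact: the raw base draw is
scrubbed of accidental CG dinucleotides before CpGs are planted, so the
CpG list is exact; duplications copy a probe footprint plus one flanking
base on each side (conversion context preserved) and use A↔T substitutions
for mismatches — these survive conversion in all four genome variants and
can neither create nor destroy a CpG, so a 47/50 copy yields an off-target
hit of exactly 47 in the design genome. Planted variants sit on isolated
probes (non-overlapping footprints) so each (probe, category) pair is
unambiguous; a fraction is planted below the MAF filter to test exclusion.
Distal DHSs are anchored on runs of ≥ 3 background CpGs away from TSSs,
and their methylation truth is anti-correlated with the per-cell-type
presence matrix.

What the generator does **not** emulate — and hence what a green test does
not establish: dye and probe-type bias (no Type I/II intensity asymmetry),
batch effects, repeat families and segmental duplication structure beyond
the planted copies, gapped homology, non-CpG methylation biology (ch
probes are carried through I/O only), INDEL realism beyond short
deletions, and genome-scale performance. Conclusions about real arrays
require the full-scale external inputs.

## Acceptance contract

The published evaluation's headline numbers derive from a full reference
genome, vendor manifests, a population variant catalog and
regulatory-track downloads; they are not reproducible offline at desk
scale. Acceptance for this package is therefore property-based —
scanner/oracle equivalence, exact recovery of planted cross-reactive
probes, variant categories and disagreement types, β/M formula exactness,
DMP calibration and power, pooled-ratio identity, a fixed-table log OR
check and Wald-CI coverage — implemented one test per criterion in
`tests/testthat/test-acceptance.R`. `scripts/acceptance.R` runs the
pipeline end-to-end at a given seed and writes an (empty) report object;
there are no numeric targets to report.

## Known limitations

* The scanner's completeness guarantee holds only down to 47 matches with
  the default seed length; the reporting floor of 40 is best-effort.
* Detection p-values are granular for small control sets (multiples of
  `1/(n+1)`), which is visible when every probe is far brighter than
  background.
* The moderation prior assumes exchangeable residual variances; strong
  variance structure (e.g. probe-type-specific noise) would call for
  stratified fits.
* `compare_platforms` assumes shared probe identifiers between manifests;
  it does not attempt coordinate-based matching.
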