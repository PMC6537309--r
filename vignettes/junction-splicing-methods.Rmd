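---
title: "Methods: junction-read detection of regulated alternative splicing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: junction-read detection of regulated alternative splicing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rasekit)
```

# The model

`rasekit` treats alternative splicing as a competition between two
junction paths. Every event couples a *model* path (the constitutive
splice) with an *alternative* path, and the only data used to quantify
the competition are reads spanning splice junctions. For an event in one
condition, the AS ratio is

$$\hat\psi = \frac{n_\text{alt}}{n_\text{alt} + n_\text{model}},$$

the junction-read analogue of percent-spliced-in. Differential splicing
between conditions $a$ and $b$ is assessed on the pooled 2×2 table
$(n^a_\text{alt}, n^a_\text{model}; n^b_\text{alt}, n^b_\text{model})$
with a two-sided Fisher exact test, and an event is called regulated
(a RASE) when

* $p < 0.05$ (strict), and
* $|\hat\psi_b - \hat\psi_a| > 0.2$ (strict).

The implicit sampling assumption is binomial: conditional on the total
junction depth of an event, the alternative-read count is
$\mathrm{Bin}(n, \psi)$. The Fisher test is exact under that model with
both margins conditioned on; the ratio filter removes events whose
statistical significance comes from depth rather than effect size. The
ratio change is read as an **absolute difference** of per-condition AS
ratios: a 0–1-bounded quantity compared against a threshold of 0.2 only
makes sense on the difference scale, and the per-condition ratio
definition above pins both operands.

Raw p-values, not multiplicity-adjusted ones, feed the call — the
calling contract is a joint p-and-effect filter, and BH q-values are
reported in the output for readers who want them without affecting the
decision rule.

## Pooling

Counts are summed across the member samples of each condition before
testing, both for small replicated designs (two replicates per arm) and
for larger cohort splits (k vs k extreme groups). Pooling maximizes the
exactness of the 2×2 test at the cost of ignoring replicate-level
variability; the per-sample count table is retained on the result object
(`attr(x, "per_sample")`) for heterogeneity checks, and beta-binomial
overdispersion in the generator exists precisely to probe how pooling
behaves when samples genuinely disagree. Replicate-aware modelling is an
explicit non-goal.

# Event enumeration and typing

Events are enumerated from per-gene splice graphs (deduplicated exons,
transcript exon chains, and all consecutive-exon junctions). Internal
coordinates are 0-based half-open throughout; GTF input/output is
1-based inclusive and converted at the boundary. Junction identity is
`(chrom, donor_end, acceptor_start, strand)` with the donor/acceptor
*roles* assigned strand-aware (on `-` the biological donor is the right
edge).

The eight types and their operational rules:

| type | rule | model path | alternative path |
|------|------|------------|------------------|
| ES | exactly one exon skipped between two flanking junctions | inclusion junctions | skip junction |
| CE | ≥ 2 consecutive exons skipped as a block | inclusion junctions | skip junction |
| A5SS / A3SS | two junctions share one boundary, variable-side exons overlap; 5′/3′ is strand-aware | shorter intron (site proximal to the exon) | longer intron |
| MXE | two internal, non-overlapping exons never co-occurring in any transcript, between a shared donor and shared acceptor | transcript-5′-proximal exon's junction pair | the other exon's pair |
| 5pMXE / 3pMXE | the exclusive pair are alternative first / last exons sharing their single gene-body junction boundary | as MXE | as MXE |
| IR | an annotated intron entirely inside another transcript's exon | the spliced junction | the retained intron (no junctions) |

Two decisions here were genuinely open:

* **ES vs CE.** Both labels describe a skipped region; no standard
  boundary exists between them in junction-only data. We use the count
  of skipped exons — one exon is ES, a multi-exon cassette is CE. The
  rule is structural, deterministic, and directly testable; a rule based
  on which transcripts "independently include" the exon turned out to be
  either vacuous (in annotation-derived enumeration, inclusion and
  exclusion are both always annotated) or inconsistent with simple
  three-exon skipping cases.
* **A5SS/A3SS vs exon-choice events.** Junction pairs sharing one
  boundary are splice-*site* events only when the variable-side exons
  overlap (a shifted edge of one exon); when the candidate exons are
  disjoint the structure is an exon choice and is handled by the MXE
  family. This single overlap test cleanly separates the two families
  and also prevents skipping events from being double-reported as
  acceptor shifts.

Deduplication is by `(type, model set, alt set)`, and the final ordering
is canonical, so enumeration is invariant to transcript input order
(property-tested). Event ids — `gene:type:chrom:start-end` over the
alternative region — are stable across runs.

## Novel events

An observed junction absent from the annotation, with ≥ 2 supporting
reads (configurable), is typed against annotated anchors: both
boundaries on annotated exon edges but an unannotated combination is a
novel ES; one boundary shared with an annotated junction is a novel
A5SS/A3SS (strand-aware), with the nearest annotated junction as the
model (all of them when equidistant); junctions with no anchor are
reported as orphans, never silently dropped and never forced into an
event class. An event is "novel" when its alternative path uses at
least one unannotated junction.

## Intron retention evidence

Junction reads cannot support a *retained* intron, so IR uses boundary
coverage instead: reads whose contiguous aligned block crosses the
exon–intron boundary by ≥ `min_overhang` bases on each side, counted
separately at the 5′ and 3′ boundary, with the event-level IR support
taken as the **minimum** of the two. The minimum is conservative by
construction — genuine retention produces coverage across both
boundaries, while pre-mRNA contamination or an alternative edge often
inflates only one. This boundary-count scheme is this package's own
declared quantification; BED12 junction tables carry no boundary
information, so IR events under BED input are reported untestable
rather than guessed.

# Alignment-derived counts

`extract_junctions_from_sam()` counts one junction support per fragment
per CIGAR `N` gap whose flanking aligned blocks are both
≥ `min_overhang = 8` bases — the standard anchor requirement that keeps
spurious one-off splices from single mismapped ends. Uniqueness is
NH-tag based (NH > 1 excluded); when NH is absent, MAPQ < 10 is
excluded. Mates sharing a QNAME contribute a junction once per
fragment. These operational choices are documented here because
"uniquely mapped" has no single upstream definition.

# Expression-side conventions

* **FPKM** is `count / (exon-model length / 1e3) / (library / 1e6)`;
  the exon-model length is the union of the gene's exons in nt.
* **DEG filter.** The contract is thresholds, not modelling: call `up`
  when FC ≥ `fc_up` with the significance criterion met, `down`
  symmetrically. Fold changes are ratios of group means with a
  pseudocount of 0.1 FPKM added to both means (configurable) to keep
  unexpressed genes finite. The per-gene p-value engine is pluggable;
  the built-in default is a two-sided exact binomial test of pooled
  counts against the library-size expectation. It is deliberately
  dispersion-free — negative-binomial machinery is out of scope — so a
  planted fold change at the exact threshold value is recovered at the
  relaxed threshold pair (1.5, 2/3), not at its own boundary, where
  sampling noise drops half the genes below the cut.
* **Extreme groups.** Top-k and bottom-k samples by the driver gene's
  expression, ties broken lexicographically by sample id, so the split
  is reproducible even on tied data.
* **Correlation.** Pearson across samples on log2(FPKM + 1) by default;
  zero-variance samples are flagged and their entries set `NA` rather
  than erroring a whole cohort.

# Enrichment

One-sided hypergeometric over-representation:
$p = P(X \ge k)$ under $\mathrm{Hypergeom}(N, K, n)$, with BH control
across the tested sets and corrected p < 0.05 as the significance
convention. The universe is explicit and caller-supplied — for splicing
queries, all genes with detected junction evidence is the natural
choice; for expression queries, all expressed genes. Sets are restricted
to the universe before testing.

# Cross-dataset concordance

Matched by `(gene, type, alternative region)`, with sign conventions
harmonized before comparison: in a knockdown run, condition b is the
*low*-driver side, so its directions are inverted (`invert_a`/`invert_b`)
to make "up" uniformly mean a higher AS ratio with higher driver
expression. Each comparison event is `same`, `opposite`, or
`untestable`; dataset-b states distinguish `absent` (no counts or not
matched) from `flat`, an explicit class for events present in b with
$|\Delta\hat\psi| \le 0.05$ — small enough that a direction read off it
would be noise. The flat threshold is a dead zone, not a calling
threshold, which is why it is much smaller than 0.2.

# The synthetic generator

The generator emulates exactly the statistical structure the analysis
assumes, and nothing more:

* **Annotation:** one gene per planted event, two transcripts realizing
  the event, 100-nt exons and introns on alternating strands,
  non-overlapping 10-kb blocks of one synthetic chromosome.
* **Splicing truth:** null events share one ψ per event drawn uniform on
  (0.2, 0.8) — a realistic mid-range PSI spread; regulated events differ
  by exactly the declared effect size (default 0.3), base drawn uniform
  on (0.15, 0.55) so both values stay inside (0, 1), with the higher
  side assigned to either condition by a seeded coin flip.
* **Counts:** alternative reads are Binomial(depth, ψ) per sample —
  Beta-Binomial with intra-class correlation `dispersion` when
  heterogeneity is wanted — spread deterministically over the event's
  junction keys; model reads take the remainder. Library size is set so
  the junction-read fraction equals a planted value (default 0.2, the
  order observed in real spliced libraries).
* **Expression:** log-normal multiplicative noise around per-condition
  means with planted fold changes in both directions.
* **Reads:** optional SAM emission writes one uniquely mapped spliced
  read per junction-count unit (50-nt anchors) and boundary-crossing
  exon-body reads for IR, so the extraction path can be validated
  bit-exactly against the count-level truth.

What passing these tests does **not** show about real data: the
generator has no sequencing errors, no mapping ambiguity, no coverage
non-uniformity across a gene, no correlated events within a gene, and
no library-preparation strand errors. Calibration and power results on
synthetic data are statements about the statistical machinery under its
own assumptions, not about aligner behaviour.

# Numerical choices

* Fisher two-sided p sums hypergeometric probabilities ≤ the observed
  table's probability within a relative tie tolerance of `1e-7`
  (the convention shared by the major exact-test implementations);
  tables with an empty margin return p = 1.
* Events with zero total reads in a condition are flagged untestable and
  kept in the output; their ratios and p-values are `NA`, never 0.
* Threshold comparisons are strict (`>` 0.2, `<` 0.05) as printed in the
  calling contract.
* All tie-breaks (extreme-group membership, novel-event anchors, event
  ordering) are deterministic and documented at the function level.
* Validation problem sizes: the Fisher oracle sweep covers all 635,375
  2×2 tables with grand total ≤ 60; calibration uses 10,000 null events
  and power 1,000 planted events at depth 100 per condition — sizes at
  which the binomial standard error of the measured rates is well below
  the acceptance bands, while the whole suite stays fast enough to run
  on every change.

# Known limitations

* Pooling discards replicate-level variance; strongly overdispersed
  cohorts will show anticonservative p-values (use the per-sample table
  and the dispersion knob to quantify this).
* IR quantification is a boundary-coverage substitute, not a junction
  measurement, and is unavailable from BED12 input.
* Novel-event discovery requires an annotated anchor; fully unannotated
  splicing (orphan junctions) is reported but not typed.
* The DEG engine is threshold logic over a simple exact test; it is not
  a replacement for dispersion-aware differential expression.
* Multi-gene junction ambiguity is flagged (junctions assigned to every
  containing gene) but not resolved.
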