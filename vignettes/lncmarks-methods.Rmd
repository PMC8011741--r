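---
title: "Methods: classifying plant lncRNAs and quantifying their epigenomic context"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying plant lncRNAs and quantifying their epigenomic context}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncmarks)
library(dplyr)
```

## The problem

Plant genomes transcribe thousands of long noncoding RNAs (lncRNAs,
> 200 nt, no protein-coding evidence). Their positional classes —
intergenic (lincRNA), antisense (NAT), intronic (incRNA) — sit in very
different chromatin neighbourhoods, and in Brassicaceae a large share of
them overlaps transposable-element-derived inverted repeat regions
(IRRs), the substrate of RNA-directed DNA methylation (RdDM): 24-nt
siRNAs guide de novo cytosine methylation in all three sequence contexts
(CG, CHG, CHH with H ∈ {A, C, T}). This package packages the
genome-wide bookkeeping that such a study needs — classification,
overlap stratification, methylation quantification, metagene profiles,
stratified expression tests, cross-species homology coverage and GO
enrichment — as deterministic, testable functions over plain data
frames.

Throughout, intervals use one internal convention: 0-based half-open
`[start, end)`, as in BED. GFF3 and cytosine reports (1-based) are
converted at the I/O boundary, which removes the usual off-by-one drift.
Strand `"."` matches either strand in stranded queries, because repeat
annotations are typically unstranded.

## Classification rules

Transcripts are labelled by precedence NAT > incRNA > intergenic rules,
so every transcript receives exactly one class:

1. **NAT** — at least `min_nat_overlap` (default 1) bases of overlap
   between a transcript exon and a gene exon on the opposite strand. We
   require exon-vs-exon overlap on both sides rather than overlap with
   the gene span; the consequence, deliberate, is that an antisense
   transcript living wholly inside an intron is called incRNA, not NAT —
   "antisense" is read as antisense to mature exonic sequence.
2. **incRNA** — transcript span fully contained in a single intron of a
   gene, either strand by default (`incrna_same_strand = TRUE`
   restricts to the host strand). Partial intron overlap does not count;
   full containment is the only reading under which intronic origin is
   unambiguous, and the flag exists because the permissiveness of this
   rule is a genuine judgement call.
3. **Intergenic** — no span-level overlap with any gene. With a protein
   hit at e-value ≤ `evalue_cutoff` (default 1e-10, the standard blastx
   screening threshold) the transcript is a **putative mRNA** — an
   un-annotated gene, whatever its length; with no hit and spliced
   length > 200 nt it is a **lincRNA**.
4. Everything else — sense-overlapping non-intronic transcripts, short
   intergenic fragments — is **unclassified** rather than forced into a
   class.

Distance to the nearest gene is the end-to-start gap (0 when
overlapping), binned at 0/2/5/10/20 kb by default. Only the 2 kb and
20 kb breakpoints are anchored in common usage; the interior breakpoints
are a labelled convention.

## Methylation

The per-site level is mC / (mC + umC). Sites with zero coverage are
*undefined*, never 0 — counting them as zero would bias regional levels
downward wherever coverage drops. Regional levels are read-weighted,
Σ mC / Σ (mC + umC) over covered sites of one context in the region,
with both strands pooled. The weighted form is additive in numerator
and denominator (splitting a region and recombining counts is exact),
robust at low coverage, and reduces to the mean of site levels under
uniform depth. The minimum per-site coverage filter defaults to 1 read,
i.e. no filter beyond non-zero coverage. When biological replicates are
available they are pooled at the count level before aggregation.

## 24-nt siRNAs

Reads are filtered to the 24-nt uniquely mapped class. A transcript is
siRNA-positive under the default **containment** criterion: at least one
such read interval lies fully within the transcript's genomic span.
Unique mapping plus full containment is how "perfect sequence identity
of the siRNA to the locus" is operationalised from positioned reads
without re-aligning sequences; a cluster-overlap mode (≥ 1 bp overlap
with a called cluster) is available as an alternative.

siRNA clusters themselves have no field-standard definition, so the
package states its convention explicitly: merge 24-nt read intervals
across gaps ≤ 100 bp, keep merged intervals with ≥ 3 member reads; both
knobs are arguments. RPM normalisation divides by the total mapped
small-RNA reads of all lengths (standard practice), not the 24-nt count,
also configurable.

## IRR and H3K27me3 status, stratification

A transcript is IRR- or H3K27me3-positive on ≥ 1 bp of span overlap with
any annotated interval; thresholds in bases or as fraction-of-span, and
exon-only scoring, are flags. H3K27me3 domains are consumed as
precomputed BED intervals; when only a coverage bedGraph exists,
`domains_from_bedgraph()` offers a labelled convenience (threshold ≥ c,
merge, drop short) — it is a threshold deriver, not a peak caller with a
background model.

The stratification table reports counts and percentages per class ×
mark × status. Percentages are rounded half away from zero to one
decimal (`percent1()`), matching the "k of n (xx.x%)" reporting style;
an integer-arithmetic oracle in the tests pins the rounding rule. The
joint IRR × siRNA table exposes the conditional fraction of
siRNA-overlapping transcripts that also harbour IRRs.

## Metagene profiles

The body of each feature is divided into `body_bins` (default 40)
near-equal windows by floor arithmetic, each flank into `flank_bins`
(default 20) fixed-width windows covering `flank_bp` (default 2000) bp.
The flank width is an explicit assumption recorded in the profile
attributes. Minus-strand features are reversed so bin 1 is always 5'.
A record contributes to every bin it overlaps, weighted by overlap
length, and coverage-type bin values are per-base means — so summing
bin value × bin width over the body returns the total signal exactly,
a property the tests assert. Methylation bins are read-weighted levels
and are undefined (NA) where no covered site falls; flank bins off the
chromosome start are truncated and flagged. Aggregation over a feature
set is the per-bin mean across features, ignoring undefined bins. Flank
overlap with neighbouring features is not masked.

## Expression comparisons

Replicates are averaged per transcript before testing: the transcript,
not the replicate, is the sampling unit of a class-level comparison.
Strata are compared by a two-sided pooled-variance (Student) t-test on
raw FPKM by default, log2(FPKM + 1) by flag; stars at 0.05/0.01/0.001.
Strata with < 2 members yield NA rather than an error, and degenerate
zero-variance strata are resolved analytically (equal means → t = 0,
p = 1). Transcript lengths across classes use one-way ANOVA; the
compact letter display comes from Bonferroni-corrected pairwise pooled
t-tests, with letters assigned from maximal cliques of the
"not significantly different" relation — exhaustive clique enumeration
is exact and cheap at the handful of classes involved.

## Homology coverage

BLAST tabular HSPs are filtered at e ≤ 1e-10, grouped by (query,
subject sequence, subject strand), and chained by dynamic programming
over HSPs sorted by query start: a successor must advance both query
coordinates and subject coordinates in the strand direction, with
inter-HSP subject gaps ≤ 10 kb (overlaps always allowed). The chain
maximises total bitscore; the best group across subjects is the
representative homologous region. Coverage divides the *merged* chained
query footprint by the query length, so overlapping HSPs are counted
once — the alternative (summing HSP lengths) can exceed 1 and was
rejected. The DP is verified against exhaustive subset enumeration on
instances of up to 10 HSPs. The intent is a transparent, documented
stand-in for representative-region pickers in the genBlastA mould: the
coverage statistic, not bit-identical ranking, is the quantity of
interest.

RT-PCR band matrices (cells `+++`/`+`/`-`) are summarised per line
group by the number of lines with a *strong* band; "expressed" counts
strong bands only. On the twelve-lncRNA worked matrix this is the only
reading under which the published summary counts (7 of 12 across the six
B. rapa lines; 6, 1, 1 and 4 of 12 across the three B. oleracea
cultivars) match the printed matrix, and the acceptance suite asserts
exactly that.

## GO enrichment

One upper-tail hypergeometric test per term with ≥ 1 study hit:
P(X ≥ k) for X ~ Hypergeom(N, K, n), evaluated in log space through the
distribution function. The background is an explicit input — all
supplied annotated genes — rather than a hidden genome-wide default,
because the reference background of web tools is not reproducible
offline. Terms are tested as given, with no GO-graph propagation to
ancestors. Results carry both BH-FDR q-values (significance flag at 1%
FDR) and raw-p stars at 0.05/0.01/0.001; both conventions circulate in
figure legends, so both are emitted rather than silently reconciling
them.

## The synthetic-data generator

`sim_config()` defaults define the study conditions: ten chromosomes of
800 kb; 350 genes; 500 lincRNAs, 230 NATs, 90 incRNAs and 180 putative
mRNAs (about 1 000 transcripts); per-class IRR overlap fractions
0.650/0.550/0.717/0.641, siRNA fractions 0.187/0.140/0.174/0.150 and
H3K27me3 fractions 0.108/0.157/0.163/0.108; single-exon fractions
0.657/0.724/0.710; mean spliced lengths 725/1271/779/1305 nt
(log-normal, sdlog 0.45); plant-typical base methylation CG 0.40 /
CHG 0.20 / CHH 0.08 with a +0.20 boost inside IRRs and siRNA source
windows at 20× Poisson depth; log-normal FPKM (μ = 1, σ = 1) with a
2-fold effect for siRNA-positive transcripts; and per-genome homolog
presence 0.80/0.55/0.55/0.30 with mean coverage 0.75/0.60/0.60/0.45,
giving a planted conservation ordering.

Placement makes every truth label unambiguous: units (a gene, possibly
with an attached NAT or a hosted incRNA, or an intergenic transcript)
are laid left to right with random gaps, so intergenic transcripts never
touch genes; NATs start inside the first exon of their host gene on the
opposite strand; incRNAs sit inside a deliberately enlarged intron.
Marks are planted per transcript with exact per-class counts: IRRs and
H3K27me3 domains are drawn inside the spans of selected transcripts and
otherwise only in guaranteed-free intergenic zones, so recomputing
status from the emitted files reproduces the manifest exactly. siRNA
positives are drawn preferentially (85%) from the IRR-positive subset,
planting the nested siRNA-in-IRR structure that makes the conditional
fraction exceed the marginal one. Source windows sit fully inside their
transcripts; background includes off-length (21/22-nt) reads, 24-nt
multi-mappers, and free-zone 24-nt unique reads, so the length,
uniqueness and containment filters all do real work. Methylated counts
are binomial per site; elevated regions carry beta-distributed means
(concentration 100) around base + boost, recorded in the manifest so
estimates are compared against the realized truth; with boost = 0 the
jitter is switched off and regions sit exactly at background, which is
what makes the "no elevation" check well-calibrated. Each file type has
its own RNG stream derived from the master seed, so adding one file
type never perturbs the others and a config is byte-reproducible.

What the generator does **not** emulate: real sequence composition,
mapping ambiguity, bisulfite conversion error, overlapping or nested
genes, chromosome-scale variation in feature density, replicate-level
biological variance beyond a small log-normal jitter. Passing the
recovery suite therefore demonstrates correctness of the bookkeeping —
coordinate conventions, precedence, containment, weighting, statistics —
not robustness to dirty real-world data.

## Problem sizes and numerical choices

The unit suite runs on a two-chromosome dataset (~105 transcripts); the
acceptance suite generates the full default configuration (~1 000
transcripts, ten chromosomes) once and drives the complete pipeline over
it, which takes on the order of a minute. Oracle equivalences use exact
enumeration at small n: bitmap union for interval merging, transitive
closure for clusters, all-subset chaining for ≤ 10 HSPs,
binomial-coefficient sums for the hypergeometric tail at N ≤ 60,
hand-computed BH examples. Statistical recovery checks use 3-standard-
error bands; the null-calibration simulations draw from a normal
distribution, where the pooled t-test is exact, so the nominal-size
check is a property of the implementation rather than of a skewed data
model.

Degenerate inputs resolve explicitly rather than by error where a value
is well-defined: zero-coverage sites are undefined, empty strata are NA,
all-constant ANOVA gives F = 0, zero-width profile bins are undefined,
abutting half-open intervals do not overlap, and ties in percentage
rounding go away from zero.

## Known limitations

- H3K27me3 domains are taken as given (or thresholded from coverage);
  there is no peak calling against an input control.
- The NAT overlap rule is exon-based with a 1-bp default; studies using
  span-based or fraction thresholds will count differently at the
  margins.
- Coverage of homologous regions chains HSPs per subject sequence;
  homologs split across subject scaffolds are represented by the best
  single scaffold.
- Enrichment reproduces the hypergeometric/BH machinery but not any
  specific web tool's background or term propagation, so term lists are
  comparable in method, not in exact membership.
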