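---
title: "Methods: barcoded synthetic tandem-repeat promoter screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: barcoded synthetic tandem-repeat promoter screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The screen

BC-STAR-PROM is a massively parallel reporter assay for finding
transcription factors (TFs) that respond to a signal — a drug, a serum
factor, a stress — without assuming anything about which TFs those might
be. It exploits the fact that most TF binding motifs are short (6–12 bp)
and therefore occur spontaneously in random DNA: `motif_occupancy_estimate()`
gives the closed-form expectation. A library of reporter plasmids is built
in which each promoter is a tandem array of six 84-bp repeat units, each
carrying 68 random base pairs, upstream of a minimal promoter. Any binding
site present by chance in those 408 random bp is amplified sixfold by the
repeat structure. Each plasmid additionally carries a random 20-nt barcode
in the reporter 3' UTR, so the expression of every promoter in a pooled
transfection can be read out by sequencing barcode counts over a drug
time course.

`bcstarprom` implements the complete dry-lab side of such a screen as
composable, pipe-friendly functions over tibbles, plus a synthetic-data
generator that produces libraries, reads and expression programs with full
ground truth, so every stage can be validated end to end.

## Library design

**Barcodes.** The degenerate synthesis pattern `HHDDDDHHBBVVDDDDHDBV`
allows exactly three nucleotides at each of 20 positions (IUPAC codes H, D,
V, B), which prevents long homopolymers and gives a space of
$3^{20} \approx 3.5\times10^9$ barcodes — vastly more than any plasmid
library, so each plasmid's barcode is effectively unique
(`degenerate_space_size()`, `sample_barcodes()`).

**Sample indexes.** Multiplexed samples are distinguished by 6-nt indexes
designed to a minimum pairwise Hamming distance of 3
(`design_indexes()`, greedy randomized search with a Singleton-bound
feasibility pre-check). Distance 3 means a single sequencing error still
maps a read uniquely to its sample, and at least three errors are needed
to convert one index into another; demultiplexing therefore defaults to
one tolerated mismatch.

**Constructs.** `assemble_construct()` places a promoter insert and a
barcode into a fixed vector context whose landmark order is
NheI < promoter < HindIII < reporter stub < barcode < XbaI, so a single
NheI + XbaI digest releases one fragment carrying both the promoter and
its barcode. The 8-nt repeat flanks, the minimal-promoter stub, the
reporter stub (carrying single ApaI, FspI and HincII sites) and the
constant 20-nt spacer 5' of the barcode are not dictated by the assay;
they are package constants (`default_template()`), with the reporter stub
sized so the NheI–XbaI span is 2275 bp, the scale of the real association
fragment. All internal coordinates are 0-based half-open; the classical
1-based read positions (index 1–6, spacer 7–26, barcode 27–46) are
converted at the API boundary.

## Barcode–promoter association

The linking layer is established exactly as in the wet protocol, in
silico: `insilico_digest()` cuts at every recognition-site occurrence
(cut positions modelled at the site's first base; overhang chemistry is
abstracted), `circularize_fragment()` joins the fragment ends — bringing
the 3'-terminal barcode next to the 5'-terminal promoter — and
`linearize_circle()` reopens each circle with three enzymes
independently. Three enzymes are used because any single cut could, by
chance, fall inside the barcode–promoter junction of a particular
plasmid; with three independent aliquots at least one template almost
always keeps the junction intact.

Junction reads (150 nt across the ligation junction) are parsed by
anchored extraction: constant anchors (the barcode spacer, the NheI site
plus left repeat flank) tolerate one substitution, but barcodes are
matched **exactly** — the random $3^{20}$ space guarantees no minimum
distance between barcodes, so error correction could silently merge
distinct plasmids. Long reads spanning the whole NheI–XbaI fragment are
parsed by the same anchored splitting with a reverse-complement retry.

`build_association_table()` retains pairs with read support strictly
greater than 50 and *drops and reports* any barcode for which two
promoters both pass the threshold: given the barcode-space argument such
conflicts indicate chimeric molecules, not genuine reuse, so majority
voting would be unsafe. Promoters legitimately linked to several barcodes
are kept and serve as internal replicates (`validate_association()`).

## From reads to a count table

`count_screen_reads()` follows the screen's counting recipe: clip the
reporter 3' UTR at the first XbaI anchor at or after position 47 (the
position guard protects barcodes that contain an XbaI-like subsequence),
demultiplex on the 5' index with at most one mismatch, slice the barcode
window (positions 27–46), count exact barcode sequences per sample, and
finally keep only barcodes observed in **every** sample whose promoter
association is known. That presence filter is the screen's guard against
barcodes born from sequencing errors; it also guarantees strictly
positive counts downstream. The pipeline is deterministic and independent
of read order, and reads failing any step are tallied in a QC funnel
rather than silently dropped. Base qualities are ignored for matching
(the counting is sequence-exact), matching the assay's FASTA-collapse
step.

## Quantification

**Normalization.** `median_normalize()` divides each count by its
sample's (column's) median and rescales by the median of all entries of
the count table, so every column ends with the same median on a
count-like scale. We read "the median of all of the reads of the
experiment" as the median over all table entries, not of column sums;
the interpretation is isolated in this one function.

**Fold changes.** `fold_changes()` divides each barcode's value by the
mean of its control samples (time-0 plus all vehicle time points, by
default). The pseudocount defaults to **0**: the presence-in-all-samples
filter already guarantees positive counts, and a zero pseudocount lets
the global rescaling constant cancel algebraically, so fold changes are
computed from the depth ratios (count / column median) and are *exactly* —
bitwise — invariant to multiplying any sample's counts by a constant.
A positive pseudocount (applied on the normalized scale) is available for
tables that bypass the presence filter, at the cost of that exact
invariance.

**Ranking.** The drug-response score of a barcode is the mean fold change
of the drug samples over the 1, 2, 4 and 8 h time series divided by the
mean fold change of the vehicle samples at the same times
(`drug_response_score()`); barcodes are ranked per drug by descending
score, ties broken lexicographically by barcode so the ranking is a
deterministic permutation.

**Response groups.** `merge_replicates_and_cluster()` merges each
replicate's top-20 promoter responses, averages log2 fold-change profiles
per promoter, and clusters with complete linkage on Euclidean distance
(`stats::hclust`), cutting the tree into 4 groups by default. The tree-cut
criterion is not dictated by the assay; a fixed `k_groups` with
configurable value is the simplest reproducible choice.

**QC.** `cv_filter()` implements the transfection-uniformity gate
(coefficient of variation below 12% by default).

## Motif analysis

`pwm_scan()` scores every window of a position-frequency matrix
(log-odds under a uniform background, total pseudocount 0.8 per column
split over the bases) on both strands, reporting hits whose *relative*
score $(s - s_{\min})/(s_{\max} - s_{\min})$ reaches 0.85 — a common
community threshold; the assay itself states none. Scanning targets the
concatenated 68-nt random cores with the constant flanks masked: flanks
are shared library-wide and would only produce uninformative ubiquitous
hits. Reverse-strand hits are reported in forward coordinates, and
scanning is strand-symmetric by construction (property-tested).

`shared_motifs()` returns the motifs hitting every member of a response
group, the group-level TF hypothesis generator. `motif_set_enrichment()`
asks the complementary ranking-wide question with a weighted
Kolmogorov–Smirnov running-sum statistic over the score-ordered promoter
list (member weights $|\log_2 \text{score}|^p$, $p = 1$ by default),
promoter-label permutation p-values $(k+1)/(N_{perm}+1)$ on $|ES|$, and
Benjamini–Hochberg FDR across the motif panel. The original assay's
enrichment adaptation is described only in outline, so this is a
documented reconstruction of classic GSEA with every choice (exponent,
permutation count, two-sidedness) configurable; it is validated by
calibration (uniform p-values on random sets) and planted-motif recovery
rather than against published tables. Because ranking-based enrichment
mixes time points, per-time-point rankings can be passed instead to focus
on, say, strictly immediate-early responses.

No motif database ships with the package: `make_motif_panel()` builds a
synthetic 20-motif panel from field-standard consensus strings (CArG box
CC(A/T)6GG, AP-1, CRE, NF-kB, E-box, GATA, ...); `parse_jaspar()` /
`write_jaspar()` read and write the standard JASPAR PFM text format for
users with real matrices.

## The synthetic-data generator

`sim_config()` fixes the study conditions: ~3000 plasmids, six repeats,
log10-normal baseline abundance (mean 2, sd 0.8 in log10 read units,
emulating the wide basal-expression range of random promoters), a drug
plus vehicle design sampled at 0, 1, 2, 4 and 8 h at 10^6 reads per
sample, substitution-only errors at 0.001 per base, and 2% of constructs
reusing an existing promoter under a fresh barcode (multi-barcode
promoters). Planted responder groups default to an immediate-early
archetype (CArG consensus, peak at 1 h) and a delayed archetype (NF-kB
consensus, peak at 3 h), 0.5% of plasmids each with amplitude 9 (peak
fold change 10).

Induction kinetics use the gamma-like pulse
$1 + A\,(t/\tau)\,e^{1-t/\tau}$, which is exactly 1 at $t=0$ and peaks at
$1+A$ exactly at $t=\tau$; the real kinetics are known only graphically,
so the functional form is the package's own idealisation
(immediate-early $\tau \approx$ 1–2 h, delayed $\tau \approx$ 3–4 h).
Counts are multinomial given the sample depth — the minimal noise model
for pooled amplicon sequencing; no quantitative noise model is published
for this assay, so nothing richer is assumed.

Two deliberate simplifications matter for interpreting green tests:

* **Landmark-free random cores.** Repeat cores (and barcode cassettes)
  are rejection-sampled so no restriction landmark can occur inside or
  across their boundaries. Real random DNA contains such sites, which is
  one reason the real assay associated most but not all promoters.
  The exclusion makes "association recovery equals ground truth exactly"
  a well-defined property; it slightly biases core composition
  (six 6-mers of $4^{68}$-space excluded).
* **No PCR/duplicate structure, no indels, no quality-value realism.**
  Errors are i.i.d. substitutions; exonuclease removal of non-circularized
  molecules is modelled by never emitting them.

Passing tests therefore demonstrate correctness of the pipeline's
algorithms under the assay's statistical design — not robustness to
artefacts the generator does not emulate (chimeras, PCR jackpots,
indel-rich reads).

## Numerical and degenerate-input choices

* Zero-median count columns, empty promoter groups, motif sets equal to
  the whole universe, circularizing a circle, and sub-threshold designs
  all raise typed errors naming the offending object.
* Permutation p-values are never 0 by the $(k+1)/(N+1)$ convention;
  enrichment scores lie in $[-1, 1]$ by construction.
* Clustering is deterministic given the input ordering; the merged
  promoter set is sorted before clustering.
* The index-design search refuses requests beyond the Singleton bound
  immediately instead of exhausting attempts.

## Problem sizes used in the validation suite

The shipped tests exercise the full study scale where the property
demands it and smaller libraries elsewhere: association recovery on a
500-plasmid library at 60x junction coverage; exact count identity on
3000 barcodes x 10 samples x 10^5 reads/sample; ranking recovery with 20
planted inductions (amplitudes 4-30) among 3000 barcodes at 10^6
reads/sample; enrichment calibration with 200 random sets at 999
permutations and planted-CArG recovery against the 20-motif panel on a
400-plasmid screen. All stochastic harnesses run at fixed seed 1.

## Known limitations

* Biological conclusions (which TF responds to which drug) require real
  motif databases and real reads; the shipped panel is synthetic.
* The enrichment reconstruction cannot be compared numerically to the
  original assay's supplementary tables; calibration is property-based.
* Barcode-level statistical testing is intentionally absent: the screen
  ranks responses and validates hits individually, so the package ranks
  too and reserves null-calibrated inference for the motif layer.
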