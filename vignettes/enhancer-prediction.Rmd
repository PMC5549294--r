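---
title: "Enhancer discovery from chromatin-mark coverage: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enhancer discovery from chromatin-mark coverage: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enhancerscan)
```

## The problem and the model

Enhancers are distal regulatory elements marked by open chromatin (DNase I
hypersensitivity) and a characteristic histone-modification signature: high
H3K4me1 with low H3K4me3, plus H3K27ac when the enhancer is active.
`enhancerscan` discovers them genome-wide from four coverage tracks
(DNase-seq, H3K4me1, H3K27ac, H3K4me3 — RPM-normalized bedGraphs) with a
supervised approach:

1. **Training.** A random forest of binary classification trees is fit on
   two balanced classes: a set of known enhancer elements (positives) and
   an equal number of promoter regions, TSS ± 1 kb, sampled uniformly from
   the gene annotation (negatives). Each element's feature vector is the
   mean coverage of each marker over the element. A third of each class is
   held out; the model is scored with a confusion matrix on that held-out
   set.
2. **Scanning.** The genome is tiled into 200-bp windows, each window's
   mean marker coverages are scored by the forest, and windows with
   P(enhancer) ≥ 0.5 are classed enhancer.
3. **Merging.** Enhancer windows within 1 bp of each other are merged into
   continuous elements; the call's probability is the maximum over its
   member windows, preserving the strongest window evidence through the
   merge.
4. **Validation.** A call survives only if a DNase hypersensitive site
   peak with q < 0.01 overlaps it by at least 1 bp — a deliberately strict
   false-positive guard. Validation is monotone: more peaks, or a looser
   q cutoff, can only grow the validated set.
5. **States.** Validated enhancers are split into *active* (mean H3K27ac
   at or above threshold) and *primed* (below). The default threshold is
   the genome-wide mean of the H3K27ac track, i.e. "above background";
   there is no universally accepted absolute RPM cutoff, and the
   genome-wide mean adapts to library depth. It is always overridable and
   is recorded in every output header.
6. **eRNA.** When GRO-seq strand tracks are supplied, each call is
   annotated with mean plus-strand (sense) and minus-strand (antisense)
   coverage — active enhancers show strong bidirectional transcription.

### Assumptions

* Input bedGraphs are already RPM-normalized; an optional flag rescales
  raw values. Tracks are step functions: uncovered bases are implicitly 0.
* The two training classes are enhancers and promoters only. Background
  windows (low everything) are therefore not represented at training time,
  and their scores are model-dependent; the DHS validation step is what
  keeps such windows out of the final call set.
* Nearest-gene distances are edge-to-edge and unstranded. Whether
  peak-to-gene distance should be measured from the TSS instead is a
  genuine open choice; edge distance was chosen as the less assumption-laden
  default, and the TSS is available in the annotation for callers who want
  the other convention.

## Coordinates

All I/O follows the conventions of the formats themselves: BED, bedGraph
and narrowPeak are 0-based half-open; GTF is 1-based inclusive. Internally
every interval is a `GRanges` (1-based closed, the Bioconductor idiom);
conversion happens only at the file boundary. TSS of a `+` gene is its
first base; of a `-` gene, its last.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `window_size` | 200 | bp | scan resolution of the classifier |
| `merge_gap` | 1 | bp | adjacent enhancer windows always merge |
| `dhs_q_max` | 0.01 | FDR | validation peak cutoff |
| `min_dhs_overlap` | 1 | bp | "at least a single bp" of DHS support |
| `promoter_flank` | 1000 | bp | promoter negatives are TSS ± 1 kb |
| `test_fraction` | 1/3 | — | held-out share per class |
| `metagene_flank` | 3000 | bp | heatmap/metagene half-window |
| `promoter_upstream/downstream` | 250 / 1000 | bp | promoter-proximal co-occupancy window |
| `h3k27ac_active_threshold` | genome mean | RPM | active/primed split, see above |
| `prob_threshold` | 0.5 | — | window-classing probability |
| `flank` | 0 | bp | feature extraction flank |
| `n_trees` | 500 | — | classical random-forest default |

The feature `flank` deserves a note: features are "mean coverage within a
set distance along the element", and that distance is not fixed by any
convention. The default of 0 (element-body mean) is the least arbitrary
choice; the flank is stored in the model and enforced at prediction time so
training and scanning can never disagree.

Random-forest settings follow the classical defaults: 500 trees,
`floor(sqrt(p))` features per split (minimum 1), no depth cap. Constant
features warn rather than fail, since a flat track is valid (if useless)
input.

## Signal math

* **Mean coverage** over a region is Σ(value × covered bp)/width, with
  uncovered bases contributing 0. It is linear in track values and
  additive over track superposition, which the tests exploit.
* **RPGC (1× normalization).** Sequencing depth is
  mapped reads × fragment length / effective genome size; the scale factor
  `egs / (n_mapped × fragment_length)` makes genome-wide mean extended-read
  coverage exactly 1.
* **Effective genome size** is the count of non-N bases in the FASTA
  (falling back to the sum of chromosome lengths without one). This is the
  standard simple approximation to mappability-based EGS estimation, and
  the value is always overridable where it is consumed.
* **Fragment length** is estimated by strand cross-correlation: plus-strand
  5′-start and minus-strand 5′-end densities are binned at 10 bp, the minus
  density is shifted left by each candidate shift in 0…`max_shift`, and the
  Pearson correlation profile is recorded; the estimate is the argmax.
  Shifts within read length ± 10 bp are excluded from the argmax — the
  "phantom peak" at the read length is a mappability artifact that would
  otherwise shadow the true fragment-length maximum. Binning at 10 bp
  bounds the estimator's resolution at ±10 bp, which matches the precision
  this quantity is used at (MACS2 `--extsize` etc.). The 10-bp bin and
  ±10 bp guard half-width are declared defaults of this implementation,
  not field constants.

## Expression integration

FPKM_g = count_g × 10⁹/(length_g × library total), with exonic length from
the union of a gene's exons; TPM_g = (count_g/length_g) × 10⁶ / Σ_j
(count_j/length_j), so TPM always sums to one million when any count is
positive. The library total defaults to the sum of the supplied counts so
the function is self-contained, but can be given independently (e.g. the
aligner's mapped-read count). `gene_expression_near_peaks` joins each peak
to its nearest gene; ties (two genes at the same gap) are broken by lower
gene start, then lexicographic id, so outputs are reproducible. Genes with
several annotated TSSs are reduced to one record per gene id (first in
genome order) with a log message.

The promoter-proximal co-occupancy window (−250/+1000 around the TSS) is
strand-aware: "upstream" means 5′ of the TSS on the gene's own
orientation, so for a minus-strand gene it extends to larger coordinates.
A gene counts as co-occupied only if *every* supplied peak set overlaps
its window by ≥ 1 bp, which makes the count antitone in the number of
sets.

## The synthetic benchmark

Because genuine training data (ENCODE enhancers, cell-line coverage
tracks) cannot ship with a package, every stage is exercised on a
deterministic simulator:

* **Genome:** two 1-Mb chromosomes (desk-scale; the real pipeline's only
  dependence on genome size is linear scan time).
* **Truth:** 50 enhancers (500 bp) and 150 genes (1–3 kb), placed
  uniformly with ≥ 2 kb spacing so planted signals never blend;
  60% of enhancers are active. All placement, states and expression
  levels are pure functions of the seed.
* **Signal:** Gaussian bumps on a 10-bp grid. Enhancers get a central
  DNase bump (σ = 80 bp, amplitude 4), flanking H3K4me1 (and, if active,
  H3K27ac) bumps at ±250 bp (σ = 120) forming the peak-valley-peak shape
  of the flanking nucleosomes, and divergent GRO-seq bumps at ±150 bp with
  a 6:1 (sense) and 5:1 (antisense) active:primed amplitude contrast — the
  qualitative contrast reported for real active versus primed enhancers,
  used here as a design default rather than a reproduction claim.
  Promoters get H3K4me3 (amplitude 4), moderate DNase and low H3K4me1.
  Background is exponential noise with mean 0.05 × peak amplitude / snr;
  the default snr of 5 represents a reasonably deep, well-behaved library.
  Values are rounded to 4 decimals so tracks round-trip bit-identically
  through bedGraph.
* **DHS peaks:** one q-passing peak (−log10 q ≥ 2) per enhancer plus 30
  decoys with −log10 q < 2 that the q-filter must remove.
* **Counts:** negative binomial (size 10) around planted log-normal means,
  with a tenth of genes silent.

What the simulator does *not* model: mappability structure, copy-number
and GC biases, enhancer-dense clusters closer than 2 kb, partially active
states, chromatin-domain–scale correlations, and read-level artifacts
(trimming/alignment are upstream of this package's inputs). Passing the
benchmark therefore demonstrates that the machinery is correct and
recovers planted structure under noise — not that real-data accuracy will
match the benchmark's; on real tracks the classifier's held-out accuracy
is expected to sit below the synthetic ceiling.

Benchmark problem sizes were chosen so the whole suite runs comfortably on
a laptop: the end-to-end check uses the default 2 × 1 Mb genome across
five seeds (10,000 scan windows each), and oracle-equivalence checks run
on a few-kb toy genome with >1000 randomized instances.

## Numerical and degenerate-case choices

* Merging uses gap ≤ `merge_gap` (so `reduce(min.gapwidth = merge_gap + 1)`);
  merging is idempotent and order-insensitive.
* An element flanked past a chromosome end is clipped and its mean uses
  the clipped width — no phantom zero-padding bias.
* Metagene midpoint of an even-width element is start + width/2 (integer
  floor); heatmap rank ties fall back to genome order. Bins clipped at a
  chromosome edge contribute the clipped part's mean; fully out-of-bounds
  bins are 0.
* A missing narrowPeak q-value (sentinel −1) fails the q-filter:
  validation evidence must be conservative.
* Readers reject malformed records (overlaps, start ≥ end, non-numeric
  values) with line numbers rather than silently repairing them; records
  on unknown chromosomes are dropped with a count.
* An empty DHS set validates nothing (with a warning); an empty genome
  yields an empty window list; all-zero counts yield all-zero FPKM/TPM.
* The pipeline is single-threaded by design: scan time at desk scale is
  seconds, and determinism questions about parallel reduction order never
  arise. Results are independent of chromosome processing order.

## Known limitations

* Two-class training means the score of featureless background windows is
  not calibrated; do not interpret window probabilities as posterior
  enhancer probabilities genome-wide. The DHS gate is integral to the
  method, not optional polish.
* The active/primed threshold is a single global cutoff; graded or
  bivalent states are out of scope.
* No BAM/bigWig input: coverage arrives as bedGraph, read positions as
  TSV. No peak calling: DHS peaks are consumed, not computed.
* `nearest_feature` is exact but quadratic per chromosome in the worst
  case; at annotation scales (10⁴–10⁵ features) this is not a practical
  concern.
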