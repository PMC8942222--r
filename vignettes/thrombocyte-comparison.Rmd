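---
title: "Comparing young and mature thrombocyte transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing young and mature thrombocyte transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thrombocompare)
```

## The scientific setting

Zebrafish thrombocytes are nucleated blood cells functionally equivalent to
mammalian platelets. In a reporter line where young thrombocytes carry RFP
and mature thrombocytes carry a stronger GFP signal, the two maturation
stages can be sorted and sequenced separately, and their transcriptomes
compared. `thrombocompare` implements that comparison as a reusable,
deterministic pipeline operating on transcript-level quantification output
(the five-column Salmon `quant.sf` layout): it quantifies, classifies,
compares, and maps the two populations, projects the results onto human
orthologs, and relates them to external megakaryocyte and platelet gene
lists.

## The model and its rules

**TPM and gene aggregation.** Transcript abundance is expressed in
transcripts per million:

$$TPM_i = 10^6 \cdot \frac{c_i/\ell_i}{\sum_j c_j/\ell_j},$$

with $c_i$ the read count and $\ell_i$ the effective length. The vector
sums to $10^6$ by construction. Gene abundance is the sum of member
transcript TPMs — the simplest tximport-style abundance semantics. We do
not implement counts-based recomputation variants: raw TPM is the only
scale the downstream rules use.

**Expressed and highly expressed.** A gene is *expressed* when its TPM is
strictly greater than 1. Over the expressed genes only, log TPM is
standardised to a z-score using the sample (n−1) standard deviation, and a
gene is *highly expressed* when its z strictly exceeds 1.5. Both
thresholds are strict: a gene at exactly TPM = 1 or z = 1.5 does not
qualify. Non-expressed genes receive no log TPM or z (avoiding log 0) and
take no part in the normalisation. We use the natural log; the
classification is provably invariant to the base, since changing base
rescales numerator and denominator identically — the test suite asserts
this invariance directly.

**Five TPM intervals.** The TPM axis is partitioned as ZERO = {0},
SUB1 = (0, 1), LOW_1_5 = [1, 5), MID_5_30 = [5, 30),
HIGH_30_PLUS = [30, ∞). Left-closed upper bins match the "30 and higher"
reading of the top interval. This leaves a deliberate tension at exactly
1 TPM: such a gene falls in LOW_1_5 but is still not expressed under the
strict rule. The boundary case cannot be decided from the descriptive
interval names alone; we fixed this convention once and document it here.

**Decile overlap mapping.** Each population's expressed genes are sorted
by decreasing TPM (quantile 1 = most highly expressed) with ties broken by
ascending gene identifier, and quantile $i$ spans ranks
$(\lceil (i-1)n/10 \rceil,\ \lceil in/10 \rceil]$. Tie and remainder
handling are underdetermined by the verbal "top 10% (approximately)"
description; the lexicographic tie-break plus ceiling boundaries make the
assignment deterministic, input-order independent, and maximally even
(sizes differ by at most 1). The overlap matrix cell $(i, j)$ counts genes
in quantile $i$ of population A that sit in quantile $j$ of population B;
its grand total is the number of genes expressed in both populations.

**Set algebra and ortholog collapsing.** Gene-list deduplication keeps
first occurrences and reports the removal count, mirroring an audited
spreadsheet "remove duplicates" step. Identifier matching is
case-sensitive exact match after whitespace trimming — zebrafish symbols
are lower-case and human symbols upper-case, so case carries meaning.
Ortholog projection sends each query gene to *all* its human partners
(raw hits), then collapses duplicates only at the human-identifier level:
two zebrafish paralogs hitting one human gene contribute one distinct
ortholog and one redundant hit. Reported percentages are integers
truncated toward zero (17.53% prints as 17%), the only convention
consistent with all the ratios the pipeline reports.

**Heat-map preprocessing.** Cells are clustered by k-means for each
k in 2..10 (multiple restarts, per-k seeded streams); the retained k
maximises the mean silhouette width. Selecting the cluster number by eye
against a t-SNE embedding is inherently irreproducible, so the silhouette
criterion replaces it; `fixed_k` pins the choice when an external decision
(e.g. 4 clusters) should be reproduced. Per-cluster gene means are the
displayed matrix, and rows are standardised with the sample sd. The
often-quoted "−2 to 2" display range is a consequence of standardisation,
not a clamp — no truncation is applied, and constant rows are zeroed and
flagged rather than dropped. One ambiguity deserves note: descriptions of
this kind of analysis sometimes say "genes were clustered" while
describing clusters of *cells* whose per-cluster gene means are displayed.
We implement cell clustering plus gene-wise display scaling, and accept
externally supplied assignments through the model object for any other
scheme.

## The synthetic-data generator

The generator emulates, at desk scale, the statistical structure of the
two thrombocyte populations and their companion resources. Its defaults
*are* the study conditions:

* **Zero inflation.** A gene has zero TPM with probability 0.4009 (GFP,
  mature) or 0.4912 (RFP, young), and TPM uniform in (0, 1) with
  probability 0.2019 / 0.3455 — the observed interval fractions of the
  two populations.
* **Expressed magnitude.** Otherwise TPM = 1 + a lognormal draw. The
  per-population parameters (GFP meanlog 1.868, sdlog 1.942; RFP meanlog
  0.921, sdlog 2.144) are solved analytically so that the three expressed
  intervals approximate the observed proportions (GFP
  15.94/15.01/8.71%, RFP 9.57/4.68/2.05% of all genes): matching the two
  interior interval boundaries (5 and 30 TPM) of the shifted lognormal
  CDF to the conditional proportions gives two equations in
  (meanlog, sdlog) per population. Exact matching of all four interval
  masses with a two-parameter family is not attempted. The mature
  population has the heavier right tail, as observed. No dispersion
  information beyond interval percentages informs this choice; the
  lognormal is a modelling convenience, and parameter-recovery tests
  check only the quantities the generator explicitly encodes.
* **Transcript structure.** Gene abundance is split over 1–3 isoforms
  with random weights; counts are back-computed as TPM × effective
  length (rescaled to a fixed depth), so recomputing TPM from counts
  reproduces the generated values exactly up to the global per-million
  normalisation — the quantification formula inverts the generator, and
  the tests assert this as an identity.
* **Ortholog map.** Each source gene has a human partner with
  probability 0.72; with probability 0.10 a human gene is shared by a
  group of 2–3 source paralogs, so projection produces duplicate hits
  that collapse at the human level. Generator-side bookkeeping
  (mapped, distinct, redundant counts) is carried as attributes and
  cross-checked against the projection in tests.
* **External lists.** Megakaryocyte- and platelet-like lists hit
  configured overlap fractions with the thrombocyte set exactly up to
  integer rounding (defaults 0.46, 0.17, and 0.146 three-way, with list
  sizes 0.843 and 0.308 of the thrombocyte set — the ratios observed
  between the three transcriptomes). The two lists' non-thrombocyte pads
  are disjoint, so the three-way overlap equals the M∩P overlap inside
  the thrombocyte set; overlap structure outside the thrombocyte set is
  not modelled.

One scale subtlety: the generator draws gene-level TPM from the mixture
directly, and these calibrated values are what the interval fractions
refer to. A real quantification table, however, always sums to one
million, so the bundle writer emits count tables on that normalised scale;
running the pipeline on them yields TPM values larger by the
normalisation factor, and correspondingly larger expressed fractions.
Interval-calibration checks therefore address the generated gene table,
while pipeline-level checks address set identities, determinism, and
parameter recovery — quantities invariant to that global scale.

**What the generator does not emulate.** There is no cell-level structure
(no barcodes, no per-cell sparsity — the populations are merged, as in the
study's TPM analysis), no read-level error model, no real gene symbols,
and no correlation between expression level and ortholog coverage.
Passing tests on synthetic data therefore demonstrate the pipeline's
algebraic and statistical correctness under the stated population
structure, not robustness to artefacts of real sequencing data.

**Determinism.** Every generator derives its stream from the single
config seed plus a fixed per-generator offset, so adding one generator
call does not shift another's draws, populations use distinct streams,
and all results are bit-reproducible given the seed.

## Numerical choices and degenerate inputs

* Sample (n−1) standard deviation everywhere, matching the default of the
  spreadsheet and statistical software this style of analysis is done in;
  at n in the thousands the difference from the population sd is far
  below every tolerance used.
* All-zero count tables, fewer than 2 expressed genes, zero log-TPM
  variance, fewer than 10 expressed genes (decile partition), identical
  cells (clustering), and infeasible overlap configurations raise
  immediate, named errors rather than producing silent output.
* Unmapped transcripts default to the lenient policy — each becomes its
  own gene, flagged — because genes absent from curated databases
  (identifiers beginning "LOC") are retained, never dropped; a strict
  mode lists offenders and aborts.
* Empty gene lists warn rather than error; an empty interval table
  reports zero percentages with an explicit flag.
* The pipeline materialises every intermediate list and matrix it
  computes, so each report count can be re-derived from an emitted file;
  reruns with identical inputs are byte-identical (nothing
  time-dependent enters any output file).

## Problem sizes used by the test suite

Unit and property tests run on tables of tens to hundreds of rows with
20–500 randomized repetitions per property; calibration and
parameter-recovery checks use populations of 10,000 genes (matching the
scale at which binomial sampling error, about half a percentage point for
the zero fraction, is small relative to the acceptance band); pipeline
round-trips use 300–400-gene bundles. These sizes were chosen so each
statistical check has adequate power while the full suite stays
interactive.

## Known limitations

* The ortholog map is an input; no orthology inference (synteny, BLAST)
  is performed, and annotation quality is whatever the supplied table
  carries.
* The five-interval boundaries and the decile tie-break are fixed
  conventions for underdetermined verbal descriptions; results at the
  exact boundaries depend on them.
* Functional enrichment (GO/KEGG/PANTHER classification) and
  differential-expression testing are out of scope; the pipeline stops at
  set-level and distribution-level comparison.
* Heat-map rendering is out of scope: the cluster assignments, mean-count
  matrix, and row-scaled matrix are the artifacts.
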