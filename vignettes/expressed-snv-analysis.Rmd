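---
title: "Analyzing expressed SNVs in single cells with cellsnv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing expressed SNVs in single cells with cellsnv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellsnv)
```

# The data model

`cellsnv` works from two inputs: a genes-by-cells raw count matrix
(MatrixMarket triplet directory or dense TSV) and a tab-delimited table
of per-cell SNV read counts, either in the verbose column layout of
barcoded read counters (chromosome, position, ref, alt, barcode/read
group, variant count, reference count) or in a compact dialect keyed by
a canonical SNV identifier `chrom:pos:ref>alt`. Positions are 1-based
everywhere; multiallelic sites are distinct loci.

The central container is a cells × SNVs matrix with three aligned
layers: variant counts, reference counts and an observed mask. The mask
is what lets the package maintain the distinction that motivates the
whole design:

* **no signal** — the locus has no reads in that cell. The expressed
  variant allele fraction `VAF_RNA = N_VAR / (N_VAR + N_REF)` is
  *undefined* there, never 0, and such cells are drawn in a reserved
  grey in every plot.
* **negative signal** — reference-only coverage. The gene is expressed,
  the variant is not: VAF = 0.
* **variant signal** — variant-only (VAF = 1, monoallelic variant
  expression) or biallelic coverage.

Rows whose two counts are both zero carry no information beyond the
mask and are dropped at load time with a reported count. Duplicated
(SNV, barcode) rows indicate an upstream fault and error by default
(`dedup_policy = "sum"` aggregates them instead). Cell barcodes from
the two inputs are reconciled by `harmonize_barcodes()`, whose `"auto"`
policy retries the intersection after stripping a trailing `-<digits>`
GEM-well suffix from whichever side carries one.

# Per-cell metrics and their conventions

For a selected SNV set, `compute_cell_metrics()` summarizes each cell:

* `n_snvs` — loci with `n_var >= 1`. Reference-only coverage is a
  negative signal and deliberately does not count as an "expressed
  SNV".
* `total_vaf` — Σ N_VAR / Σ (N_VAR + N_REF) over the covered selected
  loci: a depth-weighted magnitude, always between the smallest and
  largest per-locus VAF of the cell.
* `mean_vaf`, `median_vaf` — unweighted central tendency over covered
  loci, *including* VAF = 0 loci; excluding the negative signal would
  bias every summary toward 1.

Cells covering no selected locus keep defined zero totals but undefined
ratios; the TSV writer serializes undefined as an empty field (never
the text "NA"), and counts as integers with ratios at full double
precision, so read-back restores values exactly.

Two median/binning conventions are fixed to avoid dialect drift: the
median of an even count is the mean of the two central values, and
histograms use equal-width left-closed bins with a right-closed final
bin — 50 bins on [0, 1] for VAF metrics, integer-aligned edges for
count metrics. The per-cell-across-SNVs and per-SNV-across-cells
readings of "mean/median VAF" are both available: the former in
`cell_metrics`, the latter in `snv_profiles()`.

# SNV-level filters

Two filters (`filter_spec`) remove low-confidence loci, e.g. SNVs
detected in fewer than 20 cells or entries with sequencing depth below
3 reads. Depth is applied per entry and *first*, so an entry failing
the depth floor does not count toward its SNV's cell support; the
alternative order would let sub-threshold entries rescue an SNV the
user asked to exclude. Filtering is monotone and idempotent, and cells
are never dropped — cell QC belongs to the expression pipeline.
Applying the depth rule per entry rather than per-SNV average keeps the
rule local and the observed mask exact.

# Origin classification

Without cell-matched DNA, the probable origin of an expressed SNV can
be inferred from its cross-cell profile: germline heterozygous loci
show balanced allelic expression (many biallelic cells, VAF centered
near 0.5); germline homozygous loci show monoallelic variant expression
in essentially all expressing cells; somatic variants are carried by a
cell subset at transcription-consistent VAF; RNA-level events (editing,
transcriptional infidelity) appear as sporadic low-count, low-VAF
observations across cells.

These qualitative patterns are made operational by explicit numeric
thresholds (`origin_thresholds()`), every one of them a package choice
and a settable parameter:

| rule (first match wins) | condition, defaults |
|---|---|
| coverage gate | `n_cells_covered >= 10`, else `unclassified` |
| `germline_hom` | var-only fraction ≥ 0.95 and mean VAF ≥ 0.95 |
| `germline_het` | biallelic fraction ≥ 0.2 and median VAF in [0.35, 0.65] |
| `somatic_like` | carrier fraction in [0.05, 0.5] and median VAF among carriers ≥ 0.2 |
| `rna_origin_like` | median VAF < 0.2 and median N_VAR among carriers ≤ 2 |

"Carrier" means state var-only or biallelic — a literal reading of
variant presence. The rule order runs from the most to the least
constrained pattern because overlapping profiles exist; the `_like`
suffixes are deliberate — these are heuristics over expression
evidence, not genotype calls. Every call carries the evidence values
that reproduce it deterministically, and hom/het/somatic labels are
invariant under scaling all counts of a profile (only the RNA rule
consults count magnitude).

Random monoallelic expression — X-inactivation or transcriptional
bursting, which this package (like the underlying data) cannot
distinguish — is flagged *orthogonally* to the label, since such loci
are typically germline heterozygous as well: biallelic fraction ≤ 0.1,
both monoallelic tallies nonzero, and their ratio within [1/3, 3].
Below the coverage gate the flag is `NA` (undetermined), not `FALSE`.

# SNV clustering on the transposed matrix

To group SNVs with similar transcriptional activity, the matrix is
transposed so cells act as features. Because "no signal" must remain
distinguishable from "negative signal" after the unobserved entries are
given a numeric value, each SNV's feature vector concatenates its
per-cell VAF (unobserved → 0) with an explicit per-cell observed
indicator. PCA, an SNN graph and Louvain follow, plus 2D coordinates
(UMAP, or PCA for very small SNV sets). On planted data this separates
homozygous from heterozygous germline loci essentially perfectly
(adjusted Rand ≥ 0.9 in the validation suite).

# Cell embeddings

The original workflows in this space delegate expression processing to
an external single-cell framework; `cellsnv` instead fixes a minimal,
fully documented pipeline so that results are self-contained and
reproducible from `(input, params, seed)` alone: library-size
normalization to 10,000 counts per cell → `log1p` → top 2,000 variable
genes by dispersion (variance/mean) → per-gene z-scores clipped at ±10
→ PCA to 30 components → 15-nearest-neighbor SNN graph (Jaccard
weights, pruned at 1/15) → Louvain at resolution 1.0 → UMAP
(`min_dist` 0.3) and/or t-SNE (perplexity 30, reduced automatically
for small n) in 2 or 3 dimensions. 3D output simply requests three
components from the same method. All stochastic steps run
single-threaded from the seed, so coordinates are bit-identical across
runs. Precomputed embeddings from any external processing can be
attached instead (`attach_embedding()`), bypassing the pipeline.

Multi-sample integration intersects genes, concatenates counts under
`"<sampleid>_"`-prefixed barcodes, and replaces anchor-based batch
correction with per-sample standardization of each gene before the
joint PCA. This removes per-sample location and scale differences — on
split-sample tests shared groups mix to near-perfect sample entropy —
but it does not model nonlinear batch effects; strongly batched data
should be integrated externally and attached as a precomputed
embedding.

# The synthetic generator

`simulate_dataset()` plants ground truth for every pattern above. Per
cell, a size factor is drawn log-normal (`sdlog` 0.5, unit mean —
library-size variation typical of droplet data); gene counts are
negative binomial (size 2) around Gamma-distributed base means, with
10% of genes shifted 4-fold per expression group, the magnitude of real
cell-type markers, so the planted groups represent distinct cell
types. Locus depth is Poisson(5 × size factor) — zero-depth pairs are
omitted, creating true no-signal entries — and the variant read count
given depth D follows the class: Binomial(D, 0.5) for het; D for hom;
Binomial(D, 0.5) inside a single shared subclone of fraction 0.2 and 0
elsewhere for somatic; Binomial(D, 0.02) in all cells for RNA-origin;
and for bursting, a per-cell fair allele choice with all reads from the
chosen allele. Somatic loci are simulated heterozygous *within* the
subclone (one mutated allele of two), not clonally homozygous.

The generator emulates coverage sparsity, library-size variation and
allele sampling; it does not emulate doublets, ambient RNA,
allele-specific mapping bias, position-level error profiles, or any
coupling between a locus and its host gene's expression (locus coverage
shares only the cell's size factor with the expression matrix). Passing
the recovery tests therefore demonstrates that the rules and pipelines
recover their own generative patterns at realistic sparsity — not that
the thresholds are optimal on any particular tissue.

# Validation problem sizes and numerical choices

The validation suite runs the generator at its default conditions —
300 cells, 500 genes, 3 expression groups, locus coverage rate 5, 50
SNVs per class (somatic fraction 0.2, RNA conversion rate 0.02) — and
requires macro-averaged recall ≥ 0.9 over the four origin classes,
monoallelic-flag sensitivity and specificity ≥ 0.9, and adjusted Rand
≥ 0.9 for both hom/het SNV clustering and expression-group recovery;
smaller configurations back the unit tests. Vectorized metrics are
checked against brute-force per-entry loops on random matrices up to
50 × 20 (integers exactly, ratios to 1e-12). Degenerate inputs are
handled explicitly: empty tables error, all-zero expression matrices
load with a note, filters that remove everything warn and return an
empty matrix, and undefined metrics propagate as `NA` end to end —
selection predicates never match them and plots draw them in the
reserved color.

# Known limitations

* Origin labels are threshold heuristics over expression evidence;
  they are not genotype calls, carry no likelihoods, and loci under
  the coverage gate stay unclassified.
* RNA-origin and low-frequency somatic patterns genuinely overlap; at
  the default thresholds a minority of simulated RNA-origin loci fall
  into `somatic_like` (macro recall ~0.95, not 1.0). The rule order
  resolves ties deterministically rather than probabilistically.
* Random monoallelic expression cannot be attributed to X-inactivation
  vs transcriptional bursting from these data; the flag names neither.
* Integration is a linear per-sample standardization, not anchor-based
  correction.
* No BAM/VCF parsing, no read-level counting, no phasing, no external
  variant-database annotation: the package starts from read-count
  tables produced upstream.
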