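# chromtrace

Stromal cell types — endothelial cells, fibroblasts, macrophages — are found
in every organ, yet their chromatin is not organ-agnostic: a fraction of
open regions is shared by most cells of a tissue regardless of cell type.
`chromtrace` is a single-cell ATAC-seq analysis pipeline built around the
question of whether that organ-level signature is strong enough to trace a
stromal cell back to its tissue of origin from accessibility alone. Because
public multi-organ atlases cannot be shipped at desk scale, the package
includes a seedable fragment simulator with machine-readable ground truth,
so every stage — QC, embedding, markers, footprints, metacells, tracing —
is validated as a parameter-recovery experiment: the generator plants the
structure, the pipeline must recover it, and must fail to when it is
removed.

## What it computes

Starting from 10x-style fragment files (chrom, start, end, barcode, count;
0-based half-open; both fragment ends are Tn5 insertion sites):

* **QC** — per-barcode fragment depth and TSS enrichment (mean insertion
  count at TSS ± 50 bp over the outermost 100 bp flank mean, floored at
  0.1); cells retained iff depth ≥ 1000 and enrichment ≥ 4; KNN doublet
  scores (K = 10) from synthetic cell-pair doublets projected into the LSI
  basis.
* **Embedding** — 5-kb tile matrix; TF-IDF
  `X = ln(1 + 10^4 · TF · IDF)` with `IDF = ln(1 + n/(1 + df))` on
  binarized counts; 4 rounds of iterative LSI (truncated SVD, 30
  dimensions, 65,000 variable features, clustering resolutions
  0.1/0.2/0.4), dropping dimensions correlated with log depth beyond
  |r| = 0.75; shared-nearest-neighbor Louvain clustering (k.param 30,
  resolution 1, at most 60 clusters).
* **Peaks and markers** — capped peak matrix (ceiling 4); group-vs-rest
  Wilcoxon markers with BH FDR (genes: FDR ≤ 0.01, log2FC ≥ 1.25; peaks:
  FDR ≤ 0.1, log2FC ≥ 0.5); distance-decay gene activity scores
  (`exp(−d/5000)`, ±100 kb) with KNN imputation.
* **Similarity** — binarized accessible sets (peak detected in ≥ 5% of a
  group), Jaccard similarity matrices, mean intra-cell-type Jaccard, and
  chromatin-module detection (average-linkage tree cut + hypergeometric
  tissue association).
* **Motifs** — hypergeometric motif enrichment in marker peaks
  (FDR ≤ 0.1, log2FC ≥ 0.1) and flank-normalized Tn5 insertion footprints
  around motif centers.
* **Metacells** — adaptive Gaussian kernel on the embedding; archetypal
  analysis `min ||M − M B A||_F^2` over column-stochastic A and B
  (90 metacells, waypoint initialization from 10 kernel eigenvectors,
  alternating Frank–Wolfe with exact line search, tolerance 1e-5, 10–50
  iterations plus 5 refinement steps); hard assignment by argmax of A.
* **Tracing** — per-metacell tissue composition; tissue signatures from
  associated modules or top differential peaks; held-out (50/50 split)
  tissue-of-origin prediction for stromal cells by Jaccard scoring against
  the signatures; combinatorial region + gene gating.

## Worked example

The `analysis/` directory holds the numbered workflow; each script runs one
pipeline stage on the default synthetic study (9 tissues, 3 shared stromal
types plus one organ-restricted type per tissue, ~2,400 barcodes, ~6.4 M
fragments) and reports what it found. Running them in order:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_qc.R
# ... through ...
Rscript analysis/08_tracing.R
```

prints, among other things (seed 1):

```
retained 2257 / 2376 barcodes
normal cells retained: 99.5%
planted low-quality cells excluded: 100.0%

clusters: 36 (generative populations: 36)
cluster purity vs (tissue, type): 0.972

mean intra-type Jaccard:
  shared stromal types:   0.753
  organ-restricted types: 0.839

normalized footprint depth at the motif center (flank = 1):
  KLF ~ 0.49-0.52 in every cell type        (generative depletion 0.5)

distinct metacell ids: 90
median metacell purity: 1.000; fraction >= 0.8: 0.889

held-out stromal tissue-of-origin accuracy: 1.000 (n = 804, unclassified 0)
```

Reading these: QC recovers exactly the planted low-quality population;
clustering resolves all 36 generative (tissue, cell type) populations;
shared stromal types are less internally similar across organs than
organ-restricted types (the planted tissue peaks diverge their accessible
sets); the aggregated footprint dip recovers the simulated 50% insertion
depletion; the metacell stage produces the configured 90 metacells, almost
all dominated by a single population; and held-out stromal cells are traced
back to their organ of origin essentially perfectly — while a control
simulation without tissue-level peaks drops tracing accuracy to chance
(~1/9; see the acceptance suite).

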