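# spatialseg

Quantifying **spatial immune segregation** in multi-regional tumour
profiling: cell-graph topology of the tumour microenvironment, multi-regional
transcriptomic divergence, and the peritumoural-minus-core immune gradient.

## Who this is for

Computational pathology and tumour-immunology analysts working with
multi-regional sampling designs — a tumour core plus peritumoural tissue
sampled at increasing distances from the margin (here 1 cm and 3 cm) — who
need to measure whether immune cells are *excluded* from the core and
*enriched* at the boundary, and whether that spatial organisation (rather
than bulk immune quantity) relates to outcome.

Inputs are the standard artefacts of such a study: typed nucleus centroids
from H&E segmentation/classification (CSV/TSV or HoVer-Net-style JSON),
region annotations (GeoJSON polygons or annulus CSV), a gene × sample raw
count matrix with sample metadata (TSV or MatrixMarket), and gene sets in
GMT format. Seeded synthetic generators for both modalities, with full
ground truth, make every stage testable without patient data.

## The statistics at the core

* **Cell-pair graphs.** For a type pair (A, B), each A-cell is linked to its
  *k* nearest B-cells (default *k* = 5, symmetrised); candidate edges longer
  than 25 µm — the short-range interaction radius of cell-graph pathology —
  are removed. Per cell: Degree, Nsubgraph (connected-component size),
  Min/MeanEdgeLength, local clustering coefficient
  2T(v)/deg(v)(deg(v)−1), and betweenness centrality
  Σ<sub>s≠v≠t</sub> σ<sub>st</sub>(v)/σ<sub>st</sub>, normalised per
  component by (n−1)(n−2)/2.
* **Transcriptomics.** Median-total-count normalization to log2
  (x<sub>gs</sub> = log2(c<sub>gs</sub>·median(totals)/total<sub>s</sub> + 1));
  cross-group pairwise Euclidean transcriptome distances; differential
  expression with a Shapiro–Wilk-gated t/Wilcoxon battery,
  Benjamini–Hochberg correction, and two significance profiles
  (|log2FC| > 0.5 & adj. p < 0.05; |log2FC| > 1.5 & FDR < 0.05); ssGSEA-style
  rank-weighted running-sum gene-set scores (weight rank^0.75).
* **The gradient.** Per patient, lymphocyte abundance (fraction, density, or
  TIL proportion = mononuclear inflammatory cells / stromal compartment) in
  the peritumoural band **minus** the tumour core. Outcome groups are
  compared on the gradient and, as a deliberate null contrast, on raw
  peritumoural abundance.

## Worked example

```r
library(spatialseg)

# synthetic tissue with 4x lymphocyte enrichment in the peritumoural bands
sim <- simulate_tissue(tissue_sim_config(rho = 4, seed = 1))
sim$cells
#> cell_table: 5554 cells | slide sim_slide | patient sim_patient
#>   types:   lymphocyte=2247 macrophage=306 neutrophil=84 stromal=2523 tumour=394 other=0
#>   regions: core=956 peri_1cm=1764 peri_3cm=2834

ab <- region_abundance(sim$cells, sim$regions)
peritumoural_core_difference(ab, basis = "density", peri_region = "pooled")
#>    patient_id     peri     core difference   basis peri_region
#> 1 sim_patient 807.5219 230.7747   576.7472 density      pooled
```

The planted world has core lymphocyte density 2×10⁻⁴/µm² (= 200/mm²) and
4× that in the bands: the recovered densities (231 and 808 cells/mm²) and
the positive difference (+577 cells/mm²) read back the planted segregation.

```r
g <- build_pair_graph(sim$cells, graph_config("lymphocyte"), region = "peri_1cm")
g
#> cell_pair_graph lymphocyte-lymphocyte: 762 nodes, 1306 edges (k=5, <=25.0 um) [peri_1cm]

aggregate_features(node_features(g), sim$cells) |>
  subset(region == "peri_1cm" & cell_type == "lymphocyte")
#>    region  cell_type               feature        mean       median   n n_excluded
#>  peri_1cm lymphocyte                Degree  3.42782152  3.000000000 762          0
#>  peri_1cm lymphocyte             Nsubgraph 11.96062992  9.000000000 762          0
#>  peri_1cm lymphocyte         MinEdgeLength 10.37595342  9.361713215 707         55
#>  peri_1cm lymphocyte        MeanEdgeLength 15.70828800 15.804717403 707         55
#>  peri_1cm lymphocyte ClusteringCoefficient  0.58561345  0.666666667 762          0
#>  peri_1cm lymphocyte           Betweenness  0.09855265  0.008250573 762          0
```

Mean degree 3.4 and clustering coefficient 0.59 reflect the tight
lymphocyte clusters of the enriched band; the 55 excluded cells are
isolated lymphocytes with no edge within 25 µm, whose edge-length features
are undefined by construction.

See `vignettes/spatial-immune-segregation.Rmd` for the model descriptions,
parameter rationale, numerical conventions, and the limitations of the
synthetic world.

## Acceptance script

`scripts/acceptance.R` re-runs the whole pipeline from scratch against the
installed package — tissue simulation, per-region graphs, a 10-patient
outcome cohort, expression simulation, normalization, distances,
differential expression and signature scoring — logging headline numbers to
stderr, and writes a JSON report to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
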