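# rabnet

Resilience-guided analysis of protein–protein interaction networks (PPINs)
and prioritization of candidate metastasis markers.

## The problem

Interaction networks built around a protein family (here motivated by the
Rab GTPases and their role in epithelial-to-mesenchymal transition, EMT) are
grown incrementally from literature and database edges. Two questions then
arise:

1. **How large should the network be?** Expanding adds context but also
   noise and computational cost. `rabnet` scores each network in an
   expansion series by its *resilience to random node failure* and selects
   the smallest network whose resilience has plateaued.
2. **Which neighbours of the disease (seed) genes are promising novel
   candidates?** `rabnet` implements an adapted MaxLink workflow: direct
   neighbours of seed genes are candidates, genes with prior cancer
   annotation are removed, genes whose seed connectivity is explained by
   their overall degree are removed, and the survivors are tested for
   differential expression between primary and metastatic tumour cohorts.

## The model

For a network of size `N`, nodes are removed uniformly at random at a
failure rate `f = (nodes removed)/N`. The fragmentation state is scored by
a modified Shannon diversity index over the component sizes `C_i` (removed
nodes count as singleton components, so `Σ C_i = N` at every `f`):

    H(f) = − Σ_i (C_i/N) · log_N (C_i/N)

With the base-`N` logarithm, an intact connected network has `H = 0` and a
fully defragmented one (N singletons) has `H = 1`. Averaging `H` over 500
random removals per grid point and sweeping `f` over [0, 1] gives an
entropy curve whose area under the curve (trapezoidal rule) is the
accumulated entropy `H_msh`, and

    resilience = 1 − H_msh

so resilience is near 1 for robust networks and near 0 for fragile ones.
Across an expansion series the resilience scores are min–max normalized and
the optimal size is the smallest one from which successive changes stay
below 7%.

Downstream, hub detection uses the kneedle elbow of the rank-ordered degree
curve, the degree distribution is summarised by a log–log least-squares
power-law exponent (`p(k) = k^−γ`), the connectivity filter uses a loess
fit of seed connectivity against total degree with elimination inside the
95% confidence band, and differential expression uses cohort-mean fold
changes with two-group Kruskal–Wallis tests, stratified into
high / medium / low significance tiers.

Since the original study's inputs are large external resources, the package
ships a seeded synthetic generator (`synth_config()`, `synth_dataset()`,
`write_synth_fixtures()`) that produces every input the pipeline consumes:
a preferential-attachment network with confidence-scored edges and an
expansion pool, a seed-gene list, a Disease Ontology map, and log-normal
FPKM cohorts with planted fold changes and TNM metadata.

## Worked example

```r
library(rabnet)

cfg <- synth_config(seed = 42, n_nodes = 150)
ds  <- synth_dataset(cfg)
ds$network
#> <ppi_network> 150 nodes, 444 edges

curve <- resilience_curve(ds$network, n_bins = "exact", iterations = 500, seed = 42)
curve
#> <resilience_curve> N = 150, 151 grid points, 500 iterations
#>   H_msh = 0.5850  resilience = 0.4150  (seed 42)

topology_summary(ds$network)
#> <topology_summary> N = 150, E = 444
#>   density 0.0397  <k> 5.92  clustering 0.1181
#>   CPL 1.736 intermediate nodes (2.736 edges)  gamma 1.649
#>   hubs: 22 (elbow degree 8)

net   <- label_seeds(ds$network, ds$seed_genes)
cands <- find_candidates(net)                      # 91 candidates
cands <- annotation_filter(cands, ds$doid_map)     # 73 remain
cands <- connectivity_filter(cands)                # 45 final
hits  <- call_hits(cands, ds$study)
sum(hits$is_hit)
#> [1] 10
head(hits[hits$is_hit, c("gene", "cancer_type", "log2fc", "p_value", "tier")], 4)
#>     gene cancer_type log2fc  p_value tier
#> 50 G0029        SYN1   2.97 6.81e-09 high
#> 56 G0053        SYN1   3.31 8.49e-10 high
#> 57 G0054        SYN1   3.13 5.71e-09 high
#> 71 G0096        SYN1   2.19 8.70e-08 high
```

A 150-node synthetic network with a modest mean degree is moderately
fragile (resilience 0.41): random removal of around half its nodes already
fragments it substantially. The ten hits are exactly the ten genes the
generator planted with a log2 fold change of 3 in the metastatic cohort;
all reach the high-significance tier (|log2FC| > 2, P < 0.001).

A thin command-line interface over the same functions is installed with the
package:

```sh
Rscript $(Rscript -e 'cat(system.file("scripts", "rabnet", package = "rabnet"))') \
  simulate --seed 7 --outdir fixtures/
# then: build, expand, resilience, topology, maxlink, diffexpr
```

## Documentation

The methods vignette (`vignettes/resilience-methods.Rmd`) describes the
entropy model and its assumptions, the numerical choices (grid, binning,
pseudocounts, tie handling), the synthetic generator's design, and known
limitations.
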