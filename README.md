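# dropletMultiome

Empty-droplet detection for single-nucleus multiome (ATAC + gene expression)
data.

In droplet multiome assays the nuclei are permeabilized before encapsulation,
so nuclei-free droplets capture a *soup* of ambient RNA and DNA fragments and
show non-zero counts in both modalities. Pipelines that call cells with a
hard library-size threshold (a k-means line in log-count space) discard real
cell types with small libraries. `dropletMultiome` takes the EmptyDrops
approach — profile the soup, then test each droplet for deviation from it —
and generalizes it to two modalities:

1. **Cluster library sizes.** Per modality, a three-component Gaussian
   mixture on log10 totals separates the technical-error cluster (~1 count),
   the ambient cluster, and the nuclei, yielding boundaries `b` (density
   crossing of the two lowest components) and `l` (1.5 or 2 ambient sigmas).
2. **Profile the soup.** Counts of the ambient-cluster droplets
   (`b <= t <= l`) are summed per feature and smoothed with Simple
   Good-Turing into proportions `p`; the over-dispersion `alpha` is fitted by
   maximum likelihood.
3. **Test each droplet.** Under the null a droplet's counts are
   Dirichlet-multinomial,
   `L = t! Γ(α) / Γ(t+α) · Π_g Γ(x_g + α p_g) / (x_g! Γ(α p_g))`,
   and a Monte-Carlo p-value `(M_c + 1)/(M + 1)` ranks the observed
   likelihood among `M` simulated null likelihoods at the same total.
4. **Aggregate and call.** RNA and ATAC p-values are combined by their
   arithmetic mean (dependence-robust), Benjamini-Hochberg corrected across
   barcodes into `FDR` (plus an RNA-only `FDR_RNA` column), and two lines
   parallel to the k-means line force `FDR = 1` below the ambient anchor
   point and, optionally, `FDR = 0` for very large droplets. Default calling
   threshold: `FDR <= 0.001`.

The package also ships a synthetic multiome generator with ground-truth
labels (technical / ambient / nucleus / downsampled-and-scrambled small
nucleus / integer-amplified empty), baseline callers (shiftable k-means
line, RNA-only), and ROC evaluation utilities, so the method's error control
can be measured end to end without any external data.

## Worked example

```r
library(dropletMultiome)

# a synthetic experiment with known truth: 3,000 technical + 3,000 ambient
# barcodes, 500 nuclei, 200 small scrambled nuclei, 300 amplified empties
sim <- simulate_dataset(sim_config_ordering_benchmark(seed = 3))

res <- multiome_call(sim$counts, seed = 3)
#> RNA clusters: b = 6.9, l = 222.5 (means 0.10 / 1.96 / 3.17)
#> ATAC clusters: b = 4.9, l = 128.9 (means 0.09 / 1.60 / 3.56)
#> soup droplets: 2900 RNA, 2977 ATAC
#> over-dispersion alpha: RNA 93.8, ATAC 48.3
#> tested barcodes: 4000 RNA, 4015 ATAC
#> called 700 of 4016 tested barcodes at FDR <= 0.001

evaluate_calls(setNames(res$table$is_cell, res$table$barcode), sim$truth)
#>   n_called tpr fpr fdp
#> 1      700   1   0   0
```

Reading the output: the mixture located the technical-error / ambient
boundaries (`b`) at ~7 RNA and ~5 ATAC counts and the ambient-cluster ends
(`l`) at ~222 and ~129 counts; ~2,900 ambient droplets per modality defined
the soup, whose fitted over-dispersion (`alpha`) is ~94 (RNA) and ~48
(ATAC). All 700 true nuclei (500 + 200 small) were recovered at the 0.1%
FDR threshold with zero false calls. `res$table` holds the per-barcode
columns `t_rna`, `t_atac`, `p_rna`, `p_atac`, `p_agg`, `FDR`, `FDR_RNA`,
`below_lower`, `above_upper`, `is_cell`; `write_call_outputs(res, dir)`
writes them as TSV plus a JSON run report.

Real data in CellRanger-arc layout loads with
`read_multiome_dir("raw_feature_bc_matrix/")`, and
`inst/cli/multiome-tools.R` exposes `call` / `simulate` / `evaluate`
subcommands for shell use.

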