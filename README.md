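# spliceStrata

Splicing-factor-stratified alternative-splicing analysis for bulk RNA-seq
cohorts.

## What it does, and for whom

Tumor cohorts often show dysregulated splicing factors (e.g. SF3B1 in
pancreatic ductal adenocarcinoma), and the analysis question is whether a
driver factor's expression level reorganizes the downstream splicing
landscape. spliceStrata is for computational biologists who have a
transcript annotation (GTF), transcript-level TPM abundances and
gene-level counts for a cohort, and want a reproducible answer:

1. **Event catalog** — local alternative-splicing events detected from the
   annotation and classified into the 7 canonical types: skipped exon
   (SE), mutually exclusive exons (MX), alternative 5′/3′ splice site
   (A5/A3), retained intron (RI), alternative first/last exon (AF/AL).
2. **PSI** — per event and sample, the percent spliced in
   Ψ = Σ TPM(inclusion isoforms) / Σ TPM(all isoforms of the event),
   with explicit missingness below a 1-TPM expression floor.
3. **Strata** — samples classified into low / intermediate / high driver
   expression by a univariate *equal-variance* Gaussian mixture (selected
   by BIC = −2ℓ + 2G·log n) on TMM-normalized log2 expression.
4. **Differential splicing** — per event, ΔΨ = mean Ψ(high) − mean Ψ(low)
   with two-sided Mann–Whitney rank-sum tests and Benjamini–Hochberg
   control; significant if adjusted p < 0.05 and |ΔΨ| ≥ 0.1.
5. **Composition** — per sample, the relative frequency
   rf(event i) = Ψᵢ / Σⱼ Ψⱼ, aggregated over the 7 types and compared
   between strata with Wilcoxon and Kolmogorov–Smirnov tests.
6. **Associations** — Spearman gene–gene correlations, hypergeometric
   gene-set over-representation (gene ratio = hits / set size), and the
   IHC combined score (percentage bin 0–4 × intensity 0–3, range 0–12).

A synthetic-cohort generator with planted ground truth (driver mixture,
shifted events, composition bias) makes every stage testable without any
external data; see the methods vignette
(`vignettes/splicing-strata-methods.Rmd`) for the model, defaults and
limitations.

## Worked example

Simulate a 94-sample cohort with a trimodal driver and planted splicing
shifts, then run every stage:

```r
library(spliceStrata)
cfg <- pipeline_config(outdir = "demo_out", overrides = list(seed = 7L))
run_pipeline(cfg)   # simulate -> events -> psi -> strata -> diffsplice
                    #          -> composition -> report

table(read_strata("demo_out/strata.tsv")$labels)
#>          low intermediate         high
#>           28           39           27
```

The mixture recovers three expression groups. Differential splicing
between the high and low strata:

```r
ds <- read.delim("demo_out/diff_splicing.tsv", comment.char = "#")
sum(!is.na(ds$adj_p)); sum(ds$significant)
#> [1] 70
#> [1] 35
head(ds[order(ds$adj_p), c("event_type", "delta_psi", "adj_p")], 3)
#>   event_type delta_psi       adj_p
#> 1         A3 0.3020326 4.15383e-10
#> 3         A3 0.3027060 4.15383e-10
#> 4         A3 0.2770317 4.15383e-10
```

All 70 planted events are quantified and tested; the 35 events the
generator shifted (ΔΨ = 0.3) are exactly the significant ones. The
composition comparison shows the planted directional pattern — SE/A5/A3
over-represented in the high stratum, MX/AF/AL in the low stratum:

```r
read.delim("demo_out/composition_comparison.tsv", comment.char = "#")
#>   event_type mean_rf_high mean_rf_low wilcoxon_p significant
#> 1         SE       0.1920       0.149   2.08e-10        TRUE
#> 2         MX       0.0974       0.137   2.08e-10        TRUE
#> 3         A5       0.2071       0.174   2.08e-10        TRUE
#> 4         A3       0.1847       0.143   2.08e-10        TRUE
#> 5         RI       0.1287       0.124   2.08e-10        TRUE
#> 6         AF       0.0808       0.121   2.08e-10        TRUE
#> 7         AL       0.1093       0.151   2.08e-10        TRUE
```

(`mean_rf_*` are unitless relative frequencies summing to 1 per sample;
RI was simulated neutral but moves slightly because relative frequencies
are compositional.)

The same stages run from the command line:

```sh
Rscript inst/cli/splicestrata simulate --outdir demo_out --seed 7
Rscript inst/cli/splicestrata events   --outdir demo_out
```

Real-data runs replace the `simulate` stage by pointing `annotation`,
`tpm`, `counts` and `driver_gene_id` in the config at your own files
(`write_pipeline_config()` / `--config`).

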