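# conjfdr

Cross-trait pleiotropy analysis of GWAS summary statistics in R: conditional
and conjunctional false discovery rates, stratified conditional Q-Q curves,
MAF-aware LD pruning, and two-sample Mendelian randomization.

## The problem

Two complex traits — say neuroticism and birth weight — can share genetic
architecture even when no single SNP reaches genome-wide significance in
either scan alone. Given only the two traits' per-SNP p-values, `conjfdr`

1. **harmonizes** the two summary-statistics tables on rsID,
2. **prunes** linked SNPs (windowed greedy removal at `r² > 0.2`, dropping
   the smaller-MAF member of each linked pair),
3. draws **stratified conditional Q-Q curves** — trait A's p-value quantiles
   within SNP strata `p_B ≤ 1, 0.1, 0.01, 10⁻³, 10⁻⁴`; progressive leftward
   deflection is the classic signature of pleiotropic enrichment,
4. computes the per-SNP empirical **conditional FDR**

   cFDR(A|B)ᵢ = min(1, p_{A,i} · #{j : p_{B,j} ≤ p_{B,i}} /
   #{j : p_{A,j} ≤ p_{A,i} ∧ p_{B,j} ≤ p_{B,i}})

   in both conditioning directions, and the **conjunctional FDR**
   ccFDRᵢ = max(cFDR(A|B)ᵢ, cFDR(B|A)ᵢ), small values of which flag SNPs
   associated with *both* traits,
5. **selects** significant SNPs (cFDR < 0.01, a strict 0.001 tier, and
   pleiotropic SNPs at ccFDR < 0.05) with Manhattan-plot and BED exports, and
6. estimates the **causal effect** between the traits with five two-sample
   MR estimators: inverse-variance weighted (IVW), MR-Egger, weighted
   median, and the simple/weighted mode.

A synthetic-data generator draws paired z-scores from a four-component
mixture (null/null, A-only, B-only, shared) with optional block-equicorrelated
LD and per-SNP MAF, so every stage can be validated against known labels.

## Worked example

```r
library(conjfdr)

spec <- mixture_spec(pi00 = 0.90, pi10 = 0.04, pi01 = 0.04, pi11 = 0.02,
                     sigma_a = 3, sigma_b = 3, n_snps = 50000, seed = 42)
sim <- simulate_paired_stats(spec)
tab <- cfdr_table(sim$stats)
rep <- select_by_threshold(tab, "ccfdr", 0.05)
rep
#> selection_report: 154 SNP(s) with ccfdr < 0.05
mean(sim$labels[match(rep$selection$snp, sim$stats$snp)] == "shared")
#> [1] 0.9220779
```

154 of 50,000 SNPs are called pleiotropic at ccFDR < 0.05; 92% of them are
truly shared (the generator planted 2%, i.e. ~1,000, most too weak to
detect), so the realized false-discovery proportion (8%) is near the
nominal 5% level. The strongest calls:

```r
head(tab[order(tab$ccfdr), c("snp", "chr", "pos", "p_a", "p_b", "ccfdr")], 3)
#>             snp chr      pos      p_a      p_b    ccfdr
#> 30068 rs0030068  14  5190000 8.22e-11 5.62e-11 8.22e-09
#> 13719 rs0013719   7   810000 1.00e-09 1.83e-20 9.01e-09
#> 40094 rs0040094  18 14540000 4.19e-10 1.83e-14 1.68e-08
```

MR on a simulated instrument set with true causal slope 0.3:

```r
set <- simulate_mr_instruments(mr_sim_spec(n_instruments = 50,
                                           true_effect = 0.3, seed = 11))
mr_all(set, seed = 7)$table[, c("method", "b", "se", "pval")]
#>                      method     b     se     pval
#> 1                  MR Egger 0.347 0.1067 2.08e-03
#> 2           Weighted median 0.311 0.0655 2.02e-06
#> 3 Inverse variance weighted 0.322 0.0438 2.19e-13
#> 4               Simple mode 0.374 0.1230 2.40e-03
#> 5             Weighted mode 0.330 0.0991 8.57e-04
```

All five estimators bracket the true slope 0.3 within their standard errors.

## Command line

```sh
Rscript -e 'conjfdr::conjfdr_cli()' run-all \
  --sumstats-a trait_a.tsv --sumstats-b trait_b.tsv \
  --cfdr-threshold 0.01 --ccfdr-threshold 0.05 \
  --strata 1,0.1,0.01,0.001,0.0001 --out run_dir --seed 1
```

Subcommands `simulate`, `merge`, `prune`, `qq`, `cfdr`, `select`, `mr` run
single stages; `--config file` accepts `key = value` settings. The run
directory contains the merged and pruned tables, Q-Q curve data, the full
cFDR table, selection reports at all three thresholds, MR results and a
JSON run summary with per-stage row bookkeeping.

## Vignette

See `vignettes/cross-trait-pleiotropy.Rmd` for the statistical model,
estimator conventions, what the synthetic generator does and does not
emulate, and known limitations.
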