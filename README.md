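# rohdiv

Genome-wide diversity, runs of homozygosity (ROH) and effective population
size from SNP-array genotypes of a single population — the standard
workflow of conservation genetics in dog breeds and other small, closed
populations, implemented as a tested, reusable R package.

Given PLINK-format genotypes (text PED/MAP or binary BED/BIM/FAM), rohdiv

* applies array quality control (autosomes only; locus call rate ≥ 0.95;
  MAF ≥ 0.05; individuals with > 10% missingness removed);
* computes per-locus and mean observed/expected heterozygosity, MAF, the
  population inbreeding index
  `F_IS = (1/L) Σ (1 − H_O,l / H_E,l)`, and per-individual
  method-of-moments inbreeding from homozygosity excess;
* detects ROH with the sliding-window procedure (50-SNP windows, ≤ 1 het
  and ≤ 2 missing calls per window, window fraction ≥ 0.05, minimum
  length 1 Mb, ≥ 1 SNP / 50 kb, gaps ≤ 100 kb), with the minimum SNP
  count set by the false-positive bound
  `s = ⌈ ln(α/(N·L)) / ln(1 − H̄_O) ⌉`;
* derives `F_ROH = Σ L_ROH / L_AUTO` per individual against the
  SNP-covered autosome length, tabulates ROH by length class, and maps
  per-SNP ROH incidence and shared "islands";
* prunes SNPs by variance inflation factor (VIF < 2, 50-SNP windows,
  5-SNP step) and estimates contemporary Ne from mean inter-chromosome
  r² with the standard small-sample correction,
  `N̂e = (1/3 + √(1/9 − 2.76 r²_drift)) / (2 r²_drift)`;
* ships a seeded genotype simulator (Poisson marker maps, Hardy-Weinberg
  genotypes, plantable homozygous IBD tracts with known per-individual
  F_ROH, Wright-Fisher drift populations) so the whole pipeline is
  testable without any data download.

See `vignettes/rohdiv-methods.Rmd` for the full methods account.

## Worked example

Simulate 24 individuals on a dense 5-chromosome map, plant per-individual
homozygous tracts with known F_ROH, and run the full pipeline:

```r
library(rohdiv)

cfg <- synth_config(n_individuals = 24, n_chromosomes = 5,
                    chrom_length_bp = 52e6, snp_spacing_bp = 13e3,
                    missing_rate = 0, seed = 42)
set.seed(42)
targets <- runif(24, 0.05, 0.225)
d <- simulate_dataset(cfg, target_f_roh = targets)

b <- run_pipeline(d$genotypes, out_dir = "results_demo")
print(b$qc_report)
#> QC report
#>   loci: 19791 in -> 18595 out
#>     removed: unmapped=0 sex=0 call-rate=0 maf=1196
#>   individuals: 24 in -> 24 out (removed 0)
print(b$diversity)
#> H_O  = 0.3210 (sd 0.1253)
#> H_E  = 0.3572 (sd 0.1210)
#> MAF  = 0.2664 (sd 0.1297)
#> F_IS = 0.0857 (over 18595 loci)
attr(b$roh_segments, "min_snps")
#> [1] 42
b$roh_classes
#>   class n_runs mean_length_mb
#> 1   1-2    274       1.456530
#> 2   2-4    140       2.904394
#> 3   4-8     29       5.267819
#> 4  8-16      1      10.331657
head(b$inbreeding, 3)
#>   individual_id n_segments sum_l_roh      f_roh   f_marker
#> 1       ind_001         23  50849965 0.19567027 0.16002799
#> 2       ind_002         25  56683124 0.21811622 0.16032911
#> 3       ind_003         11  25769463 0.09916069 0.03250401
b$inbreeding_correlation
#> [1] 0.98
mean(abs(b$inbreeding$f_roh - targets))
#> [1] 0.0063
```

Reading the output: planting is Hardy-Weinberg homozygosity inside tracts
of published length classes, so QC keeps ~94% of loci (only the MAF
filter bites on an error-free simulation); the derived minimum run size
is 42 SNPs at this scale; recovered `f_roh` tracks the planted targets
with mean absolute error 0.0063; and the two molecular inbreeding
measures correlate at r = 0.98, as expected when all inbreeding signal
comes from ROH.

Effective population size from a drifting Wright-Fisher population of
true size 50:

```r
g <- simulate_drift_population(true_ne = 50, n_sampled = 50,
                               n_loci = 2000, seed = 1)
estimate_ne(g)
#> LD Ne: n_pairs=1619598 S=50.0 mean_r2=0.02628 r2_drift=0.00500 ne_hat= 64.5 (ok)
```

A shell entry point with the same stages and flags lives at
`inst/scripts/rohdiv-pipeline.R`:

```sh
Rscript inst/scripts/rohdiv-pipeline.R --simulate --seed 1 --out demo_out
Rscript inst/scripts/rohdiv-pipeline.R --in mypanel --out mypanel_out --vif 2
```

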