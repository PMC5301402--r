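# vgrscan

Detects **variable genomic regions (VGR)** — genomic intervals where two
related populations differ strongly in allele frequency — from SNP-array
genotypes. The package was built for two-cohort designs such as a local
breed versus a derived strain, where the question is which parts of the
genome were reshaped by crossbreeding, introgression and selection, and
where naive association between marker and cohort label is confounded by
relatedness within cohorts.

It implements the full analysis as composable R functions:

- **PLINK text I/O and marker QC** — `read_ped_map()`, `write_ped_map()`,
  `apply_qc()` with the PLINK-style filters `--geno` (missingness),
  `--maf`, `--hwe` (exact test).
- **Per-SNP differentiation statistics** — the Weir–Cockerham (1984)
  fixation-index estimator
  `theta_hat = a / (a + b + c)`, where `a`, `b`, `c` are the
  among-population, among-individual and within-individual variance
  components; Fisher's exact allelic test (PLINK two-sided convention);
  the exact Hardy–Weinberg test; Pearson's chi-square; the genomic
  inflation factor `lambda = median(chi2) / 0.4549`; Bonferroni
  thresholds.
- **EMMAX-style mixed-model association** — `ibs_kinship()` builds the
  identity-by-state relationship matrix; `emma_reml()` fits
  `y = X beta + u + e`, `Var(y) = sigma_g^2 K + sigma_e^2 I` by REML on
  the null model via eigendecomposition; `emmax_scan()` tests every
  marker by generalized least squares with the variance components held
  fixed, using the cohort label (0/1) as the phenotype.
- **Region calling** — `call_regions()` applies the peak-extension rule:
  the top `n_top` ranked SNPs seed regions, SNPs in the top 0.5% within
  1.5 Mb extend them, overlapping regions merge;
  `intersect_region_sets()` keeps only regions supported by both the
  Fst and the mixed-model scans.
- **Annotation** — `annotate_regions()` maps VGR to user-supplied
  candidate-gene intervals (BED or TSV), reporting inside / overlapping /
  proximal relations.
- **Synthetic data** — `simulate_dataset()` draws two cohorts under the
  Balding–Nichols model with planted divergent regions, optional full-sib
  pairs and missingness, so every stage is testable without external
  data; `recovery_score()` scores called VGR against the planted truth.

## Worked example

Simulate a study of 41 + 141 individuals at 5,000 SNPs with background
divergence F = 0.05 and two planted regions at F = 0.5, then run the whole
pipeline (QC, both scans, region calling, intersection):

```r
library(vgrscan)

cfg <- sim_config(n_pop_a = 41, n_pop_b = 141, n_chrom = 5,
                  markers_per_chrom = 1000, f_background = 0.05,
                  planted_regions = data.frame(chrom = c("2", "4"),
                                               start_bp = c(30e6, 60e6),
                                               end_bp   = c(33e6, 63e6)),
                  seed = 42)
run <- run_pipeline(pipeline_config(sim = cfg,
                                    region = region_params(n_top = 10),
                                    out_dir = "vgr_out", seed = 42))
run
#> vgrscan pipeline run (seed 42 )
#>   markers: 5000 -> 4713 after QC; 182 samples
#>   lambda: Fisher 7.34 | EMMAX 1.18
#>   regions: 2 Fst-side, 2 EMMAX-side, 2 dual-support VGR
#>   recovery: sensitivity 1.00, 0 false positive(s)

run$vgrs
#>   vgr chrom start_bp   end_bp plink_peak_pos plink_peak_value emmax_peak_pos
#> 1   1     2 30084997 32910659       31066408            1.000       31066408
#> 2   2     4 60056256 62458497       60056256            0.873       60056256
#>   emmax_peak_value
#> 1        1.00e-300
#> 2         1.77e-29
```

Both planted regions come back as dual-support VGR: the table gives each
region's span, the Fst peak (`plink_peak_value`, here 1.00 and 0.87) and
the mixed-model peak p-value. The Fisher inflation factor (7.34) reflects
genuine genome-wide divergence between the cohorts; the mixed model
absorbs the cohort structure through the kinship matrix (lambda 1.18).
`vgr_out/` holds the serialized tracks, kinship, region tables
(TSV + BED), Manhattan plots and a JSON run manifest.

A command-line wrapper with PLINK-style flags is installed at
`inst/cli/vgr-pipeline.R`:

```sh
Rscript inst/cli/vgr-pipeline.R --ped study.ped --map study.map \
    --geno 0.1 --maf 0.05 --hwe 0.001 --n-top 50 --window-mb 1.5 \
    --genes candidates.bed --out study_vgr
```

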