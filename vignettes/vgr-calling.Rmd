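---
title: "Calling variable genomic regions between two populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling variable genomic regions between two populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vgrscan)
```

## The problem

Two related populations — in the motivating setting, a hardy local sheep
breed and a highly prolific strain derived from it by crossbreeding and
introgression — are genotyped on the same medium-density SNP array. The
question is which genomic intervals differentiate them: regions reshaped
by selection, introgression of major genes, or drift. Two complications
shape the design. First, allele frequencies differ genome-wide between
any two breeds, so "significance" of a single marker is less informative
than its rank within the genome-wide distribution. Second, the cohorts
carry internal structure (families, flocks), which inflates naive
association tests between marker and cohort label.

`vgrscan` addresses this with two complementary scans run on the same
QC'd genotypes, followed by a rank-based region caller that only reports
regions supported by **both** scans:

1. a counts-based scan: per-SNP Weir–Cockerham Fst and Fisher's exact
   allelic test, blind to within-cohort structure;
2. a mixed-model scan (EMMAX): the cohort label, coded 0/1 and treated as
   a quantitative trait, regressed on each marker with an
   identity-by-state (IBS) kinship matrix absorbing relatedness.

A region flagged by the Fst ranking but not by the mixed model is
suspect of being a relatedness artifact; requiring dual support is the
package's main guard against spurious calls.

## Statistical components

### Weir–Cockerham Fst

For two populations with sample sizes $n_1, n_2$, allele frequencies
$p_1, p_2$ and heterozygote frequencies $h_1, h_2$ at a biallelic locus,
the 1984 analysis-of-variance estimator decomposes allelic variance into
an among-population component $a$, an among-individual-within-population
component $b$ and a within-individual component $c$, and estimates

$$\hat\theta = \frac{a}{a + b + c}.$$

`weir_cockerham_fst()` implements the component formulas exactly (the
test suite checks them against an independent transcription to 1e-12).
$\hat\theta$ is slightly negative on average under no differentiation —
that is a property of the estimator, not a bug — and equals 1 at a fixed
difference. It is undefined when $a + b + c = 0$ (monomorphic locus);
such loci get `NA` and are excluded from ranking. Because the estimator
assumes a common diploid sampling scheme that does not hold for
hemizygous males, Fst is computed on autosomes only; X markers carry
`NA` in the Fst track and can therefore gain region support only from
the mixed-model side.

### Fisher's exact allelic test

The 2×2 table of allele counts (rows = populations) is tested with the
two-sided convention used by PLINK: the p-value sums hypergeometric
probabilities of all tables, with the observed margins, whose
probability does not exceed the observed table's (relative tie slack
1e-7). The implementation enumerates the hypergeometric support directly
(vectorized over markers); on small tables it agrees with both
`stats::fisher.test()` and an exhaustive enumeration oracle to 1e-10.
Counts-based tests use pairwise-complete individuals: missing genotypes
are dropped per marker, never imputed, because exactness of the
conditional distribution depends on the realized counts.

### Marker QC

`apply_qc()` removes markers sequentially by missingness (> 0.1 by
default, PLINK `--geno 0.1`), pooled minor allele frequency (< 0.05,
`--maf`), and the exact Hardy–Weinberg test (p < 0.001, `--hwe`). The
sample set for the HWE test is configurable (`hwe_population`):

- `"pooled"` — both cohorts together (the generic default of
  `qc_params()`);
- `"per_population"` — each cohort separately, a marker failing in
  either;
- `"population_A_only"` — cohort A alone.

`run_pipeline()` defaults to `"population_A_only"`. The reason is
substantive: when the phenotype is case/control (here, the breed label),
PLINK's `--hwe` tests controls only. Testing the pooled cohorts would
reject under the Wahlund effect — pooling two diverged populations
creates a heterozygote deficit proportional to their differentiation —
and would therefore preferentially remove exactly the strongly divergent
markers the scan is looking for. Testing within one cohort measures
genotyping quality, not divergence.

### EMMAX mixed model

`ibs_kinship()` computes $K_{ij}$ as the mean over markers non-missing
in both individuals of $(2 - |g_i - g_j|)/2$, the average fraction of
alleles shared by state; the diagonal is 1 by construction. The kinship
uses autosomal markers by default and includes the tested markers (no
leave-one-chromosome-out), matching standard EMMAX practice. The
heterozygosity-weighted IBS variant offered by some kinship tools is not
replicated; plain IBS is used.

`emma_reml()` maximizes the restricted likelihood of the null model
$y = X\beta + u + e$, $\mathrm{Var}(y) = \sigma_g^2 K + \sigma_e^2 I$,
in the single ratio $\delta = \sigma_e^2 / \sigma_g^2$, after
eigendecomposing the kinship projected orthogonally to $X$. The profile
is evaluated on a $\log_{10}\delta$ grid over $[-10, 10]$ with 100
intervals; each sign change of the derivative is polished with
`uniroot` (tolerance 1e-10), and the best of all candidates and the two
boundaries is returned. A flat profile (e.g. $K = I$, where $\delta$ is
unidentifiable) returns the upper boundary with `degenerate = TRUE`; a
phenotype lying in the kinship's leading eigenspace drives $\delta$ to
the lower boundary (all-genetic), also flagged. With breed as the
phenotype, $\delta$ is typically tiny — the cohort split *is* structure
in $K$ — and that is the expected behaviour, not a failure mode.

`emmax_scan()` then whitens the phenotype, intercept and mean-imputed
dosages by $V^{-1/2}$ and fits each marker by the whitened simple
regression, reporting the Wald statistic $\hat\beta^2/\mathrm{se}^2$
against $\chi^2_1$ (an F-test with $n - 2$ denominator df is available
via `test = "f"`; at $n \approx 180$ the difference is negligible).
Mean imputation is used here (and not in the counts-based tests)
because GLS operates on complete vectors; with ~1% missingness the
attenuation is immaterial. Both autosomes and X are scanned.

### Genomic inflation

`genomic_inflation()` converts p-values to 1-df chi-square quantiles and
returns the median divided by 0.4549364 (the $\chi^2_1$ median). It is
the pipeline's main diagnostic: on genuinely diverged cohorts the
Fisher-track lambda is large (every marker carries true signal plus
structure), while the EMMAX track should sit near 1. Note that a
Fisher-derived lambda is slightly deflated under the null because the
exact test is conservative at the median.

### Region calling

`call_regions()` implements the peak-extension rule. Markers are ranked
(rank 1 = largest Fst or smallest p; ties broken by genome position so
results are deterministic). The `n_top` best markers (default 50) seed
regions; markers ranked in the top `secondary_fraction` (default 0.005,
computed as `ceiling(0.005 * N_ranked)`) and lying within `window_bp`
(default 1.5 Mb) of a seed extend it; the region is the closed span of
seed plus extensions, and overlapping or book-ended regions merge
transitively (book-ended intervals merge to avoid 1-bp artifacts). The
default `n_top` is an explicit count rather than a recomputed fraction
because "top 0.1%" of a ~46k panel is conventionally rounded to a round
seed count. Two open choices were resolved as follows:

- the 1.5-Mb window is anchored on seeds only; extension markers do not
  re-anchor the window (neighbor-of-neighbor chaining arises only
  through region merging);
- `n_top` should be scaled with the panel: 50 seeds in a 46k-marker
  panel is the top ~0.1%, but on a 5k-marker example the same 50 would
  be the top 1% and admit background regions (the README example uses
  `n_top = 10` for this reason).

`intersect_region_sets()` builds the bipartite overlap graph between the
two per-method region sets (closed intervals; zero-length regions are
points, which is what lets single-SNP peaks from the two methods
coincide) and emits one VGR per connected component containing both
methods, spanning the component's union and carrying each side's best
peak.

### Annotation

Gene intervals are read from BED (0-based half-open, converted) or TSV
(1-based closed). The gap between closed intervals $[a,b]$ and $[c,d]$
with $b < c$ is $c - b$. The proximity flank defaults to 3 Mb: "close
to" a region is not a sharply defined notion in this literature, and
3 Mb covers the distances at which candidate genes near (not inside)
regions are conventionally discussed; it is exposed as a parameter.

## The simulator, and what passing tests mean

`simulate_dataset()` draws, per marker, an ancestral frequency
$p_0 \sim U(0.05, 0.95)$ and per population
$p \sim \mathrm{Beta}(p_0(1-F)/F,\ (1-p_0)(1-F)/F)$ — the
Balding–Nichols model, under which loci have expected differentiation
$\approx F$. Neutral loci use `f_background` (default 0.05, a typical
between-breed value within a species); planted regions use their own
`f_selected` (default 0.5, the magnitude of the strongest peaks reported
in between-breed scans). Genotypes are binomial (Hardy–Weinberg within
population); optional full-sib pairs are gene-dropped from simulated
parents; missingness is i.i.d. (default 1%). Balding–Nichols was chosen
over a coalescent backend because it parameterizes Fst directly, making
planted effect sizes interpretable and recovery tests sharp.

`default_study_config()` fixes the study conditions used by the
acceptance experiments: cohorts of 41 and 141, 26 autosomes plus X with
1,724 markers each (46,548 total, within 1% of a 46,563-SNP post-QC
panel), ten planted 2-Mb regions at $F = 0.5$ on autosomes 1–10, 1%
missingness. One pipeline run at this scale takes seconds.

The simulator deliberately omits linkage disequilibrium, recombination
maps, demographic history, sex-specific X dosages and genotyping batch
effects. Consequently, passing recovery tests demonstrate that the
statistics, ranking and interval logic are correct and well calibrated
under the generating model — they do not certify sensitivity on real
arrays, where LD widens peaks and background selection signatures are
not block-shaped.

## Test problem sizes and numerical choices

The suite's experiments (all seeded, all deterministic):

- estimator oracles: 200 random genotype configurations against an
  independent transcription (1e-12); Fisher and HWE exact tests against
  exhaustive enumeration at allele margins ≤ 30 / n ≤ 50 (1e-10);
- null calibration: a panmictic 100 + 100 split at 5,000 markers — mean
  $\hat\theta$ within ±0.01 of 0, Fisher type-I error at $\alpha=0.05$
  inside the exact binomial 99% band, EMMAX lambda in [0.9, 1.1];
- confounding contrast: 200 + 200 individuals composed entirely of
  full-sib pairs, no divergence — median Fisher lambda > 1.2 while
  median EMMAX lambda stays in [0.9, 1.1] (median over three
  replicates);
- REML recovery: $n = 500$ block kinship, $\sigma_g^2 = \sigma_e^2 = 1$,
  200 replicates — median $\hat\delta$ in [0.7, 1.4];
- planted-region recovery: 20 study-scale replicates — median
  sensitivity ≥ 0.8 with ≤ 2 false-positive VGR (observed: sensitivity
  1.0, 0 false positives on the default conditions);
- region-caller equivalence with a brute-force reapplication of the
  rule on 1,000 random small tracks.

Numerical conventions worth knowing: p-values are clamped to
$[10^{-300}, 1]$ (complete separation otherwise underflows to 0);
kinship eigenvalues are clamped at 0 after a PSD check at −1e-8;
zero-variance dosage columns yield `NA` p-values; all intervals are
1-based closed internally, converted at the BED boundary; chromosome
labels sort numerically with X last.

## Limitations

- Exactly two populations; the Fst machinery is the $r = 2$ case.
- No haplotype or LD-aware statistics (XP-EHH-style scans are out of
  scope), and no FDR control over regions — the caller is intentionally
  the rank-based rule, whose output is a candidate list.
- The mixed model supports an arbitrary fixed-effect design in
  `emma_reml()`, but the pipeline exposes the intercept-only null.
- Sample-level QC (per-individual call rate, sex checks) is not
  implemented; inputs are assumed sample-clean.
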