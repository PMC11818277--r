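# qvburden

Rare-variant collapsing analysis of red blood cell (RBC) related phenotypes
in small, deeply phenotyped cohorts — the setting of critically ill
patients, where anemia is common, prognostically important, and partly
heritable, but cohorts are far too small for single-variant association.

## What it does

`qvburden` implements a complete gene-set burden pipeline for exome data:

1. **Variant catalog** — ingest annotated variants (VCF or TSV), decompose
   multi-allelics, classify consequences into impact classes (high-impact =
   splice acceptor/donor, stop gained, frameshift, stop loss, start loss),
   bin population allele frequencies, and summarise the cohort spectrum
   (class shares, AF bins, singletons, SNV/indel types, cohort overlaps).
2. **Qualifying variants (QVs)** — the rare high-impact subset: consequence
   class HI, population AF < 0.001 or absent from the reference database,
   and a cohort allele-count cap `floor(2 n MAF)` derived from an observed
   minor-allele-frequency ceiling (3% by default, giving caps of 3 alleles
   at n = 50 and 4 at n = 77).
3. **Gene sets and burden** — GMT collections with overlap algebra,
   restriction to QV-bearing genes, and per-person burden under the
   dominant model: the number of distinct qualifying sites at which a
   person carries at least one alternate allele.
4. **Association** — the core statistic is the stratified
   Cochran–Mantel–Haenszel test over per-gene carrier 2×2 tables:

   - common odds ratio: `OR_MH = Σ(aᵢdᵢ/nᵢ) / Σ(bᵢcᵢ/nᵢ)`
   - 95% CI from the Robins–Breslow–Greenland variance of `log OR_MH`
   - exact p-values from the convolution of per-stratum central
     hypergeometric distributions of the a-cells (two-sided = twice the
     smaller tail, capped at 1), or the continuity-corrected CMH
     chi-square (df = 1)

   plus an exome-wide single-variant Fisher scan with QQ/Manhattan
   coordinates, Bonferroni threshold and genomic-inflation lambda.
5. **Phenotypes** — longitudinal CBC panels (RBC, HGB, HCT, MCV, MCH,
   MCHC, RDW) reduced to first / final / min–max endpoints (the worst
   value of the stay: series minimum, except RDW where the maximum is
   unfavourable), anemia grading (severe < 80 g/L, moderate 80–109 g/L,
   below the 130/120 g/L male/female reference), Mann–Whitney group
   comparisons and Spearman scale correlations, all under
   Benjamini–Hochberg FDR.
6. **Regression** — OLS of each endpoint on sex, age, clinical status
   (dummy-coded) and per-set QV count, with standardized betas,
   R² + overall-F p, Durbin–Watson, Breusch–Pagan, VIF and Shapiro–Wilk
   diagnostics, screened at FDR 0.1 per analysis family.
7. **Synthetic cohorts** — a generator with full ground truth (variant
   spectrum, planted set-level odds ratios, planted standardized genetic
   effects on RBC endpoints) so every stage is testable without patient
   data.

`run_pipeline()` chains all stages from one YAML config and writes
TSV/JSON outputs plus a reproducibility manifest.

## Worked example

```r
library(qvburden)

cfg <- sim_config(seed = 42, n_samples = 300, n_genes = 120,
                  mean_variants_per_gene = 30,
                  impact_mix = c(HI = 0.2, MISSENSE = 0.3,
                                 SYNONYMOUS = 0.3, OTHER = 0.2),
                  planted_or = 5)
cohort <- simulate_cohort(cfg)

qv <- qualify_variants(cohort$catalog, cohort$genotypes,
                       qv_config(max_cohort_alt_alleles = 18))
groups <- setNames(cohort$phenotype$group, cohort$phenotype$sample_id)
geneset_burden_test(qv, cohort$genotypes, cohort$catalog,
                    cohort$collection, groups[rownames(cohort$genotypes)])
```

```
         set   or ci_low ci_high       p      q strata_used  mode testable significant
1 SET_CAUSAL 9.05  2.544   32.18 0.00025 0.0005           7 exact     TRUE        TRUE
2   SET_NULL 1.48  0.248    8.87 0.98468 0.9847           4 exact     TRUE       FALSE
```

The generator planted a set-carrier odds ratio of 5 on `SET_CAUSAL` and
nothing on `SET_NULL`. The gene-stratified exact CMH test recovers a
significant common odds ratio for the causal set (9.05, 95% CI 2.5–32 —
wide, as expected from a handful of carriers per gene) and leaves the null
set flat. `strata_used` counts the informative per-gene 2×2 tables;
`q` is the BH-adjusted p across the tested sets.

Grading the final hemoglobin endpoints of the same simulated cohort:

```r
ep <- extract_endpoints(cohort$panel)
table(classify_anemia(ep$final[ep$parameter == "HGB"], cohort$phenotype$sex))
```

```
           none below-reference        moderate          severe 
            108             116              75               1 
```

## Vignette

`vignettes/qvburden-methods.Rmd` documents the statistical model, its
conventions (two-sided exact p-value definitions, AF bin boundaries,
dominant-model burden counting), the synthetic-data generator and what
passing tests do and do not establish about real cohorts.
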