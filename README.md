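# lncdiscover

Discovery and characterization of intergenic long non-coding RNAs (lincRNAs)
in acute myeloid leukemia (AML), as a tested, reusable R pipeline.

## What it is for

Novel lncRNAs are found by assembling transcripts from deep RNA-seq of a
disease cohort and filtering the assembled models down to credible,
disease-associated candidates. `lncdiscover` implements that filter cascade
and the downstream analyses such a candidate receives, for
bioinformaticians who want the screening logic and its statistics as
plain, testable functions rather than a one-off script:

* **Discovery cascade** (`run_cascade()`): keep a transcript iff it is
  longer than 200 bp, intergenic with respect to a reference annotation,
  expressed at mean ≥ 0.5 RPKM across all samples, supported by DNase-I and
  H3K4me3 peaks at its TSS (±1 kb), multi-exonic without abnormally long
  exons, and differentially expressed between the disease and normal groups
  (Welch t on log2(CPM+1), Benjamini–Hochberg FDR < 0.05, fold change
  > 1.5). All flags are computed independently, so every rejection carries
  a complete failure attribution.
* **Isoform usage** (`exon_usage()`, `compare_usage()`): alternative
  start/termination exon quantification from exon-level counts, as
  length-normalized usage shares.
* **Cohort statistics** (`bin_expressors()`, `group_association()`,
  `correlation_rank()`, `km_logrank()`, `ph_multivariable()`, `ddct()`,
  `fraction_distribution()`): expressor binning, Kruskal–Wallis + Dunn
  subgroup association, Pearson correlation ranking, Kaplan–Meier/log-rank
  and multivariable Cox survival with censoring at allogeneic stem-cell
  transplantation, plus qPCR ΔΔCT and polysome-fraction utilities.
* **ChIRP-seq post-processing** (`replicate_consensus()`,
  `annotate_peaks()`, `state_enrichment()`, `peaks_to_genes()`,
  `set_overlap_test()`): replicate consensus peaks, one-category-per-peak
  genomic annotation (promoter/UTR/exon/intron/downstream/distal, 3 kb
  windows), chromatin-state enrichment by midpoint permutation, and
  hypergeometric gene-set overlap with an explicit universe.
* **Drug screening** (`fit_4pl()`, `dss()`, `sdss_screen()`):
  four-parameter-logistic dose–response fits, area-based drug sensitivity
  scores (DSS, 0–100), and the selective score sDSS = DSS(KO) − DSS(WT)
  with the ±1 screening filter.
* **Synthetic data** (`simulate_study()` and the `generate_*()` family):
  generates every input with planted ground truth — candidates, decoys
  that each violate exactly one criterion, peak tracks, jittered ChIRP
  replicates, a survival cohort with a planted hazard ratio of 0.63, and
  dose–response plates with a planted sDSS of 1.633 — so the whole
  pipeline is testable end to end without any external data.
* **Orchestration** (`pipeline_config()`, `run_pipeline()`): one YAML-
  configurable entry point running simulate → discover → isoform → cohort
  → chirp → drugscreen into stage directories with a JSON + Markdown
  report, deterministic given the seed.

All genomic intervals are `GRanges`; GTF and BED/narrowPeak I/O goes
through `rtracklayer`; survival models through `survival`; curve fitting
through `minpack.lm`.

## Worked example

Simulate the default study and run the discovery cascade:

```r
library(lncdiscover)

sim  <- simulate_study(sim_config(seed = 1))
disc <- run_cascade(sim$assembled, sim$reference, sim$counts, sim$groups,
                    sim$tracks$dnase, sim$tracks$h3k4me3)
disc
#> Discovery cascade: 145 transcripts -> 10 candidate(s)
#> log2FC > 0 means higher in AML
#>   fail length_gt_200      5
#>   fail intergenic         5
#>   fail mean_rpkm_ge_0.5   5
#>   fail dnase_support      5
#>   fail h3k4me3_support    5
#>   fail multi_exon         5
#>   fail exon_size_ok       5
#>   fail de_significant     110
```

The 145 assembled transcripts are 10 planted candidates, 35 decoys (5 per
violation class) and 100 stable background transcripts. Each attrition line
counts the transcripts failing that criterion: every decoy class shows up
in exactly its own line, the 100 background transcripts plus the 5 `not_DE`
and 5 unexpressed decoys fail only the DE call, and the candidate set is
exactly the planted one:

```r
setequal(disc$candidates, sim$truth$planted_candidates)
#> TRUE
```

The drug screen recovers the planted selective arsenic-trioxide response
(true sDSS 1.633) and nothing else passes the ±1 filter:

```r
head(sdss_screen(sim$plates, "KO", "WT", threshold = 1), 3)
#>               drug dss_a dss_b  sdss passes_filter
#> 1 arsenic_trioxide  42.5  40.9  1.62          TRUE
#> 2           drug_F  41.4  41.6 -0.25         FALSE
#> 3           drug_H  17.2  17.0  0.20         FALSE
```

`dss_a`/`dss_b` are the per-group drug sensitivity scores (0 = inactive,
100 = full inhibition over the whole dose range); `sdss` is their
difference, so positive values mean the knockout line is more sensitive.

A multivariable proportional-hazards model on the simulated cohort
(n = 300, planted hazard ratio 0.63 for the high-expression group, records
censored at transplantation):

```r
grp <- median_split(sim$cohort$expression)
ph_multivariable(
  data.frame(time = sim$cohort$os_days, event = sim$cohort$os_event,
             expr_high = as.integer(grp == "high"),
             age = sim$cohort$age, NPM1 = as.integer(sim$cohort$NPM1)),
  c("expr_high", "age", "NPM1"),
  transplant_time = sim$cohort$transplant_days)
#>   covariate    coef    HR ci_lower ci_upper        p flagged
#> 1 expr_high -0.3178 0.728    0.522     1.01 6.07e-02   FALSE
#> 2       age  0.0371 1.038    1.021     1.06 1.09e-05   FALSE
#> 3      NPM1 -0.4927 0.611    0.420     0.89 1.02e-02   FALSE
```

The hazard ratio for the high-expression group is an estimate from one
n = 300 cohort; across 100 replicates at n = 2000 the Wald CI covers the
planted 0.63 at nominal rates (see the acceptance script below).

The full pipeline, one call:

```r
run_pipeline(pipeline_config(out_dir = "run1", seed = 1))
```

writes `run1/simulate/`, `run1/discover/`, …, `run1/summary.json` and
`run1/report.md`; rerunning with the same config and seed reproduces
`summary.json` byte for byte.

## Vignette

`vignettes/lncrna-discovery-methods.Rmd` documents the model and every
statistical and numerical choice: the filter definitions and their
boundary conventions, the DE engine substitution, what the synthetic
generator emulates and what passing tests do and do not show about real
data, tie rules, degenerate-input behaviour, and known limitations.
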