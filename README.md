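# fociscreen

Quantification of gamma-H2AX foci in lymphocyte nuclei and screening of a
cohort for radiosensitivity outliers.

Gamma-H2AX — histone H2AX phosphorylated at Ser139 — forms a
microscopically visible nuclear focus at each DNA double-strand break.
Scoring the mean number of foci per cell in blood lymphocytes under three
exposure conditions (unirradiated *preexisting* damage; *initial* damage
30 min after 0.5 Gy ex vivo X-rays; *remaining* damage 24 h after 2 Gy)
characterises an individual's DNA damage load and repair capacity.
Individuals whose rates fall far above the cohort's Gaussian-fitted
distribution are candidate radiosensitivity outliers — the people most
likely to suffer radiotherapy-related side effects. This package is for
radiation biologists and biodosimetry labs who want that analysis chain
as tested, scriptable code.

It implements:

* **Image quantification** — maximum-intensity projection of two-channel
  z-stacks (5 planes, 0.75 um apart), Otsu + watershed DAPI nucleus
  segmentation, objective apoptotic exclusion (fragmentation and solidity
  rules), and Laplacian-of-Gaussian spot counting with background-relative
  prominence: `quantify_field()`.
* **Scoring sufficiency** — how many cells must be scored for a stable
  per-individual rate: at each 200-cell checkpoint the agreement
  `100 x mean(first n) / mean(first N)` is compared against a +/-15%
  tolerance band: `cumulative_agreement()`, `fraction_within_tolerance()`,
  `minimum_cells()`.
* **Cohort statistics** — Gaussian fits *N(mu, sigma)* of per-individual
  rates (moment or binned least squares), Kolmogorov-Smirnov and
  Monte-Carlo Lilliefors normality tests, two-sample t-tests with relative
  increases, one-sided SD-exceedance calls
  (`k = max {j : rate > mu + j sigma}`, j in 1..3) against either group's
  fit, and the three-class outlier taxonomy (`preexisting_only` / `both` /
  `remaining_only`): `fit_cohort_distribution()`, `classify_outliers()`,
  `outlier_taxonomy()`.
* **Synthetic data** — a cohort generator (truncated-Gaussian
  between-individual rates, Poisson or negative-binomial within-individual
  counts, planted outlier subpopulations) and a two-channel microscope
  simulator with ground truth: `generate_cohort()`, `generate_zstack()`.
* **A pipeline driver** — `run_pipeline()` with YAML configuration and a
  run manifest; a thin CLI lives in `inst/scripts/foci-pipeline.R`
  (verbs `simulate`, `quantify`, `sufficiency`, `stats`, `all`).

## Worked example

```r
library(fociscreen)

params  <- cohort_params(seed = 7)        # 59 healthy (HI), 136 patients (RC)
cohort  <- generate_cohort(params)        # per-cell counts + planted truth
summaries <- summarize_individuals(cohort$records)
head(summaries, 3)
#>   individual_id group   condition mean_foci n_cells sufficient
#> 1        HI_001    HI     initial     4.731    1000       TRUE
#> 2        HI_001    HI preexisting     0.730    1000       TRUE
#> 3        HI_001    HI   remaining     2.103    1000       TRUE
```

Fit the patient distribution and call outliers at the 2-SD cut-off in the
two informative conditions:

```r
rcs     <- summaries[summaries$group == "RC", ]
fit_pre <- fit_cohort_distribution(
  rcs$mean_foci[rcs$condition == "preexisting"], group = "RC",
  condition = "preexisting")
fit_pre
#> Gaussian fit (moment): mu = 0.864, sigma = 0.759 foci/cell, n = 136
fit_rem <- fit_cohort_distribution(
  rcs$mean_foci[rcs$condition == "remaining"], group = "RC",
  condition = "remaining")

tax <- outlier_taxonomy(
  classify_outliers(rcs, fit_pre, "preexisting"),
  classify_outliers(rcs, fit_rem, "remaining"))
table(tax$class)
#>             both             none preexisting_only   remaining_only
#>                7              117                6                6
```

19 of 136 patients (14%) are flagged; the generator planted 20. The
`cohort$truth` table says which, and comparing the two shows every flagged
individual was planted: one planted outlier fell just short of the 2-SD
line, and a few planted `both` individuals were caught in only one
condition. With outliers disabled
(`cohort_params(outlier_fraction = 0, seed = 7)`) the same machinery
reports the bulk group difference instead:

```r
#> preexisting mean HI 0.518  mean RC 0.591  increase 14.1%  p 0.00017
#> remaining   mean HI 2.698  mean RC 2.837  increase  5.2%  p 0.066
```

i.e. a modest, statistically visible elevation of patient damage rates —
the sampled-cohort analogue of the calibrated population difference
(0.49 vs 0.59 and 2.63 vs 2.97 foci/cell).

And from images instead of count tables:

```r
truth <- simulate_image_truth(n_nuclei = 25, mean_foci = 2, seed = 11)
stack <- generate_zstack(truth)       # 512 x 512 x 5 planes, 2 channels
field <- quantify_field(stack)        # project -> segment -> QC -> count
mean(field$records$foci_count)        # vs mean(truth$nuclei$n_foci)
```

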