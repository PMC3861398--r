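# nestmorph

Tumor-nest morphometrics and prognostic scoring from stained tissue-core
images.

In invasive carcinomas, tumor cells grow as *nests* — connected epithelial
islands surrounded by stroma — and the geometry of those nests carries
prognostic information. Given brightfield images of cytokeratin/DAB-stained
tissue-microarray cores and a clinical table with follow-up, nestmorph:

1. **segments** the DAB-positive nests (H-DAB color deconvolution, Otsu
   binarization, morphological opening, hole filling, optional scripted
   expert overrides, 8-connected labeling with a minimum object size);
2. **measures** eight per-core parameters: nest number, total and average
   perimeter, total and average area, total-area/total-perimeter, average
   area/perimeter, and circularity
   `(1/n) * sum(4 * pi * A_i / P_i^2)` — areas are pixel counts, perimeters
   are Moore-contour lengths with sqrt(2) diagonal steps;
3. **grades** each parameter into I/II/III by an exhaustive best-P
   two-cutpoint search (the X-tile principle): over all ordered pairs of
   observed values whose three induced groups each hold at least 10% of the
   cohort, pick the pair maximizing the 2-df log-rank chi-square. Grade
   scores are summed into integrated score 1 (number + circularity + total
   perimeter, range 3-9) and score 2 (the four size/ratio parameters, range
   4-12), each re-divided into low/middle/high tiles by the same search;
4. **evaluates** the result: Kaplan-Meier / log-rank across tiles, Pearson
   chi-square association, ROC for recurrence within five years
   (trapezoidal AUC with Hanley-McNeil CI), and a multivariate Cox model
   with Efron ties and ordinal coding of graded variables.

Because the best-P search is anti-conservative by construction, every
cutpoint result reports both the raw p-value and a labeled
selection-corrected p-value (Sidak bound over the scanned grid).

No public imaging cohort accompanies this problem, so the package includes
a first-class synthetic-data module: seeded core images with exact analytic
ground truth (circle / ellipse / perturbed-ellipse "blob" nests, unstained
vessel- and nerve-like distractors, Gaussian noise) and survival cohorts
with a known log-linear score-hazard law. The whole pipeline is exercised
end to end on a default bundle of 404 cores / 202 patients.

## Worked example

```r
library(nestmorph)

spec <- syntheticImageSpec(n_nests = 8, shape_family = "circle",
                           noise_sd = 0, size_range_px = c(12, 25),
                           seed = 42)
sim <- simulateCoreImage(spec)
res <- coreFeaturePipeline(sim$image)
res$segmentation
#> NestSegmentation: 8 nests on 512 x 512 raster
res$features
#>   core_id number total_perimeter average_perimeter total_area average_area
#> 1   core1      8        1039.117          129.8896      10490      1311.25
#>   ta_over_tp avg_a_over_p circularity degenerate
#> 1   10.09511     9.788987   0.9478224      FALSE
```

All 8 ground-truth nests are recovered; the per-nest pixel areas match the
analytic circle areas to well under 1%, and the mean circularity of the
digitized disks is 0.948 (a perfect continuous disk scores exactly 1; the
Moore-contour digitization of mid-sized disks lands a few percent below).

Grading and survival, on a synthetic cohort with a known hazard ratio of
1.5 per score step:

```r
cohort <- simulateCohort(syntheticCohortSpec(n_patients = 2000,
                                             baseline_hazard = 0.02,
                                             seed = 60601))
coxMultivariate(cohort, "score1")$table
#>   covariate       hr       lo       hi           p
#> 1    score1 1.496151 1.432541 1.562585 7.987748e-74
```

The full pipeline (simulate images + clinical table, segment, measure,
grade, evaluate, report) runs from one config:

```r
cfg <- runConfig(out_dir = "my_run", seed = 1)
runAll(cfg)   # writes features_cores.csv, grades.csv, results.json, report.md
```

or from the shell via the thin CLI wrapper
(`inst/cli/nestmorph run-all --config config.json`), whose commands
`simulate / segment / features / grade / survival / report / run-all` map
onto the exported `run*()` functions and whose exit codes distinguish
config errors (2), data errors (3) and statistical degeneracy (4).

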