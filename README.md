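# riskclust

Unsupervised discovery of distinct subgroups in high-risk patient cohorts.

## The problem

Risk models used in population health management assign each patient a
percentile risk of hospitalization or death, and patients above a cutoff
(here: percentile ≥ 75) are managed as "high risk". But high-risk patients
are heterogeneous — a frail home-bound 85-year-old, a patient with
metastatic cancer, and a patient with untreated polysubstance use all score
high for entirely different reasons — and one-size-fits-all care programs
serve them poorly. `riskclust` implements a pipeline that partitions a
high-risk cohort, described by a mixed-type administrative/EHR feature
table (sociodemographic, comorbidity, psychobehavioral, pharmacy, vitals,
laboratory, and prior-utilization domains), into *distinct, homogeneous*
subgroups while leaving atypical patients unassigned as outliers.

## The method

For a standardized patient × feature matrix **X** (n × p):

1. **t-SNE** maps **X** to two dimensions. Per-point Gaussian bandwidths
   σᵢ are calibrated so each conditional distribution p(j|i) ∝
   exp(−‖xᵢ−xⱼ‖²/2σᵢ²) has a target perplexity (2^H = Perp); the joint
   P = (p(j|i)+p(i|j))/2n is matched to a Student-t kernel
   Q ∝ (1+‖yᵢ−yⱼ‖²)⁻¹ by gradient descent on KL(P‖Q) with exact O(n²)
   gradients.
2. **OPTICS** orders the embedded points by density reachability: the core
   distance of a point is the distance to its min_pts-th neighbor, and
   reachability(q) = max(core(p), d(p,q)) along a smallest-reachability
   priority queue. Flat clusters come from a reachability cut ε′ (or
   ξ-steep areas); points outside any cluster keep a reserved noise label.
   min_pts and the cut are tuned on separate training subsamples by
   median silhouette with a penalty toward a 25% outlier fraction.
3. **One-versus-rest ridge profiling**: for each cluster c and each of 100
   penalties λ on a log grid, solve
   β̂(λ) = (XᵀX + λI)⁻¹ Xᵀ(y − ȳ) with y = 1[cluster = c] (noise
   excluded, intercept unpenalized), average β̂ over the grid, and scale to
   unit max |β|. The per-variable **range** of these normalized
   coefficients across clusters (max − min) ranks variables by how much
   they discriminate subgroups; the top 20 are flagged and every cluster
   gets a top-5 evidence list with a suggested category
   (comorbidity / sociodemographic / psychobehavioral).
4. **Reporting**: per-cluster two-year outcomes — mortality, any
   hospitalization, mean inpatient days, ED visits — with outliers as a
   first-class row.

Because the real cohorts this design targets live in restricted data
warehouses, the package ships a synthetic cohort generator
(`study_structure()`, `generate_cohort()`) that plants known subgroup
structure — 12 subgroups with broad clinical, psychobehavioral, or
sociodemographic signatures, 25% deliberately unclusterable background,
repeated lab/vital measures, pharmacy fill histories, missingness, and
subgroup-linked outcomes — so the whole pipeline is testable against
ground truth.

## Worked example

```r
library(riskclust)
result <- run_pipeline(list(seed = 1))
result
#> pipeline_result: 12 clusters on the validation set (38.0% noise)
#>   planted-label ARI (clustered points): 0.947
head(result$outcomes[, c("group", "n", "mortality_pct", "mean_ip_days")])
result$evidence[["2"]]$evidence   # top-5 variables for cluster 2
```

The pipeline generates a 3,000-patient synthetic cohort, prepares ~116
analysis variables (pruning two planted near-duplicates and two
near-constant flags from 119), draws 5 disjoint risk-stratified sets of
600, embeds and clusters the 4 training sets to tune OPTICS, then clusters
the held-out validation set. The printed summary says the final clustering
found 12 subgroups covering ~62% of validation patients and that, where
ground truth is known, clustered patients agree with the planted labels at
ARI ≈ 0.95. `result$outcomes` is the per-cluster outcome table (observed
two-year mortality spans 0%–56% across clusters, around generative
subgroup values of 1%–45%), and each cluster's evidence list names the variables that
distinguish it — e.g. a cluster whose top variables are `medicaid`,
`homeless`, `copay_exempt` is sociodemographic, not clinical.

A thin CLI wrapping the same functions is installed at
`inst/exec/riskclust` (subcommands `synth`, `features`, `sample`, `embed`,
`cluster`, `tune`, `profile`, `report`, `run-all`).

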