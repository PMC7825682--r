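# cpapnet

Network-medicine analysis of CPAP treatment response in obstructive sleep
apnea (OSA), for sleep-medicine researchers and biostatisticians who want
the whole chain — patient network, phenotype communities, response classes,
screening cutoff — as tested, reusable R functions.

## What it does

Obstructive sleep apnea severity is graded from the apnea–hypopnea index
(AHI, events/h): `norm` (< 5), `mild` (5–15), `mod` (15–30), `sev` (≥ 30).
The package implements a two-stage analysis of how anthropometric risk
factors relate to the AHI drop after one night of CPAP titration:

1. **Risk-compatibility network.** Each patient is discretized into six
   classes (gender; age group; hypertension, BP > 140/90 mmHg; obesity,
   BMI > 30 kg/m²; thick neck, NC ≥ 43 cm men / ≥ 40 cm women; sleepiness,
   Epworth ≥ 11). Patients sharing at least 4 of 6 classes are connected,
   with the shared count (4–6) as edge weight. Communities are found by
   maximizing modularity

   *M* = Σ<sub>C</sub> [ *w*<sub>in</sub>(*C*)/*W* − (*S*<sub>C</sub>/2*W*)² ]

   with a Louvain-style greedy scheme (exhaustively verified against a
   set-partition oracle on small graphs), and each community is labeled a
   **best** (≥ 85% of severe patients reclassified to norm/mild after CPAP)
   or **good** response class. A LinLog-regime force layout
   (attraction exponent 1, repulsion −1) provides the visual diagnostic.
2. **Screening statistics.** Neck circumference as a score for OSA
   diagnosis: tie-aware ROC/AUC (exactly U/(n₁n₂) of the Mann–Whitney
   test), Hanley–McNeil confidence interval, sensitivity/specificity/PPV/
   NPV/LR± tables over integer cm cutoffs, Youden-optimal cutoff, and the
   evaluation of that cutoff against the network's response classes.

Because the underlying clinical datasets are not redistributable, the
package ships a synthetic-cohort generator calibrated to the published
summary statistics (truncated-normal marginals, a Gaussian copula for the
NC–AHI rank correlation, a thick/thin-neck response model, and
planted-community cohorts for recovery benchmarks). See the vignette
`vignettes/cpap-network-analysis.Rmd` for the model and every default.

## Worked example

```r
library(cpapnet)

## stage 2: NC as a screening score on simulated OSA (n=836) vs control (n=65)
cohorts <- generate_screening_cohorts(seed = 1)
roc <- roc_auc(cohorts$neck_circumference, cohorts$osa_label)
roc
#> ROC: AUC 0.751 (95% CI 0.700-0.802), 836 positives / 65 negatives

tab <- cutoff_metrics_table(cohorts$neck_circumference, cohorts$osa_label, 39:46)
round(head(tab, 3), 4)
#>   cutoff sensitivity specificity    ppv    npv lr_pos lr_neg
#> 1     39      0.8923      0.4308 0.9527 0.2373 1.5676 0.2499
#> 2     40      0.8481      0.5077 0.9568 0.2062 1.7227 0.2992
#> 3     41      0.7955      0.5846 0.9610 0.1818 1.9150 0.3499
youden_from_table(tab)
#> [1] 42
#> attr(,"J")
#> [1] 0.4008

## stage 1: network analysis of a simulated one-night CPAP cohort (n=145)
rec  <- generate_d1_like(seed = 1)
prof <- discretize_patients(rec)
net  <- build_network(prof, threshold = 4)
net
#> Risk-compatibility network: 145 patients, 4543 edges (threshold 4/6)
part <- detect_communities(net, seed = 1)
part
#> Community partition: 3 communities, modularity 0.2267

imp <- community_improvements(rec, part)
round(imp, 2)
#>     1     2     3
#> 70.91 89.36 89.74
label_response_classes(imp)$label
#>      1      2      3
#> "good" "best" "best"
```

Reading the output: on this simulated draw the NC screening AUC is 0.751
(a single draw scatters around the ~0.72 long-run mean), and the
Youden-optimal cutoff lands at 42 cm (the across-seed mode is 41 cm). The
simulated CPAP cohort splits into three phenotype communities; the two
whose severe patients were reclassified to norm/mild in ~89% of cases form
the best response class, the 71% community the good one — the thick-neck /
thin-neck response gap built into the generator, recovered by the network
stage. `run_pipeline(pipeline_config(), "out/")` chains both stages and
writes the CSV/JSON/GEXF reports; `inst/cli/cpapnet.R` exposes the same
stages as shell subcommands.

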