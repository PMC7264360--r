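# survmediate

Linked neural-network mediation analysis for censored survival data.

## The problem

A driver gene panel predicts patient survival. Does a candidate *mediator*
gene set — an apoptosis pathway, an immune-response signature — actually carry
that effect? `survmediate` answers this with a linked-network experiment:

- a **direct survival network** maps driver-panel expression to a log-hazard,
  trained with a Cox proportional-hazards partial-likelihood loss
  (Breslow ties):
  `L(h) = -Σ_{i: δ_i=1} [ h_i − log Σ_{j: t_j ≥ t_i} exp(h_j) ]`;
- a **multitask network** predicts mediator-set expression from the driver
  panel (ReLU hidden layers, one regression output per gene, ADAM);
- a **mediator survival network** is trained independently on the *observed*
  mediator expression.

On held-out folds, composing the last two (predicted expression → pre-trained
mediator net) gives a "mediated" hazard. The **percent mediated effect (PME)**
is the censored concordance of the composed hazards restricted to the patient
pairs the direct model ranked correctly: ≈1 means the driver's effect survives
the mediator route, ≈0.5 means no information, ≈0 means inverse mediation.
Calibration uses randomized-hazard nulls (i.i.d. standard-normal hazards, 50
replicates × k folds), paired two-sided Wilcoxon signed-rank tests (exact
distribution for ≤ 12 tie-free pairs), a median p, and a simulated p from
10,000 fresh random-hazard functions pushed through the same machinery.

The package also ships the supporting tooling: censoring-aware concordance and
pair partitioning, Kaplan-Meier / Cox-PH baselines, k-fold cross-validation
with training-fold-only log1p + z-scaling, permutation gene-set benchmarking,
a synthetic-cohort generator with planted mediation structure, and a CLI.

For whom: computational biologists and biostatisticians exploring mediation
hypotheses on expression + survival cohorts (TCGA-like), and methods
developers who need a fully seeded, testable reference implementation.

## Worked example

```r
library(survmediate)

co    <- generate_cohort(synthetic_config(seed = 1))   # 248 genes x 400 patients
folds <- make_folds(co$outcomes$patient_id, 10, seed = 2)

dcfg <- survnet_config(hidden_layer_sizes = 16, epochs = 80, seed = 3)
mtc  <- multitask_config(hidden_layer_sizes = c(32, 32), epochs = 60,
                         weight_decay = 2, seed = 3)
specs <- lapply(c("mediator", "inverse", "null"), function(nm)
  mediation_spec(co$gene_sets$driver_panel, co$gene_sets[[nm]],
                 direct_config = dcfg, mediator_config = dcfg, mt_config = mtc))

reports <- mediation_experiment(co$expr, co$outcomes, specs, folds,
                                n_null_reps = 50, n_sim = 500, seed = 4)
for (r in reports) print(r)
```

Output from this exact run:

```
<mediation_report> mediator: median PME 0.935, median Wilcoxon p 0.001953, simulated p 0
<mediation_report> inverse: median PME 0.173, median Wilcoxon p 0.001953, simulated p 0
<mediation_report> null: median PME 0.679, median Wilcoxon p 0.005859, simulated p 0
```

Reading it: the planted mediator set preserves 93.5% of the direct model's
correct rankings (strong mediation); the planted inverse set reverses them
(PME 0.173, the anti-mediation regime); the null set sits above 0.5 — a known
optimism of composing two networks fit on the same training fold, discussed
under "Known limitations" in the methods vignette
(`vignettes/linked-network-mediation.Rmd`). The randomized-hazard null band in
this run is [0.36, 0.67].

## Command line

```sh
Rscript inst/cli/survmediate simulate --out_dir results --master_seed 7
Rscript inst/cli/survmediate survival --out_dir results   # CV benchmark + 50 permutation sets
Rscript inst/cli/survmediate mediate  --out_dir results   # PME + nulls + simulated p
Rscript inst/cli/survmediate report   --out_dir results
```

Subcommands accept `--config file.json` plus `--key value` overrides; every
output JSON embeds the effective configuration and the master seed. Exit
codes: 0 ok, 1 input error, 2 runtime failure.

Input formats: expression as genes × patients TSV (header row of patient ids,
first column gene ids, empty cell = missing), clinical as TSV with
`patient_id`, `time_days`, `event` (1/0 or true/false), gene sets as GMT.

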