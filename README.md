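# audisem

Semantic labeling and machine-learning comparison for audiometric patient
records.

## What it does and for whom

Population hearing surveys (NHANES-style tables of pure-tone thresholds at
0.5–8 kHz for both ears, plus demographics, comorbidities and lifestyle
factors) ship unlabeled. Audiology and clinical-informatics researchers who
want supervised models on such data first need clinically meaningful labels
for hearing-loss **type** (normal / conductive / sensorineural / mixed),
**severity** (normal / mild / moderate / severe / profound), **laterality**
(bilateral / unilateral left / right) and a **treatment recommendation**.

`audisem` provides:

* derived per-ear clinical quantities — pure-tone average
  (PTA = mean of air-conduction thresholds over 0.5/1/2/4 kHz), mean
  air-bone gap (ABG = mean of per-frequency `max(air − bone, 0)`), and the
  evidence predicates built on them;
* a **forward-chaining rule engine** over an editable 18-rule clinical rule
  base: mixed hearing loss when both conductive evidence (ABG ≥ 15 dB, or
  abnormal tympanogram when bone conduction is unavailable) and
  sensorineural evidence (bone-conduction PTA > 25 dB HL) occur in the same
  patient; severity by worse-ear PTA band with profound strictly above
  90 dB HL; bilateral when both ears have loss (PTA > 25 dB HL); treatment
  by decision table, including cochlear-implant evaluation for bilateral
  severe-to-profound sensorineural loss. Every inference carries a trace of
  fired rule ids, and `validate_rule_base()` proves exhaustiveness and
  exclusivity by brute-force sweep over a 234,256-point feature grid;
* **SNOMED CT mapping** of the label vocabularies (sensorineural 60700002,
  conductive 44057008, mixed 36885005; concepts without an authoritative
  code are retained uncoded);
* a **K-Means baseline** (k = 4 type, k = 5 severity, k = 4 laterality;
  k-means++ with 10 restarts; elbow/silhouette diagnostics; exact optimal
  cluster-to-label assignment);
* a **Random Forest comparison harness** that trains probability forests on
  either labeling strategy and scores both against the semantic reference
  (accuracy, per-class precision/recall/F1, log loss, stratified 5-fold CV);
* a **synthetic cohort generator** with known generative truth, so the whole
  pipeline is testable without downloading anything, plus CSV round-trip IO,
  RDF Turtle export and a CLI (`inst/cli/audisem`).

## Worked example

```r
library(audisem)
g    <- generate_cohort(cohort_config(300, seed = 42))
labs <- label_cohort(g$cohort)
labs[1:3, c("patient_id", "hl_type", "severity", "laterality", "treatment")]
#>   patient_id hl_type severity      laterality           treatment
#> 1     P00001   mixed moderate unilateral_left surgical_evaluation
#> 2     P00002   mixed moderate       bilateral surgical_evaluation
#> 3     P00003  normal   normal          normal          monitoring

annotate_labels(labs[, c("hl_type", "severity", "laterality", "treatment")])[1, c("hl_type", "hl_type_snomed")]
#>   hl_type hl_type_snomed
#> 1   mixed       36885005

compare_strategies(g$cohort, seed = 42, spec = forest_spec(100))
#> <strategy_comparison>
#>                metric rf_kmeans rf_ontology
#>     test_accuracy_pct   64.4068     93.4426
#>  cv_mean_accuracy_pct   67.9640     96.0316
#>            cv_std_pct    3.2773      1.6362
#>      f1_sensorineural    0.5161      0.9767
#>         f1_conductive    0.6667      0.8235
#>              f1_mixed    0.2222      0.6667
#>             f1_normal    0.7667      1.0000
#>              log_loss    5.9691      0.2307
```

Patient 1 has a moderate mixed loss in the left ear only, so the rules
recommend surgical evaluation (the conductive component is potentially
correctable); the mixed type maps to SNOMED CT concept 36885005. In the
comparison, both forests are scored against the rule-engine labels: the
forest trained on rule-engine targets with semantic feature enrichment
reproduces the clinical labels far better than the one trained on
cluster-derived targets, and the gap is widest for mixed hearing loss —
clustering by feature similarity rarely isolates the patients whose
audiograms carry both a conductive and a sensorineural signature.

From a shell:

```sh
Rscript inst/cli/audisem simulate --n 500 --seed 7 --out cohort.csv
Rscript inst/cli/audisem label --in cohort.csv --out labeled.csv
Rscript inst/cli/audisem compare --in cohort.csv --seed 7 --out comparison.csv
Rscript inst/cli/audisem export --in cohort.csv --out cohort.ttl
```

## Package layout

* `R/` — generator, feature derivation, rule engine and rule-file IO,
  SNOMED mapping, K-Means baseline, forest pipeline, CSV/Turtle IO, CLI.
* `inst/extdata/hearing_rules.txt` — the editable 18-rule clinical rule base.
* `inst/extdata/snomed_map.tsv` — the editable SNOMED CT mapping.
* `vignettes/hearing-loss-semantic-labeling.Rmd` — the methods vignette:
  model, assumptions, parameter defaults, design decisions, limitations.
* `tests/testthat/` — unit, property and acceptance tests.
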