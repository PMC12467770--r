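# expressivity

Quantifying what an image classifier silently knows. A model trained only to
detect severe left ventricular hypertrophy (SLVH) from chest-radiograph-like
images is never shown the patient's age, sex, or echocardiographic
dimensions (IVSDd, LVPWDd, LVIDd) — yet an effective model should encode
them, because they drive the label. This package measures that encoding: the
**expressivity** of an attribute in a layer's representation, defined as the
mutual information $I(F;A)$ between the $n \times d$ feature matrix $F$
harvested at that layer and the scalar attribute $A$, estimated neurally and
reported in nats.

The estimator maximizes the Donsker–Varadhan lower bound

$$ I(F;A) \ \ge\ \mathbb{E}_{P_{FA}}[T_\theta(f,a)]
   - \log \mathbb{E}_{P_F\otimes P_A}[e^{T_\theta(f,a)}] $$

with a small critic MLP $T_\theta$ (default 256–64–1, ELU, Xavier; Adam
1e-3, batch 100) scoring matched feature–attribute pairs against mismatched
pairs built by seeded derangements, an EMA-stabilized marginal term in the
gradient, held-out plateau stopping, and averaging over M = 10 independent
seeds. Around this core the package provides everything needed to exercise
it end to end without any external data: a synthetic echo-linked cohort and
toy radiograph renderer with controllable attribute injection (closed-form
true MI for validation), class-balanced subset construction, small conv and
frozen-encoder transformer backbones with early/mid/final layer taps,
AUROC/AUPRC with bootstrap CIs, and a cached, fully reproducible pipeline.

Intended users: researchers auditing what medical-imaging classifiers
internalize (interpretability, fairness screening), and anyone needing a
validated, dependency-light MI probe for learned representations in R.

## Worked example

```r
library(expressivity)

## a cohort whose five attributes are injected into a feature channel at
## known true MI (nats): age 1.0 > sex 0.6 > IVSDd 0.35 > LVPWDd 0.2 > LVIDd 0.05
out <- ordering_experiment(n = 5000, d = 8,
                           train_cfg = mine_train_config(n_seeds = 2),
                           seed = 1)
round(out$estimates, 3)
#>    age    sex  IVSDd LVPWDd  LVIDd
#>  0.986  0.595  0.318  0.184  0.049
out$match
#> [1] TRUE

## expressivity of one attribute in one layer of a trained backbone
cohort <- sample_cohort(cohort_config(n = 1200, seed = 5))
images <- render_images(cohort, render_config(size = 64), seed = 6)
sel    <- make_balanced_subset(cohort$slvh,
                               rep(c("train", "val"), c(1000, 200)), seed = 3)
model  <- build_backbone(backbone_config("conv", input_size = 64,
                                         base_width = 8), seed = 1)
model  <- train_classifier(model, images[sel$train, ], cohort$slvh[sel$train],
                           images[sel$val, ], cohort$slvh[sel$val],
                           train_run_config(learning_rate = 1e-3, epochs = 6,
                                            seed = 101))
feats  <- extract_features(model, images[sel$train, ], "final")
expressivity(feats, attribute_vector(cohort$IVSDd[sel$train],
                                     "continuous", "IVSDd"),
             train_cfg = mine_train_config(n_seeds = 2), seed0 = 7)
#> <expressivity> IVSDd @ final: 0.2095 +/- 0.0268 nats (M = 2 seeds)
```

The first block reads: the estimator recovers the injected hierarchy — its
five estimates sit within a few hundredths of a nat of the designed values
and rank identically. The second reads: after training only on the binary
SLVH label, the classifier's pre-logit layer carries about 0.21 nats of
information about the septal wall thickness it was never shown.

The full pipeline (simulate → balance → train → extract → expressivity →
evaluate → report) runs from one config:

```r
cfg <- run_config(seed = 1, outdir = "my_run")   # desk-scale defaults
run_pipeline(cfg)
report_summary(cfg)
```

or from the shell via `inst/cli/expressivity-pipeline.R` with subcommands
`simulate | balance | train | extract | expressivity | evaluate | report |
run-all` and flags `--config --seed --out --stage --force` (numeric defaults
live in `inst/extdata/default_config.yaml`).

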