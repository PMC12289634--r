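# larynxseg

Semantic segmentation of laryngeal structures in endoscopy frames, in R.

During a continuous laryngoscopy exercise (CLE) test a laryngoscope films
the larynx while the patient exercises; exercise-induced laryngeal
obstruction (EILO) appears as progressive narrowing of the airway.
Assessing it objectively requires delineating, in every frame, the
**trachea** (the dark airway opening, class 1) and the **supraglottis**
(the surrounding mucosal structures, class 2) against background
(class 0). `larynxseg` implements the full pipeline for this three-class
segmentation problem:

* a **seeded synthetic scene generator** — nested-ellipse laryngeal
  scenes with exact ground-truth masks and controllable obstruction,
  illumination, viewing angle and noise — so every stage is testable
  without clinical data;
* **pre-processing**: content-box crop detection on raw frames, paired
  image/mask augmentation (random resized crops, horizontal flips,
  rotation), PCA/t-SNE embedding checks, and seeded 0.7/0.2/0.1
  train/val/test splitting;
* a **hierarchical vision-transformer segmentation model**: overlapping
  patch embeddings (4×4-pixel first-stage patches), a four-stage encoder
  producing a 1/4–1/32 feature pyramid, efficient self-attention with
  key/value sequence reduction
  (reshape N×C → (N/R)×(C·R), then a learned projection back to C),
  Mix-FFN blocks
  `x_out = MLP(GELU(Conv3×3(MLP(x_in)))) + x_in`
  in place of positional encodings, and an all-MLP decoder producing
  per-pixel class logits — with forward *and* analytically derived
  backward passes written in R;
* **training**: pixel-averaged cross-entropy `CE = −Σ t_i log f(s)_i`,
  AdamW (weight decay 1e−2), batch size 4, early stopping after 10
  non-improving validation epochs, best-validation checkpointing;
* **evaluation**: per-class Dice `DSC = 2|T∩P| / (|T|+|P|)` plus IoU,
  F1, precision, recall (macro-averaged over images) and inference
  timing (ms/image, FPS);
* **mask post-processing**: outlier removal (keep the dominant
  connected component), enclosed-gap filling, and disc-based boundary
  smoothing — deterministic, idempotent, and metric-neutral.

## Worked example

Train a micro-capacity model on 60 synthetic 64×64 scenes (training set
doubled by augmentation) and evaluate on the held-out test split:

```r
library(larynxseg)

cfg <- experiment_config(
  n_samples = 60, image_size = c(64, 64),
  train_cfg = train_config(learning_rate = 1e-3, max_epochs = 8, seed = 11))
res <- run_experiment(cfg, verbose = TRUE)
#> epoch   1  train 0.8355  val 0.7031
#> ...
#> epoch   8  train 0.0667  val 0.0576
res$metrics
#>   class      dice       iou        f1 precision    recall
#> 1     1 0.8170583 0.7312604 0.8170583 0.8615250 0.7871070
#> 2     2 0.9631491 0.9291421 0.9631491 0.9679509 0.9584333
```

The loss columns are training/validation cross-entropy per epoch. The
report rows are the two anatomical classes: after eight epochs the model
segments the supraglottis with Dice 0.96 and the thinner, harder trachea
with Dice 0.82 on unseen scenes (post-processing applied). Timing on
this machine: ~34 ms/image, ~30 FPS for the micro model.

Individual stages are exported directly, e.g.:

```r
s     <- render_sample(sample_scene_params(7, obstruction = 0.5))
mask  <- predict(res$model, s$image)       # H x W classes 0/1/2
clean <- postprocess_mask(mask)            # refined mask
dice_score(clean, s$mask, cls = 1)         # trachea Dice
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/larynxseg.R` (subcommands `generate`, `train`, `predict`,
`evaluate`, `postprocess`, `experiment`, `ablation`).

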