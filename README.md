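# annotRR

Reliability metrics for temporal surgical workflow annotations.

Surgical data science starts from temporal annotations: raters mark the
start and end of each **phase** (e.g., gastric pouch creation) and each
**step** (e.g., trocar placement) of an operative video. Whether those
annotations can be trusted is an empirical question about the raters and
the label schema: how well do two raters agree on the same video
(inter-rater reliability), and how consistent is one rater over time
(intra-rater reliability)? `annotRR` is a toolkit for answering it. It
targets surgical data scientists and annotation-team leads who need to
validate a label schema or an annotation workflow before building on it.

The package provides:

* a machine-readable hierarchical **annotation ontology** for laparoscopic
  Roux-en-Y gastric bypass (LRYGB): 12 phases and 46 steps with facultative
  flags and phase→step parentage, shipped as a versioned YAML fixture;
* exact integer-millisecond **interval algebra**: time-weighted confusion
  matrices, accuracy, per-class/macro precision, recall and F1, and Cohen's
  kappa κ = (p_o − p_e)/(1 − p_e), all computed by an interval sweep that is
  provably identical to dense 1 ms sampling;
* the **symmetric protocol** for two human annotations: each is treated once
  as ground truth and metrics are averaged (which forces swap-averaged
  precision to equal swap-averaged recall exactly);
* **application-dependent (AD) metrics**: average transitional delay (ATD),
  coefficient of transitional moments (C_TM), noise level (NL), and
  δ-relaxed accuracy/precision/recall/F1 that forgive label disagreement
  within δ (default 5 s) of a true transition;
* per-video evaluation, cohort **mean ± SD aggregation**, reliability-table
  rendering, duration bar charts and timeline ribbon plots;
* a **synthetic two-rater simulator** — log-normal phase durations,
  facultative-element inclusion, boundary jitter, label substitutions,
  spurious insertions, omissions — so every metric is validated by
  recovering the noise parameters that were injected.

## Worked example

Simulate ten LRYGB-like videos annotated by two noisy raters (2 s boundary
jitter SD, 2% label substitutions, on average 0.5 spurious insertions and
10% facultative omissions per track), then evaluate inter-rater reliability:

```r
library(annotRR)

o  <- load_ontology(lrygb_ontology_path())
pc <- perturbation_config(jitter_sd_ms = 2000, substitution_rate = 0.02,
                          insertion_rate = 0.5, deletion_rate = 0.1)
cohort  <- generate_cohort(o, cohort_profile("strasbourg", o), pc, pc,
                           n = 10, seed = 17)
reports <- lapply(1:10, function(i)
  evaluate_video_pair(cohort$rater_a[[i]], cohort$rater_b[[i]]))
dr <- aggregate_dataset(reports, "sim")
cat(render_table(dr, "text"), sep = "\n")
```

```
sim    Cohen's kappa  Accuracy    Precision    Recall       F1-score     ATD (seconds)  C_TM         NL           AD-accuracy  AD-precision  AD-recall    AD-F1-score
phase  85.1 ± 10.3    87.3 ± 9.0  78.3 ± 13.8  78.3 ± 13.8  76.9 ± 13.7  0.0 ± 0.0      102.3 ± 3.4  14.2 ± 10.5  87.6 ± 9.0   86.7 ± 9.1    79.8 ± 12.8  78.6 ± 12.6
step   92.5 ± 4.5     92.7 ± 4.4  90.2 ± 5.0   90.2 ± 5.0   89.8 ± 5.2   0.0 ± 0.0      100.2 ± 0.2  4.9 ± 2.4    93.8 ± 4.3   94.6 ± 3.3    91.8 ± 4.8   91.5 ± 5.1
```

Reading the numbers: agreement columns are mean ± SD across videos, in
percent. Kappa is slightly below accuracy (it always is — it discounts
chance agreement). Precision equals recall because of the symmetric swap
averaging. C_TM just above 100% and a nonzero NL reflect the injected
spurious insertions; the AD columns sit above their classical counterparts
because the 5 s relaxation absorbs boundary jitter. The swap-averaged
*signed* ATD is 0 by construction — the per-direction values carry the sign:

```r
r <- reports[[1]]$phase
sprintf("%+.2f / %+.2f s", r$directions$a_as_gt$atd_s, r$directions$b_as_gt$atd_s)
#> "+0.24 / -0.24 s"
```

Intra-rater reliability is the same pipeline applied to one rater's two
annotation passes. Annotation CSVs on disk (`read_annotation_file()` /
`write_annotation_file()`) plug into the same functions; a thin command-line
wrapper ships at `inst/cli/annotRR.R`:

```sh
Rscript inst/cli/annotRR.R simulate --profile bern --n 10 --seed 17 --out sim/
Rscript inst/cli/annotRR.R evaluate --a sim/rater_a --b sim/rater_b \
    --delta-seconds 5 --out report/
```

See the vignette (`vignettes/reliability-metrics.Rmd`) for the model,
conventions, and the design of the noise channels.

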