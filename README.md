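# latentreplay

Privacy-aware domain-incremental continual learning on latent feature
vectors, built around KDE-based generative latent replay and
knowledge-distillation regularisation.

## The problem

In clinical image classification — the motivating case is white-blood-cell
(monocyte / eosinophil / lymphocyte) classification across hospitals and
sample sources — the class set stays fixed while the input distribution
shifts between data sources: different scanners, stains, blood vs bone
marrow. Fine-tuning a classifier on each new dataset in sequence
(*domain-incremental learning*) causes catastrophic forgetting: accuracy
on earlier domains collapses. Storing raw past images for rehearsal fixes
this but is often impossible for privacy reasons.

`latentreplay` implements a replay strategy that never stores raw data.
Features are assumed to come from a **frozen backbone**, so each domain is
a labeled set of latent vectors `z ∈ R^d`. The method:

1. **Compress** each task's latents with K-means (`K = 10` centers per
   domain by default; a BIC criterion can choose `K` instead) and retain
   *only the cluster centers*.
2. **Model** all retained centers with a Gaussian kernel density estimate
   whose per-dimension bandwidths follow Silverman's rule,
   `h_j = σ_j · (4 / ((d+2) m))^(1/(d+4))`. The KDE is the generator
   `G^{t-1}` of all past tasks; after 4 tasks with `K = 10` it holds
   exactly 40 support points, independent of the training-set sizes.
3. **Replay**: while training on task `t`, every mini-batch (size 64) is
   an exact 50/50 split of current-task rows and synthetic latents
   sampled from `G^{t-1}`. Synthetic rows get hard pseudo-labels from the
   frozen previous model (the *teacher*).
4. **Distill**: the training loss is
   `loss = (1 − α)·loss_CE + α·loss_KLD`, where `loss_KLD` is the KL
   divergence from the teacher's softmax to the student's, pulling the
   student toward its past behaviour (`α` in `[0, 1]`, grid
   `{0.01, 0.1, 0.2, 0.3, 0.4, 0.5}`, default `0.2`).

Evaluation uses the train-test matrix `P` (`p_ij` = accuracy on task `j`
after training session `i`) and the standard continual-learning metrics:

- `ACC = (1/T) Σ_j p_{T,j}` — mean accuracy after the final session,
- `BWT = (1/(T−1)) Σ_{j<T} mean_{i>j}(p_{i,j} − p_{j,j})` — signed
  backward transfer (negative = forgetting),
- `ILM = (2/(T(T+1))) Σ_{j≤i} p_{i,j}` — mean over the lower triangle.

The trainable model is a small fully-connected head
(`[512, 256, 128, 64, 32]`, ReLU, linear output) over the frozen
features, trained with Adam. Strategies provided: `naive` (sequential
fine-tuning, lower bound), `joint` (train on everything at once, upper
bound), `proposed` (replay + distillation), the single-component
ablations `glr_only` / `dst_only`, and `gmm_replay` (per-domain Gaussian
mixtures instead of the KDE).

A synthetic benchmark generator ships with the package: 4 domains over a
shared 3-class label set in `d = 16` latent space, with controllable
between-domain mean translation, scaling and rotation, so the whole
pipeline runs end to end without any image data. An optional plug-in
boundary (`extract_features()`) accepts real image folders plus any
user-supplied frozen feature extractor.

## Worked example

```r
library(latentreplay)

seq4 <- make_sequence(default_benchmark_specs())  # 4 shifted domains
for (s in c("naive", "proposed")) {
  res <- run_strategy(seq4, run_config(strategy = s, n_repeats = 1),
                      repeat_seed = 1)
  cat(s, "train-test matrix P (rows = after session i):\n")
  print(round(res$P, 1))
  m <- cl_metrics(res$P)
  cat(sprintf("ACC = %.2f  BWT = %.2f  ILM = %.2f\n\n", m$acc, m$bwt, m$ilm))
}
```

```
naive train-test matrix P (rows = after session i):
     D1   D2   D3   D4
D1 96.7 71.3 33.3 49.3
D2 89.3 96.0 34.0 44.7
D3 36.7 33.3 92.7 60.7
D4 40.7 33.3 66.7 92.0
ACC = 58.17  BWT = -43.26  ILM = 67.73

proposed train-test matrix P (rows = after session i):
     D1   D2   D3   D4
D1 96.7 71.3 33.3 49.3
D2 95.3 94.7 33.3 46.7
D3 95.3 92.7 87.3 44.7
D4 96.7 94.0 85.3 90.7
ACC = 91.67  BWT = -1.41  ILM = 92.87
```

Reading the matrices: each row is the state of the model after one more
training session, each column one domain's test set. Under naive
fine-tuning, accuracy on domain `D1` collapses from 96.7 to 40.7 as later
domains are learned (the forgetting signature, `BWT = −43`). With replay
and distillation the first column stays above 95 throughout and backward
transfer is near zero, at almost no cost on the newly learned domains.

The same runs are available from the shell:

```sh
Rscript inst/scripts/latentreplay.R simulate --out seq/
Rscript inst/scripts/latentreplay.R run --sequence seq/ --out results/ --strategy proposed
Rscript inst/scripts/latentreplay.R metrics --matrix results/P_repeat0.tsv
```

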