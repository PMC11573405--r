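# condiff — guided conditional diffusion classification of wound images

`condiff` is an R implementation of a *generative discriminative* image
classifier, built for the problem of deciding from a photograph whether a
diabetic foot ulcer looks infected — a two-class task with high
inter-class similarity and strong intra-class variation, where ordinary
discriminative CNNs overfit small clinical datasets.

Instead of a classification head, the method compares class-conditional
reconstructions of the input:

1. the guide image $x_0$ is partially noised through a variance-preserving
   forward diffusion, $x_s = \sqrt{\bar\alpha_s}x_0 +
   \sqrt{1-\bar\alpha_s}z$ with $s = \mathrm{round}(t_0 T)$;
2. the perturbed image is denoised twice with classifier-free-guided DDIM
   sampling — once conditioned on each class $y$, mixing conditional and
   unconditional noise estimates as
   $\tilde\epsilon = (1-\omega)\epsilon_\theta(x_t,t) +
   \omega\,\epsilon_\theta(x_t,t,y)$ — giving syntheses
   $\hat x_0^{(y_1)}, \hat x_0^{(y_2)}$;
3. the label is assigned by minimum squared Euclidean distance in a
   triplet-loss-trained embedding $f_\phi$:
   $\hat y = \arg\min_y \lVert f_\phi(x_0) -
   f_\phi(\hat x_0^{(y)})\rVert_2^2$.

Training is two-stage: Stage 1 fits the conditional denoiser
$\epsilon_\theta(x_t, t, y)$ by noise-prediction MSE with label dropout;
Stage 2 trains $f_\phi$ on triplets whose (positive, negative) pair is a
conditional synthesis with probability $p_{gen}$. The package also ships
Score-CAM similarity heatmaps, a synthetic two-class wound-image generator
with subject-wise anti-leakage splitting (three magnification captures per
subject emulate the "natural augmentation" that makes sample-wise splits
leak), and an evaluation harness (confusion metrics with "infected" as the
positive class, subject-wise k-fold scoring, noise-strength sweeps, and
the inter-condition divergence diagnostic).

Everything runs on a plain CPU at desk scale (32×32 images); the neural
networks are small, hand-written, and fully seeded, so every prediction is
bit-reproducible.

## Worked example

```r
library(condiff)

# a synthetic two-class wound study: 60 subjects, one 32x32 image each
ds  <- generate_wound_dataset(wound_spec(n_subjects = 60, seed = 11))
fit <- condiff_fit(ds, cfg = sampler_config(omega = 0.75, t0 = 0.8,
                                            n_steps = 30, seed = 12),
                   seed = 13)   # ~4 minutes on one CPU

held <- ds$manifest[ds$manifest$split %in% c("val", "test"), ]
res  <- condiff_predict_batch(ds$images, held, fit)
head(res[, c("image_id", "label", "predicted", "d_uninfected",
             "d_infected", "margin")], 3)
#>       image_id      label  predicted d_uninfected d_infected margin
#> 1 subj007_mag2   infected   infected       3.2136     1.0990  2.115
#> 2 subj010_mag2 uninfected uninfected       0.1555     2.5251  2.370
#> 3 subj014_mag2   infected   infected       3.6256     0.9136  2.712
mean(res$predicted == res$label)
#> [1] 0.9444444
```

Each row reports the squared embedding distance from the guide to its
uninfected-conditioned and infected-conditioned synthesis; the prediction
is the argmin and `margin` is the distance gap (embeddings live on the
unit sphere, so squared distances lie in [0, 4]). A subject-wise 5-fold
report with per-fold means and standard deviations comes from
`kfold_evaluate(ds$images, held, fit, k = 5)`, and
`divergence_vs_t0()` / `sweep_t0()` reproduce the noise-strength
diagnostics. `similarity_scorecam(fit$embedder, guide, synthesis)` shows
which regions the embedding treats as shared between a guide and a
synthesis.

A thin command-line interface over the same functions is installed at
`system.file("cli", "condiff.R", package = "condiff")` with subcommands
`simulate`, `train`, `classify`, `evaluate`, `sweep-t0`, `explain`.

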