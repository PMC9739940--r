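# seedlingmix

Single-view, top-down depth cameras are the cheapest route to
high-throughput seedling phenotyping, but their point clouds carry two
problems that wreck leaf-area measurements: *hover points* — spurious
returns strung along the viewing ray at object silhouettes, plus sparse
outliers — and inter-leaf occlusion, which makes the visible part of a leaf
under-measure its true area. `seedlingmix` is an R implementation of a
processing stack that addresses both, end to end:

1. **Neighborhood-space-constraint filtering.** For each point, `D` = mean
   distance to its `N` nearest neighbours and `W` = angle between the
   locally fitted plane normal and the viewing axis (folded to [0°, 90°]);
   a point is deleted iff `D >= d` or `W >= c`, with operating point
   `N = 12`, `d = 0.0034` m, `c = 60°`. Hover chains lie along the viewing
   ray (`W ~ 90°`), outliers fail the density test, and the flat ribbon a
   top-down camera measures on a thin stem passes both tests — so stems
   survive where classical statistical/radius filters delete them.
2. **Self-supervised occlusion data.** Intact leaves are occluded
   synthetically by placing 14 viewpoints (8 cube corners + 6 face centers)
   around each leaf and removing the 15%, 25% or 50% of points nearest a
   drawn viewpoint.
3. **A mixer-based encoder/decoder network** (four resolutions
   2048/1024/512/256, neighbour counts 32/16/8/4) whose stages aggregate
   curvature-sampled neighbourhoods, `max-pool LBR(concat(F_i - F_ik,
   repeat(F_i, k)))`, and mix features within and across point groups by a
   residual two-MLP block, `Fc = Fs + MLP(LN(Fs))`,
   `Fo = Fc + t(MLP(t(LN(Fc))))`. Heads provide object classification,
   per-point stem/leaf scores, a 5-D instance embedding clustered by
   mean-shift, and a progressive completion decoder emitting
   256/512/1024/2048-point clouds trained with a four-stage Chamfer loss.
   The network and all its gradients are implemented from scratch in base R
   matrix algebra and train on a CPU.
4. **Leaf-area phenotyping.** PCA-projected Delaunay triangulation with a
   hole guard, areas mapped back to cm² through the recorded normalization
   transforms, and R²/MSE correlation against reference areas.

Because no public dataset exists for this task, the package includes a
synthetic seedling generator (curved leaf patches with closed-form areas, a
camera-visible stem ribbon, ground/tray background, and a hover/outlier
noise model) that makes every stage testable without downloads. See the
methods vignette (`vignettes/seedlingmix-methods.Rmd`) for the model,
parameter and design details.

## Worked example

Generate a noisy scene, clean it, and measure the filter:

```r
library(seedlingmix)

scene <- noisy_scene(7)                     # seedling + tray + sensor noise
plant <- preprocess_scene(scene)            # crop, ground/tray cut, filter
nrow(scene$points); nrow(plant$points)

eff <- filter_efficacy(1:3)                 # scored against the noise mask
round(eff, 3)
```

```
[1] 15761
[1] 4754
  seed noise_removed plant_removed
1    1         0.976         0.014
2    2         0.983         0.023
3    3         0.989         0.008
```

The scene shrinks from 15,761 points (plant + ground + tray + injected
noise) to a 4,754-point plant-only cloud; across scenes the filter removes
97–99% of the injected hover/outlier points while deleting under 3% of true
plant points — stems included, which is the point of the normal-offset test.

Train the desk-scale completion network on 50 synthetic leaf pairs and
complete an occluded leaf (about 5 minutes on one CPU):

```r
cfg   <- desk_stage_config()
pairs <- build_completion_dataset(leaf_cohort(1:50), seed = 1)
tset  <- completion_training_set(pairs, cfg, seed = 1)
fit   <- mixnet_train(mixnet_init(cfg, seed = 1), tset,
                      train_config("completion", batch_size = 8,
                                   epochs = 30, lr0 = 0.01, seed = 0))

ho  <- build_completion_dataset(leaf_cohort(201:206), seed = 2)
pr  <- ho[[4]]                              # a 50%-missing held-out leaf
inf <- mixnet_infer(fit$model, pr$partial, "completion")
c(partial   = chamfer_distance(pr$partial,   pr$complete),
  completed = chamfer_distance(inf$completed, pr$complete))
```

```
   partial  completed
0.09580673 0.05554676
```

(`mixnet_infer` notes that it resamples the 128-point partial up to the
network's 256-point resolution.) The completed cloud keeps every input
point, adds only predicted points that contribute new surface, and here
cuts the Chamfer distance to the intact leaf by 42%; averaged over a
held-out cohort this is what improves the leaf-area correlation. The
numbers are what the code prints at these seeds; a 30-epoch CPU run is
stochastic but fully reproducible.

## Command line

A thin CLI over the package functions lives at `inst/cli/seedlingmix.R`:

```sh
Rscript inst/cli/seedlingmix.R simulate --out scene.ply --leaves 2 \
    --background --noise --seed 7
Rscript inst/cli/seedlingmix.R preprocess --in scene.ply --out plant.ply \
    --box 0.5,0.5,0.7 --tray-cut 0.12 --knn 12 --dist 0.0034 --angle 60
Rscript inst/cli/seedlingmix.R phenotype --in leaf.ply
```

Training, inference and the full scene-to-phenotype pipeline are R
functions: `mixnet_train()`, `mixnet_infer()`, `run_pipeline()`.
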