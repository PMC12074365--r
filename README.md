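# mdpsoseg

Adaptive clustering-based segmentation of brain lesions in co-registered
multi-modal MRI (FLAIR, T1CE, T1, T2), for researchers who need accurate
whole-tumor delineation without the large annotated datasets and opaque
decision-making of deep segmentation networks. The package combines an
unsupervised, *granularity-adaptive* clustering stage with interpretable
texture/region features and a random-forest voxel classifier, and ships a
synthetic multi-modal phantom generator so every stage is testable offline.

## The method

**Multidimensional PSO clustering.** Every image element (pixel or voxel)
is a point in a joint spatial–intensity feature space,

    p = (x_1, ..., x_S, I_flair(x), I_t1c(x), I_t1(x), I_t2(x)),

with S = 2 for slices and S = 3 for volumes. A candidate segmentation is a
set of 2·d centroids in this space; elements are assigned to their nearest
centroid under the transformed, weighted distance

    δ_c(p) = Σ_m w_m · f(|p_m − c_m| · α_m),      f(x) = e^{x²} − 1,

whose superlinear transform makes a single large attribute discrepancy
dominate many small ones. The swarm minimizes the balance-seeking fitness

    fitness = (d / A) · Σ_i e_i² / A_i,

where A is the element count and A_i, e_i are the per-cluster sizes and
cumulative transformed errors: the d prefactor penalizes needless
fragmentation while the e_i²/A_i terms penalize coarse, high-error
clusters. Crucially, the optimizer is a *multidimensional* particle swarm:
each particle carries, besides per-dimension positional state, a discrete
dimension index d ∈ {dmin..dmax} with its own velocity, so the swarm
selects the number of clusters and the centroid placement jointly. The
inertia weight anneals linearly from 0.9 to 0.4.

**Supervised refinement.** Cluster-level descriptors (size, bounding box,
aspect ratio, density, eccentricity, convexity, spatial moments,
box-counting fractal dimension, per-modality intensity statistics and
co-occurrence contrast/homogeneity) are attached to every member element
and concatenated with voxel-level descriptors and the responses of a
randomized, k-means-pruned, modality-assigned Gabor filter bank. A random
forest classifies voxels into tumor/background; the cluster block is the
channel through which regional context suppresses the scattered errors of
purely local texture classification.

**Evaluation.** The package implements ASA (achievable segmentation
accuracy), a lesion-focused Dice-like ASA variant with majority-rule
cluster calling, the Dice/precision/sensitivity/accuracy/specificity
battery, and the 95th-percentile Hausdorff distance.

## Worked example

```r
library(mdpsoseg)

ph  <- generate_phantom(phantom_spec(shape = c(64, 64), seed = 7))
ph
#> Synthetic phantom: 64 x 64, 1 lesion(s), 315 lesion elements

seg <- mdpso_segment(ph$image, pso = pso_config(64, 15, 5, 10, seed = 11))
seg
#> MDPSO segmentation
#>   grid: 64 x 64 (voxel elements)
#>   selected dimension index d^: 5 -> 10 clusters
#>   fitness: 0.107605

asa_dice(seg$labels, ph$lesion_labels)
#> [1] 1
asa(seg$labels, ph$regions)
#> [1] 0.9915
label_clusters_majority(seg$labels, ph$lesion_mask)
#> [1]  2  4  5 10
```

The swarm searched d ∈ {5..10} and settled on d̂ = 5, i.e. 10 clusters;
four of them are majority-lesion and together they tile the ground-truth
lesion exactly (lesion ASA-Dice 1.0), while the full partition reaches an
ASA of 0.99 against the three-region ground truth (tissue / rim / core).
`summary(seg)` lists per-cluster sizes and error sums, `plot(seg)` draws
the label map, and `fitted(seg)` returns the integer label grid.

A full supervised run — phantom generation, clustering, Gabor bank
selection, forest training and the metric battery — is one call:

```r
res <- run_pipeline(run_config("artifacts", seed = 5,
                               split = list(train = 1:6, validation = 7,
                                            test = 8:12)))
res$summary
```

A thin command-line wrapper with `normalize`, `make-phantoms`, `cluster`,
`evaluate` and `run` subcommands is installed at
`system.file("cli", "mdpsoseg", package = "mdpsoseg")`.

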