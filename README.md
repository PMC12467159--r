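# octatex

Texture-based classification of en-face OCTA (optical coherence
tomography angiography) images of the ocular vascular layers, for
detecting age-related macular degeneration (AMD) without lesion
segmentation.

OCTA renders dye-free greyscale images of blood flow at four depth
slabs — the superficial inner retina, deep inner retina, outer retina
and choriocapillaris. AMD pathology (choroidal neovascularisation,
capillary dropout, geographic atrophy) disrupts the local vascular
micro-texture of these slabs. `octatex` quantifies that texture with
dense local descriptors, summarises each image as a histogram feature
vector, and classifies *eyes* (one image per layer per eye) into binary
condition tasks: healthy vs wet AMD, dry vs wet AMD, and CNV vs
non-CNV. It is aimed at researchers in ophthalmic image analysis who
need an interpretable, small-data alternative to CNN pipelines.

## The descriptors and the two pipelines

For a centre pixel with grey level `g_c` and `p` circular neighbours
`g_0..g_{p-1}` at radius `r` (off-grid samples bilinearly interpolated),

* **LBP**: `LBP_{p,r} = Σ_n s(g_n − g_c) 2^n`, `s(x) = 1` iff `x ≥ 0`,
  giving `2^p` histogram bins;
* **riu2 LBP**: codes whose circular 0/1 transition count
  `u(LBP_{p,r}) ≤ 2` are labelled by their bit count (0..`p`), all other
  codes pool into label `p+1` — a rotation-invariant, `p+2`-bin
  summary;
* **BRIEF**: `n` random pixel pairs `(X_i, Y_i)` inside an `S×S` patch
  are tested with `τ = 1` iff `P(X_i) − P(Y_i) >` threshold, summed
  with weights `2^{i−1}`; the threshold is `3σ`, with `σ` estimated per
  image as the s.d. of the image minus its Gaussian-blurred copy.

Per-layer histograms are concatenated (in canonical layer order) over
any of the 15 layer combinations. Two classification pipelines are
provided:

1. **whole** — the concatenated histograms go straight into the
   classifier;
2. **reduced** — per training fold: centre/scale each feature
   (population s.d.), eigendecompose the covariance
   `Σ = SDᵀSD/(N−1)`, keep the smallest `K` leading components whose
   explained-variance percentages `PV_i = 100 λ_i / Σλ_j` cumulate to
   ≥ 95, and project both fold halves onto them.

Evaluation is stratified 10-fold cross-validation with grid search over
KNN (`k ∈ {1,3,5,7,9}` × Euclidean/Manhattan/Chebyshev) and C-SVM
(`C ∈ {0.1,1,5,10,50,100}`, linear/RBF/polynomial kernels,
`γ ∈ {1e-5..1}`, `d ∈ {2..9}`), reporting mean ± sd of AUC
(Mann–Whitney pair-ranking form) plus accuracy, sensitivity,
specificity and precision.

Because the clinical datasets this methodology was developed on are
private, the package ships a seeded synthetic generator of two-class
vascular textures (smooth spline vessels vs added granular lesion
clusters and dropout patches) with controllable separability, so the
entire pipeline is testable end to end.

## Worked example

```r
library(octatex)
man <- generate_dataset(synthetic_spec(n_eyes = c(10, 10), image_size = 96,
                                       layers = "superficial",
                                       lesion_density = 1, speckle_sd = 10,
                                       seed = 42), "demo")
fm <- extract_features(man, "lbp_riu2", list(p = 8, r = 1),
                       layers = "superficial", task = "healthy_vs_wet")
rep <- run_grid(fm$D, fm$outcome,
                configs = c(knn_grid(),
                            svm_grid(C = c(1, 10), kernels = "linear")),
                mode = "reduced", k = 5, seed = 42)
print(fm)
print(rep)
```

```
feature matrix: 20 eyes x 10 features (lbp_riu2_p8r1_norm; layers: superficial)
grid search over 17 configs (reduced features): best KNN(k=1,euclidean), mean AUC 1.00 +/- 0.00
```

Each of the 20 eyes is summarised by its 10-bin riu2 histogram
(`p + 2 = 10`); the lesion texture of the synthetic "wet AMD" class is
fully separable at lesion density 1, so the best cross-validated
configuration reaches mean AUC 1.00 ± 0.00. At `lesion_density = 0` the
two classes are identically distributed and the best grid point stays
inside the chance band.

The same pipeline is scriptable from the shell:

```sh
Rscript inst/cli/octatex simulate --out data --n-eyes 10,10 --size 96 --seed 42
Rscript inst/cli/octatex evaluate --manifest data/manifest.csv \
    --task healthy_vs_wet --descriptor lbp_riu2 --params '{"p":8,"r":1}' \
    --mode reduced --layers superficial --seed 42 --out report.json
```

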