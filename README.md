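# dpmrf — nonparametric brain-tumor segmentation with DP mixtures and MRF smoothing

`dpmrf` segments 2-D multimodal MR brain-tumor slices **without fixing the
number of clusters in advance**. It is aimed at medical-image-analysis work
where the cluster count is the awkward parameter: glioma appearance varies so
much between patients that any fixed class number is a guess.

The pipeline, per modality, is

1. **Perona–Malik anisotropic diffusion** — edge-preserving denoising,
   `I_s ← I_s + (Δt/4) Σ_p c(|I_p−I_s|)(I_p−I_s)` with
   `c(x) = exp(−(x/q)²)` or `1/(1+(x/q)²)`;
2. **collapsed Gibbs sampling of a Dirichlet-process Gaussian mixture**
   whose label conditional carries a Potts-style MRF factor:

   ```
   p(S_i = k) ∝ n_k · exp(λ Σ_{l∈∂(i)} ω_il δ(k, S_l)) · t(x_i | stats_k)
   p(new)    ∝ α · t(x_i | ∅)
   ```

   with Student-t predictives from a conjugate normal–inverse-gamma base
   measure, cluster parameters integrated out. The chain stops once fewer
   than 1% of sites change assignment for 3 consecutive sweeps (cap 200);

3. **multimodal fusion**: the tumor cluster of the contrast-enhanced T1
   (T1C) segmentation is the enhancing core (GTV), the tumor cluster of the
   FLAIR segmentation is the whole tumor, edema is the exact set difference
   FLAIR − T1C, and CTV = core + edema;
4. **evaluation**: TP/TN/FP/FN, Dice, Jaccard, sensitivity, specificity
   against ground truth.

A synthetic co-registered FLAIR/T1C phantom generator with Rician noise and
pixel-exact ground truth makes the whole pipeline testable with no external
data. I/O is NIfTI (`RNifti`) and grayscale PNG; the Gibbs core is compiled
(Rcpp) but fully driven by R's RNG, so one seed makes runs bit-identical.

## Worked example

```r
library(dpmrf)

ph  <- makePhantom(PhantomSpec(seed = 1))     # 128x128 FLAIR/T1C pair, 5% Rician noise
res <- runPipeline(flair = ph@flair, t1c = ph@t1c, truth = ph@truth, seed = 1)

res$masks
#> TumorMasks 128x128: core 448 px, edema 1356 px, whole 1804 px

sapply(res$metrics, function(m) m@dsc)
#>  core edema whole
#>     1     1     1

head(as.data.frame(res$traces$flair))
#>   iteration nClusters nChanged
#> 1         1        20     9574
#> 2         2        20     8115
#> 3         3        19     6853
#> 4         4        16     4151
#> 5         5        12     1935
#> 6         6         8     1316
```

The trace shows the sampler at work: it starts from 20 intensity-quantile
clusters, merges down (here to 5 clusters at convergence), and the number of
changed assignments per sweep decays until the 1% stopping rule fires. On
this phantom the recovered core, edema and whole-tumor masks match the
generated ground truth exactly (Dice 1.0); at other seeds Dice stays ≥ 0.99.

```r
res$metrics$core
#> MetricsReport
#>   TP=448 TN=15936 FP=0 FN=0
#>   DSC=1.0000 Jaccard=1.0000 Sens=1.0000 Spec=1.0000
```

A command-line front end over the same functions ships in
`inst/cli/dpmrf.R`, with subcommands `simulate`, `denoise`, `segment`,
`fuse`, `evaluate` and `run`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "dpmrf.R", package = "dpmrf"))')
Rscript $CLI simulate --out phantom --shape 64 --seed 4
Rscript $CLI run --flair phantom/flair.png --t1c phantom/t1c.png \
                 --out results --seed 4
```

## Package layout

| Where | What |
|---|---|
| `R/imageIO.R` | NIfTI/PNG image and label-mask I/O, grid conventions |
| `R/diffusion.R` | anisotropic diffusion (coefficients, step, loop) |
| `R/dpCore.R` | CRP weights, NIG predictive, cluster-count formulas |
| `R/graph.R`, `R/sampler.R`, `src/sampler.cpp` | neighbor graphs, MRF costs, collapsed Gibbs |
| `R/fusion.R` | tumor-cluster selection, edema difference, CTV composition |
| `R/metrics.R` | confusion counts and overlap scores |
| `R/synthetic.R` | phantom specification, Rician noise, generator |
| `R/pipeline.R`, `inst/cli/dpmrf.R` | orchestration and CLI |
| `vignettes/tumor-segmentation.Rmd` | model, assumptions, parameter choices, limitations |
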