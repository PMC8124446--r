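# vistamm

Spatial immune exclusion scoring and prognostic gene screening in myeloma
bone marrow.

Multiple myeloma progresses as malignant plasma cells escape CD8⁺ T-cell
control, and the immune checkpoint VISTA — expressed mainly by CD11b⁺
myeloid cells in the marrow — is implicated in that escape. `vistamm`
implements, as tested reusable R code, the two quantitative procedures such
a study needs:

1. **A multiplex-immunofluorescence image pipeline.** Spectrally unmixed
   channels (DAPI, CD138, CD8, CD11b, VISTA, optional autofluorescence) are
   background-corrected and normalized per channel; foreground is defined
   as any normalized channel exceeding 0.2 (components > 5000 px² ≈ 293 µm²
   only); the tumor compartment is where the 10 px Gaussian-smoothed CD138
   signal exceeds 0.2; nuclei come from a watershed on background-corrected
   DAPI; cells are Voronoi regions of the foreground seeded by nuclei;
   cells with area in [500, 5000] px² are phenotyped by mean normalized
   intensity (thresholds 0.5 for CD138, 1.5 for CD8/CD11b/VISTA), and very
   large VISTA⁺ megakaryocytes are excluded. Per patient, compartment
   densities define the **VISTA-associated T-cell exclusion score**

   score = (d_VISTA⁺CD11b⁺,tumor / d_VISTA⁺CD11b⁺,stroma) × (d_CD8,stroma / d_CD8,tumor)

   (pseudocount ε = 0.1 cells/mm² in each ratio), whose median split is
   compared by Kaplan–Meier, log-rank and Cox analysis.

2. **A three-stage prognostic gene screen** over immune-related gene lists
   in log2 expression cohorts: (i) list-level ridge-penalized Cox, with the
   penalty chosen by 10-fold cross-validated partial likelihood inside a
   leave-one-out outer loop that gives every discovery patient an
   out-of-sample risk score, validated in independent cohorts; (ii)
   per-gene Cox (per SD) in discovery and validation plus an ISS-adjusted
   multivariate model; (iii) multivariate validation in a second cohort
   with ISS stage and a time-dependent autologous-transplant covariate —
   Holm-corrected at every stage.

A synthetic-data module (`generate_image()`, `generate_survival_cohort()`,
`generate_screen_cohorts()`) produces ground-truthed images and simulated
cohorts with the statistical structure both arms assume, so the whole
pipeline is testable end to end without clinical data. The methods
vignette (`vignettes/methods.Rmd`) documents every model, default and
design decision.

## Worked example

Simulate one bone-marrow region, run the pipeline, and score it:

```r
library(vistamm)

g   <- generate_image(image_spec(), seed = 7)   # 512x512 px, ~50 cells
res <- process_region(g$image)                  # normalize/segment/phenotype
nrow(res$cells)                                 # phenotyped cells
#> [1] 46
attr(res$cells, "n_megakaryocytes")             # excluded giant VISTA+ cell
#> [1] 1
prof <- patient_spatial_profile(list(res), "pt01")
prof
#> <patient_spatial_profile> pt01 - exclusion score: 4.999
```

A score near 1 means no preferential localization; scores well above 1
mean VISTA⁺CD11b⁺ cells concentrate in the tumor while CD8 T cells are
held in the stroma. The screening arm at full scale (discovery n = 1000,
validation n = 600, second validation n = 700; one planted gene at
HR 0.75/SD among 100 noise genes in seven lists):

```r
res <- run_screen(cohorts, gene_lists, seed = 20260927)  # analysis/02_gene_screen.R
res$stage1$list_name[res$stage1$passed]
#> [1] "list3"                    # only the list holding the planted gene
res$stage3
#>    gene    hr ci_low ci_high       p  p_holm passed
#> 1 g0101 0.803  0.735   0.878 1.3e-06 1.3e-06   TRUE
```

The planted protective gene is recovered as the sole final survivor with
its hazard ratio near the planted 0.75.

The `analysis/` scripts are the narrative drivers: `01_spatial_pipeline.R`
(22-patient imaging cohort, exclusion-score split), `02_gene_screen.R`
(full-scale screen), `03_operating_characteristics.R` (recovery rates and
null calibration); each writes its tables under `results/`.

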