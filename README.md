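# shapetraj

Spatiotemporal shape analysis of anatomical surfaces for detecting
presymptomatic structural change.

## What it does, and for whom

In familial neurodegenerative disease (e.g. genetic frontotemporal
dementia), subcortical structures change shape years before symptom
onset. Given one triangle mesh per subject per hemisphere, each labelled
with the subject's estimated years to expected symptom onset (EYO) and
covariates (mutation-carrier status, sex, site, family), `shapetraj`
estimates *when* and *where* carriers' shapes start to deviate from
non-carriers'. It is aimed at neuroimaging groups who already extract
subcortical surface meshes and want a deformation-based alternative to
volume summaries and vertex-wise testing.

The pipeline is built on large-deformation diffeomorphic metric mapping
(LDDMM) with an orientation-free varifold data term:

* surfaces are compared by the kernel metric
  `⟨[A],[B]⟩ = Σ_kl exp(−‖c_k−c_l‖²/λ_W²) (τ_k·τ_l)²/(‖τ_k‖‖τ_l‖)`
  over triangle centres `c` and area-weighted normals `τ`;
* deformations are geodesic flows parametrised by momenta `α_p` on a
  control-point grid, integrated from the Hamiltonian system
  `ẋ_p = Σ_q K(x_p,x_q) α_q`, `α̇_p = −Σ_q (α_p·α_q) ∇₁K(x_p,x_q)`;
* a population-average geodesic trajectory `(B₀, β₀)` is regressed
  through all subject shapes over EYO; per-subject residual deformations
  `α_i(0)` from the trajectory are parallel-transported to the baseline
  space with Jacobi fields; the trajectory parametrisation is clustered
  (spectral clustering of a position/momentum similarity), and each
  cluster's mean transported momentum is reduced to amplitude and
  orientation descriptors tested with linear mixed models
  (`value ~ group*EYO + sex + site + (1|family)`) and Wald tests, overall
  and every 5 years of EYO with Bonferroni correction.

A synthetic bilateral cohort generator with exact ground truth
(`generate_cohort()`) stands in for the non-distributable clinical data
and makes every stage testable end to end.

See the vignette `vignettes/shape-trajectories.Rmd` for the model,
parameter meanings and design decisions.

## Worked example

A full synthetic analysis — 200 subjects, a planted orientation-only
divergence starting at EYO −10 in carriers — runs in about 8 minutes on
one core:

```r
library(shapetraj)

gen <- generate_cohort(synth_config(seed = 7, mesh_subdiv = 2))
params <- pipeline_params(max_iter = 12, n_init = 50, seed = 7)
res <- run_shape_pipeline(gen$cohort, params)
chk <- end_to_end_truth_check(res, gen$truth)

round(chk$endpoint_rms, 3)          # trajectory endpoint error (mm)
chk$best_cluster                    # cluster overlapping the planted patch
subset(res$analysis$omnibus, p_bonferroni <= 0.05,
       select = c(descriptor, cluster, test, wald_chi2, df, p_bonferroni))
subset(res$analysis$at_eyo, p_bonferroni <= 0.05,
       select = c(descriptor, cluster, test, estimate, p_bonferroni))
```

Output from this exact run:

```
endpoint_rms: 0.694
best_cluster: 10   jaccard: 0.21
  descriptor cluster     test wald_chi2 df p_bonferroni
 orientation      10 T1_group  20.52337  2 0.0006989334
  descriptor cluster        test   estimate p_bonferroni
 orientation      10 at_eyo(-10) -0.2828092 1.065361e-02
 orientation      10  at_eyo(-5) -0.3654756 4.288038e-04
 orientation      10   at_eyo(0) -0.4481419 6.634672e-05
 orientation      10   at_eyo(5) -0.5308082 4.123552e-05
 orientation      10  at_eyo(10) -0.6134746 5.318821e-05
```

Reading: the estimated population trajectory tracks the planted one to
0.7 mm vertex RMS at its far end; the cluster with the best overlap of
the planted anterior patch (cluster 10) is the only cluster–descriptor
combination surviving Bonferroni correction, in the **orientation**
descriptor (Wald χ² = 20.5, df 2) — no amplitude descriptor comes close,
so the planted rotation-at-fixed-amplitude effect is recovered as a pure
orientation effect, the package's core claim. The time-resolved contrasts
become (corrected-)significant at EYO −10, exactly the planted divergence
onset, and grow monotonically thereafter.

## Command line

A thin CLI over the same functions is installed with the package
(`inst/cli/shapetraj`): `shapetraj synth --out dir`,
`shapetraj register --source a.ply --target b.ply --lambda-v 11
--lambda-w 5 --gamma 0.1 --out momenta`, and
`shapetraj run-all --config analysis.yaml` for the config-driven pipeline
(`?run_pipeline` documents the YAML schema).

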