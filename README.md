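# sustainz

Subtype and Stage Inference (SuStaIn) for regional brain atrophy z-scores,
as an R package plus a reproducible analysis workflow.

Cohorts of genetic frontotemporal dementia mutation carriers mix people at
very different disease stages who may follow different spatial patterns of
atrophy. `sustainz` disentangles the two axes from single cross-sectional
MRI-derived regional volumes: it clusters carriers into *progression
subtypes*, each an ordering of z-score events, and *stages* every carrier
along their subtype's ordering. It is aimed at researchers modeling
presymptomatic-to-symptomatic neurodegeneration who need subtype/stage
estimates, their uncertainty, and a stage-adjusted clinical comparison
layer — and at anyone wanting a fully synthetic, ground-truthed testbed for
this model family.

## The model

Regional volumes are corrected for age, sex, total intracranial volume and
scanner field strength by linear regression in a control population, then
z-scored against the controls and sign-flipped so z increases with atrophy.
A *z-score event* `(b, z_r)` is region *b* reaching threshold
`z_r ∈ {1, 2, 3}`; a subtype is an ordering *S* of all `E` events; the
expected z of region *b* at stage *k* is piecewise linear through
`(0, 0)`, `(pos(b, z_r), z_r)` and `(E, z_max = 5)`:

```
L(x | c, k) = ∏_b N(x_b ; g_b^c(k), σ),    σ = 1
P(x | c)    = 1/(E+1) ∑_k L(x | c, k)
log L(data) = ∑_i log ∑_c f_c P(x_i | c)
```

Sequences are fitted by greedy single-event relocation from random
restarts inside a hierarchical-splitting EM over subtypes; ordering
uncertainty comes from Metropolis–Hastings over sequences; the number of
subtypes is chosen by a cross-validated information criterion
(`CVIC = −2 × out-of-fold log-likelihood`) with a one-standard-error rule.
Subjects with more stage-0 posterior mass than any subtype are labeled
*normal-appearing*; the rest get their most probable subtype and a
probability-weighted expected stage.

Because the cohort this emulates is access-controlled, the package ships a
synthetic generator (`synth_config()` / `generate_cohort()`) with known
ground truth: 300 controls, 82 carriers, two latent orderings
(temporal-led vs frontal+temporal-led), covariate effects on raw volumes,
annual follow-ups, and a clinical score battery. See the vignette
(`vignettes/subtype-stage-inference.Rmd`) for assumptions and limitations.

## Worked example

The numbered scripts under `analysis/` run the whole study on the default
synthetic cohort and write tables to `results/`:

```sh
Rscript analysis/01_simulate.R      # cohort + ground truth + scores
Rscript analysis/02_normalize.R     # control model + z-scores
Rscript analysis/03_fit_sustain.R   # CVIC selection + final fit + MCMC
Rscript analysis/04_assign.R        # subtype/stage assignments
Rscript analysis/05_stats.R         # statistical comparison layer
Rscript analysis/06_longitudinal.R  # follow-up consistency
```

Selected output from one run (seed 42):

```
control z-scores: max |mean| = 7.33e-15, max |SD - 1| = 1.11e-16
CVIC by C: 1949.3 / 1792.3 / 1788.8 (SE 62.8 / 34.9 / 33.4) -> chose C = 2
subtype temporal first five events: temporal_pole:z1, hippocampus:z1,
  hippocampus:z2, amygdala:z1, hippocampus:z3
true stage >= 5 assigned their true subtype: 100% (n=31)
Spearman cor(expected stage, true stage) = 0.90
mutation vs subtype: IVS10+16 p = 0.012, R406W p = 0.0099 (all temporal);
  P301L p = 2.5e-05 (frontotemporal)
stage-EYO correlation: overall r = 0.71
cbi_memory: temporal offset +6.4 (p = 1.1e-06); tmt_a_time: temporal
  offset -13.7, i.e. worse in frontotemporal (p = 0.0038)
longitudinal: 83/96 follow-ups same label, 1 subtype-to-subtype flip,
  stage nondecreasing at 92%
```

Read: the covariate correction is exact on the fitting controls; two
subtypes are selected; the temporal ordering starts in medial temporal
structures; progressed carriers are subtyped essentially perfectly and
expected stage tracks true stage; intronic/late-exon mutations map to the
temporal subtype and P301L to the frontotemporal one; memory scores are
selectively worse in the temporal subtype and executive measures in the
frontotemporal subtype — the structural pattern the model family is
designed to expose.

`run_pipeline(pipeline_config(...))` runs the same stages from a single
(YAML/JSON-loadable) config with a manifest of all artifacts.

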