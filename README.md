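# spcregress

Label-free spectral-count proteomics for two-group biomarker discovery,
built around the question of whether proteins shed by cervical biopsy
samples can predict spontaneous regression of high-grade premalignant
lesions (CIN2-3). Given peptide-spectrum-match (PSM) exports or
protein x sample spectral-count matrices with *regression* /
*persistence* labels and a learning/validation split, the package
implements the full downstream chain:

1. **Identification filtering** — charge-dependent SEQUEST Xcorr gates
   (1.9 / 2.3 / 2.6 for z = 2 / 3 / >= 4), the two-path protein
   acceptance rule (>= 2 unique peptides on the Xcorr gate alone; a
   single-peptide protein needs >= 7 residues, a run of >= 3 consecutive
   matched b-/y-ions and >= 3 occurrences in one sample), and the 30%
   group-presence filter.
2. **Counting and normalization** — +1 offset (so "<= 1 vs > 1" is a
   detection rule) and per-sample scaling by the sample's total count
   relative to its group average, in both the published (`as_printed`)
   and the conventional (`depth_corrected`) orientation.
3. **PLS-DA target projection** — NIPALS PLS1 on the centered matrix with
   the class coded regression = 0 / persistence = 1, collapsed to a
   single target-projection (TP) component
   (w_TP = b/||b||, t_TP = X_c w_TP), oriented so persistence scores are
   positive, with signed selectivity ratios
   SR_i = sign(p_i) · ||t_TP p_i||² / ||x_i − t_TP p_i||².
4. **DIVA test** — a Monte-Carlo correct classification rate (CCR, 50 =
   chance, 100 = complete separation) per protein and the SR significance
   limit attaining a CCR objective.
5. **Double cross-validation** — 5 outer x 4 inner stratified folds; the
   inner loop picks the number of PLS components, the outer loop reports
   pooled held-out classification.
6. **Classifiers** — ROC/Youden decision stumps, an exhaustive-Gini
   two-node tree with competitor ranking, and one-variable logistic
   ranking with separation detection.
7. **Synthetic data** — seeded generators reproducing the study design
   (20 + 20 samples, 163 background + 2 planted proteins, overdispersed
   counts, per-sample depth variation) and a PSM boundary battery with an
   embedded accept/reject oracle.

A transcription of the study's 165-protein identification table ships as
`inst/extdata/table1_proteins.tsv` and parses with
`read_protein_catalog()` (decimal commas normalized).

See the vignette (`vignettes/spectral-count-workflow.Rmd`) for the models,
the parameter choices and their rationale, and known limitations.

## Worked example

```r
library(spcregress)

m  <- generate_spc_dataset(sim_config(seed = 42))
nz <- normalize_spc(add_offset(m), mode = "depth_corrected")

tp <- plsda_tp(nz, n_components = 2)
tp
#> tp_model: 2-component PLS-DA collapsed to one target-projection component
#>   proteins: 165  samples: 40
#>   score-sign agreement with groups: 100%
#>   |SR| range: 0 .. 2.368

dv <- diva_test(nz, objective = 90, n_splits = 100, seed = 42)
dv
#> DIVA test: objective CCR 90%, 100 splits
#>   SR significance limit: +/- 2.368
#>   significant proteins: 1 of 165
```

Every sample's oriented TP score falls on its group's side, and at a 90%
CCR objective exactly one protein — the planted strong discriminator —
clears the selectivity-ratio limit (its |SR|, 2.368, becomes the limit).
Honest performance and the detection-rule classifier:

```r
double_cv(nz, plan = cv_plan(seed = 42))
#> double cross-validation (5 outer x 4 inner folds)
#>   components per outer fold: 3 3 1 1 2
#>   pooled held-out CCR: 70% (final A = 1)

rule <- roc_threshold(add_offset(m)$counts["PLANTED_ZNF441_LIKE", ],
                      m$group, accession = "PLANTED_ZNF441_LIKE")
rule
#> rule [roc]: PLANTED_ZNF441_LIKE > 1.5 -> regression
apply_rules(rule, add_offset(m))$confusion
#>              predicted
#> actual        regression persistence
#>   regression          20           0
#>   persistence          0          20
```

The held-out pooled CCR (70% here) is the honest multivariate estimate on
one noisy replicate, while the single-marker detection stump — "offset
count > 1", i.e. *detected* means regression — classifies all 40 samples
of this replicate correctly, mirroring how a presence/absence marker can
outperform the full profile.

A thin CLI wraps the same functions:

```sh
exec/spcregress simulate --seed 3 --out sim/
exec/spcregress diva --matrix sim/spc_matrix.tsv --labels sim/spc_labels.tsv \
    --mode depth_corrected --objective 90 --splits 100 --seed 1 --out out/
```

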