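# clinCMap

Connectivity-map drug repurposing driven entirely by clinical laboratory
results. Instead of gene-expression signatures, **clinCMap** matches what a
drug does to routine lab tests (glucose, LDL, alkaline phosphatase, ...)
against what a disease does to the same tests, and ranks drug–disease pairs
by how strongly the two signatures oppose each other.

The package is for computational drug-repurposing researchers who have (or
can simulate) two data arms:

* a **longitudinal arm** — prescription and lab-result histories, one row
  per lab measurement with the binary drug-exposure vector at measurement
  time;
* a **survey arm** — case/control subjects with disease status and numeric
  lab values.

## The model

**Drug effect vectors.** For each lab test, measurements are modeled with a
continuous self-controlled case series (CSCCS): a linear model with one
baseline intercept per patient,

    y_ij = alpha_i + beta' x_ij + eps_ij,   eps_ij ~ N(0, sigma^2),

where `x_ij` is the 0/1 drug-exposure vector when patient *i*'s *j*-th
measurement was taken. The patient baselines are nuisance parameters;
setting the gradient in `alpha` to zero shows they equal the per-patient
means, so the fit reduces to within-patient centering of `y` and `X`.
Because only a small portion of drugs moves any given lab, the centered
problem carries an L1 penalty:

    argmin_beta  1/2 || (y - Z ybar) - (X - Z Xbar) beta ||^2 + lambda ||beta||_1 .

The penalty is chosen by patient-grouped cross-validation, coefficients get
post-selection t-tests, and each (drug, lab) pair is called +1 / −1 / 0
(significant increase / decrease / nothing at p < 0.05).

**Disease sign vectors.** Per lab, cases and controls are compared with the
Wilcoxon rank-sum (Mann–Whitney U) test; significant labs are called +1 or
−1 by comparing the group means.

**Scoring.** A drug–disease pair is scored by the negative dot product of
the two ternary vectors,

    TS = − CV_drug · CV_disease ,

so each lab where the drug opposes the disease (complementary) adds +1 and
each lab where it reinforces it (adverse) subtracts 1. Rankings are
evaluated against a gold-standard indication list with precision@K and the
fold-enrichment score FE = (n/m)/(N/M) per rank bin.

## Worked example

Everything below is synthetic and seeded; `simulateStudy()` plants three
diseases (each shifting four labs), five complementary drugs per disease
and three inert drugs, and derives the gold standard implied by that truth.

```r
library(clinCMap)

study <- simulateStudy(seed = 42)
drugVecs    <- buildDrugEffectVectors(study$ehr, minPatientsPerDrug = 1, seed = 42)
diseaseVecs <- buildDiseaseVectors(study$survey, minSamples = 10)
drugVecs
#> SignVectorSet (drug): 18 x 12 [+25 / -27 / 0 164]
diseaseVecs
#> SignVectorSet (disease): 3 x 12 [+7 / -6 / 0 23]

sm <- computeScoreMatrix(drugVecs, diseaseVecs)
ranking <- rankDrugs(sm, "disease1")
head(ranking, 6)
#>   rank drug_id score
#> 1    1  drug01     3
#> 2    2  drug02     3
#> 3    3  drug03     3
#> 4    4  drug04     3
#> 5    5  drug05     3
#> 6    6  drug07     1

gold <- indications(study$gold)[["disease1"]]
precisionAtK(ranking$drug_id, gold, 5)
#> [1] 1
fe <- foldEnrichment(ranking$drug_id, gold, 5)
fe
#>   group m n  FE
#> 1     1 5 5 3.6
#> 2     2 5 0 0.0
#> 3     3 5 0 0.0
#> 4     4 3 0 0.0
feTrend(fe)
#> [1] -1.08
```

The five planted drugs for `disease1` (those whose lab effects oppose the
disease's shifts on three labs, true score +3) come out on top with
estimated score 3; precision@5 is 1, the first rank bin is 3.6-fold
enriched in gold-standard drugs, and the enrichment decays down the
ranking (negative trend) — the behaviour a sound repurposing score must
show.

`runPipeline()` drives the same flow from a YAML config and writes every
table (vectors, scores, rankings, evaluation, co-clustering) plus a run
manifest; `inst/cli/clincmap.R` is a thin command-line wrapper with
`simulate | drug-vectors | disease-vectors | score | evaluate | cluster |
run` subcommands.

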