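# pichiasec

Predicting whether a recombinant protein will be secreted into the culture
supernatant when expressed in *Pichia pastoris*.

*P. pastoris* is a workhorse host for recombinant protein production
because most heterologous proteins it expresses are exported straight into
the culture medium, where they can be harvested without cell disruption.
Not every protein cooperates: some are retained intracellularly no matter
how the expression construct is tuned, and finding that out experimentally
costs weeks. `pichiasec` addresses this with a sequence-based classifier:
given a mature protein sequence (signal peptide already removed), it
returns a **secretion propensity** in [0, 1] together with a confidence
grade, so that candidate constructs can be triaged before anyone touches a
fermenter.

The package is aimed at protein engineers choosing expression hosts and at
computational biologists studying sequence determinants of secretion.

## Method

Sequences of arbitrary length are converted to fixed-length **pseudo amino
acid composition (PseAAC)** vectors built from six physicochemical scales
(hydrophobicity, hydrophilicity, side-chain mass, pK of the α-COOH group,
pK of the α-NH3+ group, pI at 25 °C), each normalized to mean 0 / RMS 1
over the 20 residues. Writing f<sub>u</sub> for the relative frequency of
residue *u* and H<sub>k</sub>(R<sub>i</sub>) for normalized scale *k* at
position *i*:

* **Type I (parallel correlation):** lag-*j* factors
  θ<sub>j</sub> = ⟨ (1/m) Σ<sub>k</sub> [H<sub>k</sub>(R<sub>i+j</sub>) −
  H<sub>k</sub>(R<sub>i</sub>)]² ⟩<sub>i</sub>, giving a vector of
  dimension 20 + λ;
* **Type II (series correlation):** one track per scale,
  τ<sub>j,k</sub> = ⟨ H<sub>k</sub>(R<sub>i</sub>)
  H<sub>k</sub>(R<sub>i+j</sub>) ⟩<sub>i</sub>, dimension 20 + i·λ for
  *i* scales.

Both are combined with the composition as x<sub>u</sub> =
f<sub>u</sub> / (1 + w Σ corr) and x<sub>20+v</sub> =
w·corr<sub>v</sub> / (1 + w Σ corr), so every vector sums to 1. The weight
*w* and the maximum correlation rank λ are the two tunable parameters.

A **random forest** (500 trees by default) is trained on labeled vectors;
its vote fraction for the secreted class is the propensity *O*, the binary
call is *O* ≥ 0.5, and the **reliability index**
RI = ⌊20·|O − 0.5|⌋ ∈ {0,…,10} grades each call's confidence.

Evaluation follows the protocol this kind of predictor is judged by:
stratified 20-fold cross-validation with pooled confusion counts;
sensitivity, specificity, overall accuracy Q2 = (TP+TN)/N, Matthews
correlation coefficient, and rank-method AUC; an RI-coverage curve; a
(type, w, λ) parameter sweep; and an N-/C-terminal truncation scan that
localizes the secretion signal along the sequence. A synthetic fixture
generator plants compositional or positional signal in two-class sequence
sets so the entire pipeline is testable without any external dataset.

## Worked example

```r
library(pichiasec)

# a synthetic two-class set: positives carry 15% excess hydrophobic mass
ds <- generate_fixture(fixture_spec(200, 200, c(80, 200), delta = 0.15, seed = 1))

# cross-validate the predictor at Type I, w = 0.05, lambda = 5
cv <- cross_validate(ds, pseaac_params("I", w = 0.05, lambda = 5),
                     folds = 20, seed = 1)
cv
#> 20-fold cross-validation (400 proteins)
#> MCC 0.910 | Q2 0.955 | sensitivity 0.960 | specificity 0.950 | AUC 0.992
#>   counts: TP 192, FN 8, TN 190, FP 10
```

MCC 0.91 means the planted compositional signal is recovered almost
perfectly out-of-fold; AUC 0.99 says the propensity ranks positives above
negatives nearly everywhere. For single proteins:

```r
feats <- encode_batch(ds, pseaac_params("I", 0.05, 5))
model <- train_forest(feats, ds$labels, seed = 1,
                      params = pseaac_params("I", 0.05, 5))
predict(model, ds$sequences[1:2])
#>       id propensity     call RI
#> 1 POS0001      0.898 secreted  7
#> 2 POS0002      0.974 secreted  9
```

A propensity of 0.97 with RI 9 is a near-certain secretion call; values
near 0.5 (RI 0–2) should be treated as uninformative.

The six-protein β-galactosidase expression panel shipped with the package
(predicted propensities vs measured extracellular percentages) links the
score to real measurements:

```r
panel <- read.delim(system.file("extdata", "beta_galactosidase_panel.tsv",
                                package = "pichiasec"), comment.char = "#")
propensity_correlation(panel$propensity, panel$extracellular_pct)
#> $slope      130.0262
#> $intercept  -29.14378
#> $r_squared  0.9684941
#> $n          6
```

R² ≈ 0.97: the propensity is close to linear in the measured secretion
percentage on this panel.

A thin command-line interface wraps the same functions
(`inst/exec/pichiasec`): subcommands `encode`, `train`, `predict`, `cv`,
`sweep`, `scan-terminal`, `fixture`, each accepting `--seed` and writing a
JSON config echo beside its outputs.

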