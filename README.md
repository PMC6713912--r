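# hairpin3d

Classify candidate microRNA precursor hairpins against pseudohairpin decoys
using a compact, purely structural 36-dimensional descriptor.

MicroRNA (miRNA) genes are excised from stem-loop precursors of roughly
50–180 nt, but a hairpin-shaped fold is not unique to miRNAs: eukaryotic
genomes are full of *pseudohairpins* — segments that fold into stem-loops
without ever entering the miRNA biogenesis pathway. Telling the two apart
computationally is a standard two-class learning problem, and most published
feature sets for it mix hundreds of sequence, structure and thermodynamic
descriptors. `hairpin3d` takes the opposite approach: a single geometric
encoding of the secondary structure, 36 numbers per hairpin, fed to ordinary
classifiers.

## The descriptor

Each sequence is folded into one dot-bracket secondary structure, and every
base is written in lowercase if it sits in a base pair, uppercase otherwise
(the *characteristic sequence*). Each letter is then mapped to a corner of
the cube {−1, +1}³ using the three chemical dichotomies of RNA bases:

| axis | +1 | −1 |
|------|----|----|
| x | purine (A, G) | pyrimidine (C, U) |
| y | amino (A, C) | keto (G, U) |
| z | strong H-bond (G, C) | weak H-bond (A, U) |

so A = (+1, +1, −1), C = (−1, +1, +1), G = (+1, −1, +1), U = (−1, −1, −1),
and a bonded (lowercase) base takes the negated vector of its uppercase
form. Cumulative summation of these vectors from the origin traces a 3D
curve P₁…P_N through the molecule. Grouping curve points into 12 classes —
base identity (A, C, G, U) × pairing state (unpaired `.`, pair-opening `(`,
pair-closing `)`) — and taking each class's geometric center divided by the
sequence length N gives

  f(b, s) = (1 / (N·n_k)) Σ_{i ∈ S(b,s)} P_i ∈ [−1, +1]³,

12 classes × 3 coordinates = 36 features, with absent classes contributing
exactly (0, 0, 0).

Folding uses a built-in maximum base-pairing dynamic program (Nussinov-style,
Watson–Crick plus G–U wobble, minimum loop of 3, deterministic traceback) or,
optionally, any RNAfold-compatible external folder for thermodynamic MFE
structures.

Training follows the balanced Monte Carlo protocol: equally sized random
samples from both classes, a stratified 70% learning / 30% testing split,
repeated (1000-fold by default) with decision-tree, naïve-Bayes and
random-forest learners, keeping each classifier's model with the highest
held-out accuracy. A synthetic corpus generator (imperfect stem-loops as
positives, dinucleotide-shuffled decoys as negatives) makes the whole
pipeline testable without any external data.

## Worked example

```r
library(hairpin3d)

# a labeled synthetic corpus: 60 hairpins, 60 shuffled decoys
corpus <- simulate_corpus(synth_config(n_pos = 60, n_neg = 60, seed = 42))

pos <- featurize_hairpins(corpus$pos, label = "positive")
neg <- featurize_hairpins(corpus$neg, label = "negative")

cv <- monte_carlo_cv(pos, neg, cv_config(repeats = 5, seed = 42))
cv
#> <hairpin_cv> 5 Monte Carlo repetitions, 70%/30% split, 3 classifier(s)
#> # A tibble: 3 × 5
#>   classifier    median_accuracy best_accuracy median_f_measure best_repetition
#>   <chr>                   <dbl>         <dbl>            <dbl>           <int>
#> 1 decision_tree           0.611         0.667            0.667               5
#> 2 naive_bayes             0.75          0.75             0.743               3
#> 3 random_forest           0.694         0.75             0.703               3
```

Each row summarizes one classifier across the five held-out 30% test sets
(36 rows each here): the median and best accuracy, the median F-measure, and
which repetition produced the saved best model. `tidy(cv)` returns the full
per-repetition metric table (confusion counts, accuracy, sensitivity,
specificity, precision, recall, F-measure) and `autoplot(cv)` draws the
metric distributions.

Applying the best random forest to new sequences:

```r
predict(cv$best_models$random_forest, neg[1:5, ])
#> # A tibble: 5 × 4
#>   id           label    score model_kind
#>   <chr>        <chr>    <dbl> <chr>
#> 1 syn_neg_0001 negative  0.23 random_forest
#> 2 syn_neg_0002 negative  0.08 random_forest
#> 3 syn_neg_0003 negative  0.15 random_forest
#> 4 syn_neg_0004 negative  0.25 random_forest
#> 5 syn_neg_0005 negative  0.48 random_forest
```

`score` is the positive-class probability (here the forest vote fraction);
sequences score as `miRNA` at 0.5 and above. The folding/encoding layers are
equally usable on their own:

```r
f <- fold_hairpins(tibble::tibble(id = "hp1",
                   sequence = "GCGCCAGAAUUCGAAAGAAUUCUGGCGC"))
encode_structure(f)[, c("id", "structure", "characteristic", "score")]
#> # A tibble: 1 × 4
#>   id    structure                    characteristic               score
#>   <chr> <chr>                        <chr>                        <dbl>
#> 1 hp1   ((((((((((((....)))))))))))) gcgccagaauucGAAAgaauucuggcgc    12
```

## Command line

The same workflow is available as a thin script over the package functions:

```sh
Rscript inst/cli/hairpin3d.R simulate --n-pos 200 --n-neg 200 --seed 1 -o corpus/
Rscript inst/cli/hairpin3d.R fold corpus/positives.fa -o positives.vienna
Rscript inst/cli/hairpin3d.R featurize corpus/positives.fa -o positives.tsv
Rscript inst/cli/hairpin3d.R train --pos corpus/positives.fa --neg corpus/negatives.fa \
    --repeats 1000 --seed 1 -o models/
Rscript inst/cli/hairpin3d.R predict --model models/best_random_forest.model \
    new_candidates.fa -o predictions.tsv
```

Every command writes a key=value run manifest next to its output and exits
with 0 (success), 2 (input error), 3 (missing external folder), 4
(schema/model mismatch) or 1 (unexpected).

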