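---
title: "Classifying miRNA hairpins from 3D structure curves: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying miRNA hairpins from 3D structure curves: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hairpin3d)
```

## The problem

MicroRNA precursors are stem-loop RNAs, but so are countless genomic
segments that never produce a miRNA. Given a candidate hairpin sequence,
`hairpin3d` asks a single question: does its secondary-structure *geometry*,
summarized in 36 numbers, look like a miRNA precursor or like a
pseudohairpin? This vignette documents the model, every tunable parameter,
the synthetic corpus the package validates itself on, and the design
decisions that were genuinely open.

## From sequence to descriptor

**Folding.** Each sequence gets exactly one pseudoknot-free dot-bracket
structure. The default engine is a maximum base-pairing dynamic program:
among all non-crossing sets of admissible pairs (Watson–Crick A–U/G–C plus
the G–U wobble) whose hairpin loops enclose at least `min_loop` unpaired
bases, it returns one with the greatest number of pairs. This is a
combinatorial, not thermodynamic, model: it has no stacking energies, no
temperature, and it will pair far more of a random sequence than a free-energy
folder would. We chose it as the default because it is dependency-free,
exactly testable (its optimum can be verified by exhaustive enumeration on
short sequences, which the test suite does), and fully deterministic. A
thermodynamic MFE folder is available behind the `engine = "external"`
adapter, which accepts any RNAfold-compatible command; the descriptor and
classifiers are agnostic to which engine produced the structure, but models
trained on one engine's structures should only be applied to features from
the same engine.

Folding parameters:

* `min_loop` (bases, default 3) — the smallest hairpin loop a pair may
  enclose; 3 matches the physical minimum that thermodynamic folders
  enforce. Sequences shorter than `min_loop + 2` fold to the all-unpaired
  structure rather than raising an error.
* `allowed_pairs` (default `AU, UA, GC, CG, GU, UG`) — must be symmetric.
  Restricting to Watson–Crick pairs is one argument away.
* Traceback ties are broken deterministically: prefer leaving the interval's
  right end unpaired, then pair it with the leftmost admissible partner.
  Isolated (lonely) pairs are allowed; the maximum-pairing objective has no
  reason to forbid them, and forbidding them would be an additional model
  choice with no anchor.

**Case encoding.** The dot-bracket string is folded into the sequence
itself: unpaired bases stay uppercase, paired bases become lowercase. We
read "nonbonding/bonding" as dot/bracket and pair it with
"uppercase/lowercase" in the same order; the convention lives in a single
internal constant, so the opposite reading is a one-line change, and the
three-state dot-bracket string is retained alongside the letters — the case
coding alone cannot distinguish `(` from `)`, and the descriptor uses all
three states.

**The curve and the 36 features.** Every letter maps to a corner of
{−1, +1}³ via the three base dichotomies (purine/pyrimidine on x,
amino/keto on y, strong/weak hydrogen bonding on z), with lowercase letters
negated — pairing sends a base to the antipodal corner, so a base and its
bonded form cancel. The curve is the cumulative sum of these vectors from
the origin; the descriptor is, for each of the 12 (base × state) classes,
the class's mean curve point divided by the sequence length, zero for absent
classes. Consequences worth knowing:

* every feature lies in [−1, 1], and the encoding needs no per-corpus
  scaling;
* the division by length makes hairpins of different sizes comparable
  (corpora mix ~50–180 nt);
* the descriptor is order-sensitive — two sequences with identical class
  composition but different arrangements get different features — which is
  the point of routing composition through a curve;
* it contains *no explicit pairing fraction, loop count or energy*: only
  where, on average, each class of base sits in the three chemical
  coordinates.

The 36 column names (`A_unpaired_x` … `U_close_z`) are frozen and written
into every feature table header, so files are self-describing. An
independent naive per-position recomputation of the descriptor agrees with
the packaged implementation to 10⁻¹² in the test suite.

## The learning protocol

Class imbalance is removed before learning: `balanced_sample()` draws
`min(|pos|, |neg|)` records from each class without replacement. Each Monte
Carlo repetition then splits the balanced table stratified by class — the
per-class learning size is round-half-up of 0.70 × class size, the
remainder is the test set — trains the requested classifiers, and evaluates
on the held-out rows. Defaults are 1000 repetitions and a 0.70 learning
fraction. Per classifier, the model with the highest held-out accuracy is
kept (ties to the earliest repetition).

Classifier choices the package freezes, since the protocol itself does not
pin them:

* decision tree: a single `rpart` classification tree at its defaults;
* naive Bayes: Gaussian per feature with class priors from training
  frequencies, and a variance floor of 10⁻⁹ so that features constant
  within a class (absent descriptor classes are exactly 0) cannot produce
  degenerate likelihoods;
* random forest: 100 trees, ⌈√36⌉ = 6 features per split, both exposed in
  `cv_config()`.

Prediction scores are positive-class probabilities (posterior, leaf
fraction, vote fraction); the label threshold is 0.5 with ties going to the
positive class. Metrics follow the standard confusion-matrix formulas;
ratios with a zero denominator are reported as 0 and flagged in an
`undefined_metrics` column rather than propagating `NaN`.

**Reproducibility.** Repetition *r* runs under the derived seed
`(seed × 48271 + r) mod (2³¹ − 1)` — a fixed multiplicative congruential
scheme — so any single repetition can be reproduced in isolation, and whole
runs with equal configuration are byte-identical. All CLI randomness is
surfaced as one `--seed`.

## The synthetic corpus

`simulate_corpus()` provides labeled data without downloads. Positives are
stem–loop–stem sequences: stem length uniform on 18–30 bp, loop uniform on
4–12 nt, bases drawn at a target GC of 0.5, the 3′ arm the reverse
complement of the 5′ arm with each base broken with probability 0.10
(mismatches) and single-base bulges inserted at 0.05 per stem position —
roughly the imperfect stems of real precursors. Negatives default to
dinucleotide-preserving shuffles of such hairpins (an exact
Altschul–Erickson Euler-walk shuffle), which is the honest analogue of
pseudohairpins: identical mono- and dinucleotide composition, no designed
stem. An easier `random_matched` mode (i.i.d. bases at matched lengths)
exists as a baseline.

What the generator does **not** emulate: biogenesis sequence motifs, the
length–GC correlations of real genomes, conservation, or expression
evidence. Passing tests on this corpus therefore demonstrate that the
pipeline is correct and that the descriptor captures structural geometry —
not that the reported synthetic accuracies transfer to miRBase-scale data.

**Problem sizes.** The package validates itself on 200 + 200 records with
10 Monte Carlo repetitions (the scale `scripts/acceptance.R` runs), and the
unit suites use 40–1000 records per property; these sizes give stable
medians while keeping a full check of the package fast.

## Known limitations

The main one is a direct consequence of two honest choices above. The
descriptor encodes only normalized class centers, and the maximum-pairing
folder assigns even shuffled sequences a high paired fraction, so on the
default corpus — composition-matched decoys, geometric features only — the
classes overlap substantially: the acceptance script's median held-out
accuracies land around 0.7, and the three classifiers sit within a few
points of each other rather than the forest dominating. Users who need
stronger separation on composition-matched negatives should treat these 36
features as one block among several, not as a complete feature set.

Other limitations: no pseudoknots, no suboptimal structures, no ROC/AUC or
probability calibration, and ambiguity codes (N, R, Y, …) are rejected
outright — the cube mapping is undefined for them, and silently imputing a
base would corrupt the curve.
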