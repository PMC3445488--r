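---
title: "Predicting protease cleavage sites with mRMR feature selection and random forests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protease cleavage sites with mRMR feature selection and random forests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cleavesite)
```

## The problem

Proteinases cleave their substrates at specific peptide bonds. A cleavage
site is annotated as the two consecutive residues P1–P1' flanking the
scissile bond; given a protein sequence, the task is to decide for each
candidate bond whether it is cleaved. `cleavesite` treats this as binary
classification of fixed-size peptide windows centred on the bond, followed
by a feature-selection analysis that asks *which* residue properties, at
*which* window positions, carry the signal.

## Windows and coordinates

For a window of size $W = 2k$ ($W \in \{16, 18, 20, 22\}$) around the P1
residue at protein position $p$, window site $s$ covers protein position
$p - k + s$, so the window spans positions $p-k+1 \dots p+k$ and sites $k$
and $k+1$ always hold the annotated pair $p$, $p+1$ (sites 11 and 12 for
$W = 22$). Positions beyond either terminus are filled with the padding
symbol `X`, whose features are all zero. Coordinates are 1-based
throughout; non-standard letters in input sequences are rejected by
default (optionally mapped to `X`), because `X` is reserved for padding
and silently coercing unknown residues would distort the frequency
feature.

Negative windows are centred on non-cleavage bonds. They are pooled across
the whole protein set and sampled globally, without replacement, at a
fixed negative:positive ratio (default 3:1). A global pool — rather than a
per-protein quota — is used because the target is an overall class ratio;
per-protein allocation would over-sample short proteins. Negatives are
drawn after the protein-level train/test split, within each side, so no
distance-from-true-site constraint is imposed (none is biologically
motivated, and imposing one would optimistically bias the negatives
towards easy cases).

## The 32-feature residue encoding

Each non-padding residue contributes 32 features, concatenated in a fixed
order; a size-22 window therefore has $22 \times 32 = 704$ named columns
`AA{site}_{family}_{k}`:

| family     | width | content |
|------------|-------|---------|
| `pssm`     | 20    | PSI-BLAST conservation scores against each amino acid, column order A R N D C Q E G H I L K M F P S T W Y V |
| `disorder` | 1     | per-residue intrinsic-disorder score in $[0,1]$ |
| `aafactor` | 5     | Atchley factors: polarity, secondary-structure propensity, molecular volume, codon diversity, electrostatic charge |
| `sa`       | 2     | solvent accessibility one-hot: buried = 10, exposed = 01 |
| `ss`       | 3     | secondary structure one-hot: helix = 100, strand = 010, other = 001 |
| `freq`     | 1     | occurrence frequency of this residue's symbol at this window site among training positives |

PSSM scores are used as the raw PSI-BLAST log-odds integers. No squashing
or rescaling is applied: the downstream consumers (3-state discretization
for mutual information, and tree splits in the forest) are monotone
transformations away from scale, so a sigmoid would change nothing
qualitative while adding an arbitrary constant. The reader accepts the
standard ASCII matrix dialect and takes the first 20 score columns.

The frequency family deserves a note. The per-site frequency table is the
empirical distribution of the 21 symbols (20 amino acids + `X`) at each
window site among *training positives*; the feature of a residue is the
lookup of its own symbol at its site. By default the table is built once
from all training positives before cross-validation — the classical
protocol for this analysis, which leaks a small amount of label
information into CV folds. `run_pipeline(fold_safe_freq = TRUE)` instead
rebuilds the table inside each CV training fold and re-encodes that fold's
held-out windows, giving a slightly pessimistic but leakage-free CV
estimate. The default reproduces the classical protocol; the flag exists
so the cost of the leak can be measured rather than argued about.

External per-residue predictions (PSSM, disorder, secondary structure,
accessibility) enter through a *provider* contract: the package never runs
PSI-BLAST or structure predictors itself, it reads their file formats (or
synthetic stand-ins) and encodes from there.

## Feature ranking: mutual information and mRMR

Relevance and redundancy are both measured by mutual information in bits,

$$I(X;Y) = \sum_{x,y} p(x,y)\,\log_2 \frac{p(x,y)}{p(x)\,p(y)},$$

estimated by the plug-in (empirical frequency) estimator on discretized
features. Continuous columns are binned into 3 states at
$\mu \pm \alpha\sigma$ (default $\alpha = 1$); one-hot indicator columns
pass through as 2 states; constant columns collapse to one state and have
relevance 0 by definition. Three states at $\mu \pm \sigma$ is the common
practice for discrete mRMR on continuous features; $\alpha$ and the log
base are surfaced as parameters so their influence can be explored, but
the defaults are the package's committed choices.

**MaxRel** ranks features by $I(f; \text{label})$ alone. **mRMR** builds a
greedy forward ordering: round 1 picks the most relevant feature, and
round $h+1$ picks the unselected feature maximizing

$$I(f;\text{label}) \;-\; \frac{1}{|S|}\sum_{g \in S} I(f; g),$$

the *difference* (MID) form of the criterion, with $S$ the already
selected set. The difference form is used because the selection criterion
combines relevance and redundancy additively; the quotient (MIQ) variant
is a different estimator family and is out of scope. Exact score ties
resolve to the lower original column index so every ranking is
reproducible. A smaller selection round means a better
relevance/redundancy trade-off.

## Incremental feature selection and metrics

With the mRMR ordering $f_1, f_2, \dots, f_N$, IFS evaluates the nested
prefixes $S_i = \{f_1, \dots, f_i\}$: for each $i$ a random forest is
scored by stratified 5-fold cross-validation restricted to $S_i$, and
Sn/Sp/Ac/MCC are recorded:

$$\mathrm{Sn} = \frac{TP}{TP+FN},\quad
\mathrm{Sp} = \frac{TN}{TN+FP},\quad
\mathrm{Ac} = \frac{TP+TN}{TP+TN+FP+FN},$$

$$\mathrm{MCC} = \frac{TP \cdot TN - FP \cdot FN}
{\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}.$$

The optimal feature set is the prefix with maximal MCC, ties resolved to
the smallest prefix (parsimony). MCC is the selection criterion because
the class ratio is 3:1 and accuracy saturates at 75% for the trivial
all-negative classifier. Degenerate confusion tables follow the standard
conventions: a zero MCC denominator factor gives MCC = 0 (with a warning);
Sn or Sp with a zero denominator is reported as missing.

Folds are stratified at window level (each fold keeps the 3:1 balance);
with a few hundred positives, unstratified folds would make the per-prefix
MCC estimates noticeably less stable. Fold assignment is shared across all
prefix sizes under one seed, so IFS rows are directly comparable and a
capped run (`max_prefix`) is row-for-row identical with the leading rows
of an uncapped run. `step` allows coarse scans; `run_pipeline` uses a
two-phase scan (every prefix up to 12, then every 4th up to 60) to keep
the study-scale scenario's compute proportionate — the MCC curve's rise
happens in the first dozen prefixes and the plateau needs only sparse
sampling.

## The random forest stage

Classification uses the Breiman–Cutler random forest (the `randomForest`
package): each tree is grown on a with-replacement bootstrap of the
training windows, fully grown and unpruned, with
$m_{\text{try}} = \lfloor \log_2 M \rfloor + 1$ variables tried per split
(the classical "much less than M" convention). The default is 100 trees —
enough that CV estimates are stable run-to-run at this problem size —
with the tree count exposed for leaner configurations. Prediction is by
majority vote; an exact vote tie (possible with an even tree count)
resolves to the positive class, a documented, tested convention chosen so
ties err towards sensitivity in the imbalanced setting. Models store
their feature names and refuse prediction inputs whose columns do not
match by name, so column order can never silently corrupt a prediction.

Final reporting trains once on all training windows restricted to the
optimal feature set and evaluates on windows from held-out proteins; the
evaluator refuses any train/test accession overlap.

## The synthetic data generator

Real inputs require UniProt annotations plus PSI-BLAST/disorder/structure
runs, none of which are reproducible offline. The generator therefore
produces the *geometry* of the study conditions with a planted, tunable
signal:

* **Sequences**: i.i.d. from a background distribution (default uniform
  over the 20 amino acids, which keeps null calibration analytic — every
  symbol has frequency 0.05 under the null).
* **Motif**: at each planted P1 position, the bond residues are redrawn
  from per-site emissions mixed with the background at `strength`
  (default 0.8). Defaults: P1 (site 11) R = 0.50, D = 0.30; P1' (site 12)
  S = 0.30, A = 0.25, G = 0.25 — the arginine/aspartate and
  small-residue preferences seen around real cleavage sites. Strength 0
  makes positives indistinguishable from background (tested by
  chi-square); strength 1 emits the motif exactly.
* **Providers**: synthetic PSSMs are integer noise (sd 2) with +8 on the
  own-residue column, so conservation tracks the sequence and the argmax
  recovers the residue at >80% of positions; disorder is uniform noise
  (deliberately uninformative); strand probability rises to 0.60 within
  ±2 residues of a planted bond and buried probability to 0.85 at the
  bond residues, echoing the strand/buried preferences of real sites.
* **Default scenario**: 459 proteins (lengths uniform 60–600) carrying
  712 planted sites, split protein-wise 371/88, negatives at 3:1 within
  each split — about 578/1734 training and 134/402 testing windows.

What passing tests on this generator do show: the pipeline's machinery —
encoding, ranking, IFS, evaluation — recovers a signal planted at the
bond sites, concentrated in the site-11/12 features, with cross-validated
MCC well above 0.5. What they do not show: performance on real proteomes,
where sequence composition is non-uniform and autocorrelated, homologous
proteins share windows, disorder is informative, and the motif differs by
protease family. The synthetic signal is deliberately stronger and
cleaner than nature; numbers obtained on it characterise the software,
not any protease.

## Numerical and degenerate-input choices

* Mutual information: log base 2 (bits) everywhere; plug-in estimator;
  zero-probability cells contribute zero.
* Discretization: $\mu \pm 1\sigma$, 3 states; binary columns pass
  through; constant columns are a single state with relevance 0, ranked
  last.
* Tie-breaks: mRMR and MaxRel by original column index; optimal prefix by
  smallest size; forest vote ties to positive.
* Splits: `test_fraction` near 0 or 1 is floored/capped so both sides are
  non-empty; fewer than 2 proteins is an error.
* Over-requested negatives drain the pool with a warning rather than
  failing, since short fixture proteins hit this routinely.
* All randomness (splits, negative sampling, folds, forests, generator)
  flows through explicit integer seeds; the full pipeline is bit
  reproducible under one master seed.

## Problem sizes used in the shipped checks

The shipped test-suite and the acceptance script run the default scenario
(2,300 training windows × 704 features) with mRMR stopped after 60 rounds
and the two-phase IFS scan described above, plus oracle comparisons at
small sizes (≤ 200 samples, ≤ 8 features) where exhaustive independent
re-implementations are feasible. These sizes were chosen so the whole
analysis re-runs from scratch in minutes on one CPU while still exercising
the study-scale geometry end to end.

## Known limitations

* The optimal feature *list* on real data depends on the upstream
  predictors' versions and databases; only the procedure, not a specific
  65-feature list, is reproducible.
* The plug-in MI estimator is biased upward at small sample sizes; with
  ~2,300 windows and ≤3 states the bias is far below the between-feature
  relevance differences that drive the ranking, but rankings from a few
  dozen windows should not be over-interpreted.
* `disorder` enters as a single score per residue; predictors that emit
  per-class disorder probabilities must be reduced to one score upstream.
* No homology reduction is performed on input protein sets; if near
  duplicates span the train/test split, holdout metrics are optimistic.
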