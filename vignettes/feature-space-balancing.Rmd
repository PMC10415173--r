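---
title: "Feature-space balancing for k-mer based taxonomic classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature-space balancing for k-mer based taxonomic classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kbalance)
```

## The problem

Taxonomic classification assigns a DNA fragment — here, fixed-length
fragments of around 1500 nt, as produced by shotgun metagenomic protocols —
to a taxon at a chosen rank (superkingdom, phylum, genus). kbalance
implements a lightweight alternative to alignment- and deep-learning-based
classifiers: each fragment is reduced to its **relative k-mer frequency
profile**, and simple ensemble classifiers are trained on those profiles.
The distinctive step is a label-blind **feature-space balancing** of the
training set, which markedly improves the macro-averaged precision of the
downstream classifiers by flattening the density of training samples over
the profile space.

## The feature space

For word length $k$, a sequence of length $L$ contains $L-k+1$ sliding
windows. Every window consisting solely of A, C, G, T is counted; the
profile is

$$x_w = \frac{\text{count}(w)}{\sum_{w'} \text{count}(w')},
  \qquad w \in \{A,C,G,T\}^k,$$

a point on the $4^k$-simplex. Windows containing ambiguity codes (N, R, Y,
...) are skipped **and excluded from the denominator**, so profiles remain
on the simplex for any input; a record with no valid window is dropped with
a message rather than silently producing NaNs. Features are ordered
lexicographically with A < C < G < T, and that ordering is stored in file
headers and model fingerprints so columns never silently permute between
runs. Both strands are kept distinct (no reverse-complement collapsing):
all $4^k$ words are separate features. The default $k = 3$ (64 features)
is the best runtime/precision trade-off for this family of pipelines;
$k \le 8$ is enforced as a guard against accidental $4^k$ blow-up.

## The balancing algorithm

Training collections assembled from reference genomes are dense in some
regions of profile space and sparse in others — many near-identical
fragments of over-represented genomes versus few from rare taxa.
Classifiers then spend their capacity on the dense regions (overfitting
there) while underfitting the sparse ones. Balancing undersamples the
dense regions.

Each of the $D = 4^k$ dimensions of $[0,1]$ is discretized into $G$
equidistant bins (`floor(x * G)`, the value 1.0 clamped into the last
bin), so a profile lives in a cell of a conceptual $G^D$ grid. Only
occupied cells are stored, in a hash map keyed by the exact index tuple —
memory grows with the number of occupied cells (at most the number of
samples), never with $G^D$.

Candidates are streamed in a seeded random permutation of the training
rows, without replacement:

1. **Initialisation.** The first $\lfloor 0.3\,N \rfloor$ candidates are
   accepted unconditionally ($N$ is the target training-set size). They
   count toward the budget, the cell counts and the running maximum.
2. **Screening.** For a candidate in cell $g$, let $C_g$ be the current
   count in that cell and $C_{\max}$ the highest cell count observed so
   far. The candidate is **accepted** if $C_g < C_{\max}$ and **rejected**
   (discarded permanently) if $C_g = C_{\max}$. Sparse cells therefore
   fill preferentially; empty regions stay empty — this is undersampling,
   not synthesis.
3. **Escape hatch.** After 10 consecutive rejections the next candidate is
   accepted unconditionally (and may raise $C_{\max}$), so the stream
   cannot stall once every remaining candidate sits in a saturated cell.
4. The loop ends when $N$ samples are accepted or the stream is exhausted.

Defaults are $G = 10$ and an `init_fraction` of 0.3; the budget $N$ is the
user's main lever (larger grids cost more and change results little; in
the large-scale regime this method targets, $N$ on the order of $6\times
10^5$ is a sensible ceiling).

Design choices worth stating explicitly, since several variants are
defensible:

* **Without-replacement stream.** A "randomly selected" candidate could
  also be drawn with replacement; a permutation guarantees termination,
  forbids duplicate training rows, and makes "10 *consecutive* rejections"
  well defined. This is the one place where another implementation of the
  same idea could legitimately produce different accepted sets.
* **Global rejection counter.** The counter is shared across cells and
  resets on any acceptance — the simplest reading of "consecutive".
* **Initialisation is label-blind**, uniform over the whole set, like the
  screening itself. (The method never looks at labels; it balances
  geometry, not classes.)
* Diagnostics record, per occupied cell, the occupancy before
  ($C_{\text{before}}$) and after ($C_{\text{after}}$) balancing,
  $\bar C = (C_{\text{before}}+C_{\text{after}})/2$ and
  $\Delta C = C_{\text{after}}-C_{\text{before}} \le 0$;
  `autoplot()` shows $-\Delta C$ against $\bar C$ on log–log axes, where
  density-targeted removal appears as a positive trend.

The implementation is validated index-for-index against an independent
dense-array reference implementation (the full $G^D$ count array,
feasible at $k=1$) across many seeds.

## Classifiers

The classifiers are deliberately ordinary, and stand on standard fits
(`rpart`, `class::knn`, `MASS::lda`, `e1071::svm`, `nnet`):

| family | construction | defaults |
|---|---|---|
| `bagged_trees` | trees on bootstrap resamples, majority vote | 100 learners |
| `subspace_knn` | KNN on random feature subsets, majority vote | 30 learners, $\lceil D/2 \rceil$ features, $k_{nn}=10$, Euclidean |
| `subspace_discriminant` | LDA on random feature subsets, vote | 30 learners, $\lceil D/2 \rceil$ features |
| `svm_linear` / `svm_gaussian` / `svm_polynomial` | single SVM, internally standardised | libsvm defaults |
| `mlp` | one hidden layer, softmax, standardised inputs | 512 units, fixed iteration cap |

Votes are hard labels; ties break towards the lowest index in the model's
lexicographically ordered class list, so prediction is reproducible.
Tree and KNN families use the raw profiles (already in $[0,1]$); SVM and
MLP standardise internally. Every fit is deterministic given its seed, and
models carry a feature fingerprint (dimension and k-mer ordering) that
prediction verifies, plus a format version checked on `load_model()`.
These defaults are this package's own documented choices; no claim is made
of matching any other implementation's default hyperparameters, and the
package's qualitative conclusions do not depend on them. The MLP's
"small network" default caps iterations rather than monitoring a
validation set.

## Evaluation

The metric is macro-average precision,

$$\mathrm{MAP} = \frac{1}{|C|} \sum_{i \in C}
  \frac{TP_i}{TP_i + FP_i},$$

the unweighted mean of per-class precision, so rare classes count as much
as common ones. The class set $C$ is the union of observed and predicted
labels. A class that is never predicted has an undefined precision ratio;
it scores 0 here (the conservative choice — a degenerate model that never
risks a class is penalised), and the count of such classes is reported as
`n_undefined` so the drop-from-mean variant can be recomputed.

## The synthetic benchmark

Testing a balancing method needs data whose feature-space density is
controllably non-uniform, with known labels, and without external
downloads. The generator draws each class from a first-order Markov chain
over A, C, G, T. The built-in presets use GC-parameterised "sticky"
chains,

$$P = \alpha I + (1-\alpha)\,\mathbf{1}\pi^\top, \qquad
  \pi = \left(\tfrac{1-gc}{2}, \tfrac{gc}{2}, \tfrac{gc}{2},
  \tfrac{1-gc}{2}\right),$$

whose stationary composition is exactly $\pi$ for any stickiness
$\alpha$, so GC targets are hit exactly while $\alpha$ controls
run-length structure.

* `separated4`: four equally weighted classes with GC targets
  0.30 / 0.43 / 0.57 / 0.70.
* `blob_imbalanced`: the same four classes, with 85% of the sampling
  weight on the `gc43` class — one dense blob in feature space, three
  sparse regions.

Two generator choices matter and were fixed at design time:

* **Stickiness** ($\alpha$ = 0.65 / 0.55 / 0.65 / 0.55 across the four
  classes). With a plain composition chain ($\alpha = 0$), every 1500-nt
  fragment's 3-mer frequencies sit below 0.1 and all profiles collapse
  into a single $G=10$ grid cell, making balancing a no-op by
  construction. Stickiness puts homopolymer-run features
  (AAA, TTT, CCC, GGG) into the 0.1–0.3 range with real per-sequence
  spread, so profiles occupy tens of cells — the regime the method is
  about. Real genomic fragments reach this regime through repeats and
  low-complexity regions.
* **Alternating texture.** Classes adjacent in GC differ in stickiness,
  so they also differ in a higher-order statistic, as real taxa differ in
  oligonucleotide usage beyond base composition. This is why $k = 3$
  profiles separate the classes better than $k = 1$ profiles — with
  identical textures, composition ($k=1$) would already carry all the
  between-class signal and larger $k$ would only add variance.

What the generator does **not** emulate: repeat families, codon and gene
structure, contamination, sequencing error, shared phylogenetic signal
between classes. Passing tests on these benchmarks therefore demonstrate
the correctness and the qualitative behaviour of the pipeline (balancing
targets dense cells; balanced training beats size-matched random
subsampling under density imbalance; $k=3 \ge k=1$; near-perfect recovery
of well-separated classes), not absolute precision values on real genomic
collections.

## Scale of the shipped experiments

The packaged tests and the acceptance script run the benchmarks at
desk scale: 2 000 training / 800 test fragments of 1500 nt, $k \le 3$,
budgets around 800, 3–10 replicate seeds. These sizes were chosen so the
full suite runs in minutes on one core while leaving the comparisons'
directions far from their decision boundaries; the same code paths run
unchanged on collections several orders of magnitude larger, where the
balancing budget $N$ and grid size $G$ defaults are tuned for.

## Numerical and degenerate-input choices

* Profiles sum to 1 within 1e-9 by construction (exact rational counts).
* `floor(x * G)` with the 1.0-clamp makes bins half-open except the last;
  ties at bin edges are deterministic.
* An empty grid with `init_fraction = 0` rejects its first candidate
  ($C_g = 0 = C_{\max}$) until the escape hatch fires; the default 0.3
  initialisation avoids this corner. It is deliberately not special-cased:
  the accept rule is applied verbatim.
* Single-class training data yield a constant predictor for families that
  allow it; discriminant/SVM families refuse with an error.
* `U` (RNA) folds to `T`; lower-case folds to upper-case; sequences with
  characters outside the IUPAC set are refused with the record index.

## Limitations

* Balancing is label-blind by design; it does not address class imbalance
  per se and can starve a minority class whose profiles coincide with a
  dense majority region.
* One model per taxonomic rank; no hierarchical consistency between ranks.
* No reverse-complement canonicalisation: strand-flipped duplicates count
  as distinct feature vectors.
* The k-mer counter and the balancer are exact but single-threaded R;
  very large collections will want chunked profile computation (the
  profile TSV format is append-friendly).
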