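---
title: "Classifying phage, chromosome and plasmid fragments: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying phage, chromosome and plasmid fragments: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Assembled metagenomes are a mixture of prokaryotic chromosome fragments and
mobile genetic elements — bacteriophages and plasmids. Telling the three
apart matters for studying horizontal gene transfer, virulence and
antibiotic-resistance spread, but most assembled contigs are short (hundreds
of bases), too short for gene-based homology tools, and k-mer frequency
vectors become noisy at those lengths. `mgeclass` takes the alternative
route: it feeds the *raw sequence*, one-hot encoded two ways, to a dual-path
convolutional network and lets the convolutions learn the discriminative
composition signals directly.

## Sequence representation

A fragment of length $L$ is encoded twice:

* **Base one-hot matrix** ($2L \times 4$). Each base of the forward strand,
  then each base of the reverse complement, becomes a 4-bit one-hot row:
  A = [0,0,0,1], C = [0,0,1,0], G = [0,1,0,0], T = [1,0,0,0]. The map is
  strand-symmetric: the vector of a base's complement is the reversal of the
  base's vector, so the two strands carry mirrored rather than unrelated
  codes. This view is informative for non-coding sequence.
* **Codon one-hot matrix** ($2(L-2) \times 64$). The fragment is expanded
  into all six reading frames (forward offsets 0, 1, 2, then the reverse
  complement at offsets 0, 1, 2); each complete codon becomes a 64-bit
  one-hot row. Incomplete trailing codons are discarded, which is where the
  exact row count $2(L-2)$ comes from (the sum of $\lfloor (L-o)/3 \rfloor$
  over offsets and strands). This view is informative for coding sequence
  without requiring an ORF call.

Choices the representation had to make, and why:

* **Codon column order** is lexicographic over A < C < G < T (AAA = 1, ...,
  TTT = 64). Any fixed order works for a learned model; lexicographic is
  reproducible and auditable.
* **Ambiguous letters** (N and the other IUPAC codes) become all-zero rows
  rather than errors: real assemblies contain them, and a zero row simply
  contributes nothing to a convolution.
* **Strand and frame order** is fixed (forward first) so encodings are
  bit-reproducible.
* **Padding.** Each length group's network has a fixed input shape
  ($2 L_{max}$ rows); shorter fragments are zero-padded *after* the data
  rows, identically at training and prediction time. Global average pooling
  plus consistent padding keeps the train and test input distributions
  matched.

## The network

One model per length group: group A serves 100–400 bp, B 401–800 bp, C
801–1,200 bp (the published ranges overlap at their endpoints; we assign
boundaries to the lower group to make routing deterministic). Each model has
a base path and a codon path with identical layout:

| layer | configuration |
|---|---|
| conv 1 | 64 kernels, length 6, ReLU |
| maxpool | length 3 |
| batchnorm + dropout | per-channel over batch × time |
| conv 2 | 128 kernels, length 3, ReLU |
| maxpool | length 3 |
| batchnorm + dropout | |
| conv 3 | 256 kernels, length 3, ReLU |
| global average pooling | one mean per feature map |

The two 256-vectors are concatenated (512), passed through a dense ReLU
layer of the same width, and a 3-way softmax emits the (phage, chromosome,
plasmid) probability triple. Training uses Adam on categorical
cross-entropy.

### What the source description leaves open, and our defaults

The published architecture names the optimizer and loss but not the training
hyperparameters. We surface all of them as arguments instead of hard-coding
guesses: dropout rate (default 0.3, a conventional mid-range value), Adam
learning rate 1e-3 with standard moment decays, 20 epochs, batch size 128.
"Batch normalization layers with the dropout operation" is read literally as
batchnorm followed by dropout in one block. Convolutions use no implicit
padding ("valid") because the input is already zero-padded externally to the
group shape. The dense width (512) follows from "the same number of nodes as
the previous layer" applied to the 256+256 concatenation; for single-path
ablation models the concatenation and dense width are 256.

### Implementation notes

No deep-learning framework is assumed: the network — forward pass,
backpropagation, batchnorm, inverted dropout, Adam — is implemented in
RcppArmadillo, in single precision, with im2col+GEMM convolutions. The
one-hot structure of the input makes the first convolution a gather-sum
(and its weight gradient a scatter-add), which removes the single largest
GEMM. Numerical specifics worth knowing:

* Batchnorm inference uses exponential running moments (momentum 0.9) with
  **bias correction** ($\hat\mu = \text{EMA}/(1-0.9^t)$). Without the
  correction, short trainings (few dozen batches) systematically misscale
  inference activations; this is observable as a large train/test accuracy
  gap and was fixed for exactly that reason.
* All randomness (weight init, shuffling, dropout) derives from explicit
  integer seeds via a dedicated Mersenne Twister, so runs are reproducible
  to the bit on one platform.
* Adam moment estimates live inside one `train_model()` call; a second call
  continues from the current weights with fresh moments.
* An untrained model (zero batchnorm updates) falls back to identity
  normalisation, so seeded-but-untrained models still produce valid,
  reproducible softmax triples — useful for structural tests.
* Argmax ties in labelling break in the fixed order phage > chromosome >
  plasmid (ties are measure-zero but must not be platform-dependent).

## Windowed prediction of long sequences

Sequences longer than 1,200 bp are cut into non-overlapping 1,200 bp
windows, the last window keeping whatever remains. Each window is scored by
its length group's model and the triple for the whole sequence is the
length-weighted average $\sum_i w_i \, s_i$ with $w_i = \ell_i / L$. A
2,500 bp sequence therefore produces windows of 1,200, 1,200 and 100 bp
routed to models C, C and A with weights 1200/2500, 1200/2500, 100/2500.

Two edge cases the published description does not settle; our choices:

* **Remainder windows shorter than 100 bp** are still scored (routed to
  group A, zero-padded) and weighted by their true length — dropping them
  would silently break the weight normalisation.
* **Whole fragments shorter than 100 bp** are below the smallest training
  length and would be out-of-distribution; they are skipped with a warning
  (and an optional skip file in the CLI), never silently dropped.

With a user threshold $t$, a prediction whose maximum score is below $t$
keeps its argmax class but gains an "uncertain " prefix, yielding six output
categories; at the default $t = 0$ the argmax label is always certain, and
raising $t$ can only grow the uncertain set (a property the tests assert).

## The fragment simulator: a stated world

The original training corpus is hundreds of thousands of genome-derived
fragments; reproducing it requires external downloads, so the package ships
a self-contained generator that emulates the *statistical shape* of that
protocol:

* **Class "genomes"** are order-3 Markov chains over {A,C,G,T} whose
  context rows are drawn from a symmetric Dirichlet with concentration
  $\alpha = 0.3$ — low enough that each class has a distinctly peaky
  oligonucleotide composition, which is the feature axis real phages,
  chromosomes and plasmids differ along (codon usage, tetranucleotide
  bias). The three models must be pairwise separated by a mean per-row
  total-variation distance above 0.25; this makes the default fixtures
  "easy" by construction, and a naive 3-mer nearest-centroid baseline
  confirms it (accuracy > 0.9), so a green learnability test certifies the
  training machinery, not miraculous feature learning.
* **Fragments** have i.i.d. uniform lengths on the closed group ranges
  (100–400, 400–800, 800–1,200, 5,000–10,000 bp) and uniform start
  positions; the error-free preset returns verbatim substrings.
* **Substitution channel:** each base is independently replaced by a
  uniformly chosen *different* base with probability `p_sub` (the published
  protocol sets equal error rates at read start and end, which collapses to
  a position-independent rate).
* **Indel channel:** each position independently triggers an event with
  probability `p_indel`; the event is an insertion of a uniform random base
  before the position or a deletion of it, 50/50 (reading "insertion and
  deletion error rates both 0.5" as the split between the two event types).
  Insertion bases are uniform because the simulator being emulated does not
  document its insertion model.

What the generator deliberately does **not** emulate: technology-specific
error profiles (quality ramps, homopolymer errors), paired ends,
coverage/abundance structure, shared sequence between classes (prophages,
integrated plasmids), or the phylogenetic correlation structure of real
genomes. A model that is perfect on this synthetic world has demonstrated
that the encoding, network and training loop work — not that it matches the
published tool's accuracy on real data, which is explicitly out of scope
here.

## Evaluation machinery

* **Confusion matrix** (3×3, rows = truth, columns = prediction, fixed
  class order). Uncertain predictions are excluded by default
  (`uncertain = "drop"`) or mapped to their class (`"strip"`).
* **One-vs-rest metrics** per class: TPR = TP/(TP+FN) and
  FPR = FP/(TN+FP) from argmax labels; AUC ranks the positive class's
  softmax score against all other fragments. The production AUC builds the
  ROC curve explicitly (tie-grouped operating points, trapezoidal area);
  the test suite checks it against an independent $O(n^2)$ Mann–Whitney
  count with half credit for ties, to 1e-9. The multiclass construction is
  one-vs-rest on the raw class score — the only construction consistent
  with reporting a per-class AUC from a 3-class softmax.
* **Threshold sweep:** uncertain rate plus accuracy/TPR/FPR on the certain
  subset, per threshold; rows where everything is uncertain are `NA`, not
  errors.
* **Derived scores:** life_score = (phage − chromosome)/phage and
  trans_score = (plasmid − chromosome)/plasmid. Zero denominators are
  flagged (`*_defined = FALSE`), not thrown: they occur legitimately at the
  simplex boundary.

## Scale of the shipped tests

The acceptance-grade learnability test runs the stated protocol — 2,000
fragments per class in group A, 1,500/500 train/test split — but with 6
training epochs (the criterion allows up to 20): on the stated synthetic
world the model converges well before that, and 6 epochs keep the suite
inside a desktop-CPU budget. The label-shuffled control trains on 600
fragments per class for 3 epochs, since chance-level accuracy is scale-free.
The path-ablation property test (single path must not beat the dual path by
more than 0.05 accuracy) runs at 800 fragments per class for the same
reason. None of these reductions change what is being asserted, only the
compute spent asserting it.

## Known limitations

* Synthetic Markov classes are far cleaner than real genomes; accuracy
  numbers on them say nothing quantitative about real metagenomes.
* Single precision bounds reproducibility across BLAS builds; seeded runs
  are bit-reproducible only on a fixed platform.
* The CNN engine is CPU-only and trains at desk scale (thousands of
  fragments), not corpus scale (hundreds of thousands).
* Chimeric sequences (e.g. a prophage–chromosome junction) receive one
  blended score triple; the windowing machinery localises signal only down
  to 1,200 bp resolution.
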