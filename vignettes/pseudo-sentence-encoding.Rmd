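---
title: "Encoding primer-template interactions as pseudo-sentences and predicting PCR outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Encoding primer-template interactions as pseudo-sentences and predicting PCR outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcrlingo)
```

## The idea

Whether a PCR succeeds depends not on the primer or the template alone
but on the duplexes they can form: partial 3'-anchored primer-template
binding, primer hairpins, primer dimers, and — once product
accumulates — binding of primers to the fully complementary amplicon.
`pcrlingo` turns the whole set of predicted duplexes for one
primer-pair x template combination into an ordered list of five-letter
words (a *pseudo-sentence*) and trains a recurrent (LSTM) binary
classifier on labeled sentences, so that PCR success becomes a
sentence-classification problem.

## The pentacode alphabet

Each base pair (primer base against the template-strand base it faces)
falls into one of five stability classes:

| class | base pairs |
|------|-------------------------------|
| 0 | A-T, T-A |
| 1 | C-G, G-C |
| 2 | A-A, A-G, G-A, G-G, C-C |
| 3 | T-T, T-C, C-T |
| 4 | C-A, A-C, G-T, T-G |

Classes 0-1 are the Watson-Crick pairs; 2-4 group mismatches by their
effect on duplex stability. Each class maps to one letter per
*context*: `a-e` for initial-stage binding in forward orientation
(early cycles, primer on the original template), `f-j` initial-stage
reverse, `p-t` / `u-y` for middle-stage binding (late cycles, primer on
the fully complementary PCR product), and `k-o` for hairpins and
dimers. Letters at the two selected priming sites are uppercased.
A word always uses a single context set and a single case, so the
vocabulary holds 5^5 x 5 x 2 = 31,250 distinct pentacodes
(`vocabulary_size()`).

## From duplexes to words

A letter run is chunked into 5-letter words starting from the 3' end; a
5' remainder shorter than five letters is dropped. With `n` chunks, the
chunk at distance `d` from the 3' end is emitted `n - d` times, so the
3'-most chunk is the most repeated and longer duplexes emit
quadratically more words (`n(n+1)/2` in total). This realizes, in one
monotone rule, the two facts the encoding must carry: binding length
and 3'-proximity both matter, and the 3' terminus matters most.
The source material never shows partial words or spells the repetition
counts out, so both the dropped-remainder rule and the `n - d`
multiplicity are fixed here as package contracts and covered by tests.

A sentence is assembled in a fixed order: hairpin words first, then
dimer words, then — walking the template forward strand by candidate
start — each binding candidate's initial-stage words, with the two
selected priming sites uppercased and immediately followed by their
middle-stage words. Middle-stage words stay lowercase: uppercase is
reserved for marking the initial-stage priming words, and the
middle-stage letter sets already identify those words unambiguously.
Repetition applies to every region type, including hairpins and
dimers, for uniformity.

## Finding binding candidates

For every 3'-terminal primer suffix of length 5 to 22 and every
position on either template strand, a candidate is reported when the
Watson-Crick match count reaches `ceiling(0.8 * length)`. Only maximal
candidates survive: a qualifying suffix wholly contained in a longer
qualifying suffix at the same 3' anchor is suppressed, so one binding
event yields one region. Coordinates are 0-based half-open on the
forward strand; "forward" orientation means the primer anneals to the
reverse-complement strand (its text matches the forward strand), so
extension proceeds along the forward strand.

Hairpins require at least 5 contiguous Watson-Crick pairs with a loop
of at least 3 bases (the physical minimum); dimers at least 5
contiguous pairs at any antiparallel offset, including self-dimers.
Structures with at least 5 paired bases and a recessed 3' end are
extended (one fill-in to the partner's 5' end, no strand displacement)
and the products join the primer set for one further round by default,
capped at 16 members. Lettering of hairpins/dimers into words uses the
stricter 6-base threshold; the two thresholds are deliberately separate
configuration values (`extension_min`, `structure_word_min`) because
detection-for-extension and lettering are described with different
minimum lengths, and the package does not guess a single intent.

## Thermodynamics and priming-site selection

Duplex stability is the bare nearest-neighbor stack sum
`dG = dH - T dS` evaluated at the 56 C annealing temperature
(329.15 K), with dH in kcal/mol and dS in cal/(mol K). No initiation,
terminal or salt corrections are applied — the model the encoding needs
is a relative ranking of candidate sites, and adding corrections is a
configuration hook rather than a default. Watson-Crick stacks use the
unified nearest-neighbor set; single-mismatch stacks use published
single-mismatch series; any stack still undefined after symmetrization
is filled with the arithmetic mean of defined stacks carrying the same
mismatch class(es). The table ships as an editable TSV
(`inst/extdata/nn_stacks.tsv`) with a `source_tag` column, and the
loader enforces exact strand symmetry, so a duplex scores identically
read from either strand.

The priming sites are the forward x reverse candidate pair minimizing
the summed dG subject to a span (`rev_end - fwd_start`, the would-be
amplicon) of at least 100 bases. The span endpoints are a package
choice; the separation rule is stated only as "100 bases or more".
Ties break deterministically: lower forward-site energy first, then
smaller forward start.

## The classifier

Tokens are indexed densely (0 = padding, 1 = out-of-vocabulary),
embedded (default 128 dimensions), and run through an LSTM (default one
layer, 128 hidden units, forget-gate bias 1) whose hidden state at the
last real token feeds a two-logit softmax head trained with
cross-entropy and Adam (learning rate 1e-3, batch 32, default 200
epochs). The original architecture and hyperparameters behind the
reference results were never published, so these values are fixed by
this package and numerical parity with the reference accuracies is not
claimed. The head is zero-initialized, so an untrained model outputs
probability 0.5 for everything; with imbalanced data the first epochs
collapse to the majority class — on PCR-style data, negative-class
accuracy 1.0 and positive-class accuracy 0.0, which the evaluation
history records per epoch (positive, negative, and all-sample
accuracy). Gradients are checked against finite differences in the
test suite; padding rows carry no gradient, and sequences are padded
per batch with no truncation by default. All randomness flows from one
seeded generator recorded in the run manifest.

## Evaluation

Cross-validation splits samples within each (template, label) stratum,
dealing shuffled samples round-robin into k = 5 groups (per-stratum
sizes differ by at most one); each group validates once and the five
validation cross tables sum into one pooled table. The cross table is
oriented rows = prediction, columns = PCR result; sensitivity
`tp/(tp+fn)`, specificity `tn/(tn+fp)` and accuracy `(tp+tn)/total`
follow. Undersampling, when requested, precedes the split and
subsamples majority-label samples per template down to the minority
count. Conditions are compared with both Student's and Welch's
two-sided t-tests over the five fold-level metric values. Test-set
style evaluation applies each fold's model separately and reports mean
and spread rather than averaging the five models' votes.

## The synthetic generator

`generate_dataset()` emulates the study geometry: 31 random templates
of 435-481 bases (GC 0.4-0.6), 72 primer pairs of 19-22 nt planted with
100-150 bp amplicons, about a quarter exact matches and a quarter
degraded matches (mutations at 8% per base, never in the 3'-terminal 5
bases, because a single 3' base can decide whether extension starts).
Labels derive from the same thermodynamic engine the encoder uses:
label 1 iff the selected priming sites both score below tau = -12
kcal/mol, a value between full-length planted duplexes (about -15 to
-25 at 56 C) and spurious partial bindings (above about -8), flipped
with probability 0.05 by default. This circularity is deliberate: the
generator tests that the label signal is *representable in the
pseudo-language*, not that the threshold model is biologically true.
Synthetic data therefore cannot show that the encoder captures real
PCR chemistry, polymerase kinetics, or the sequence structure of 16S
amplicon families — passing tests demonstrate internal consistency and
recoverability, nothing more.

## Problem sizes in the shipped checks

The test suite validates the candidate search and site selection
against brute-force enumeration on 50 random instances up to 200 bp,
encodes the full 126-pair x 31-template design (3,906 sentences), and
runs the end-to-end recovery on a 20-pair x 10-template dataset with
noise-free labels through 5-fold cross-validation at 30 epochs with a
32/32 model. At that scale the planted positives are about 5% of
samples; the pooled accuracy criterion (>= 0.85) is met while the
per-epoch history reproduces the all-negative early regime that
imbalanced PCR matrices induce. Separable-corpus checks (disjoint
token sets) verify that the classifier itself learns to high accuracy
when the signal is unambiguous, and shuffled-label nonsense sentences
confirm it finds nothing when there is nothing to find.

## Known limitations

- The duplex model is contiguous-window only: no bulges, internal
  loops, or secondary-structure folding energetics.
- Mismatch nearest-neighbor parameters are transcriptions of published
  single-mismatch series with mean-filled gaps; applications that
  depend on absolute mismatch energies should review and, if needed,
  replace `nn_stacks.tsv`.
- The LSTM is CPU-bound plain R; it is sized for corpora of a few
  thousand short sentences, not for genome-scale screens.
- With heavily imbalanced labels and few positives the classifier can
  sit in the all-negative regime for many epochs; per-template
  undersampling mitigates this but shrinks small datasets severely.
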