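---
title: "Weak supervision from curated records: models, parameters and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weak supervision from curated records: models, parameters and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(curex)
```

## The problem and the model

Curated biomedical databases record standardized field values per article —
a study's target phenotype, the ancestry group and experimental stage of
its samples — without pointing at the supporting text. Using those records
as supervision means every candidate passage found by dictionary matching
carries a *noisy* label: the curated terminology may be a synonym, an
abbreviation or a typo of what the article says, and even an exact string
match can sit in the wrong context (a literature review rather than the
study's own sample description).

`curex` handles this with three cooperating pieces:

1. **A committee of weak classifiers.** Each member gives a hard 0/1 vote
   on whether a (passage, curated-record) pair is a genuine training
   positive. Members are cheap and individually unreliable: positional
   rules (mention in title/abstract), string rules (exact, substring,
   concept-synonym match against the curated term), shape rules (compound
   token), lexicon rules (sample-description words, stage cues in the
   context window), and one learned logistic-regression member trained on
   the raw weak labels. The learned member votes on its own training set
   only through 5-fold out-of-fold prediction, so it never labels rows it
   was fitted on.

2. **An EM label estimator.** With `M` the `I x J` vote matrix, `p_i` the
   probability that passage `i` is truly positive, and `e_j` the scalar
   error rate of member `j`, iterate from `e_j(0) = 0`:

   $$p_i(t) = \frac{\sum_j (1 - e_j(t-1)) M_{ij} + k}{J + K}, \qquad
     e_j(t) = \frac{\sum_i \left[p_i(t)(1 - M_{ij}) + (1 - p_i(t)) M_{ij}\right] + k'}{I + K'}$$

   until `max_i |p_i(t) - p_i(t-1)| < tol`. The `e` update is the expected
   disagreement between member `j`'s votes and the current beliefs. An
   alternative update, `e_j(t) = (\sum_i p_i(t) M_{ij} + k')/(I + K')`, is
   selectable as `variant = "paper_literal"`: it penalizes agreement with
   probable positives, which contradicts the role of `1 - e_j` as a
   reliability weight in the `p` update, so the disagreement form is the
   default; the literal form is retained for fidelity experiments. The
   model assumes votes are conditionally independent given the true label
   and that one scalar error rate per member suffices (no per-class
   confusion matrix — deliberately simpler than a full Dawid–Skene
   estimator).

3. **Importance reweighting and a cost-sensitive linear SVM.** The cost of
   a noisy-labeled example approximates the ratio between the clean and
   the noise-perturbed conditional label probabilities. With
   `y_i = round(p_hat_i)` (0.5 rounds up) and `q` the positive fraction of
   the hardened labels: positives get `c_i = p_hat_i / q`; negatives get
   `c_i = (1 - p_hat_i)/(1 - q)` under the default `lemma_consistent`
   variant. The alternative `paper_literal` negative numerator `p_hat_i`
   rewards examples that look positive but were hardened negative, which
   inverts the reweighting logic; it is kept selectable but not default.
   When a class is empty its denominator is replaced by 1 so costs stay
   finite. The classifier minimizes
   $\tfrac{\lambda}{2}\lVert w\rVert^2 + \sum_i c_i \max(0, 1 - y_i(w^\top x_i + b))^2$ —
   the L2-regularized *squared* hinge, the objective used by common linear
   SVM implementations. The squared hinge is differentiable, which lets a
   deterministic batch L-BFGS-B solve from a zero start reach the unique
   minimizer reproducibly; per-example costs multiply the loss exactly as
   example replication would.

## Task pipelines

**Phenotype ranking.** Mentions of any dictionary disease/trait are
matched longest-first at word boundaries (hyphen and space
interchangeable), windows of up to 10 tokens per side are taken across
sentence boundaries, and features are character 2–4-grams of the mention,
word (1,2)-grams and character 2–4-grams of the context (each block
TF-IDF-weighted and L2-normalized separately), plus binary positional
flags. After the cost-weighted SVM labels each mention, votes are
aggregated per candidate phenotype and document: `P_TF = V_p/(V_p + V_n)`
rewards candidates whose mentions are consistently predicted positive,
`P_IDF = V_p / \sum V_p` rewards candidates that dominate the document's
positive votes. Their harmonic mean is the default ranking score —
both ratios are small and outlier-prone, and the harmonic mean punishes
candidates strong on only one of them; `(0,0)` is defined as 0 by limit
consistency. Ties break by higher `V_p`, then lexicographically.

**Stage-ethnicity tuples.** Ethnicity surface terms (country names,
adjectivals, demonyms) are mapped to 14 top-level groups; windows stay
within the sentence. Features are a one-hot entity indicator, Porter-
stemmed context (1,2)-grams and section-title terms (TF-IDF), normalized
offsets from article and section start, and the entity's same-article
mention count, all standardized to zero mean and unit variance with
training statistics. Two committees chain: positive/negative first, then
initial/replication on the positives (convention: 1 = initial). The
stage-cue rule votes replication only when a replication cue appears
without an initial cue; with no cue, or both, it votes initial, because a
study always has an initial stage while replication is optional. The same
default-initial tie-break applies to the weak label when an ethnicity is
curated under both stages. Predicted `(stage, ethnicity)` pairs are
deduplicated per document.

## Tunable parameters

| Parameter | Default | Notes |
|---|---|---|
| EM priors `k/K`, `k'/K'` | 1/2, 1/2 | uniform Beta smoothing on both updates |
| EM `tol`, `max_iter` | 1e-6, 100 | max absolute change in `p`; non-convergence is reported, not fatal |
| hardening threshold | 0.5, half-up | `round(p_hat)`; ties go positive |
| SVM regularization `reg` | 1.0 | coefficient of `||w||^2/2`; class imbalance is handled by the costs only |
| optimizer | L-BFGS-B, tol 1e-4, ≤10000 iter | batch, zero start, no shuffling: bit-reproducible |
| n-gram ranges | char 2–4, word 1–2 | keeps the feature space near 10^5 on realistic corpora |
| context window | 10 tokens/side | cross-sentence for phenotypes, within-sentence for ethnicity |
| ranking method | harmonic | arithmetic available |
| base member folds | 5 | out-of-fold voting inside the training set |

All randomness (fold assignment, corpus generation, shuffles) flows from a
single root seed, so any run is reproducible from its recorded
configuration.

## What the synthetic corpora emulate — and what they do not

The generators produce (i) committee matrices from known truth — labels
drawn with a class prior, each member flipping independently with its own
error rate below 0.5 — and (ii) miniature corpora in the package's real
file formats. Phenotype corpora plant one or two targets per document (two
with probability 0.51, matching an average of about 1.5 targets), place
them in the title and abstract with probability 0.9, and record a curated
term that is the canonical name, a synonym (probability 0.3) or a
one-character typo (probability 0.1). Stage-ethnicity corpora plant one to
three tuples per document, link each mention to a stage cue in the same
sentence with probability 0.8 (otherwise the sentence names the sample but
no stage), add distractor ethnicities in non-sample contexts, and perturb
a document's curated record with probability 0.3 (a stage flip or an
ethnicity swapped for a distractor). These values were fixed as the
generator's study conditions; vocabulary sizes (about 50 phenotypes, 14
ethnicity groups with about 70 surface terms, a 65-term sample lexicon and
8 stage cues) are small bundled reconstructions, not licensed resources.

The corpora are templated, so their language is far more regular than real
articles: the sample-description lexicon separates positive from
distractor contexts almost perfectly, abbreviations and anaphora are
absent, every curated ethnicity is textually supported, and dictionary
coverage is complete. Passing pipeline tests on these corpora therefore
demonstrates that the machinery is wired correctly and behaves sensibly
under controlled noise — not that real-corpus accuracy figures would be
reproduced. The problem sizes used throughout (up to 200 documents, about
1 000 passages, feature spaces of a few thousand dimensions, 10–20 seeded
replicates) were chosen so the full pipeline remains comfortable on a
single CPU.

## Numerical choices and degenerate inputs

Character spans are 0-based half-open; tokens are alphanumeric runs with
internal apostrophes; sentences split at `[.!?]` followed by whitespace
and a capital or digit. Digit tokens collapse to one placeholder in
word-level vocabularies so arbitrary sample sizes do not inflate the
feature space. TF-IDF uses the smoothed form `log((1+N)/(1+df)) + 1` with
per-block L2 normalization; standardization uses population variance with
zero-variance dimensions left unscaled. Curly typography is normalized to
ASCII on ingestion. Duplicate curated rows collapse silently; a dictionary
term mapped to two entities is a hard error, because a silently resolved
conflict would corrupt the weak labels. Empty articles, empty test
corpora and documents with zero positive votes all yield empty (not
erroneous) results; training with a single hardened class raises an
explicit degenerate-training error. A document-frequency question with no
clean answer — whether phenotype context n-grams should be weighted per
mention or per document — is resolved by fitting document-frequency
statistics over passages, and the ambiguity is noted here.

## Known limitations

**The vote-pool EM shrinks and biases its estimates.** Because the `p`
update divides by `J + K` rather than normalizing a likelihood, `p_hat`
is confined to `[k/(J+K), (J+k)/(J+K)]` and in practice to a band whose
upper edge is roughly `(J(1-\bar e) + k)/(J+K)`. Two consequences follow.
First, `e_hat` is inflated additively: even an error-free member
disagrees with beliefs that never reach 1, so at a class prior of 0.4
with seven members the error floor is about 0.16, and absolute error-rate
recovery is limited to roughly ±0.1 — the estimator preserves the
*ranking* of member reliabilities (rank correlation above 0.85 in the
test suite) but not their absolute values. Second, hardening at the fixed
0.5 threshold is conservative: with a three-member committee, two votes
out of three fall below 0.5 once estimated error rates exceed about 0.1.
In the stage committee this maps 2-of-3 "initial" agreement to
"replication", which can make the cost-sensitive chain *worse* than
training directly on the raw weak labels whenever those labels are only
mildly noisy — the synthetic benchmark exhibits exactly this (macro F1
about 0.88 versus 0.96 at the default noise level). The committee earns
its keep only when weak-label noise is heavy relative to the committee's
own miscalibration; on the bundled corpora it is not. Both update
variants and all priors are exposed so this trade-off can be explored.

**Other limitations.** Rule lexicons are reconstructions; the synonym
mechanism is a flat term-to-concept file rather than a terminology
service; the sentence splitter has no abbreviation model; studies with
more than two stages, tribal or fine-grained ancestry terms, and
ethnicities only implied by geography are out of scope, as are PDF or
full JATS ingestion.
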