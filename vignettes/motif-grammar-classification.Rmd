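---
title: "Motif-grammar classification of binding peaks: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif-grammar classification of binding peaks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Genome-wide binding experiments (ChIP, DamID) for a transcription factor
yield peak sets that mix directly bound sites with sites occupied indirectly,
by tethering to a partner protein that contacts the DNA. `motifgrammar`
asks whether the *motif grammar* of a peak set — which binding-site motifs
occur inside the peaks, and how often — suffices to classify bound regions
against matched random regions, and uses the structure of the resulting
sparse model to nominate candidate protein–protein interactors (PPIs) of the
profiled "anchor" factor. Motifs that carry model weight but frequently
occur in peaks *without* the anchor's own motif are the tethering
candidates.

## The model

Peaks and a size/length-matched random background are scored against a PWM
library. For a PWM with column probabilities $p_i(b)$ and a zero-order
background $q(b)$, a window $b_1..b_w$ scores

$$S = \sum_{i=1}^{w} \log_2 \frac{p_i(b_i)}{q(b_i)}$$

in bits, on both strands; windows with $S \ge$ a cutoff (default 6 bits)
count as instances. Counts are normalized to motifs per kilobase, giving the
feature matrix $M_{np}$ (peaks × motifs/kb). A lasso-penalized logistic
model is fit along a descending penalty grid with 10-fold cross-validated
AUC at every $\lambda$. Two selection rules are provided:

* **1-s.e. rule** — the largest $\lambda$ whose CV AUC is within one
  standard error of the maximum (the usual sparse default).
* **Knowledge-based rule** — compress further: take the largest $\lambda$ at
  which the anchor factor's own motif still has a nonzero coefficient, i.e.
  stop *just before the anchor would be lost*. The premise is biological
  prior knowledge: whatever the minimal predictive model of the anchor's
  binding is, it must contain the anchor's own binding element.

The knowledge rule is most interesting precisely when the anchor motif is a
weak feature (short, low information content — typical of homeodomain
elements): then it enters the path late, many stronger cofactor motifs are
already active at $\lambda^*$, and the rule acts as a principled,
hypothesis-driven stopping point rather than a trivial one.

Comparator classifiers (a linear-kernel max-margin classifier with its
penalty `C` tuned by 10-fold CV over a decade grid, and a 500-tree random
forest with $\sqrt{p}$ features per split) are provided for the standard
model-comparison workflow; both are implemented in the package (squared
hinge + BFGS; compiled CART/gini forest) because no SVM or forest library is
assumed present. Performance is reported as ROC/AUC (Mann–Whitney,
average-rank ties), sensitivity, specificity, PPV and FDR, with `NA` as the
undefined sentinel for empty denominators.

## Replicate concordance and co-occurrence

Two replicate experiments are compared three ways: coordinate overlap
partitions the peaks into unique/shared subsets (`A`, `B1`, `B2`, `C`);
*cross-prediction* applies one experiment's model to the other's peaks and
reports the positive-prediction rate; and a *direct-contrast* model labels
peaks by experiment of origin — a near-random AUC means the two experiments
share grammar even where their coordinates disagree. Binary motif presence
within positive peaks yields the co-occurrence matrix (entry = fraction of
all peaks containing both motifs; diagonal = prevalence) and the
anchor-exclusive fraction freq(m) − freq(m ∧ anchor), which is zero for the
anchor itself by construction and quantifies how often a motif appears
without the anchor — the indirect-binding signature.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| scan threshold | 6 bits | per-instance log2 likelihood-ratio cutoff |
| PWM pseudocount | 1e-4 (at load) | avoids −∞ scores from literal zeros |
| per-kb normalization | on | count / (peak length / 1000) |
| split fraction | 0.75 | stratified train proportion |
| CV folds | 10 | both for λ and for the comparator's C |
| λ grid | 100 points, ratio 0.001 | dense enough for the anchor-retention scan |
| cutoff | 0.5 | score threshold for confusion-based metrics |

The score's base and cutoff are configurable: published pipelines state a
score cutoff (e.g. "score 6") without fixing the log base or instance
de-overlapping, so this package defines the score explicitly as summed log2
likelihood ratios, keeps all above-threshold windows by default, and exposes
a greedy overlap-merge flag.

## The synthetic stated world

Every stage is testable without downloads via a seeded generator. Defaults
(the *strong-signal configuration* used by the test suite): 500 positives
per replicate and 500 background peaks; peak lengths Normal(500, 120) bp
truncated to [100, 1200]; genome GC 0.42; anchor planted in 60% of
positives; 4 cofactors planted at 0.4 each (background leak 0.05); 50 decoy
motifs never planted; an indirect subset (15% of positives, exactly
⌈0.15·n⌉ peaks) carrying at least one cofactor and never the anchor;
replicate 2 reuses 55% of replicate-1 coordinates jittered by up to 10% of
peak length, the rest drawn fresh from the same grammar.

Design choices behind the generator, made once and documented here:

* **Exact allocation.** The anchor is planted in exactly
  round(0.6·n) positives (outside the indirect subset) and the indirect
  subset has exactly ⌈0.15·n⌉ members, rather than independent Bernoulli
  draws; stated rates are hit deterministically, and configurations whose
  anchor and indirect demands exceed the peak count are rejected.
* **Shared peaks are stronger sites.** Peaks chosen to be shared between
  replicates get planting probabilities multiplied by 1.3 (capped at 1).
  Reproducible peaks being higher-affinity is the standard explanation for
  shared peaks being predicted better than unique ones; without it shared
  and unique subsets would be statistically identical and that comparison
  would be a coin flip.
* **Motif geometry.** The anchor is short and degenerate (width 6, consensus
  probability 0.85 — roughly 60% of planted instances clear the 6-bit
  cutoff), cofactors long and sharp (width 12, consensus 0.96, ~zero random
  hits), decoys widths 6–12 at consensus 0.94. This realizes the regime the
  method targets: cofactors enter the lasso path before the weak anchor, so
  the knowledge model retains them, while the anchor stays clearly
  informative. Short decoys hit often at 6 bits (~2/peak) — realistic
  scanning noise, balanced between classes.
* **Planting.** Instances are sampled column-wise from the PWM, placed
  uniformly inside the peak without overlapping previous plantings (100
  tries, then error), into the genome itself, so replicate-shared windows
  carry identical instances.

What a green test does *not* establish: the generator is zero-order iid
(no repeats, no nucleosome or GC structure), peaks are independent, and
motif instances are planted rather than arising from binding energetics; so
passing tests validate the machinery and its statistical behavior, not
biological truth on real data.

## Numerical notes

* **Near-threshold knife edge.** One-mismatch windows of short sharp motifs
  score within ~0.1 bits of the 6-bit cutoff. Hit counts are therefore
  knife-edge sensitive to the background frequencies; estimating *separate*
  background models for two peak sets being compared can flip such windows
  across the cutoff in one set only and manufacture spurious class
  differences. All cross-set comparisons must share one background model
  (the pipeline pools sequences from both sets; `featurizer()` documents
  the hazard).
* Windows containing non-ACGT bases score −∞ and can never pass a finite
  threshold (conservative handling of ambiguity codes).
* The λ grid's top point sits a factor 1.001 above the empirical
  all-zero λ so the path provably starts from the null model.
* The 1-s.e. rule uses the CV AUC (not deviance), with ties resolved toward
  the larger λ; non-monotone anchor re-entry along the path triggers a
  warning and the largest qualifying λ, never a silent interior choice.
* PWM similarity is the best mean column-wise Pearson correlation over
  ungapped offsets (minimum overlap 4 columns) and both orientations;
  zero-variance columns contribute 0.
* Columns with zero variance are guarded in standardization (scale set to
  1, coefficient forced to 0 by the penalty).

## Interpretation guardrails

The split of the one-standard-error versus knowledge-based model is a
sparsity/prior trade, not a performance optimization: the knowledge model
is never larger than the 1-s.e. model when its λ is at least as large, and
always contains the anchor. Candidate ranking (active non-anchor motifs by
|coefficient|, annotated with anchor-exclusive fractions) is a screen for
follow-up, not an inference of interaction; decoy contamination in the
synthetic world is the measured false-candidate rate under ideal
conditions and will be higher on real data with correlated motifs.

## Known limitations

Zero-order background only (no Markov chains); no de novo motif discovery
(import externally discovered PWMs via MEME format); no E-value enrichment
statistics; ungapped PWM similarity rather than full motif-tree clustering;
single-genome workflows (no liftover). The paper-scale λ values and exact
feature counts from any specific real dataset are data-dependent and not
targets of the synthetic tests.
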