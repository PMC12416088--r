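---
title: "Methods: active learning to rank for text screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: active learning to rank for text screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alscreen)
```

## The screening model

`alscreen` treats screening as active learning to rank. The corpus `K`
splits at every instant into the unlabeled pool `Ku` and the labeled sets
`K+` (relevant) and `K-` (irrelevant), with `K = Ku ∪ K+ ∪ K-` disjointly —
this identity is maintained by construction and checked by property tests.
A ranking agent orders `Ku`; an oracle (human annotator, or the known label
in simulation) labels the top of the queue; the agent retrains and re-ranks.
The assumptions are the usual ones for this family of tools: each record's
relevance is a fixed property (labels are taken as ground truth; a
label-noise knob exists in the generator for future robustness studies),
relevance is learnable from lexical features of title+abstract text, and
one label per record suffices (no interrater design — with every record
screened by exactly one expert, interrater reliability is not computable
and is deliberately not reported).

### Agents and hand-off

An agent bundles four components. Only the querier is mandatory; a
classifier is present exactly when a vectorizer is, since scores require
features. Chains of agents model staged screening: e.g. a calibration stage
of random labels, a fast lexical learner, then a stronger (or merely
different) learner. Hand-off carries all labels and cached feature matrices
forward and resets the segment counters `k, k+, k-` and the trailing
irrelevant run `Δk`. Two deliberate conventions, where the narrative this
design follows is ambiguous:

* **Segment counters count only labels made under the current agent.** A
  `labeled_count` threshold of 13 after a 2-label predecessor therefore
  fires at the 15th label overall.
* **`Δk` resets to zero on hand-off**: each agent's stopping run is judged
  on its own labels, not inherited from its predecessor.

Stopping is evaluated after every label: global stop first (empty pool or
user stop), then the active agent's policy; a met policy with no successor
is itself a global stop, after which the relevant collection is exported
and outstanding allocations are flushed to the log as unlabeled rows.

## Default components and tunable parameters

| knob | default | why |
|---|---|---|
| TF-IDF n-gram range | (1, 2) | uni+bigrams; pairs of consecutive words capture short phrases that unigrams miss |
| TF-IDF dialect | counts, `idf = ln((1+N)/(1+df)) + 1`, L2 rows | the standard smoothed dialect; the underlying method names TF-IDF without fixing a formula, so this is a documented package convention |
| tokenizer | split on non-alphanumerics, lowercase, no stop words | simplest reproducible choice; stop-word removal is left off because the balancer and idf already damp ubiquitous terms |
| balancer | inverse class frequency, multiplier 1 | `w_c = m_c·N/(2N_c)` gives mean weight 1 and equalizes total class mass; `m` is the single boost knob |
| naive Bayes `alpha` | 1 | Laplace smoothing |
| logistic `lambda` | 1e-3 | small fixed ridge: deterministic, robust to separable training sets |
| linear SVM `cost` | 1 | squared-hinge, L2; optimized by L-BFGS from zero, so runs are deterministic |
| bagged trees | 100 trees, depth 8, `mtry = √p` | conventional forest-shaped defaults; hand-written because no tree package is available in the target environment — functional, not performance-tuned |
| hybrid querier `ε` | 0.05 | promote `⌈εn⌉` random pool records into random positions of the certainty ranking (seeded); the mixing mechanics are this package's choice |
| uncertainty boundary | 0.5 (probabilities), 0 (decision values) | distance to the decision boundary for each score kind |
| task server workers | 2 | one retrain per free worker; an occupied server waits for the next label |
| prior sampling | per-class size `1 + Geometric(p = 0.5)` | which quantity the geometric law governs is not pinned down by the sources; per-class set sizes always yield a trainable 1+1 seed and are documented as this package's protocol |

All ties — everywhere a ranking is produced — break by ascending corpus
position, and every random draw flows from a user seed through a
deterministic seed-derivation chain, so a (corpus, chain, seed) triple
reproduces byte-identical event logs.

## The crowd scheduler

The multi-annotator service is specified as a discrete-event system over
integer ticks and is fully deterministic under a seed; a live deployment
would map the same contract onto wall-clock time. Design choices:

* **Allocations never expire.** A record checked out to an annotator stays
  theirs until labeled or explicitly released; requests by others skip it.
* **Requests are never blocked by training**: they are answered from the
  ranking in force at that tick.
* **A retrain snapshots the labels present at its start**; labels arriving
  during training enter the next round, and the finished ranking replaces
  the old one atomically without touching live allocations.
* **Event-log columns**: one row per label, carrying the queue position
  (iteration, rank) captured when the record was served, but the training
  set size and model name of the ranking *in force when the label arrives*.
  The latter choice keeps training-set sizes monotone within a model
  segment even when an annotator labels an old allocation late — the
  invariant the replay verifier enforces. Records still allocated when the
  run stops are appended as unlabeled rows.

`run_simulation` is an independent synchronous driver over the same state
primitives and the same retrain policy (model-free agents rank once per
segment; classifier agents wait for one relevant plus one irrelevant
label); the test suite checks that a single scripted annotator with
synchronous retraining reproduces the simulator's labeling order
event-for-event.

## What the synthetic generator emulates — and what it does not

`generate_corpus()` draws documents as bags of tokens from two multinomial
vocabularies: relevant documents take each token from a signal vocabulary
with probability `separability`, everything else from a shared background.
Defaults (`n = 200`, prevalence 0.1, separability 0.9, mean length 30)
emulate the defining statistics of screening corpora: low prevalence and a
class-separable vocabulary. The model is chosen because its optimal
classifier is known (multinomial naive Bayes is correctly specified), so
learner behavior on it is interpretable.

It does **not** emulate natural language: no syntax, no topic drift, no
near-duplicate records, no heterogeneous document lengths by venue, no
multilingual text. A green screening-efficiency test therefore establishes
that the loop — features, balancer, classifier, querier, stopping —
functions and beats random ordering on a separable corpus; it does not
establish performance on real systematic-review data, which is exactly why
external benchmark figures are not reproduced here.

The crowd fixture (`generate_crowd_fixture()`) reproduces a canonical
multi-annotator scenario: 100 records, four annotators, a three-agent
chain (2-label random start, naive Bayes until 13 further labels, then an
SVM agent with a consecutive-irrelevant stop), and exactly three records
still allocated-but-unlabeled when the system stops, so the event-log
replay reports 97 labeled records. The final agent's run-length threshold
cannot be known a priori — the label sequence is emergent — so the
generator measures the trailing irrelevant run on a trial replay with the
stop disabled, sets the threshold to that length, verifies by a full
replay, and raises a generation error if an earlier irrelevant run would
fire first. The labeled count is thus `n_records − outstanding_allocations`
by construction for any seed. Two deviations from the scenario's
surface narrative, both deliberate: the third agent retrains (a frozen
15-label ranking can leave one relevant record so deep in the queue that
the trailing run becomes degenerate on some seeds; retraining makes the
stop reachable for every seed — per-agent `retrain = FALSE` remains
available and tested), and the second agent's threshold is 13 *segment*
labels so the cumulative count at hand-off is still 15.

## Metric conventions

The evaluation metrics are named in the screening literature but rarely
given formulas; the package fixes the conventional ones and treats them as
its definitions: Cohen-style `WSS@r = (N − n_r)/N − (1 − r)` with `n_r`
the smallest screening count reaching recall `r`; `ERF@f = r(⌊fN⌋)/R − f`;
`TD = (1-based screening position)/N`, with never-screened records taking
their extrapolated position in the final model's ranking; ATD the mean TD
over `K+`; and the normalized loss
`(A_perfect − A_actual)/(A_perfect − A_worst)` over the cumulative step
curve, which is 0 for the perfect ordering, 1 for the worst, and strictly
decreases whenever an adjacent (irrelevant, relevant) pair is swapped —
verified exhaustively for `N ≤ 6`. Percent displays round to one decimal;
internal comparisons are exact.

Degenerate inputs are signaled, not guessed at: WSS at an unreached recall
level, loss on a single-class corpus, and TD of an irrelevant record raise
typed errors.

## Known limitations

* The linear SVM is a dense-coefficient L-BFGS implementation; adequate at
  desk scale (hundreds of records, tens of thousands of terms), not at
  corpus sizes where LIBLINEAR-class solvers matter.
* The bagged-tree classifier exists for completeness of the component
  enumeration; it is slow on wide TF-IDF matrices and is not a tuned
  random forest.
* glmnet's logistic objective normalizes by the number of observations, so
  the duplicated-row = doubled-weight identity holds exactly for naive
  Bayes and the SVM but only approximately for logistic regression.
* xlsx is read (via readxl) but not written; no xlsx writer is available
  in the supported dependency set.
* The project container is a plain directory (JSON config + CSV logs +
  MatrixMarket feature matrices) rather than a zip archive, keeping the
  artifact text-only and dependency-free.
* Transformer/semantic feature extractors and performance-triggered
  automatic hand-off are out of scope.
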