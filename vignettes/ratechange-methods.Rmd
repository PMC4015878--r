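---
title: "Mining rate-change evidence for transcriptional regulation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining rate-change evidence for transcriptional regulation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratechange)
```

## The problem

Gene regulatory network (GRN) models with time delays need evidence about
*when* and *how fast* a regulation acts, not just that it acts. Biological
databases rarely record temporal information, but abstracts frequently
describe a transcriptional regulation process being sped up, delayed,
extended or otherwise altered in rate — qualitative time-delay evidence.
`ratechange` implements a pipeline that (i) filters abstract sentences
likely to describe such events, (ii) classifies them with deterministic
ontology rules, and (iii) extracts dependency-path features that let a
decision tree separate direct from indirect evidence. A synthetic corpus
generator with the same textual structure makes every stage testable
offline.

## The sentence filter

Working at sentence resolution (the standard locality assumption in
biomedical relation extraction), each sentence is compared with two trigger
lexicons: a "regulate" list (regulation verbs such as *regulate*, *induce*,
*repress*) and a rate-change list organized into three disjoint direction
classes — `Quicken` (e.g. *accelerate*, *enhance*), `Delay` (e.g. *slow*,
*prevent*, *delay*) and `Change` (e.g. *alter*, *rate change*). The lexicon
is written as the uniform unit vector $y$ over its $n$ entries and the
sentence as a binary indicator $x$ with $m$ matched entries, so

$$\cos(x, y) = \frac{x \cdot y}{\lVert x\rVert\,\lVert y\rVert} = \sqrt{m/n}.$$

Binary indicators (rather than counts) make the score invariant to word
repetition, and the normalization removes the bias toward overlong
sentences. A sentence is kept when all three conditions hold:

* at least `min_noun_genes` (default 2) gene mentions tagged as nouns
  (`NN`-prefixed Penn Treebank tags);
* regulate-lexicon score strictly greater than `theta_regulate`
  (default 0.1);
* rate-change-lexicon score strictly greater than `theta_temporal`
  (default 0.15).

"Exceeds" is read as strict inequality, and the looser pre-filter stage
("positive score against both lists") is available by setting both
thresholds to zero. With the shipped lexicon sizes (24 regulate entries, 43
rate-change entries) a single match already clears each default threshold;
the thresholds matter for longer, user-supplied lexicons.

## Word normalization and tagging

Gene mentions are found by case-insensitive exact token matching against a
yeast synonym dictionary (longest non-overlapping match first); fuzzy
matching is deliberately avoided because yeast symbols are short and fuzzing
inflates false positives. Matched tokens are replaced by the placeholder
`genename`, and trigger-word variants collapse to the head form in the first
column of an editable normalization dictionary (e.g. *slowed*, *slows*,
*slowing* → *slow*). Normalization runs **after** tagging so the tags
reflect the original surface forms — a sentence full of `genename` tokens
would mislead any tagger.

No syntactic toolchain is bundled. The POS tagger is a small deterministic
rule cascade (closed-class lexicon, orthographic cues for gene-symbol-like
tokens, suffix heuristics); both it and the dependency-parse source sit
behind provider contracts, so a heavier backend can be substituted without
touching the pipeline. The tests pin the built-in backends and snapshot
their outputs. The built-in tagger is sufficient for the two places tags
matter: the noun-tagged-gene filter condition and the keyword–tag feature
family.

## The two ontologies

The rate-change ontology catalogs sub-processes whose alteration changes
transcription rate, in two branches: chromatin-domain events (nucleosome
composition/decomposition, chromosome structure modification, histone
chemical modification, chromatin remodeling, nuclear change, DNA structure)
and transcription events (promoter activity, RNA polymerase activity and
binding, transcription behavior). The negative ontology catalogs contexts
that *look* like regulation rate changes textually but are not
transcriptional regulation: cell-cycle regulation, DNA replication and
repair, translation, and other processes. Each node carries textual
patterns — sets of normalized keywords that must co-occur anywhere in the
sentence (order-free, whole-sentence scope; multi-word keywords match as
contiguous token n-grams).

Relations between nodes are typed `is_a`, `part_of` or `result_from`, and
[`infer_relation_closure()`] computes the least fixed point under the
composition table

```
r ∘ is_a → r          is_a ∘ r → r          (for every r)
part_of ∘ result_from → result_from
result_from ∘ part_of → result_from
part_of ∘ part_of     → part_of
```

Pairs outside the table (e.g. `result_from ∘ result_from`) infer nothing —
the table is treated as exhaustive. The property suite checks the closure
against a brute-force path-enumeration oracle on random DAGs.

The shipped pattern inventories are a curated approximation: the complete
original inventories are only partially recoverable, so the patterns ship
as editable JSON data seeded from the published sub-class names, instance
tallies (e.g. promoter activity 101, transcription behavior 343; cell cycle
71, DNA replication and repair 49, translation 35) and the worked example
sentences. Keeping patterns as data, not code, is intentional: refining the
ontology requires editing two JSON files, nothing else.

## Deterministic rules

* **Regulation-based rule** — positive iff at least one rate-change pattern
  fires.
* **Combined rule** — positive iff at least one rate-change pattern fires
  *and* no negative pattern fires. The veto is unconditional regardless of
  how many positive patterns fire.

Because the combined rule only removes predicted positives, its
predicted-positive set is a subset of the regulation rule's on any corpus,
so TP and FP can only decrease — the mechanism by which the negative
ontology trades a little recall for precision. Both rules are pure
functions of the normalized token multiset.

## Direct-evidence features

Positives split into direct evidence (regulator, regulatee and rate change
all named) and two indirect subclasses: incomplete regulation information
(subclass I) and genetic-engineering manipulation contexts such as
multicopy plasmids and fusion constructs (subclass II). Three feature
families are built over a dependency parse:

1. `kw|<head>|<tag>` — ontology keyword with its POS tag;
2. `wrw|<w1>|<type>|<w2>` — consecutive token pairs along the gene–keyword
   shortest dependency path, joined by the dependency type;
3. `gkd|genename|<keyword>|<distance>` — the gene–keyword shortest-path
   length.

Post-processing reduces feature diversity: dependency types collapse to the
second level of the typed-dependency hierarchy (editable mapping table,
e.g. `nsubj`/`nsubjpass`/`csubj` → `subj`) and path lengths bin into
`near`/`moderate`/`far`. The published binning ("less than three", "four to
six", "larger than six") leaves length exactly 3 unassigned; it is assigned
to `near` so the bins are contiguous — the minimal extension, and the only
degenerate-input decision in this module. `original_combined` mode skips
post-processing (specific types, raw integer lengths), `all_rules` uses one
binary feature per firing ontology pattern, and `baseline_ace` approximates
the classical relation-extraction baseline (bag of words between entity
mentions plus parse-path features); the exact historical baseline inventory
is summarized rather than enumerated in its source, so this mode is
documented as an approximation. Shortest paths are undirected (the standard
convention for dependency-path features), computed by BFS with a
deterministic lexicographic tie-break (vacuous on trees, but pinned down
for general graphs).

## Evaluation

`compute_metrics()` derives precision, recall, F1 (harmonic mean of the
unrounded precision and recall) and accuracy as percentages, with the
degenerate conventions P = 0 when TP+FP = 0, R = 0 when TP+FN = 0, F1 = 0
when P+R = 0. Rounding is half-up to two decimals — base R's banker's
rounding would disagree with conventional table formatting on exact ties.
Cross-validation is stratified ten-fold with a fixed default seed; folds
are dealt round-robin after a within-class shuffle, so fold sizes differ by
at most one, and per-fold test confusion matrices are **summed** so the
aggregate total equals the corpus size. The tree learner is `rpart` behind
a two-method fit/predict contract; a minimal pure-R Gini tree ships as an
independent cross-check engine, and single-class training degenerates to a
constant predictor with a warning. `coverage_curve()` measures how quickly
randomly ordered sentences expose the ontology patterns (averaged
cumulative fraction over shuffles) — the diagnostic used to argue that a
modest corpus already covers most patterns.

## The synthetic corpus generator

The generator's defaults emulate the annotated corpus' composition: 1309
sentences, 357/1309 positive, 211/357 of positives direct, and negatives
mixed proportionally to the negative-ontology tallies (71 : 49 : 35 with
the remainder in other processes). Sentences are slot templates
(`<gene> <rate-word> <regulate-word> of <gene> <pattern keywords> ...`)
rather than fluent English — the pipeline consumes tokens, not grammar — and
come with typed chain parses whose path lengths equal token distances, so
evidence geometry is controlled exactly: direct positives place a gene
within distance ≤ 3 of the planted keywords, subclass-I indirect positives
place them at distance ≥ 7, and subclass-II positives carry
plasmid/construct markers at moderate distance. Half of the negatives also
carry positive-looking keywords, reproducing the false-positive phenomenon
the veto ontology exists for. Label noise flips gold labels independently
with the configured probability; the pre-noise label is retained for
diagnostics.

What passing on synthetic data shows — and does not. Because the generator
plants the same patterns the rules read, the combined rule attains F1 =
100% at zero noise **by construction**; that is a correctness check of the
matching and veto logic, not an estimate of real-corpus performance. Real
abstracts add unmodeled difficulty: paraphrase beyond the normalization
dictionary, patterns split across clauses, nested and negated assertions,
gene-name ambiguity. Real-corpus figures therefore come only from the
bundled reference confusion counts (reproduced as arithmetic) and from the
ten bundled published example sentences, all of which the combined rule
classifies correctly with the shipped data files.

## Problem sizes and numerical choices

The test-suite and acceptance-script runs use generated corpora of 120–500
sentences, 200-replicate property sweeps (random DAGs ≤ 8 nodes, random
trees ≤ 10 tokens, all cosine cases m ≤ n ≤ 50) and 100-shuffle coverage
curves — sizes chosen so the full suite completes in well under a minute
per module while keeping binomial checks at 99% confidence meaningful.
All randomness flows through explicit integer seeds; library calls save
and restore the caller's RNG state. Tolerances are exact (1e-12) for
closed-form identities and 99% binomial intervals for stochastic rates.

## Known limitations

* Dictionary-based gene recognition has no disambiguation; a token like
  `ATG1` is matched even when it denotes a codon, which is precisely why
  the negative ontology's `codon` pattern matters.
* The built-in tagger and chain-parse provider are deliberately simple;
  wrw/gkd features over real text improve with a genuine parser plugged
  into the provider contract.
* Ontology pattern matching is whole-sentence co-occurrence; clause-scoped
  matching could reduce false vetoes in long coordinated sentences.
* The regulate lexicon is a curated seed list, editable but not exhaustive.
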