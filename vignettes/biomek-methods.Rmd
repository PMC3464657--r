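---
title: "Meta-knowledge assignment for biomedical events: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-knowledge assignment for biomedical events: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

A biomedical event is a structured proposition: a typed trigger expression
plus role-labelled Theme/Cause arguments that may themselves be events.  Its
*meta-knowledge* is the contextual interpretation the sentence puts on it —
whether it is an investigation, observation, analysis, fact or method
(Knowledge Type), how confidently it is asserted (Certainty Level: L3 full,
L2 high-but-incomplete, L1 speculative), whether it is negated (Polarity),
at what intensity it occurs (Manner) and whether it is this study's result
or prior work (Source).  Each dimension has a default (Other, L3, Positive,
Neutral, Current) assigned when the sentence offers no explicit evidence
otherwise.  Two binary hyper-dimensions are derived from combinations of the
assigned values (see below).

`biomek` treats each dimension as an independent multi-class problem over
events that carry an explicit trigger; trigger-less events are excluded (and
any event whose argument event was excluded goes with it, so no dangling
reference survives).  Inter-event and inter-dimension dependencies are
deliberately not modelled.

## Features

All words in feature names are base forms (lemmas); dependency edges keep
their original direction as arrows in the names, while graph search is
undirected.  Per event the following groups are extracted:

* **Cue-path features** — shortest dependency paths between every event
  participant head token (trigger, argument heads; a nested argument event
  contributes its trigger token) and every cue mention matched in the
  sentence, prefixed with each matching lexicon entry's `dimension:value`.
  Path features comprise the length, word/dependency n-grams (n = 2–4),
  governor–dependent word n-grams (n = 1–3), edge walks
  (word–dependency–word) with one-sided sub-structures, and vertex walks
  (dependency–word–dependency) with word-dropped sub-structures.  The
  published worked example prints a vertex-walk with a word in an edge slot
  ("–SUB→ be ←unable–"); we follow the prose definition
  (dependency-word-dependency, i.e. "–SUB→ be ←PRD–") and treat the printed
  form as a typesetting slip.
* **Trigger features** — all dependency paths of ≤ 2 steps from the trigger,
  with token features (character types, character 1–4-grams, lemma, POS) of
  the path words, mixed word+dependency n-grams (n = 2–4), word n-grams
  (n = 2–3) and dependency bigrams.
* **Trigger–argument pair features** — word n-grams (n = 1–4) over the
  window from 3 words before the first mention to 3 words after the last,
  every word encoded as lemma/POS/position (before, between, after),
  prefixed by the argument's role.
* **Sentence features** — absolute sentence index and relative position
  (index / sentence count): Knowledge Type values correlate with document
  position (facts and observations early, analyses late).
* **Citation feature** — one indicator set when the sentence matches a
  bracketed number (`[108]`) or a parenthesis ending in four digits
  (`(..., 1998)`); citations often mark prior work not covered by cue
  dictionaries.
* **Stacked scores** (optional) — one real-valued feature per
  (dimension, value), 16 in the full scheme, holding an auxiliary model's
  decision scores; emitted as its own group so normalisation applies.

Where a sentence carries graphs from several parsers, groups are emitted
under parser-distinct tags; the published system combined two parsers but
does not state a merge rule, so keeping the groups separate (and letting the
linear model weight them) is our choice.  An ambiguity in the n-gram
phrasing — whether "word and dependency n-grams (n = 2,3,4)" counts words,
edges or both — is resolved by counting *alternating elements* of the path
(word, edge, word, …), which reproduces all printed examples
(`be ←PRD–` as a 2-gram, `←PRD– unable ←AMOD–` as a 3-gram).

**Hashing and normalisation.** Feature names are hashed by 32-bit FNV-1a of
`group tag + name` into `2^20` indices (colliding features sum; counts are
non-negative so no sign trick is used).  Each group is scaled to unit
Euclidean length before hashing and the concatenated vector to unit length
afterwards ("type-based normalisation"), so no group dominates by sheer
feature count.

## Cue lexicons

Candidate cue words are the annotated cue mentions of the training corpus
(optionally extended from an external word list).  For each
(word, dimension, value) triple, pointwise mutual information is computed
over events — an event co-occurs with a word when the word is a cue mention
in its sentence — and entries with PMI ≥ τ are kept, default τ = −1.5.  The
log base is 2 (a free choice: any base only rescales τ, so τ is
configurable).  Counting is per event, matching is on lower-cased lemmas
with multi-word cues matched longest-first, and the threshold applies per
(word, dimension, value) triple rather than per word.  A permissive τ keeps
weakly associated entries by design; near-zero-PMI entries mean that cue
words acquire prefixes for values they do not signal, and the classifier has
to learn which path-word combinations matter — this is visible in the
synthetic experiments and is the intended behaviour of the threshold.

## Learning

One binary L2-regularised squared-hinge ("L2-SVM") linear model per value,
one-vs-rest, with C = 1 for negative examples and each class's positive
cost multiplied by its negative:positive count ratio ("biased
regularisation factors"; majority classes consequently get factors below 1).
The bias term is an appended constant feature, hence regularised — the
reference system "sets" a bias term without stating whether it is
regularised, and the appended-feature reading is the simpler one.  The
solver is L-BFGS on the smooth squared-hinge objective restricted to the
hashed columns active in the training data, gradient tolerance 1e-4,
entirely deterministic.  Prediction returns the argmax decision score so
every event receives a value even when all scores are negative; exact ties
break towards the earlier value in the fixed, defaults-first value order.
Token-level cue detection adds an explicit `NONE` class and uses the
multi-label rule (all positive scores plus the argmax; `NONE` as argmax
means "no cue") instead of thresholding.

## Hyper-dimensions

The contributing dimensions are fixed (KT + CL for Hypothesis; KT + Source +
CL for New Knowledge) but the rule tables are not published, so they are
configuration with these defaults: *Hypothesis* = Yes iff KT is
Investigation, or KT is Analysis with CL ∈ {L1, L2}; *New Knowledge* = Yes
iff Source is Current, CL is L3 and KT ∈ {Observation, Analysis}.  The
rationale: an enquiry or a speculative analysis is hypothetical; a confident
observation or analysis of the current study is new knowledge, while facts,
methods and prior work are not.

## The synthetic world

The generator emits the exact standoff and parse dialects the readers
consume.  Sentences follow two templates ("In a *C1…C5* study of cells, X
protein activates the Y gene", and a nested variant "… induced expression of
the Y gene" yielding a regulation event whose Theme is the expression
event).  The five slot words carry the cue lemma of each non-default
dimension value, or inert filler adjectives for defaults — defaults are
emitted with no cue.  By construction the slots hang off the preamble noun,
three dependency steps and more than three tokens from the trigger: cue
evidence is reachable by the shortest-path features but invisible to the
2-step trigger neighbourhood and the ±3-word windows, so ablating cue-path
features removes the cue signal cleanly, which is what the feature-ablation
acceptance check exploits.

Default per-dimension value distributions follow the reference corpus's
relative frequencies (KT ≈ 31.4/5.3/34.7/17.8/8.1/2.7% for
Other/Investigation/Observation/Analysis/Fact/Method; 6.1% Negative; 91.9/
6.0/2.1% L3/L2/L1; 3.8/0.9% High/Low; 1.5% Source Other).  KT is reweighted
by document position (strength 0.5 by default): Fact/Observation early,
Analysis/Investigation late.  Citations (`[ n ]` tokens) are appended with a
single injection probability (0.1), independent of the sampled values — the
config deliberately exposes one probability rather than a Source-conditional
one.  Label noise resamples a gold value uniformly from the other values
*without touching cues*, creating a clean Bayes-error floor for degradation
tests; the noise variates are drawn unconditionally so corpora generated at
different noise rates from one seed share text and cues and differ only in
labels.  Cue ambiguity optionally substitutes a shared ambiguous cue word.

What a green test does and does not establish: the synthetic world has a
tiny vocabulary, fixed sentence templates, gold parses and (by default)
perfectly reliable cues, so recovery there validates the *machinery* —
feature wiring, normalisation, cost-weighted learning, evaluation — not
performance on real prose, where cues are sparse, ambiguous and
annotator-dependent and parses are noisy.

## Numerical and reporting conventions

* Offsets are 0-based half-open; discontinuous spans collapse to the
  smallest continuous covering span (applied to triggers as well as
  arguments — the published rule is stated for arguments only).
* Percentages are rounded half-up to one decimal **only at reporting time**;
  macro averages are unweighted means over all legal values including
  zero-support rows, computed on unrounded intermediates (required to
  reproduce the published majority-baseline table cell-for-cell, e.g. macro
  F 8.5 = 50.704…/6).
* The published distribution table's ratio column reproduces only from
  unrounded proportions, rounded to two decimals at the end; the acceptance
  suite asserts this.
* Models refuse to predict with a lexicon other than the one they were
  trained with (checksum guard), since hashed cue-path features are
  meaningless across lexicons.
* Annotation transfer requires exact agreement on event type and
  role-labelled core-argument spans and skips ambiguous id-map matches: a
  conservative rule, preferring missed transfers to wrong ones.

## Known limitations

No scope resolution (event-level cues are matched, not scoped); no secondary
arguments beyond pass-through; no kernels or joint inference; CL is assigned
independently even though in practice it is most meaningful when KT is
Analysis; predicted values are not linked to the specific cue token that
triggered them (matched mentions are merely recorded alongside).
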