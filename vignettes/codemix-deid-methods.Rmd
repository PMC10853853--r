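---
title: "Methods: de-identifying code-mixed Chinese-English clinical text"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: de-identifying code-mixed Chinese-English clinical text}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmdeid)
```

## The problem

Taiwanese medical records are frequently written in a mixture of English
and traditional Chinese, with the ROC calendar transliterated as "mk"
("前夫mk1300309 married" — married on the slashed ROC date 130/03/09).
Protected health information (PHI) must be detected and removed before
such text can be reused. This package implements the components needed
to *study* that task reproducibly: a domain model for annotated
code-mixed text, metrics that quantify mixing, baseline and pluggable
taggers, a translation-normalization route, a prompt-based LLM route,
a stratified evaluation protocol — and, because the clinical corpus
this design targets is restricted, a seeded synthetic generator that
emulates its statistical structure.

## Domain model

**Taxonomy.** Six coarse PHI categories (Date, Age, Name, Location,
Profession, ID) refine into 20 fine types (e.g. Name → Patient, Person,
Doctor; Location → 12 types from Named location to Market). The mapping
is total and surjective and is frozen in `phi_schema()`.

**Tokenization.** `tokenize_mixed()` emits one token per Han character,
maximal Latin-letter runs (internal apostrophes/hyphens allowed),
maximal digit runs, and single punctuation/symbol characters. Tokens
carry a language tag: `HAN`, `LATIN`, or `NEUTRAL`
(language-independent). Two deliberate choices:

* *Per-character Chinese tokens, no word segmentation.* Mixing indices
  and vocabulary checks become exactly reproducible without an external
  segmenter; a segmenter could be plugged in, but is not the default.
* *Romanized abbreviations count as Latin.* Only digits, punctuation
  and symbols are language-independent, so the ROC prefix "mk" is an
  English-script token, not a neutral one.

Offsets are 0-based, half-open, and counted in characters (not bytes) —
the only convention that stays unambiguous under multi-byte CJK text.

**Span encoding.** PHI spans are encoded per token with the BILOU
scheme (Begin / Inside / Last / Outside / Unit-length). Annotations
whose boundaries fall inside a token are *expanded outward* to token
boundaries, never truncated: over-masking is the safe direction for
de-identification. `repair_bilou()` restores grammar validity of
arbitrary label sequences by re-encoding maximal same-type runs as `U`
or `B…L`; within a run it additionally splits wherever an `L`/`U` label
is followed by `B`/`U`, so *valid* adjacent entities of the same type
pass through unchanged. This keeps the repair idempotent and makes
`decode(encode(x)) = x` hold exactly, which a run-merging repair would
violate for adjacent same-type entities.

## The code-mixing index

For a tokenized sentence with `n` tokens, `u` language-independent
tokens, and `W` the majority-language token count,

$$\mathrm{CMI} = 1 - \frac{W}{n - u},$$

defined as 0 when the sentence is monolingual or consists only of
numeric/symbolic tokens. For two languages the index is bounded by 0.5
(even split). Corpus aggregates, reported on a ×100 scale:

* `AvgCMI_L`: mean CMI over the set of L-dominated sentences,
  *including* those with CMI 0;
* `CMIC`: implemented as the mean CMI over all language-dominated
  sentences, i.e. the convex combination of `AvgCMI_EN` and `AvgCMI_ZH`
  weighted by the dominated-set sizes. A corpus-level formula is not
  fully recoverable from the source material this design follows, so
  this sentence-count-weighted definition is a declared design choice;
  it is consistent with corpus-level values being reported on a 0–100
  scale while per-sentence values are bounded by 0.5.
* Dominance ties break toward English (the emulated corpora are
  majority-English); the tie-break is an argument, not a constant.
* CMI histograms default to six bins — {0}, then five equal-width
  intervals up to 0.5 — because the binning used for sentence-error
  analysis is otherwise unspecified; the edges are overridable.

## The synthetic corpus generator

The generator's defaults *are* the stated world it emulates:

* **Category mix.** Four sentence categories with default proportions
  taken from the emulated training corpus (English-only 0.335,
  Chinese-only 0.122, mixed 0.221, numeric/symbolic 0.322 of 61,630
  sentences).
* **PHI rates.** A 20 × 4 matrix of expected PHI counts per sentence
  conditioned on category, defaulting to the emulated training-set
  counts normalized per category. This reproduces the qualitative
  structure that matters: Date dominates numeric/symbolic sentences,
  Age concentrates in English-only ones, Name and Profession in mixed
  ones, ID in Chinese-only ones.
* **Lexicons.** Each fine type has surface pools per script class
  (English, Chinese, numeric), including slashed dates, "mk" dates,
  Chinese-numeral dates and festival names, army-style numeric hospital
  names, and Chinese/English person names built from per-type component
  pools.
* **OOV control.** Every pool is split into disjoint `shared`,
  `heldout` and `surrogate` slices. Test-split mentions draw from the
  held-out slice with probability `oov_target`, directly realizing the
  definition of OOV as "a mention containing at least one token absent
  from the training vocabulary". Shared slices are deliberately small
  enough that a desk-scale training split (roughly a thousand
  sentences) observes essentially every shared surface; with large
  shared pools the uncontrolled remainder would leak into the OOV rate.
  This sizing was chosen once, from the coverage argument, not tuned
  against test outcomes.
* **Ambiguity.** With `ambiguity_rate > 0` (default 0.05, a mild level)
  a fraction of non-numeric shared surfaces is duplicated under a second
  fine type of the same script, preferring the same coarse category —
  emulating genuinely ambiguous surfaces such as a place name that is
  also a hospital name. At `ambiguity_rate = 0` the default lexicon
  guarantees that every token text occupies exactly one
  (BILOU position, fine type) role corpus-wide, the regime in which a
  most-frequent-tag dictionary can achieve perfect recall on its own
  training data; an audit of this property is part of the test suite.
* **Seeding.** One integer seed drives a hierarchical RNG stream per
  document; generation is byte-reproducible and never touches the
  caller's global RNG state.

**Resynthesis.** `resynthesize()` replaces every mention with a
same-fine-type surrogate from the disjoint surrogate slice, consistent
within a document (same original → same surrogate) and
pattern-preserving where the original surface is recognized (slashed
dates stay slashed, "mk" dates stay "mk", Chinese surfaces stay
Chinese). The underlying principle-based procedure is not fully
specified in the source material; consistency and pattern preservation
are this package's reconstruction of it.

**What a green test does not establish.** The generator emulates
surface statistics, not clinical language: fillers are drawn from small
vocabularies, sentences have no syntax, discourse or negation, and
ambiguity is injected synthetically rather than arising from natural
polysemy. Results on generated corpora support *relative* and
*structural* claims (degradation with OOV, equivalence of pipelines,
metric identities), not absolute performance claims about real notes —
which is why the headline F-scores of the study this package emulates
are explicitly not acceptance targets.

## Taggers

The dictionary-based approach (DBA) compiles every training token's
BILOU label counts (O included, so frequent ordinary words are not
hallucinated as PHI) and assigns each token its most frequent label;
ties break lexicographically and are flagged. Keys are raw,
case-sensitive token texts ("NKUST" is case-bearing); case folding is
an option, off by default. Unseen tokens are O. Because per-token
lookup ignores the BILOU grammar, predictions pass through
`repair_bilou()` before span decoding. Learned sequence taggers plug in
behind `new_tagger()`; pretrained-transformer fine-tuning is
deliberately outside the core (the first-WordPiece alignment convention
belongs to such an adapter's contract, not to this package).

## Translation normalization

Sentences with CMI = 0 pass through; mixed sentences are routed to
their dominant language and rewritten by a `Translator` (a contract —
the bundled implementations are identity and test mocks, no MT model is
shipped). Gold labels survive translation by *mask-and-restore*: PHI
mentions become opaque placeholders before the translator sees the
text and are restored, with recomputed offsets, afterwards. This
guarantees label integrity at a documented cost: the translator never
sees the PHI surface, so it cannot use it as context, and mentions are
never themselves translated. If a translator drops or duplicates a
placeholder, the sentence is kept untranslated (fail-safe) and counted.
Predictions on normalized text are evaluated against the
identically-normalized gold corpus — the same normalization is applied
at training and prediction time, and with the identity translator the
whole route is provably a no-op (an acceptance criterion).

## The prompt-based LLM framework

The prompt has four parts concatenated in order: a task instruction
("Extracting Private Information"), a sentence introduction containing
the literal `<SENTENCE>` placeholder plus PHI definitions rendered from
the schema, a constraint block (only the defined types; no translation
of extracted text; one `TYPE: mention` line each), and the retrieval
message `PHIs:`. The exact reference wording is not recoverable, so the
default template is a reconstruction and fully overridable.

Responses are parsed totally (any byte string yields a result): lines
whose type matches a schema label or a documented alias become
candidates; out-of-schema lines ("MEDICATION: haldol") are counted as
constraint violations; refusal phrases flag the run. The same prompt is
sent k = 3 times at temperature = top-p = 0.5 (recorded with the
backend) and candidate *identities* — (mention, type) pairs, not spans,
because runs may phrase boundaries differently — are retained when they
appear in at least 2 runs. Survivors are aligned once, each mention to
its leftmost not-yet-consumed exact occurrence; repeated identical
mentions consume successive occurrences, and unalignable mentions
(e.g. Chinese PHI translated into English by the model) are dropped and
counted. When a voted mention occurs more than once in the sentence,
the leftmost-unconsumed convention decides — the reference behavior is
unstated, so this is a documented choice.

The core is offline-first: every bundled backend is a deterministic
mock, and no network adapter ships in the package. Sending clinical
text to an external LLM service transmits patient data to an
unauthorized third party; that concern is part of the design, not a
footnote.

## Evaluation protocol

Entity-level matching is greedy maximum matching per document:
candidate pairs must agree on (mapped) type; `exact` also requires
identical offsets, `approximate` requires character overlap (default
≥ 1 character, with a configurable minimum-overlap fraction, since the
reference approximate-match rule is cited but not restated). Ties break
by larger overlap, then leftmost. From pooled TP/FP/FN come micro
precision/recall/F; macro-F averages per-type F over types with at
least one gold instance (types absent from gold are excluded, not
scored 0). At the `coarse_mapped` level both sides map to coarse types
first, so a wrong fine type within the right coarse category counts as
a true positive — by construction coarse-mapped micro-F ≥ fine micro-F,
and approximate-F ≥ exact-F.

Sentence error rate uses the strictest reading of token correctness:
a sentence is wrong if any token's *full* BILOU label (position and
type) differs. Rates are reported per CMI bin; empty bins are absent
rather than 0, and the bin-size-weighted mean equals the overall rate.

Stratified scoring splits by sentence category, CMI bin, or IV/OOV
status. Sentence-level strata conserve pooled counts exactly under any
criterion (matched spans overlap, hence share a sentence). For the OOV
stratifier each annotation is assigned by its own mention's vocabulary
status; under exact matching conservation is again exact, while under
approximate matching a matched pair could in principle straddle the
IV/OOV boundary — the conservation tests therefore pin the exact
criterion.

## Numerical and degenerate-input conventions

* 0/0 → 0 for precision, recall and F.
* Empty sentence → category NUMERIC_SYMBOLIC, CMI 0, dominant NONE.
* Empty training set → empty dictionary (every prediction O); empty
  vocabulary → every mention OOV.
* `min_count > k` in voting and a missing `<SENTENCE>` placeholder are
  configuration errors, raised eagerly.
* Corpus JSON is the lossless native format. CoNLL does not record
  whitespace, so reading reconstructs text by joining tokens with
  single spaces (consecutive Han characters joined without a space);
  labels, types and token sequences round-trip exactly, and a
  CoNLL-derived corpus round-trips bit-exactly thereafter. Standoff
  (.txt/.ann) preserves text and offsets exactly.
* Run configurations are echoed as JSON (not YAML) so the pipeline
  depends only on `jsonlite`.

## Known limitations

* Only Latin and Han scripts are modeled; the two-language CMI bound
  (0.5) does not generalize to three or more languages.
* The generator's sentences are statistically faithful but not
  linguistically natural (see above).
* No significance testing between systems and no calibration analysis.
* The LLM route's reference prompt, output format and span-resolution
  rules are reconstructions; all are configurable so alternatives can
  be evaluated.
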