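---
title: "Extracting directed brain-region connectivity from text: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting directed brain-region connectivity from text: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The extraction model

`neuroconn` is a knowledge-based relation extractor: it never learns from
data, it applies a fixed set of linguistic rules. The underlying model of a
connectivity statement is

> *trigger pattern* + *two argument spans* + *dictionary-validated regions*
> → one or more directed relations (agent → target),

with the directionality read off the pattern rather than inferred. This
design trades recall for precision: a sentence without one of the 18
trigger patterns can never produce a relation (a hard recall ceiling), but
when a pattern fires, the parse-tree rules and the dictionary act as two
independent filters that few false candidates survive.

### Trigger patterns

Each pattern is a case-insensitive regular expression over a keyword stem
and a closing preposition, allowing a bounded number of interleaved words
(e.g. `project(ing|s|ed)? (\w+ ){0,2}to`): inflection and adverbs must not
block a match, but the bound keeps the pattern from spanning clause
boundaries. The published transcriptions of these expressions contain
typographic artifacts (stray spaces inside quantifiers, inconsistent
escaping); we normalize them to syntactically valid equivalents that
preserve the stated optionality and word-gap counts, and additionally
accept the single-l spelling "traveling" alongside "travelling". The
interleaved-word unit tolerates a trailing comma or semicolon so that
conjunction lists ("from Pa, Pt, and other midline nuclei to …") fit
inside dual-slot patterns.

Overlapping matches are resolved by *subsumption*: a match whose character
span lies strictly inside another match's span is dropped, so the
dual-slot `projection from … to` beats its prefix `projection from`. Ties
on identical spans keep the first pattern in table order.

**Role table.** The description of the method states the direction
semantics only through examples, so the full 18-row role table is a design
choice of this package: text following {projection from / of / target of,
receive input/fiber/innervation/afferent from, exit through/from, and
every "from" slot} is the **agent**; text following {innervate,
innervation of, projection to, project to/into, and every "to" slot} is
the **target**. The table is config-overridable (`compile_patterns()`),
and a test flips it deliberately to confirm directions invert.

### Argument identification

The first argument is the **first NP after the pattern** in the bracketed
constituency tree, located in pre-order so the outermost such NP wins
("Pa in rats", not just "Pa"). An immediately following PP containing
"including" is appended, because enumerations after "limbic structures
including …" carry the actual regions. If no NP follows, the match is
abandoned.

The second argument comes from the typed dependency edges through three
rule groups, tried in presentation order (subject group → direct-object
special case → verbal modifier); the first non-empty result wins:

* **Subject group** (`nsubj`, `nsubjpass`, `xsubj`, `nn`): keyword as
  governor → the relation's dependent plus *every* word that dependent
  governs (determiners included — stop-word removal discards them later);
  keyword as dependent → the prepositional dependent of the keyword's
  governor, plus its `amod`/`nn` modifiers.
* **dobj → nsubj special case**: when the keyword is a direct object, the
  verb's nominal subject is the candidate, expanded one level through
  `amod`/`nn`/`prep`, and `amod`/`nn` once more under each `prep`
  dependent. The recursion depth is inferred from the single published
  worked analysis and kept fixed.
* **vmod rule**: keyword as reduced-relative modifier → the modified noun
  plus its `amod`/`nn` modifiers.

All rule outputs are position-sorted, exclude the keyword token, and are
checked against independent brute-force oracles (naive re-enumerations of
each rule description) on randomized dependency graphs.

Dual-slot patterns ("projections from X to Y") bypass the dependency
search entirely: both slots are syntactically local, so the between-slot
text and the NP after the closing preposition are used directly.

**Voice.** A keyword participating in an `nsubjpass` edge marks the clause
passive and flips the role table for that match. Dual-slot patterns are
never flipped (their slots are anchored to prepositions, not to syntax).

**Parser independence.** All rules consume an internal tree/edge
representation loadable from plain-text fixtures, so rule behaviour cannot
drift with parser versions. `map_dependency_labels()` adapts
Universal-Dependencies output (`obj`→`dobj`, `compound`→`nn`,
`acl`→`vmod`, `nsubj:pass`→`nsubjpass`, `nmod`/`obl`+`case`→`prep_X`) for
live parsers.

### Dictionary decision

The cascade (`match_text()`) runs per argument span: (1) whole-string
lookup; (2) split on "and"/"or"/commas/semicolons; (3a) per-piece retry
after removing the stop words *of, the, area, part*; (3b) substring search
of dictionary surface forms inside the piece, then token-by-token lookup.
Finally only the longest non-overlapping matches are kept. Whole-piece
hits are *full* matches; step-3b hits cover only part of their piece and
are flagged *partial*.

Numerical/design choices here:

* Canonical names and synonyms match case-insensitively; **acronyms match
  case-sensitively** by default ("Pa" the nucleus must not match the
  syllable "pa"); a flag relaxes this.
* Step-3b substring search requires surface forms of ≥ 3 characters at
  word boundaries — a precision guard; two-letter acronyms can still match
  as whole tokens.
* The stop-word list is exactly the four words above but extendable; no
  stemming is done — plural variants belong in the dictionary as synonyms
  ("Suprachiasmatic nuclei").
* Conjunction-ambiguous phrases ("dorsal and ventral cortex") are *not*
  expanded into multiple regions; resolving them was found to cost
  precision, so the span is matched as-is through the cascade.
* Direction-qualified regions ("anterior PVT") are separate dictionary
  entries, never derived.

### Relations, dedup, graph

Every (agent-region, target-region) combination of the two spans yields a
relation; a pair whose two sides normalize to the same canonical region is
suppressed. Document-level deduplication keeps the first occurrence of
each *ordered* pair (A→B and B→A stay distinct, supporting separate
agent/target degree counts) and records the merged mention count.

The connectivity graph is a directed multigraph — one edge per mention —
with provenance attributes. Edge betweenness follows the Girvan–Newman
convention: computed on the collapsed simple *undirected* graph over
unordered node pairs (a `directed = TRUE` flag switches to ordered pairs
on the directed collapsed graph), with equal-length shortest paths
splitting the count fractionally; scores attach to the collapsed region
pair while the stored graph keeps its parallel edges. The computation is
delegated to `igraph` and cross-checked against a brute-force all-pairs
enumeration in the tests. Export color bins (green→yellow→orange→red) are
empirical quartiles of the mapped attribute — a rendering convention only.

### Evaluation

Precision = 100·TP/(TP+FP), recall = 100·TP/(TP+FN), F = 2PR/(P+R) with
F = 0 when both are 0, all rounded half-up to two decimals — the
convention of published evaluation tables. We always report the ratio
identities of the raw counts; e.g. 107 full matches among 161 retrieved
give precision 66.46%, and no independently rounded figure is substituted.
Precision with zero retrieved relations is reported as 0 with an explicit
flag. Gold pairs are matched *orderlessly* (pairwise interaction
annotations carry no direction); strict mode accepts only full string
matches of both mentions, lenient also accepts word-boundary partial
matches, and NLP-based mode additionally credits predictions explicitly
flagged as dictionary-validated-but-unannotated, with the false-negative
count then taken against the remaining gold total. Direction accuracy is
computed only over true positives and compared with the
first-mention→second-mention majority baseline.

## The synthetic fixture generator

`generate_fixture_corpus()` instantiates documents from five relation
templates keyed to the trigger patterns — active ("X projects densely to
Y"), passive ("Y was strongly innervated by X"), "receives dense input
from", dual-slot with 1–3 conjoined agents, and an "including"
enumeration — plus two distractor kinds (no trigger at all; a trigger with
no dictionary region). Each relation sentence carries its gold directed
pairs and a deterministic template-derived constituency tree and
dependency edge set. Defaults: 3 sentences per document, 20% distractors,
25% passive among two-region sentences, region counts 2/3/4 weighted
0.5/0.3/0.2 — a mixture in which roughly every syntactic route of the
extractor is exercised in a 50-document corpus, the size used by the
package's end-to-end checks. A fixed seed makes output bit-exact, and the
generator restores the caller's RNG state.

What the generator *does not* emulate — and what passing tests therefore
do not show about real text: parser errors (fixture parses are correct by
construction), mentions missing from the dictionary, nested or ambiguous
conjunctions, anaphora and relations spanning sentences, negation and
hedging ("no substantial differences … innervate" *is* extracted — such
statements are deliberately left to downstream expert judgment). On real
corpora precision and recall are far below the fixture's 100%; the
fixture establishes correctness of the machinery, not field performance.

## Degenerate inputs and tie-breaks

* Empty text → empty sentence list; empty dictionary → every lookup
  misses; empty relation set → empty graph and empty rankings.
* Sentence splitting protects a fixed abbreviation list ("et al.",
  "e.g.", "Fig."); single capital letters are *not* treated as initials,
  because single-letter region symbols legitimately end sentences.
* Ranking ties (equal degree or mention count) break alphabetically;
  overlapping dictionary matches break by span length, then start
  position.
* Duplicate surface forms across dictionary entries warn and keep the
  first entry; duplicate canonical names are an error.
* Abbreviation expansion rewrites only free-standing short forms, so the
  operation is idempotent; the definition site itself is never rewritten.

## Problem sizes used by the checks

The shipped checks run a 50-document fixture corpus end to end, compare
the dependency rules with their brute-force oracles on 10,000 random
graphs of ≤ 8 edges, and edge betweenness with an all-pairs enumeration on
1,000 random graphs of ≤ 8 nodes — sizes at which the oracles are exact
and exhaustive while the whole suite stays fast.

## Known limitations

Sentence-level only; recall is bounded by trigger coverage; dictionary
coverage dominates end-to-end accuracy on real text (the bundled
30-entry dictionary is a fixture, not a resource); the role table rows
not fixed by published examples are this package's choices, though
config-overridable; "too generic" but dictionary-valid candidate pairs
are surfaced as ordinary relations — no automatic filter stands in for
expert judgment.
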