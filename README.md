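# neuroconn

Rule-based extraction of **directed brain-region connectivity relations**
from neuroscience text.

Findings about neuroanatomical projections ("the suprachiasmatic nucleus
projects densely to Pa", "the aPVT was strongly innervated by the ventral
subiculum") are scattered across decades of publications. `neuroconn`
implements a high-precision, knowledge-based pipeline that turns such
sentences into a directed connectivity multigraph between canonical brain
regions:

1. **Trigger patterns.** 18 case-insensitive regular expressions over
   connectivity keywords (`project to`, `innervate`, `receive input from`,
   `projection from … to …`, …) nominate candidate sentences. Patterns
   tolerate interleaved words ("project *densely* to") and carry role
   semantics: whether the text after the pattern names the **agent**
   (source) or the **target** (destination) of the projection.
2. **Argument identification over parse trees.** The first argument is the
   first noun phrase (NP) after the pattern in the constituency parse
   (extended with a following "including" PP). The second — possibly
   long-distance — argument comes from typed dependency edges
   (`nsubj`, `nsubjpass`, `xsubj`, `nn`, `dobj`, `vmod`, collapsed
   prepositions `prep_X`) via three rule groups: a subject/noun-compound
   group, a `dobj`→sibling-`nsubj` special case, and a `vmod` rule for
   reduced relatives ("orexin neurons projecting to …").
3. **Dictionary normalization.** Candidate spans are matched against a
   brain-region dictionary (canonical name + acronyms + synonyms) through a
   staged cascade: whole-string lookup; splitting on conjunctions and
   punctuation; stop-word removal ("of", "the", "area", "part");
   substring and token-level search; longest-non-overlapping match
   selection ("midline thalamus" beats "thalamus").
4. **Directionality.** Each pattern's role table orients the relation
   (agent → target); passive voice (keyword in `nsubjpass`) flips the
   roles, so "aPVT was innervated by the ventral subiculum" yields
   ventral subiculum → aPVT.
5. **Evaluation & graph.** Predictions are scored against gold pairwise
   annotations with precision / recall / F = 2PR/(P+R) in *strict* (full
   string matches), *lenient* (+ word-boundary partial matches) and
   *NLP-based* (+ dictionary-validated unannotated candidates) modes;
   direction accuracy is computed over true positives, against a
   first-mention → second-mention majority baseline. Relations build a
   directed multigraph (one edge per mention) with degree rankings and
   Girvan–Newman edge betweenness.

Everything runs parser-free from bracketed `.ptb` trees and
`label(gov-i, dep-j)` dependency triples (fixtures ship with the package);
a `map_dependency_labels()` shim adapts Universal-Dependencies output from
any live parser.

## Worked example

```r
library(neuroconn)
dict <- nc_example_dictionary()

ex <- worked_example("pa_pt_dual")
ex$sentence
#> <sentence we.pa_pt_dual.s0, 17 tokens> These experiments confirm projections
#> from Pa, Pt, and other midline nuclei to the amygdala.

extract_from_sentence(ex$sentence, ex$tree, ex$edges, dict)[,
  c("agent", "target", "agent_kind", "target_kind", "pattern")]
#>   agent   target agent_kind target_kind            pattern
#> 1    Pa Amygdala       full        full projection from to
#> 2    Pt Amygdala       full        full projection from to
```

The dual-slot pattern `projection from … to …` takes both arguments
locally: the conjunction list between "from" and "to" splits into the
agents Pa and Pt (the unlisted "other midline nuclei" has no dictionary
entry and is dropped), and the NP after "to" normalizes to the target
Amygdala — two directed relations from one sentence.

On a synthetic corpus with known gold relations the pipeline recovers
everything:

```r
fx  <- generate_fixture_corpus(fixture_spec(n_docs = 20, seed = 7))
rel <- extract_corpus(fx$documents, fx$parses, dict)
score(rel, fx$gold, mode = "lenient")
#> <lenient evaluation> TP=83 FP=0 FN=0  P=100.00% R=100.00% F=100.00%

top_regions(build_graph(rel), 3)
#>                     region agent target total
#> 1      Paracentral nucleus     6      9    15
#> 2            Parietal lobe     2     10    12
#> 3 Medial prefrontal cortex     6      3     9
```

`agent`/`target` count out- and in-mentions per region; `total` is their
sum, the node's mention degree in the connectivity graph.

## Command line

```sh
Rscript inst/scripts/neuroconn fixtures --out fx --seed 7 --n-docs 20
Rscript inst/scripts/neuroconn extract  --docs fx/docs --dict inst/extdata/brain_regions.tsv --parses fx/parses --out out
Rscript inst/scripts/neuroconn evaluate --pred out/relations.tsv --gold fx/gold.xml --mode strict
Rscript inst/scripts/neuroconn graph    --relations out/relations.tsv --out out/graph.graphml
Rscript inst/scripts/neuroconn patterns
```

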