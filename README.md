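# gsmtrace — a traceable workspace for genome-scale metabolic model reconstruction

Reconstructing a genome-scale metabolic model (GSM) for a non-model organism
is never a single-tool affair: an annotation-based draft is merged with
orthology-derived reactions transferred from template species, gaps are
filled from a reference database, and experts hand-curate the result. Months
later, nobody remembers *why* a particular reaction is in the model.
`gsmtrace` is an R toolkit for that workflow built around one idea: **every
entity in the model carries process metadata** — which reconstruction
category (annotation, orthology, gap-filling, manual), which tool, which
source, and at which pipeline step it entered — so the finished model can be
audited, compared, re-run and explored.

It is aimed at systems-biology groups assembling GSMs for newly sequenced
organisms from heterogeneous inputs (SBML drafts, template models, reaction
databases, curation notes), and at anyone who needs the reconstruction to be
*replayable* rather than a one-off artifact.

## What it does

* **Provenance-tracked model store** — typed entities (reactions, compounds,
  genes, pathways, proteins, ontology classes), typed relations, per-entity
  source tags; merging unions attribute values instead of overwriting, so
  conflicting evidence is kept, never silently resolved.
* **Topological producibility suite** over the bipartite reaction/compound
  graph. The *scope* of a seed set *S* (the growth medium) is the least
  fixpoint of network expansion:

  Σ⁰ = S,  Σⁱ⁺¹ = Σⁱ ∪ { products(r) : reactants(r) ⊆ Σⁱ }

  A reaction fires only when **all** its reactants are reachable; reversible
  reactions act as two directed reactions; stoichiometric coefficients are
  deliberately ignored (presence/absence semantics, weaker than flux
  feasibility). On top of the scope: unproducible-target detection, minimal
  unblocking-compound enumeration, production-path extraction, and
  **topological gap-filling** — cardinality-minimal sets of database
  reactions X ⊆ D∖M with targets T ⊆ scope(M ∪ X, S), found by iterative
  deepening with backward-path pruning and verified exhaustively.
* **Class/instance reaction instantiation** — database reactions written
  against compound *classes* (ontology nodes) are expanded into variants
  over each class's direct instances, which is what makes the classic
  folate-pathway gap fillable (see below).
* **Interoperability** — SBML Level 2/3 (fbc gene associations, notes-based
  process metadata), a canonical flat text dialect that round-trips
  byte-stably, stoichiometric-matrix TSV, identifier mapping against a
  MetaNetX-style dictionary, and RDF Turtle export for semantic queries.
* **Replayable curation** — manual edits are tab-separated *forms* with a
  mandatory justification and source; they apply deterministically, stamp
  `manual` tags, and replay onto a regenerated base (drifted targets are
  skipped with a report, not a crash).
* **Reports and wiki** — pathway completeness rates, provenance set algebra
  (counts, overlaps, exclusives per category/tool/source), gene-association
  ratio and mass/charge balance checks, model diffs, and a deterministic
  static wiki with one page per entity.
* **Pipeline runner** — a YAML configuration chains all of the above with a
  run log of parameters, input digests and entity-count deltas; identical
  configuration and inputs reproduce the identical model.

## Worked example: the tetrahydrofolate class/instance gap

The packaged fixture encodes folate biosynthesis — pathways PWY-6147 and
PWY-6614, eight reactions from seed GTP to the target THF-GLU-N. The draft
holds seven of the eight steps (3 from annotation, 4 from orthology, one
found by both, one from an earlier gap-filling round). The missing
dihydrofolate reductase is written in the database against the compound
*class* `DIHYDROFOLATE-GLU-N`, while the upstream synthase produces the
*instance* `DIHYDROFOLATE` — so the generic reaction can never fire:

```r
library(gsmtrace)
fx <- make_folate_fixture()
fx$draft
#> <gsm_model 'folate-draft'> [ref: metacyc]
#>   reaction: 7, compound: 14, gene: 3, pathway: 2, protein: 0, class: 0
#>   relations: 30, tags: 11

unproducible_targets(fx$draft, fx$seeds, fx$targets)
#> [1] "THF-GLU-N"

comp <- gapfill(fx$draft, fx$database, fx$seeds, fx$targets, enumerate = TRUE)
comp
#> <gsm_completion> 1 minimal solution(s) of size 1
#>   union: 1 reactions; intersection: 1 reactions
#>   - DIHYDROFOLATEREDUCT-RXN-THF/NADP//DIHYDROFOLATE/NADPH/PROTON.37.
```

Gap-filling finds exactly one minimal completion: the *instantiated* variant
of the reductase that consumes the instance. Applying it completes both
pathways, and the provenance breakdown shows where each of the eight
reactions came from:

```r
filled <- apply_completion(fx$draft, fx$database, comp$solutions[[1]])
pathway_completeness(filled, fx$pathway_defs)
#> <gsm_completeness>
#>   pathway total present ratio
#>  PWY-6147     4       4  1.00
#>  PWY-6614     4       4  1.00

provenance_breakdown(filled, "category", etype = "reaction")
#> <gsm_breakdown> by category (reaction): 8 distinct entities
#>   annotation         3 total,     2 exclusive
#>   gap-filling        2 total,     2 exclusive
#>   orthology          4 total,     3 exclusive
```

`generate_wiki(filled, "site", fx$pathway_defs)` renders the same model as a
browsable static site with per-reaction provenance badges.

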