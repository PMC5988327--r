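---
title: "Methods: provenance-tracked GSM reconstruction and topological producibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: provenance-tracked GSM reconstruction and topological producibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsmtrace)
```

## The problem

A genome-scale metabolic model (GSM) for a newly sequenced organism is
assembled from heterogeneous evidence: an annotation-based draft, reactions
transferred from curated template models by orthology, database reactions
added by gap-filling, and manual expert edits. The scientific value of the
finished model depends on being able to answer, for every reaction, *where
it came from and why it is there* — and on being able to re-run the whole
assembly when an input (a genome re-annotation, a new template model)
changes. `gsmtrace` treats that traceability as the primary datum: the model
store pairs every entity with *source tags* `(category, tool, source, step,
comment)`, and every operation in the package either preserves or extends
them, never deletes them.

## The data model and its invariants

A model is a set of typed entities (`reaction`, `compound`, `gene`,
`pathway`, `protein`, `class`), typed relations (`consumes`/`produces` with
a positive stoichiometric coefficient, `is_in_pathway`, `is_linked_to` for
gene–reaction links, `catalyzes`, `has_xref`, `is_a` for ontology
membership), and tags. Invariants enforced throughout: ids are unique and
case-preserved; an entity's type is fixed for life (re-adding with another
type is a typed error); attribute keys are case-insensitive multimap keys
whose value lists stay ordered; all relation endpoints and tag subjects
resolve; a reaction has at least one reactant and one product unless flagged
as a boundary/exchange reaction.

Two design choices here were genuinely open and deserve their rationale:

* **Attribute conflicts union, never overwrite.** When merging two sources
  that disagree (say, two `direction` values), both values are kept in the
  ordered list and the disagreement is visible to reports. Any overwrite
  policy would silently erase evidence, which defeats the purpose of a
  traceable store; flagged unions are the conservative choice.
* **Identifier escaping lives only at the SBML boundary.** Reference
  databases use ids with dots and slashes (e.g. the instantiated reaction
  `DIHYDROFOLATEREDUCT-RXN-THF/NADP//DIHYDROFOLATE/NADPH/PROTON.37.`). SBML
  SIds cannot carry them, so export escapes each forbidden character (and a
  leading digit) as `__<codepoint>__` and import reverses it; an id
  containing a literal escape sequence is refused by name rather than
  round-tripped ambiguously. The store itself never mangles ids.

The flat text dialect (`[entities]` / `[relations]` / `[tags]` sections,
tab-separated, percent-encoded metacharacters) is written canonically —
everything sorted under C collation — so `write(read(write(M)))` is
byte-identical to `write(M)` and flat files can be checksummed and diffed.

## Producibility: network expansion semantics

All topological operators share one semantics. Given seeds $S$ (the growth
medium), the *scope* is the least fixpoint of

$$\Sigma^0 = S, \qquad
  \Sigma^{i+1} = \Sigma^i \cup \{\, \mathrm{products}(r) :
  \mathrm{reactants}(r) \subseteq \Sigma^i \,\}$$

with three deliberate choices:

* **Coefficients are ignored.** Producibility is presence/absence; this is
  weaker than flux feasibility and is documented as the divergence point
  from constraint-based validation (which this package does not do — the
  mass/charge balance checks in `quality_report()` are the only place
  stoichiometry is arithmetic).
* **Reversible reactions are two directed reactions**, each of which must
  satisfy its own reactant side. Firing one direction does not grant the
  other.
* **Self-loops do not bootstrap**: a compound appearing on both sides of a
  reaction still needs its reactant occurrence satisfied from elsewhere —
  a direct consequence of least-fixpoint semantics.

The implementation expands breadth-synchronously so each compound gets a
well-defined *layer* (first iteration producing it; seeds are 0), which the
path extractor reuses. Termination is bounded by one iteration per compound;
the result is independent of scan order (the test suite checks it against a
naive scan-until-stable oracle written separately).

`production_path()` builds a witness backwards from the target, at each
compound choosing the lexicographically first reaction that fired at that
compound's layer, and returns the chosen reactions ordered by layer. Because
every chosen reaction's reactants lie in strictly earlier layers, replaying
the sequence in order never lacks a reactant — a property the suite verifies
with an explicit replay simulator.

`unblocking_compounds()` enumerates *subset-minimal* sets of non-seed
compounds whose addition to the medium unblocks all targets, sizes explored
in increasing cardinality (so the output is sorted by cardinality, then
lexicographically, and both cardinality- and subset-minimality are visible —
the minimality notion was an open choice, so both are exposed).

## Topological gap-filling

`gapfill(draft, database, seeds, targets)` searches for cardinality-minimal
$X \subseteq D \setminus M$ with $T \subseteq
\mathrm{scope}(M \cup X, S)$:

1. **Feasibility**: if even the full database leaves targets unreachable,
   a typed error lists them.
2. **Backward pruning**: candidates not on any backward path from a target
   (computed on the union graph) cannot belong to a minimal completion and
   are dropped.
3. **Iterative deepening**: each cardinality level is enumerated
   exhaustively while `choose(n, k)` stays below `exhaustive_limit`
   (default 20 000); with `enumerate = TRUE` all minimal-cardinality
   solutions plus their union and intersection are returned (which of the
   three a curator wants is genuinely situational, so all are exposed behind
   flags).
4. **Greedy fallback**: above the limit, a greedy set-cover pass (most new
   producible targets, then compounds, lexicographic tie-break) followed by
   single-removal pruning returns one solution explicitly marked
   `heuristic` — minimality is then not guaranteed and the object says so.

Every solution is re-verified post hoc in the tests: targets producible with
it, not producible after removing any single member, and full agreement with
exhaustive subset enumeration on all instances with at most 12 candidates.

**Class/instance instantiation.** Reference databases write some reactions
against compound classes. `instantiate_class_reactions()` adds, per reaction
with class participants that have direct `is_a` instances, one variant per
element of the cartesian product across class slots (cap 64 variants per
reaction, capped reactions skipped and reported; the `is_a` graph must be
acyclic). Variants record their parent in an `instance-of` attribute rather
than an `is_a` relation, because `is_a` is reserved for links *to class
entities* and a parent reaction is not a class. Pathway completeness counts
a defined reaction as present when the model carries it or any `instance-of`
variant of it — this is what lets an instantiated variant legitimately stand
in for its generic parent in a completion-rate of 1.0.

## Curation and diffing

Curation forms are flat tab-separated blocks, not interactive prompts, so
they are diffable and replayable. A form without a non-empty justification
*and* source is invalid — the audit trail is mandatory, not optional.
Applying a form stamps `manual` tags on every touched entity and appends the
form to the model's log; `replay_log()` re-applies a log onto a (possibly
regenerated) base, skipping forms whose target disappeared upstream with a
report rather than an error, because upstream regeneration legitimately
changes the base. Deletions keep no tombstone in the model itself — history
lives in the log only.

`diff_models()` partitions ids per category into added/removed/changed with
attribute- and relation-level deltas; `diff(a,b)$added == diff(b,a)$removed`
holds by construction and is property-tested.

## Reports, wiki, RDF

The provenance breakdown publishes counts, pairwise overlap matrices and
exclusive counts per category/tool/source and never assumes the groups are
disjoint — published per-category counts generally do not sum to the model
total precisely because methods overlap, so overlaps are always explicit.
The gene-association ratio excludes boundary/exchange reactions from its
denominator by default (configurable; a convention, since nothing forces
either choice). Mass balance is the per-element sum of coefficient-weighted
Hill-notation formula counts over products minus reactants; any participant
with a missing or non-elemental formula (R-groups, polymers) makes the
reaction `undetermined`, never silently balanced.

The wiki is static hypertext regenerated from the model — one page per
entity, per-type indexes, per-category/tool/source pages, and a pathway
index sorted by completion rate. Determinism (byte-identical output for an
identical model) and zero dangling internal links are tested invariants.
External database links are URL templates keyed by the declared reference
database and are emitted as configured even when unverifiable offline.

RDF export writes one triple per relation, one per entity attribute value,
and a five-predicate provenance node per tag (taggedEntity, category, tool,
source, step — the free-text comment stays in the flat format), so the
triple count obeys a closed form the tests recount. There is no SPARQL
endpoint; files are the interface.

## The pipeline runner

A YAML configuration lists ordered steps over registered operations
(read/merge/map/gapfill/curate/write/report/wiki). External reconstruction
tools are never invoked — their SBML/TSV outputs are declared step inputs,
which keeps runs self-contained and desk-testable. Each step stamps its
index into the tags it creates and appends a log record with parameters,
md5 digests of inputs, and entity/reaction-count deltas; deltas telescope to
the final model size, and identical configuration plus inputs reproduce the
identical model (tested byte-for-byte through the flat writer). A failing
step halts with the partial log and reached model attached to the error.

## The synthetic generator and what the tests do (and do not) show

`random_network()` emulates the topological shape the operators care about:
compounds with a designated growth medium, reactions drawing reactants from
the already-reachable pool, and a *leak probability* (default 0.2) that
draws a reactant from the unreachable pool instead, creating genuinely
blocked branches — the situation gap-filling and unblocking analysis exist
for. Reversible fraction defaults to 0.2, roughly the shape of directed
reaction databases; determinism per seed is part of the contract. What it
does **not** emulate: realistic degree distributions, currency metabolites,
compartments, or stoichiometric detail — so passing oracle suites shows the
*operators are correct on the semantics*, not that the semantics captures
everything about real metabolism (coefficient-blind expansion notably cannot
see cofactor cycling).

The folate fixture is the one hand-built instance: eight reactions across
PWY-6147/PWY-6614 from GTP to THF-GLU-N, schematic one-to-one
stoichiometries, five neutral cofactor seeds, and the class/instance
mismatch placed exactly where it occurs in the reference database, so the
draft's only blockage is the one the instantiated reductase variant
repairs. The draft carries 7 of the 8 steps: 3 annotation-tagged, 4
orthology-tagged (one reaction tagged by both), plus one reaction from an
earlier gap-filling round — the reading that makes the per-category tag
counts and the 7/8 coverage simultaneously consistent.

## Problem sizes and numerical choices

The shipped suites use 200 generated networks of 10–50 compounds for the
scope oracle, 12 instances of 12 reactions (≤ 12 gap-filling candidates,
brute force to cardinality 3) for the search oracles, and the folate fixture
for the end-to-end case study — sizes at which exhaustive enumeration is an
uncontested ground truth while the whole suite stays fast. Ties are broken
lexicographically under C collation everywhere (enumeration order,
path-witness choice, greedy fallback), which is what makes every output of
the package reproducible across platforms and locales. Floating point
appears only in completeness ratios and balance sums (tolerance 1e-9 on the
latter); all set algebra is exact.

## Known limitations

* Producibility is purely topological; a "producible" target may still be
  flux-infeasible. Constraint-based validation belongs to external FBA
  tooling, which consumes this package's SBML export.
* SBML carries reaction- and species-level process metadata in notes;
  gene-entity tags survive only in the flat dialect.
* Identifier mapping is single-pass by design: dictionaries with transitive
  chains are rejected as input errors rather than resolved.
* The greedy gap-filling fallback can return non-minimal completions; it
  always says so, and the exact path is used whenever the combinatorics
  allow.
* The wiki is regenerated, never edited; there is no server, history, or
  search — RDF export plus external query engines cover structured
  exploration.
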