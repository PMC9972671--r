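---
title: "Representing, scoring and validating sequence alignments"
author: "salonr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Representing, scoring and validating sequence alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salonr)
```

# The model

`salonr` represents a pairwise or multiple sequence alignment as a typed
object graph under the SALON vocabulary (<https://w3id.org/salon>): an
`Alignment` contains one or more `SubAlignment`s (clusters of sequences that
share a property, e.g. a phylogenetic clade), each holding
`AlignmentSequence`s of equal aligned length, their annotated `Feature`s
(1-based inclusive `fstart`/`fstop` coordinates, the MACSIM convention), the
derived `AlignmentColumn`s, and `Score`s attached to `ScoreFunction`s that
declare their own `scoreMin`/`scoreMax` bounds. DNA and protein sequences
are distinguished by the `molecule` slot and mapped to the
`DNAAlignmentSequence`/`ProteinAlignmentSequence` subclasses.

Two modelling choices deserve a note:

* **Cardinality is validation, not construction.** The vocabulary requires
  an alignment to contain at least one sub-alignment and a sub-alignment to
  hold at least two sequences. We deliberately allow such objects to be
  *constructed* — they arise naturally while assembling data — and report
  the violation from `validateAlignment()` instead.
* **Aligned length includes gaps.** The `length` of a sequence, when not
  supplied by the input, is the character count of the aligned string
  including gap symbols. The vocabulary leaves this undefined; we record it
  as our choice rather than assert it as the schema's intent.

The schema itself ships as a queryable registry (`builtinSchema()`): the
class hierarchy, the 14 object properties with their 4 inverse pairs, the
data properties with datatypes, and the two minimum-cardinality rules. The
registry covers the entities the vocabulary names explicitly; the published
ontology contains further classes and axioms that are not enumerated
anywhere we can reconstruct them from, so they are intentionally out of
scope. Two registry decisions were genuinely open:

* The domain of `hasAssociationWithProtein` is printed as
  `SequenceAlignment`, a name appearing nowhere else. We register it as an
  alias resolving to both `Alignment` and `AlignmentSequence`, because the
  published usage associates a protein with a *sequence* instance
  (`salon:BB11001_1aab_`) while the printed domain reads like the whole
  alignment.
* `ReliabilityMeasure` is not in the top-level class list; since GUIDANCE
  and Heads-or-Tails are per-column confidence functions, we register it as
  a subclass of `ColumnScoreFunction`.
* The printed domain of `scoreMin`/`scoreMax` is ambiguous in our source
  material ("AlignmentScore or ColumnScoreFunction"); bounds belong to
  score *functions* in every worked example, so we register
  `AlignmentScoreFunction`/`ColumnScoreFunction` as the domains.

# Score functions

Three built-in metrics cover the published catalogue
(`scoreFunctionCatalog()`):

* **Percent totally conserved columns.** A column scores 1 iff all
  characters are identical *and* none is the gap character; "totally" is
  read strictly, so a single gap breaks conservation (our decision; the
  source leaves it undefined, and the strict reading makes
  `conserved ≤ non-gap` a theorem). The alignment level is
  `100·k/n ∈ [0,100]`.
* **Percent non-gaps.** A column scores 1 iff it contains no gap.
* **Column entropy.** `H = −Σ p_a log2 p_a` over the frequency distribution
  of *non-gap* characters. The base-2 logarithm and the exclusion of gaps
  are forced by the published range: only `log2` over the 20-symbol
  amino-acid alphabet yields the printed maximum 4.322 = `log2(20)`; a 21st
  gap symbol would raise it to `log2(21) ≈ 4.392`. A single-residue column
  scores 0. An all-gap column has no defined entropy; we raise an error and
  let the caller decide the policy (the synthetic generator never produces
  such columns).

The alignment-level entropy is the sum of the per-column values, so its
natural maximum is `nColumns × 4.322`. Our source material prints the
maximum as *number of sequences* × 4.322, which is inconsistent with
summing per-column values; we set `scoreMax = nColumns × log2(20)` and
record the discrepancy here rather than guessing the intended reading.

Entropy values are compared to the printed constant 4.322 with absolute
tolerance `5e-4`, matching its 3-decimal precision.

# Validation rules

`validateAlignment()` natively evaluates what the vocabulary expresses as
SWRL rules (the equivalent rule texts are exported by `swrlRuleTexts()` for
users who prefer a reasoner):

* **Score bounds.** A score `v` under a function with bounds `[min, max]`
  is incorrect iff `v > max` or `v < min` — four mutually exclusive rules
  (`alignment`/`column` × `gt_max`/`lt_min`). Bounds are *inclusive*: the
  worked example's column score of 1 under a `[0, 1]` function must
  validate, so equality passes. A function with no declared bound on a side
  disables that side's check with a warning.
* **Cardinality.** ≥ 1 sub-alignment per alignment, ≥ 2 sequences per
  sub-alignment.
* **Reliability.** Each column's confidence under a `ReliabilityMeasure` is
  compared *strictly* to the cutoff; a score equal to the cutoff passes in
  both directions. The flagging direction (`below_cutoff`/`above_cutoff`)
  has no default because published usage is inconsistent — GUIDANCE filters
  columns below the cutoff, while other descriptions mark columns exceeding
  it — so the caller must state it. Flagged columns are reported as
  `unreliable_column` violations but never flip the verdict: unreliability
  is a filtering aid, not an incorrectness.
* **Schema assertions.** Every relation the model maps to is checked
  against the registry's domains, ranges and datatypes.

All problems are collected into a `ValidationReport`; nothing is thrown.
The verdict is `correct` iff no violation other than `unreliable_column`
entries exists.

# RDF mapping

Instance IRIs are minted deterministically as
`base + alignmentId + "_" + localId` with characters outside
`[A-Za-z0-9_]` replaced by `_`, following the published instance pattern
(`salon:BB11001_1aab_`). The base namespace defaults to the SALON IRI and
is configurable, since the publication shows only a single instance-IRI
example. Blank nodes are never used — every entity is globally addressable.
Score-function IRIs embed the function's kind so that an alignment-level
and a column-level function sharing a name remain distinct individuals.

Both the forward property and its declared inverse are materialized
(`hasSequence` *and* `isSequenceOf`, etc.), so triple stores without
inference still answer inverse queries; `alignmentFromGraph()` normalizes
inverse-only graphs back to the forward form, and a graph carrying only
inverse statements reconstructs the same model. Literals are typed per the
registry (`integer`/`decimal` as XSD types; `string` and single-character
`short` as plain literals), and numeric lexical forms are written with 17
significant digits so doubles survive a round-trip bit-exactly.

No RDF library exists in this package's R dependency footprint, so the
four serializations (Turtle, RDF/XML, N-Triples, JSON-LD) and their
parsers are implemented natively for the constrained profile the package
emits: absolute IRIs, no blank nodes, plain or XSD-typed literals, no
collections. They are not general-purpose RDF parsers — Turtle read
support, for instance, covers prefix declarations, `a`, predicate-object
lists and escaped literals, which is exactly what the serializer produces
(plus the common flat triple-per-line style). Round-trip equality of the
triple set across all four formats is enforced by tests.

# Enrichment and description lines

Remote data flows through exactly one channel: an injected client function
executing SPARQL text. The query builders emit federated `SELECT` queries
with a `SERVICE` clause against a configurable UniProt endpoint, keyed on
the accession (or PDB id) through a `VALUES` clause whose literal is
escape-safe. The concrete UniProt predicate paths are a configurable
mapping (`uniprotPredicateMap()`), not hard-coded, because endpoint
vocabularies drift. Tests never contact the network: `fixtureEndpointClient()`
answers from canned tables, including simulated transport failures —
failures degrade gracefully per accession, mirroring the reality that
federated queries fail when any participating endpoint does.

When one key maps to several UniProtKB entries (typical for a PDB structure
shared by close homologs), the record with the strongest protein-existence
evidence is selected — PE code 1 ("evidence at protein level") is the
strongest, so we sort ascending, missing codes last, ties by accession —
and *all* other candidates are surfaced in `ambiguousMatches`, since the
final call belongs to the domain expert. Retrieved associations are
persisted into the local graph as `hasAssociationWithProtein` triples
(insert-on-arrival, so later queries need not re-federate); the richer
protein fields live on the `ProteinRecord` objects because the vocabulary
registers no data properties for them beyond the accession.

Description lines follow the two public conventions:
`>db|UniqueIdentifier|EntryName ProteinName OS=... GN=... PE=N` (unknown
modifiers such as `OX=`/`SV=` are retained verbatim on parse) and
`>accession description [organism]`. Absent optional fields omit their
token entirely; generation followed by dialect parsing is the identity on
every populated field. One edge is worth noting: the mandatory
`db|id|entry` triplet cannot express a missing entry name, which we render
as `UNKNOWN` rather than emit a malformed header.

# The synthetic generator

`generateAlignment()` emulates the *shape* of curated reference alignments:
a controllable fraction of totally conserved columns (exactly
`round(conservation × nColumns)` of them, enforced constructively), a
per-cell gap probability in the remaining columns, guaranteed absence of
all-gap columns, and features with valid coordinates. It does **not**
simulate an evolutionary substitution/indel process, phylogenetic
correlation between sequences, or realistic residue composition — so
passing round-trip and scoring tests demonstrates representational and
arithmetic correctness, not biological realism of the fixtures.

Defaults are chosen once to resemble a small curated reference family:
4 sequences × 60 columns (the scale of the smallest benchmark families),
conservation 0.3, gap rate 0.1, one feature. The generator draws from its
own RNG stream and restores the global `.Random.seed`, so the same spec and
seed give byte-identical MACSIM XML regardless of surrounding code. Test
suites run it at reduced sizes (typically 3 sequences × 8 columns over 20
seeds for the representation round-trips) — enough to exercise every mapped
field and both gap/conservation regimes while keeping the suite fast; the
sizes are the package's choice of test scale, with the structural
guarantees independent of them.

# Degenerate inputs and numerical choices

* Consensus ties break lexicographically among the tied characters
  (deterministic); an all-gap column's consensus is the gap character.
* The gap alphabet is `{-, .}`; a file mixing both is rejected rather than
  silently normalized, and a gapless alignment defaults to `-`.
* Residues are uppercased on parse for deterministic comparisons; gap
  symbols are preserved.
* MACSIM elements outside the mapped set travel in a pass-through bag and
  are re-emitted verbatim, so richer files survive read/write cycles.
* An empty column string, an empty score list, and an alignment with no
  columns are errors at the scoring layer (there is nothing meaningful to
  average); the validator, by contrast, never throws.

# Known limitations

* The RDF layer reads the profile it writes; arbitrary third-party RDF
  (blank nodes, collections, reification) is out of scope.
* The schema registry models the explicitly named fragment of the
  vocabulary, not the full published axiom inventory.
* Alignment *computation* is out of scope — the package describes,
  validates and enriches alignments, it does not produce them.
* 3D structural annotation is excluded from the model, matching the
  vocabulary's own scope.
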