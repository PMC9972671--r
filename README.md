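# salonr

Sequence alignments are usually exchanged as loosely specified text formats
(MACSIM XML, FASTA with ad-hoc description lines), which makes it hard to
link an alignment to the wealth of public knowledge about its sequences, or
to check mechanically that the alignment's quality scores even make sense.
`salonr` addresses this for bioinformaticians who work with pairwise and
multiple sequence alignments: it represents alignments under the SALON
vocabulary (<https://w3id.org/salon>), a formal OWL schema for alignments,
sub-alignments, sequences, columns, features, scores and construction
methods, and builds validation, scoring, semantic enrichment and FASTA
header standardization on top of that representation.

## What it does

* **Typed alignment model** — S4 classes (`Alignment`, `SubAlignment`,
  `AlignmentSequence`, `AlignmentColumn`, `Feature`, `Score`,
  `ScoreFunction`, `ReliabilityMeasure`, ...) with validity checks, plus a
  queryable schema registry of the SALON classes, its 14 object properties
  (4 inverse pairs), data properties and cardinality rules.
* **I/O** — MACSIM XML (BAliBASE dialect) and FASTA with UniProtKB/NCBI
  description-line dialects, both lossless round-trips.
* **RDF mapping** — deterministic IRI minting
  (`salon:BB11001_1aab_` pattern), forward *and* inverse property
  materialization, typed literals, and four serializations (Turtle,
  RDF/XML, N-Triples, JSON-LD) that parse back to identical triple sets;
  plus a SPARQL `INSERT DATA` export for repository population.
* **Scoring** — column score functions with declared bounds:

  * percent totally-conserved columns and percent non-gaps: a column scores
    `s_j ∈ {0, 1}`, the alignment scores `100 · Σ s_j / n ∈ [0, 100]`;
  * column entropy `H_j = −Σ_a p_a log2 p_a` over the non-gap residue
    frequencies, so `H_j ∈ [0, log2 20] = [0, 4.322]` bits for proteins,
    with the alignment-level score `Σ_j H_j`.
* **Validation** — native implementation of the correctness rules: a score
  `v` under a function with bounds `[min, max]` is incorrect iff `v > max`
  or `v < min` (four rules, alignment- and column-level, bounds inclusive),
  cardinality rules (an alignment has ≥ 1 sub-alignment, a sub-alignment
  ≥ 2 sequences), and unreliable-column flagging against a reliability
  measure cutoff (e.g. GUIDANCE confidences). Equivalent SWRL rule texts
  are exported for users running an OWL reasoner.
* **Enrichment and headers** — federated SPARQL query builders against the
  UniProtKB endpoint (injected client; fully offline in tests), protein
  association triples merged into the graph, ambiguous PDB→UniProtKB
  mappings surfaced for expert review, and `>db|ID|Entry Name OS=... GN=...
  PE=N` / `>accession description [organism]` description-line generation.
* **Synthetic fixtures** — a seeded BAliBASE-style alignment generator with
  controllable conservation, gap rate and features.

## Worked example

```r
library(salonr)

aln <- generateAlignment(nSequences = 4, nColumns = 20, conservation = 0.4,
                         gapRate = 0.1, seed = 42)
aln
#> Alignment 'SYN42': 1 sub-alignment(s), 4 sequence(s), 0 alignment score(s)

scoreAlignment(aln, "percent_totally_conserved")$alignmentScore@value
#> [1] 40
```

40 means 8 of the 20 columns are totally conserved — exactly the
`conservation = 0.4` the generator was asked for.

```r
round(scoreAlignment(aln, "entropy")$alignmentScore@value, 3)
#> [1] 19.343
```

19.343 bits summed over 20 columns: the 8 conserved columns contribute 0
each, the 12 variable columns average ~1.6 bits against a 2-bit maximum for
4 sequences.

```r
validateAlignment(aln)
#> ValidationReport: verdict correct with 0 violation(s); 0 unreliable column(s)

toRdf(aln)
#> TripleGraph: 162 triple(s), base < https://w3id.org/salon# >
```

The graph serializes to any of the four RDF formats and reconstructs the
identical model:

```r
cat(substr(serializeRdf(toRdf(aln), "turtle"), 1, 210))
#> @prefix salon: <https://w3id.org/salon#> .
#> @prefix xsd: <http://www.w3.org/2001/XMLSchema#> .
#> @prefix rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#> .
#>
#> salon:SYN42 a salon:Alignment ;
#>     salon:hasSubAlignment salon:SYN42_SYN42 ;
```

A command-line interface wrapping the same functions is installed as
`inst/scripts/salon` (subcommands `fixture`, `convert`, `score`,
`validate`, `enrich`, `header`; exit code 0 = correct/success,
1 = validation incorrect, 2 = usage/IO error):

```sh
Rscript inst/scripts/salon fixture --seqs 4 --cols 20 --seed 1 --out f.xml
Rscript inst/scripts/salon convert --in f.xml --format turtle --out f.ttl
Rscript inst/scripts/salon validate --in f.ttl --report json
```

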