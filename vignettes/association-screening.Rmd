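---
title: "Association-network screening and the built-in phylogenetics pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Association-network screening and the built-in phylogenetics pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(assocnet)
```

## The model

`assocnet` screens a sequence collection by the structure of its
*collective* BLASTN results rather than by per-query hit ranks. The
underlying object is a bipartite graph: one node per supplied query, one
node per database subject that any query hit, and one edge per (query,
subject) pair. The association count of a subject is its number of
distinct query neighbors. The working assumption is biological: a
database sequence recovered independently by several members of a
collection is more likely to be genuinely related to the collection than
a sequence that appears once with a high score — rank in any single hit
list is a noisy signal of relatedness because substitution rates vary
and similarity is not monophyly.

Three modelling decisions shape the graph:

* **One edge per pair.** BLAST may report several HSPs for one
  (query, subject) pair; an association is treated as atomic evidence,
  so HSPs collapse to the single best one (highest bit score, then
  lowest e-value, then longest alignment, then input order). Nothing in
  the association definition uses rank numerically; rank is stored only
  as an edge attribute and as an optional gate.
* **Gates precede counting.** Per-edge evidence gates (maximum e-value,
  minimum bit score, minimum percent identity, maximum rank) combine
  conjunctively and are applied when the network is built, so an
  association below the evidence threshold never contributes to a
  count. The pre-gate network is available by building with an empty
  gate. Whether counting should happen before or after thresholding was
  a genuinely open choice; counting gated evidence is the one that makes
  "associated with at least *m* supplied sequences" mean *credibly*
  associated.
* **Self hits are set aside.** A subject whose id equals any supplied
  query id is stored as a self edge and excluded from counts by default
  (`count_self = TRUE` reverses this). Queries trivially recovering
  themselves, or each other, would otherwise inflate every count in
  collections that are already in the searched database.

## Screening semantics

`screening_criteria()` has four parts: the minimum association count
`min_associations` (default **2** — the smallest count that is a
multi-association signal; 1 reduces to plain BLAST screening), the edge
gate, and explicit `include_ids` / `exclude_ids` toggles. A hit is
retained iff it clears the threshold and is not excluded, or is
explicitly included; include and exclude overlap is an error, never a
silent precedence. Dropped hits carry a single reason with fixed
precedence `excluded → gated → below_min_associations`, so reports are
deterministic. Force-inclusion of hits below the threshold is supported
deliberately: the report is a working document, and an investigator may
know a sequence matters for reasons the counts cannot see.

The in-memory report carries a creation timestamp, but the serialized
report document omits it: the package guarantees that re-screening with
a report's stored criteria reproduces the document byte-for-byte, and a
volatile timestamp inside the artifact would break exactly the
reproducibility the provenance system promises.

Sequence selection always carries the collection's queries (minus
explicit excludes) plus one record per retained hit. Hit residues come
from a subject FASTA when one is available; otherwise they are
reconstructed from the stored HSP subject rows of XML input (longest
aligned segment, gaps stripped, reverse-complemented on the minus
strand) and flagged as *partial*, because an HSP covers only the aligned
region. Partial reconstructions are adequate for exploratory trees but
are not full-length records, and the flag propagates so downstream users
can tell the difference.

## Built-in alignment and tree inference

The built-ins exist so the full pipeline runs with no external binaries;
they are classical algorithms with fixed tie-breaks, not replacements
for a production aligner or a likelihood tree program. The adapter
surface (FASTA in / equal-length FASTA-or-PHYLIP out for aligners,
PHYLIP in / Newick out for tree programs) is how ClustalW, the PHYLIP
suite or PhyML plug in; which of their methods to expose is left to the
adapter, and whatever is run is recorded in provenance.

* **Pairwise alignment** is Needleman–Wunsch with linear gap penalties,
  defaults match +1 / mismatch −1 / gap −2 — simple, documented,
  overridable. Traceback ties resolve diagonal > up > left at every
  cell, chosen at fill time, so the alignment is unique. The kernel is
  in C++ (Rcpp) as alignment kernels in this field invariably are.
* **Multiple alignment** is center-star: the center maximizes total
  pairwise score (ties: lexicographically first id), every other
  sequence aligns to the center, and gaps merge under "once a gap,
  always a gap". Every row de-gaps back to its input sequence exactly —
  that invariant is property-tested.
* **Distances** are p-distances over comparable sites (both rows in
  `{A,C,G,T,U}`; gaps and ambiguity codes are skipped; zero comparable
  sites is an error, not a zero), optionally Jukes–Cantor corrected.
  The correction diverges at `p = 3/4`; saturated pairs error rather
  than returning an arbitrary large value.
* **Neighbor joining** follows Saitou–Nei with the Studier–Keppler `Q`
  criterion. Branch lengths use the standard formulas; negative branch
  lengths are *kept* by default because they preserve additivity (NJ on
  an additive matrix then reproduces path lengths to machine precision,
  tested at 1e-9), with `clamp_negative = TRUE` for presentation. `Q`
  ties resolve by the lexicographically smallest pair of cluster ids,
  where a merged cluster is identified by its smallest member leaf id —
  a deterministic NJ needs some identity for internal clusters and this
  is the simplest order-free choice. Children print smaller id
  first, so permuting or relabeling the input matrix cannot change the
  serialized tree. Two taxa split their distance evenly; the final
  three clusters join on a trifurcating node (the output is unrooted).

## Formats

FASTA (60-column), a minimal read-only GenBank flat-file subset (LOCUS /
DEFINITION / ACCESSION / ORIGIN; feature tables ignored — the pipeline
needs identity and residues only), and a raw format. "Raw" is
deliberately minimal: one sequence per non-empty line, whitespace
stripped, ids auto-assigned `raw_1, raw_2, …` — the simplest
deterministic reading of an underspecified import format. Residues are
uppercased at ingest and `U` is preserved rather than converted to `T`,
keeping import lossless.

BLAST results load from NCBI XML or 12-column tabular reports. Subject
identity is the verbatim `sseqid` / `Hit_accession` string (falling back
to `Hit_id`): version-stripping or other normalization would silently
merge distinct records, so it is left to the caller. Tabular input
carries no subject descriptions or aligned segments; XML carries both,
and networks built from the two formats of the same run are identical on
all shared fields.

PHYLIP output is sequential, relaxed-names by default (modern programs
accept long names, and strict 10-character truncation destroys accession
information); strict mode is available and refuses name collisions
rather than silently merging rows. Newick serialization sanitizes labels
containing metacharacters via a returned map. GraphML, edge-list TSV and
JSON report documents are canonically sorted (hits by descending
association count then id; edges by query then rank) so equal networks
serialize to identical bytes.

## Pipeline, queue and provenance

A workspace is a plain directory (`collections/`, `blast/`, `networks/`,
`reports/`, `alignments/`, `trees/`, `provenance/`, `queue/`). The job
queue is a single JSON state file written atomically (temp file + rename);
jobs move `queued → running → done|failed`, a failure stores its message
and touches nothing else, and reopening the workspace after a process
restart loses nothing. One worker runs at a time; the contract is
specified rather than any concurrency mechanism. A `full` job executes
the staged pipeline directly inside the job rather than enqueueing one
sub-job per stage: the stages share in-memory state (the selected
sequence set has no standalone stage), and a single job keeps the
failure unit equal to the run.

`run_pipeline()` resolves every defaulted parameter *before* running, so
the provenance record lists each parameter actually used, with artifact
checksums and tool versions. Replaying a record re-runs the resolved
config and verifies the checksums; all built-in stages are deterministic
(no timestamps inside artifacts), so replay is byte-exact. Fan-out is
many-to-one in both places the wizard allows it: several alignment
parameter sets against one screening report, several tree parameter sets
against one alignment.

## The synthetic fixture generator

`generate_fixture()` is the test bed: it plants an incidence matrix
(explicit, or sampled at a given density with every subject guaranteed
at least one query), derives all sequences from one random ancestor by
per-site substitution (default length 200, substitution rate 0.05 —
desk-scale stand-ins for partial 16S reads at typical within-genus
divergence), and emits one tabular row per planted pair plus an XML
mirror of the same rows. Percent identity is the *realized* positionwise
identity; `bit_score = 2 ×` identical sites; `evalue = 10^(−bit/10)`, a
documented monotone stand-in — consumers only depend on ordering and
gate behavior, not on Karlin–Altschul statistics. Ranks are assigned per
query by descending bit score. Everything is a pure function of the
seed.

What the generator does *not* emulate: local alignments (every hit spans
the full sequence, so HSP coordinates are trivial), indels, chimeras,
multi-HSP hits, rank noise from database composition, or realistic
e-value magnitudes. Tests passing on these fixtures therefore
demonstrate the bookkeeping — counting, gating, screening, format
round-trips, tree recovery — not robustness to messy real alignments.
With the default length 200, tabular percent identities are exact
multiples of 0.5 and survive 3-decimal formatting exactly, which is what
makes XML/tabular network parity byte-exact.

## Numerical and testing choices

* NJ input must be symmetric within 1e-8 with a zero diagonal; additive
  recovery is asserted to 1e-9 (observed error is ~1e-14).
* Branch lengths serialize with 12 significant digits; exports print
  numbers with `%.15g`, enough to round-trip doubles.
* Degenerate inputs error loudly: empty sequences, single-taxon
  matrices, saturated distances, zero comparable sites, include/exclude
  overlap, strict-PHYLIP name collisions.
* Test problem sizes: random fixtures up to 50 queries × 200 subjects
  for the counting oracle, 100 randomized monotonicity trials per
  property, 50 random trees of 4–20 leaves for NJ, 100 instances per
  format round-trip. These sizes exercise every code path at desk scale;
  the methods themselves are O(n²)–O(n³) and are not intended for
  thousand-taxon matrices.

## Limitations

Center-star alignment is a desk-scale fallback; its alignments are
usable for distance trees of closely related sequences but inferior to
progressive or iterative aligners on divergent sets. The built-in tree
method is distance NJ only — likelihood, parsimony and bootstrap belong
to external tools. GenBank support is read-only and minimal. Live BLAST
execution is out of scope by design: the package consumes report files,
and an adapter that runs `blastn` must simply produce files these
parsers accept.
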