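# assocnet

Association networks from collective BLASTN results, for screening
sequence collections before phylogenetic analysis.

## The problem

Environmental surveys (16S rRNA gene libraries and the like) routinely
screen their sequences by BLASTN and keep each query's top hits. But the
top-ranked hit is not always the most closely related phylotype, and
throwing *every* hit of every query into one multiple alignment makes the
alignment poor, the computation expensive, and the resulting tree hard to
read. `assocnet` takes the middle road: it looks at the **collective**
BLASTN results of a whole collection. If queries *A*, *B* and *C* each
return database sequence *a* as a hit — at whatever rank — then *a* is
*associated* with all three, and its **association count** is 3. Hits
associated with many supplied sequences are strong candidates for a
phylogenetically meaningful tree even when they rank low in any single
hit list.

Formally, the package builds a bipartite graph `G = (Q ∪ H, E)` between
query nodes `Q` and hit nodes `H`, with one edge per (query, subject)
pair carrying the best BLAST evidence for that pair (bit score `S`,
e-value `E`, percent identity, rank). For a hit `h`, the association
count is `deg(h)` over distinct query neighbors, self hits excluded.
Per-edge gates (`E ≤ E_max`, `S ≥ S_min`, identity ≥ threshold, rank ≤
limit) are applied conjunctively before counting, and the screening
filter retains `h` iff `deg(h) ≥ m` (default `m = 2`), subject to
explicit per-sequence include/exclude toggles.

Downstream of screening the package carries the selected sequences
through the classic distance pipeline with built-in, dependency-free
fallbacks: Needleman–Wunsch pairwise alignment (linear gap penalties,
deterministic traceback), center-star multiple alignment, p-distance with
optional Jukes–Cantor correction `d = −(3/4)·ln(1 − 4p/3)`, and
Saitou–Nei neighbor joining minimizing
`Q(i,j) = (n−2)·d(i,j) − R_i − R_j`, which recovers additive distance
matrices exactly. Alignments export as sequential PHYLIP (relaxed or
strict names), trees as Newick and minimal SVG, networks as GraphML /
TSV / JSON. Production-scale alignments and likelihood trees are meant
to come from dedicated tools (ClustalW, the PHYLIP suite, PhyML) through
the file formats above; the built-ins keep the whole pipeline runnable
and testable at desk scale.

Runs are orchestrated through a file-backed workspace with a persistent
FIFO job queue and a permanent provenance record of every stage's
parameters (defaults included) and artifact checksums, so any run can be
replayed byte-for-byte.

## Worked example

A synthetic fixture stands in for a small survey: 5 queries, 30 database
subjects, planted association structure, all descended from one ancestor
so percent identities are realistic and known.

```r
library(assocnet)
spec   <- fixture_spec(n_queries = 5, n_subjects = 30, density = 0.2, seed = 42)
bundle <- generate_fixture(spec)

results <- parse_blast_tabular(text = bundle$blast_tab)
net     <- build_network(results, gate = edge_gate(max_evalue = 1e-10))
net
#> <assoc_network> 5 query node(s), 30 hit node(s), 37 edge(s), 0 self edge(s)

head(association_counts(net))
#> s015 s005 s016 s018 s029 s030
#>    3    2    2    2    2    2

report <- apply_screening(net, screening_criteria(min_associations = 2))
report
#> <screening_report> min_associations=2: 6 retained, 24 dropped
report$retained[, c("subject_id", "association_count")]
#>   subject_id association_count
#> 1       s015                 3
#> 2       s005                 2
#> ...
```

Subject `s015` was recovered by three different queries — exactly the
multi-association signal the screening is after — while 24 singleton
hits are dropped. The retained hits then flow on to alignment and tree
inference:

```r
coll <- create_collection("survey", bundle$queries)
seqs <- select_sequences(report, coll, subject_db = bundle$subjects)
seqs
#> <sequence_set> 11 member(s): 5 query, 6 hit (0 partial)
aln  <- star_align(seqs)
tree <- neighbor_joining(distance_matrix(aln, model = "jc69"))
cat(write_newick(tree))
#> (((q001:0.0438997585676,q004:0.0928414090278):...);
```

The same flow runs end to end, with provenance, from a config:

```r
ws  <- workspace("my_run")
rec <- run_pipeline(ws, read_pipeline_config("config.yaml"))
```

or from the shell via the thin CLI in `inst/cli/assocnet`
(`assocnet fixture | import | network | screen | run | queue ...`).

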