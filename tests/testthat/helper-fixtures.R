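# Shared test fixtures and independent oracles.

# The motivating association example: queries A, B and C each return
# subject "a" as a hit, at differing ranks (A also hits x, B also hits x
# and y), so a's association count is 3.
abc_tabular <- function() {
  paste(
    "A\ta\t98.000\t100\t2\t0\t1\t100\t1\t100\t1e-50\t180",
    "A\tx\t90.000\t100\t10\t0\t1\t100\t1\t100\t1e-30\t120",
    "B\tx\t95.000\t100\t5\t0\t1\t100\t1\t100\t1e-40\t150",
    "B\ta\t94.000\t100\t6\t0\t1\t100\t1\t100\t1e-38\t140",
    "B\ty\t91.000\t100\t9\t0\t1\t100\t1\t100\t1e-31\t121",
    "C\ty\t97.000\t100\t3\t0\t1\t100\t1\t100\t1e-45\t170",
    "C\tx\t96.000\t100\t4\t0\t1\t100\t1\t100\t1e-42\t160",
    "C\ta\t92.000\t100\t8\t0\t1\t100\t1\t100\t1e-33\t130",
    sep = "\n")
}

abc_network <- function(gate = edge_gate()) {
  build_network(parse_blast_tabular(text = abc_tabular()), gate = gate)
}

# Minimal hand-built BLAST XML (one iteration per element of `hits`, each a
# list of lists with subject/bit/evalue/ident/alen/sseq/sfrom/sto fields).
blast_xml_text <- function(queries) {
  iters <- vapply(seq_along(queries), function(qi) {
    q <- queries[[qi]]
    hits <- vapply(seq_along(q$hits), function(hi) {
      h <- q$hits[[hi]]
      hsps <- vapply(h$hsps, function(hsp) {
        paste0("<Hsp><Hsp_num>1</Hsp_num>",
               "<Hsp_bit-score>", hsp$bit, "</Hsp_bit-score>",
               "<Hsp_evalue>", hsp$evalue, "</Hsp_evalue>",
               "<Hsp_query-from>1</Hsp_query-from>",
               "<Hsp_query-to>", hsp$alen, "</Hsp_query-to>",
               "<Hsp_hit-from>", hsp$sfrom %||NA% 1, "</Hsp_hit-from>",
               "<Hsp_hit-to>", hsp$sto %||NA% hsp$alen, "</Hsp_hit-to>",
               "<Hsp_identity>", hsp$ident, "</Hsp_identity>",
               "<Hsp_align-len>", hsp$alen, "</Hsp_align-len>",
               if (!is.null(hsp$sseq)) paste0("<Hsp_hseq>", hsp$sseq, "</Hsp_hseq>") else "",
               "</Hsp>")
      }, character(1))
      paste0("<Hit><Hit_num>", hi, "</Hit_num>",
             "<Hit_id>gnl|", h$subject, "</Hit_id>",
             "<Hit_def>", if (is.null(h$def)) "" else h$def, "</Hit_def>",
             "<Hit_accession>", h$subject, "</Hit_accession>",
             "<Hit_len>", 100, "</Hit_len><Hit_hsps>",
             paste(hsps, collapse = ""), "</Hit_hsps></Hit>")
    }, character(1))
    paste0("<Iteration><Iteration_iter-num>", qi, "</Iteration_iter-num>",
           "<Iteration_query-def>", q$query, "</Iteration_query-def>",
           "<Iteration_hits>", paste(hits, collapse = ""),
           "</Iteration_hits></Iteration>")
  }, character(1))
  paste0('<?xml version="1.0"?><BlastOutput>',
         "<BlastOutput_program>blastn</BlastOutput_program>",
         "<BlastOutput_iterations>", paste(iters, collapse = ""),
         "</BlastOutput_iterations></BlastOutput>")
}

`%||NA%` <- function(a, b) if (is.null(a)) b else a

# Exhaustive-enumeration oracle for global alignment score: recursively
# tries all three moves at every position (no DP sharing), so it is
# independent of the implementation under test. Only usable for short
# sequences.
bf_nw_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    best <- -Inf
    if (i > 0 && j > 0) {
      s <- if (substr(a, i, i) == substr(b, j, j)) match else mismatch
      best <- max(best, rec(i - 1, j - 1) + s)
    }
    if (i > 0) best <- max(best, rec(i - 1, j) + gap)
    if (j > 0) best <- max(best, rec(i, j - 1) + gap)
    best
  }
  rec(nchar(a), nchar(b))
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# Random binary tree with branch lengths; its cophenetic matrix is additive
# by construction and serves as the NJ ground truth.
rand_additive <- function(n_leaves, min_bl = 0.05, max_bl = 1.0) {
  tr <- ape::rtree(n_leaves, br = NULL)
  tr$edge.length <- stats::runif(nrow(tr$edge), min_bl, max_bl)
  tr$tip.label <- sprintf("t%02d", seq_len(n_leaves))
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}

expect_score_of_alignment <- function(res, match = 1, mismatch = -1, gap = -2) {
  a <- strsplit(res$a, "")[[1]]; b <- strsplit(res$b, "")[[1]]
  s <- sum(ifelse(a == "-" | b == "-", gap, ifelse(a == b, match, mismatch)))
  expect_equal(s, res$score)
}
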