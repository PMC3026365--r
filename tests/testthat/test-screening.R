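test_that("the minimum-association threshold retains and drops correctly", {
  net <- abc_network()
  # subject a is associated with all three queries
  r3 <- apply_screening(net, screening_criteria(min_associations = 3))
  expect_true("a" %in% r3$retained$subject_id)
  r4 <- apply_screening(net, screening_criteria(min_associations = 4))
  expect_true("a" %in% r4$dropped$subject_id)
  expect_equal(r4$dropped$reason[r4$dropped$subject_id == "a"],
               "below_min_associations")
  for (m in 1:3) {
    rm_ <- apply_screening(net, screening_criteria(min_associations = m))
    expect_true("a" %in% rm_$retained$subject_id)
  }
  # min 1 with no gate retains every hit
  r1 <- apply_screening(net, screening_criteria(min_associations = 1))
  expect_equal(nrow(r1$dropped), 0L)
  expect_setequal(r1$retained$subject_id, c("a", "x", "y"))
})

test_that("include/exclude toggles dominate the threshold", {
  net <- abc_network()
  # y has count 2; force it out. a has count 3; force-in is a no-op.
  crit <- screening_criteria(min_associations = 2, exclude_ids = "y")
  rep <- apply_screening(net, crit)
  expect_false("y" %in% rep$retained$subject_id)
  expect_equal(rep$dropped$reason[rep$dropped$subject_id == "y"], "excluded")
  # a hit below threshold but included is retained
  crit2 <- screening_criteria(min_associations = 3, include_ids = "y")
  rep2 <- apply_screening(net, crit2)
  expect_true("y" %in% rep2$retained$subject_id)
  expect_error(screening_criteria(include_ids = "a", exclude_ids = "a"),
               "both include and exclude.*a")
})

test_that("a hit losing all edges to the gate is dropped as gated", {
  net <- abc_network()
  # only the A->a edge (bit 180) survives a 175 bound: x and y lose all
  # evidence and are gated, a stays with count 1
  crit <- screening_criteria(min_associations = 1,
                             gate = edge_gate(min_bit_score = 175))
  rep <- apply_screening(net, crit)
  expect_equal(rep$retained$subject_id, "a")
  expect_equal(rep$retained$association_count, 1L)
  expect_setequal(rep$dropped$subject_id, c("x", "y"))
  expect_true(all(rep$dropped$reason == "gated"))
  # exclusion outranks the gated reason
  crit2 <- screening_criteria(min_associations = 1,
                              gate = edge_gate(min_bit_score = 1e6),
                              exclude_ids = "a")
  rep2 <- apply_screening(net, crit2)
  expect_equal(rep2$dropped$reason[rep2$dropped$subject_id == "a"], "excluded")
  expect_true(all(rep2$dropped$reason[rep2$dropped$subject_id != "a"] == "gated"))
})

test_that("retained and dropped partition the hit nodes", {
  for (seed in c(21, 22)) {
    b <- generate_fixture(fixture_spec(8, 30, density = 0.3, seed = seed))
    net <- build_network(parse_blast_tabular(text = b$blast_tab))
    for (m in c(1, 2, 4)) {
      rep <- apply_screening(net, screening_criteria(min_associations = m))
      ids <- c(rep$retained$subject_id, rep$dropped$subject_id)
      expect_setequal(ids, net$hit_nodes$id)
      expect_equal(length(ids), nrow(net$hit_nodes))
    }
  }
})

test_that("raising the threshold only shrinks the retained set", {
  for (seed in c(31, 32, 33)) {
    b <- generate_fixture(fixture_spec(10, 40, density = 0.25, seed = seed))
    net <- build_network(parse_blast_tabular(text = b$blast_tab))
    prev <- NULL
    for (m in 1:6) {
      cur <- apply_screening(net, screening_criteria(min_associations = m))
      cur_ids <- cur$retained$subject_id
      if (!is.null(prev)) expect_true(all(cur_ids %in% prev))
      prev <- cur_ids
    }
  }
})

test_that("re-screening with a report's stored criteria is byte-identical", {
  net <- abc_network()
  crit <- screening_criteria(min_associations = 2,
                             gate = edge_gate(max_evalue = 1e-30),
                             exclude_ids = "x")
  rep1 <- apply_screening(net, crit)
  rep2 <- apply_screening(net, rep1$criteria)
  expect_identical(as.character(write_screening_report(rep1)),
                   as.character(write_screening_report(rep2)))
  expect_identical(as.character(write_screening_tsv(rep1)),
                   as.character(write_screening_tsv(rep2)))
})

test_that("sequence selection combines queries and resolvable hits", {
  coll <- create_collection("abc", read_fasta(
    text = ">A\nACGTACGT\n>B\nACGTTCGT\n>C\nACGAACGT\n"))
  db <- read_fasta(text = ">a\nACGTACGA\n>x\nACCTACGT\n>y\nACGTACCT\n")
  net <- abc_network()
  rep <- apply_screening(net, screening_criteria(min_associations = 3))
  ss <- select_sequences(rep, coll, subject_db = db)
  expect_equal(nrow(ss$members), 5L)  # 3 queries + hits a, x
  expect_equal(unname(ss$origin[c("A", "a")]), c("query", "hit"))
  # no retained hits -> queries only
  rep9 <- apply_screening(net, screening_criteria(min_associations = 9))
  ss9 <- select_sequences(rep9, coll, subject_db = db)
  expect_equal(ss9$members$id, c("A", "B", "C"))
  # missing source for a retained hit
  expect_error(select_sequences(rep, coll, subject_db = db[db$id != "a", ]),
               "no sequence source.*a")
})

test_that("hit sequences reconstruct from HSP segments", {
  ev <- parse_blast_xml(text = blast_xml_text(list(
    list(query = "q1", hits = list(
      list(subject = "s1", hsps = list(
        list(bit = 90, evalue = "1e-30", ident = 4, alen = 5,
             sseq = "AC-GT"))))))))[[1]]$hits
  ev$query_id <- "q1"
  rec <- reconstruct_hit_sequence(ev)
  expect_equal(rec$residues, "ACGT")
  expect_true(rec$partial)

  # minus strand: reverse complement after gap stripping
  evm <- ev; evm$strand <- "minus"; evm$subject_aligned_segment <- "AACG"
  expect_equal(reconstruct_hit_sequence(evm)$residues, "CGTT")

  # the longest aligned segment wins
  ev2 <- rbind(ev, ev)
  ev2$align_length <- c(80L, 120L)
  ev2$subject_aligned_segment <- c("AAAA", "CCCC")
  expect_equal(reconstruct_hit_sequence(ev2)$residues, "CCCC")

  evna <- ev; evna$subject_aligned_segment <- NA_character_
  expect_error(reconstruct_hit_sequence(evna), "cannot reconstruct")
})

test_that("selection falls back to reconstruction from the network", {
  b <- generate_fixture(fixture_spec(3, 6, density = 0.6, seed = 44))
  res <- parse_blast_xml(text = b$blast_xml)
  net <- build_network(res)
  coll <- create_collection("fx", b$queries)
  rep <- apply_screening(net, screening_criteria(min_associations = 1))
  ss <- select_sequences(rep, coll, subject_db = NULL, net = net)
  expect_setequal(ss$partial_ids, rep$retained$subject_id)
  # reconstructed residues match the planted subject sequences (plus strand,
  # ungapped segments cover the full subject)
  for (h in ss$partial_ids) {
    expect_equal(ss$members$residues[ss$members$id == h],
                 b$subjects$residues[b$subjects$id == h])
  }
})
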