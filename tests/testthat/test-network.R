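test_that("a hit listed by three queries has association count 3", {
  net <- abc_network()
  expect_equal(association_counts(net)[["a"]], 3L)
  expect_equal(sort(neighbors(net, "a")$neighbor), c("A", "B", "C"))
  expect_equal(sort(neighbors(net, "A")$neighbor), c("a", "x"))
  expect_error(neighbors(net, "zzz"), "unknown node id 'zzz'")
})

test_that("an empty result list builds an empty network", {
  net <- build_network(list())
  expect_equal(length(net$query_nodes), 0L)
  expect_equal(nrow(net$hit_nodes), 0L)
  expect_equal(nrow(net$edges), 0L)
  # empty exports are still well-formed documents
  expect_silent(xml2::read_xml(as.character(export_graphml(net))))
  expect_match(as.character(export_edge_list(net)), "^query\tsubject")
  expect_silent(jsonlite::fromJSON(as.character(export_report_doc(net))))
})

test_that("gate bounds drop edges conjunctively", {
  tab <- paste0("q1\ts1\t99\t100\t1\t0\t1\t100\t1\t100\t1e-20\t120\n",
                "q1\ts2\t88\t100\t12\t0\t1\t100\t1\t100\t1e-5\t60\n")
  res <- parse_blast_tabular(text = tab)
  net <- build_network(res, gate = edge_gate(max_evalue = 1e-10))
  expect_equal(net$edges$subject_id, "s1")
  # conjunctive: identity bound additionally removes s1
  net2 <- build_network(res, gate = edge_gate(max_evalue = 1e-10,
                                              min_percent_identity = 99.5))
  expect_equal(nrow(net2$edges), 0L)
  # rank gate
  net3 <- build_network(res, gate = edge_gate(max_rank = 1))
  expect_equal(net3$edges$subject_id, "s1")
  expect_error(edge_gate(max_rank = 0), "max_rank")
  expect_error(edge_gate(min_percent_identity = 150), "0, 100")
})

test_that("tightening any single gate bound never adds an edge", {
  set.seed(101)
  for (trial in 1:25) {
    b <- generate_fixture(fixture_spec(6, 25, density = 0.3,
                                       seed = 1000 + trial))
    res <- parse_blast_tabular(text = b$blast_tab)
    all_ev <- do.call(rbind, lapply(res, function(r) r$hits))
    gate0 <- edge_gate(
      max_evalue = stats::quantile(all_ev$evalue, runif(1, 0.3, 1)),
      min_bit_score = stats::quantile(all_ev$bit_score, runif(1, 0, 0.7)),
      min_percent_identity = stats::quantile(all_ev$percent_identity,
                                             runif(1, 0, 0.7)),
      max_rank = sample(1:10, 1))
    loose <- build_network(res, gate = gate0)
    ekey <- function(n) paste(n$edges$query_id, n$edges$subject_id)
    tighten <- sample(c("max_evalue", "min_bit_score",
                        "min_percent_identity", "max_rank"), 1)
    g <- unclass(gate0)
    g[[tighten]] <- switch(tighten,
      max_evalue = g$max_evalue / 10,
      min_bit_score = g$min_bit_score * 1.2,
      min_percent_identity = min(100, g$min_percent_identity + 2),
      max_rank = max(1L, g$max_rank - 1L))
    tight <- build_network(res, gate = do.call(edge_gate, g))
    expect_true(all(ekey(tight) %in% ekey(loose)))
  }
})

test_that("network content is independent of result order", {
  res <- parse_blast_tabular(text = abc_tabular())
  set.seed(9)
  for (k in 1:5) {
    perm <- sample(res)
    net1 <- build_network(res); net2 <- build_network(perm)
    expect_identical(net1$edges, net2$edges)
    expect_identical(net1$hit_nodes, net2$hit_nodes)
    expect_identical(as.character(export_graphml(net1)),
                     as.character(export_graphml(net2)))
    expect_identical(as.character(export_edge_list(net1)),
                     as.character(export_edge_list(net2)))
  }
})

test_that("association counts sum to the number of non-self edges", {
  for (seed in c(3, 14, 15)) {
    b <- generate_fixture(fixture_spec(10, 40, density = 0.25, seed = seed))
    net <- build_network(parse_blast_tabular(text = b$blast_tab))
    expect_equal(sum(association_counts(net)), nrow(net$edges))
  }
})

test_that("self hits are excluded from counts unless requested", {
  tab <- paste0("q1\tq2\t99\t100\t1\t0\t1\t100\t1\t100\t1e-20\t120\n",
                "q1\ts1\t98\t100\t2\t0\t1\t100\t1\t100\t1e-18\t110\n",
                "q2\ts1\t97\t100\t3\t0\t1\t100\t1\t100\t1e-17\t100\n")
  res <- parse_blast_tabular(text = tab)
  net <- build_network(res)
  expect_equal(association_counts(net), c(s1 = 2L))
  expect_equal(nrow(net$self_edges), 1L)
  net2 <- build_network(res, count_self = TRUE)
  expect_equal(association_counts(net2)[c("q2", "s1")], c(q2 = 1L, s1 = 2L))
})

test_that("GraphML export carries partitions, counts and evidence", {
  net <- abc_network()
  txt <- as.character(export_graphml(net))
  # byte-stable re-export
  expect_identical(txt, as.character(export_graphml(abc_network())))
  gf <- withr::local_tempfile(fileext = ".graphml")
  export_graphml(net, gf)
  g <- igraph::read_graph(gf, format = "graphml")
  expect_equal(igraph::vcount(g), 6L)  # A,B,C + a,x,y
  expect_equal(igraph::ecount(g), 8L)
  va <- igraph::vertex_attr(g)
  expect_setequal(va$id[va$partition == "query"], c("A", "B", "C"))
  expect_equal(va$association_count[va$id == "a"], 3)
  # hit degrees in the graph equal association counts
  hit_deg <- igraph::degree(g)[match(c("a", "x", "y"), va$id)]
  expect_equal(unname(hit_deg),
               unname(as.numeric(association_counts(net)[c("a", "x", "y")])))
  expect_true(all(igraph::edge_attr(g, "evalue") > 0))
})

test_that("hit degrees from an independent graph library match counts", {
  b <- generate_fixture(fixture_spec(12, 50, density = 0.2, seed = 77))
  net <- build_network(parse_blast_tabular(text = b$blast_tab))
  g <- igraph::graph_from_data_frame(
    net$edges[, c("query_id", "subject_id")], directed = FALSE)
  deg <- igraph::degree(g)
  cnt <- association_counts(net)
  expect_equal(unname(deg[names(cnt)]), unname(as.numeric(cnt)))
})

test_that("duplicate query ids are rejected by name", {
  res <- parse_blast_tabular(text = abc_tabular())
  expect_error(build_network(c(res, res[1])), "duplicate query id.*A")
})

test_that("the report document mirrors the network content", {
  net <- abc_network()
  doc <- jsonlite::fromJSON(as.character(export_report_doc(net)),
                            simplifyVector = TRUE)
  expect_equal(doc$queries, c("A", "B", "C"))
  expect_equal(doc$n_edges, 8L)
  expect_equal(doc$hits$subject_id[1], "a")  # sorted by descending count
  expect_equal(doc$hits$association_count, c(3L, 3L, 2L))
})
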