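# The association network: a bipartite graph between supplied query
# sequences and their collective BLASTN hits. A hit listed by several
# queries is "associated" with each of them; its association count is the
# number of distinct queries listing it. This collective view surfaces
# sequences of phylogenetic interest even when they rank low in any single
# hit list.

#' Per-edge evidence gate
#'
#' Thresholds applied to each (query, hit) edge before association counting.
#' Bounds combine conjunctively; an absent (`NULL`) bound is no constraint.
#'
#' @param max_evalue keep edges with e-value less than or equal to this.
#' @param min_bit_score keep edges with bit score greater than or equal to this.
#' @param min_percent_identity keep edges with percent identity (0-100)
#'   greater than or equal to this.
#' @param max_rank keep edges whose hit ranked at or above (numerically at
#'   most) this position in the query's hit list.
#' @return an object of class `edge_gate`.
#' @export
edge_gate <- function(max_evalue = NULL, min_bit_score = NULL,
                      min_percent_identity = NULL, max_rank = NULL) {
  chk <- function(x, nm) {
    if (!is.null(x)) {
      if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
        stop(sprintf("gate bound '%s' must be a single finite number", nm),
             call. = FALSE)
      }
    }
    x
  }
  if (!is.null(max_rank) && (chk(max_rank, "max_rank") < 1 ||
                             max_rank != as.integer(max_rank))) {
    stop("gate bound 'max_rank' must be an integer >= 1", call. = FALSE)
  }
  if (!is.null(min_percent_identity) &&
      (chk(min_percent_identity, "min_percent_identity") < 0 ||
       min_percent_identity > 100)) {
    stop("gate bound 'min_percent_identity' must lie in [0, 100]", call. = FALSE)
  }
  structure(list(max_evalue = chk(max_evalue, "max_evalue"),
                 min_bit_score = chk(min_bit_score, "min_bit_score"),
                 min_percent_identity = min_percent_identity,
                 max_rank = if (is.null(max_rank)) NULL else as.integer(max_rank)),
            class = "edge_gate")
}

# Logical vector: which edges pass every present bound.
.gate_pass <- function(gate, edges) {
  ok <- rep(TRUE, nrow(edges))
  if (!is.null(gate$max_evalue)) ok <- ok & edges$evalue <= gate$max_evalue
  if (!is.null(gate$min_bit_score)) ok <- ok & edges$bit_score >= gate$min_bit_score
  if (!is.null(gate$min_percent_identity)) {
    ok <- ok & edges$percent_identity >= gate$min_percent_identity
  }
  if (!is.null(gate$max_rank)) ok <- ok & edges$rank <= gate$max_rank
  ok
}

#' Build the association network from collective BLAST results
#'
#' An edge (query, hit) exists iff the hit appears in that query's
#' deduplicated hit list and passes every present gate bound. Hits whose id
#' equals a query id are stored separately as self edges and excluded from
#' association counts unless `count_self = TRUE`. The network is canonically
#' sorted, so its content is independent of the order of `results`.
#'
#' @param results list of `query_result` objects (see [parse_blast_xml()],
#'   [parse_blast_tabular()]); query ids must be distinct.
#' @param gate an [edge_gate()]; the default passes everything.
#' @param count_self logical; count self hits toward association counts?
#' @return an object of class `assoc_network` with elements `query_nodes`,
#'   `hit_nodes` (id, description, association_count), `edges`,
#'   `self_edges`, `gate_applied`, `count_self`.
#' @export
build_network <- function(results, gate = edge_gate(), count_self = FALSE) {
  stopifnot(is.list(results), inherits(gate, "edge_gate"))
  qids <- vapply(results, function(r) r$query_id, character(1))
  dup <- unique(qids[duplicated(qids)])
  if (length(dup)) {
    stop(sprintf("duplicate query id(s) across results: %s",
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  edges <- do.call(rbind, c(list(cbind(query_id = character(0), .hit_df())),
                            lapply(results, function(r) {
                              if (!nrow(r$hits)) return(NULL)
                              cbind(query_id = r$query_id, r$hits,
                                    stringsAsFactors = FALSE)
                            })))
  edges <- edges[.gate_pass(gate, edges), , drop = FALSE]
  # self edge: the subject id equals some supplied query id (a query
  # recovering itself or a fellow query); these would trivially inflate
  # counts, so they are stored apart unless count_self is set.
  is_self <- edges$subject_id %in% qids
  self_edges <- edges[is_self, , drop = FALSE]
  main <- if (count_self) edges else edges[!is_self, , drop = FALSE]
  o <- order(main$query_id, main$rank)
  main <- main[o, , drop = FALSE]
  rownames(main) <- NULL
  rownames(self_edges) <- NULL
  counts <- tapply(main$query_id, main$subject_id,
                   function(q) length(unique(q)))
  hit_ids <- sort(names(counts))
  if (is.null(hit_ids)) hit_ids <- character(0)
  desc <- vapply(hit_ids, function(h) {
    d <- unique(main$subject_description[main$subject_id == h])
    d <- d[nzchar(d)]
    if (length(d)) d[1] else ""
  }, character(1), USE.NAMES = FALSE)
  hit_nodes <- data.frame(id = hit_ids, description = desc,
                          association_count = as.integer(counts[hit_ids]),
                          stringsAsFactors = FALSE)
  o2 <- order(-hit_nodes$association_count, hit_nodes$id)
  hit_nodes <- hit_nodes[o2, , drop = FALSE]
  rownames(hit_nodes) <- NULL
  structure(list(query_nodes = sort(qids), hit_nodes = hit_nodes,
                 edges = main, self_edges = self_edges,
                 gate_applied = gate, count_self = count_self),
            class = "assoc_network")
}

#' @export
print.assoc_network <- function(x, ...) {
  cat(sprintf("<assoc_network> %d query node(s), %d hit node(s), %d edge(s), %d self edge(s)\n",
              length(x$query_nodes), nrow(x$hit_nodes), nrow(x$edges),
              if (x$count_self) 0L else nrow(x$self_edges)))
  invisible(x)
}

#' Association counts of every hit node
#'
#' The association count of a hit is the number of distinct supplied queries
#' whose (gated) hit lists contain it; self edges are excluded unless the
#' network was built with `count_self = TRUE`.
#'
#' @param net an `assoc_network`.
#' @return a named integer vector, subject id to count, covering every
#'   stored hit node.
#' @export
association_counts <- function(net) {
  stopifnot(inherits(net, "assoc_network"))
  stats::setNames(net$hit_nodes$association_count, net$hit_nodes$id)
}

#' Neighbors of a network node
#'
#' For a hit node, the queries associated with it; for a query node, its
#' gated hits. Each neighbor row carries the edge evidence (rank, e-value,
#' bit score, percent identity).
#'
#' @param net an `assoc_network`.
#' @param node_id a query or hit node id of the network.
#' @return a data frame with columns `neighbor`, `rank`, `evalue`,
#'   `bit_score`, `percent_identity`.
#' @export
neighbors <- function(net, node_id) {
  stopifnot(inherits(net, "assoc_network"), .is_string(node_id))
  keep_cols <- c("rank", "evalue", "bit_score", "percent_identity")
  if (node_id %in% net$query_nodes) {
    e <- net$edges[net$edges$query_id == node_id, , drop = FALSE]
    out <- cbind(data.frame(neighbor = e$subject_id, stringsAsFactors = FALSE),
                 e[, keep_cols, drop = FALSE])
  } else if (node_id %in% net$hit_nodes$id) {
    e <- net$edges[net$edges$subject_id == node_id, , drop = FALSE]
    out <- cbind(data.frame(neighbor = e$query_id, stringsAsFactors = FALSE),
                 e[, keep_cols, drop = FALSE])
    out <- out[order(out$neighbor), , drop = FALSE]
  } else {
    stop(sprintf("unknown node id '%s'", node_id), call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

# Canonical orderings shared by all exports: hits by descending association
# count then ascending id; edges by query id then rank.
.sorted_edges <- function(net) {
  e <- net$edges[order(net$edges$query_id, net$edges$rank), , drop = FALSE]
  rownames(e) <- NULL
  e
}

#' Export the association network as GraphML
#'
#' Nodes carry a `partition` attribute (`query` or `hit`); hit nodes
#' additionally carry `description` and `association_count`; edges carry
#' `rank`, `evalue`, `bit_score`, `percent_identity`. Output is sorted
#' canonically so that re-exporting an equal network is byte-identical.
#'
#' @param net an `assoc_network`.
#' @param file path, connection, or `NULL` to return text invisibly.
#' @return the GraphML text, invisibly.
#' @export
export_graphml <- function(net, file = NULL) {
  stopifnot(inherits(net, "assoc_network"))
  l <- c('<?xml version="1.0" encoding="UTF-8"?>',
         '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
         '  <key id="partition" for="node" attr.name="partition" attr.type="string"/>',
         '  <key id="description" for="node" attr.name="description" attr.type="string"/>',
         '  <key id="association_count" for="node" attr.name="association_count" attr.type="int"/>',
         '  <key id="rank" for="edge" attr.name="rank" attr.type="int"/>',
         '  <key id="evalue" for="edge" attr.name="evalue" attr.type="double"/>',
         '  <key id="bit_score" for="edge" attr.name="bit_score" attr.type="double"/>',
         '  <key id="percent_identity" for="edge" attr.name="percent_identity" attr.type="double"/>',
         '  <graph id="association_network" edgedefault="undirected">')
  for (q in net$query_nodes) {
    l <- c(l, sprintf('    <node id="%s"><data key="partition">query</data></node>',
                      .xml_escape(q)))
  }
  hn <- net$hit_nodes
  for (k in seq_len(nrow(hn))) {
    if (hn$id[k] %in% net$query_nodes) next  # already emitted as a query node
    l <- c(l, sprintf(paste0('    <node id="%s"><data key="partition">hit</data>',
                             '<data key="description">%s</data>',
                             '<data key="association_count">%d</data></node>'),
                      .xml_escape(hn$id[k]), .xml_escape(hn$description[k]),
                      hn$association_count[k]))
  }
  e <- .sorted_edges(net)
  for (k in seq_len(nrow(e))) {
    l <- c(l, sprintf(paste0('    <edge source="%s" target="%s">',
                             '<data key="rank">%d</data>',
                             '<data key="evalue">%s</data>',
                             '<data key="bit_score">%s</data>',
                             '<data key="percent_identity">%s</data></edge>'),
                      .xml_escape(e$query_id[k]), .xml_escape(e$subject_id[k]),
                      e$rank[k], .num_chr(e$evalue[k]),
                      .num_chr(e$bit_score[k]), .num_chr(e$percent_identity[k])))
  }
  l <- c(l, '  </graph>', '</graphml>')
  .output_lines(l, file)
}

#' Export the association network as a TSV edge list
#'
#' Columns: query, subject, rank, evalue, bit_score, percent_identity;
#' sorted by query id then rank for byte-stable output.
#'
#' @inheritParams export_graphml
#' @return the TSV text, invisibly.
#' @export
export_edge_list <- function(net, file = NULL) {
  stopifnot(inherits(net, "assoc_network"))
  e <- .sorted_edges(net)
  l <- c("query\tsubject\trank\tevalue\tbit_score\tpercent_identity",
         sprintf("%s\t%s\t%d\t%s\t%s\t%s", e$query_id, e$subject_id, e$rank,
                 .num_chr(e$evalue), .num_chr(e$bit_score),
                 .num_chr(e$percent_identity)))
  .output_lines(l, file)
}

#' Export the association network as a structured report document (JSON)
#'
#' Machine-readable counterpart of the interactive screening view: every
#' hit with its description, association count and sorted query neighbors,
#' plus the gate snapshot. Deterministically sorted.
#'
#' @inheritParams export_graphml
#' @return the JSON text, invisibly.
#' @export
export_report_doc <- function(net, file = NULL) {
  stopifnot(inherits(net, "assoc_network"))
  hn <- net$hit_nodes
  hits <- lapply(seq_len(nrow(hn)), function(k) {
    nb <- sort(unique(net$edges$query_id[net$edges$subject_id == hn$id[k]]))
    list(subject_id = hn$id[k], description = hn$description[k],
         association_count = hn$association_count[k], queries = nb)
  })
  doc <- list(queries = as.list(net$query_nodes),
              gate = .gate_as_list(net$gate_applied),
              count_self = net$count_self,
              n_edges = nrow(net$edges),
              hits = hits)
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null", digits = NA,
                          pretty = TRUE)
  .output_lines(as.character(txt), file)
}

# Gate as a fully-populated named list (NULL bounds serialized as null).
.gate_as_list <- function(gate) {
  list(max_evalue = gate$max_evalue, min_bit_score = gate$min_bit_score,
       min_percent_identity = gate$min_percent_identity,
       max_rank = gate$max_rank)
}
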