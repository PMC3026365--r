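# Screening: the minimum-association filter plus per-sequence toggles that
# turn an association network into the sequence set passed to alignment.

#' Screening criteria
#'
#' A hit is retained when its association count reaches `min_associations`
#' (and it is not excluded), or when it is explicitly included. The gate is
#' applied to edges before counting.
#'
#' @param min_associations minimum number of distinct associated queries a
#'   hit must have (default 2: a hit shared by at least two supplied
#'   sequences is the motivating multi-association signal; 1 reduces to
#'   plain BLAST screening).
#' @param gate an [edge_gate()] applied before association counting.
#' @param include_ids subject ids forced into the retained set.
#' @param exclude_ids subject (or query) ids forced out.
#' @return an object of class `screening_criteria`.
#' @export
screening_criteria <- function(min_associations = 2L, gate = edge_gate(),
                               include_ids = character(),
                               exclude_ids = character()) {
  stopifnot(is.numeric(min_associations), length(min_associations) == 1L,
            min_associations >= 1, inherits(gate, "edge_gate"))
  include_ids <- as.character(include_ids)
  exclude_ids <- as.character(exclude_ids)
  both <- intersect(include_ids, exclude_ids)
  if (length(both)) {
    stop(sprintf("ids in both include and exclude: %s",
                 paste(sort(both), collapse = ", ")), call. = FALSE)
  }
  structure(list(min_associations = as.integer(min_associations), gate = gate,
                 include_ids = include_ids, exclude_ids = exclude_ids),
            class = "screening_criteria")
}

#' Apply screening criteria to an association network
#'
#' Partitions the network's hit nodes into retained and dropped sets. The
#' criteria gate is applied on top of the network's edges (conjunctively)
#' and counts are recomputed, so a network built with an empty gate can be
#' screened under any gate. A dropped hit carries the first matching reason
#' in the fixed order excluded, gated, below_min_associations.
#'
#' @param net an `assoc_network`.
#' @param criteria a [screening_criteria()].
#' @return an object of class `screening_report` with elements `criteria`,
#'   `retained`, `dropped` (data frames with `subject_id`, `description`,
#'   `association_count`, list-column `queries`, and for dropped a
#'   `reason`), and `created_at`.
#' @export
apply_screening <- function(net, criteria) {
  stopifnot(inherits(net, "assoc_network"),
            inherits(criteria, "screening_criteria"))
  pre_hits <- net$hit_nodes  # all hit nodes of the supplied network
  regated <- build_network(.as_query_results(net), gate = criteria$gate,
                           count_self = net$count_self)
  counts <- association_counts(regated)
  hit_tbl <- function(ids) {
    if (!length(ids)) {
      return(data.frame(subject_id = character(), description = character(),
                        association_count = integer(),
                        stringsAsFactors = FALSE))
    }
    cnt <- ifelse(ids %in% names(counts), counts[ids], 0L)
    desc <- pre_hits$description[match(ids, pre_hits$id)]
    data.frame(subject_id = ids, description = desc,
               association_count = as.integer(cnt), stringsAsFactors = FALSE)
  }
  all_ids <- pre_hits$id
  cnt_all <- stats::setNames(rep(0L, length(all_ids)), all_ids)
  present <- intersect(all_ids, names(counts))
  cnt_all[present] <- counts[present]
  excluded <- all_ids %in% criteria$exclude_ids
  included <- all_ids %in% criteria$include_ids
  gated_out <- !(all_ids %in% regated$hit_nodes$id)
  below <- cnt_all < criteria$min_associations
  retain <- (!excluded & !below) | (included & !excluded)
  reason <- rep(NA_character_, length(all_ids))
  reason[!retain] <- ifelse(excluded[!retain], "excluded",
                     ifelse(gated_out[!retain], "gated",
                            "below_min_associations"))
  neighbors_of <- function(ids) {
    lapply(ids, function(h) {
      sort(unique(regated$edges$query_id[regated$edges$subject_id == h]))
    })
  }
  mk <- function(sel, with_reason = FALSE) {
    ids <- all_ids[sel]
    tbl <- hit_tbl(ids)
    # canonical report order: descending count, ascending id
    o <- order(-tbl$association_count, tbl$subject_id)
    tbl <- tbl[o, , drop = FALSE]
    tbl$queries <- neighbors_of(tbl$subject_id)
    if (with_reason) tbl$reason <- reason[sel][o]
    rownames(tbl) <- NULL
    tbl
  }
  structure(list(criteria = criteria, retained = mk(retain),
                 dropped = mk(!retain, with_reason = TRUE),
                 created_at = .timestamp()),
            class = "screening_report")
}

# Reassemble query_result objects from a network's stored edges (self edges
# included) so screening can re-gate from the pre-threshold evidence.
.as_query_results <- function(net) {
  edges <- rbind(net$edges, if (!net$count_self) net$self_edges)
  lapply(net$query_nodes, function(q) {
    h <- edges[edges$query_id == q, setdiff(names(edges), "query_id"),
               drop = FALSE]
    h <- h[order(h$rank), , drop = FALSE]
    rownames(h) <- NULL
    .query_result(q, h)
  })
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("<screening_report> min_associations=%d: %d retained, %d dropped\n",
              x$criteria$min_associations, nrow(x$retained), nrow(x$dropped)))
  invisible(x)
}

#' Serialize a screening report as JSON
#'
#' The document stores the criteria snapshot and the retained/dropped hit
#' tables. Re-screening with the stored criteria reproduces the document
#' byte-for-byte, so volatile metadata (the in-memory creation time) is not
#' serialized.
#'
#' @param report a `screening_report`.
#' @param file path, connection, or `NULL` to return text invisibly.
#' @return the JSON text, invisibly.
#' @export
write_screening_report <- function(report, file = NULL) {
  stopifnot(inherits(report, "screening_report"))
  cr <- report$criteria
  tbl <- function(df) {
    lapply(seq_len(nrow(df)), function(k) {
      out <- list(subject_id = df$subject_id[k], description = df$description[k],
                  association_count = df$association_count[k],
                  queries = df$queries[[k]])
      if ("reason" %in% names(df)) out$reason <- df$reason[k]
      out
    })
  }
  doc <- list(criteria = list(min_associations = cr$min_associations,
                              gate = .gate_as_list(cr$gate),
                              include_ids = as.list(sort(cr$include_ids)),
                              exclude_ids = as.list(sort(cr$exclude_ids))),
              retained = tbl(report$retained),
              dropped = tbl(report$dropped))
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null", digits = NA,
                          pretty = TRUE)
  .output_lines(as.character(txt), file)
}

#' Tab-separated summary of a screening report
#'
#' @inheritParams write_screening_report
#' @return the TSV text, invisibly.
#' @export
write_screening_tsv <- function(report, file = NULL) {
  stopifnot(inherits(report, "screening_report"))
  row <- function(df, status) {
    if (!nrow(df)) return(character())
    sprintf("%s\t%s\t%d\t%s\t%s\t%s", df$subject_id, status,
            df$association_count,
            vapply(df$queries, paste, character(1), collapse = ","),
            if ("reason" %in% names(df)) df$reason else "",
            df$description)
  }
  l <- c("subject_id\tstatus\tassociation_count\tqueries\treason\tdescription",
         row(report$retained, "retained"), row(report$dropped, "dropped"))
  .output_lines(l, file)
}

#' Reconstruct a hit sequence from its alignment evidence
#'
#' When no subject database is available, a partial hit sequence can be
#' rebuilt from the stored HSP subject rows (XML input only): the edge with
#' the largest aligned length is taken, gaps removed, and the result
#' reverse-complemented when the hit was on the minus strand.
#'
#' @param evidence data frame of all edges of one hit (rows of
#'   `net$edges` with one `subject_id`).
#' @return a one-row sequence-record data frame with an extra `partial`
#'   column set to `TRUE`.
#' @export
reconstruct_hit_sequence <- function(evidence) {
  stopifnot(is.data.frame(evidence), nrow(evidence) >= 1L)
  sid <- unique(evidence$subject_id)
  stopifnot(length(sid) == 1L)
  has_seg <- !is.na(evidence$subject_aligned_segment) &
    nzchar(evidence$subject_aligned_segment)
  if (!any(has_seg)) {
    stop(sprintf("no aligned-segment data for hit '%s'; cannot reconstruct", sid),
         call. = FALSE)
  }
  ev <- evidence[has_seg, , drop = FALSE]
  best <- ev[order(-ev$align_length)[1L], , drop = FALSE]
  residues <- toupper(gsub("-", "", best$subject_aligned_segment, fixed = TRUE))
  if (identical(best$strand, "minus")) residues <- reverse_complement(residues)
  rec <- .record_df(id = sid, description = best$subject_description,
                    residues = residues, source_format = "reconstructed")
  rec$partial <- TRUE
  rec
}

#' Assemble the sequence set passed to alignment
#'
#' Members are the collection's query records (minus any explicitly
#' excluded) followed by one record per retained hit. Hit residues come
#' from `subject_db` when provided; otherwise they are reconstructed from
#' the network's stored HSP segments ([reconstruct_hit_sequence()]).
#'
#' @param report a `screening_report`.
#' @param collection the screened [create_collection()] object.
#' @param subject_db optional sequence-record data frame (e.g. from
#'   [read_fasta()]) holding subject sequences by id.
#' @param net the `assoc_network` the report came from; needed only when
#'   hits must be reconstructed.
#' @return an object of class `sequence_set` with elements `members`
#'   (record data frame, queries first), `origin` (named map id ->
#'   query/hit) and `partial_ids`.
#' @export
select_sequences <- function(report, collection, subject_db = NULL, net = NULL) {
  stopifnot(inherits(report, "screening_report"),
            inherits(collection, "collection"))
  queries <- collection$records
  excl <- report$criteria$exclude_ids
  queries <- queries[!(queries$id %in% excl), , drop = FALSE]
  hit_ids <- report$retained$subject_id
  unresolved <- character()
  partial_ids <- character()
  hit_recs <- NULL
  for (h in hit_ids) {
    if (!is.null(subject_db) && h %in% subject_db$id) {
      rec <- subject_db[match(h, subject_db$id), , drop = FALSE]
      rec <- .record_df(id = rec$id, accession = rec$accession,
                        description = rec$description, residues = rec$residues,
                        source_format = rec$source_format)
      rec$partial <- FALSE
    } else if (!is.null(net) &&
               any(net$edges$subject_id == h &
                   !is.na(net$edges$subject_aligned_segment))) {
      rec <- reconstruct_hit_sequence(
        net$edges[net$edges$subject_id == h, , drop = FALSE])
      partial_ids <- c(partial_ids, h)
    } else {
      unresolved <- c(unresolved, h)
      next
    }
    hit_recs <- if (is.null(hit_recs)) rec else rbind(hit_recs, rec)
  }
  if (length(unresolved)) {
    stop(sprintf("no sequence source for retained hit(s): %s",
                 paste(unresolved, collapse = ", ")), call. = FALSE)
  }
  queries$partial <- rep(FALSE, nrow(queries))
  members <- rbind(queries, hit_recs)
  dup <- unique(members$id[duplicated(members$id)])
  if (length(dup)) {
    stop(sprintf("duplicate member id(s) in sequence set: %s",
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  rownames(members) <- NULL
  origin <- stats::setNames(c(rep("query", nrow(queries)),
                              rep("hit", length(hit_ids))), members$id)
  structure(list(members = members, origin = origin,
                 partial_ids = partial_ids),
            class = "sequence_set")
}

#' @export
print.sequence_set <- function(x, ...) {
  cat(sprintf("<sequence_set> %d member(s): %d query, %d hit (%d partial)\n",
              nrow(x$members), sum(x$origin == "query"),
              sum(x$origin == "hit"), length(x$partial_ids)))
  invisible(x)
}
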