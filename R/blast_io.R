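# BLASTN result parsing: NCBI XML and tabular (outfmt 6/7) reports are
# normalized to one evidence row per (query, subject) pair, HSPs collapsed
# to the single best.

.BLAST12 <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
              "qstart", "qend", "sstart", "send", "evalue", "bitscore")

# Empty per-query hit table; rank is assigned after deduplication.
.hit_df <- function() {
  data.frame(subject_id = character(), subject_description = character(),
             rank = integer(), evalue = numeric(), bit_score = numeric(),
             percent_identity = numeric(), align_length = integer(),
             q_start = integer(), q_end = integer(),
             s_start = integer(), s_end = integer(),
             strand = character(), subject_aligned_segment = character(),
             stringsAsFactors = FALSE)
}

.query_result <- function(query_id, hits) {
  structure(list(query_id = query_id, hits = hits), class = "query_result")
}

#' @export
print.query_result <- function(x, ...) {
  cat(sprintf("<query_result> %s: %d hit(s)\n", x$query_id, nrow(x$hits)))
  invisible(x)
}

#' Collapse evidence rows for one (query, subject) pair
#'
#' Selects the single best row by highest bit score; ties are broken by
#' lowest e-value, then largest alignment length, then first occurrence in
#' input order. This is the rule by which multiple HSPs (or duplicated
#' tabular rows) become one edge of association evidence.
#'
#' @param rows a data frame of candidate evidence rows for one pair.
#' @return the selected single-row data frame.
#' @export
dedupe_evidence <- function(rows) {
  stopifnot(is.data.frame(rows), nrow(rows) >= 1L)
  o <- order(-rows$bit_score, rows$evalue, -rows$align_length,
             seq_len(nrow(rows)))
  rows[o[1L], , drop = FALSE]
}

# Apply the dedupe rule per subject and assign contiguous ranks in order of
# first appearance of each subject.
.dedupe_hits <- function(hits) {
  if (!nrow(hits)) {
    hits$rank <- integer(0)
    return(hits)
  }
  if (!anyDuplicated(hits$subject_id)) {
    hits$rank <- seq_len(nrow(hits))
    rownames(hits) <- NULL
    return(hits)
  }
  first_seen <- !duplicated(hits$subject_id)
  order_ids <- hits$subject_id[first_seen]
  kept <- do.call(rbind, lapply(order_ids, function(sid) {
    dedupe_evidence(hits[hits$subject_id == sid, , drop = FALSE])
  }))
  kept$rank <- seq_len(nrow(kept))
  rownames(kept) <- NULL
  kept
}

.xml_text1 <- function(node, xpath) {
  n <- xml2::xml_find_first(node, xpath)
  if (inherits(n, "xml_missing")) NA_character_ else xml2::xml_text(n)
}

#' Parse an NCBI BLAST XML report
#'
#' Accepts single- or multi-iteration BLASTN XML. Each `Hit` contributes one
#' evidence row carrying its best HSP (see [dedupe_evidence()]); the HSP
#' subject row (gaps included) is kept as `subject_aligned_segment` so hit
#' sequences can be reconstructed offline. Subject identity is
#' `Hit_accession` when present, else `Hit_id`. An iteration with zero hits
#' yields a result with an empty hit table (not an error).
#'
#' @inheritParams read_fasta
#' @return a list of `query_result` objects, one per iteration.
#' @export
parse_blast_xml <- function(file, text = NULL) {
  doc <- tryCatch(xml2::read_xml(.input_string(file, text)),
                  error = function(e) {
                    stop(sprintf("BLAST XML parse error: %s", conditionMessage(e)),
                         call. = FALSE)
                  })
  if (!identical(xml2::xml_name(doc), "BlastOutput")) {
    stop(sprintf("BLAST XML parse error: root element is <%s>, expected <BlastOutput>",
                 xml2::xml_name(doc)), call. = FALSE)
  }
  iters <- xml2::xml_find_all(doc, ".//Iteration")
  lapply(iters, function(it) {
    qdef <- .xml_text1(it, "./Iteration_query-def")
    qid <- if (!is.na(qdef) && nzchar(qdef)) {
      sub("\\s.*$", "", qdef)
    } else .xml_text1(it, "./Iteration_query-ID")
    hit_nodes <- xml2::xml_find_all(it, "./Iteration_hits/Hit")
    hits <- .hit_df()
    for (h in hit_nodes) {
      acc <- .xml_text1(h, "./Hit_accession")
      sid <- if (!is.na(acc) && nzchar(acc)) acc else .xml_text1(h, "./Hit_id")
      if (is.na(sid) || !nzchar(sid)) {
        stop("BLAST XML parse error: Hit with neither Hit_accession nor Hit_id",
             call. = FALSE)
      }
      sdef <- .xml_text1(h, "./Hit_def")
      if (is.na(sdef)) sdef <- ""
      hsps <- xml2::xml_find_all(h, "./Hit_hsps/Hsp")
      if (!length(hsps)) next
      rows <- do.call(rbind, lapply(hsps, function(hsp) {
        num <- function(xp) as.numeric(.xml_text1(hsp, xp))
        s_from <- as.integer(num("./Hsp_hit-from"))
        s_to <- as.integer(num("./Hsp_hit-to"))
        alen <- as.integer(num("./Hsp_align-len"))
        ident <- num("./Hsp_identity")
        seg <- .xml_text1(hsp, "./Hsp_hseq")
        data.frame(subject_id = sid, subject_description = sdef,
                   rank = NA_integer_,
                   evalue = num("./Hsp_evalue"),
                   bit_score = num("./Hsp_bit-score"),
                   percent_identity = 100 * ident / alen,
                   align_length = alen,
                   q_start = as.integer(num("./Hsp_query-from")),
                   q_end = as.integer(num("./Hsp_query-to")),
                   s_start = s_from, s_end = s_to,
                   strand = if (s_from > s_to) "minus" else "plus",
                   subject_aligned_segment = if (is.na(seg)) NA_character_ else seg,
                   stringsAsFactors = FALSE)
      }))
      hits <- rbind(hits, rows)
    }
    .query_result(qid, .dedupe_hits(hits))
  })
}

#' Parse a tabular BLAST report (outfmt 6/7)
#'
#' Rows are grouped by query in file order; per (query, subject) pair the
#' best row is kept ([dedupe_evidence()]) and ranks follow deduplicated
#' order of first appearance. Lines beginning with `#` are comments.
#'
#' @inheritParams read_fasta
#' @param columns ordered column names; defaults to the standard 12-column
#'   layout (`qseqid sseqid pident length mismatch gapopen qstart qend
#'   sstart send evalue bitscore`).
#' @return a list of `query_result` objects.
#' @export
parse_blast_tabular <- function(file, text = NULL, columns = .BLAST12) {
  needed <- c("qseqid", "sseqid", "pident", "length", "qstart", "qend",
              "sstart", "send", "evalue", "bitscore")
  if (!all(needed %in% columns)) {
    stop(sprintf("tabular column layout must include: %s",
                 paste(setdiff(needed, columns), collapse = ", ")), call. = FALSE)
  }
  lines <- .input_lines(file, text)
  lineno <- seq_along(lines)
  data_sel <- nzchar(trimws(lines)) & !startsWith(lines, "#")
  lines <- lines[data_sel]; lineno <- lineno[data_sel]
  if (!length(lines)) return(list())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != length(columns))) {
    bad <- which(nf != length(columns))[1]
    stop(sprintf("tabular parse error at line %d: %d field(s), expected %d",
                 lineno[bad], nf[bad], length(columns)), call. = FALSE)
  }
  m <- matrix(unlist(fields), ncol = length(columns), byrow = TRUE,
              dimnames = list(NULL, columns))
  num <- function(col) {
    v <- suppressWarnings(as.numeric(m[, col]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop(sprintf("tabular parse error at line %d: field '%s' = '%s' is not numeric",
                   lineno[bad], col, m[bad, col]), call. = FALSE)
    }
    v
  }
  s_start <- as.integer(num("sstart")); s_end <- as.integer(num("send"))
  rows <- data.frame(
    query_id = m[, "qseqid"],
    subject_id = m[, "sseqid"], subject_description = "",
    rank = NA_integer_,
    evalue = num("evalue"), bit_score = num("bitscore"),
    percent_identity = num("pident"),
    align_length = as.integer(num("length")),
    q_start = as.integer(num("qstart")), q_end = as.integer(num("qend")),
    s_start = s_start, s_end = s_end,
    strand = ifelse(s_start > s_end, "minus", "plus"),
    subject_aligned_segment = NA_character_,
    stringsAsFactors = FALSE)
  qids <- unique(rows$query_id)
  lapply(qids, function(q) {
    h <- rows[rows$query_id == q, setdiff(names(rows), "query_id"), drop = FALSE]
    .query_result(q, .dedupe_hits(h))
  })
}
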