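# PHYLIP sequential alignment format. Relaxed dialect (full names followed
# by whitespace) is the default; strict dialect pads/truncates names to the
# classic 10 characters and refuses silent collisions.

#' Write an alignment in PHYLIP (sequential) format
#'
#' Header `n L`, then one row per sequence. In the relaxed dialect names
#' are written in full (internal whitespace replaced by `_`) followed by
#' two spaces; in the strict dialect names are truncated/padded to 10
#' characters and a collision after truncation is an error.
#'
#' @param aln an `msa`.
#' @param file path, connection, or `NULL` to return text invisibly.
#' @param dialect `"relaxed"` (default) or `"strict"`.
#' @return the PHYLIP text, invisibly; attribute `sanitization_map` maps
#'   written names back to originals when renaming occurred.
#' @export
write_phylip <- function(aln, file = NULL, dialect = c("relaxed", "strict")) {
  stopifnot(inherits(aln, "msa"))
  dialect <- match.arg(dialect)
  ids <- aln$ids
  if (dialect == "strict") {
    names10 <- substr(gsub("[[:space:]]", "_", ids), 1L, 10L)
    dup <- unique(names10[duplicated(names10)])
    if (length(dup)) {
      offenders <- ids[names10 %in% dup]
      stop(sprintf("strict PHYLIP name collision after 10-character truncation: %s",
                   paste(offenders, collapse = ", ")), call. = FALSE)
    }
    written <- formatC(names10, width = 10, flag = "-")
  } else {
    written <- gsub("[[:space:]]", "_", ids)
  }
  l <- c(sprintf("%d %d", length(ids), nchar(aln$rows[[1]])),
         paste0(written, "  ", unname(aln$rows)))
  out <- .output_lines(l, file)
  clean <- trimws(written)
  if (any(clean != ids)) {
    attr(out, "sanitization_map") <- stats::setNames(ids, clean)
  }
  invisible(out)
}

#' Read a PHYLIP (sequential) alignment
#'
#' Accepts both dialects written by [write_phylip()]: the name is the first
#' whitespace-delimited token of each row, the sequence the concatenation
#' of the remaining tokens. The header must match the body.
#'
#' @inheritParams read_fasta
#' @return an `msa`.
#' @export
read_phylip <- function(file, text = NULL) {
  lines <- .input_lines(file, text)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("PHYLIP parse error: empty input", call. = FALSE)
  hdr <- suppressWarnings(as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]]))
  if (length(hdr) != 2L || anyNA(hdr)) {
    stop("PHYLIP parse error: header must be 'n L'", call. = FALSE)
  }
  n <- hdr[1]; L <- hdr[2]
  body <- lines[-1]
  if (length(body) != n) {
    stop(sprintf("PHYLIP parse error: header declares %d sequence(s), found %d rows",
                 n, length(body)), call. = FALSE)
  }
  ids <- character(n); rows <- character(n)
  for (k in seq_len(n)) {
    toks <- strsplit(trimws(body[k]), "\\s+")[[1]]
    if (length(toks) < 2L) {
      stop(sprintf("PHYLIP parse error at row %d: missing sequence", k),
           call. = FALSE)
    }
    ids[k] <- toks[1]
    rows[k] <- paste(toks[-1], collapse = "")
    if (nchar(rows[k]) != L) {
      stop(sprintf("PHYLIP parse error at row %d ('%s'): %d column(s), header declares %d",
                   k, ids[k], nchar(rows[k]), L), call. = FALSE)
    }
  }
  if (anyDuplicated(ids)) {
    stop("PHYLIP parse error: duplicate sequence names", call. = FALSE)
  }
  .msa(ids, rows, params = list(source = "phylip"))
}
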