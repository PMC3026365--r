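# Sequence import/export: FASTA, GenBank flat file (read-only subset), raw
# text, and the Collection container that enters the pipeline.

# Canonical sequence-record table. Every reader returns one of these.
.record_df <- function(id = character(), accession = NA_character_,
                       description = "", residues = character(),
                       source_format = NA_character_) {
  n <- length(id)
  data.frame(id = as.character(id),
             accession = rep_len(as.character(accession), n),
             description = rep_len(as.character(description), n),
             residues = as.character(residues),
             source_format = rep_len(as.character(source_format), n),
             stringsAsFactors = FALSE)
}

.validate_records <- function(records, where = "records") {
  stopifnot(is.data.frame(records))
  needed <- c("id", "accession", "description", "residues", "source_format")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop(sprintf("%s is missing columns: %s", where,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (any(!nzchar(records$id))) stop(sprintf("%s has empty ids", where), call. = FALSE)
  if (any(!nzchar(records$residues))) {
    stop(sprintf("%s has empty residues for id(s): %s", where,
                 paste(records$id[!nzchar(records$residues)], collapse = ", ")),
         call. = FALSE)
  }
  if (any(grepl("[-[:space:]]", records$residues))) {
    stop(sprintf("%s contains gap or whitespace characters in residues", where),
         call. = FALSE)
  }
  invisible(records)
}

#' Read sequences from a FASTA stream
#'
#' One record per `>` header. The record id is the first whitespace-delimited
#' token of the header; the remainder becomes the description. Sequence lines
#' are concatenated and uppercased. `U` is preserved (not converted to `T`).
#'
#' @param file path or connection to FASTA text.
#' @param text literal FASTA content (alternative to `file`).
#' @return a data frame of sequence records with columns `id`, `accession`,
#'   `description`, `residues`, `source_format`.
#' @examples
#' read_fasta(text = ">q1 desc\nACGT\n")
#' @export
read_fasta <- function(file, text = NULL) {
  lines <- .input_lines(file, text)
  ids <- character(); descs <- character(); seqs <- character()
  header_line <- integer()
  cur_seq <- NULL
  flush <- function() {
    if (!is.null(cur_seq)) {
      if (!nzchar(cur_seq)) {
        stop(sprintf("FASTA parse error at line %d: empty record body for '%s'",
                     header_line[length(ids)], ids[length(ids)]), call. = FALSE)
      }
      seqs[length(seqs) + 1L] <<- cur_seq
    }
  }
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (startsWith(ln, ">")) {
      flush()
      header <- sub("^>\\s*", "", ln)
      id <- sub("\\s.*$", "", header)
      if (!nzchar(id)) {
        stop(sprintf("FASTA parse error at line %d: header with no id", i),
             call. = FALSE)
      }
      desc <- if (identical(id, header)) "" else
        trimws(substring(header, nchar(id) + 1L))
      ids <- c(ids, id); descs <- c(descs, desc)
      header_line <- c(header_line, i)
      cur_seq <- ""
    } else if (nzchar(trimws(ln))) {
      if (is.null(cur_seq)) {
        stop(sprintf("FASTA parse error at line %d: sequence data before any header", i),
             call. = FALSE)
      }
      cur_seq <- paste0(cur_seq, toupper(gsub("[[:space:]]", "", ln)))
    }
  }
  flush()
  .record_df(id = ids, description = descs, residues = seqs,
             source_format = "fasta")
}

#' Read sequences from GenBank flat-file entries
#'
#' Minimal read-only subset: id from the LOCUS name, accession from
#' ACCESSION, description from DEFINITION, residues from the ORIGIN block
#' with coordinates and whitespace stripped. Feature tables are ignored.
#' Entries are separated by `//`.
#'
#' @inheritParams read_fasta
#' @return a data frame of sequence records.
#' @export
read_genbank <- function(file, text = NULL) {
  lines <- .input_lines(file, text)
  if (!length(lines)) return(.record_df(source_format = "genbank"))
  # split into entries on terminator lines
  entry_idx <- cumsum(c(TRUE, grepl("^//\\s*$", utils::head(lines, -1))))
  keep <- !grepl("^//\\s*$", lines) & nzchar(trimws(lines))
  out <- NULL
  for (e in unique(entry_idx[keep])) {
    el <- lines[entry_idx == e & keep]
    if (!length(el)) next
    locus_i <- grep("^LOCUS\\b", el)
    label <- if (length(locus_i)) {
      strsplit(trimws(sub("^LOCUS", "", el[locus_i[1]])), "\\s+")[[1]][1]
    } else NA_character_
    if (!length(locus_i) || is.na(label) || !nzchar(label)) {
      stop(sprintf("GenBank parse error in entry %d: missing LOCUS name", e),
           call. = FALSE)
    }
    origin_i <- grep("^ORIGIN\\b", el)
    if (!length(origin_i)) {
      stop(sprintf("GenBank parse error in entry '%s': missing ORIGIN block", label),
           call. = FALSE)
    }
    seq_lines <- el[seq.int(origin_i[1] + 1L, length.out = max(0L, length(el) - origin_i[1]))]
    residues <- toupper(gsub("[0-9[:space:]/]", "", paste(seq_lines, collapse = "")))
    if (!nzchar(residues)) {
      stop(sprintf("GenBank parse error in entry '%s': empty ORIGIN block", label),
           call. = FALSE)
    }
    def_i <- grep("^DEFINITION\\b", el)
    description <- if (length(def_i)) {
      # DEFINITION may continue over indented lines
      j <- def_i[1] + 1L
      parts <- trimws(sub("^DEFINITION", "", el[def_i[1]]))
      while (j <= length(el) && grepl("^\\s", el[j])) {
        parts <- c(parts, trimws(el[j])); j <- j + 1L
      }
      trimws(paste(parts, collapse = " "))
    } else ""
    acc_i <- grep("^ACCESSION\\b", el)
    accession <- if (length(acc_i)) {
      strsplit(trimws(sub("^ACCESSION", "", el[acc_i[1]])), "\\s+")[[1]][1]
    } else NA_character_
    rec <- .record_df(id = label, accession = accession,
                      description = description, residues = residues,
                      source_format = "genbank")
    out <- if (is.null(out)) rec else rbind(out, rec)
  }
  if (is.null(out)) out <- .record_df(source_format = "genbank")
  out
}

#' Read sequences from raw text
#'
#' Each non-empty line is one record; internal whitespace is removed and the
#' residues uppercased. Ids are auto-assigned `raw_1`, `raw_2`, ... in order.
#'
#' @inheritParams read_fasta
#' @return a data frame of sequence records.
#' @export
read_raw <- function(file, text = NULL) {
  lines <- .input_lines(file, text)
  seqs <- character(); src_line <- integer()
  for (i in seq_along(lines)) {
    s <- toupper(gsub("[[:space:]]", "", lines[[i]]))
    if (!nzchar(s)) next
    bad <- setdiff(unique(strsplit(s, "", fixed = TRUE)[[1]]), .IUPAC_NT)
    if (length(bad)) {
      stop(sprintf("raw parse error at line %d: non-IUPAC character(s) %s",
                   i, paste(sQuote(bad), collapse = ", ")), call. = FALSE)
    }
    seqs <- c(seqs, s); src_line <- c(src_line, i)
  }
  .record_df(id = if (length(seqs)) paste0("raw_", seq_along(seqs)) else character(),
             residues = seqs, source_format = "raw")
}

#' Write sequence records as FASTA
#'
#' Standard FASTA with 60-column wrapping; the header is `id description`
#' (description omitted when empty). `read_fasta(write_fasta(x))` preserves
#' id, description and residues exactly.
#'
#' @param records a sequence-record data frame (see [read_fasta()]).
#' @param file path or connection; `NULL` to return the text invisibly.
#' @return the FASTA text, invisibly.
#' @export
write_fasta <- function(records, file = NULL) {
  if (nrow(records)) .validate_records(records)
  lines <- character()
  for (k in seq_len(nrow(records))) {
    desc <- records$description[k]
    header <- if (nzchar(desc) && !is.na(desc)) {
      paste0(">", records$id[k], " ", desc)
    } else paste0(">", records$id[k])
    seq <- records$residues[k]
    starts <- seq.int(1L, nchar(seq), by = 60L)
    lines <- c(lines, header, substring(seq, starts, pmin(starts + 59L, nchar(seq))))
  }
  .output_lines(lines, file)
}

#' Create a sequence Collection
#'
#' A Collection is the named, timestamped set of query records that enters
#' the screening pipeline. Import parameters (at minimum the source format
#' and record count) are stored with it.
#'
#' @param name collection name.
#' @param records sequence-record data frame with unique, non-empty ids.
#' @param import_params named list of import parameters to record.
#' @return an object of class `collection`.
#' @export
create_collection <- function(name, records, import_params = list()) {
  stopifnot(.is_string(name))
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("a collection requires at least one sequence record", call. = FALSE)
  }
  .validate_records(records)
  dup <- unique(records$id[duplicated(records$id)])
  if (length(dup)) {
    stop(sprintf("duplicate record id(s): %s", paste(dup, collapse = ", ")),
         call. = FALSE)
  }
  params <- utils::modifyList(
    list(source_format = records$source_format[1], record_count = nrow(records)),
    import_params)
  structure(list(name = name, created_at = .timestamp(),
                 records = records, import_params = params),
            class = "collection")
}

#' @export
print.collection <- function(x, ...) {
  cat(sprintf("<collection> '%s': %d record(s), format %s, created %s\n",
              x$name, nrow(x$records),
              x$import_params$source_format, x$created_at))
  invisible(x)
}
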