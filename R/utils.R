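# Shared internal helpers.

# IUPAC nucleotide one-letter codes accepted on import ('-' is forbidden in
# unaligned residues; it only appears in alignment rows).
.IUPAC_NT <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N")

# Resolve the (file, text) input convention used by all readers: `file` is a
# path or connection; `text` is literal content (character vector, split on
# newlines). Returns a character vector of lines with CR stripped.
.input_lines <- function(file, text) {
  if (!missing(text) && !is.null(text)) {
    lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  } else {
    if (missing(file) || is.null(file)) {
      stop("either 'file' or 'text' must be supplied", call. = FALSE)
    }
    if (is.character(file) && !file.exists(file)) {
      stop(sprintf("input file '%s' does not exist", file), call. = FALSE)
    }
    lines <- readLines(file, warn = FALSE)
  }
  sub("\r$", "", lines)
}

.input_string <- function(file, text) {
  paste(.input_lines(file, text), collapse = "\n")
}

# Write lines to a path, connection, or return them invisibly when file is
# NULL. Always uses "\n" separators for byte-stable output.
.output_lines <- function(lines, file) {
  txt <- paste0(paste(lines, collapse = "\n"), if (length(lines)) "\n" else "")
  if (!is.null(file)) {
    con <- if (inherits(file, "connection")) file else {
      fc <- file(file, open = "wb"); on.exit(close(fc)); fc
    }
    writeBin(charToRaw(txt), con)
  }
  invisible(txt)
}

.is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

#' Reverse complement of a nucleotide string
#'
#' Complements IUPAC nucleotide codes (U complements to A) and reverses the
#' string. Gap characters are preserved in place.
#'
#' @param x a single nucleotide string.
#' @return the reverse complement as a single string.
#' @examples
#' reverse_complement("AACG")  # "CGTT"
#' @export
reverse_complement <- function(x) {
  stopifnot(.is_string(x))
  comp <- chartr("ACGTURYSWKMBDHVNacgturyswkmbdhvn",
                 "TGCAAYRSWMKVHDBNtgcaayrswmkvhdbn", x)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

# XML-escape text content / attribute values.
.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

# Fixed decimal-text rendering for exported numbers: enough digits to
# round-trip a double, no locale dependence.
.num_chr <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.15g", v)
  }, character(1))
}

# Timestamp in a fixed format (UTC) so provenance records are locale-stable.
.timestamp <- function() {
  format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
}
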