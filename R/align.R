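# Built-in alignment fallbacks: pairwise Needleman-Wunsch and a
# center-star multiple alignment. These exist so the full pipeline runs at
# desk scale with no external binaries; production alignments are expected
# to come from a dedicated aligner through the adapter interface.

#' Pairwise global alignment (Needleman-Wunsch)
#'
#' Maximizes the linear-gap score with the given match/mismatch/gap values.
#' Traceback ties are broken diagonal > up > left at every cell, so the
#' alignment is unique and deterministic.
#'
#' @param a,b non-empty nucleotide strings.
#' @param match,mismatch,gap scoring parameters (defaults +1/-1/-2).
#' @return a list with `a`, `b` (aligned strings of equal length) and
#'   `score`.
#' @examples
#' nw_pairwise("ACGT", "ACGT")$score  # 4
#' @export
nw_pairwise <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  if (!.is_string(a) || !nzchar(a) || !.is_string(b) || !nzchar(b)) {
    stop("both sequences must be non-empty strings", call. = FALSE)
  }
  .nw_align_cpp(a, b, match, mismatch, gap)
}

# Normalize a sequence input (sequence_set, record data frame, or named
# character vector) to a named character vector of residues.
.as_named_seqs <- function(seqs) {
  if (inherits(seqs, "sequence_set")) seqs <- seqs$members
  if (is.data.frame(seqs)) {
    return(stats::setNames(seqs$residues, seqs$id))
  }
  if (is.character(seqs)) {
    if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
      stop("sequences must be named", call. = FALSE)
    }
    return(seqs)
  }
  stop("unsupported sequence container", call. = FALSE)
}

#' Center-star multiple alignment
#'
#' The center is the sequence with the highest total pairwise alignment
#' score against all others (ties broken by lexicographically first id).
#' Every other sequence is aligned to the center pairwise and the gaps are
#' merged into the center's coordinate system ("once a gap, always a gap").
#' Removing gaps from any row reproduces its input sequence exactly.
#'
#' @param seqs a `sequence_set`, sequence-record data frame, or named
#'   character vector with at least two sequences.
#' @inheritParams nw_pairwise
#' @return an object of class `msa`: list with `ids`, `rows` (named
#'   equal-length aligned strings) and `params`.
#' @export
star_align <- function(seqs, match = 1, mismatch = -1, gap = -2) {
  x <- .as_named_seqs(seqs)
  n <- length(x)
  if (n < 2L) stop("multiple alignment requires at least 2 sequences", call. = FALSE)
  if (anyDuplicated(names(x))) stop("duplicate sequence ids", call. = FALSE)
  ids <- names(x)
  # total pairwise score of each candidate center
  totals <- stats::setNames(numeric(n), ids)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      s <- .nw_align_cpp(x[[i]], x[[j]], match, mismatch, gap)$score
      totals[i] <- totals[i] + s
      totals[j] <- totals[j] + s
    }
  }
  center <- ids[order(-totals, ids)][1L]
  others <- setdiff(ids, center)
  cseq <- x[[center]]
  L <- nchar(cseq)
  pair <- lapply(others, function(id) .nw_align_cpp(cseq, x[[id]], match, mismatch, gap))
  names(pair) <- others
  # gaps inserted before center residue p (slot p in 1..L+1; slot L+1 =
  # after the last residue); master pattern = per-slot maximum
  slot_gaps <- function(crow) {
    chars <- strsplit(crow, "", fixed = TRUE)[[1]]
    g <- integer(L + 1L); p <- 1L; run <- 0L
    for (ch in chars) {
      if (ch == "-") run <- run + 1L
      else { g[p] <- run; run <- 0L; p <- p + 1L }
    }
    g[L + 1L] <- run
    g
  }
  gaps <- lapply(pair, function(al) slot_gaps(al$a))
  master <- Reduce(pmax, gaps, integer(L + 1L))
  cres <- strsplit(cseq, "", fixed = TRUE)[[1]]
  pad <- function(k) strrep("-", k)
  center_row <- paste0(paste0(vapply(seq_len(L), function(p) {
    paste0(pad(master[p]), cres[p])
  }, character(1)), collapse = ""), pad(master[L + 1L]))
  expand_row <- function(al) {
    cc <- strsplit(al$a, "", fixed = TRUE)[[1]]
    sc <- strsplit(al$b, "", fixed = TRUE)[[1]]
    out <- character(L + 1L)
    p <- 1L; buf <- character()
    for (k in seq_along(cc)) {
      if (cc[k] == "-") {
        buf <- c(buf, sc[k])
      } else {
        out[p] <- paste0(pad(master[p] - length(buf)),
                         paste(buf, collapse = ""), sc[k])
        buf <- character(); p <- p + 1L
      }
    }
    out[L + 1L] <- paste0(pad(master[L + 1L] - length(buf)),
                          paste(buf, collapse = ""))
    paste(out, collapse = "")
  }
  rows <- c(stats::setNames(list(center_row), center),
            lapply(pair, expand_row))
  rows <- unlist(rows)[ids]  # restore input order
  structure(list(ids = ids, rows = rows,
                 params = list(method = "center_star", match = match,
                               mismatch = mismatch, gap = gap,
                               center = center)),
            class = "msa")
}

# Internal msa constructor used by readers.
.msa <- function(ids, rows, params = list()) {
  stopifnot(length(ids) == length(rows))
  widths <- unique(nchar(rows))
  if (length(widths) > 1L) {
    stop("alignment rows have unequal lengths", call. = FALSE)
  }
  structure(list(ids = ids, rows = stats::setNames(rows, ids), params = params),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d sequence(s), %d column(s)%s\n", length(x$ids),
              if (length(x$rows)) nchar(x$rows[[1]]) else 0L,
              if (!is.null(x$params$method)) paste0(", method ", x$params$method) else ""))
  invisible(x)
}

#' Uncorrected p-distance between two aligned rows
#'
#' Comparable sites are the positions where both rows carry an unambiguous
#' nucleotide (`A`, `C`, `G`, `T` or `U`); the distance is the fraction of
#' comparable sites that differ (`T` and `U` are distinct characters and
#' count as a mismatch). Positions with a gap or ambiguity code in either
#' row are skipped.
#'
#' @param row_i,row_j equal-length aligned strings.
#' @return a number in `[0, 1]`.
#' @export
p_distance <- function(row_i, row_j) {
  stopifnot(.is_string(row_i), .is_string(row_j))
  if (nchar(row_i) != nchar(row_j)) {
    stop("aligned rows must have equal length", call. = FALSE)
  }
  a <- strsplit(toupper(row_i), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(row_j), "", fixed = TRUE)[[1]]
  plain <- c("A", "C", "G", "T", "U")
  comp <- a %in% plain & b %in% plain
  if (!any(comp)) {
    stop("no comparable sites: p-distance undefined", call. = FALSE)
  }
  sum(a[comp] != b[comp]) / sum(comp)
}

#' Jukes-Cantor corrected distance
#'
#' The standard one-parameter correction `d = -(3/4) * log(1 - 4p/3)`:
#' monotone increasing in the p-distance, `d(0) = 0`, and diverging as `p`
#' approaches the saturation point 3/4.
#'
#' @param p p-distance(s) in `[0, 0.75)`.
#' @return corrected distance(s), always `>= p`.
#' @export
jc69_distance <- function(p) {
  stopifnot(is.numeric(p))
  if (any(p < 0)) stop("p-distance must be non-negative", call. = FALSE)
  if (any(p >= 0.75)) {
    stop("p-distance at or beyond 0.75: Jukes-Cantor correction saturates",
         call. = FALSE)
  }
  -0.75 * log(1 - 4 * p / 3)
}

#' Pairwise distance matrix of an alignment
#'
#' @param aln an `msa`.
#' @param model `"p"` for the raw p-distance or `"jc69"` for the
#'   Jukes-Cantor correction.
#' @return a symmetric numeric matrix with zero diagonal and the alignment
#'   ids as dimnames.
#' @export
distance_matrix <- function(aln, model = c("p", "jc69")) {
  stopifnot(inherits(aln, "msa"))
  model <- match.arg(model)
  n <- length(aln$ids)
  d <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        p <- p_distance(aln$rows[[i]], aln$rows[[j]])
        v <- if (model == "jc69") jc69_distance(p) else p
        d[i, j] <- v; d[j, i] <- v
      }
    }
  }
  d
}
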