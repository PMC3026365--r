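# Synthetic fixtures with planted association structure: query collections,
# subject databases and simulated BLAST reports whose ground truth (the
# incidence matrix) is known exactly. This emulates an environmental 16S
# survey in which some database sequences are recovered by several of the
# supplied phylotypes.

#' Specify a synthetic fixture
#'
#' @param n_queries,n_subjects positive dimensions of the planted incidence
#'   matrix.
#' @param incidence optional binary `n_queries x n_subjects` matrix stating
#'   exactly which (query, subject) pairs produce a BLAST row. Mutually
#'   exclusive with `density`.
#' @param density probability in `(0, 1]` that a pair is planted; subjects
#'   left with no query are given one (every subject must be hit at least
#'   once).
#' @param seq_length sequence length (default 200, a desk-scale stand-in
#'   for partial 16S reads).
#' @param mutation_rate per-site substitution rate in `[0, 0.3]` from the
#'   shared ancestor; drives realized percent identity.
#' @param seed integer seed (required; the bundle is a pure function of the
#'   spec).
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_queries, n_subjects, incidence = NULL,
                         density = NULL, seq_length = 200L,
                         mutation_rate = 0.05, seed) {
  stopifnot(is.numeric(n_queries), n_queries >= 1,
            is.numeric(n_subjects), n_subjects >= 1,
            is.numeric(seq_length), seq_length >= 1)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L) {
    stop("fixture_spec requires an integer seed", call. = FALSE)
  }
  if (!is.numeric(mutation_rate) || mutation_rate < 0 || mutation_rate > 0.3) {
    stop("mutation_rate must lie in [0, 0.3]", call. = FALSE)
  }
  if (is.null(incidence) == is.null(density)) {
    if (is.null(incidence)) {
      stop("supply exactly one of 'incidence' or 'density'", call. = FALSE)
    }
    stop("supply exactly one of 'incidence' or 'density', not both", call. = FALSE)
  }
  if (!is.null(density) && (density <= 0 || density > 1)) {
    stop("density must lie in (0, 1]", call. = FALSE)
  }
  if (!is.null(incidence)) {
    incidence <- as.matrix(incidence)
    if (nrow(incidence) != n_queries || ncol(incidence) != n_subjects ||
        !all(incidence %in% c(0, 1))) {
      stop("incidence must be a binary n_queries x n_subjects matrix",
           call. = FALSE)
    }
    if (any(colSums(incidence) == 0)) {
      stop("incidence has an all-zero subject column (every subject must be hit at least once)",
           call. = FALSE)
    }
  }
  structure(list(n_queries = as.integer(n_queries),
                 n_subjects = as.integer(n_subjects),
                 incidence = incidence, density = density,
                 seq_length = as.integer(seq_length),
                 mutation_rate = mutation_rate, seed = as.integer(seed)),
            class = "fixture_spec")
}

# Run code under a private RNG stream without disturbing the caller's.
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.mutate_seq <- function(chars, rate) {
  hit <- stats::runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(ch) {
      sample(setdiff(c("A", "C", "G", "T"), ch), 1L)
    }, character(1))
  }
  chars
}

#' Generate a synthetic fixture bundle
#'
#' Deterministic given the spec's seed. All sequences descend from one
#' random ancestor by per-site substitution, so every planted (query,
#' subject) pair has a high, internally consistent percent identity. For
#' each planted pair one tabular BLAST row is emitted: percent identity is
#' the realized positionwise identity, `bit_score = 2 * (number of
#' identical sites)`, and `evalue = 10^(-bit_score / 10)` - a documented
#' deterministic monotone stand-in (only ordering and gate behavior matter
#' downstream, not BLAST's score statistics). Ranks are assigned per query
#' by descending bit score (ties by subject id). Unplanted pairs emit no
#' row.
#'
#' @param spec a [fixture_spec()].
#' @return an object of class `fixture_bundle`: list with `spec`,
#'   `queries` and `subjects` (sequence-record data frames), `blast_tab`
#'   (tabular report text), `blast_xml` (the same rows as BLAST XML) and
#'   `planted` (the realized incidence matrix).
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  .with_seed(spec$seed, {
    nq <- spec$n_queries; ns <- spec$n_subjects; L <- spec$seq_length
    qids <- sprintf("q%03d", seq_len(nq))
    sids <- sprintf("s%03d", seq_len(ns))
    planted <- spec$incidence
    if (is.null(planted)) {
      planted <- matrix(as.integer(stats::runif(nq * ns) < spec$density), nq, ns)
      for (s in which(colSums(planted) == 0)) {
        planted[sample.int(nq, 1L), s] <- 1L
      }
    }
    dimnames(planted) <- list(qids, sids)
    ancestor <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    qmat <- vapply(seq_len(nq), function(i) .mutate_seq(ancestor, spec$mutation_rate),
                   character(L))
    smat <- vapply(seq_len(ns), function(i) .mutate_seq(ancestor, spec$mutation_rate),
                   character(L))
    queries <- .record_df(id = qids, description = "synthetic query",
                          residues = apply(qmat, 2, paste, collapse = ""),
                          source_format = "fasta")
    subjects <- .record_df(id = sids, description = "synthetic subject",
                           residues = apply(smat, 2, paste, collapse = ""),
                           source_format = "fasta")
    # one row per planted pair, ranked within query by descending bit score
    tab_lines <- character()
    xml_iter <- character()
    for (qi in seq_len(nq)) {
      sel <- which(planted[qi, ] == 1L)
      nident <- vapply(sel, function(si) sum(qmat[, qi] == smat[, si]), integer(1))
      bit <- 2 * nident
      o <- order(-bit, sids[sel])
      sel <- sel[o]; nident <- nident[o]; bit <- bit[o]
      pid_txt <- sprintf("%.3f", 100 * nident / L)
      ev_txt <- sprintf("%.6e", 10^(-bit / 10))
      tab_lines <- c(tab_lines, sprintf(
        "%s\t%s\t%s\t%d\t%d\t0\t1\t%d\t1\t%d\t%s\t%s",
        qids[qi], sids[sel], pid_txt, L, L - nident, L, L, ev_txt,
        sprintf("%.1f", bit)))
      hits <- if (length(sel)) paste0(vapply(seq_along(sel), function(k) {
        si <- sel[k]
        paste0("<Hit><Hit_num>", k, "</Hit_num>",
               "<Hit_id>", sids[si], "</Hit_id>",
               "<Hit_def></Hit_def>",
               "<Hit_accession>", sids[si], "</Hit_accession>",
               "<Hit_len>", L, "</Hit_len><Hit_hsps><Hsp>",
               "<Hsp_num>1</Hsp_num>",
               "<Hsp_bit-score>", sprintf("%.1f", bit[k]), "</Hsp_bit-score>",
               "<Hsp_evalue>", ev_txt[k], "</Hsp_evalue>",
               "<Hsp_query-from>1</Hsp_query-from>",
               "<Hsp_query-to>", L, "</Hsp_query-to>",
               "<Hsp_hit-from>1</Hsp_hit-from>",
               "<Hsp_hit-to>", L, "</Hsp_hit-to>",
               "<Hsp_identity>", nident[k], "</Hsp_identity>",
               "<Hsp_align-len>", L, "</Hsp_align-len>",
               "<Hsp_hseq>", subjects$residues[si], "</Hsp_hseq>",
               "</Hsp></Hit_hsps></Hit>")
      }, character(1)), collapse = "") else ""
      # tabular output cannot represent a hitless query, so the XML mirror
      # also omits it; the two reports then describe identical networks
      if (!length(sel)) next
      xml_iter <- c(xml_iter, paste0(
        "<Iteration><Iteration_iter-num>", qi, "</Iteration_iter-num>",
        "<Iteration_query-ID>Query_", qi, "</Iteration_query-ID>",
        "<Iteration_query-def>", qids[qi], " synthetic query</Iteration_query-def>",
        "<Iteration_query-len>", L, "</Iteration_query-len>",
        "<Iteration_hits>", hits, "</Iteration_hits></Iteration>"))
    }
    blast_xml <- paste0(
      '<?xml version="1.0"?>\n<BlastOutput>',
      "<BlastOutput_program>blastn</BlastOutput_program>",
      "<BlastOutput_version>synthetic</BlastOutput_version>",
      "<BlastOutput_iterations>", paste(xml_iter, collapse = ""),
      "</BlastOutput_iterations></BlastOutput>\n")
    structure(list(spec = spec, queries = queries, subjects = subjects,
                   blast_tab = paste0(paste(tab_lines, collapse = "\n"),
                                      if (length(tab_lines)) "\n" else ""),
                   blast_xml = blast_xml, planted = planted),
              class = "fixture_bundle")
  })
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat(sprintf("<fixture_bundle> %d query x %d subject, %d planted pair(s), seed %d\n",
              x$spec$n_queries, x$spec$n_subjects, sum(x$planted),
              x$spec$seed))
  invisible(x)
}

#' Planted association counts
#'
#' The ground-truth association count of every subject: the column sums of
#' the planted incidence matrix.
#'
#' @param x a `fixture_spec` (with explicit incidence) or `fixture_bundle`.
#' @return a named integer vector, subject id to count.
#' @export
planted_counts <- function(x) {
  if (inherits(x, "fixture_bundle")) {
    m <- x$planted
  } else if (inherits(x, "fixture_spec")) {
    if (is.null(x$incidence)) {
      stop("a density-based spec has no realized incidence; generate the bundle first",
           call. = FALSE)
    }
    m <- x$incidence
    dimnames(m) <- list(sprintf("q%03d", seq_len(nrow(m))),
                        sprintf("s%03d", seq_len(ncol(m))))
  } else {
    stop("expected a fixture_spec or fixture_bundle", call. = FALSE)
  }
  stats::setNames(as.integer(colSums(m)), colnames(m))
}

#' Write a fixture bundle to a directory
#'
#' Writes `queries.fasta`, `subjects.fasta`, `blast.tsv`, `blast.xml` and
#' `planted.tsv`.
#'
#' @param bundle a `fixture_bundle`.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_fixture <- function(bundle, dir) {
  stopifnot(inherits(bundle, "fixture_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(bundle$queries, file.path(dir, "queries.fasta"))
  write_fasta(bundle$subjects, file.path(dir, "subjects.fasta"))
  .output_lines(sub("\n$", "", bundle$blast_tab), file.path(dir, "blast.tsv"))
  .output_lines(sub("\n$", "", bundle$blast_xml), file.path(dir, "blast.xml"))
  p <- bundle$planted
  .output_lines(c(paste(c("query", colnames(p)), collapse = "\t"),
                  vapply(seq_len(nrow(p)), function(i) {
                    paste(c(rownames(p)[i], p[i, ]), collapse = "\t")
                  }, character(1))),
                file.path(dir, "planted.tsv"))
  invisible(dir)
}
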