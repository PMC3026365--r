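# Newick serialization (via ape) with label sanitization, plus a minimal
# SVG cladogram renderer for tree artifacts.

# Replace Newick-breaking characters in labels and resolve any collisions;
# returns the sanitized labels plus the original strings for reversal.
.sanitize_labels <- function(labels) {
  clean <- gsub("[][ (),:;'\t]", "_", labels)
  while (anyDuplicated(clean)) {
    dup <- which(duplicated(clean) | duplicated(clean, fromLast = TRUE))
    clean[dup] <- paste0(clean[dup], "_", seq_along(dup))
  }
  list(labels = clean, original = labels,
       changed = any(clean != labels))
}

#' Write a tree as Newick
#'
#' Standard Newick with branch lengths, terminated by `;`. Labels
#' containing Newick metacharacters (space, parentheses, comma, colon,
#' semicolon, quote) are replaced via a sanitization map returned in the
#' `sanitization_map` attribute.
#'
#' @param tree a `phylo` object.
#' @param file path, connection, or `NULL` to return text invisibly.
#' @return the Newick string, invisibly; attribute `sanitization_map` is a
#'   named character vector (sanitized -> original) when renaming occurred.
#' @export
write_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "phylo"))
  san <- .sanitize_labels(tree$tip.label)
  tree$tip.label <- san$labels
  nwk <- ape::write.tree(tree, digits = 12)
  out <- .output_lines(nwk, file)
  if (san$changed) {
    attr(out, "sanitization_map") <- stats::setNames(san$original, san$labels)
  }
  invisible(out)
}

#' Parse a Newick tree
#'
#' Validates balance and termination before parsing (reporting the byte
#' position of the first unbalanced parenthesis or the missing `;`), then
#' reads the tree with ape.
#'
#' @inheritParams read_fasta
#' @return a `phylo` object.
#' @export
parse_newick <- function(file, text = NULL) {
  s <- trimws(.input_string(file, text))
  if (!nzchar(s)) stop("Newick parse error: empty input", call. = FALSE)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (k in seq_along(chars)) {
    if (chars[k] == "(") depth <- depth + 1L
    if (chars[k] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop(sprintf("Newick parse error at position %d: unbalanced ')'", k),
             call. = FALSE)
      }
    }
  }
  if (depth > 0L) {
    stop(sprintf("Newick parse error at position %d: %d unclosed '('",
                 length(chars), depth), call. = FALSE)
  }
  if (!endsWith(s, ";")) {
    stop(sprintf("Newick parse error at position %d: missing terminating ';'",
                 length(chars)), call. = FALSE)
  }
  tree <- tryCatch(ape::read.tree(text = s), error = function(e) NULL,
                   warning = function(w) NULL)
  if (is.null(tree)) stop("Newick parse error: malformed tree", call. = FALSE)
  tree
}

#' Render a tree as a minimal SVG cladogram
#'
#' Rectangular-edge layout with branch lengths on the horizontal axis; a
#' lightweight artifact renderer, not a publication figure.
#'
#' @param tree a `phylo` object.
#' @param file path, connection, or `NULL` to return the SVG text invisibly.
#' @param width,height canvas size in pixels.
#' @return the SVG text, invisibly.
#' @export
export_tree_svg <- function(tree, file = NULL, width = 640, height = NULL) {
  stopifnot(inherits(tree, "phylo"))
  nt <- length(tree$tip.label)
  if (is.null(height)) height <- 30 * nt + 40
  nn <- nt + tree$Nnode
  root <- nt + 1L
  el <- if (is.null(tree$edge.length)) rep(1, nrow(tree$edge)) else tree$edge.length
  xdepth <- rep(NA_real_, nn); xdepth[root] <- 0
  ord <- ape::reorder.phylo(tree, "cladewise")
  el_ord <- if (is.null(tree$edge.length)) rep(1, nrow(ord$edge)) else ord$edge.length
  for (k in seq_len(nrow(ord$edge))) {
    xdepth[ord$edge[k, 2]] <- xdepth[ord$edge[k, 1]] + el_ord[k]
  }
  y <- rep(NA_real_, nn)
  y[seq_len(nt)] <- seq_len(nt)
  repeat {
    done <- TRUE
    for (node in seq.int(nt + 1L, nn)) {
      if (is.na(y[node])) {
        kids <- tree$edge[tree$edge[, 1] == node, 2]
        if (all(!is.na(y[kids]))) y[node] <- mean(range(y[kids])) else done <- FALSE
      }
    }
    if (done) break
  }
  xmax <- max(xdepth, na.rm = TRUE)
  if (xmax <= 0) xmax <- 1
  margin <- 20; label_w <- 150
  sx <- function(v) margin + v / xmax * (width - margin * 2 - label_w)
  sy <- function(v) margin + (v - 1) / max(1, nt - 1) * (height - margin * 2)
  l <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
                 as.integer(width), as.integer(height)),
         '  <g stroke="black" fill="none" stroke-width="1">')
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]; c2 <- tree$edge[k, 2]
    l <- c(l, sprintf('    <path d="M %.2f %.2f V %.2f H %.2f"/>',
                      sx(xdepth[p]), sy(y[p]), sy(y[c2]), sx(xdepth[c2])))
  }
  l <- c(l, '  </g>', '  <g font-family="monospace" font-size="12">')
  for (t in seq_len(nt)) {
    l <- c(l, sprintf('    <text x="%.2f" y="%.2f">%s</text>',
                      sx(xdepth[t]) + 4, sy(y[t]) + 4,
                      .xml_escape(tree$tip.label[t])))
  }
  l <- c(l, '  </g>', '</svg>')
  .output_lines(l, file)
}
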