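# Built-in neighbor-joining (Saitou-Nei agglomeration with the
# Studier-Keppler Q criterion), the distance-based fallback tree method of
# the pipeline. On an additive distance matrix it recovers the generating
# topology and branch lengths exactly.

#' Neighbor-joining tree inference
#'
#' Iteratively joins the pair of clusters minimizing
#' `Q(i,j) = (n-2) d(i,j) - R_i - R_j` (R = row sums of the current
#' matrix). Branch lengths at a join are
#' `l_i = d(i,j)/2 + (R_i - R_j) / (2(n-2))`, `l_j = d(i,j) - l_i`; the
#' reduced distances are `d(u,k) = (d(i,k) + d(j,k) - d(i,j)) / 2`. Q ties
#' are broken by the lexicographically smallest pair of cluster ids, where
#' a merged cluster is identified by its smallest member leaf id, making
#' the output fully deterministic. The final three clusters are joined on
#' a trifurcating internal node (unrooted tree); `n = 2` yields the
#' two-leaf tree with the distance split evenly.
#'
#' @param d symmetric numeric matrix with zero diagonal and leaf ids as
#'   dimnames (e.g. from [distance_matrix()]).
#' @param clamp_negative logical; clamp negative branch lengths to zero
#'   (default keeps them, preserving additivity).
#' @return an unrooted tree of class `phylo` (ape).
#' @export
neighbor_joining <- function(d, clamp_negative = FALSE) {
  stopifnot(is.matrix(d), is.numeric(d))
  n <- nrow(d)
  if (n < 2L) stop("neighbor joining requires at least 2 taxa", call. = FALSE)
  if (ncol(d) != n) stop("distance matrix must be square", call. = FALSE)
  ids <- rownames(d)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("distance matrix must have unique rownames (leaf ids)", call. = FALSE)
  }
  if (max(abs(d - t(d))) > 1e-8 || any(abs(diag(d)) > 1e-12)) {
    stop("distance matrix must be symmetric with zero diagonal", call. = FALSE)
  }
  if (any(d < 0)) stop("distances must be non-negative", call. = FALSE)
  bl <- function(x) if (clamp_negative) max(x, 0) else x
  blfmt <- function(x) sprintf("%.15g", bl(x))
  san <- .sanitize_labels(ids)
  # each active cluster: newick fragment + representative id for tie-breaks
  frag <- as.list(san$labels)
  rep_id <- ids
  D <- unname(d)
  while (length(frag) > 3L) {
    m <- length(frag)
    R <- rowSums(D)
    Q <- (m - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- vapply(seq_len(nrow(cand)), function(k) {
      pr <- sort(c(rep_id[cand[k, 1]], rep_id[cand[k, 2]]))
      paste(pr, collapse = "\r")
    }, character(1))
    pick <- cand[order(key)[1L], ]
    i <- pick[[1]]; j <- pick[[2]]
    dij <- D[i, j]
    li <- dij / 2 + (R[i] - R[j]) / (2 * (m - 2))
    lj <- dij - li
    # canonical child order (smaller representative first) so relabeled or
    # permuted input matrices serialize identically
    new_frag <- if (rep_id[i] <= rep_id[j]) {
      sprintf("(%s:%s,%s:%s)", frag[[i]], blfmt(li), frag[[j]], blfmt(lj))
    } else {
      sprintf("(%s:%s,%s:%s)", frag[[j]], blfmt(lj), frag[[i]], blfmt(li))
    }
    new_rep <- min(rep_id[i], rep_id[j])
    dnew <- (D[i, ] + D[j, ] - dij) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    frag <- c(frag[keep], list(new_frag))
    rep_id <- c(rep_id[keep], new_rep)
  }
  if (length(frag) == 2L) {
    o2 <- order(rep_id)
    nwk <- sprintf("(%s:%s,%s:%s);", frag[[o2[1]]], blfmt(D[1, 2] / 2),
                   frag[[o2[2]]], blfmt(D[1, 2] / 2))
  } else {
    # three-point formulas for the central node
    la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
    lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
    lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
    o <- order(rep_id)
    lens <- c(la, lb, lc)[o]
    nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                   frag[[o[1]]], blfmt(lens[1]),
                   frag[[o[2]]], blfmt(lens[2]),
                   frag[[o[3]]], blfmt(lens[3]))
  }
  tree <- ape::read.tree(text = nwk)
  # restore original labels through the sanitization map
  tree$tip.label <- san$original[match(tree$tip.label, san$labels)]
  tree
}
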