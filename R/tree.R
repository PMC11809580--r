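#' @importFrom stats optimize setNames sd rmultinom qnorm pnorm dnorm qgamma
#'   pgamma runif rexp
#' @importFrom utils head combn write.csv read.csv
#' @importFrom ape read.tree write.tree drop.tip unroot collapse.singles
NULL

#' Parse a Newick string into an unrooted binary tree
#'
#' Trees are represented as [ape::phylo] objects, kept unrooted and binary:
#' every internal node has degree 3. A rooted input is unrooted by
#' suppressing the degree-2 root node, summing the lengths of its two
#' incident edges (as [ape::unroot] does). Internal-node labels, when
#' numeric, are interpreted as bootstrap-style support values in `[0, 100]`
#' of the edge subtending that node (the usual IQ-TREE/UFBoot convention);
#' leaf edges carry no support. Missing branch lengths are set to 0.
#'
#' @param text a Newick description with at least 3 leaves.
#' @return an unrooted binary `phylo` object.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  pos <- newick_paren_check(text)
  if (!is.na(pos)) {
    stop("malformed Newick string: unbalanced parenthesis at position ", pos)
  }
  tr <- tryCatch(
    suppressWarnings(ape::read.tree(text = text)),
    error = function(e) NULL
  )
  if (is.null(tr) || !inherits(tr, "phylo")) {
    stop("malformed Newick string: could not be parsed")
  }
  as_unrooted_tree(tr)
}

## first position where the parenthesis nesting breaks, NA if balanced
newick_paren_check <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) return(i)
  }
  if (depth != 0L) return(nchar(text))
  NA_integer_
}

#' Coerce a phylo object to the package's unrooted binary form
#'
#' @param tree a `phylo` object.
#' @return validated unrooted binary `phylo`.
#' @export
as_unrooted_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 3L) {
    stop("tree must have at least 3 leaves, got ", length(tree$tip.label))
  }
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  tree$edge.length[is.na(tree$edge.length)] <- 0
  if (ape::is.rooted(tree)) {
    tree <- ape::unroot(tree)
  }
  tree <- ape::collapse.singles(tree)
  validate_unrooted_tree(tree)
  tree
}

#' Validate the unrooted binary tree invariants
#'
#' Checks leaf-label uniqueness, nonnegative branch lengths, and the
#' degree-3 internal-node structure (an n-leaf unrooted binary tree has
#' exactly 2n - 3 edges and n - 2 internal nodes).
#'
#' @param tree a `phylo` object.
#' @return invisibly `TRUE`; errors otherwise.
#' @export
validate_unrooted_tree <- function(tree) {
  n <- length(tree$tip.label)
  if (n < 3L) stop("tree must have at least 3 leaves, got ", n)
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  }
  if (any(!nzchar(tree$tip.label))) stop("empty leaf label")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  if (tree$Nnode != n - 2L) {
    stop("tree is not an unrooted binary tree: ", tree$Nnode,
         " internal nodes for ", n, " leaves (expected ", n - 2L, ")")
  }
  if (nrow(tree$edge) != 2L * n - 3L) {
    stop("tree has ", nrow(tree$edge), " edges, expected ", 2L * n - 3L)
  }
  deg <- tabulate(c(tree$edge[, 1], tree$edge[, 2]), nbins = n + tree$Nnode)
  if (any(deg[seq_len(n)] != 1L)) stop("leaf of degree != 1")
  if (any(deg[-seq_len(n)] != 3L)) stop("internal node of degree != 3")
  invisible(TRUE)
}

#' Write a tree as a Newick string
#'
#' Edge supports (internal-node labels) and branch lengths round-trip
#' through [parse_newick()].
#'
#' @param tree a `phylo` object.
#' @param file optional path; when `NULL` the string is returned.
#' @return the Newick string (invisibly when writing to file).
#' @export
write_newick <- function(tree, file = NULL) {
  txt <- ape::write.tree(tree, digits = 12)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

## ---- splits ---------------------------------------------------------------

## logical node x tip membership matrix: tips on the child side of each node
tips_below <- function(tree) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  below <- matrix(FALSE, nrow = nn, ncol = n)
  below[cbind(seq_len(n), seq_len(n))] <- TRUE
  po <- reorder(tree, "postorder")$edge
  for (i in seq_len(nrow(po))) {
    below[po[i, 1], ] <- below[po[i, 1], ] | below[po[i, 2], ]
  }
  below
}

split_sep <- "\t"

#' Canonical key of a bipartition
#'
#' The canonical string form of the split `{block, complement}` of
#' `leaves`: the block not containing the lexicographically smallest
#' leaf, sorted and concatenated.
#'
#' @param block character vector, one block of the bipartition.
#' @param leaves the full leaf-label set.
#' @return a character key, comparable across trees on the same leaves.
#' @export
canonical_split <- function(block, leaves) {
  ref <- min(leaves)
  if (ref %in% block) block <- setdiff(leaves, block)
  paste(sort(block), collapse = split_sep)
}

split_block <- function(key) strsplit(key, split_sep, fixed = TRUE)[[1]]

#' Nontrivial splits of an unrooted tree
#'
#' One split per internal edge (an n-leaf binary tree has n - 3 of them),
#' in a canonical string form: the bipartition block not containing the
#' lexicographically smallest leaf, sorted and concatenated. Names give the
#' row index of the corresponding edge in `tree$edge`.
#'
#' @param tree a `phylo` object.
#' @return named character vector of canonical split keys.
#' @export
tree_splits <- function(tree) {
  n <- length(tree$tip.label)
  below <- tips_below(tree)
  idx <- internal_edges(tree)
  keys <- vapply(idx, function(e) {
    block <- tree$tip.label[below[tree$edge[e, 2], ]]
    canonical_split(block, tree$tip.label)
  }, character(1))
  setNames(keys, idx)
}

#' Indices of internal (nontrivial-split) edges
#' @param tree a `phylo` object.
#' @return integer vector of row indices into `tree$edge`.
#' @export
internal_edges <- function(tree) {
  which(tree$edge[, 2] > length(tree$tip.label))
}

#' Index of the pendant edge of a leaf
#' @param tree a `phylo` object.
#' @param label a leaf label.
#' @return the row index into `tree$edge`.
#' @export
leaf_edge <- function(tree, label) {
  tip <- match(label, tree$tip.label)
  if (is.na(tip)) stop("leaf '", label, "' not in tree")
  which(tree$edge[, 2] == tip)
}

#' Robinson-Foulds distance between two unrooted trees
#'
#' The size of the symmetric difference of the two nontrivial split sets.
#' Zero iff the topologies agree; at most 2(n - 3) for n-leaf trees.
#'
#' @param t1,t2 `phylo` objects on identical leaf-label sets.
#' @return nonnegative integer.
#' @export
rf_distance <- function(t1, t2) {
  l1 <- sort(t1$tip.label)
  l2 <- sort(t2$tip.label)
  if (!identical(l1, l2)) {
    stop("leaf sets differ: only in first tree {",
         paste(setdiff(l1, l2), collapse = ", "), "}, only in second {",
         paste(setdiff(l2, l1), collapse = ", "), "}")
  }
  s1 <- tree_splits(t1)
  s2 <- tree_splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

#' Prune a leaf from an unrooted tree
#'
#' Removes the leaf and its pendant edge; the resulting degree-2 node is
#' suppressed and its two incident edge lengths are summed. Supports of
#' surviving internal edges are preserved.
#'
#' @param tree a `phylo` object with at least 4 leaves.
#' @param label the leaf to remove.
#' @return an unrooted binary `phylo` on the remaining leaves.
#' @export
prune_taxon <- function(tree, label) {
  if (!label %in% tree$tip.label) stop("leaf '", label, "' not in tree")
  if (length(tree$tip.label) < 4L) {
    stop("pruning would leave fewer than 3 leaves")
  }
  res <- ape::drop.tip(tree, label, collapse.singles = TRUE)
  res <- as_unrooted_tree(res)
  res
}

## ---- topological (node-count) distances between edges ---------------------

## all-pairs node distances in edge counts (unweighted BFS on the tree graph)
node_hop_matrix <- function(tree) {
  nn <- length(tree$tip.label) + tree$Nnode
  adj <- vector("list", nn)
  for (i in seq_len(nrow(tree$edge))) {
    a <- tree$edge[i, 1]; b <- tree$edge[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  d <- matrix(NA_integer_, nn, nn)
  for (s in seq_len(nn)) {
    dist <- rep(NA_integer_, nn)
    dist[s] <- 0L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
      }
    }
    d[s, ] <- dist
  }
  d
}

#' Node-count distance between two edges
#'
#' The number of nodes on the unique path connecting the two edges,
#' counted inclusively: 0 for the same edge, 1 for edges sharing a node.
#'
#' @param tree a `phylo` object.
#' @param e1,e2 row indices into `tree$edge`.
#' @param hops optional precomputed [node_hop_matrix] (internal use).
#' @return nonnegative integer.
#' @export
edge_node_distance <- function(tree, e1, e2, hops = NULL) {
  m <- nrow(tree$edge)
  if (e1 < 1L || e1 > m || e2 < 1L || e2 > m) stop("edge index not in tree")
  if (e1 == e2) return(0L)
  if (is.null(hops)) hops <- node_hop_matrix(tree)
  a <- tree$edge[e1, ]; b <- tree$edge[e2, ]
  min(hops[a[1], b[1]], hops[a[1], b[2]],
      hops[a[2], b[1]], hops[a[2], b[2]]) + 1L
}

#' Matrix of node-count distances between all edges of a tree
#' @param tree a `phylo` object.
#' @return integer matrix, one row/column per row of `tree$edge`.
#' @export
edge_dist_matrix <- function(tree) {
  hops <- node_hop_matrix(tree)
  m <- nrow(tree$edge)
  out <- matrix(0L, m, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i != j) out[i, j] <- edge_node_distance(tree, i, j, hops)
    }
  }
  out
}

## ---- edge supports --------------------------------------------------------

#' Supports of the edges of a tree
#'
#' Internal-node labels are read as supports of the edge subtending the
#' node; leaf edges and edges whose label is empty/non-numeric get `NA`.
#'
#' @param tree a `phylo` object.
#' @return numeric vector, one entry per row of `tree$edge`.
#' @export
edge_supports <- function(tree) {
  m <- nrow(tree$edge)
  sup <- rep(NA_real_, m)
  if (is.null(tree$node.label)) return(sup)
  n <- length(tree$tip.label)
  for (e in internal_edges(tree)) {
    lbl <- tree$node.label[tree$edge[e, 2] - n]
    if (!is.null(lbl) && !is.na(lbl) && nzchar(lbl)) {
      val <- suppressWarnings(as.numeric(lbl))
      sup[e] <- val
    }
  }
  sup
}

#' Attach per-edge supports to a tree as internal-node labels
#' @param tree a `phylo` object.
#' @param supports numeric vector, one per row of `tree$edge` (`NA` allowed
#'   on leaf edges, which carry no support).
#' @return the tree with `node.label` set.
#' @export
set_edge_supports <- function(tree, supports) {
  stopifnot(length(supports) == nrow(tree$edge))
  n <- length(tree$tip.label)
  lab <- rep("", tree$Nnode)
  for (e in internal_edges(tree)) {
    if (!is.na(supports[e])) {
      lab[tree$edge[e, 2] - n] <- format(supports[e], digits = 6)
    }
  }
  tree$node.label <- lab
  tree
}
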