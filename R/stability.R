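#' Taxon influence index
#'
#' Robinson-Foulds distance between the pruned tree (full tree with the
#' focal taxon removed) and the inferred tree (re-inferred without the
#' taxon), plus its normalized form: the RF distance divided by
#' 2(m - 3), the maximum possible RF distance between two trees on the
#' m leaves actually compared. A TII of 0 means the inference is stable
#' for the addition of this taxon.
#'
#' @param pruned,inferred `phylo` objects on identical leaf sets (both
#'   lacking the focal taxon).
#' @return list with `tii` (integer) and `tii_norm` in `[0, 1]`.
#' @export
tii <- function(pruned, inferred) {
  d <- rf_distance(pruned, inferred)
  m <- length(pruned$tip.label)
  denom <- 2L * (m - 3L)
  list(tii = d, tii_norm = if (denom > 0) d / denom else 0)
}

#' Is a full-tree split still present after removing the focal taxon?
#'
#' A split of the full tree counts as present in the inferred tree when
#' deleting the focal taxon from it yields either a trivial split (a
#' block of size <= 1, induced by a pendant edge of every tree) or a
#' split induced by some edge of the inferred tree.
#'
#' @param block character vector: one block of the full-tree split (the
#'   other block is its complement in the full leaf set).
#' @param inferred the inferred tree (without `s`).
#' @param s the focal taxon.
#' @param full_leaves leaf set of the full tree.
#' @param inferred_splits optional precomputed [tree_splits] of `inferred`.
#' @return logical.
#' @export
edge_present_after_removal <- function(block, inferred, s, full_leaves,
                                       inferred_splits = tree_splits(inferred)) {
  blk <- setdiff(block, s)
  other <- setdiff(setdiff(full_leaves, block), s)
  if (length(blk) <= 1L || length(other) <= 1L) return(TRUE)
  key <- canonical_split(blk, inferred$tip.label)
  key %in% inferred_splits
}

#' Disruption radius of a taxon addition
#'
#' The maximum node-count distance from the focal taxon's pendant edge in
#' the full tree to any internal edge of the full tree whose split (after
#' removing the taxon) is absent from the inferred tree; 0 when no edge
#' differs. Normalized by the maximum distance of any internal edge to
#' the taxon's pendant edge.
#'
#' @param full the full tree (contains `s`).
#' @param inferred the inferred tree (leaves = leaves(full) minus `s`).
#' @param s the focal taxon.
#' @return list with `raw` (integer) and `normalized` in `[0, 1]`.
#' @export
disruption_radius <- function(full, inferred, s) {
  if (!setequal(setdiff(full$tip.label, s), inferred$tip.label)) {
    stop("leaf sets incompatible: inferred must equal full minus '", s, "'")
  }
  e_s <- leaf_edge(full, s)
  hops <- node_hop_matrix(full)
  ie <- internal_edges(full)
  if (!length(ie)) return(list(raw = 0L, normalized = 0))
  dists <- vapply(ie, function(e) edge_node_distance(full, e_s, e, hops),
                  integer(1))
  below <- tips_below(full)
  inf_splits <- tree_splits(inferred)
  absent <- vapply(seq_along(ie), function(i) {
    block <- full$tip.label[below[full$edge[ie[i], 2], ]]
    !edge_present_after_removal(block, inferred, s, full$tip.label,
                                inf_splits)
  }, logical(1))
  denom <- max(dists)
  raw <- if (any(absent)) max(dists[absent]) else 0L
  list(raw = as.integer(raw),
       normalized = if (denom > 0) raw / denom else 0)
}

#' Mean distance of unstable edges to low-support edges
#'
#' For each internal edge of the inferred tree whose split is absent from
#' the pruned tree ("unstable" edge), the node-count distance to the
#' closest edge with bootstrap support below `threshold`, normalized
#' per edge by that edge's maximum distance to any internal edge; the
#' mean over unstable edges is returned. `NA` when no unstable edge
#' exists (stable case). When the tree has no low-support edge at all,
#' each per-edge term is set to 1 (maximal: the unstable edge is far from
#' any region of uncertainty).
#'
#' @param inferred the inferred tree, carrying supports.
#' @param pruned the pruned tree (identical leaf set).
#' @param threshold low-support cutoff in percent (default 70).
#' @return mean normalized distance, or `NA_real_` when stable.
#' @export
unstable_to_low_support_distance <- function(inferred, pruned,
                                             threshold = 70) {
  sup <- edge_supports(inferred)
  ie <- internal_edges(inferred)
  if (all(is.na(sup[ie]))) stop("inferred tree carries no support values")
  inf_splits <- tree_splits(inferred)
  pr_splits <- tree_splits(pruned)
  unstable <- as.integer(names(inf_splits)[!(inf_splits %in% pr_splits)])
  if (!length(unstable)) return(NA_real_)
  low <- which(!is.na(sup) & sup < threshold)
  hops <- node_hop_matrix(inferred)
  terms <- vapply(unstable, function(e) {
    denom <- max(vapply(ie, function(j)
      edge_node_distance(inferred, e, j, hops), integer(1)))
    if (!length(low)) return(1)
    d <- min(vapply(low, function(j)
      edge_node_distance(inferred, e, j, hops), integer(1)))
    if (denom > 0) d / denom else 0
  }, numeric(1))
  mean(terms)
}

#' Assemble the per-taxon stability record
#'
#' @param s focal taxon.
#' @param full full tree (with supports or not).
#' @param inferred inferred tree on the reduced alignment (with supports
#'   for the low-support distance; `NA` is reported when absent).
#' @param pruned full tree with `s` pruned.
#' @param au_p,sh_p topology-test p-values (only defined for unstable
#'   additions; pass `NA` otherwise).
#' @param alpha significance level for the instability label.
#' @return one-row data frame.
#' @export
stability_record <- function(s, full, inferred, pruned,
                             au_p = NA_real_, sh_p = NA_real_,
                             alpha = 0.05) {
  ti <- tii(pruned, inferred)
  dr <- disruption_radius(full, inferred, s)
  low <- if (ti$tii > 0 && !all(is.na(edge_supports(inferred)))) {
    unstable_to_low_support_distance(inferred, pruned)
  } else NA_real_
  data.frame(
    taxon = s,
    tii = ti$tii,
    tii_norm = ti$tii_norm,
    disruption_radius = dr$normalized,
    mean_unstable_low_support_dist = low,
    au_p = au_p,
    sh_p = sh_p,
    stable = ti$tii == 0L,
    significant_instability = ti$tii != 0L && !is.na(au_p) && au_p < alpha,
    stringsAsFactors = FALSE
  )
}
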