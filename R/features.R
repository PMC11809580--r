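## Summary statistics for predicting stability. All are computed from the
## inferred tree Ts*, the placement of the focal taxon, the augmented tree
## Ts+, and the alignment -- never from the full tree, so they remain
## cheap predictors rather than a direct assay of stability. Standard
## deviations are population SDs (divide by N) throughout, which stay
## well-defined for N = 1.

pop_sd <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) <= 1L) return(0)
  sqrt(mean((x - mean(x))^2))
}

#' Spread of high-quality insertion locations
#'
#' Mean and population SD of node-count distances between all pairs of
#' candidate insertion edges, normalized by the maximum distance between
#' any two edges of the inferred tree. A single candidate (LWR > 0.99)
#' gives (0, 0).
#'
#' @param placement a `placement_set`.
#' @param tree the inferred tree the placement was computed on.
#' @return list with `insertion_dist_mean` and `insertion_dist_sd`.
#' @export
insertion_distance_stats <- function(placement, tree) {
  edges <- placement$edge
  if (length(edges) < 2L) {
    return(list(insertion_dist_mean = 0, insertion_dist_sd = 0))
  }
  dm <- edge_dist_matrix(tree)
  diam <- max(dm)
  pairs <- combn(edges, 2)
  d <- dm[cbind(pairs[1, ], pairs[2, ])] / diam
  list(insertion_dist_mean = mean(d), insertion_dist_sd = pop_sd(d))
}

#' Branch-length features of the best insertion
#'
#' Insertion-branch and pendant lengths are normalized by the mean branch
#' length of the augmented tree; the distance to the nearest node is the
#' ratio of the shorter of the two pieces of the split insertion branch
#' to its full length (0 for a zero-length insertion branch, at most
#' 0.5 for a midpoint attachment).
#'
#' @param tree the inferred tree.
#' @param placement a `placement_set`.
#' @param tplus the augmented tree from [best_placement_tree()].
#' @return list with `insertion_branch_length`, `norm_dist_nearest_node`,
#'   `pendant_length`.
#' @export
branch_features <- function(tree, placement, tplus) {
  best <- placement[1, ]
  b <- tree$edge.length[best$edge]
  mean_bl <- mean(tplus$edge.length)
  ndn <- if (b > 0) min(best$distal_length, b - best$distal_length) / b else 0
  list(
    insertion_branch_length = if (mean_bl > 0) b / mean_bl else 0,
    norm_dist_nearest_node = ndn,
    pendant_length = if (mean_bl > 0) best$pendant_length / mean_bl else 0
  )
}

#' Bootstrap-support features
#'
#' Mean and population SD over the internal-edge supports of the
#' inferred tree, and the node-count distance from the best insertion
#' edge to the nearest low-support (< `threshold`) edge, normalized by
#' the maximum distance of any edge to the insertion edge; 1 when the
#' tree has no low-support edge.
#'
#' @param tree the inferred tree carrying supports.
#' @param placement a `placement_set`.
#' @param threshold low-support cutoff in percent.
#' @return list with `bootstrap_mean`, `bootstrap_sd`,
#'   `dist_low_bootstrap_edge`.
#' @export
support_features <- function(tree, placement, threshold = 70) {
  sup <- edge_supports(tree)
  ie <- internal_edges(tree)
  vals <- sup[ie]
  if (all(is.na(vals))) stop("inferred tree carries no support values")
  best_edge <- placement$edge[1]
  dm <- edge_dist_matrix(tree)
  denom <- max(dm[best_edge, ])
  low <- which(!is.na(sup) & sup < threshold)
  d <- if (!length(low)) 1
       else if (denom > 0) min(dm[best_edge, low]) / denom
       else 0
  list(bootstrap_mean = mean(vals, na.rm = TRUE),
       bootstrap_sd = pop_sd(vals),
       dist_low_bootstrap_edge = d)
}

#' Sequence-versus-patristic distance features of the added taxon
#'
#' For every other taxon t, `ratio_t = seqdist(t, s) / patristic(t, s)`
#' in the augmented tree: mean and SD over t (`distance_ratio_*`). For
#' the closest-sequence comparison, with c the taxon nearest to s in
#' sequence distance, the per-taxon quantity is
#' `ratio_t(s) / ratio_t(c)` over the remaining taxa
#' (`ratio_diff_closest_*`). The sibling statistic `as/aC` compares the
#' mean sequence distance of s to the insertion edge's sister clade C'
#' with the mean pairwise sequence distance between the inserted-below
#' clade C and C'.
#'
#' @param aln the full alignment (contains `s`).
#' @param s the added taxon.
#' @param tree the inferred tree (without `s`).
#' @param placement a `placement_set`.
#' @param tplus the augmented tree.
#' @param model a [subst_model].
#' @param D optional precomputed [corrected_distance_matrix] of `aln`.
#' @return list of the five statistics.
#' @export
sequence_distance_features <- function(aln, s, tree, placement, tplus,
                                       model, D = NULL) {
  if (is.null(D)) D <- corrected_distance_matrix(aln, model)
  pat_d <- ape::cophenetic.phylo(tplus)
  taxa <- setdiff(tplus$tip.label, s)
  pd <- pat_d[taxa, s]
  if (any(pd == 0)) {
    stop("zero patristic distance to pair: ", taxa[which(pd == 0)[1]], " / ", s)
  }
  ratio_s <- D[taxa, s] / pd
  cl <- taxa[which.min(D[taxa, s])]
  rest <- setdiff(taxa, cl)
  pd_c <- pat_d[rest, cl]
  if (any(pd_c == 0)) {
    stop("zero patristic distance to pair: ", rest[which(pd_c == 0)[1]],
         " / ", cl)
  }
  ratio_c <- D[rest, cl] / pd_c
  rel <- (D[rest, s] / pat_d[rest, s]) / ratio_c

  sib <- insertion_sibling_ratio(aln, s, tree, placement, D)
  list(distance_ratio_mean = mean(ratio_s),
       distance_ratio_sd = pop_sd(ratio_s),
       ratio_diff_closest_mean = mean(rel),
       ratio_diff_closest_sd = pop_sd(rel),
       dist_diff_insertion_sibling = sib)
}

## as/aC: C = leaf block of the best insertion edge on the far side from
## the canonical reference leaf; at the other endpoint the smaller of the
## two remaining subtrees is the sister C' (ties broken by canonical
## order of the subtree's smallest member)
insertion_sibling_ratio <- function(aln, s, tree, placement, D) {
  e <- placement$edge[1]
  n <- length(tree$tip.label)
  below <- tips_below(tree)
  ref <- min(tree$tip.label)
  blk <- tree$tip.label[below[tree$edge[e, 2], ]]
  has_ref <- ref %in% blk
  C <- if (has_ref) setdiff(tree$tip.label, blk) else blk
  v <- if (has_ref) tree$edge[e, 2] else tree$edge[e, 1]
  if (v <= n) {
    ## insertion on the reference leaf's own pendant edge: the leaf
    ## itself is the only subtree on that side
    Cp <- tree$tip.label[v]
  } else {
    inc <- setdiff(which(tree$edge[, 1] == v | tree$edge[, 2] == v), e)
    cand <- lapply(inc, function(j) {
      if (tree$edge[j, 1] == v) tree$tip.label[below[tree$edge[j, 2], ]]
      else setdiff(tree$tip.label, tree$tip.label[below[v, ]])
    })
    cand <- Filter(function(x) length(x) > 0 && !any(x %in% C), cand)
    if (!length(cand)) return(NA_real_)
    ord <- order(lengths(cand), vapply(cand, min, character(1)))
    Cp <- cand[[ord[1]]]
  }
  a_s <- mean(D[s, Cp])
  a_C <- mean(D[C, Cp, drop = FALSE])
  if (a_C == 0) return(NA_real_)
  a_s / a_C
}

#' Insertion height
#'
#' Patristic distance from the attachment point of the added taxon in
#' the augmented tree to the nearest other leaf, normalized by half the
#' patristic leaf-pair diameter.
#'
#' @param tplus the augmented tree (contains `s`).
#' @param s the added taxon.
#' @return normalized height in `[0, 1]`.
#' @export
insertion_height <- function(tplus, s) {
  tip <- match(s, tplus$tip.label)
  e <- which(tplus$edge[, 2] == tip)
  m <- tplus$edge[e, 1]                 # attachment node
  nd <- ape::dist.nodes(tplus)
  others <- setdiff(seq_along(tplus$tip.label), tip)
  raw <- min(nd[m, others])
  diam <- max(nd[others, others])
  if (diam == 0) return(0)
  raw / (diam / 2)
}

#' Neighbor-joining taxon influence index feature
#'
#' Normalized TII of `s` computed entirely with neighbor joining on
#' model-corrected distances: NJ tree on the full alignment pruned of
#' `s`, versus NJ tree on the alignment without `s`. `NA` when the
#' alignment has fewer than 5 taxa.
#'
#' @param aln the full alignment.
#' @param s the focal taxon.
#' @param model a [subst_model].
#' @param D optional precomputed distance matrix of `aln`.
#' @return normalized TII in `[0, 1]`, or `NA`.
#' @export
nj_tii_feature <- function(aln, s, model, D = NULL) {
  if (nrow(aln) < 5L) return(NA_real_)
  if (is.null(D)) D <- corrected_distance_matrix(aln, model)
  full_nj <- nj_tree(D)
  red <- setdiff(rownames(aln), s)
  reduced_nj <- nj_tree(D[red, red])
  pruned_nj <- prune_taxon(full_nj, s)
  tii(pruned_nj, reduced_nj)$tii_norm
}

#' Assemble one feature vector for a taxon addition
#'
#' Combines all summary statistics into a single row; any sub-feature
#' that fails is recorded as `NA` (missing, never zero-filled) and the
#' failure is signalled as a warning.
#'
#' @param aln full alignment.
#' @param s focal taxon.
#' @param tree inferred tree (with supports).
#' @param placement a `placement_set` of `s` on `tree`.
#' @param tplus augmented tree.
#' @param model a [subst_model].
#' @param pythia_difficulty optional externally supplied difficulty score
#'   in `[0, 1]` (never computed internally).
#' @param D optional precomputed distance matrix of `aln`.
#' @return one-row data frame of the feature battery.
#' @export
assemble_features <- function(aln, s, tree, placement, tplus, model,
                              pythia_difficulty = NA_real_, D = NULL) {
  grab <- function(expr) {
    tryCatch(expr, error = function(e) {
      warning("feature failed for taxon '", s, "': ", conditionMessage(e))
      NULL
    })
  }
  ins <- grab(insertion_distance_stats(placement, tree))
  br <- grab(branch_features(tree, placement, tplus))
  sup <- grab(support_features(tree, placement))
  sq <- grab(sequence_distance_features(aln, s, tree, placement, tplus,
                                        model, D = D))
  hei <- grab(insertion_height(tplus, s))
  njt <- grab(nj_tii_feature(aln, s, model, D = D))
  na_or <- function(x, field = NULL) {
    if (is.null(x)) return(NA_real_)
    if (!is.null(field)) x <- x[[field]]
    if (is.null(x)) NA_real_ else x
  }
  data.frame(
    taxon = s,
    insertion_dist_mean = na_or(ins, "insertion_dist_mean"),
    insertion_dist_sd = na_or(ins, "insertion_dist_sd"),
    lwr = placement$lwr[1],
    n_insertion_locations = nrow(placement),
    insertion_branch_length = na_or(br, "insertion_branch_length"),
    norm_dist_nearest_node = na_or(br, "norm_dist_nearest_node"),
    pendant_length = na_or(br, "pendant_length"),
    dist_low_bootstrap_edge = na_or(sup, "dist_low_bootstrap_edge"),
    bootstrap_mean = na_or(sup, "bootstrap_mean"),
    bootstrap_sd = na_or(sup, "bootstrap_sd"),
    distance_ratio_mean = na_or(sq, "distance_ratio_mean"),
    distance_ratio_sd = na_or(sq, "distance_ratio_sd"),
    ratio_diff_closest_mean = na_or(sq, "ratio_diff_closest_mean"),
    ratio_diff_closest_sd = na_or(sq, "ratio_diff_closest_sd"),
    dist_diff_insertion_sibling = na_or(sq, "dist_diff_insertion_sibling"),
    insertion_height = na_or(hei),
    nj_tii = na_or(njt),
    pythia_difficulty = pythia_difficulty,
    stringsAsFactors = FALSE
  )
}
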